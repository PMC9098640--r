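test_that("toy fold construction is deterministic with near-ideal CA spacing", {
  a <- make_toy_structure(64, seed = 1)
  b <- make_toy_structure(64, seed = 1)
  expect_identical(a$ca, b$ca)
  expect_identical(a$cb, b$cb)
  expect_identical(a$aa, b$aa)
  d <- sqrt(rowSums(diff(a$ca)^2))
  # ideal helix spacing dominates; short loop junctions deviate a little
  expect_equal(stats::median(d), 3.83, tolerance = 0.02)
  expect_true(all(d > 2.5 & d < 6))
  expect_true(all(abs(sqrt(rowSums((a$cb - a$ca)^2)) - 1.53) < 1e-9))
  # modelable types and glycine present in the sequence
  expect_true(all(c("W", "F", "Y", "H", "L", "G") %in% a$aa))
  expect_error(make_toy_structure(4), "at least 8")
})

test_that("decoy displacement statistics follow the Gaussian model", {
  toy <- make_toy_structure(32)
  # sigma = 0 reproduces the parent exactly
  same <- make_decoys(toy, sigma = 0, count = 2, seed = 1)
  expect_equal(attr(same[[1]], "rmsd_to_parent"), 0, tolerance = 1e-12)
  # pre-superposition RMSD concentrates near sigma * sqrt(3)
  sigma <- 1.2
  dec <- make_decoys(toy, sigma = sigma, count = 150, seed = 2)
  pre <- vapply(dec, attr, numeric(1), "rmsd_pre")
  expect_equal(mean(pre), sigma * sqrt(3), tolerance = 0.05)
  # larger sigma gives stochastically larger realized RMSD
  mean_rmsd <- vapply(c(0.5, 1, 2, 4), function(s) {
    mean(vapply(make_decoys(toy, s, 30, seed = 5), attr, numeric(1),
                "rmsd_to_parent"))
  }, numeric(1))
  expect_true(all(diff(mean_rmsd) > 0))
  # same seed, same decoys
  d1 <- make_decoys(toy, 1, 3, seed = 9)
  d2 <- make_decoys(toy, 1, 3, seed = 9)
  expect_identical(d1[[2]]$ca, d2[[2]]$ca)
})

test_that("simulated tables are reproducible and telescope by construction", {
  dir1 <- tempfile()
  dir2 <- tempfile()
  toy <- make_toy_structure(24)
  spec <- simulation_spec(seed = 4, noise_sd = 0.01)
  simulate_labeling(toy, spec, dir1)
  simulate_labeling(toy, spec, dir2)
  for (f in c("isotopologues.csv", "fragments.csv", "ground_truth.csv")) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))))
  }
  # complete adjacent ladders: emitted events sum to f(last ion) * P
  iso <- read.csv(file.path(dir1, "isotopologues.csv"))
  frg <- read.csv(file.path(dir1, "fragments.csv"))
  g_iso <- split(iso, paste(iso$peptide_id, iso$condition, iso$dose_id,
                            iso$replicate))
  g_frg <- split(frg, paste(frg$peptide_id, frg$condition, frg$dose_id,
                            frg$replicate))
  for (k in names(g_frg)[1:10]) {
    is <- g_iso[[k]][order(g_iso[[k]]$n_ox), ]
    fg <- g_frg[[k]]
    P <- peptide_mean_oxidation(is$area)
    lad <- fragment_ladder(fg$peptide_id[1], "z",
                           c(is$span_start[1], is$span_end[1]),
                           fg$index, fg$oxidized_area, fg$unoxidized_area)
    out <- residue_oxidation_from_ladder(lad, P)
    f_last <- ion_oxidation_fraction(fg$oxidized_area[which.max(fg$index)],
                                     fg$unoxidized_area[which.max(fg$index)])
    expect_equal(sum(out$events), f_last * P, tolerance = 1e-12)
  }
})

test_that("noiseless data invert exactly: slope and lnPF recovered", {
  fx <- fixture_dataset(n = 24, seed = 6)
  cfg <- make_config(fx$paths[c("isotopologues", "fragments", "doses",
                                "sequence", "reactivity", "calibration")],
                     out_dir = file.path(fx$dir, "out"))
  cfg$inputs$models <- fx$paths$structure
  stage_quant(cfg)
  pf <- stage_lnpf(cfg)
  mg <- merge(pf, fx$truth, by = "residue")
  expect_gt(nrow(mg), 3)
  expect_lt(max(abs(mg$slope - mg$slope_true)), 1e-9)
  expect_lt(max(abs(mg$lnpf - mg$lnpf_true)), 1e-9)
})

test_that("with noise, slope confidence intervals usually cover the truth", {
  fx <- fixture_dataset(n = 24, seed = 12, noise_sd = 0.02)
  cfg <- make_config(fx$paths[c("isotopologues", "fragments", "doses",
                                "sequence", "reactivity", "calibration")],
                     out_dir = file.path(fx$dir, "out"))
  cfg$inputs$models <- fx$paths$structure
  stage_quant(cfg)
  pf <- stage_lnpf(cfg)
  mg <- merge(pf, fx$truth, by = "residue")
  covered <- mg$slope_ci_low <= mg$slope_true &
    mg$slope_true <= mg$slope_ci_high
  expect_gte(mean(covered), 0.75)  # nominal 95%, small-sample fixture
})

test_that("a zero-slope calibration cannot be inverted", {
  toy <- make_toy_structure(24)
  expect_error(simulation_spec(calibration = calibration_line(m = 0, b = 1)),
               "non-zero")
})
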