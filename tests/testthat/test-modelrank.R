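test_that("footprinting reward is a negative logistic in the NC deviation", {
  # midpoint at delta = d0
  expect_equal(hrf_residue_score(10, 6), -0.5)
  # perfect agreement is most rewarded
  expect_equal(hrf_residue_score(5, 5), -1 / (1 + exp(-4)), tolerance = 1e-12)
  # strictly increasing (toward 0) in the deviation, symmetric in sign
  d <- seq(0, 12, by = 0.25)
  s <- hrf_residue_score(d, 0)
  expect_true(all(diff(s) > 0))
  expect_true(all(s > -1 & s < 0))
  expect_equal(hrf_residue_score(3, 7), hrf_residue_score(7, 3))
})

test_that("model score sums rewards over predicted residues with weight 9", {
  toy <- make_toy_structure(24)
  nc <- neighbor_counts(toy)
  resl <- toy$resno[toy$aa %in% MODELABLE_RESIDUES]
  pred <- data.frame(residue = resl, nc_pred = unname(nc[as.character(resl)]))
  sc <- score_model(toy, pred, base_score = -100)
  # perfect model: every per-residue deviation is zero
  expect_equal(sc$hrf_sum, length(resl) * (-1 / (1 + exp(-4))),
               tolerance = 1e-12)
  expect_equal(sc$total, -100 + 9.0 * sc$hrf_sum)
  expect_true(all(sc$per_residue$score < 0 & sc$per_residue$score > -1))
  # arithmetic of the total for a known reward sum
  expect_equal(-100 + 9.0 * (-3), -127)
  # empty or non-overlapping predictions are errors
  expect_error(score_model(toy, pred[0, ]), "no neighbor-count predictions")
  expect_error(score_model(toy, data.frame(residue = 999, nc_pred = 3)),
               "no overlap")
  expect_error(score_model(toy, rbind(pred, data.frame(residue = 999,
                                                       nc_pred = 3))),
               "999")
})

test_that("ranking sorts ascending by total with lexicographic tie-break", {
  tab <- data.frame(model_id = c("A", "B", "C"), total = c(-5, -9, -7))
  top <- rank_and_select(tab, 2)
  expect_equal(top$model_id, c("B", "C"))
  expect_equal(top$rank, 1:2)
  ties <- data.frame(model_id = c("m3", "m1", "m2"), total = -4)
  expect_equal(rank_and_select(ties, 3)$model_id, c("m1", "m2", "m3"))
  expect_warning(all3 <- rank_and_select(tab, 10), "exceeds")
  expect_equal(nrow(all3), 3)
  expect_error(rank_and_select(rbind(tab, tab[1, ]), 2), "duplicate")
})

test_that("ranking is invariant to a common shift of base scores", {
  toy <- make_toy_structure(24)
  dec <- make_decoys(toy, sigma = 1.5, count = 6, seed = 2)
  nc <- neighbor_counts(toy)
  resl <- toy$resno[toy$aa %in% MODELABLE_RESIDUES]
  pred <- data.frame(residue = resl, nc_pred = unname(nc[as.character(resl)]))
  models <- c(list(toy), dec)
  ids <- vapply(models, `[[`, character(1), "model_id")
  base0 <- setNames(seq(-10, by = 2, length.out = length(ids)), ids)
  r1 <- score_models(models, pred, base_scores = base0)
  r2 <- score_models(models, pred, base_scores = base0 + 137)
  expect_equal(r1$model_id, r2$model_id)
  expect_equal(r2$total - r1$total, rep(137, length(ids)))
})

test_that("element-wise closer NC deviations never score worse (dominance)", {
  set.seed(9)
  for (i in 1:50) {
    k <- 8
    pred <- runif(k, 0, 12)
    dA <- runif(k, 0, 5)
    dB <- dA + runif(k, 0, 5)          # B deviates at least as much everywhere
    sA <- sum(hrf_residue_score(pred + dA, pred))
    sB <- sum(hrf_residue_score(pred + dB, pred))
    expect_lte(sA, sB)
  }
})

test_that("merging a rescored ensemble keeps one scoring rule for all models", {
  toy <- make_toy_structure(24)
  nc <- neighbor_counts(toy)
  resl <- toy$resno[toy$aa %in% MODELABLE_RESIDUES]
  pred <- data.frame(residue = resl, nc_pred = unname(nc[as.character(resl)]))
  decoys <- make_decoys(toy, sigma = 3, count = 5, seed = 8)
  # an ensemble member identical to the truth dominates at equal base score
  perfect <- toy
  perfect$model_id <- "mover_perfect"
  tab <- merge_rescore(decoys, list(perfect), pred)
  expect_equal(tab$model_id[tab$rank == 1], "mover_perfect")
  expect_equal(unique(tab$set[tab$model_id == "mover_perfect"]), "ensemble")
  # empty ensemble leaves the ranking unchanged
  alone <- score_models(decoys, pred)
  merged <- merge_rescore(decoys, list(), pred)
  expect_equal(merged$model_id, alone$model_id)
  # id collisions across the sets are rejected
  expect_error(merge_rescore(decoys, decoys[1], pred), "duplicate")
})

test_that("Kabsch RMSD is zero for rigid copies and matches bio3d", {
  set.seed(10)
  a <- points_model("a", matrix(rnorm(15, sd = 4), 5, 3))
  expect_equal(as.numeric(kabsch_rmsd_ca(a, a)), 0)
  R <- random_rotation(2)
  moved <- transform_model(a, R, c(4, 5, -6))
  expect_lt(as.numeric(kabsch_rmsd_ca(a, moved)), 1e-9)
  # independent cross-check against bio3d's superposition machinery
  b <- points_model("b", a$ca + matrix(rnorm(15, sd = 1), 5, 3))
  ours <- as.numeric(kabsch_rmsd_ca(a, b))
  xyz_a <- as.numeric(t(a$ca))
  xyz_b <- as.numeric(t(b$ca))
  fitted <- bio3d::fit.xyz(xyz_a, xyz_b, fixed.inds = 1:15,
                           mobile.inds = 1:15)
  theirs <- bio3d::rmsd(xyz_a, fitted)
  # bio3d::rmsd rounds to three decimals, so compare at that resolution
  expect_equal(ours, theirs, tolerance = 1e-3)
  expect_equal(attr(kabsch_rmsd_ca(a, b), "n_matched"), 5L)
  expect_error(kabsch_rmsd_ca(a, points_model("c", matrix(rnorm(9), 3, 3) +
                                                100)), NA)
})

test_that("RMSD requires at least three shared residue positions", {
  a <- points_model("a", matrix(rnorm(15), 5, 3))
  b <- points_model("b", matrix(rnorm(15), 5, 3))
  b$resno <- c(1L, 2L, 10L, 11L, 12L)
  expect_error(kabsch_rmsd_ca(a, b), "fewer than 3")
})

test_that("funnel report summarizes top scorers at fixed half-open bins", {
  tab <- data.frame(model_id = paste0("m", 1:4), total = c(-4, -3, -2, -1),
                    rmsd = c(1, 2, 3, 4))
  fr <- funnel_report(tab, top_n = 4, cutoff = 5, bin = 0.5)
  expect_equal(fr$mean_rmsd, 2.5)
  expect_equal(fr$frac_under_cutoff, 1.0)
  # binning rule: half-open [k*bin, (k+1)*bin)
  tab2 <- data.frame(model_id = c("a", "b"), total = c(-2, -1),
                     rmsd = c(0.1, 0.6))
  h <- funnel_report(tab2, top_n = 2, bin = 0.5)$histogram
  expect_equal(h$count, c(1L, 1L))
  expect_equal(h$bin_lo, c(0, 0.5))
  # boundary lands in the upper bin
  tab3 <- data.frame(model_id = "a", total = -1, rmsd = 0.5)
  h3 <- funnel_report(tab3, top_n = 1, bin = 0.5)$histogram
  expect_equal(h3$count, c(0L, 1L))
})
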