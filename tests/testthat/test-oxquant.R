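test_that("peptide-average oxidation is the intensity-weighted event count", {
  expect_identical(peptide_mean_oxidation(100), 0)
  expect_equal(peptide_mean_oxidation(c(70, 20, 10)), 0.4)
  # invariant under uniform rescaling
  expect_equal(peptide_mean_oxidation(7 * c(70, 20, 10)), 0.4)
  # bounded by the largest state present
  expect_lte(peptide_mean_oxidation(c(1, 5, 94)), 2)
  expect_error(peptide_mean_oxidation(c(0, 0, 0)), "empty signal")
  expect_error(peptide_mean_oxidation(c(-1, 2)), "non-negative")
})

test_that("ion oxidation fraction is the oxidized share of the ion signal", {
  expect_equal(ion_oxidation_fraction(0, 50), 0)
  expect_equal(ion_oxidation_fraction(50, 50), 0.5)
  expect_equal(ion_oxidation_fraction(30, 70), 0.3)
  expect_error(ion_oxidation_fraction(0, 0), "missing ion")
  expect_error(ion_oxidation_fraction(-1, 2), "non-negative")
})

test_that("complete z-ladders distribute events residue by residue and telescope", {
  # fractions 0.2 / 0.5 / 0.9 at z1..z3, P = 1
  lad <- fragment_ladder("pep", "z", span = c(21, 23), index = 1:3,
                         oxidized = c(20, 50, 90),
                         unoxidized = c(80, 50, 10))
  out <- residue_oxidation_from_ladder(lad, 1.0)
  # z1 covers the C-terminal residue (position 23)
  expect_equal(out$pos_start, c(23, 22, 21))
  expect_equal(out$pos_end, c(23, 22, 21))
  expect_equal(out$events, c(0.2, 0.3, 0.4))
  expect_equal(sum(out$events), 0.9 * 1.0)  # telescoping to f(z3)*P
})

test_that("gaps from absent ions become contiguous residue-group records", {
  # z2 missing (zero total intensity -> absent, not fraction zero)
  lad <- fragment_ladder("pep", "z", span = c(1, 3), index = 1:3,
                         oxidized = c(20, 0, 90),
                         unoxidized = c(80, 0, 10))
  expect_equal(attr(lad, "absent"), 2L)
  out <- residue_oxidation_from_ladder(lad, 1.0)
  expect_equal(out$events, c(0.2, 0.7))
  expect_equal(out$n_residues, c(1L, 2L))
  expect_equal(out$pos_start, c(3L, 1L))
  expect_equal(out$pos_end, c(3L, 2L))
})

test_that("zero peptide oxidation yields zero residue events", {
  lad <- fragment_ladder("pep", "z", span = c(1, 3), index = 1:3,
                         oxidized = c(20, 50, 90),
                         unoxidized = c(80, 50, 10))
  expect_equal(residue_oxidation_from_ladder(lad, 0)$events, c(0, 0, 0))
})

test_that("negative fraction differences are flagged, never clamped", {
  lad <- fragment_ladder("pep", "z", span = c(1, 2), index = 1:2,
                         oxidized = c(50, 30), unoxidized = c(50, 70))
  out <- residue_oxidation_from_ladder(lad, 1.0)
  expect_equal(out$events, c(0.5, -0.2))
  expect_equal(out$negative, c(FALSE, TRUE))
})

test_that("c-series and z-series ladders assign the same residue pattern", {
  # per-residue events over a 5-residue peptide at positions 11..15
  e <- c(0.05, 0.20, 0.10, 0.30, 0.15)
  P <- sum(e)
  span <- c(11L, 15L)
  f_c <- cumsum(e) / P            # c ions count from the N-terminus
  f_z <- cumsum(rev(e)) / P       # z ions from the C-terminus
  tot <- 1000
  lad_c <- fragment_ladder("p", "c", span, 1:5, f_c * tot, (1 - f_c) * tot)
  lad_z <- fragment_ladder("p", "z", span, 1:5, f_z * tot, (1 - f_z) * tot)
  out_c <- residue_oxidation_from_ladder(lad_c, P)
  out_z <- residue_oxidation_from_ladder(lad_z, P)
  key <- function(d) d[order(d$pos_start), c("pos_start", "pos_end", "events")]
  expect_equal(key(out_c), key(out_z), ignore_attr = TRUE)
  expect_equal(key(out_c)$events, e)
})

test_that("background subtraction uses control means and flags negatives", {
  lab <- data.frame(pos_start = c(1, 2, 3), pos_end = c(1, 2, 3),
                    dose_id = "d1", replicate = 1,
                    events = c(0.5, 0.2, 0.1))
  ctl <- data.frame(pos_start = rep(c(1, 2, 3), 2), pos_end = rep(c(1, 2, 3), 2),
                    dose_id = "d1", replicate = rep(1:2, each = 3),
                    events = c(0.2, 0.2, 0.2, 0.2, 0.2, 0.2))
  out <- background_subtract(lab, ctl)
  expect_equal(out$events, c(0.3, 0.0, -0.1))
  expect_equal(out$negative, c(FALSE, FALSE, TRUE))
  expect_equal(out$control_mean, rep(0.2, 3))
  # unmatched labeled position -> informative error
  lab2 <- rbind(lab, data.frame(pos_start = 9, pos_end = 9, dose_id = "d1",
                                replicate = 1, events = 0.4))
  expect_error(background_subtract(lab2, ctl), "9-9")
})

test_that("ladder validation rejects malformed input", {
  expect_error(fragment_ladder("p", "z", c(1, 3), c(1, 1), c(1, 1), c(1, 1)),
               "unique")
  expect_error(fragment_ladder("p", "z", c(1, 3), 4, 1, 1), "1..peptide")
  expect_error(fragment_ladder("p", "q", c(1, 3), 1, 1, 1))
})
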