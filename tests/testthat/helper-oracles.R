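# Independent naive re-implementations and small builders used as oracles.
# These deliberately use explicit loops / generic optimizers so they share
# no code path with the package implementations they check.

naive_peptide_mean <- function(intensities) {
  num <- 0
  den <- 0
  for (k in seq_along(intensities)) {
    num <- num + (k - 1) * intensities[k]
    den <- den + intensities[k]
  }
  num / den
}

naive_fraction <- function(ox, unox) ox / (ox + unox)

# loop re-implementation of the ladder-difference rule (z or c series)
naive_ladder_events <- function(series, span, index, ox, unox, P) {
  ord <- order(index)
  index <- index[ord]; ox <- ox[ord]; unox <- unox[ord]
  out <- data.frame(pos_start = integer(), pos_end = integer(),
                    events = numeric())
  f_prev <- 0
  i_prev <- 0
  for (t in seq_along(index)) {
    f_t <- naive_fraction(ox[t], unox[t])
    ev <- (f_t - f_prev) * P
    if (series == "c") {
      lo <- span[1] + i_prev
      hi <- span[1] + index[t] - 1
    } else {
      lo <- span[2] - index[t] + 1
      hi <- span[2] - i_prev
    }
    out <- rbind(out, data.frame(pos_start = lo, pos_end = hi, events = ev))
    f_prev <- f_t
    i_prev <- index[t]
  }
  out
}

# brute-force through-origin slope: golden-section minimization of the sum
# of squared residuals
brute_origin_slope <- function(x, y) {
  obj <- function(s) sum((y - s * x)^2)
  hint <- sum(x * y) / sum(x^2)
  w <- max(1, abs(hint)) * 10
  stats::optimize(obj, interval = c(hint - w, hint + w),
                  tol = .Machine$double.eps^0.5)$minimum
}

# rotation matrix from Euler angles (z-y-x)
euler_rot <- function(a, b, g) {
  Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
               byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(g), -sin(g), 0, sin(g), cos(g)), 3, 3,
               byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# brute-force minimum RMSD over the rotation group, multi-start BFGS on the
# Euler-angle parameterization
brute_min_rmsd <- function(P, Q, n_starts = 24, seed = 42) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  obj <- function(par) {
    R <- euler_rot(par[1], par[2], par[3])
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  set.seed(seed)
  best <- Inf
  for (s in seq_len(n_starts)) {
    start <- stats::runif(3, -pi, pi)
    fit <- try(stats::optim(start, obj, method = "BFGS",
                            control = list(reltol = 1e-14, maxit = 2000)),
               silent = TRUE)
    if (!inherits(fit, "try-error") && fit$value < best) best <- fit$value
  }
  best
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# apply a rigid transform to every coordinate set of a model
transform_model <- function(model, R, t) {
  ap <- function(m) if (is.null(m)) NULL else sweep(m %*% t(R), 2, t, "+")
  structure_model(paste0(model$model_id, "_rt"), resno = model$resno,
                  aa = model$aa, ca = ap(model$ca), cb = ap(model$cb),
                  n = ap(model$n), c = ap(model$c))
}

# minimal model from a CA point cloud (CB offset so the constructor is happy)
points_model <- function(id, pts) {
  pts <- as.matrix(pts)
  structure_model(id, resno = seq_len(nrow(pts)),
                  aa = rep("A", nrow(pts)),
                  ca = pts, cb = pts + matrix(rep(c(0.9, 0.9, 0.9),
                                                  each = nrow(pts)), ncol = 3))
}

# write a run_config list directly (bypassing YAML) for stage-level tests
make_config <- function(paths, out_dir, params = list(), seed = 1L) {
  defaults <- list(weight = 9.0, d0 = 4.0, tau = 1.0,
                   nc = list(dist_midpoint = 9.0, dist_steepness = 1.0,
                             angle_midpoint = pi / 2,
                             angle_steepness = 2 * pi),
                   residue_offset = 0L, top_n = 20L, funnel_top_n = 250L,
                   rmsd_cutoff = 5.0, hist_bin = 0.5,
                   modelable = MODELABLE_RESIDUES, chain = NULL)
  structure(list(inputs = paths, params = utils::modifyList(defaults, params),
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

# standard noiseless fixture dataset shared by several test files
fixture_dataset <- function(n = 48, seed = 11, noise_sd = 0,
                            dir = tempfile("hrpf_fix")) {
  toy <- make_toy_structure(n, seed = seed)
  spec <- simulation_spec(seed = seed, noise_sd = noise_sd)
  paths <- simulate_labeling(toy, spec, dir)
  list(toy = toy, spec = spec, paths = paths, dir = dir,
       truth = utils::read.csv(paths$ground_truth,
                               colClasses = c(aa = "character")))
}
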