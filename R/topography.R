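#' Conical neighbor count parameters
#'
#' The neighbor count weighs each neighbor by a logistic distance term and
#' a logistic angular (cone) term around the side-chain direction:
#' `D(d) = 1/(1 + exp((d - dist_midpoint)/dist_steepness))` and
#' `A(theta) = 1/(1 + exp(angle_steepness * (theta - angle_midpoint)))`.
#' Defaults: 9 Angstrom distance midpoint with unit steepness, 90-degree
#' cone midpoint with steepness `2*pi`. These constants are deliberately
#' configuration, not code: alternate parameterizations of the burial
#' metric can be swapped in without touching the scoring.
#'
#' @param dist_midpoint Distance (Angstrom) at which a neighbor counts 0.5.
#' @param dist_steepness Logistic scale of the distance term (Angstrom).
#' @param angle_midpoint Cone half-angle midpoint (radians).
#' @param angle_steepness Logistic steepness of the angular term (1/radian).
#' @return List of class `nc_params`.
#' @export
nc_params <- function(dist_midpoint = 9.0, dist_steepness = 1.0,
                      angle_midpoint = pi / 2, angle_steepness = 2 * pi) {
  stopifnot(dist_steepness > 0, angle_steepness > 0)
  structure(list(dist_midpoint = dist_midpoint,
                 dist_steepness = dist_steepness,
                 angle_midpoint = angle_midpoint,
                 angle_steepness = angle_steepness),
            class = "nc_params")
}

#' Conical neighbor counts for all residues of a model
#'
#' For residue i, `NC_i = sum_{j != i} D(d_ij) * A(theta_ij)` where `d_ij`
#' is the CB-CB distance and `theta_ij` the angle between residue i's
#' side-chain vector `CB_i - CA_i` and the direction to the neighbor
#' `CB_j - CB_i`. CB anchors (not CA) are used because the hydroxyl radical
#' probes side chains. Each term lies in (0, 1), so `0 <= NC_i <= N - 1`.
#'
#' @param model A [structure_model()].
#' @param params [nc_params()].
#' @return Named numeric vector of neighbor counts (names = residue
#'   positions).
#' @export
neighbor_counts <- function(model, params = nc_params()) {
  stopifnot(inherits(model, "structure_model"),
            inherits(params, "nc_params"))
  B <- model$cb
  A <- model$ca
  nres <- nrow(B)
  nc <- numeric(nres)
  if (nres > 1L) {
    s <- B - A                                  # side-chain vectors
    sn <- sqrt(rowSums(s^2))
    if (any(sn < 1e-8)) stop("zero-length side-chain vector (CB == CA)")
    for (i in seq_len(nres)) {
      v <- sweep(B[-i, , drop = FALSE], 2, B[i, ])  # CB_j - CB_i
      d <- sqrt(rowSums(v^2))
      if (any(d < 1e-8)) stop("coincident CB atoms at residue ",
                              model$resno[i])
      cth <- pmin(1, pmax(-1, (v %*% s[i, ]) / (d * sn[i])))
      theta <- acos(cth)
      D <- 1 / (1 + exp((d - params$dist_midpoint) / params$dist_steepness))
      Ang <- 1 / (1 + exp(params$angle_steepness *
                            (theta - params$angle_midpoint)))
      nc[i] <- sum(D * Ang)
    }
  }
  setNames(nc, model$resno)
}

#' Conical neighbor count of a single residue
#'
#' @param model A [structure_model()].
#' @param i Residue position (must be present in `model$resno`).
#' @param params [nc_params()].
#' @return Non-negative scalar.
#' @export
conical_neighbor_count <- function(model, i, params = nc_params()) {
  if (!i %in% model$resno) stop("residue ", i, " not in model")
  unname(neighbor_counts(model, params)[as.character(i)])
}

#' Fit the lnPF to neighbor-count calibration line
#'
#' Ordinary least squares of observed neighbor count on measured lnPF,
#' `NC = m * lnPF + b`, with the Pearson correlation reported alongside.
#'
#' @param lnpf,nc Numeric vectors (paired), at least two distinct lnPF
#'   values.
#' @return List of class `calibration_line`: `m`, `b`, `r`, `n`.
#' @export
fit_calibration <- function(lnpf, nc) {
  if (length(lnpf) != length(nc)) stop("lnpf and nc must pair up")
  if (length(lnpf) < 2L) stop("need at least 2 pairs")
  if (any(!is.finite(lnpf)) || any(!is.finite(nc))) stop("non-finite input")
  if (diff(range(lnpf)) == 0) {
    stop("degenerate design: all lnPF values identical")
  }
  fit <- lm(nc ~ lnpf)
  co <- coef(fit)
  r <- if (diff(range(nc)) == 0) 0 else cor(lnpf, nc)
  calibration_line(m = unname(co[2]), b = unname(co[1]), r = r,
                   n = length(lnpf))
}

#' Construct a calibration line
#'
#' @param m Slope (neighbor count per lnPF unit), non-zero.
#' @param b Intercept (neighbor count).
#' @param r Optional Pearson correlation of the training pairs.
#' @param n Optional number of training pairs.
#' @return List of class `calibration_line`.
#' @export
calibration_line <- function(m, b, r = NA_real_, n = NA_integer_) {
  if (!is.finite(m) || !is.finite(b)) stop("calibration must be finite")
  if (m == 0) stop("calibration slope must be non-zero")
  structure(list(m = m, b = b, r = r, n = n), class = "calibration_line")
}

#' Predict neighbor count from lnPF
#'
#' Evaluates the calibration line `m * lnPF + b`; physically a neighbor
#' count cannot be negative, so predictions below zero are clamped to zero
#' and flagged.
#'
#' @param lnpf Numeric vector of lnPF values.
#' @param calib A [calibration_line()].
#' @return data.frame with `lnpf`, `nc_pred`, `clamped`.
#' @export
predict_nc <- function(lnpf, calib) {
  stopifnot(inherits(calib, "calibration_line"), all(is.finite(lnpf)))
  raw <- calib$m * lnpf + calib$b
  data.frame(lnpf = lnpf, nc_pred = pmax(0, raw), clamped = raw < 0)
}
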