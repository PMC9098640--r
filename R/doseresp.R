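#' Zero-intercept dose-response regression
#'
#' Fits oxidation events against radical dose (dosimeter response, the
#' magnitude of the adenine absorbance change) by least squares through the
#' origin: `slope = sum(x*y) / sum(x^2)`. The 95% confidence interval uses
#' the t distribution with n-1 degrees of freedom and the through-origin
#' residual variance `sum((y - slope*x)^2) / (n - 1)`.
#'
#' @param x Dosimeter responses (absorbance units), `>= 0`, at least one
#'   positive.
#' @param y Background-corrected oxidation events, same length as `x`.
#' @param conf_level Confidence level, default 0.95.
#' @return List of class `slope_fit`: `slope`, `ci_low`, `ci_high`, `se`,
#'   `n_points`, `conf_level`.
#' @examples
#' fit_dose_response(c(0.1, 0.2, 0.4), c(0.2, 0.4, 0.8))$slope # 2
#' @export
fit_dose_response <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 points")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite input")
  if (any(x < 0)) stop("dosimeter responses must be >= 0")
  sxx <- sum(x^2)
  if (sxx == 0) stop("degenerate design: all dosimeter responses are zero")
  n <- length(x)
  slope <- sum(x * y) / sxx
  rss <- sum((y - slope * x)^2)
  se <- sqrt(rss / (n - 1)) / sqrt(sxx)
  tq <- qt(1 - (1 - conf_level) / 2, df = n - 1)
  structure(list(slope = slope,
                 ci_low = slope - tq * se,
                 ci_high = slope + tq * se,
                 se = se, n_points = n, conf_level = conf_level),
            class = "slope_fit")
}

#' Protection factor from reactivity and dose-response slope
#'
#' Converts a residue's dose-response slope to the natural log of its
#' protection factor, `lnPF = ln(R / slope)`, where `R` is the residue
#' type's normalized relative intrinsic reactivity. The confidence interval
#' maps monotonically: a larger slope means less protection, so
#' `[ln(R/ci_high), ln(R/ci_low)]`. Non-positive slopes give an undefined
#' PF; such records are returned flagged as excluded rather than raising.
#' A slope CI lower bound at or below zero gives an unbounded upper lnPF
#' limit (`Inf`).
#'
#' @param R Intrinsic reactivity (> 0, dimensionless, internally consistent
#'   across residue types).
#' @param fit A `slope_fit` from [fit_dose_response()].
#' @return List of class `protection_record`: `lnpf`, `lnpf_ci_low`,
#'   `lnpf_ci_high`, `slope`, `R`, `excluded`, `excluded_reason`.
#' @export
lnpf <- function(R, fit) {
  stopifnot(inherits(fit, "slope_fit"))
  if (!is.finite(R) || R <= 0) stop("reactivity R must be finite and > 0")
  if (fit$slope <= 0) {
    return(structure(list(lnpf = NA_real_, lnpf_ci_low = NA_real_,
                          lnpf_ci_high = NA_real_, slope = fit$slope, R = R,
                          excluded = TRUE,
                          excluded_reason = "non-positive dose-response slope"),
                     class = "protection_record"))
  }
  structure(list(
    lnpf = log(R / fit$slope),
    lnpf_ci_low = log(R / fit$ci_high),
    lnpf_ci_high = if (fit$ci_low > 0) log(R / fit$ci_low) else Inf,
    slope = fit$slope, R = R,
    excluded = FALSE, excluded_reason = NA_character_),
    class = "protection_record")
}

#' Modelable residue types
#'
#' The residue types whose lnPF values are carried into structure scoring:
#' tryptophan, phenylalanine, tyrosine, histidine and leucine. Other types
#' have too context-dependent an intrinsic reactivity; sulfur-containing
#' residues (Met, Cys) suffer uncontrolled secondary oxidation and are
#' always excluded.
#' @export
MODELABLE_RESIDUES <- c("W", "F", "Y", "H", "L")

#' Filter protection records to the modelable residue set
#'
#' Keeps records whose amino-acid type is in `keep` (default
#' [MODELABLE_RESIDUES]); Met and Cys are removed regardless of `keep`.
#' Every exclusion is recorded with its reason in the `exclusions`
#' attribute of the result.
#'
#' @param records data.frame with at least columns `residue`, `aa`
#'   (one-letter amino-acid codes).
#' @param keep Character vector of one-letter codes to retain.
#' @return Filtered data.frame; attribute `exclusions` is a data.frame of
#'   `residue`, `aa`, `reason`.
#' @export
select_modelable <- function(records, keep = MODELABLE_RESIDUES) {
  stopifnot(is.data.frame(records), all(c("residue", "aa") %in% names(records)))
  keep <- setdiff(toupper(keep), c("M", "C"))
  aa <- toupper(records$aa)
  reason <- ifelse(aa %in% c("M", "C"),
                   "sulfur-containing (secondary oxidation)",
                   ifelse(aa %in% keep, NA_character_,
                          "residue type outside modelable set"))
  drop <- !is.na(reason)
  out <- records[!drop, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("no modelable residues remain after filtering")
  }
  attr(out, "exclusions") <- data.frame(
    residue = records$residue[drop], aa = aa[drop], reason = reason[drop],
    stringsAsFactors = FALSE)
  out
}

#' Read an intrinsic-reactivity table
#'
#' Reads a CSV with columns `aa` (one-letter code) and `R` (normalized
#' relative intrinsic reactivity, > 0) into a named numeric vector. The
#' table must be internally consistent (one normalization across types).
#' The packaged `reactivity_placeholder.csv` carries synthetic
#' literature-magnitude values for demonstration; real analyses must supply
#' measured reactivities.
#'
#' @param path CSV file path.
#' @return Named numeric vector, names are one-letter codes.
#' @export
read_reactivity_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(aa = "character"))
  if (!all(c("aa", "R") %in% names(tab))) {
    stop("reactivity table needs columns 'aa' and 'R': ", path)
  }
  if (any(!is.finite(tab$R)) || any(tab$R <= 0)) {
    stop("reactivities must be finite and > 0")
  }
  if (anyDuplicated(tab$aa)) stop("duplicate amino-acid types in ", path)
  setNames(tab$R, toupper(tab$aa))
}

#' Per-residue protection factors from a dose-response table
#'
#' Convenience wrapper: groups a tidy point table by residue, fits the
#' zero-intercept dose response, and converts to lnPF via the reactivity
#' table.
#'
#' @param points data.frame with columns `residue`, `aa`, `x` (dosimeter
#'   response), `y` (corrected oxidation events).
#' @param reactivity Named numeric vector (one-letter code -> R).
#' @param conf_level Confidence level for slope and lnPF intervals.
#' @return data.frame: `residue`, `aa`, `slope`, `slope_ci_low`,
#'   `slope_ci_high`, `n_points`, `lnpf`, `lnpf_ci_low`, `lnpf_ci_high`,
#'   `excluded`, `excluded_reason`.
#' @export
protection_factors <- function(points, reactivity, conf_level = 0.95) {
  need <- c("residue", "aa", "x", "y")
  stopifnot(is.data.frame(points), all(need %in% names(points)))
  res <- lapply(split(points, points$residue), function(d) {
    aa <- toupper(d$aa[1])
    fit <- fit_dose_response(d$x, d$y, conf_level)
    if (!aa %in% names(reactivity)) {
      stop("no intrinsic reactivity for residue type '", aa, "'")
    }
    pr <- lnpf(reactivity[[aa]], fit)
    data.frame(residue = d$residue[1], aa = aa,
               slope = fit$slope, slope_ci_low = fit$ci_low,
               slope_ci_high = fit$ci_high, n_points = fit$n_points,
               lnpf = pr$lnpf, lnpf_ci_low = pr$lnpf_ci_low,
               lnpf_ci_high = pr$lnpf_ci_high,
               excluded = pr$excluded, excluded_reason = pr$excluded_reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$residue), , drop = FALSE]
  rownames(out) <- NULL
  out
}
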