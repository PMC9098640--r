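#' Per-residue footprinting reward score
#'
#' Rewards agreement between a model's observed neighbor count and the
#' neighbor count predicted from the measured lnPF. With
#' `delta = |observed - predicted|`, the score is
#' `s(delta) = -1 / (1 + exp((delta - d0) / tau))`: strictly negative,
#' most negative (about -1) at perfect agreement, approaching 0 as the
#' deviation grows, with midpoint -0.5 at `delta = d0`. Vectorized.
#'
#' @param nc_observed,nc_predicted Non-negative neighbor counts.
#' @param d0 Deviation (neighbors) at which the reward is half-strength.
#' @param tau Logistic softness of the reward (neighbors).
#' @return Scores in (-1, 0).
#' @export
hrf_residue_score <- function(nc_observed, nc_predicted, d0 = 4.0, tau = 1.0) {
  stopifnot(all(is.finite(nc_observed)), all(is.finite(nc_predicted)),
            all(nc_observed >= 0), all(nc_predicted >= 0), tau > 0)
  delta <- abs(nc_observed - nc_predicted)
  -1 / (1 + exp((delta - d0) / tau))
}

#' Score a model against neighbor-count predictions
#'
#' Computes observed neighbor counts for the model, evaluates the
#' footprinting reward at every residue with a prediction, sums them, and
#' forms `total = base_score + weight * hrf_sum`. The default weight of 9.0
#' balances the footprinting reward against typical all-atom base scores.
#'
#' @param model A [structure_model()].
#' @param predictions data.frame with columns `residue`, `nc_pred` (e.g.
#'   from [predict_nc()] joined to residue positions).
#' @param base_score External model score (dimensionless); 0 when ranking
#'   on footprinting agreement alone.
#' @param weight Multiplier on the summed per-residue reward.
#' @param d0,tau Reward shape, see [hrf_residue_score()].
#' @param params Neighbor-count parameters.
#' @return List of class `hrf_score`: `model_id`, `per_residue` (data.frame
#'   `residue`, `nc_observed`, `nc_pred`, `score`), `hrf_sum`, `base_score`,
#'   `weight`, `total`.
#' @export
score_model <- function(model, predictions, base_score = 0, weight = 9.0,
                        d0 = 4.0, tau = 1.0, params = nc_params()) {
  stopifnot(inherits(model, "structure_model"), is.data.frame(predictions),
            all(c("residue", "nc_pred") %in% names(predictions)))
  if (nrow(predictions) == 0L) stop("no neighbor-count predictions supplied")
  missing <- setdiff(predictions$residue, model$resno)
  if (length(missing) == nrow(predictions)) {
    stop("no overlap between predicted residues and model positions")
  }
  if (length(missing) > 0L) {
    stop("predicted residue(s) absent from model ", model$model_id, ": ",
         paste(missing, collapse = ", "))
  }
  nc <- neighbor_counts(model, params)
  obs <- unname(nc[as.character(predictions$residue)])
  sc <- hrf_residue_score(obs, predictions$nc_pred, d0 = d0, tau = tau)
  hrf_sum <- sum(sc)
  structure(list(
    model_id = model$model_id,
    per_residue = data.frame(residue = predictions$residue,
                             nc_observed = obs,
                             nc_pred = predictions$nc_pred,
                             score = sc),
    hrf_sum = hrf_sum, base_score = base_score, weight = weight,
    total = base_score + weight * hrf_sum),
    class = "hrf_score")
}

#' Rank models by total score and select the best
#'
#' Sorts ascending by total score (more negative is better) with a
#' deterministic lexicographic tie-break on model id, and returns the top
#' `top_n`.
#'
#' @param models data.frame with at least `model_id` and `total`.
#' @param top_n Number of models to keep (default 20); if larger than the
#'   set, the whole set is returned with a warning.
#' @return The selected rows, ordered, with a `rank` column (1 = best).
#' @export
rank_and_select <- function(models, top_n = 20L) {
  stopifnot(is.data.frame(models),
            all(c("model_id", "total") %in% names(models)))
  if (anyDuplicated(models$model_id)) stop("duplicate model ids")
  ord <- order(models$total, models$model_id)
  out <- models[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (top_n > nrow(out)) {
    warning("top_n (", top_n, ") exceeds the number of models (",
            nrow(out), "); returning all")
    top_n <- nrow(out)
  }
  rownames(out) <- NULL
  out[seq_len(top_n), , drop = FALSE]
}

#' Score and rank a set of models
#'
#' Applies [score_model()] across a list of models with their base scores
#' and returns a ranked table (all models, ranked; use [rank_and_select()]
#' on the result for a top-n subset).
#'
#' @param models List of [structure_model()]s.
#' @param predictions data.frame `residue`, `nc_pred`.
#' @param base_scores Named numeric vector (model_id -> base score);
#'   missing ids default to 0.
#' @inheritParams score_model
#' @return data.frame `model_id`, `base_score`, `hrf_sum`, `total`, `rank`.
#' @export
score_models <- function(models, predictions, base_scores = NULL,
                         weight = 9.0, d0 = 4.0, tau = 1.0,
                         params = nc_params()) {
  rows <- lapply(models, function(m) {
    base <- if (!is.null(base_scores) && m$model_id %in% names(base_scores)) {
      base_scores[[m$model_id]]
    } else 0
    s <- score_model(m, predictions, base_score = base, weight = weight,
                     d0 = d0, tau = tau, params = params)
    data.frame(model_id = s$model_id, base_score = s$base_score,
               hrf_sum = s$hrf_sum, total = s$total,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rank_and_select(tab, top_n = nrow(tab))
}

#' Merge an ensemble into a scored model distribution and rescore
#'
#' Rescores the union of a base set (e.g. ab initio models) and an ensemble
#' set (e.g. relaxation "mover" models carrying their own base scores)
#' under one weight/configuration, and ranks the combined distribution.
#'
#' @param base_set,ensemble_set Lists of [structure_model()]s; model ids
#'   must not collide across sets.
#' @param predictions data.frame `residue`, `nc_pred`.
#' @param base_scores Named numeric vector covering both sets.
#' @inheritParams score_model
#' @return Ranked data.frame as from [score_models()], with a `set` column.
#' @export
merge_rescore <- function(base_set, ensemble_set, predictions,
                          base_scores = NULL, weight = 9.0, d0 = 4.0,
                          tau = 1.0, params = nc_params()) {
  ids_base <- vapply(base_set, `[[`, character(1), "model_id")
  ids_ens <- vapply(ensemble_set, `[[`, character(1), "model_id")
  dup <- intersect(ids_base, ids_ens)
  if (length(dup) > 0L) {
    stop("duplicate model ids across sets: ", paste(dup, collapse = ", "))
  }
  tab <- score_models(c(base_set, ensemble_set), predictions,
                      base_scores = base_scores, weight = weight,
                      d0 = d0, tau = tau, params = params)
  tab$set <- ifelse(tab$model_id %in% ids_ens, "ensemble", "base")
  tab
}

#' Kabsch C-alpha RMSD between two models
#'
#' Optimal least-squares rigid superposition (proper rotation enforced via
#' the SVD determinant correction) of the C-alpha atoms at the residue
#' positions the two models share, followed by the root mean square
#' deviation over all matched atoms -- no outlier rejection.
#'
#' @param a,b [structure_model()]s; at least 3 shared residue positions.
#' @return RMSD in Angstrom; attribute `n_matched` gives the number of
#'   atom pairs used.
#' @export
kabsch_rmsd_ca <- function(a, b) {
  stopifnot(inherits(a, "structure_model"), inherits(b, "structure_model"))
  common <- intersect(a$resno, b$resno)
  if (length(common) < 3L) stop("fewer than 3 matched residue positions")
  P <- a$ca[match(common, a$resno), , drop = FALSE]
  Q <- b$ca[match(common, b$resno), , drop = FALSE]
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  s <- svd(crossprod(Pc, Qc))           # covariance P^T Q
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)             # rotates P onto Q
  diffs <- Pc %*% R - Qc
  structure(sqrt(sum(diffs^2) / length(common)), n_matched = length(common))
}

#' Funnel report for a ranked, RMSD-annotated model set
#'
#' Summarizes score-RMSD funnels: mean RMSD of the `top_n` best-scoring
#' models, the fraction of them under an RMSD cutoff, a fixed-bin-width
#' histogram of their RMSDs (half-open bins `[k*bin, (k+1)*bin)`), and the
#' score-vs-RMSD table for plotting.
#'
#' @param models data.frame with `model_id`, `total` and `rmsd` (Angstrom,
#'   versus a reference model).
#' @param top_n Number of top-scoring models summarized (default 250).
#' @param cutoff RMSD threshold (Angstrom, default 5).
#' @param bin Histogram bin width (Angstrom, default 0.5).
#' @return List of class `funnel_report`: `top_n`, `mean_rmsd`,
#'   `frac_under_cutoff`, `cutoff`, `histogram` (data.frame `bin_lo`,
#'   `bin_hi`, `count`), `table` (score vs RMSD, ranked).
#' @export
funnel_report <- function(models, top_n = 250L, cutoff = 5.0, bin = 0.5) {
  stopifnot(is.data.frame(models),
            all(c("model_id", "total", "rmsd") %in% names(models)),
            bin > 0)
  ranked <- rank_and_select(models, top_n = nrow(models))
  top <- head(ranked, min(top_n, nrow(ranked)))
  idx <- floor(top$rmsd / bin)
  counts <- table(factor(idx, levels = seq(0, max(idx))))
  hist <- data.frame(bin_lo = as.numeric(names(counts)) * bin,
                     bin_hi = (as.numeric(names(counts)) + 1) * bin,
                     count = as.integer(counts))
  structure(list(top_n = nrow(top),
                 mean_rmsd = mean(top$rmsd),
                 frac_under_cutoff = mean(top$rmsd < cutoff),
                 cutoff = cutoff,
                 histogram = hist,
                 table = ranked[, c("model_id", "total", "rmsd", "rank")]),
            class = "funnel_report")
}
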