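#' Average oxidation events per peptide
#'
#' Computes the intensity-weighted mean number of oxidation events from the
#' isotopologue (oxidation-state) intensity distribution of a peptide. The
#' k-th element of `intensities` is the integrated area of the k-times
#' oxidized form, starting at k = 0 (unoxidized).
#'
#' @param intensities Numeric vector of non-negative areas, index 1 holding
#'   the unoxidized form.
#' @return Events per peptide (non-negative scalar), invariant under uniform
#'   rescaling of the intensities and bounded by the largest oxidation state
#'   present.
#' @examples
#' peptide_mean_oxidation(c(70, 20, 10)) # 0.4
#' @export
peptide_mean_oxidation <- function(intensities) {
  if (length(intensities) == 0L || !is.numeric(intensities)) {
    stop("intensities must be a non-empty numeric vector")
  }
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("intensities must be finite and non-negative")
  }
  total <- sum(intensities)
  if (total <= 0) {
    stop("empty signal: all isotopologue intensities are zero")
  }
  k <- seq_along(intensities) - 1
  sum(k * intensities) / total
}

#' Oxidation fraction of a sequence ion
#'
#' Fraction of a c- or z-ion's signal carried by its oxidized form:
#' `oxidized / (oxidized + unoxidized)`. Vectorized over paired inputs.
#'
#' @param oxidized,unoxidized Non-negative intensities (areas).
#' @return Fractions in \[0, 1\].
#' @export
ion_oxidation_fraction <- function(oxidized, unoxidized) {
  if (length(oxidized) != length(unoxidized)) {
    stop("oxidized and unoxidized must have equal length")
  }
  bad <- !is.finite(oxidized) | !is.finite(unoxidized) |
    oxidized < 0 | unoxidized < 0
  if (any(bad)) stop("intensities must be finite and non-negative")
  total <- oxidized + unoxidized
  if (any(total == 0)) {
    stop("missing ion: oxidized + unoxidized intensity is zero ",
         "(mark the ion absent instead of passing zeros)")
  }
  oxidized / total
}

#' Construct a fragment-ion ladder
#'
#' A ladder holds the oxidized/unoxidized intensities of a peptide's ETD
#' sequence ions. Ion index i counts residues from the series' terminus:
#' c-ions from the N-terminus, z-ions from the C-terminus. Entries whose
#' total intensity is zero are dropped as absent ions (recorded in the
#' `absent` attribute), never treated as fraction zero.
#'
#' @param peptide_id Identifier string.
#' @param series `"c"` or `"z"`.
#' @param span Length-2 integer vector: 1-based inclusive residue interval
#'   of the peptide in the protein.
#' @param index Integer ion indices, `1 <= index <= peptide length`, unique.
#' @param oxidized,unoxidized Ion intensities, non-negative.
#' @return Object of class `fragment_ladder`.
#' @export
fragment_ladder <- function(peptide_id, series, span, index,
                            oxidized, unoxidized) {
  series <- match.arg(series, c("c", "z"))
  span <- as.integer(span)
  if (length(span) != 2L || span[1] > span[2]) {
    stop("span must be a 1-based inclusive interval c(start, end)")
  }
  len <- span[2] - span[1] + 1L
  index <- as.integer(index)
  if (anyDuplicated(index)) stop("ion indices must be unique")
  if (any(index < 1L) || any(index > len)) {
    stop("ion indices must lie in 1..peptide length (", len, ")")
  }
  if (any(oxidized < 0) || any(unoxidized < 0)) {
    stop("intensities must be non-negative")
  }
  absent <- (oxidized + unoxidized) == 0
  keep <- !absent
  ord <- order(index[keep])
  structure(
    list(peptide_id = peptide_id, series = series, span = span,
         index = index[keep][ord],
         oxidized = oxidized[keep][ord],
         unoxidized = unoxidized[keep][ord]),
    absent = index[absent],
    class = "fragment_ladder")
}

#' Residue-level oxidation events from a fragment ladder
#'
#' Distributes the peptide's average oxidation events `P` onto residues via
#' fractional differences of consecutive available sequence ions. For
#' consecutive available indices i > j the residue group covering positions
#' j+1..i (counted from the series' terminus) receives
#' `(f(ion_i) - f(ion_j)) * P`, with `f(ion_0) = 0`. Adjacent indices yield
#' single-residue records; gaps (absent ions) yield contiguous-group
#' records. The emitted events telescope: their sum equals
#' `f(ion_imax) * P`. Negative differences (measurement noise) are emitted
#' flagged, never clamped.
#'
#' @param ladder A [fragment_ladder()].
#' @param P Events per peptide from [peptide_mean_oxidation()].
#' @return data.frame with columns `peptide_id`, `pos_start`, `pos_end`
#'   (1-based protein positions, `pos_start <= pos_end`), `n_residues`,
#'   `events`, `negative` (logical noise flag).
#' @export
residue_oxidation_from_ladder <- function(ladder, P) {
  stopifnot(inherits(ladder, "fragment_ladder"), is.numeric(P), P >= 0)
  if (length(ladder$index) == 0L) {
    return(data.frame(peptide_id = character(), pos_start = integer(),
                      pos_end = integer(), n_residues = integer(),
                      events = numeric(), negative = logical()))
  }
  f <- ion_oxidation_fraction(ladder$oxidized, ladder$unoxidized)
  idx <- c(0L, ladder$index)
  f <- c(0, f)
  dif <- diff(f) * P
  i_hi <- idx[-1L]
  i_lo <- idx[-length(idx)]
  # ion index -> protein positions, respecting the series' terminus
  if (ladder$series == "c") {
    pos_start <- ladder$span[1] + i_lo
    pos_end <- ladder$span[1] + i_hi - 1L
  } else {
    pos_start <- ladder$span[2] - i_hi + 1L
    pos_end <- ladder$span[2] - i_lo
  }
  data.frame(peptide_id = ladder$peptide_id,
             pos_start = pos_start, pos_end = pos_end,
             n_residues = i_hi - i_lo,
             events = dif,
             negative = dif < 0)
}

#' Subtract background (control) oxidation
#'
#' Corrects labeled per-residue oxidation events by subtracting the mean
#' control (no-irradiation) events of the same residue or residue group at
#' the same dose. Control replicates are averaged per residue group and
#' dose. Negative corrected values are retained and flagged.
#'
#' @param labeled,control data.frames with columns `pos_start`, `pos_end`,
#'   `dose_id`, `replicate`, `events` (as produced by the quantification
#'   stage; `peptide_id` and other columns are carried through from
#'   `labeled`).
#' @return `labeled` with `events` replaced by corrected values, plus
#'   columns `events_raw`, `control_mean` and `negative`.
#' @export
background_subtract <- function(labeled, control) {
  need <- c("pos_start", "pos_end", "dose_id", "events")
  if (!all(need %in% names(labeled)) || !all(need %in% names(control))) {
    stop("labeled and control need columns: ", paste(need, collapse = ", "))
  }
  key <- function(d) paste(d$pos_start, d$pos_end, d$dose_id, sep = "|")
  ctrl_mean <- tapply(control$events, key(control), mean)
  lk <- key(labeled)
  miss <- !(lk %in% names(ctrl_mean))
  if (any(miss)) {
    pos <- unique(paste0(labeled$pos_start[miss], "-", labeled$pos_end[miss],
                         " (dose ", labeled$dose_id[miss], ")"))
    stop("no matching control for labeled residue(s): ",
         paste(pos, collapse = ", "))
  }
  out <- labeled
  out$events_raw <- labeled$events
  out$control_mean <- as.numeric(ctrl_mean[lk])
  out$events <- out$events_raw - out$control_mean
  out$negative <- out$events < 0
  out
}
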