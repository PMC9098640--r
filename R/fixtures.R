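#' Placeholder intrinsic-reactivity table
#'
#' Synthetic, literature-magnitude relative reactivities of the 20 amino
#' acid types toward hydroxyl radical, normalized to tryptophan = 1. These
#' are NOT measured values: they exist so the pipeline and its fixtures can
#' run end to end. Real analyses must supply a measured, internally
#' consistent table (see [read_reactivity_table()]). The same values are
#' shipped as `inst/extdata/reactivity_placeholder.csv`.
#'
#' @return Named numeric vector (one-letter code -> R).
#' @export
default_reactivity <- function() {
  c(C = 1.30, W = 1.00, Y = 0.77, M = 0.65, F = 0.41, H = 0.29, R = 0.26,
    I = 0.14, L = 0.10, V = 0.065, P = 0.050, Q = 0.041, T = 0.0038,
    K = 0.026, E = 0.018, A = 0.006, D = 0.0057, N = 0.0035, S = 0.0024,
    G = 0.0006)
}

# deterministic toy sequence: cycled motif guaranteeing Trp/Phe/Tyr/His/Leu
# and glycine coverage
.toy_sequence <- function(n) {
  motif <- strsplit("LAGWSEFKAYHTLVNDGQFRIW", "")[[1]]
  rep(motif, length.out = n)
}

#' Deterministic compact toy fold
#'
#' Builds an antiparallel helix-bundle C-alpha trace with ideal alpha-helix
#' parameters (2.3 Angstrom radius, 1.5 Angstrom rise, 100 degrees per
#' residue; consecutive CA-CA about 3.8 Angstrom within helices), short
#' connecting loops, two-residue extended terminal tails projecting away
#' from the fold (real chain termini are typically solvent exposed),
#' backbone N and C placed from the local trace geometry and C-beta built
#' via [pseudo_cb()]. The sequence is a fixed cycled motif containing the
#' modelable types (W, F, Y, H, L) and glycine. Buried core residues have
#' visibly higher neighbor counts than the chain termini.
#'
#' @param n Number of residues (>= 8).
#' @param seed Integer seed (the construction is fully deterministic; the
#'   seed is kept for interface symmetry with the stochastic generators).
#' @param model_id Identifier (default "toy").
#' @return A [structure_model()].
#' @export
make_toy_structure <- function(n = 64L, seed = 1L, model_id = "toy") {
  n <- as.integer(n)
  if (n < 8L) stop("toy structure needs at least 8 residues")
  helix_len <- 14L
  loop_len <- 2L
  rise <- 1.5
  radius <- 2.3
  turn <- 100 * pi / 180
  sep <- 8.0
  tail_len <- 2L
  centers <- matrix(c(0, 0, sep, 0, sep, sep, 0, sep, sep / 2, -sep,
                      -sep, sep / 2, 2 * sep, sep / 2), ncol = 2,
                    byrow = TRUE)
  n_core <- n - 2L * tail_len
  ca_core <- matrix(NA_real_, n_core, 3)
  i <- 1L
  k <- 0L  # helix index
  while (i <= n_core) {
    cen <- centers[(k %% nrow(centers)) + 1L, ]
    dirz <- if (k %% 2L == 0L) 1 else -1
    t_max <- min(helix_len, n_core - i + 1L)
    tt <- seq_len(t_max) - 1L
    z0 <- if (dirz > 0) 0 else rise * (helix_len - 1L)
    ang <- dirz * turn * tt + k * pi / 3
    ca_core[i:(i + t_max - 1L), ] <- cbind(cen[1] + radius * cos(ang),
                                           cen[2] + radius * sin(ang),
                                           z0 + dirz * rise * tt)
    i <- i + t_max
    # connecting loop toward the next helix start
    if (i <= n_core) {
      cen2 <- centers[((k + 1L) %% nrow(centers)) + 1L, ]
      dirz2 <- if ((k + 1L) %% 2L == 0L) 1 else -1
      z02 <- if (dirz2 > 0) 0 else rise * (helix_len - 1L)
      nxt <- c(cen2[1] + radius * cos((k + 1L) * pi / 3),
               cen2[2] + radius * sin((k + 1L) * pi / 3), z02)
      prev <- ca_core[i - 1L, ]
      l_max <- min(loop_len, n_core - i + 1L)
      for (l in seq_len(l_max)) {
        frac <- l / (loop_len + 1)
        bow <- 1.5 * sin(pi * frac)  # arc out of the line, avoids collinearity
        ca_core[i, ] <- prev + frac * (nxt - prev) + c(0, 0, bow * dirz)
        i <- i + 1L
      }
      k <- k + 1L
    }
  }
  # extended terminal tails projecting away from the fold centroid, with a
  # slight out-of-line kink so consecutive tangents never become exactly
  # antiparallel
  unit <- function(v) v / sqrt(sum(v^2))
  ctr <- colMeans(ca_core)
  mk_tail <- function(anchor) {
    u <- unit(anchor - ctr)
    p <- unit(c(-u[2], u[1], 0.3))
    out <- matrix(NA_real_, tail_len, 3)
    for (t in seq_len(tail_len)) {
      out[t, ] <- anchor + 3.6 * t * u + 1.0 * sin(t) * p
    }
    out
  }
  n_tail <- mk_tail(ca_core[1L, ])
  c_tail <- mk_tail(ca_core[n_core, ])
  ca <- rbind(n_tail[tail_len:1L, , drop = FALSE], ca_core, c_tail)
  # backbone N and C from the local trace, tilted off-axis so that the
  # N-CA-C frame is never degenerate
  nm <- matrix(NA_real_, n, 3)
  cm <- matrix(NA_real_, n, 3)
  for (j in seq_len(n)) {
    t_prev <- if (j > 1L) unit(ca[j - 1L, ] - ca[j, ]) else
      -unit(ca[j + 1L, ] - ca[j, ])
    t_next <- if (j < n) unit(ca[j + 1L, ] - ca[j, ]) else
      unit(ca[j, ] - ca[j - 1L, ])
    perp <- c(t_prev[2] * t_next[3] - t_prev[3] * t_next[2],
              t_prev[3] * t_next[1] - t_prev[1] * t_next[3],
              t_prev[1] * t_next[2] - t_prev[2] * t_next[1])
    if (sqrt(sum(perp^2)) < 1e-6) {
      perp <- if (abs(t_next[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    }
    perp <- unit(perp)
    nm[j, ] <- ca[j, ] + 1.46 * unit(t_prev + 0.4 * perp)
    cm[j, ] <- ca[j, ] + 1.52 * unit(t_next + 0.4 * perp)
  }
  aa <- .toy_sequence(n)
  cb <- t(vapply(seq_len(n), function(j) pseudo_cb(nm[j, ], ca[j, ], cm[j, ]),
                 numeric(3)))
  structure_model(model_id, resno = seq_len(n), aa = aa,
                  ca = ca, cb = cb, n = nm, c = cm)
}

#' Gaussian perturbation decoys
#'
#' Generates decoys by independent per-atom Gaussian displacement of every
#' coordinate (CA, CB, and backbone N/C when present). Each decoy is
#' labeled with its realized post-superposition C-alpha RMSD to the parent
#' (attribute `rmsd_to_parent`) and the pre-superposition RMSD (attribute
#' `rmsd_pre`, expected about `sigma * sqrt(3)`).
#'
#' @param model Parent [structure_model()].
#' @param sigma Per-coordinate displacement standard deviation (Angstrom).
#' @param count Number of decoys.
#' @param seed Integer seed.
#' @param id_prefix Prefix for decoy model ids.
#' @return List of `structure_model`s.
#' @export
make_decoys <- function(model, sigma, count, seed = 1L,
                        id_prefix = NULL) {
  stopifnot(inherits(model, "structure_model"), sigma >= 0, count >= 0)
  if (is.null(id_prefix)) {
    id_prefix <- sprintf("%s_decoy_s%g", model$model_id, sigma)
  }
  set.seed(seed)
  nres <- length(model$resno)
  lapply(seq_len(count), function(k) {
    jiggle <- function(m) {
      if (is.null(m)) return(NULL)
      m + matrix(rnorm(nres * 3, 0, sigma), nres, 3)
    }
    dec <- structure_model(sprintf("%s_%04d", id_prefix, k),
                           resno = model$resno, aa = model$aa,
                           ca = jiggle(model$ca), cb = jiggle(model$cb),
                           n = jiggle(model$n), c = jiggle(model$c))
    attr(dec, "rmsd_to_parent") <- as.numeric(kabsch_rmsd_ca(model, dec))
    attr(dec, "rmsd_pre") <- sqrt(mean(rowSums((dec$ca - model$ca)^2)))
    dec
  })
}

#' Simulation specification for synthetic labeling data
#'
#' Describes the synthetic multi-dose labeling experiment: dosimeter
#' responses per dose, replicate count, additive Gaussian noise on
#' oxidation events, constant per-residue background oxidation, the
#' lnPF-to-neighbor-count calibration used to derive ground truth from the
#' structure, the reactivity table, peptide layout, and seed.
#'
#' Defaults emulate the study conditions: four peroxide doses measured by
#' adenine dosimetry, triplicate labeled and triplicate no-irradiation
#' control samples per dose.
#'
#' @param doses Named numeric vector, dose id -> dosimeter response
#'   (magnitude of the adenine absorbance change, AU).
#' @param replicates Replicates per dose and condition.
#' @param noise_sd Standard deviation of additive Gaussian noise on
#'   per-residue oxidation events (0 = exact data).
#' @param background Constant background oxidation events per residue
#'   (laser-off control level).
#' @param calibration [calibration_line()] relating lnPF to neighbor count.
#' @param reactivity Named numeric reactivity vector.
#' @param peptide_lengths Integer cycle of peptide lengths used to partition
#'   the sequence.
#' @param total_area Total isotopologue area per peptide (arbitrary units).
#' @param params [nc_params()] used for the ground-truth neighbor counts.
#' @param seed Integer seed.
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(doses = c(d10 = 0.05, d25 = 0.12, d50 = 0.25,
                                      d100 = 0.50),
                            replicates = 3L, noise_sd = 0,
                            background = 0.02,
                            calibration = calibration_line(m = 3, b = 2),
                            reactivity = default_reactivity(),
                            peptide_lengths = c(10L, 9L, 11L, 8L, 12L),
                            total_area = 1e6,
                            params = nc_params(),
                            seed = 1L) {
  stopifnot(length(doses) >= 2L, all(doses >= 0), replicates >= 1L,
            noise_sd >= 0, background >= 0,
            inherits(calibration, "calibration_line"),
            inherits(params, "nc_params"))
  if (is.null(names(doses)) || any(names(doses) == "")) {
    stop("doses must be a named vector (dose_id -> dosimeter response)")
  }
  structure(list(doses = doses, replicates = as.integer(replicates),
                 noise_sd = noise_sd, background = background,
                 calibration = calibration, reactivity = reactivity,
                 peptide_lengths = as.integer(peptide_lengths),
                 total_area = total_area, params = params,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# partition 1..n into consecutive peptides with cycled lengths
.peptide_layout <- function(n, lengths_cycle) {
  spans <- list()
  start <- 1L
  k <- 1L
  while (start <= n) {
    len <- lengths_cycle[((k - 1L) %% length(lengths_cycle)) + 1L]
    end <- min(start + len - 1L, n)
    spans[[k]] <- c(start, end)
    start <- end + 1L
    k <- k + 1L
  }
  spans
}

#' Simulate a multi-dose labeling dataset from a structure
#'
#' Inverts the analysis chain to make self-consistent synthetic data with
#' known ground truth: the structure's conical neighbor counts define true
#' lnPF through the inverse calibration, true dose-response slopes follow
#' from the reactivity table (`slope = R * exp(-lnPF)`), per-residue
#' oxidation events are `background + slope * x` plus optional noise
#' (truncated at zero to keep intensities physical), and peptide
#' isotopologue tables plus complete z-ion fragment ladders are constructed
#' so the quantification stage recovers the events exactly. With zero
#' noise, running the full pipeline returns the ground-truth lnPF to
#' numerical precision.
#'
#' @param model A [structure_model()] whose residues include modelable
#'   types.
#' @param spec A [simulation_spec()].
#' @param out_dir Directory for the CSV/PDB outputs (created if needed).
#' @return Invisible list of output paths (`isotopologues`, `fragments`,
#'   `doses`, `sequence`, `reactivity`, `calibration`, `ground_truth`,
#'   `structure`) plus the ground-truth data.frame (`truth`).
#' @export
simulate_labeling <- function(model, spec, out_dir) {
  stopifnot(inherits(model, "structure_model"),
            inherits(spec, "simulation_spec"))
  if (!any(model$aa %in% MODELABLE_RESIDUES)) {
    stop("model contains no modelable residue types")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(spec$seed)
  nres <- length(model$resno)
  nc <- neighbor_counts(model, spec$params)
  m <- spec$calibration$m
  b <- spec$calibration$b
  lnpf_true <- (nc - b) / m
  missing_r <- setdiff(model$aa, names(spec$reactivity))
  if (length(missing_r) > 0L) {
    stop("reactivity table lacks type(s): ", paste(missing_r, collapse = ", "))
  }
  R <- unname(spec$reactivity[model$aa])
  slope_true <- R * exp(-lnpf_true)
  spans <- .peptide_layout(nres, spec$peptide_lengths)

  iso <- list()
  frg <- list()
  for (s in seq_along(spans)) {
    span <- spans[[s]]
    pep_id <- sprintf("pep%02d", s)
    pos <- span[1]:span[2]
    len <- length(pos)
    for (dose_id in names(spec$doses)) {
      x <- spec$doses[[dose_id]]
      for (cond in c("labeled", "control")) {
        for (rep_i in seq_len(spec$replicates)) {
          mu <- spec$background +
            if (cond == "labeled") slope_true[pos] * x else numeric(len)
          e <- mu + if (spec$noise_sd > 0) {
            rnorm(len, 0, spec$noise_sd)
          } else 0
          e <- pmax(e, 0)
          P <- sum(e)
          K <- max(2L, ceiling(P - 1e-12))
          p <- P / K
          areas <- spec$total_area * dbinom(0:K, K, p)
          iso[[length(iso) + 1L]] <- data.frame(
            peptide_id = pep_id, span_start = span[1], span_end = span[2],
            condition = cond, dose_id = dose_id, replicate = rep_i,
            n_ox = 0:K, area = areas)
          # complete z-ion ladder: f(z_i) = cumulative C-terminal events / P
          f <- if (P > 0) cumsum(rev(e)) / P else rep(0, len)
          f <- pmin(f, 1)
          T_i <- spec$total_area / 2
          frg[[length(frg) + 1L]] <- data.frame(
            peptide_id = pep_id, series = "z", index = seq_len(len),
            condition = cond, dose_id = dose_id, replicate = rep_i,
            oxidized_area = f * T_i, unoxidized_area = (1 - f) * T_i)
        }
      }
    }
  }
  iso <- do.call(rbind, iso)
  frg <- do.call(rbind, frg)

  truth <- data.frame(residue = model$resno, aa = model$aa,
                      nc_true = unname(nc), lnpf_true = unname(lnpf_true),
                      slope_true = slope_true)
  paths <- list(
    isotopologues = file.path(out_dir, "isotopologues.csv"),
    fragments = file.path(out_dir, "fragments.csv"),
    doses = file.path(out_dir, "doses.csv"),
    sequence = file.path(out_dir, "sequence.csv"),
    reactivity = file.path(out_dir, "reactivity.csv"),
    calibration = file.path(out_dir, "calibration.csv"),
    ground_truth = file.path(out_dir, "ground_truth.csv"),
    structure = file.path(out_dir, "structure.pdb"))
  write.csv(iso, paths$isotopologues, row.names = FALSE)
  write.csv(frg, paths$fragments, row.names = FALSE)
  write.csv(data.frame(dose_id = names(spec$doses),
                       x = unname(spec$doses)),
            paths$doses, row.names = FALSE)
  write.csv(data.frame(residue = model$resno, aa = model$aa),
            paths$sequence, row.names = FALSE)
  write.csv(data.frame(aa = names(spec$reactivity),
                       R = unname(spec$reactivity)),
            paths$reactivity, row.names = FALSE)
  write.csv(data.frame(m = m, b = b), paths$calibration, row.names = FALSE)
  write.csv(truth, paths$ground_truth, row.names = FALSE)
  write_structure_models(model, paths$structure)
  invisible(c(paths, list(truth = truth)))
}
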