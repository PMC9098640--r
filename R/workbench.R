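#' Read and validate a pipeline run configuration
#'
#' Loads a YAML configuration, checks it against the known schema (unknown
#' keys are rejected), fills defaults, and verifies that required input
#' files exist. Relative input paths are resolved against the config file's
#' directory.
#'
#' @param path YAML file.
#' @param overrides Optional named list merged over the file contents
#'   (e.g. from command-line flags); same schema.
#' @return List of class `run_config` with elements `inputs`, `params`,
#'   `seed`, `out_dir`.
#' @export
read_run_config <- function(path, overrides = NULL) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(overrides)) cfg <- utils::modifyList(cfg, overrides)
  top_known <- c("inputs", "params", "seed", "out_dir")
  unknown <- setdiff(names(cfg), top_known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  in_known <- c("isotopologues", "fragments", "doses", "sequence",
                "reactivity", "calibration", "models", "ensemble",
                "base_scores", "reference")
  unknown <- setdiff(names(cfg$inputs), in_known)
  if (length(unknown) > 0L) {
    stop("unknown inputs key(s): ", paste(unknown, collapse = ", "))
  }
  par_known <- c("weight", "d0", "tau", "nc", "residue_offset", "top_n",
                 "funnel_top_n", "rmsd_cutoff", "hist_bin", "modelable",
                 "chain")
  unknown <- setdiff(names(cfg$params), par_known)
  if (length(unknown) > 0L) {
    stop("unknown params key(s): ", paste(unknown, collapse = ", "))
  }
  defaults <- list(weight = 9.0, d0 = 4.0, tau = 1.0,
                   nc = list(dist_midpoint = 9.0, dist_steepness = 1.0,
                             angle_midpoint = pi / 2,
                             angle_steepness = 2 * pi),
                   residue_offset = 0L, top_n = 20L, funnel_top_n = 250L,
                   rmsd_cutoff = 5.0, hist_bin = 0.5,
                   modelable = MODELABLE_RESIDUES, chain = NULL)
  params <- utils::modifyList(defaults, if (is.null(cfg$params)) list()
                              else cfg$params)
  base_dir <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base_dir, p)
    p
  }
  inputs <- cfg$inputs
  file_keys <- setdiff(in_known, "calibration")
  for (k in file_keys) inputs[[k]] <- resolve(inputs[[k]])
  if (is.character(inputs$calibration)) {
    inputs$calibration <- resolve(inputs$calibration)
  }
  required <- c("isotopologues", "fragments", "doses", "sequence",
                "reactivity", "models")
  for (k in required) {
    if (is.null(inputs[[k]])) stop("config error: inputs$", k, " is required")
    if (!file.exists(inputs[[k]])) {
      stop("config error: inputs$", k, " not found: ", inputs[[k]])
    }
  }
  for (k in c("ensemble", "base_scores", "reference")) {
    if (!is.null(inputs[[k]]) && !file.exists(inputs[[k]])) {
      stop("config error: inputs$", k, " not found: ", inputs[[k]])
    }
  }
  if (is.null(inputs$calibration)) {
    stop("config error: inputs$calibration is required ",
         "(a CSV path or a list with m and b)")
  }
  out_dir <- cfg$out_dir
  if (is.null(out_dir)) out_dir <- file.path(base_dir, "hrpf_out")
  structure(list(inputs = inputs, params = params,
                 seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
                 out_dir = out_dir),
            class = "run_config")
}

.cfg_nc_params <- function(config) {
  do.call(nc_params, config$params$nc)
}

.cfg_calibration <- function(config) {
  cal <- config$inputs$calibration
  if (is.character(cal)) {
    tab <- read.csv(cal)
    calibration_line(m = tab$m[1], b = tab$b[1])
  } else {
    calibration_line(m = cal$m, b = cal$b)
  }
}

.read_models <- function(path, chain = NULL, prefix = NULL) {
  models <- read_structure_models(path, chain = chain)
  if (!is.null(prefix)) {
    for (i in seq_along(models)) {
      models[[i]]$model_id <- sprintf("%s_%d", prefix, i)
    }
  }
  models
}

#' Quantification stage: intensity tables to corrected residue oxidation
#'
#' Computes events per peptide (isotopologue table), distributes them onto
#' residues through the fragment ladders, and subtracts the mean control
#' background per residue group and dose. Writes
#' `residue_oxidation.csv` under the configured output directory.
#'
#' @param config A [read_run_config()] result.
#' @return The corrected per-residue oxidation data.frame, invisibly
#'   written to disk.
#' @export
stage_quant <- function(config) {
  iso <- read.csv(config$inputs$isotopologues)
  frg <- read.csv(config$inputs$fragments)
  need_iso <- c("peptide_id", "span_start", "span_end", "condition",
                "dose_id", "replicate", "n_ox", "area")
  need_frg <- c("peptide_id", "series", "index", "condition", "dose_id",
                "replicate", "oxidized_area", "unoxidized_area")
  if (!all(need_iso %in% names(iso))) {
    stop("isotopologue table needs columns: ",
         paste(need_iso, collapse = ", "))
  }
  if (!all(need_frg %in% names(frg))) {
    stop("fragment table needs columns: ", paste(need_frg, collapse = ", "))
  }
  key <- function(d) paste(d$peptide_id, d$condition, d$dose_id,
                           d$replicate, sep = "|")
  iso_split <- split(iso, key(iso))
  frg_split <- split(frg, key(frg))
  rows <- lapply(names(frg_split), function(k) {
    fg <- frg_split[[k]]
    is <- iso_split[[k]]
    if (is.null(is)) {
      stop("fragment rows without isotopologue rows for group ", k)
    }
    is <- is[order(is$n_ox), , drop = FALSE]
    P <- peptide_mean_oxidation(is$area)
    lad <- fragment_ladder(fg$peptide_id[1], fg$series[1],
                           span = c(is$span_start[1], is$span_end[1]),
                           index = fg$index, oxidized = fg$oxidized_area,
                           unoxidized = fg$unoxidized_area)
    res <- residue_oxidation_from_ladder(lad, P)
    if (nrow(res) == 0L) return(NULL)
    res$condition <- fg$condition[1]
    res$dose_id <- fg$dose_id[1]
    res$replicate <- fg$replicate[1]
    res
  })
  events <- do.call(rbind, rows)
  corrected <- background_subtract(events[events$condition == "labeled", ],
                                   events[events$condition == "control", ])
  corrected$condition <- NULL
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  write.csv(corrected, file.path(config$out_dir, "residue_oxidation.csv"),
            row.names = FALSE)
  invisible(corrected)
}

# attach amino-acid types and reduce group records: groups spanning more
# than one residue are dropped unless exactly one member is modelable,
# in which case the group's events are attributed to that residue
.per_residue_points <- function(corrected, seq_tab, doses, modelable) {
  aa_of <- setNames(toupper(seq_tab$aa), seq_tab$residue)
  keep_types <- setdiff(toupper(modelable), c("M", "C"))
  dropped <- list()
  rows <- lapply(seq_len(nrow(corrected)), function(i) {
    r <- corrected[i, ]
    pos <- r$pos_start:r$pos_end
    if (length(pos) == 1L) {
      return(data.frame(residue = pos, aa = aa_of[[as.character(pos)]],
                        dose_id = r$dose_id, replicate = r$replicate,
                        events = r$events))
    }
    mod <- pos[aa_of[as.character(pos)] %in% keep_types]
    if (length(mod) == 1L) {
      return(data.frame(residue = mod, aa = aa_of[[as.character(mod)]],
                        dose_id = r$dose_id, replicate = r$replicate,
                        events = r$events))
    }
    dropped[[length(dropped) + 1L]] <<- data.frame(
      pos_start = r$pos_start, pos_end = r$pos_end,
      reason = if (length(mod) == 0L) {
        "group without modelable residue"
      } else "group with multiple modelable residues")
    NULL
  })
  pts <- do.call(rbind, rows)
  x_of <- setNames(doses$x, doses$dose_id)
  pts$x <- unname(x_of[as.character(pts$dose_id)])
  pts$y <- pts$events
  attr(pts, "dropped_groups") <- if (length(dropped) > 0L) {
    do.call(rbind, dropped)
  } else NULL
  pts
}

#' Protection-factor stage: dose-response fits and lnPF
#'
#' Joins corrected residue oxidation with the dosimeter responses, fits the
#' zero-intercept dose response per residue, converts to lnPF via the
#' reactivity table, and filters to the modelable residue set. Writes
#' `protection_factors.csv` (all fitted residues, with modelable flag) and
#' `exclusions.csv` (residues removed, with reasons).
#'
#' @param config A [read_run_config()] result.
#' @return data.frame of modelable protection records.
#' @export
stage_lnpf <- function(config) {
  corrected <- read.csv(file.path(config$out_dir, "residue_oxidation.csv"))
  seq_tab <- read.csv(config$inputs$sequence,
                      colClasses = c(aa = "character"))
  doses <- read.csv(config$inputs$doses)
  reactivity <- read_reactivity_table(config$inputs$reactivity)
  pts <- .per_residue_points(corrected, seq_tab, doses,
                             config$params$modelable)
  pf <- protection_factors(pts, reactivity)
  sel <- select_modelable(pf[!pf$excluded, , drop = FALSE],
                          keep = config$params$modelable)
  pf$modelable <- pf$residue %in% sel$residue
  write.csv(pf, file.path(config$out_dir, "protection_factors.csv"),
            row.names = FALSE)
  excl <- attr(sel, "exclusions")
  slope_excl <- pf[pf$excluded, c("residue", "aa", "excluded_reason")]
  names(slope_excl)[3] <- "reason"
  excl <- rbind(excl, slope_excl)
  write.csv(excl, file.path(config$out_dir, "exclusions.csv"),
            row.names = FALSE)
  invisible(sel)
}

#' Topography stage: neighbor counts and predictions
#'
#' Computes conical neighbor-count profiles for every candidate model,
#' converts measured lnPF to predicted neighbor counts through the
#' calibration line (applying the configured residue-number offset so
#' labeling positions match structure numbering), and, when a reference
#' structure is supplied, reports the lnPF versus observed-neighbor-count
#' correlation. Writes `neighbor_counts.csv`, `nc_predictions.csv` and
#' (optionally) `nc_correlation.csv`.
#'
#' @param config A [read_run_config()] result.
#' @return The predictions data.frame (`residue`, `lnpf`, `nc_pred`,
#'   `clamped`), residue numbers already in structure numbering.
#' @export
stage_nc <- function(config) {
  pf <- read.csv(file.path(config$out_dir, "protection_factors.csv"))
  pf <- pf[pf$modelable, , drop = FALSE]
  calib <- .cfg_calibration(config)
  params <- .cfg_nc_params(config)
  models <- .read_models(config$inputs$models, chain = config$params$chain)
  prof <- do.call(rbind, lapply(models, function(m) {
    nc <- neighbor_counts(m, params)
    data.frame(model_id = m$model_id, residue = as.integer(names(nc)),
               nc = unname(nc))
  }))
  write.csv(prof, file.path(config$out_dir, "neighbor_counts.csv"),
            row.names = FALSE)
  pred <- predict_nc(pf$lnpf, calib)
  pred <- data.frame(residue = pf$residue + config$params$residue_offset,
                     lnpf = pred$lnpf, nc_pred = pred$nc_pred,
                     clamped = pred$clamped)
  write.csv(pred, file.path(config$out_dir, "nc_predictions.csv"),
            row.names = FALSE)
  if (!is.null(config$inputs$reference)) {
    ref <- read_structure_models(config$inputs$reference,
                                 chain = config$params$chain)[[1]]
    nc_ref <- neighbor_counts(ref, params)
    ok <- as.character(pred$residue) %in% names(nc_ref)
    if (sum(ok) >= 2L && diff(range(pred$lnpf[ok])) > 0) {
      cl <- fit_calibration(pred$lnpf[ok],
                            unname(nc_ref[as.character(pred$residue[ok])]))
      write.csv(data.frame(m = cl$m, b = cl$b, pearson_r = cl$r, n = cl$n),
                file.path(config$out_dir, "nc_correlation.csv"),
                row.names = FALSE)
    }
  }
  invisible(pred)
}

#' Scoring stage: footprinting reward and totals
#'
#' Scores every candidate model (and optional ensemble models) against the
#' neighbor-count predictions, combining with external base scores under
#' the configured weight. Writes `scores.csv`.
#'
#' @param config A [read_run_config()] result.
#' @return Ranked scores data.frame.
#' @export
stage_score <- function(config) {
  pred <- read.csv(file.path(config$out_dir, "nc_predictions.csv"))
  params <- .cfg_nc_params(config)
  models <- .read_models(config$inputs$models, chain = config$params$chain)
  base_scores <- NULL
  if (!is.null(config$inputs$base_scores)) {
    bs <- read.csv(config$inputs$base_scores)
    base_scores <- setNames(bs$score, bs$model_id)
  }
  if (!is.null(config$inputs$ensemble)) {
    ens <- .read_models(config$inputs$ensemble, chain = config$params$chain)
    tab <- merge_rescore(models, ens, pred, base_scores = base_scores,
                         weight = config$params$weight,
                         d0 = config$params$d0, tau = config$params$tau,
                         params = params)
  } else {
    tab <- score_models(models, pred, base_scores = base_scores,
                        weight = config$params$weight,
                        d0 = config$params$d0, tau = config$params$tau,
                        params = params)
    tab$set <- "base"
  }
  write.csv(tab, file.path(config$out_dir, "scores.csv"), row.names = FALSE)
  invisible(tab)
}

#' Ranking stage: top-n selection
#'
#' Selects the configured number of top-scoring models from `scores.csv`
#' and writes `ranked.csv`.
#'
#' @param config A [read_run_config()] result.
#' @return The selected subset.
#' @export
stage_rank <- function(config) {
  tab <- read.csv(file.path(config$out_dir, "scores.csv"))
  top <- rank_and_select(tab[, setdiff(names(tab), "rank")],
                         top_n = min(config$params$top_n, nrow(tab)))
  write.csv(top, file.path(config$out_dir, "ranked.csv"), row.names = FALSE)
  invisible(top)
}

#' Report stage: RMSD funnel versus a reference structure
#'
#' Computes Kabsch C-alpha RMSD of every scored model to the reference
#' structure and writes the funnel summary (`funnel_summary.csv`),
#' histogram (`funnel_hist.csv`) and the full score-vs-RMSD table
#' (`funnel_table.csv`). Skipped (with a message) when no reference is
#' configured.
#'
#' @param config A [read_run_config()] result.
#' @return The [funnel_report()] object, or `NULL` when skipped.
#' @export
stage_report <- function(config) {
  if (is.null(config$inputs$reference)) {
    message("report stage skipped: no reference structure configured")
    return(invisible(NULL))
  }
  tab <- read.csv(file.path(config$out_dir, "scores.csv"))
  ref <- read_structure_models(config$inputs$reference,
                               chain = config$params$chain)[[1]]
  all_models <- .read_models(config$inputs$models,
                             chain = config$params$chain)
  if (!is.null(config$inputs$ensemble)) {
    all_models <- c(all_models,
                    .read_models(config$inputs$ensemble,
                                 chain = config$params$chain))
  }
  ids <- vapply(all_models, `[[`, character(1), "model_id")
  rmsd <- vapply(all_models, function(m) as.numeric(kabsch_rmsd_ca(ref, m)),
                 numeric(1))
  tab$rmsd <- rmsd[match(tab$model_id, ids)]
  fr <- funnel_report(tab, top_n = config$params$funnel_top_n,
                       cutoff = config$params$rmsd_cutoff,
                       bin = config$params$hist_bin)
  write.csv(data.frame(top_n = fr$top_n, mean_rmsd = fr$mean_rmsd,
                       frac_under_cutoff = fr$frac_under_cutoff,
                       cutoff = fr$cutoff),
            file.path(config$out_dir, "funnel_summary.csv"),
            row.names = FALSE)
  write.csv(fr$histogram, file.path(config$out_dir, "funnel_hist.csv"),
            row.names = FALSE)
  write.csv(fr$table, file.path(config$out_dir, "funnel_table.csv"),
            row.names = FALSE)
  invisible(rep)
}

#' Run the full pipeline
#'
#' Executes quantification, protection-factor, topography, scoring, ranking
#' and report stages in order, aborting with the failing stage named if one
#' errors (partial outputs are preserved). A provenance manifest
#' (`manifest.json`: resolved configuration, input file hashes, package
#' version, output file hashes) is written last; it contains no timestamps,
#' so a rerun from identical inputs reproduces byte-identical outputs.
#'
#' @param config A [read_run_config()] result (or a path to a YAML config).
#' @return Invisible list with each stage's result and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  stages <- list(quant = stage_quant, lnpf = stage_lnpf, nc = stage_nc,
                 score = stage_score, rank = stage_rank,
                 report = stage_report)
  results <- list()
  for (nm in names(stages)) {
    results[[nm]] <- tryCatch(stages[[nm]](config), error = function(e) {
      stop("pipeline stage '", nm, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message("stage ", nm, ": done")
  }
  in_files <- Filter(function(p) is.character(p) && file.exists(p),
                     config$inputs)
  out_files <- list.files(config$out_dir, pattern = "\\.csv$",
                          full.names = TRUE)
  manifest <- list(
    package = "hrpfscore",
    version = as.character(utils::packageVersion("hrpfscore")),
    config = list(inputs = config$inputs, params = config$params,
                  seed = config$seed, out_dir = config$out_dir),
    input_md5 = as.list(tools::md5sum(unlist(in_files))),
    output_md5 = as.list(tools::md5sum(sort(out_files))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(results, list(manifest = manifest)))
}
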