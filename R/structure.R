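#' Construct a structure model
#'
#' A light container for the per-residue coordinates the scoring needs:
#' C-alpha and C-beta positions (a pseudo-C-beta is constructed from the
#' backbone for glycine or wherever C-beta is missing), plus optional
#' backbone N and C.
#'
#' @param model_id Identifier string.
#' @param resno Integer vector of unique, strictly increasing 1-based
#'   sequence positions.
#' @param aa One-letter amino-acid codes, same length as `resno`.
#' @param ca,cb,n,c Numeric N x 3 coordinate matrices (Angstrom). `cb` rows
#'   may be `NA` where C-beta is absent; they are filled from `n`/`ca`/`c`
#'   via [pseudo_cb()].
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(model_id, resno, aa, ca, cb = NULL,
                            n = NULL, c = NULL) {
  resno <- as.integer(resno)
  nres <- length(resno)
  if (nres < 1L) stop("empty model")
  if (is.unsorted(resno, strictly = TRUE)) {
    stop("residue positions must be unique and strictly increasing")
  }
  if (length(aa) != nres) stop("aa length mismatch")
  as_mat <- function(m, what, required = TRUE) {
    if (is.null(m)) {
      if (required) stop(what, " coordinates required")
      return(NULL)
    }
    m <- as.matrix(m)
    if (!all(dim(m) == c(nres, 3L))) stop(what, " must be an N x 3 matrix")
    m
  }
  ca <- as_mat(ca, "CA")
  if (any(!is.finite(ca))) stop("CA coordinates must be finite")
  n <- as_mat(n, "N", required = FALSE)
  c <- as_mat(c, "C", required = FALSE)
  if (is.null(cb)) cb <- matrix(NA_real_, nres, 3L) else cb <- as_mat(cb, "CB")
  missing_cb <- !stats::complete.cases(cb)
  if (any(missing_cb)) {
    if (is.null(n) || is.null(c)) {
      stop("missing CB at residue(s) ",
           paste(resno[missing_cb], collapse = ", "),
           " and no backbone N/C to build a pseudo-CB from")
    }
    for (i in which(missing_cb)) {
      cb[i, ] <- pseudo_cb(n[i, ], ca[i, ], c[i, ])
    }
  }
  if (any(!is.finite(cb))) stop("CB coordinates must be finite")
  structure(list(model_id = model_id, resno = resno,
                 aa = toupper(aa), ca = ca, cb = cb, n = n, c = c),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model", x$model_id, "-", length(x$resno), "residues,",
      "positions", x$resno[1], "..", x$resno[length(x$resno)], "\n")
  invisible(x)
}

#' Pseudo-C-beta from backbone geometry
#'
#' Places an idealized side-chain C-beta 1.53 Angstrom from C-alpha along
#' the tetrahedral direction implied by the local N-CA-C frame. Used for
#' glycine and residues with missing side chains. Deterministic and
#' equivariant under rigid transforms.
#'
#' @param n,ca,c Length-3 backbone coordinates (Angstrom).
#' @return Length-3 C-beta coordinate.
#' @export
pseudo_cb <- function(n, ca, c) {
  stopifnot(length(n) == 3L, length(ca) == 3L, length(c) == 3L,
            all(is.finite(c(n, ca, c))))
  unit <- function(v) {
    nv <- sqrt(sum(v^2))
    if (nv < 1e-8) stop("degenerate geometry: coincident backbone atoms")
    v / nv
  }
  b <- unit(ca - n)
  g <- unit(c - ca)
  a <- c(b[2] * g[3] - b[3] * g[2],
         b[3] * g[1] - b[1] * g[3],
         b[1] * g[2] - b[2] * g[1])
  if (sqrt(sum(a^2)) < 1e-6) {
    stop("degenerate geometry: collinear backbone atoms")
  }
  # idealized tetrahedral direction in the local (normal, b, g) frame
  dir <- -0.58273431 * unit(a) + 0.56802827 * b - 0.54067466 * g
  ca + 1.53 * dir / sqrt(sum(dir^2))
}

# one-letter <-> three-letter residue codes (bio3d::aa321/aa123 cover the
# standard set; kept local to avoid masking)
.aa123 <- function(aa1) bio3d::aa123(aa1)
.aa321 <- function(aa3) bio3d::aa321(aa3)

#' Read structure models from a PDB file
#'
#' Parses single- or multi-MODEL PDB files via bio3d, extracting per-residue
#' N, CA, C and CB coordinates for one chain. Missing C-beta atoms
#' (glycine) are rebuilt with [pseudo_cb()].
#'
#' @param path PDB file.
#' @param chain Chain identifier; default the first chain present.
#' @param model_ids Optional character vector of ids, one per MODEL record;
#'   defaults to `"<basename>_<k>"` (or the basename alone for single-model
#'   files).
#' @return List of `structure_model` objects.
#' @export
read_structure_models <- function(path, chain = NULL, model_ids = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (is.null(chain)) chain <- at$chain[1]
  sel <- at$chain == chain & at$elety %in% c("N", "CA", "C", "CB")
  at <- at[sel, , drop = FALSE]
  if (nrow(at) == 0L) stop("no usable atoms for chain ", chain, " in ", path)
  xyz <- pdb$xyz[, atom2xyz(which(sel)), drop = FALSE]
  nmod <- nrow(xyz)
  resno <- sort(unique(at$resno))
  base <- sub("\\.pdb$", "", basename(path))
  if (is.null(model_ids)) {
    model_ids <- if (nmod == 1L) base else paste0(base, "_", seq_len(nmod))
  }
  if (length(model_ids) != nmod) stop("model_ids length != number of MODELs")
  aa <- vapply(resno, function(r) {
    .aa321(at$resid[at$resno == r][1])
  }, character(1))
  row_of <- function(ele) {
    vapply(resno, function(r) {
      w <- which(at$resno == r & at$elety == ele)
      if (length(w) == 0L) NA_integer_ else w[1]
    }, integer(1))
  }
  rows <- lapply(c(N = "N", CA = "CA", C = "C", CB = "CB"), row_of)
  if (anyNA(rows$CA)) stop("residue(s) missing CA in ", path)
  lapply(seq_len(nmod), function(k) {
    coords <- matrix(xyz[k, ], ncol = 3L, byrow = TRUE)
    get <- function(r) {
      m <- matrix(NA_real_, length(resno), 3L)
      ok <- !is.na(r)
      m[ok, ] <- coords[r[ok], , drop = FALSE]
      m
    }
    structure_model(model_ids[k], resno = resno, aa = aa,
                    ca = get(rows$CA), cb = get(rows$CB),
                    n = get(rows$N), c = get(rows$C))
  })
}

# xyz column indices for atom rows (bio3d convention)
atom2xyz <- function(i) as.vector(rbind(3 * i - 2, 3 * i - 1, 3 * i))

#' Write structure models to a (multi-MODEL) PDB file
#'
#' Writes N, CA, C and CB records per residue (CB omitted for glycine)
#' through bio3d's ATOM-record formatter, wrapping each model in
#' MODEL/ENDMDL records when more than one is given.
#'
#' @param models A `structure_model` or list of them (identical residue
#'   layout).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structure_models <- function(models, path) {
  if (inherits(models, "structure_model")) models <- list(models)
  m1 <- models[[1]]
  has_bb <- !is.null(m1$n) && !is.null(m1$c)
  elety <- c(if (has_bb) "N", "CA", if (has_bb) "C", "CB")
  per_res <- lapply(seq_along(m1$resno), function(i) {
    e <- elety
    if (m1$aa[i] == "G") e <- setdiff(e, "CB")
    e
  })
  ele_flat <- unlist(per_res)
  res_flat <- rep(m1$resno, lengths(per_res))
  aa_flat <- rep(.aa123(m1$aa), lengths(per_res))
  cat("", file = path)  # truncate
  multi <- length(models) > 1L
  for (k in seq_along(models)) {
    m <- models[[k]]
    coords <- do.call(rbind, lapply(seq_along(m$resno), function(i) {
      rows <- list(CA = m$ca[i, ], CB = m$cb[i, ])
      if (has_bb) rows <- c(list(N = m$n[i, ]), rows["CA"],
                            list(C = m$c[i, ]), rows["CB"])
      do.call(rbind, rows[per_res[[i]]])
    }))
    if (multi) cat(sprintf("MODEL     %4d\n", k), file = path, append = TRUE)
    bio3d::write.pdb(file = path, xyz = as.numeric(t(coords)),
                     resno = res_flat, resid = aa_flat,
                     eleno = seq_along(ele_flat), elety = ele_flat,
                     chain = rep("A", length(ele_flat)),
                     append = TRUE, end = FALSE)
    if (multi) cat("ENDMDL\n", file = path, append = TRUE)
  }
  cat("END   \n", file = path, append = TRUE)
  invisible(path)
}
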