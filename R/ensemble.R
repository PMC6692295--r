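# Ensemble comparison: least-squares superposition, per-residue RMSD
# profiles against a reference (or the ensemble mean), and detection of
# regions where two ensembles differ significantly in their deviation
# from a common reference.

#' Least-squares (Kabsch) superposition
#'
#' Finds the proper rotation and translation minimizing the C-alpha RMSD
#' of `mobile` onto `reference` over a selection, via SVD of the
#' cross-covariance matrix with the usual determinant correction.
#'
#' @param mobile,reference coordinate matrices (n x 3) or structures
#'   accepted by [coords_of()].
#' @param selection optional integer vector of row indices used for the
#'   fit (default: all rows). Both structures must use the same indexing.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   `rmsd` (over the selection), and `transformed` (all mobile
#'   coordinates after the transform). The transform maps x to
#'   `x %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  P <- coords_of(mobile)
  Q <- coords_of(reference)
  if (is.null(selection)) selection <- seq_len(nrow(P))
  if (length(selection) < 3L) stop("need >= 3 atoms to superpose")
  if (max(selection) > nrow(P) || max(selection) > nrow(Q))
    stop("selection out of range for mobile/reference")
  Ps <- P[selection, , drop = FALSE]
  Qs <- Q[selection, , drop = FALSE]
  pbar <- colMeans(Ps); qbar <- colMeans(Qs)
  Pc <- sweep(Ps, 2L, pbar); Qc <- sweep(Qs, 2L, qbar)
  sv <- svd(crossprod(Pc, Qc))          # A = P' Q, R = V D U^t
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- qbar - as.numeric(R %*% pbar)
  moved <- P %*% t(R) + matrix(t_vec, nrow(P), 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved[selection, , drop = FALSE] - Qs)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd, transformed = moved)
}

# iteratively superposed coordinate mean of a list of n x 3 matrices
.mean_structure <- function(coord_list, selection, iterations = 2L) {
  ref <- coord_list[[1L]]
  for (it in seq_len(iterations)) {
    aligned <- lapply(coord_list, function(x)
      kabsch_superpose(x, ref, selection)$transformed)
    ref <- Reduce(`+`, aligned) / length(aligned)
  }
  ref
}

#' Per-residue RMSD profile of an ensemble against a reference
#'
#' Each model is independently superposed onto the reference over
#' `selection` (residue ids); the per-residue C-alpha distance to the
#' reference is recorded, and mean and standard deviation across models
#' returned. With `reference = "mean"` the reference is the coordinate
#' average after iterative superposition.
#'
#' @param ensemble `structure_ensemble` (of protomers).
#' @param reference a structure, or the string `"mean"`.
#' @param selection residue ids used for superposition (default: the
#'   shared 27-130 comparison window intersected with available residues).
#' @return object of class `rmsd_profile`: list with `residue_ids`,
#'   `mean`, `sd`, `per_model` (models x residues matrix of deviations),
#'   `reference_label`, `selection`.
#' @export
ensemble_rmsd_profile <- function(ensemble, reference = "mean",
                                  selection = NULL) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  ids <- ensemble$models[[1L]]$residue_ids
  if (is.null(selection)) {
    selection <- intersect(27:130, ids)
    if (length(selection) < 3L) selection <- ids
  }
  sel_idx <- match(selection, ids)
  if (anyNA(sel_idx)) stop("selection contains residues absent from the models")
  coord_list <- lapply(ensemble$models, coords_of)
  if (identical(reference, "mean")) {
    ref_xyz <- .mean_structure(coord_list, sel_idx)
    ref_label <- "ensemble mean"
  } else {
    ref_xyz <- coords_of(reference)
    ref_label <- "reference"
  }
  dev <- t(vapply(coord_list, function(x) {
    moved <- kabsch_superpose(x, ref_xyz, sel_idx)$transformed
    sqrt(rowSums((moved - ref_xyz)^2))
  }, numeric(nrow(ref_xyz))))
  structure(list(residue_ids = ids,
                 mean = colMeans(dev),
                 sd = apply(dev, 2L, stats::sd),
                 per_model = dev,
                 reference_label = ref_label,
                 selection = selection),
            class = "rmsd_profile")
}

#' @export
#' @method print rmsd_profile
print.rmsd_profile <- function(x, ...) {
  cat(sprintf("<rmsd_profile> %d residues, %d models vs %s; mean RMSD %.3f A\n",
              length(x$residue_ids), nrow(x$per_model), x$reference_label,
              mean(x$mean)))
  invisible(x)
}

#' Regions of significant RMSD difference between two ensembles
#'
#' Per-residue two-sample t-test on the per-model deviations of ensembles
#' A and B from a common reference; a residue qualifies when
#' p < `p_threshold` and |mean_A - mean_B| exceeds the effect threshold
#' (default 0.5 Angstrom); maximal runs of >= L qualifying residues are
#' reported with sign (+1 when B deviates farther from the reference).
#'
#' @param profiles_A,profiles_B `rmsd_profile` objects (or plain
#'   models x residues matrices of deviations).
#' @param criterion `region_criterion`; default p < 0.001,
#'   |delta RMSD| > 0.5 Angstrom, L >= 3.
#' @return data.frame of regions (see [significant_fluct_regions()]).
#' @export
delta_rmsd_regions <- function(profiles_A, profiles_B,
                               criterion = region_criterion(
                                 effect_threshold = 0.5)) {
  getm <- function(p) if (inherits(p, "rmsd_profile")) p$per_model else as.matrix(p)
  A <- getm(profiles_A); B <- getm(profiles_B)
  ids <- if (inherits(profiles_A, "rmsd_profile")) profiles_A$residue_ids
         else seq_len(ncol(A))
  .detect_regions(A, B, ids, criterion)
}

#' All-vs-all average pairwise RMSD of an ensemble
#'
#' Alternative to the reference-based profile: every unordered model pair
#' is superposed over `selection` and the pairwise RMSD averaged.
#'
#' @inheritParams ensemble_rmsd_profile
#' @return mean pairwise RMSD (scalar).
#' @export
ensemble_pairwise_rmsd <- function(ensemble, selection = NULL) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  m <- length(ensemble$models)
  if (m < 2L) stop("need >= 2 models")
  ids <- ensemble$models[[1L]]$residue_ids
  if (is.null(selection)) {
    selection <- intersect(27:130, ids)
    if (length(selection) < 3L) selection <- ids
  }
  sel_idx <- match(selection, ids)
  coord_list <- lapply(ensemble$models, coords_of)
  vals <- c()
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
    vals <- c(vals, kabsch_superpose(coord_list[[i]], coord_list[[j]],
                                     sel_idx)$rmsd)
  mean(vals)
}
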