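# Shared machinery for the per-position significance tests used by both the
# fluctuation comparison (local NMA) and the ensemble RMSD comparison: a
# position qualifies when a two-sample t-test rejects AND the effect size
# exceeds a threshold; runs of >= L consecutive qualifying positions are
# reported as regions.

#' Region-detection criterion
#'
#' @param p_threshold per-position p-value threshold (default 0.001).
#' @param effect_threshold minimum absolute difference of means. Use the
#'   string `"sigma"` (default for fluctuation comparisons) to set it to
#'   the average per-position standard deviation pooled over both
#'   ensembles; use a number (e.g. 0.5 Angstrom for RMSD comparisons) for
#'   a fixed threshold.
#' @param min_run_length minimum number of consecutive qualifying
#'   positions, L (default 3).
#' @param welch logical; Welch (unequal-variance) t-test if TRUE
#'   (default), classical pooled-variance Student test otherwise.
#' @return object of class `region_criterion`.
#' @export
region_criterion <- function(p_threshold = 0.001, effect_threshold = "sigma",
                             min_run_length = 3L, welch = TRUE) {
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold must be in (0,1)")
  if (min_run_length < 1L) stop("min_run_length must be >= 1")
  structure(list(p_threshold = p_threshold,
                 effect_threshold = effect_threshold,
                 min_run_length = as.integer(min_run_length),
                 welch = isTRUE(welch)),
            class = "region_criterion")
}

# vectorized two-sample t-test over the columns of two matrices
# (rows = models, columns = positions); returns p-values
.columnwise_t_pvalues <- function(A, B, welch = TRUE) {
  nA <- nrow(A); nB <- nrow(B)
  mA <- colMeans(A); mB <- colMeans(B)
  vA <- apply(A, 2L, stats::var); vB <- apply(B, 2L, stats::var)
  if (welch) {
    se2 <- vA / nA + vB / nB
    df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  } else {
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    se2 <- sp2 * (1 / nA + 1 / nB)
    df <- rep(nA + nB - 2, length(vA))
  }
  tstat <- (mA - mB) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se2 == 0 & mA == mB] <- 1  # identical constant columns: no evidence
  p
}

# maximal runs of TRUE with length >= L -> data.frame(start_idx, end_idx)
.qualifying_runs <- function(qual, L) {
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= L
  data.frame(start_idx = starts[keep], end_idx = ends[keep])
}

# shared worker: matrices of per-model per-position values; positions are
# labelled by `ids` (residue numbers). effect threshold resolved here.
.detect_regions <- function(A, B, ids, criterion) {
  stopifnot(ncol(A) == ncol(B), length(ids) == ncol(A))
  if (nrow(A) < 2L || nrow(B) < 2L)
    stop("both ensembles need >= 2 models for a statistical comparison")
  thr <- criterion$effect_threshold
  if (identical(thr, "sigma")) {
    thr <- mean(c(apply(A, 2L, stats::sd), apply(B, 2L, stats::sd)))
  }
  p <- .columnwise_t_pvalues(A, B, criterion$welch)
  delta <- colMeans(B) - colMeans(A)
  qual <- (p < criterion$p_threshold) & (abs(delta) > thr) & !is.na(p)
  runs <- .qualifying_runs(qual, criterion$min_run_length)
  if (nrow(runs) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      sign = integer(0), min_p = numeric(0),
                      mean_delta = numeric(0)))
  }
  out <- data.frame(
    start = ids[runs$start_idx],
    end = ids[runs$end_idx],
    sign = NA_integer_, min_p = NA_real_, mean_delta = NA_real_)
  for (i in seq_len(nrow(runs))) {
    span <- runs$start_idx[i]:runs$end_idx[i]
    out$min_p[i] <- min(p[span])
    out$mean_delta[i] <- mean(delta[span])
    out$sign[i] <- as.integer(sign(out$mean_delta[i]))
  }
  attr(out, "effect_threshold") <- thr
  out
}

#' Regions of significant fluctuation difference
#'
#' Per-residue two-sample t-test of mean square fluctuations between two
#' model ensembles. A position qualifies when p < `p_threshold` and the
#' absolute MSF difference exceeds sigma, the average per-position standard
#' deviation of MSF pooled over both ensembles; maximal runs of at least
#' `min_run_length` qualifying positions are reported.
#'
#' @param profiles_A,profiles_B numeric matrices (models x positions) of
#'   per-model MSF values, or lists of `fluctuation_profile` objects.
#' @param ids position labels (residue ids); defaults to column index.
#' @param criterion `region_criterion`; the default uses the sigma effect
#'   threshold.
#' @return data.frame with columns start, end, sign (+1 when ensemble B has
#'   larger values), min_p, mean_delta; the resolved effect threshold is
#'   attached as attribute `"effect_threshold"`.
#' @export
significant_fluct_regions <- function(profiles_A, profiles_B, ids = NULL,
                                      criterion = region_criterion()) {
  A <- .as_profile_matrix(profiles_A)
  B <- .as_profile_matrix(profiles_B)
  if (is.null(ids)) ids <- seq_len(ncol(A))
  .detect_regions(A, B, ids, criterion)
}

.as_profile_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.list(x)) {
    rows <- lapply(x, function(p) {
      if (inherits(p, "fluctuation_profile")) p$per_residue_msf else as.numeric(p)
    })
    return(do.call(rbind, rows))
  }
  stop("expected a matrix or list of profiles")
}
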