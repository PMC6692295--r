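# Hydrogen-deuterium exchange (HDX-MS) analysis: forward uptake model,
# relative fractional uptake, and two-state comparison with per-peptide
# Wald tests on a state x time linear model. No back-exchange correction
# is applied anywhere.

#' Continuous-labeling conditions
#'
#' @param sample_volume protein sample volume, uL.
#' @param buffer_volume deuterated buffer volume, uL.
#' @param time_points labeling times, minutes (default the 7-point course
#'   0.16, 1, 10, 30, 60, 120, 180).
#' @param temperature degrees C (metadata only).
#' @param pD labeling pD (metadata only).
#' @return object of class `labeling_conditions` with derived
#'   `d_fraction`.
#' @export
labeling_conditions <- function(sample_volume = 15, buffer_volume = 55,
                                time_points = c(0.16, 1, 10, 30, 60, 120, 180),
                                temperature = 20, pD = 7.0) {
  structure(list(sample_volume = sample_volume,
                 buffer_volume = buffer_volume,
                 d_fraction = deuterium_fraction(sample_volume, buffer_volume),
                 time_points = time_points,
                 temperature = temperature, pD = pD),
            class = "labeling_conditions")
}

#' Deuterium fraction of the labeling mix
#'
#' Fraction of exchangeable positions that can acquire deuterium:
#' buffer / (sample + buffer). Mixing 15 uL of sample with 55 uL of
#' deuterated buffer gives 0.786 (78.6 percent excess deuterium).
#'
#' @param sample_volume,buffer_volume volumes, uL (> 0).
#' @return deuterium fraction in (0, 1).
#' @export
deuterium_fraction <- function(sample_volume, buffer_volume) {
  if (sample_volume <= 0 || buffer_volume <= 0)
    stop("volumes must be > 0")
  buffer_volume / (sample_volume + buffer_volume)
}

#' Count exchangeable backbone amides of a peptide
#'
#' The first residue and internal prolines (positions 2..end) carry no
#' observable amide: n = length - 1 - internal prolines. The
#' `"first_two"` convention additionally drops the second residue.
#'
#' @param sequence one-letter peptide sequence.
#' @param convention `"first"` (default) or `"first_two"`.
#' @return integer count (>= 0).
#' @export
count_exchangeable <- function(sequence, convention = c("first", "first_two")) {
  convention <- match.arg(convention)
  if (!nzchar(sequence)) stop("empty sequence")
  chars <- strsplit(sequence, "")[[1L]]
  skip <- if (convention == "first") 1L else min(2L, length(chars))
  rest <- chars[-seq_len(skip)]
  length(rest) - sum(rest == "P")
}

#' HDX peptide descriptor
#'
#' @param start,end 1-based inclusive residue positions on the protein.
#' @param sequence one-letter peptide sequence (length end - start + 1).
#' @return object of class `hdx_peptide` with derived `n_exchangeable`.
#' @export
hdx_peptide <- function(start, end, sequence) {
  if (end < start) stop("end must be >= start")
  if (nchar(sequence) != end - start + 1L)
    stop("sequence length does not match start/end")
  structure(list(start = as.integer(start), end = as.integer(end),
                 sequence = sequence,
                 n_exchangeable = count_exchangeable(sequence)),
            class = "hdx_peptide")
}

#' Forward model of peptide deuterium uptake
#'
#' uptake(t) = d_fraction * sum over exchangeable residues of
#' (1 - exp(-k_obs t)): first-order exchange at per-residue observed
#' rates, saturating at n_exchangeable * d_fraction.
#'
#' @param peptide `hdx_peptide`.
#' @param rates named or positional vector of per-residue observed
#'   exchange rates, min-1, one per residue of the peptide (values for
#'   non-exchangeable positions are ignored). `Inf` is allowed (instant
#'   exchange).
#' @param conditions `labeling_conditions`.
#' @param t labeling time(s), minutes.
#' @return uptake in Da (same length as `t`).
#' @export
peptide_uptake_model <- function(peptide, rates, conditions, t) {
  stopifnot(inherits(peptide, "hdx_peptide"))
  if (any(rates < 0, na.rm = TRUE)) stop("negative exchange rate")
  chars <- strsplit(peptide$sequence, "")[[1L]]
  exch <- rep(TRUE, length(chars))
  exch[1L] <- FALSE
  exch[-1L][chars[-1L] == "P"] <- FALSE
  k <- rates[exch]
  vapply(t, function(tt) {
    conditions$d_fraction * sum(1 - exp(-k * tt))
  }, numeric(1L))
}

#' Relative fractional uptake
#'
#' Experimental uptake divided by the theoretical maximum
#' (n_exchangeable x deuterium fraction). Values above 1.05 are flagged
#' via the `"clipped"` attribute but not altered.
#'
#' @param uptake measured uptake, Da.
#' @param peptide `hdx_peptide` (or the exchangeable-amide count).
#' @param conditions `labeling_conditions`.
#' @return fractional uptake (unitless).
#' @export
relative_fractional_uptake <- function(uptake, peptide, conditions) {
  n_ex <- if (inherits(peptide, "hdx_peptide")) peptide$n_exchangeable
          else as.integer(peptide)
  if (n_ex <= 0) stop("peptide has no exchangeable amides")
  rfu <- uptake / (n_ex * conditions$d_fraction)
  if (any(rfu > 1.05)) attr(rfu, "clipped") <- TRUE
  rfu
}

#' Uptake table for one protein state
#'
#' Long-format replicate-level uptake data: one row per peptide x time x
#' replicate.
#'
#' @param data data.frame with columns start, end, sequence, time_min,
#'   replicate, uptake_Da.
#' @param state free-text state label.
#' @return object of class `uptake_table`.
#' @export
uptake_table <- function(data, state = "") {
  need <- c("start", "end", "sequence", "time_min", "replicate", "uptake_Da")
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  if (any(data$uptake_Da < 0)) stop("uptake must be >= 0")
  structure(list(data = data, state = state), class = "uptake_table")
}

#' @export
#' @method print uptake_table
print.uptake_table <- function(x, ...) {
  d <- x$data
  cat(sprintf("<uptake_table> state '%s': %d peptides x %d times x %d replicates\n",
              x$state, length(unique(paste(d$start, d$end))),
              length(unique(d$time_min)), max(d$replicate)))
  invisible(x)
}

#' Read / write an uptake table (flattened DynamX-like dialect)
#'
#' Tab-separated text, header: start, end, sequence, time_min, replicate,
#' uptake_Da (a `state` column is carried through if present).
#'
#' @param path file path.
#' @param state state label for the returned object.
#' @return `uptake_table`.
#' @export
read_uptake_table <- function(path, state = "") {
  uptake_table(utils::read.table(path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE), state = state)
}

#' @rdname read_uptake_table
#' @param table `uptake_table` to write.
#' @export
write_uptake_table <- function(table, path) {
  utils::write.table(table$data, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Wald test that a set of coefficients is zero; finite-sample F form
# (W/q against F(q, residual dof)), exact under Gaussian errors and less
# anticonservative than the chi-square form at triplicate sample sizes
.wald_test <- function(fit, pattern) {
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  idx <- grep(pattern, names(b))
  idx <- idx[!is.na(b[idx])]
  if (length(idx) == 0L) return(NA_real_)
  bi <- b[idx]
  Vi <- V[idx, idx, drop = FALSE]
  W <- as.numeric(t(bi) %*% solve(Vi, bi))
  q <- length(idx)
  stats::pf(W / q, q, stats::df.residual(fit), lower.tail = FALSE)
}

#' Compare deuterium uptake between two states
#'
#' Per shared peptide, fits the fixed-effects linear model
#' uptake ~ state + time + state:time (time categorical) on replicate-level
#' data and computes Wald tests of the state main effect ("magnitude") and
#' of the state:time interaction ("kinetics"). P-values are
#' Benjamini-Hochberg adjusted across peptides separately per test; a
#' peptide is significant when either adjusted p-value is below `alpha`.
#' Per-time differences in relative fractional uptake
#' (dRFU = RFU_A - RFU_B) classify significant peptides: `"major"` when
#' max |dRFU| > 0.10, `"minor"` when 0.05 < max |dRFU| <= 0.10, else
#' `"none"`; residues inherit the most severe class among significant
#' covering peptides.
#'
#' @param tableA,tableB `uptake_table` objects with identical peptide
#'   maps and time points, >= 2 replicates each.
#' @param conditions `labeling_conditions` (for the deuterium fraction).
#' @param alpha significance level on adjusted p-values (default 0.01).
#' @return object of class `hdx_comparison`: `peptides` data.frame
#'   (start, end, n_exchangeable, p_magnitude, p_kinetics, p_adj_magnitude,
#'   p_adj_kinetics, significant, max_abs_dRFU, class), `residues`
#'   data.frame (residue, class), and `dRFU` matrix (peptides x times).
#' @export
compare_states <- function(tableA, tableB,
                           conditions = labeling_conditions(),
                           alpha = 0.01) {
  stopifnot(inherits(tableA, "uptake_table"), inherits(tableB, "uptake_table"))
  a <- tableA$data; b <- tableB$data
  key <- function(d) sort(unique(paste(d$start, d$end, d$sequence)))
  if (!identical(key(a), key(b))) stop("peptide maps differ between states")
  if (!setequal(unique(a$time_min), unique(b$time_min)))
    stop("time points differ between states")
  if (max(a$replicate) < 2L || max(b$replicate) < 2L)
    stop("need >= 2 replicates per state")
  peps <- unique(a[, c("start", "end", "sequence")])
  peps <- peps[order(peps$start, peps$end), , drop = FALSE]
  times <- sort(unique(a$time_min))
  n_pep <- nrow(peps)
  p_mag <- p_kin <- numeric(n_pep)
  dRFU <- matrix(NA_real_, n_pep, length(times),
                 dimnames = list(NULL, paste0("t", times)))
  n_ex <- integer(n_pep)
  for (i in seq_len(n_pep)) {
    sel <- function(d) d[d$start == peps$start[i] & d$end == peps$end[i], ]
    da <- sel(a); db <- sel(b)
    df <- rbind(data.frame(uptake = da$uptake_Da, state = "A",
                           time = factor(da$time_min, levels = times)),
                data.frame(uptake = db$uptake_Da, state = "B",
                           time = factor(db$time_min, levels = times)))
    df$state <- factor(df$state, levels = c("A", "B"))
    fit <- stats::lm(uptake ~ state * time, data = df)
    p_mag[i] <- .wald_test(fit, "^stateB$")
    p_kin[i] <- .wald_test(fit, "^stateB:")
    n_ex[i] <- count_exchangeable(peps$sequence[i])
    denom <- n_ex[i] * conditions$d_fraction
    mu_a <- tapply(da$uptake_Da, factor(da$time_min, levels = times), mean)
    mu_b <- tapply(db$uptake_Da, factor(db$time_min, levels = times), mean)
    dRFU[i, ] <- (mu_a - mu_b) / denom
  }
  p_adj_mag <- stats::p.adjust(p_mag, method = "BH")
  p_adj_kin <- stats::p.adjust(p_kin, method = "BH")
  signif_pep <- (p_adj_mag < alpha) | (p_adj_kin < alpha)
  signif_pep[is.na(signif_pep)] <- FALSE
  max_abs <- apply(abs(dRFU), 1L, max)
  cls <- rep("none", n_pep)
  cls[signif_pep & max_abs > 0.10] <- "major"
  cls[signif_pep & max_abs > 0.05 & max_abs <= 0.10] <- "minor"
  pep_out <- data.frame(start = peps$start, end = peps$end,
                        sequence = peps$sequence, n_exchangeable = n_ex,
                        p_magnitude = p_mag, p_kinetics = p_kin,
                        p_adj_magnitude = p_adj_mag,
                        p_adj_kinetics = p_adj_kin,
                        significant = signif_pep,
                        max_abs_dRFU = max_abs, class = cls)
  res_range <- range(c(peps$start, peps$end))
  severity <- c(none = 0L, minor = 1L, major = 2L)
  res_cls <- rep(NA_character_, res_range[2L] - res_range[1L] + 1L)
  res_ids <- res_range[1L]:res_range[2L]
  for (j in seq_along(res_ids)) {
    cover <- which(peps$start <= res_ids[j] & peps$end >= res_ids[j])
    if (length(cover) == 0L) next
    sig_cover <- cover[signif_pep[cover]]
    res_cls[j] <- if (length(sig_cover) == 0L) "none"
                  else names(severity)[max(severity[cls[sig_cover]]) + 1L]
  }
  structure(list(peptides = pep_out,
                 residues = data.frame(residue = res_ids, class = res_cls),
                 dRFU = dRFU, alpha = alpha, times = times),
            class = "hdx_comparison")
}

#' @export
#' @method print hdx_comparison
print.hdx_comparison <- function(x, ...) {
  cat(sprintf("<hdx_comparison> %d peptides, %d significant (alpha %.3g): %d major, %d minor\n",
              nrow(x$peptides), sum(x$peptides$significant), x$alpha,
              sum(x$peptides$class == "major"),
              sum(x$peptides$class == "minor")))
  invisible(x)
}
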