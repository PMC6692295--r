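# Lipari-Szabo model-free analysis of 15N relaxation under a fully
# anisotropic rotational diffusion tensor. Internal dynamics are described
# by an order parameter S2, an internal correlation time tau_e and an
# exchange broadening Rex; global tumbling by the Woessner five-exponential
# correlation function of an asymmetric rotor. All times in seconds,
# frequencies in rad/s, field in Tesla.

#' Spin-pair constants for the 15N-1H relaxation equations
#'
#' @param B0 static field, Tesla (default 14.1, i.e. 600 MHz 1H).
#' @param gammaH,gammaN gyromagnetic ratios, rad s-1 T-1 (1H positive,
#'   15N negative).
#' @param rNH N-H bond length, Angstrom (default 1.02).
#' @param deltaSigma 15N chemical shift anisotropy, ppm (default -160).
#' @return object of class `spin_constants` with derived Larmor
#'   frequencies `omegaH`, `omegaN` (magnitudes, rad/s), dipolar constant
#'   `d` and CSA constant `c`.
#' @export
spin_constants <- function(B0 = 14.1, gammaH = 2.6752e8, gammaN = -2.7126e7,
                           rNH = 1.02, deltaSigma = -160) {
  if (B0 <= 0 || rNH <= 0) stop("B0 and rNH must be > 0")
  mu0 <- 4 * pi * 1e-7
  hbar <- 1.054571817e-34
  r_m <- rNH * 1e-10
  d <- mu0 * hbar * gammaH * gammaN / (4 * pi * r_m^3)
  omegaN_signed <- gammaN * B0
  c_csa <- omegaN_signed * deltaSigma * 1e-6 / sqrt(3)
  structure(list(B0 = B0, gammaH = gammaH, gammaN = gammaN, rNH = rNH,
                 deltaSigma = deltaSigma,
                 omegaH = abs(gammaH) * B0, omegaN = abs(gammaN) * B0,
                 d = d, c = c_csa),
            class = "spin_constants")
}

.rot_zyz <- function(alpha, beta, gamma) {
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  rz(alpha) %*% ry(beta) %*% rz(gamma)
}

#' Rotational diffusion tensor
#'
#' @param Dx,Dy,Dz principal components, s-1, conventionally ascending
#'   (reordered with a message otherwise).
#' @param angles Euler angles (alpha, beta, gamma), radians, ZYZ
#'   convention, orienting the principal frame in the molecule frame.
#' @return object of class `diffusion_tensor` with `axes` (columns =
#'   principal axes in the molecule frame) and derived `Diso`.
#' @export
diffusion_tensor <- function(Dx, Dy, Dz, angles = c(0, 0, 0)) {
  D <- c(Dx, Dy, Dz)
  if (any(D <= 0)) stop("all diffusion components must be > 0")
  axes <- .rot_zyz(angles[1L], angles[2L], angles[3L])
  if (is.unsorted(D)) {
    ord <- order(D)
    D <- D[ord]
    axes <- axes[, ord, drop = FALSE]
  }
  structure(list(Dx = D[1L], Dy = D[2L], Dz = D[3L],
                 axes = axes, Diso = mean(D)),
            class = "diffusion_tensor")
}

#' Spectral density under anisotropic tumbling with internal motion
#'
#' The model-free spectral density of an N-H vector attached to an
#' asymmetric rotor: J(w) = (2/5) sum_k A_k [S2 tau_k/(1+(w tau_k)^2) +
#' (1-S2) tau'_k/(1+(w tau'_k)^2)], with the five Woessner correlation
#' times and amplitudes determined by the tensor and the N-H direction
#' cosines, and 1/tau'_k = 1/tau_k + 1/tau_e. For a spherically symmetric
#' tensor this reduces exactly to the isotropic Lipari-Szabo form with
#' tau_m = 1/(6 Diso).
#'
#' @param omega angular frequency (rad/s), may be a vector.
#' @param S2 order parameter in \[0, 1\].
#' @param tau_e internal correlation time, s (0 disables the internal
#'   term).
#' @param tensor `diffusion_tensor`.
#' @param nh_vector unit N-H vector in the molecule frame.
#' @return J(omega), s/rad (same length as `omega`).
#' @export
spectral_density <- function(omega, S2, tau_e, tensor, nh_vector) {
  stopifnot(inherits(tensor, "diffusion_tensor"))
  if (abs(sum(nh_vector^2) - 1) > 1e-6) stop("nh_vector must be unit norm")
  wt <- .woessner_terms(tensor, nh_vector)
  .J_sum(omega, S2, tau_e, wt$taus, wt$amps)
}

# five Woessner correlation times and amplitudes for one N-H orientation
.woessner_terms <- function(tensor, nh_vector) {
  Dx <- tensor$Dx; Dy <- tensor$Dy; Dz <- tensor$Dz
  Diso <- tensor$Diso
  L2 <- (Dx * Dy + Dx * Dz + Dy * Dz) / 3
  disc2 <- Diso^2 - L2
  if (disc2 < -1e-9 * Diso^2) stop("invalid tensor: Diso^2 < L^2")
  disc <- sqrt(max(disc2, 0))
  e <- as.numeric(t(tensor$axes) %*% nh_vector)  # direction cosines
  x <- e[1L]; y <- e[2L]; z <- e[3L]
  if (disc < 1e-12 * Diso) {
    # spherical top: single correlation time, exact isotropic limit
    return(list(taus = 1 / (6 * Diso), amps = 1))
  }
  taus <- 1 / c(4 * Dx + Dy + Dz,
                Dx + 4 * Dy + Dz,
                Dx + Dy + 4 * Dz,
                6 * Diso + 6 * disc,
                6 * Diso - 6 * disc)
  dd <- (3 * (x^4 + y^4 + z^4) - 1) / 4
  del <- c(Dx - Diso, Dy - Diso, Dz - Diso) / disc
  ee <- (del[1L] * (3 * x^4 + 6 * y^2 * z^2 - 1) +
         del[2L] * (3 * y^4 + 6 * x^2 * z^2 - 1) +
         del[3L] * (3 * z^4 + 6 * x^2 * y^2 - 1)) / 12
  amps <- c(3 * y^2 * z^2, 3 * x^2 * z^2, 3 * x^2 * y^2, dd - ee, dd + ee)
  list(taus = taus, amps = amps)
}

.J_sum <- function(omega, S2, tau_e, taus, amps) {
  out <- numeric(length(omega))
  for (k in seq_along(taus)) {
    tk <- taus[k]
    tkp <- if (tau_e > 0) 1 / (1 / tk + 1 / tau_e) else 0
    term <- S2 * tk / (1 + (omega * tk)^2)
    if (tkp > 0) term <- term + (1 - S2) * tkp / (1 + (omega * tkp)^2)
    out <- out + amps[k] * term
  }
  0.4 * out
}

#' Predict 15N T1, T2 and heteronuclear NOE
#'
#' Standard reduced rate equations:
#' R1 = (d^2/4)\[J(wH-wN) + 3J(wN) + 6J(wH+wN)\] + c^2 J(wN);
#' R2 = (d^2/8)\[4J(0) + J(wH-wN) + 3J(wN) + 6J(wH) + 6J(wH+wN)\] +
#' (c^2/6)\[4J(0) + 3J(wN)\] + Rex;
#' NOE = 1 + (d^2/(4 R1)) (gammaH/gammaN) \[6J(wH+wN) - J(wH-wN)\].
#'
#' @param S2,tau_e,Rex model-free parameters (Rex in s-1, added to R2).
#' @param tensor `diffusion_tensor`.
#' @param nh_vector unit N-H vector, molecule frame.
#' @param constants `spin_constants`.
#' @return named numeric vector (T1, T2, NOE), times in seconds.
#' @export
predict_relaxation <- function(S2, tau_e = 0, Rex = 0,
                               tensor, nh_vector,
                               constants = spin_constants()) {
  wt <- .woessner_terms(tensor, nh_vector)
  wH <- constants$omegaH; wN <- constants$omegaN
  J <- .J_sum(c(0, wN, wH - wN, wH, wH + wN), S2, tau_e, wt$taus, wt$amps)
  d2 <- constants$d^2; c2 <- constants$c^2
  R1 <- d2 / 4 * (J[3L] + 3 * J[2L] + 6 * J[5L]) + c2 * J[2L]
  R2 <- d2 / 8 * (4 * J[1L] + J[3L] + 3 * J[2L] + 6 * J[4L] + 6 * J[5L]) +
    c2 / 6 * (4 * J[1L] + 3 * J[2L]) + Rex
  noe <- 1 + d2 / (4 * R1) * (constants$gammaH / constants$gammaN) *
    (6 * J[5L] - J[3L])
  c(T1 = 1 / R1, T2 = 1 / R2, NOE = noe)
}

#' Per-residue relaxation dataset
#'
#' @param table data.frame with columns residue, T1, T1_err, T2, T2_err,
#'   NOE, NOE_err (times in seconds).
#' @param nh_vectors matrix of unit N-H vectors (one row per table row),
#'   molecule frame; required for anisotropic analysis.
#' @return object of class `relaxation_dataset`.
#' @export
relaxation_dataset <- function(table, nh_vectors = NULL) {
  need <- c("residue", "T1", "T1_err", "T2", "T2_err", "NOE", "NOE_err")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  if (any(table$T1 <= 0 | table$T2 <= 0)) stop("T1 and T2 must be > 0")
  if (!is.null(nh_vectors)) {
    nh_vectors <- as.matrix(nh_vectors)
    stopifnot(nrow(nh_vectors) == nrow(table), ncol(nh_vectors) == 3L)
  }
  structure(list(table = table, nh_vectors = nh_vectors),
            class = "relaxation_dataset")
}

# chi2 of one residue's (T1, T2, NOE) against a model-free prediction;
# tau_e enters the optimizer in ns so all parameters are O(1)
.mf_chi2 <- function(par, obs, err, tensor, nh, constants, model) {
  S2 <- par[1L]
  tau_e <- if (model %in% c("m2", "m4")) par[2L] * 1e-9 else 0
  Rex <- switch(model, m3 = par[2L], m4 = par[3L], 0)
  pred <- predict_relaxation(S2, tau_e, Rex, tensor, nh, constants)
  val <- sum(((obs - pred) / err)^2)
  if (!is.finite(val)) 1e12 else val  # S2 = 0 with no tumbling term: R1 = 0
}

.MF_STARTS_S2 <- c(0.3, 0.5, 0.7, 0.85, 0.97)
.MF_STARTS_TE <- c(0.001, 0.02, 0.1, 0.5, 2)  # ns

# best bounded fit of one model for one residue, over a fixed start grid
.fit_one_model <- function(obs, err, tensor, nh, constants, model,
                           te_max = 5e-9, rex_max = 20) {
  npar <- switch(model, m1 = 1L, m2 = 2L, m3 = 2L, m4 = 3L)
  starts <- switch(model,
    m1 = lapply(.MF_STARTS_S2, function(s) s),
    m2 = ,
    m4 = unlist(lapply(.MF_STARTS_S2, function(s)
      lapply(.MF_STARTS_TE, function(te) c(s, te))), recursive = FALSE),
    m3 = lapply(.MF_STARTS_S2, function(s) c(s, 1)))
  te_max_ns <- te_max * 1e9
  lower <- c(0, 0, 0)[seq_len(npar)]
  upper <- switch(model, m1 = 1, m2 = c(1, te_max_ns), m3 = c(1, rex_max),
                  m4 = c(1, te_max_ns, rex_max))
  best <- NULL
  for (st in starts) {
    p0 <- unlist(st)
    if (model == "m4") p0 <- c(p0, 2)
    p0 <- pmin(pmax(p0, lower), upper)
    fit <- tryCatch(
      stats::nlminb(p0, .mf_chi2, lower = lower, upper = upper,
                    obs = obs, err = err, tensor = tensor, nh = nh,
                    constants = constants, model = model,
                    control = list(eval.max = 500L, iter.max = 300L)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective))
      best <- fit
  }
  if (is.null(best)) return(NULL)
  S2 <- best$par[1L]
  tau_e <- if (model %in% c("m2", "m4")) best$par[2L] * 1e-9 else 0
  Rex <- switch(model, m3 = best$par[2L], m4 = best$par[3L], 0)
  list(S2 = S2, tau_e = tau_e, Rex = Rex, chi2 = best$objective, npar = npar)
}

# accept the more complex model? Requires (a) lack of fit of the simple
# model (chi2 goodness-of-fit rejected at 10%) and (b) a significant
# chi-square drop. Measurement errors are known, so the extra-parameter
# test is the likelihood-ratio / chi-square difference form,
# delta-chi2 > qchisq(1 - alpha, extra parameters); the classical F-test
# is powerless here (at most one residual dof with 3 observables).
.model_improves <- function(simple, complex, n_obs, alpha) {
  dof_simple <- n_obs - simple$npar
  if (dof_simple > 0 &&
      stats::pchisq(simple$chi2, dof_simple, lower.tail = FALSE) > 0.10)
    return(FALSE)
  dfn <- complex$npar - simple$npar
  if (complex$chi2 >= simple$chi2) return(FALSE)
  (simple$chi2 - complex$chi2) > stats::qchisq(1 - alpha, dfn)
}

#' Fit model-free parameters per residue
#'
#' For each residue, fits the four standard model-free models
#' m1 (S2), m2 (S2, tau_e), m3 (S2, Rex), m4 (S2, tau_e, Rex) to the
#' (T1, T2, NOE) triple by error-weighted least squares with bounded
#' multi-start local optimization, and selects the simplest model not
#' rejected against a more complex one at level `alpha` (extra
#' sum-of-squares F-test, or chi-square difference when no residual
#' degrees of freedom remain).
#'
#' @param data `relaxation_dataset` with N-H vectors.
#' @param tensor `diffusion_tensor` describing global tumbling.
#' @param constants `spin_constants`.
#' @param alpha model-selection test level (default 0.20).
#' @param te_max,rex_max parameter bounds (defaults 5 ns, 20 s-1).
#' @return data.frame: residue, S2, tau_e, Rex, model, chi2.
#' @export
fit_model_free <- function(data, tensor, constants = spin_constants(),
                           alpha = 0.20, te_max = 5e-9, rex_max = 20) {
  stopifnot(inherits(data, "relaxation_dataset"))
  tb <- data$table
  if (is.null(data$nh_vectors))
    stop("N-H vectors are required for anisotropic model-free fitting")
  out <- vector("list", nrow(tb))
  for (r in seq_len(nrow(tb))) {
    obs <- c(tb$T1[r], tb$T2[r], tb$NOE[r])
    err <- c(tb$T1_err[r], tb$T2_err[r], tb$NOE_err[r])
    if (anyNA(obs)) {
      warning("residue ", tb$residue[r], " has missing observables; skipped")
      next
    }
    err[err <= 0] <- pmax(1e-6 * abs(obs[err <= 0]), 1e-12)
    nh <- data$nh_vectors[r, ]
    fits <- lapply(c("m1", "m2", "m3", "m4"), function(m)
      .fit_one_model(obs, err, tensor, nh, constants, m, te_max, rex_max))
    names(fits) <- c("m1", "m2", "m3", "m4")
    chosen <- "m1"
    ext <- c("m2", "m3")
    improves <- vapply(ext, function(m)
      .model_improves(fits$m1, fits[[m]], 3L, alpha), logical(1L))
    if (any(improves)) {
      cand <- ext[improves]
      chosen <- cand[which.min(vapply(cand, function(m) fits[[m]]$chi2,
                                      numeric(1L)))]
      if (.model_improves(fits[[chosen]], fits$m4, 3L, alpha)) chosen <- "m4"
    }
    f <- fits[[chosen]]
    out[[r]] <- data.frame(residue = tb$residue[r], S2 = f$S2,
                           tau_e = f$tau_e, Rex = f$Rex,
                           model = chosen, chi2 = f$chi2)
  }
  do.call(rbind, out)
}

#' Estimate the rotational diffusion tensor from T1/T2 ratios
#'
#' Selects rigid residues (NOE above `noe_min` and T2 within one standard
#' deviation of the 10 percent trimmed mean), then optimizes
#' (Dx, Dy, Dz, three Euler angles) to minimize the chi-square of the
#' observed versus predicted T1/T2 ratio, holding S2 = 0.9, tau_e = 0,
#' Rex = 0. Multi-start over a fixed orientation grid; deterministic.
#'
#' @param data `relaxation_dataset` with N-H vectors.
#' @param constants `spin_constants`.
#' @param noe_min rigidity filter on NOE (default 0.65).
#' @param min_rigid minimum number of rigid residues (default 15).
#' @return `diffusion_tensor` (components ascending) with attributes
#'   `chi2` and `n_rigid`.
#' @export
estimate_diffusion_tensor <- function(data, constants = spin_constants(),
                                      noe_min = 0.65, min_rigid = 15L) {
  stopifnot(inherits(data, "relaxation_dataset"))
  tb <- data$table
  if (is.null(data$nh_vectors)) stop("N-H vectors required")
  t2m <- mean(tb$T2, trim = 0.1)
  rigid <- tb$NOE > noe_min & abs(tb$T2 - t2m) <= stats::sd(tb$T2)
  rigid[is.na(rigid)] <- FALSE
  if (sum(rigid) < min_rigid)
    stop("only ", sum(rigid), " rigid residues pass the filter (need >= ",
         min_rigid, ")")
  T1 <- tb$T1[rigid]; T2 <- tb$T2[rigid]
  ratio <- T1 / T2
  rerr <- ratio * sqrt((tb$T1_err[rigid] / T1)^2 + (tb$T2_err[rigid] / T2)^2)
  rerr[rerr <= 0] <- 1e-3 * ratio[rerr <= 0]
  nh <- data$nh_vectors[rigid, , drop = FALSE]
  pred_ratio <- function(tensor) {
    vapply(seq_len(nrow(nh)), function(i) {
      p <- predict_relaxation(0.9, 0, 0, tensor, nh[i, ], constants)
      p[["T1"]] / p[["T2"]]
    }, numeric(1L))
  }
  # isotropic initial guess: 1-D search for Diso matching the mean ratio
  iso_obj <- function(logD) {
    tn <- diffusion_tensor(exp(logD), exp(logD) * 1.0001, exp(logD) * 1.0002)
    (mean(pred_ratio(tn)) - mean(ratio))^2
  }
  D0 <- exp(stats::optimize(iso_obj, c(log(1e5), log(1e9)))$minimum)
  obj <- function(par) {
    D <- exp(par[1:3])
    tn <- diffusion_tensor(D[1L], D[2L], D[3L], angles = par[4:6])
    sum(((ratio - pred_ratio(tn)) / rerr)^2)
  }
  angle_grid <- list(c(0, 0, 0), c(0, pi / 2, 0), c(pi / 2, pi / 2, 0),
                     c(pi / 4, pi / 4, pi / 4))
  best <- NULL
  for (ang in angle_grid) {
    p0 <- c(log(D0 * c(0.8, 1.0, 1.25)), ang)
    fit <- tryCatch(
      stats::nlminb(p0, obj,
                    lower = c(rep(log(1e5), 3L), rep(-2 * pi, 3L)),
                    upper = c(rep(log(1e9), 3L), rep(2 * pi, 3L))),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective))
      best <- fit
  }
  D <- exp(best$par[1:3])
  tensor <- diffusion_tensor(D[1L], D[2L], D[3L], angles = best$par[4:6])
  attr(tensor, "chi2") <- best$objective
  attr(tensor, "n_rigid") <- sum(rigid)
  tensor
}

#' Weighted-average chemical shift perturbation
#'
#' Combined 1H/15N shift difference with the usual 15N down-weighting:
#' csp = sqrt(ddH^2 + (0.159 ddN)^2). Vectorized.
#'
#' @param ddH 1H shift difference, ppm.
#' @param ddN 15N shift difference, ppm.
#' @return combined perturbation, ppm.
#' @export
csp <- function(ddH, ddN) {
  sqrt(ddH^2 + (0.159 * ddN)^2)
}

#' Read / write a per-residue relaxation table
#'
#' Tab-separated text with header columns residue, T1, T1_err, T2,
#' T2_err, NOE, NOE_err.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_relaxation_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' @rdname read_relaxation_table
#' @param table data.frame to write.
#' @export
write_relaxation_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
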