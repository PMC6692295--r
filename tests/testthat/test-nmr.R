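# Independent re-implementation of the isotropic model-free J and the
# standard rate equations, used as an oracle (kept deliberately separate
# from the package's Woessner-based code path).
oracle_iso_rates <- function(S2, tau_e, Rex, tau_m, cst) {
  J <- function(w) {
    tp <- if (tau_e > 0) tau_m * tau_e / (tau_m + tau_e) else 0
    0.4 * (S2 * tau_m / (1 + (w * tau_m)^2) +
           if (tp > 0) (1 - S2) * tp / (1 + (w * tp)^2) else 0)
  }
  wH <- cst$omegaH; wN <- cst$omegaN
  d2 <- cst$d^2; c2 <- cst$c^2
  R1 <- d2 / 4 * (J(wH - wN) + 3 * J(wN) + 6 * J(wH + wN)) + c2 * J(wN)
  R2 <- d2 / 8 * (4 * J(0) + J(wH - wN) + 3 * J(wN) + 6 * J(wH) +
                  6 * J(wH + wN)) + c2 / 6 * (4 * J(0) + 3 * J(wN)) + Rex
  noe <- 1 + d2 / (4 * R1) * (cst$gammaH / cst$gammaN) *
    (6 * J(wH + wN) - J(wH - wN))
  c(T1 = 1 / R1, T2 = 1 / R2, NOE = noe)
}

test_that("anisotropic J reduces exactly to the isotropic form", {
  D <- 2.2e7
  tn <- diffusion_tensor(D, D, D)
  tm <- 1 / (6 * D)
  S2 <- 0.85; te <- 50e-12
  w <- c(0, 1e7, 3.8e8, 3.6e9)
  for (v in list(c(0, 0, 1), c(1, 0, 0) / 1, c(1, 1, 1) / sqrt(3))) {
    Jan <- spectral_density(w, S2, te, tn, v)
    tp <- tm * te / (tm + te)
    Jiso <- 0.4 * (S2 * tm / (1 + (w * tm)^2) +
                   (1 - S2) * tp / (1 + (w * tp)^2))
    expect_equal(Jan, Jiso, tolerance = 1e-12)
  }
  # S2 = 1: internal term vanishes, J independent of tau_e
  tn2 <- paper_tensor()
  v <- c(0.3, 0.5, sqrt(1 - 0.34))
  expect_equal(spectral_density(w, 1, 1e-10, tn2, v),
               spectral_density(w, 1, 2e-9, tn2, v), tolerance = 1e-14)
  # J(0) closed form for the isotropic case
  J0 <- spectral_density(0, 0.85, 50e-12, tn, c(0, 0, 1))
  expect_equal(J0, 0.4 * (0.85 * tm + 0.15 * tm * te / (tm + te)),
               tolerance = 1e-12)
})

test_that("Woessner amplitudes are normalized for arbitrary tensors", {
  set.seed(33)
  for (i in 1:10) {
    D <- sort(stats::runif(3, 1e7, 4e7))
    tn <- diffusion_tensor(D[1], D[2], D[3],
                           angles = stats::runif(3, -pi, pi))
    v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
    wt <- filadyn:::.woessner_terms(tn, v)
    expect_equal(sum(wt$amps), 1, tolerance = 1e-10)
    expect_true(all(wt$taus > 0))
  }
})

test_that("predicted rates match the independent oracle and its limits", {
  cst <- spin_constants()
  D <- 1 / (6 * 10e-9)                       # tau_m = 10 ns
  tn <- diffusion_tensor(D, D, D)
  got <- predict_relaxation(0.85, 50e-12, 0, tn, c(0, 0, 1), cst)
  want <- oracle_iso_rates(0.85, 50e-12, 0, 10e-9, cst)
  expect_equal(got, want, tolerance = 1e-10)
  # Rex additivity: exact 2 s-1 difference in R2
  r0 <- predict_relaxation(0.85, 50e-12, 0, tn, c(0, 0, 1), cst)
  r2 <- predict_relaxation(0.85, 50e-12, 2, tn, c(0, 0, 1), cst)
  expect_equal(1 / r2[["T2"]] - 1 / r0[["T2"]], 2, tolerance = 1e-10)
  expect_equal(r2[["T1"]], r0[["T1"]])
  # extreme narrowing: T1 ~ T2 within 5%
  Df <- 1 / (6 * 0.1e-9)
  pf <- predict_relaxation(1, 0, 0, diffusion_tensor(Df, Df, Df),
                           c(0, 0, 1), cst)
  expect_lt(abs(pf[["T1"]] / pf[["T2"]] - 1), 0.05)
  # slow tumbling monotonicity R2 >= R1 over a parameter box
  tn5 <- diffusion_tensor(1 / (6 * 5e-9), 1 / (6 * 5e-9), 1 / (6 * 5e-9))
  for (S2 in c(0.5, 0.7, 0.9, 1)) for (te in c(0, 2e-11, 5e-10)) {
    p <- predict_relaxation(S2, te, 0, tn5, c(0, 0, 1), cst)
    expect_gte(1 / p[["T2"]], 1 / p[["T1"]])
  }
})

test_that("noise-free fits select the simplest generating model", {
  tn <- paper_tensor()
  nh <- matrix(c(0.3, 0.5, sqrt(1 - 0.34)), 1L)
  ds <- make_relaxation_dataset(
    data.frame(residue = 1L, S2 = 0.8, tau_e = 0, Rex = 0),
    tn, nh, noise_frac = 0, seed = 1L)
  fit <- fit_model_free(ds, tn)
  expect_identical(fit$model, "m1")
  expect_equal(fit$S2, 0.8, tolerance = 1e-4)
  # round trip for the full m4 parameterization
  ds4 <- make_relaxation_dataset(
    data.frame(residue = 1L, S2 = 0.7, tau_e = 80e-12, Rex = 4),
    tn, nh, noise_frac = 0, seed = 1L)
  fit4 <- fit_model_free(ds4, tn)
  pred <- predict_relaxation(fit4$S2, fit4$tau_e, fit4$Rex, tn, nh[1L, ])
  expect_equal(unname(pred),
               c(ds4$table$T1, ds4$table$T2, ds4$table$NOE),
               tolerance = 1e-3)
})

test_that("grossly unphysical data yields a flagged fit, not a crash", {
  tn <- paper_tensor()
  tab <- data.frame(residue = 1L, T1 = 0.1, T1_err = 0.002,
                    T2 = 0.5, T2_err = 0.01, NOE = 0.8, NOE_err = 0.02)
  ds <- relaxation_dataset(tab, matrix(c(0, 0, 1), 1L))
  fit <- fit_model_free(ds, tn)
  expect_identical(nrow(fit), 1L)
  expect_gt(fit$chi2, 10)
})

test_that("isotropic tensor estimation recovers D within 2%", {
  set.seed(3)
  nh <- unit_rows(matrix(rnorm(150), 50L))
  tr <- data.frame(residue = 1:50, S2 = 0.9, tau_e = 0, Rex = 0)
  tn_true <- diffusion_tensor(2.2e7, 2.2e7 * 1.0001, 2.2e7 * 1.0002)
  ds <- make_relaxation_dataset(tr, tn_true, nh, noise_frac = 0.01,
                                seed = 6L)
  tf <- estimate_diffusion_tensor(ds)
  expect_lt(max(abs(c(tf$Dx, tf$Dy, tf$Dz) / 2.2e7 - 1)), 0.02)
  # permuting residue order leaves the estimate unchanged
  perm <- sample(50L)
  ds2 <- relaxation_dataset(ds$table[perm, ], ds$nh_vectors[perm, ])
  tf2 <- estimate_diffusion_tensor(ds2)
  expect_equal(c(tf$Dx, tf$Dy, tf$Dz), c(tf2$Dx, tf2$Dy, tf2$Dz),
               tolerance = 1e-6)
  # too few rigid residues errors
  expect_error(estimate_diffusion_tensor(
    relaxation_dataset(ds$table[1:5, ], nh[1:5, ])), "rigid")
})

test_that("csp matches the weighted-average formula and its properties", {
  expect_identical(csp(0, 0), 0)
  expect_identical(csp(0, 1.0), 0.159)
  expect_equal(csp(0.03, 0.2), sqrt(0.03^2 + (0.159 * 0.2)^2),
               tolerance = 1e-15)
  # symmetric in sign, homogeneous of degree 1
  set.seed(12)
  h <- rnorm(20, 0, 0.05); n <- rnorm(20, 0, 0.4)
  expect_equal(csp(-h, n), csp(h, -n))
  expect_equal(csp(3 * h, 3 * n), 3 * csp(h, n), tolerance = 1e-12)
})

test_that("relaxation tables round-trip through tabular text", {
  tab <- data.frame(residue = 1:3, T1 = c(0.8, 0.82, 0.79),
                    T1_err = 0.02, T2 = 0.08, T2_err = 0.002,
                    NOE = 0.77, NOE_err = 0.02)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_relaxation_table(tab, f)
  expect_equal(read_relaxation_table(f), tab, tolerance = 1e-12)
})
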