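test_that("two-atom Hessian matches the analytic dumbbell", {
  H <- as.matrix(build_hessian(rbind(c(0, 0, 0), c(3, 0, 0)),
                               elastic_network_params(cutoff = 15, gamma = 1)))
  blk <- H[1:3, 4:6]
  expect_equal(blk, diag(c(-1, 0, 0)), tolerance = 1e-12)
  ev <- eigen(H, symmetric = TRUE)$values
  expect_equal(sort(ev), c(0, 0, 0, 0, 0, 2), tolerance = 1e-12)
  expect_error(build_hessian(rbind(c(0, 0, 0), c(20, 0, 0)),
                             elastic_network_params(cutoff = 15)),
               "disconnected")
})

test_that("Hessian is symmetric, PSD, with exactly zero block row sums", {
  for (seed in 1:3) {
    xyz <- random_cloud(30L, seed = seed)
    H <- build_hessian(xyz, elastic_network_params(cutoff = 8))
    Hd <- as.matrix(H)
    expect_lt(max(abs(Hd - t(Hd))), 1e-12)
    # translational invariance: rows sum to zero over x/y/z block structure
    n <- nrow(xyz)
    for (a in 1:3) {
      rs <- rowSums(Hd[, 3 * (seq_len(n) - 1L) + a])
      expect_lt(max(abs(rs)), 1e-10)
    }
    expect_gt(min(eigen(Hd, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  }
})

test_that("trivial mode counts: 5 for a dumbbell, 6 for non-collinear networks", {
  H2 <- build_hessian(rbind(c(0, 0, 0), c(3, 0, 0)),
                      elastic_network_params())
  m2 <- compute_modes(H2, n_modes = 1L, n_trivial_expected = 5L)
  expect_identical(m2$n_trivial, 5L)
  for (seed in 1:4) {
    xyz <- random_cloud(20L, seed = seed)
    m <- compute_modes(build_hessian(xyz, elastic_network_params(cutoff = 8)),
                       n_modes = 3L)
    expect_identical(m$n_trivial, 6L)
  }
})

test_that("shift-invert Lanczos agrees with the dense oracle", {
  xyz <- random_cloud(60L, seed = 7L)
  H <- build_hessian(xyz, elastic_network_params(cutoff = 9))
  k <- 12L
  ms <- compute_modes(H, n_modes = k, method = "arpack")
  # independent oracle: full dense eigendecomposition via base eigen
  eg <- eigen(as.matrix(H), symmetric = TRUE)
  dense_vals <- sort(eg$values)
  sel <- seq_len(ms$n_trivial + k)
  expect_equal(ms$eigenvalues[7:(6 + k)], dense_vals[7:(6 + k)],
               tolerance = 1e-8)
  # subspace agreement for the non-trivial block; the dense span is
  # extended past the cut so a degenerate pair straddling mode k cannot
  # fail the comparison spuriously
  Va <- ms$vectors[, 7:(6 + k)]
  Vd <- eg$vectors[, order(eg$values)][, 7:(6 + k + 3)]
  sv <- svd(crossprod(Va, Vd))$d
  expect_gt(min(sv), 1 - 1e-8)
  # orthonormality of returned modes
  G <- crossprod(ms$vectors)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
})

test_that("mode MSF follows the formula and its scaling laws", {
  # single mode, eigenvalue 2, concentrated on atom 0 -> msf_0 = 0.5
  fake <- structure(list(
    eigenvalues = c(rep(0, 6), 2),
    vectors = cbind(matrix(0, 9, 6), c(1, 0, 0, rep(0, 6))),
    n_trivial = 6L, zero_tol = 1e-10), class = "normal_mode_set")
  prof <- mode_msf(fake, 1L)
  expect_equal(prof$per_atom_msf, c(0.5, 0, 0))
  expect_error(mode_msf(fake, 2L), "beyond")
  # doubling gamma halves every msf value
  xyz <- random_cloud(25L, seed = 2L)
  m1 <- compute_modes(build_hessian(xyz, elastic_network_params(8, gamma = 1)),
                      n_modes = 3L)
  m2 <- compute_modes(build_hessian(xyz, elastic_network_params(8, gamma = 2)),
                      n_modes = 3L)
  expect_equal(mode_msf(m1, 1:3)$per_atom_msf,
               2 * mode_msf(m2, 1:3)$per_atom_msf, tolerance = 1e-8)
})

test_that("MSF equals the mode-restricted pseudo-inverse diagonal (oracle)", {
  xyz <- toy_protomer(10L)$ca_coords
  H <- build_hessian(xyz, elastic_network_params(cutoff = 8))
  m <- compute_modes(H, n_modes = 3L)
  prof <- mode_msf(m, 1:3)
  eg <- eigen(as.matrix(H), symmetric = TRUE)
  ord <- order(eg$values)
  cols <- ord[7:9]
  Pinv <- eg$vectors[, cols] %*% diag(1 / eg$values[cols]) %*%
    t(eg$vectors[, cols])
  oracle <- colSums(matrix(diag(Pinv), nrow = 3L))
  expect_equal(prof$per_atom_msf, oracle, tolerance = 1e-8)
})

test_that("MSF profiles are invariant under rigid transforms", {
  xyz <- random_cloud(30L, seed = 5L)
  R <- random_rotation(11L)
  moved <- xyz %*% t(R) + matrix(c(10, -4, 2), nrow(xyz), 3L, byrow = TRUE)
  p1 <- mode_msf(compute_modes(build_hessian(xyz, elastic_network_params(8)),
                               n_modes = 3L), 1:3)$per_atom_msf
  p2 <- mode_msf(compute_modes(build_hessian(moved, elastic_network_params(8)),
                               n_modes = 3L), 1:3)$per_atom_msf
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("subunit averages respect the leading-residue exclusion", {
  prot <- toy_protomer(30L)
  fil <- build_filament(prot, helical_params(10, 85), 4L)
  msf <- rep(2.5, 120)
  expect_equal(subunit_average_msf(fil, msf), rep(2.5, 4L))
  msf2 <- rep(c(rep(100, 24), rep(1, 6)), 4L)
  expect_equal(subunit_average_msf(fil, msf2, exclude_first_n = 24L),
               rep(1, 4L))
  expect_equal(subunit_average_msf(fil, msf2, exclude_first_n = 0L),
               rep(mean(msf2[1:30]), 4L))
  expect_error(subunit_average_msf(fil, msf, exclude_first_n = 30L),
               "removes all")
})

test_that("classification self-overlaps and the 'other' fallback behave", {
  prot <- toy_protomer(12L)
  fil <- build_filament(prot, helical_params(10, 85), 8L)
  f <- make_deformation_fields(fil)
  cl <- classify_mode(f$twist, fil)
  expect_identical(cl$label, "twist")
  expect_equal(unname(cl$overlaps[["twist"]]), 1, tolerance = 1e-9)
  cl2 <- classify_mode(f$stretch, fil)
  expect_identical(cl2$label, "stretch")
  # vector orthogonal to all reference fields -> other
  set.seed(42)
  u <- rnorm(3L * nrow(coords_of(fil)))
  B <- cbind(f$twist, f$stretch, f$bend)
  u <- u - B %*% solve(crossprod(B), crossprod(B, u))
  expect_identical(classify_mode(as.numeric(u), fil)$label, "other")
  # degenerate on-axis geometry errors
  line <- cbind(0, 0, seq(0, 30, by = 3))
  expect_error(make_deformation_fields(line), "axis")
})

test_that("fluctuation-difference regions follow the run-length rule", {
  set.seed(8)
  base <- matrix(rnorm(11 * 50, 1, 0.02), 11)
  A <- base + matrix(rnorm(11 * 50, 0, 0.01), 11)
  B <- base + matrix(rnorm(11 * 50, 0, 0.01), 11)
  expect_identical(nrow(significant_fluct_regions(A, A)), 0L)
  # qualifying positions exactly {10,11,12,40,41} -> single region [10,12]
  B2 <- B
  B2[, c(10:12, 40:41)] <- B2[, c(10:12, 40:41)] + 1
  regs <- significant_fluct_regions(A, B2)
  expect_identical(nrow(regs), 1L)
  expect_identical(c(regs$start, regs$end), c(10L, 12L))
  expect_identical(regs$sign, 1L)
  expect_error(significant_fluct_regions(A[1, , drop = FALSE], B), ">= 2")
})

test_that("injected MSF offsets are detected within the stated window", {
  set.seed(13)
  sigma <- 0.05
  base <- matrix(rnorm(11 * 134, 1, sigma), 11)
  A <- base + matrix(rnorm(11 * 134, 0, sigma / 5), 11)
  B <- base + matrix(rnorm(11 * 134, 0, sigma / 5), 11)
  B[, 60:70] <- B[, 60:70] + 3 * sigma
  regs <- significant_fluct_regions(A, B)
  expect_identical(nrow(regs), 1L)
  expect_gte(regs$start, 58L)
  expect_lte(regs$start, 61L)
  expect_gte(regs$end, 69L)
  expect_lte(regs$end, 72L)
  # per-position brute-force oracle for the qualifying set
  thr <- attr(regs, "effect_threshold")
  for (j in c(59L, 65L, 71L)) {
    p <- stats::t.test(A[, j], B[, j])$p.value
    qual <- p < 0.001 && abs(mean(A[, j]) - mean(B[, j])) > thr
    expect_identical(qual, j %in% seq(regs$start, regs$end))
  }
})
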