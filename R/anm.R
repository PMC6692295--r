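# Anisotropic Network Model (ANM) on C-alpha atoms: every pair of atoms
# closer than a distance cutoff is connected by a uniform spring of
# constant gamma. The Hessian of the resulting quadratic energy has
# 3x3 super-elements H_ij = -(gamma/d_ij^2) (r_ij o r_ij) off the
# diagonal and H_ii = -sum_j H_ij, giving six zero-frequency rigid-body
# modes for a connected network. All fluctuations are in relative units
# (kT/gamma = 1): the analyses compare profiles, not absolute amplitudes.

#' Elastic network parameters
#'
#' @param cutoff pairwise contact cutoff, Angstrom (default 15).
#' @param gamma uniform spring constant, arbitrary units (default 1).
#' @return object of class `elastic_network_params`.
#' @export
elastic_network_params <- function(cutoff = 15, gamma = 1) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (gamma <= 0) stop("gamma must be > 0")
  structure(list(cutoff = cutoff, gamma = gamma),
            class = "elastic_network_params")
}

# all atom pairs within cutoff, computed in row-chunks to bound memory;
# returns data.frame(i, j, dx, dy, dz, d2) with i < j
.contact_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  chunk <- max(1L, floor(2e6 / n))
  res <- list()
  s <- 1L
  while (s <= n) {
    e <- min(n, s + chunk - 1L)
    block <- xyz[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rowSums(xyz^2), `+`) -
      2 * tcrossprod(block, xyz)
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    gi <- hit[, 1L] + s - 1L
    keep <- gi < hit[, 2L]
    if (any(keep)) {
      i <- gi[keep]; j <- hit[keep, 2L]
      res[[length(res) + 1L]] <- data.frame(
        i = i, j = j,
        dx = xyz[j, 1L] - xyz[i, 1L],
        dy = xyz[j, 2L] - xyz[i, 2L],
        dz = xyz[j, 3L] - xyz[i, 3L])
    }
    s <- e + 1L
  }
  pr <- do.call(rbind, res)
  if (is.null(pr)) pr <- data.frame(i = integer(0), j = integer(0),
                                    dx = numeric(0), dy = numeric(0),
                                    dz = numeric(0))
  pr$d2 <- pr$dx^2 + pr$dy^2 + pr$dz^2
  pr
}

#' Build the ANM Hessian
#'
#' @param coords coordinate matrix (n x 3) or a structure accepted by
#'   [coords_of()].
#' @param params `elastic_network_params`.
#' @return sparse symmetric 3n x 3n Hessian (`Matrix::dgCMatrix`). Errors
#'   if the contact network is disconnected, listing component sizes.
#' @export
build_hessian <- function(coords, params = elastic_network_params()) {
  xyz <- coords_of(coords)
  n <- nrow(xyz)
  if (n < 2L) stop("need >= 2 atoms")
  pr <- .contact_pairs(xyz, params$cutoff)
  if (nrow(pr) > 0L) {
    g <- igraph::graph_from_edgelist(cbind(pr$i, pr$j), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    comp <- igraph::components(g)
  } else comp <- list(no = n, csize = rep(1L, n))
  if (comp$no > 1L)
    stop("contact network is disconnected at cutoff ", params$cutoff,
         " A: ", comp$no, " components of sizes ",
         paste(comp$csize, collapse = ", "))
  k <- params$gamma / pr$d2
  # off-diagonal super-elements: -k * r_ab for the 9 (a,b) combinations
  drs <- cbind(pr$dx, pr$dy, pr$dz)
  ii <- jj <- xx <- vector("list", 9L)
  slot <- 0L
  for (a in 1:3) for (b in 1:3) {
    slot <- slot + 1L
    ii[[slot]] <- 3L * (pr$i - 1L) + a
    jj[[slot]] <- 3L * (pr$j - 1L) + b
    xx[[slot]] <- -k * drs[, a] * drs[, b]
  }
  I <- unlist(ii); J <- unlist(jj); X <- unlist(xx)
  # diagonal super-elements accumulate +k r_a r_b over incident pairs
  atoms <- c(pr$i, pr$j)
  dI <- dJ <- dX <- vector("list", 9L)
  slot <- 0L
  for (a in 1:3) for (b in 1:3) {
    slot <- slot + 1L
    v <- c(k * drs[, a] * drs[, b], k * drs[, a] * drs[, b])
    acc <- rowsum(v, atoms)
    at <- as.integer(rownames(acc))
    dI[[slot]] <- 3L * (at - 1L) + a
    dJ[[slot]] <- 3L * (at - 1L) + b
    dX[[slot]] <- acc[, 1L]
  }
  H <- Matrix::sparseMatrix(
    i = c(I, J, unlist(dI)), j = c(J, I, unlist(dJ)),
    x = c(X, X, unlist(dX)), dims = c(3L * n, 3L * n))
  Matrix::forceSymmetric(H, uplo = "L")
}

#' Compute the lowest normal modes of an ANM Hessian
#'
#' Returns the low-eigenvalue end of the spectrum with zero (rigid-body)
#' modes flagged as trivial. Small systems use a dense symmetric
#' eigendecomposition; large ones a shift-invert Lanczos iteration
#' (sparse Cholesky of H + sigma I, ARPACK on its inverse).
#'
#' @param hessian matrix from [build_hessian()].
#' @param n_modes number of non-trivial modes wanted (>= 1).
#' @param method `"auto"` (dense below 1200 coordinates), `"dense"` or
#'   `"arpack"`.
#' @param n_trivial_expected rigid-body mode count to retain (default 6).
#' @return object of class `normal_mode_set`: `eigenvalues` (ascending),
#'   `vectors` (3N x k, unit columns), `n_trivial`, `zero_tol`.
#' @export
compute_modes <- function(hessian, n_modes = 3L,
                          method = c("auto", "dense", "arpack"),
                          n_trivial_expected = 6L) {
  method <- match.arg(method)
  dim3n <- nrow(hessian)
  if (method == "auto") method <- if (dim3n <= 1200L) "dense" else "arpack"
  nev <- min(dim3n, n_trivial_expected + n_modes + 2L)
  if (method == "dense") {
    eg <- eigen(as.matrix(Matrix::symmpart(hessian)), symmetric = TRUE)
    ord <- order(eg$values)
    lam_max <- max(eg$values)
    vals <- eg$values[ord][seq_len(nev)]
    vecs <- eg$vectors[, ord, drop = FALSE][, seq_len(nev), drop = FALSE]
  } else {
    H <- methods::as(Matrix::forceSymmetric(hessian), "CsparseMatrix")
    lam_max <- max(Matrix::rowSums(abs(H)))  # Gershgorin bound
    sigma <- 1e-7 * lam_max
    ch <- Matrix::Cholesky(H, Imult = sigma, perm = TRUE, LDL = FALSE)
    fn <- function(x, extra) as.numeric(Matrix::solve(ch, x))
    # fixed local seed: ARPACK draws its start vector from the R RNG,
    # and bit-reproducible eigenvectors are part of the contract
    ap <- .with_seed(760313L,
      igraph::arpack(fn, sym = TRUE,
                     options = list(n = dim3n, nev = nev,
                                    ncv = min(dim3n, max(4L * nev, 40L)),
                                    which = "LA", maxiter = 3000L)))
    lam <- 1 / ap$values - sigma
    ord <- order(lam)
    vals <- lam[ord]
    vecs <- ap$vectors[, ord, drop = FALSE]
  }
  vecs <- sweep(vecs, 2L, sqrt(colSums(vecs^2)), `/`)
  zero_tol <- 1e-8 * lam_max
  n_trivial <- sum(vals < zero_tol)
  structure(list(eigenvalues = vals, vectors = vecs,
                 n_trivial = n_trivial, zero_tol = zero_tol,
                 method = method),
            class = "normal_mode_set")
}

#' @export
#' @method print normal_mode_set
print.normal_mode_set <- function(x, ...) {
  nt <- x$n_trivial
  cat(sprintf("<normal_mode_set> %d modes (%d trivial), lowest non-trivial eigenvalues: %s\n",
              length(x$eigenvalues), nt,
              paste(signif(x$eigenvalues[(nt + 1):min(nt + 3, length(x$eigenvalues))], 4),
                    collapse = ", ")))
  invisible(x)
}

# column indices of the requested non-trivial modes (1 = first non-trivial)
.nontrivial_cols <- function(modes, mode_indices) {
  if (any(mode_indices < 1L)) stop("mode indices are 1-based over non-trivial modes")
  cols <- modes$n_trivial + mode_indices
  if (any(cols > length(modes$eigenvalues)))
    stop("requested mode beyond the computed set")
  if (any(modes$eigenvalues[cols] < modes$zero_tol))
    stop("requested mode is trivial (zero eigenvalue)")
  cols
}

#' Per-atom mean square fluctuations from selected modes
#'
#' MSF_i = sum_k (1/lambda_k) |u_k,i|^2 over the selected non-trivial
#' modes, in relative units (kT/gamma = 1).
#'
#' @param modes `normal_mode_set`.
#' @param mode_indices non-trivial mode numbers (1 = lowest non-trivial;
#'   default first three).
#' @return object of class `fluctuation_profile`: `per_atom_msf` (=
#'   `per_residue_msf` at C-alpha resolution) and the selected indices.
#' @export
mode_msf <- function(modes, mode_indices = 1:3) {
  cols <- .nontrivial_cols(modes, mode_indices)
  n <- nrow(modes$vectors) / 3L
  msf <- numeric(n)
  for (c0 in cols) {
    u2 <- matrix(modes$vectors[, c0]^2, nrow = 3L)
    msf <- msf + colSums(u2) / modes$eigenvalues[c0]
  }
  structure(list(per_atom_msf = msf, per_residue_msf = msf,
                 mode_indices = mode_indices),
            class = "fluctuation_profile")
}

#' Per-subunit average MSF
#'
#' Averages a fluctuation profile over each subunit of a filament,
#' excluding residues with id <= `exclude_first_n` (the buried N-terminal
#' segment; default 24).
#'
#' @param filament `filament_model` the profile was computed on.
#' @param profile `fluctuation_profile` (or numeric per-atom vector).
#' @param exclude_first_n residues 1..n are excluded (default 24).
#' @return numeric vector, one average per subunit.
#' @export
subunit_average_msf <- function(filament, profile, exclude_first_n = 24L) {
  msf <- if (inherits(profile, "fluctuation_profile")) profile$per_atom_msf
         else as.numeric(profile)
  su <- subunit_index(filament)
  res <- residue_index(filament)
  keep <- res > exclude_first_n
  if (!any(keep)) stop("exclusion removes all residues")
  as.numeric(tapply(msf[keep], su[keep], mean))
}

#' Local normal mode analysis on an axial slice
#'
#' Runs ANM on the atoms inside a z-box around a central subunit (the
#' box extends `margin_z` beyond the central subunit's own z-range).
#' Subunits contributing less than `min_subunit_fraction` of their atoms
#' to the box are excluded: cutting a chain by a flat box leaves tiny
#' weakly-attached fragments whose quasi-rigid-body motions would
#' otherwise appear as spurious near-zero modes.
#'
#' @param filament `filament_model`.
#' @param central_index 0-based central subunit (default: middle).
#' @param margin_z box margin, Angstrom (default 15).
#' @param params `elastic_network_params`.
#' @param n_modes non-trivial modes to compute (default 3).
#' @param min_subunit_fraction fragment-pruning threshold (default 0.25).
#' @return list: `modes` (`normal_mode_set`), `atom_idx` (into the
#'   filament's atom order), `coords`, `labels` (per computed mode),
#'   `profile` (`fluctuation_profile` over the first `n_modes` modes),
#'   `central_atom_idx` (central subunit's positions within the slice,
#'   NA for pruned atoms).
#' @export
local_nma <- function(filament, central_index = NULL, margin_z = 15,
                      params = elastic_network_params(), n_modes = 3L,
                      min_subunit_fraction = 0.25) {
  stopifnot(inherits(filament, "filament_model"))
  if (is.null(central_index)) central_index <- filament$n_subunits %/% 2L
  sl <- slice_filament(filament, central_index, margin_z)
  su <- subunit_index(filament)[sl$atom_idx]
  n_per <- nrow(filament$subunit_coords[[1L]])
  counts <- table(su)
  keep_sub <- as.integer(names(counts)[counts >= min_subunit_fraction * n_per])
  idx <- sl$atom_idx[su %in% keep_sub]
  xyz <- coords_of(filament)[idx, , drop = FALSE]
  H <- build_hessian(xyz, params)
  modes <- compute_modes(H, n_modes = n_modes)
  n_nt <- length(modes$eigenvalues) - modes$n_trivial
  labels <- lapply(seq_len(min(n_modes, n_nt)), function(k)
    classify_mode(modes, xyz, k))
  central_global <- which(subunit_index(filament) == central_index + 1L)
  list(modes = modes, atom_idx = idx, coords = xyz, labels = labels,
       profile = mode_msf(modes, seq_len(min(n_modes, n_nt))),
       central_atom_idx = match(central_global, idx))
}

# ---- mode character classification ---------------------------------------

# orthonormal basis of the 6 rigid-body displacement fields of a point set
.rigid_basis <- function(xyz) {
  n <- nrow(xyz)
  cen <- sweep(xyz, 2L, colMeans(xyz))
  Tx <- rep(c(1, 0, 0), n); Ty <- rep(c(0, 1, 0), n); Tz <- rep(c(0, 0, 1), n)
  rot <- function(ax) as.numeric(t(apply(cen, 1L, function(r)
    c(ax[2] * r[3] - ax[3] * r[2],
      ax[3] * r[1] - ax[1] * r[3],
      ax[1] * r[2] - ax[2] * r[1]))))
  B <- cbind(Tx, Ty, Tz, rot(c(1, 0, 0)), rot(c(0, 1, 0)), rot(c(0, 0, 1)))
  qr.Q(qr(B))[, 1:6, drop = FALSE]
}

#' Analytic deformation fields of a filament
#'
#' Generates unit-norm twist and stretch reference fields and an
#' orthonormal bend reference subspace from the atom coordinates, with
#' the six rigid-body components projected out of everything (normal
#' modes are orthogonal to rigid motions, so leaving those components in
#' would deflate overlaps for reasons unrelated to mode character).
#' Twist: atoms rotate about +Z by an angle linear in z. Stretch: axial
#' displacement linear in z. Bend: transverse displacement along x or y
#' with smooth axial profiles; half- and full-period cosines are both
#' included because the first free-free bending shape is symmetric about
#' the centre (ends and centre move in opposite transverse directions)
#' while tilt-like bending of short slices is antisymmetric.
#'
#' @param coords coordinate matrix or structure accepted by [coords_of()].
#' @return list with unit 3N-vectors `twist` and `stretch`, and `bend`,
#'   a 3N x 4 orthonormal basis of the bend subspace.
#' @export
make_deformation_fields <- function(coords) {
  xyz <- coords_of(coords)
  n <- nrow(xyz)
  z <- xyz[, 3L]
  zc <- z - mean(z)
  x <- xyz[, 1L] - mean(xyz[, 1L])
  y <- xyz[, 2L] - mean(xyz[, 2L])
  if (max(x^2 + y^2) < 1e-12)
    stop("degenerate geometry: all atoms on the filament axis")
  s <- (z - min(z)) / diff(range(z))
  interleave <- function(fx, fy, fz) as.numeric(rbind(fx, fy, fz))
  zero <- rep(0, n)
  R <- .rigid_basis(xyz)
  deflate <- function(f) {
    f <- f - R %*% crossprod(R, f)
    as.numeric(f / sqrt(sum(f^2)))
  }
  bend_raw <- cbind(interleave(cos(pi * s), zero, zero),
                    interleave(cos(2 * pi * s), zero, zero),
                    interleave(zero, cos(pi * s), zero),
                    interleave(zero, cos(2 * pi * s), zero))
  bend_raw <- apply(bend_raw, 2L, deflate)
  list(twist = deflate(interleave(-zc * y, zc * x, zero)),
       stretch = deflate(interleave(zero, zero, zc)),
       bend = qr.Q(qr(bend_raw))[, seq_len(ncol(bend_raw)), drop = FALSE])
}

#' Classify a normal mode as bend, twist, stretch or other
#'
#' Computes the normalized overlap |<u, f>| / (|u| |f|) of the mode
#' vector against the analytic reference fields of
#' [make_deformation_fields()]; the bend score is the norm of the
#' projection onto the bend subspace (the x/y directions and axial
#' profiles combined in quadrature). The label is the argmax, or
#' `"other"` when the best score is below 0.5.
#'
#' @param mode 3N mode vector, or a `normal_mode_set` together with
#'   `mode_index` (non-trivial numbering).
#' @param coords the filament (or coordinates) the mode belongs to.
#' @param mode_index non-trivial mode number when `mode` is a mode set.
#' @return list with `label` and `overlaps` (named: bend, twist, stretch).
#' @export
classify_mode <- function(mode, coords, mode_index = NULL) {
  if (inherits(mode, "normal_mode_set")) {
    if (is.null(mode_index)) stop("mode_index required with a normal_mode_set")
    mode <- mode$vectors[, .nontrivial_cols(mode, mode_index)]
  }
  u <- mode / sqrt(sum(mode^2))
  f <- make_deformation_fields(coords)
  scores <- c(bend = sqrt(sum(crossprod(f$bend, u)^2)),
              twist = abs(sum(u * f$twist)),
              stretch = abs(sum(u * f$stretch)))
  best <- which.max(scores)
  label <- if (scores[best] < 0.5) "other" else names(scores)[best]
  list(label = label, overlaps = scores)
}
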