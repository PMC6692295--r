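# Shared fixtures, all built in code.

# toy protomer: n residues on a loose helix, guaranteed connected at 15 A
toy_protomer <- function(n = 10L, seed = 1L) {
  set.seed(seed)
  i <- seq_len(n) - 1L
  xyz <- cbind(2.3 * cos(1.7 * i), 2.3 * sin(1.7 * i), 1.5 * i)
  protomer_structure(seq_len(n), paste(rep("A", n), collapse = ""), xyz)
}

# random compact connected 3-D cloud: uniform in a ball whose radius
# scales with n^(1/3) so the contact density is size-independent
random_cloud <- function(n = 50L, seed = 1L, radius = 2.2 * n^(1 / 3)) {
  set.seed(seed)
  xyz <- matrix(0, 0L, 3L)
  while (nrow(xyz) < n) {
    p <- matrix(stats::runif(3L * n, -radius, radius), ncol = 3L)
    p <- p[rowSums(p^2) <= radius^2, , drop = FALSE]
    xyz <- rbind(xyz, p)
  }
  xyz[seq_len(n), , drop = FALSE]
}

# random proper rotation matrix
random_rotation <- function(seed = 1L) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# quaternion -> rotation matrix (used by the superposition grid oracle)
quat_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L)
}

# independent superposition oracle: multi-start quaternion optimization
# (never touches the SVD path under test)
oracle_superpose_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2L, colMeans(P))
  Qc <- sweep(Q, 2L, colMeans(Q))
  obj <- function(q) {
    R <- quat_rotation(q)
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  best <- Inf
  set.seed(99)
  starts <- rbind(diag(4L), matrix(stats::rnorm(4L * 20L), ncol = 4L))
  for (s in seq_len(nrow(starts))) {
    f <- stats::optim(starts[s, ], obj, method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-14))
    best <- min(best, f$value)
  }
  best
}

paper_tensor <- function() diffusion_tensor(1.95e7, 2.15e7, 2.88e7)

unit_rows <- function(m) m / sqrt(rowSums(m^2))
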