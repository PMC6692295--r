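# Deterministic generators for every input the pipeline consumes: a
# pilin-like protomer (long N-terminal helix plus compact head), perturbed
# coordinate ensembles, relaxation data from known model-free truth, and
# HDX uptake tables from per-residue exchange rates. Every generator is a
# pure function of its arguments and seed.

# run expr with a local RNG state seeded by `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Default configuration of the synthetic world
#'
#' Collects the stated defaults in one place: a 134-residue pilin-like
#' protomer, helical symmetry rise 10 Angstrom / twist 85 degrees (30
#' subunits span roughly 30 nm), 11-model ensembles, triplicate HDX at
#' the 7-point time course, 2 percent relaxation noise.
#'
#' @param seed master seed.
#' @return named list of generator parameters.
#' @export
synthetic_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       protomer_length = 134L,
       rise = 10, twist = 85, n_subunits = 30L,
       ensemble_size = 11L,
       coordinate_noise_sd = 0.3,
       relaxation_noise = 0.02,
       hdx_noise_sd = 0.05,
       hdx_replicates = 3L,
       time_points = c(0.16, 1, 10, 30, 60, 120, 180))
}

# deterministic pseudo-sequence with a realistic composition
.make_sequence <- function(n, seed) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
  freq <- c(8.3, 5.5, 4.0, 5.5, 1.4, 3.9, 6.8, 7.1, 2.3, 6.0, 9.7, 5.8,
            2.4, 3.9, 4.7, 6.6, 5.3, 1.1, 2.9, 6.9)
  .with_seed(seed, sample(aa, n, replace = TRUE, prob = freq))
}

# ideal helix around a vertical axis at (cx, cy), n residues
.helix_trace <- function(n, cx, cy, radius, rise, turn_deg, z0 = 0,
                         phase_deg = 0) {
  i <- seq_len(n) - 1L
  th <- (phase_deg + turn_deg * i) * pi / 180
  cbind(cx + radius * cos(th), cy + radius * sin(th), z0 + rise * i)
}

#' Generate a pilin-like protomer
#'
#' C-alpha trace with the canonical pilin architecture: an ideal
#' N-terminal alpha helix for residues 1-54 (rise 1.5 Angstrom/residue,
#' radius 2.3 Angstrom, 100 degrees/residue) running along +Z but offset
#' from the eventual filament axis, and a compact solenoidal
#' helix-turn-strand stand-in head for the remaining residues, wound
#' inside a ~25 Angstrom sphere next to the helix top. N-H unit vectors
#' are drawn on a 20-degree half-angle cone around the local chain
#' normal, seed-fixed.
#'
#' @param length total residue count (>= 60; default 134).
#' @param seed RNG seed (sequence and N-H cone draws).
#' @param helix_offset lateral offset of the alpha-helix axis from the
#'   origin (the filament axis), Angstrom.
#' @return `protomer_structure` with N-H vectors.
#' @export
make_protomer <- function(length = 134L, seed = 1L, helix_offset = 6) {
  length <- as.integer(length)
  if (length < 60L) stop("length must be >= 60")
  n_helix <- 54L
  n_head <- length - n_helix
  helix <- .helix_trace(n_helix, cx = helix_offset, cy = 0, radius = 2.3,
                        rise = 1.5, turn_deg = 100)
  z_top <- helix[n_helix, 3L]
  head_height <- 24
  rise_h <- head_height / n_head
  radius_h <- 8
  chord <- sqrt(max(3.8^2 - rise_h^2, 0.1))
  turn_h <- 2 * asin(chord / (2 * radius_h)) * 180 / pi
  head <- .helix_trace(n_head, cx = helix_offset + 16, cy = 0,
                       radius = radius_h, rise = rise_h,
                       turn_deg = turn_h, z0 = z_top - 6, phase_deg = 180)
  xyz <- rbind(helix, head)
  seq1 <- .make_sequence(length, seed)
  nh <- .make_nh_vectors(xyz, seed + 1L)
  protomer_structure(residue_ids = seq_len(length), sequence = seq1,
                     ca_coords = xyz, nh_vectors = nh, chain_id = "A")
}

# unit N-H vectors on a 20-degree cone around the local chain normal
.make_nh_vectors <- function(xyz, seed) {
  n <- nrow(xyz)
  .with_seed(seed, {
    tang <- xyz[pmin(n, seq_len(n) + 1L), ] - xyz[pmax(1L, seq_len(n) - 1L), ]
    tang <- tang / sqrt(rowSums(tang^2))
    nh <- matrix(0, n, 3L)
    half_angle <- 20 * pi / 180
    for (i in seq_len(n)) {
      t_i <- tang[i, ]
      ref <- if (abs(t_i[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      p <- c(t_i[2L] * ref[3L] - t_i[3L] * ref[2L],
             t_i[3L] * ref[1L] - t_i[1L] * ref[3L],
             t_i[1L] * ref[2L] - t_i[2L] * ref[1L])
      p <- p / sqrt(sum(p^2))
      q <- c(t_i[2L] * p[3L] - t_i[3L] * p[2L],
             t_i[3L] * p[1L] - t_i[1L] * p[3L],
             t_i[1L] * p[2L] - t_i[2L] * p[1L])
      ang <- acos(stats::runif(1L, cos(half_angle), 1))
      phi <- stats::runif(1L, 0, 2 * pi)
      v <- cos(ang) * p + sin(ang) * (cos(phi) * t_i + sin(phi) * q)
      nh[i, ] <- v / sqrt(sum(v^2))
    }
    nh
  })
}

#' Generate a perturbed coordinate ensemble
#'
#' The input model plus `n - 1` copies with i.i.d. Gaussian noise of
#' standard deviation `noise_sd` added to every coordinate (a stand-in
#' for independently refined models; expected C-alpha RMSD to the
#' unperturbed model is `noise_sd * sqrt(3)`).
#'
#' @param model `protomer_structure` or `filament_model`.
#' @param n ensemble size (>= 1; default 11).
#' @param noise_sd per-coordinate noise, Angstrom.
#' @param seed RNG seed.
#' @return `structure_ensemble` (the unperturbed model first).
#' @export
make_ensemble <- function(model, n = 11L, noise_sd = 0.3, seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  .with_seed(seed, {
    perturb <- function(m) {
      if (inherits(m, "protomer_structure")) {
        m$ca_coords <- m$ca_coords +
          matrix(stats::rnorm(3L * nrow(m$ca_coords), 0, noise_sd),
                 ncol = 3L)
      } else {
        m$subunit_coords <- lapply(m$subunit_coords, function(b)
          b + matrix(stats::rnorm(3L * nrow(b), 0, noise_sd), ncol = 3L))
      }
      m
    }
    models <- c(list(model),
                lapply(seq_len(n - 1L), function(k) perturb(model)))
    structure_ensemble(models, label = sprintf("synthetic (sd %.2f A)",
                                               noise_sd))
  })
}

#' Generate a synthetic relaxation dataset from model-free truth
#'
#' Forward-models (T1, T2, NOE) for each residue from the truth table and
#' tensor, then multiplies each observable by (1 + eps) with
#' eps ~ N(0, noise_frac^2); quoted errors are noise_frac times the
#' value.
#'
#' @param truth data.frame with columns residue, S2, tau_e, Rex.
#' @param tensor `diffusion_tensor`.
#' @param nh_vectors matrix of unit N-H vectors (one row per residue of
#'   `truth`), molecule frame.
#' @param constants `spin_constants`.
#' @param noise_frac fractional Gaussian noise (default 0.02).
#' @param seed RNG seed.
#' @return `relaxation_dataset`.
#' @export
make_relaxation_dataset <- function(truth, tensor, nh_vectors,
                                    constants = spin_constants(),
                                    noise_frac = 0.02, seed = 1L) {
  stopifnot(all(c("residue", "S2", "tau_e", "Rex") %in% names(truth)),
            nrow(nh_vectors) == nrow(truth))
  .with_seed(seed, {
    n <- nrow(truth)
    pred <- t(vapply(seq_len(n), function(i)
      predict_relaxation(truth$S2[i], truth$tau_e[i], truth$Rex[i],
                         tensor, nh_vectors[i, ], constants),
      numeric(3L)))
    eps <- matrix(stats::rnorm(3L * n, 0, noise_frac), n, 3L)
    obs <- pred * (1 + eps)
    tab <- data.frame(residue = truth$residue,
                      T1 = obs[, 1L], T1_err = noise_frac * pred[, 1L],
                      T2 = obs[, 2L], T2_err = noise_frac * pred[, 2L],
                      NOE = obs[, 3L], NOE_err = noise_frac * abs(pred[, 3L]))
    relaxation_dataset(tab, nh_vectors)
  })
}

#' Generate an overlapping peptide map with full coverage
#'
#' Peptides of length 5-15 tiling the sequence with overlaps, 100
#' percent coverage, every peptide with at least one exchangeable amide.
#'
#' @param sequence one-letter protein sequence (string or vector).
#' @param seed RNG seed.
#' @param min_len,max_len peptide length bounds.
#' @return data.frame with columns start, end, sequence.
#' @export
make_peptide_map <- function(sequence, seed = 1L, min_len = 5L,
                             max_len = 15L) {
  if (length(sequence) == 1L) sequence <- strsplit(sequence, "")[[1L]]
  n <- length(sequence)
  .with_seed(seed, {
    peps <- list()
    start <- 1L
    repeat {
      len <- sample(min_len:max_len, 1L)
      end <- min(n, start + len - 1L)
      if (n - end < min_len) end <- n  # absorb a short tail
      sq <- paste(sequence[start:end], collapse = "")
      while (count_exchangeable(sq) < 1L && end < n) {
        end <- end + 1L
        sq <- paste(sequence[start:end], collapse = "")
      }
      peps[[length(peps) + 1L]] <- data.frame(start = start, end = end,
                                              sequence = sq)
      if (end >= n) break
      # overlap: next peptide starts inside the current one
      start <- start + max(2L, (end - start + 1L) %/% 2L)
      if (start > end + 1L) start <- end + 1L
    }
    do.call(rbind, peps)
  })
}

#' Generate two-state HDX uptake tables from per-residue rates
#'
#' Replicate-level uptake from the first-order forward model plus
#' Gaussian noise truncated at zero.
#'
#' @param rates_per_state named list of per-residue exchange-rate vectors
#'   (min-1), one per state, each of length nchar(sequence).
#' @param peptide_map data.frame from [make_peptide_map()] (start, end,
#'   sequence).
#' @param conditions `labeling_conditions`.
#' @param noise_sd uptake noise, Da (default 0.05).
#' @param n_replicates replicates per time point (default 3).
#' @param seed RNG seed.
#' @return named list of `uptake_table` objects, one per state.
#' @export
make_hdx_tables <- function(rates_per_state, peptide_map,
                            conditions = labeling_conditions(),
                            noise_sd = 0.05, n_replicates = 3L,
                            seed = 1L) {
  stopifnot(is.list(rates_per_state), length(rates_per_state) >= 1L)
  .with_seed(seed, {
    out <- list()
    for (state in names(rates_per_state)) {
      k_all <- rates_per_state[[state]]
      if (any(k_all < 0, na.rm = TRUE)) stop("rates must be >= 0")
      covered <- unique(unlist(mapply(seq, peptide_map$start,
                                      peptide_map$end, SIMPLIFY = FALSE)))
      gap <- setdiff(seq_along(k_all), covered)
      if (length(gap) > 0L)
        stop("peptide map leaves a coverage gap at residues ",
             paste(utils::head(gap, 5L), collapse = ", "),
             if (length(gap) > 5L) ", ..." else "")
      rows <- list()
      for (i in seq_len(nrow(peptide_map))) {
        pep <- hdx_peptide(peptide_map$start[i], peptide_map$end[i],
                           peptide_map$sequence[i])
        k <- k_all[pep$start:pep$end]
        clean <- peptide_uptake_model(pep, k, conditions,
                                      conditions$time_points)
        for (rep_i in seq_len(n_replicates)) {
          noisy <- pmax(0, clean + stats::rnorm(length(clean), 0, noise_sd))
          rows[[length(rows) + 1L]] <- data.frame(
            start = pep$start, end = pep$end, sequence = pep$sequence,
            time_min = conditions$time_points, replicate = rep_i,
            uptake_Da = noisy)
        }
      }
      out[[state]] <- uptake_table(do.call(rbind, rows), state = state)
    }
    out
  })
}

#' Default per-residue model-free truth profile
#'
#' Rigid secondary structure (S2 = 0.85) with flexible loops and termini
#' (lower S2, longer tau_e) and a few exchange-broadened residues; used
#' by the demo pipeline.
#'
#' @param n residue count.
#' @return data.frame(residue, S2, tau_e, Rex).
#' @export
default_relaxation_truth <- function(n = 110L) {
  res <- seq_len(n)
  S2 <- rep(0.85, n)
  tau_e <- rep(2e-11, n)
  Rex <- rep(0, n)
  loops <- c(52:59, 63:67, 86:91)
  loops <- loops[loops <= n]
  S2[loops] <- 0.65
  tau_e[loops] <- 5e-10
  S2[pmax(1L, n - 4L):n] <- 0.55
  exch <- c(30:36)
  exch <- exch[exch <= n]
  Rex[exch] <- 3
  data.frame(residue = res, S2 = S2, tau_e = tau_e, Rex = Rex)
}

#' Default two-state HDX rate truth
#'
#' State A ("monomer"): fast exchange in loops, slow in helix/strand.
#' State B ("pilus"): identical except `slow_region`, where rates are
#' divided by `slow_factor` (default 20, emulating burial on assembly).
#'
#' @param sequence protein sequence (vector or string).
#' @param slow_region residue ids slowed in state B (default 30:45).
#' @param slow_factor rate reduction factor (default 20).
#' @param seed seed for the per-residue base rates.
#' @return named list of rate vectors (`A`, `B`), min-1.
#' @export
default_hdx_truth <- function(sequence, slow_region = 30:45,
                              slow_factor = 20, seed = 1L) {
  if (length(sequence) == 1L) sequence <- strsplit(sequence, "")[[1L]]
  n <- length(sequence)
  .with_seed(seed, {
    base <- exp(stats::runif(n, log(0.05), log(2)))  # min-1
    kA <- base
    kB <- base
    slow <- intersect(slow_region, seq_len(n))
    kB[slow] <- kB[slow] / slow_factor
    list(A = kA, B = kB)
  })
}
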