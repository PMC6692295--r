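# Coordinate data model shared by all analysis stages. Everything is
# C-alpha level: one coordinate (and optionally one N-H unit vector) per
# residue. Units are Angstrom throughout; the filament axis is +Z.

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL", X = "UNK")
.AA1 <- stats::setNames(names(.AA3), .AA3)

#' Construct a protomer structure
#'
#' A protomer is a single subunit at C-alpha resolution: one coordinate per
#' residue, 1-based residue numbering on the mature sequence, and optional
#' backbone N-H orientation vectors (needed only for anisotropic relaxation
#' analysis).
#'
#' @param residue_ids integer vector, strictly increasing 1-based residue
#'   numbers.
#' @param sequence one-letter amino-acid string (or character vector of
#'   single letters) of the same length as `residue_ids`.
#' @param ca_coords numeric matrix, n x 3, C-alpha coordinates in Angstrom.
#' @param nh_vectors optional numeric matrix, n x 3, unit N-H bond vectors.
#' @param chain_id single character chain identifier.
#' @return object of class `protomer_structure`.
#' @export
protomer_structure <- function(residue_ids, sequence, ca_coords,
                               nh_vectors = NULL, chain_id = "A") {
  residue_ids <- as.integer(residue_ids)
  if (length(residue_ids) == 0L) stop("empty structure")
  if (any(diff(residue_ids) <= 0L))
    stop("residue_ids must be strictly increasing")
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  sequence <- as.character(sequence)
  if (length(sequence) != length(residue_ids))
    stop("sequence length does not match residue count")
  ca_coords <- as.matrix(ca_coords)
  if (!is.numeric(ca_coords) || ncol(ca_coords) != 3L ||
      nrow(ca_coords) != length(residue_ids))
    stop("ca_coords must be a numeric n x 3 matrix, one row per residue")
  dimnames(ca_coords) <- NULL
  if (!is.null(nh_vectors)) {
    nh_vectors <- as.matrix(nh_vectors)
    if (nrow(nh_vectors) != length(residue_ids) || ncol(nh_vectors) != 3L)
      stop("nh_vectors must be n x 3")
    nrm <- sqrt(rowSums(nh_vectors^2))
    if (any(abs(nrm - 1) > 1e-6))
      stop("nh_vectors must be unit vectors (|v| = 1 within 1e-6)")
    dimnames(nh_vectors) <- NULL
  }
  structure(list(residue_ids = residue_ids, sequence = sequence,
                 ca_coords = ca_coords, nh_vectors = nh_vectors,
                 chain_id = as.character(chain_id)),
            class = "protomer_structure")
}

#' @export
#' @method print protomer_structure
print.protomer_structure <- function(x, ...) {
  cat(sprintf("<protomer_structure> %d residues (%d-%d), chain %s%s\n",
              length(x$residue_ids), min(x$residue_ids), max(x$residue_ids),
              x$chain_id,
              if (is.null(x$nh_vectors)) "" else ", with N-H vectors"))
  invisible(x)
}

n_residues <- function(x) length(x$residue_ids)

#' Construct a structure ensemble
#'
#' A set of models (protomers or filaments) sharing residue numbering and
#' sequence, e.g. independently refined copies of the same structure.
#'
#' @param models list of `protomer_structure` or `filament_model` objects.
#' @param label free-text label.
#' @return object of class `structure_ensemble`.
#' @export
structure_ensemble <- function(models, label = "") {
  if (!is.list(models) || length(models) < 1L) stop("models must be a non-empty list")
  ref <- coords_of(models[[1L]])
  for (m in models[-1L]) {
    if (nrow(coords_of(m)) != nrow(ref))
      stop("all ensemble members must have the same atom count")
  }
  structure(list(models = models, label = label), class = "structure_ensemble")
}

#' @export
#' @method print structure_ensemble
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("<structure_ensemble> %d models of %d atoms%s\n",
              length(x$models), nrow(coords_of(x$models[[1L]])),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Extract the full C-alpha coordinate matrix of a model
#'
#' For a protomer this is its coordinate matrix; for a filament the
#' subunit blocks are stacked in subunit order.
#'
#' @param model `protomer_structure` or `filament_model`.
#' @return numeric matrix, total atoms x 3.
#' @export
coords_of <- function(model) {
  if (inherits(model, "protomer_structure")) return(model$ca_coords)
  if (inherits(model, "filament_model")) return(do.call(rbind, model$subunit_coords))
  if (is.matrix(model) && ncol(model) == 3L) return(model)
  stop("cannot extract coordinates from object of class ",
       paste(class(model), collapse = "/"))
}

# ---- PDB-format I/O (minimal fixed-width ATOM dialect, CA-level) ----------

.parse_pdb_atoms <- function(lines) {
  rec <- lines[startsWith(lines, "ATOM")]
  if (length(rec) == 0L) stop("no ATOM records found")
  data.frame(
    name    = trimws(substr(rec, 13, 16)),
    altloc  = substr(rec, 17, 17),
    resname = trimws(substr(rec, 18, 20)),
    chain   = substr(rec, 22, 22),
    resseq  = as.integer(substr(rec, 23, 26)),
    icode   = substr(rec, 27, 27),
    x = as.numeric(substr(rec, 31, 38)),
    y = as.numeric(substr(rec, 39, 46)),
    z = as.numeric(substr(rec, 47, 54)),
    stringsAsFactors = FALSE)
}

#' Read a structure from a PDB-format file
#'
#' Parses ATOM records at C-alpha level. A single-chain file yields a
#' `protomer_structure`; a multi-chain file with identical chain lengths
#' yields a `filament_model` whose subunits follow file order. Insertion
#' codes are rejected; for duplicate altlocs the first is kept with a
#' warning.
#'
#' @param path PDB file path.
#' @param ca_only logical; CA atoms are always what is returned, but with
#'   `ca_only = FALSE` the parser additionally checks that every residue
#'   present in the file carries a CA atom, erroring otherwise.
#' @return `protomer_structure` or `filament_model`.
#' @export
read_structure <- function(path, ca_only = TRUE) {
  at <- .parse_pdb_atoms(readLines(path))
  if (any(at$icode != " "))
    stop("insertion codes are not supported")
  if (!ca_only) {
    key <- paste(at$chain, at$resseq)
    has_ca <- tapply(at$name == "CA", key, any)
    if (!all(has_ca)) {
      bad <- names(has_ca)[!has_ca][1L]
      stop("residue ", sub("^. ", "", bad), " (chain ",
           substr(bad, 1, 1), ") lacks a CA atom")
    }
  }
  ca <- at[at$name == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no CA atoms found")
  key <- paste(ca$chain, ca$resseq)
  if (anyDuplicated(key)) {
    warning("duplicate altloc CA records; keeping first occurrence")
    ca <- ca[!duplicated(key), , drop = FALSE]
  }
  chains <- unique(ca$chain)
  mk <- function(sub, chain) {
    protomer_structure(
      residue_ids = sub$resseq,
      sequence = unname(ifelse(sub$resname %in% names(.AA1),
                               .AA1[sub$resname], "X")),
      ca_coords = cbind(sub$x, sub$y, sub$z),
      chain_id = chain)
  }
  if (length(chains) == 1L) return(mk(ca, chains))
  subs <- lapply(chains, function(ch) ca[ca$chain == ch, , drop = FALSE])
  len <- vapply(subs, nrow, 1L)
  if (length(unique(len)) != 1L)
    stop("chains have different lengths; not a symmetric filament")
  protomer <- mk(subs[[1L]], chains[1L])
  filament_model(protomer = protomer, params = NULL,
                 n_subunits = length(chains),
                 subunit_coords = lapply(subs, function(s) cbind(s$x, s$y, s$z)))
}

.CHAIN_IDS <- c(LETTERS, letters, 0:9)

#' Write a structure to a PDB-format file
#'
#' Filament subunits become successive chains (A-Z, a-z, 0-9; at most 62).
#' Round-trip through [read_structure()] reproduces coordinates to the PDB
#' fixed-width precision of 1e-3 Angstrom.
#'
#' @param model `protomer_structure` or `filament_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  if (inherits(model, "protomer_structure")) {
    blocks <- list(model$ca_coords)
    chains <- model$chain_id
  } else if (inherits(model, "filament_model")) {
    blocks <- model$subunit_coords
    if (length(blocks) > length(.CHAIN_IDS))
      stop("more than ", length(.CHAIN_IDS), " subunits: chain-id overflow")
    chains <- .CHAIN_IDS[seq_along(blocks)]
  } else stop("model must be a protomer_structure or filament_model")
  prot <- if (inherits(model, "filament_model")) model$protomer else model
  res3 <- unname(.AA3[ifelse(prot$sequence %in% names(.AA3), prot$sequence, "X")])
  n <- nrow(blocks[[1L]])
  out <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    xyz <- blocks[[b]]
    lines <- sprintf(
      "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      (b - 1L) * n + seq_len(n), res3, chains[b], prot$residue_ids,
      xyz[, 1L], xyz[, 2L], xyz[, 3L])
    out[[b]] <- c(lines, "TER")
  }
  writeLines(c(unlist(out), "END"), path)
  invisible(path)
}
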