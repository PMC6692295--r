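# Helical filament construction. Convention: positive twist is a
# counter-clockwise rotation when viewed from +Z looking down; a 1-start
# right-handed helix has positive twist together with positive rise.

#' Helical symmetry parameters
#'
#' @param rise axial rise per subunit along +Z, Angstrom (> 0).
#' @param twist rotation per subunit about +Z, degrees, signed
#'   (counter-clockwise positive viewed from +Z; |twist| <= 360).
#' @return object of class `helical_params` with a derived `handedness`
#'   flag ("right" for positive twist, "left" for negative).
#' @export
helical_params <- function(rise, twist) {
  if (!is.numeric(rise) || rise <= 0) stop("rise must be > 0")
  if (!is.numeric(twist) || abs(twist) > 360) stop("|twist| must be <= 360")
  structure(list(rise = rise, twist = twist,
                 handedness = if (twist >= 0) "right" else "left"),
            class = "helical_params")
}

.rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3L, 3L)
}

# apply k steps of the screw operator to an n x 3 coordinate block
.screw <- function(xyz, params, k) {
  out <- xyz %*% t(.rot_z(k * params$twist))
  out[, 3L] <- out[, 3L] + k * params$rise
  out
}

#' Build a helical filament from a protomer
#'
#' Subunit k (0-based) carries the protomer coordinates rotated by
#' `k * twist` about +Z and translated by `k * rise` along +Z; subunit 0 is
#' the input protomer unchanged.
#'
#' @param protomer `protomer_structure`.
#' @param params `helical_params`.
#' @param n_subunits number of subunits (>= 1).
#' @return object of class `filament_model`.
#' @export
build_filament <- function(protomer, params, n_subunits) {
  stopifnot(inherits(protomer, "protomer_structure"),
            inherits(params, "helical_params"))
  n_subunits <- as.integer(n_subunits)
  if (is.na(n_subunits) || n_subunits < 1L) stop("n_subunits must be >= 1")
  blocks <- lapply(seq_len(n_subunits) - 1L,
                   function(k) .screw(protomer$ca_coords, params, k))
  filament_model(protomer, params, n_subunits, blocks)
}

#' @rdname build_filament
#' @param subunit_coords list of per-subunit coordinate blocks (internal
#'   constructor; use [build_filament()] to generate them from symmetry).
#' @export
filament_model <- function(protomer, params, n_subunits, subunit_coords) {
  if (length(subunit_coords) != n_subunits) stop("subunit count mismatch")
  n <- vapply(subunit_coords, nrow, 1L)
  if (length(unique(n)) != 1L) stop("subunits differ in length")
  structure(list(protomer = protomer, params = params,
                 n_subunits = as.integer(n_subunits),
                 subunit_coords = subunit_coords),
            class = "filament_model")
}

#' @export
#' @method print filament_model
print.filament_model <- function(x, ...) {
  cat(sprintf("<filament_model> %d subunits x %d residues", x$n_subunits,
              nrow(x$subunit_coords[[1L]])))
  if (!is.null(x$params))
    cat(sprintf(", rise %.2f A, twist %.1f deg (%s-handed)",
                x$params$rise, x$params$twist, x$params$handedness))
  cat("\n")
  invisible(x)
}

# 1-based subunit index of every atom in coords_of(filament) order
subunit_index <- function(filament) {
  n <- nrow(filament$subunit_coords[[1L]])
  rep(seq_len(filament$n_subunits), each = n)
}

# residue id of every atom in coords_of(filament) order
residue_index <- function(filament) {
  rep(filament$protomer$residue_ids, times = filament$n_subunits)
}

#' Select an axial slice of a filament around a central subunit
#'
#' Returns the indices (into `coords_of(filament)`) of all atoms whose z
#' coordinate lies within `margin_z` of the central subunit's own z-range,
#' i.e. inside the box `[zmin(central) - margin_z, zmax(central) + margin_z]`.
#' Every atom of the central subunit is always included.
#'
#' @param filament `filament_model`.
#' @param central_index 0-based subunit index of the central subunit.
#' @param margin_z box margin along Z, Angstrom (>= 0).
#' @return list with `atom_idx` (integer indices), `z_range`, and
#'   `central_atom_idx` (indices of the central subunit's atoms within the
#'   selection).
#' @export
slice_filament <- function(filament, central_index, margin_z = 15) {
  stopifnot(inherits(filament, "filament_model"))
  if (central_index < 0 || central_index >= filament$n_subunits)
    stop("central_index out of range")
  if (margin_z < 0) stop("margin_z must be >= 0")
  xyz <- coords_of(filament)
  cen <- which(subunit_index(filament) == central_index + 1L)
  zr <- range(xyz[cen, 3L])
  lo <- zr[1L] - margin_z
  hi <- zr[2L] + margin_z
  idx <- which(xyz[, 3L] >= lo & xyz[, 3L] <= hi)
  list(atom_idx = idx, z_range = c(lo, hi),
       central_atom_idx = match(cen, idx))
}

#' Per-interface RMSD of consecutive dimers
#'
#' Validates a filament's helical symmetry: each consecutive dimer
#' (k, k+1) is superposed onto dimer (0, 1) and the C-alpha RMSD recorded.
#' For an exactly symmetric construction all values are ~0.
#'
#' @param filament `filament_model` with at least 3 subunits.
#' @return numeric vector of length `n_subunits - 1`, one value per
#'   consecutive dimer (the first is the self-comparison of dimer (0,1)).
#' @export
consecutive_interface_rmsd <- function(filament) {
  stopifnot(inherits(filament, "filament_model"))
  if (filament$n_subunits < 3L) stop("need at least 3 subunits")
  dimer <- function(k) rbind(filament$subunit_coords[[k + 1L]],
                             filament$subunit_coords[[k + 2L]])
  ref <- dimer(0L)
  vapply(seq_len(filament$n_subunits - 1L) - 1L, function(k) {
    kabsch_superpose(dimer(k), ref)$rmsd
  }, numeric(1L))
}
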