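# Voxelization of the solvent-excluded volume and the lysine/N-terminus
# accessibility test. Conventions:
#   * voxel (1,1,1) has its center at `origin`; voxel i center = origin+(i-1)*h
#   * atoms map to the nearest voxel, ties broken toward the lower index
#   * sphere radii are rounded to the nearest multiple of the voxel size,
#     ties upward, so borderline-exposed residues are not lost to grid blur

.round_to_voxel <- function(r, voxel_size) {
  floor(r / voxel_size + 0.5) * voxel_size
}

# nearest voxel index (1-based); tie at half-way goes to the lower index
.coord_to_voxel <- function(xyz, origin, voxel_size) {
  d <- sweep(xyz, 2L, origin) / voxel_size
  idx <- ceiling(d - 0.5) + 1L
  storage.mode(idx) <- "integer"
  idx
}

.voxel_center <- function(idx, origin, voxel_size) {
  sweep((idx - 1) * voxel_size, 2L, origin, "+")
}

# integer offsets within a sphere of radius k voxels (k = r/voxel_size)
.sphere_offsets <- function(k) {
  s <- -k:k
  g <- as.matrix(expand.grid(dx = s, dy = s, dz = s))
  g[rowSums(g^2) <= k^2 + 1e-9, , drop = FALSE]
}

.linear_index <- function(idx, dims) {
  (idx[, 1L]) + (idx[, 2L] - 1L) * dims[1L] +
    (idx[, 3L] - 1L) * dims[1L] * dims[2L]
}

# Atoms excluded from solvent-excluded-volume marking: the crosslinker
# attachment sites must not block themselves. Excluded are (a) lysine side
# chains (CB..NZ); (b) side-chain atoms of each chain's first residue plus its
# CA (the N-terminus is probed at the CA, whose own sphere would otherwise
# always bury it); (c) the CA of lysines whose side chain is missing, for the
# same reason (the accessibility probe falls back to the CA there).
.expansion_excluded <- function(atoms, nterm) {
  lys_side <- atoms$resname == "LYS" &
    atoms$name %in% c("CB", "CG", "CD", "CE", "NZ")
  backbone <- c("N", "C", "O", "OXT")
  first_res <- atoms$resno == nterm[atoms$chain]
  nterm_excl <- first_res & !(atoms$name %in% backbone)
  key <- paste(atoms$chain, atoms$resno)
  lys_with_nz <- unique(key[atoms$resname == "LYS" & atoms$name == "NZ"])
  lys_ca_fallback <- atoms$resname == "LYS" & atoms$name == "CA" &
    !(key %in% lys_with_nz)
  lys_side | nterm_excl | lys_ca_fallback
}

#' Voxelize a structure's solvent-excluded volume
#'
#' Places the structure on a regular grid (atom bounding box plus padding) and
#' marks every voxel within `vdw(element) + probe_increment` (rounded to the
#' nearest voxel size, ties up) of a non-excluded atom as occupied. Lysine
#' side-chain atoms (CB, CG, CD, CE, NZ) and the side chain of each chain's
#' N-terminal residue are excluded from the expansion so that the crosslinker
#' attachment sites do not bury themselves.
#'
#' @param structure An [xl_structure()].
#' @param voxel_size Grid spacing in Angstrom (default 1).
#' @param vdw Van der Waals radii table, see [vdw_table()].
#' @param probe_increment Radius increment in Angstrom added to every atomic
#'   radius; default half the water vdW radius, [water_probe_increment()].
#' @return Object of class `xl_grid`: list(origin, voxel_size, dims,
#'   occupancy (logical array), padding, probe_increment).
#' @export
build_grid <- function(structure, voxel_size = 1, vdw = vdw_table(),
                       probe_increment = water_probe_increment()) {
  stopifnot(voxel_size > 0)
  atoms <- structure$atoms
  if (!nrow(atoms)) stop("structure has no atoms")

  radii <- .round_to_voxel(vdw_radius(atoms$element, vdw) + probe_increment,
                           voxel_size)
  max_k <- max(radii) / voxel_size
  pad <- max(4, max_k + 1)

  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  lo <- apply(xyz, 2L, min)
  hi <- apply(xyz, 2L, max)
  origin <- lo - pad * voxel_size
  dims <- ceiling((hi - origin) / voxel_size - 0.5) + 1L + pad
  dims <- as.integer(pmax(dims, 1L))

  occ <- array(FALSE, dim = dims)
  keep <- !.expansion_excluded(atoms, structure$nterm)
  if (any(keep)) {
    vox <- .coord_to_voxel(xyz[keep, , drop = FALSE], origin, voxel_size)
    for (k in unique(radii[keep] / voxel_size)) {
      off <- .sphere_offsets(k)
      at <- vox[radii[keep] / voxel_size == k, , drop = FALSE]
      n_at <- nrow(at); n_off <- nrow(off)
      pts <- at[rep(seq_len(n_at), each = n_off), , drop = FALSE] +
        off[rep(seq_len(n_off), times = n_at), , drop = FALSE]
      inb <- pts[, 1L] >= 1L & pts[, 2L] >= 1L & pts[, 3L] >= 1L &
        pts[, 1L] <= dims[1L] & pts[, 2L] <= dims[2L] & pts[, 3L] <= dims[3L]
      occ[unique(.linear_index(pts[inb, , drop = FALSE], dims))] <- TRUE
    }
  }

  structure(list(origin = origin, voxel_size = voxel_size, dims = dims,
                 occupancy = occ, padding = pad,
                 probe_increment = probe_increment),
            class = "xl_grid")
}

#' @export
print.xl_grid <- function(x, ...) {
  cat(sprintf("xl_grid: %d x %d x %d voxels @ %g A (%.1f%% occupied)\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size,
              100 * mean(x$occupancy)))
  invisible(x)
}

#' Find solvent-accessible lysines and N-termini
#'
#' For each lysine a probe sphere of radius `vdw(N) + probe_increment`
#' (rounded like the occupancy spheres) is centred on its NZ atom (falling
#' back to CA when the side chain is missing); each chain N-terminus is probed
#' at its CA. A residue is solvent accessible when at least one voxel inside
#' the sphere is unoccupied; those voxels become the start voxels of the
#' surface path search. Residues with neither NZ nor CA are reported
#' unevaluable and not accessible.
#'
#' @param grid Grid from [build_grid()] on the same structure.
#' @param structure The [xl_structure()] the grid was built from.
#' @param vdw,probe_increment As in [build_grid()].
#' @return Object of class `xl_access`: list with `targets` (data.frame: id,
#'   chain, resno, kind, center_atom, evaluable, accessible), `start_voxels`
#'   (per id, integer matrix of voxel indices), `ca_xyz` (per id, CA
#'   coordinates), `ca_voxel` (per id, linear voxel index of the CA).
#' @export
find_accessible_residues <- function(grid, structure, vdw = vdw_table(),
                                     probe_increment = grid$probe_increment) {
  targets <- crosslinkable_residues(structure)
  if (!nrow(targets)) stop("structure has no lysines or N-termini")
  k <- .round_to_voxel(vdw[["N"]] + probe_increment, grid$voxel_size) /
    grid$voxel_size
  off <- .sphere_offsets(k)

  atoms <- structure$atoms
  ids <- paste(targets$chain, targets$resno, sep = ":")
  start_voxels <- stats::setNames(vector("list", nrow(targets)), ids)
  ca_xyz <- stats::setNames(vector("list", nrow(targets)), ids)
  ca_voxel <- stats::setNames(rep(NA_integer_, nrow(targets)), ids)
  targets$id <- ids
  targets$center_atom <- NA_character_
  targets$evaluable <- FALSE
  targets$accessible <- FALSE

  for (i in seq_len(nrow(targets))) {
    sel <- atoms$chain == targets$chain[i] & atoms$resno == targets$resno[i]
    res_atoms <- atoms[sel, , drop = FALSE]
    ca <- res_atoms[res_atoms$name == "CA", , drop = FALSE]
    nz <- res_atoms[res_atoms$name == "NZ", , drop = FALSE]
    center <- if (targets$kind[i] == "lysine" && nrow(nz)) nz[1L, ] else
      if (nrow(ca)) ca[1L, ] else NULL
    if (is.null(center) || !nrow(ca)) next  # unevaluable: no NZ and/or no CA
    targets$evaluable[i] <- TRUE
    targets$center_atom[i] <- center$name

    ca_xyz[[i]] <- as.numeric(ca[1L, c("x", "y", "z")])
    cav <- .coord_to_voxel(matrix(ca_xyz[[i]], 1L), grid$origin,
                           grid$voxel_size)
    cav <- pmin(pmax(cav, 1L), matrix(grid$dims, 1L))
    ca_voxel[i] <- .linear_index(cav, grid$dims)

    cvox <- .coord_to_voxel(matrix(as.numeric(center[c("x", "y", "z")]), 1L),
                            grid$origin, grid$voxel_size)
    pts <- sweep(off, 2L, as.integer(cvox), "+")
    inb <- pts[, 1L] >= 1L & pts[, 2L] >= 1L & pts[, 3L] >= 1L &
      pts[, 1L] <= grid$dims[1L] & pts[, 2L] <= grid$dims[2L] &
      pts[, 3L] <= grid$dims[3L]
    lin <- .linear_index(pts[inb, , drop = FALSE], grid$dims)
    free <- lin[!grid$occupancy[lin]]
    if (length(free)) {
      targets$accessible[i] <- TRUE
      start_voxels[[i]] <- sort(free)
    } else {
      start_voxels[[i]] <- integer(0)
    }
  }

  rownames(targets) <- NULL
  structure(list(targets = targets, start_voxels = start_voxels,
                 ca_xyz = ca_xyz, ca_voxel = ca_voxel,
                 voxel_size = grid$voxel_size, dims = grid$dims,
                 origin = grid$origin),
            class = "xl_access")
}

#' @export
print.xl_access <- function(x, ...) {
  t <- x$targets
  cat(sprintf("xl_access: %d targets (%d lysines, %d N-termini); %d accessible\n",
              nrow(t), sum(t$kind == "lysine"), sum(t$kind == "nterm"),
              sum(t$accessible)))
  invisible(x)
}

#' Dump grid occupancy as pseudo-atoms for visual inspection
#'
#' Writes one carbon pseudo-atom per occupied voxel to a PDB file; intended
#' for debugging small grids in a molecular viewer.
#'
#' @param grid An `xl_grid`.
#' @param file Output PDB path.
#' @return Invisibly, the number of occupied voxels written.
#' @export
write_grid_debug <- function(grid, file) {
  lin <- which(grid$occupancy)
  if (length(lin) > 99999L) stop("grid too large for a debug PDB dump")
  idx <- arrayInd(lin, grid$dims)
  xyz <- .voxel_center(idx, grid$origin, grid$voxel_size)
  n_at <- nrow(xyz)
  bio3d::write.pdb(file = file, type = rep("HETATM", n_at),
                   eleno = seq_len(n_at), elety = rep("C", n_at),
                   resid = rep("VOX", n_at), chain = rep("V", n_at),
                   resno = seq_len(n_at), xyz = as.numeric(t(xyz)),
                   o = rep(1, n_at), b = rep(0, n_at), elesy = rep("C", n_at))
  invisible(length(lin))
}
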