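# Synthetic structures with known geometry, and an independent shortest-path
# oracle. The structures are minimal lysine-like residues (full N, CA, C, O,
# CB, CG, CD, CE, NZ) so both the NZ accessibility test and the CA path
# endpoints are exercised; obstacles are carbon lattices dense enough to be
# contiguous at 1 A voxels.

.atom_row <- function(serial, name, element, chain, resno, resname, xyz) {
  data.frame(serial = serial, name = name, altloc = "", resname = resname,
             chain = chain, resno = resno,
             x = xyz[1], y = xyz[2], z = xyz[3],
             occupancy = 1, element = element, record = "ATOM",
             stringsAsFactors = FALSE)
}

# a lysine with its backbone in the plane orthogonal-ish to `dir` and the
# side chain extended along `dir` (unit vector); NZ ends ~6.4 A from CA
.lysine_atoms <- function(ca, dir = c(0, 0, 1), chain = "A", resno = 1L,
                          serial0 = 0L, side_chain = TRUE) {
  dir <- dir / sqrt(sum(dir^2))
  # any unit vector not parallel to dir, for backbone placement
  ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * dir) * dir
  e1 <- e1 / sqrt(sum(e1^2))
  names <- c("N", "CA", "C", "O")
  pos <- list(ca - 1.46 * e1, ca, ca + 1.53 * e1, ca + 1.53 * e1 + 1.23 * dir)
  ele <- c("N", "C", "C", "O")
  if (side_chain) {
    names <- c(names, "CB", "CG", "CD", "CE", "NZ")
    pos <- c(pos, list(ca + 1.5 * dir, ca + 2.8 * dir, ca + 4.1 * dir,
                       ca + 5.4 * dir, ca + 6.4 * dir))
    ele <- c(ele, "C", "C", "C", "C", "N")
  }
  do.call(rbind, lapply(seq_along(names), function(i)
    .atom_row(serial0 + i, names[i], ele[i], chain, resno, "LYS", pos[[i]])))
}

.carbon_lattice <- function(points, chain = "C", resno0 = 500L,
                            serial0 = 9000L) {
  do.call(rbind, lapply(seq_len(nrow(points)), function(i)
    .atom_row(serial0 + i, "C", "C", chain, resno0 + i - 1L, "OBS",
              points[i, ])))
}

# solid ball of carbons on a cubic lattice
.carbon_ball <- function(center, radius, spacing = 1) {
  s <- seq(-radius, radius, by = spacing)
  g <- as.matrix(expand.grid(s, s, s))
  g <- g[rowSums(g^2) <= radius^2, , drop = FALSE]
  sweep(g, 2L, center, "+")
}

#' Generate a synthetic test structure with known geometry
#'
#' @param kind One of:
#'   * `"free_pair"`: two lysines in empty space, CAs `separation` apart;
#'   * `"wall"`: two lysines on opposite sides of a finite carbon slab, so the
#'     surface path must detour around the slab edge;
#'   * `"buried"`: one lysine whose NZ is encased in a solid carbon shell
#'     (non-accessible) plus one free lysine;
#'   * `"helix"`: an ideal alpha-helix of lysines (round-trip / parsing
#'     fixture);
#'   * `"perturbed_ensemble"`: a reference "protein" (lysines on a sphere
#'     around a carbon core) plus models with per-residue Gaussian coordinate
#'     noise of increasing magnitude, standing in for comparative models of
#'     decreasing quality.
#' @param separation CA-CA separation in Angstrom (free_pair, wall).
#' @param wall_halfwidth Half-extent of the slab in y and z (wall).
#' @param shell_radius Radius of the carbon ball encasing the buried NZ.
#' @param n_residues Residue count (helix: helix length; perturbed_ensemble:
#'   lysines on the sphere).
#' @param n_models,sigma_max Ensemble size and largest per-coordinate noise SD
#'   (perturbed_ensemble; sigmas are evenly spaced from 0 to `sigma_max`).
#' @param sphere_radius CA sphere radius of the reference (perturbed_ensemble).
#' @param seed Seed for the ensemble noise (generation is deterministic given
#'   the seed).
#' @return List with `structure` (an [xl_structure()]; for
#'   `perturbed_ensemble` also `models`, a list of structures) and `truth`, a
#'   list of ground-truth annotations (true CA separations, detour bound,
#'   buried residue id, per-model noise sigma).
#' @export
make_fixture <- function(kind = c("free_pair", "wall", "buried", "helix",
                                  "perturbed_ensemble"),
                         separation = 10, wall_halfwidth = 10,
                         shell_radius = 4, n_residues = 10, n_models = 50,
                         sigma_max = 15, sphere_radius = 12, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(separation > 0, wall_halfwidth > 0, shell_radius > 0)

  if (kind == "free_pair") {
    atoms <- rbind(
      .lysine_atoms(c(0, 0, 0), c(0, 0, 1), resno = 1L, serial0 = 0L),
      .lysine_atoms(c(separation, 0, 0), c(0, 0, 1), resno = 5L, serial0 = 100L)
    )
    return(list(structure = xl_structure(atoms),
                truth = list(ca_separation = separation,
                             pair = c("A:1", "A:5"))))
  }

  if (kind == "wall") {
    half <- separation / 2
    atoms <- rbind(
      .lysine_atoms(c(-half, 0, 0), c(-1, 0, 0), resno = 1L, serial0 = 0L),
      .lysine_atoms(c(half, 0, 0), c(1, 0, 0), resno = 5L, serial0 = 100L)
    )
    s <- seq(-wall_halfwidth, wall_halfwidth, by = 2)
    slab <- as.matrix(expand.grid(x = 0, y = s, z = s))
    atoms <- rbind(atoms, .carbon_lattice(slab))
    # any solvent path must clear the slab edge at |y| or |z| > wall_halfwidth
    detour_lb <- 2 * sqrt(half^2 + wall_halfwidth^2)
    return(list(structure = xl_structure(atoms),
                truth = list(ca_separation = separation,
                             detour_lower_bound = detour_lb,
                             pair = c("A:1", "A:5"))))
  }

  if (kind == "buried") {
    atoms <- rbind(
      .lysine_atoms(c(0, 0, 0), c(0, 0, 1), resno = 1L, serial0 = 0L),
      .lysine_atoms(c(16, 0, 0), c(0, 0, 1), resno = 5L, serial0 = 100L)
    )
    nz <- c(0, 0, 6.4)
    ball <- .carbon_ball(nz, shell_radius, spacing = 1)
    atoms <- rbind(atoms, .carbon_lattice(ball))
    return(list(structure = xl_structure(atoms),
                truth = list(buried = "A:1", free = "A:5")))
  }

  if (kind == "helix") {
    rise <- 1.5; radius <- 2.3; twist <- 100 * pi / 180
    atoms <- do.call(rbind, lapply(seq_len(n_residues), function(i) {
      ang <- (i - 1) * twist
      ca <- c(radius * cos(ang), radius * sin(ang), (i - 1) * rise)
      dir <- c(cos(ang), sin(ang), 0)
      .lysine_atoms(ca, dir, resno = i, serial0 = (i - 1L) * 10L)
    }))
    return(list(structure = xl_structure(atoms),
                truth = list(n_residues = n_residues, rise = rise)))
  }

  # perturbed_ensemble
  ref <- .fibonacci_sphere(n_residues) * sphere_radius
  atoms <- do.call(rbind, lapply(seq_len(n_residues), function(i) {
    .lysine_atoms(ref[i, ], ref[i, ], resno = i, serial0 = (i - 1L) * 10L)
  }))
  core <- .carbon_ball(c(0, 0, 0), 5, spacing = 1.5)
  reference <- xl_structure(rbind(atoms, .carbon_lattice(core)))
  sigmas <- seq(0, sigma_max, length.out = n_models)
  models <- .with_seed(seed, lapply(sigmas, function(s) {
    shift <- matrix(stats::rnorm(n_residues * 3, 0, s), n_residues, 3)
    at <- do.call(rbind, lapply(seq_len(n_residues), function(i) {
      .lysine_atoms(ref[i, ] + shift[i, ], ref[i, ], resno = i,
                    serial0 = (i - 1L) * 10L)
    }))
    xl_structure(rbind(at, .carbon_lattice(core)))
  }))
  names(models) <- sprintf("model_%03d", seq_len(n_models))
  list(structure = reference, models = models,
       truth = list(sigma = sigmas, n_residues = n_residues,
                    sphere_radius = sphere_radius, seed = seed))
}

.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Exact grid shortest paths via an independent reference implementation
#'
#' Builds an explicit weighted graph over the free voxels of the grid
#' (26-neighbour moves with Euclidean step costs, or 6-neighbour uniform
#' moves) and solves single-source shortest paths with [igraph::distances()].
#' Entirely independent of the production search; intended for grids up to
#' roughly 64^3 voxels.
#'
#' @param grid An `xl_grid`.
#' @param source Linear voxel index (1-based) of the source; a vector of
#'   sources is allowed (all must be free voxels).
#' @param targets Linear voxel indices of the targets.
#' @param metric `"dijkstra26"` or `"bfs6"` as in [compute_sasd()].
#' @return With a single source, a numeric vector of exact path lengths
#'   (Angstrom; `Inf` when unreachable), one per target; with several sources
#'   a |sources| x |targets| matrix.
#' @export
grid_oracle <- function(grid, source, targets,
                        metric = c("dijkstra26", "bfs6")) {
  metric <- match.arg(metric)
  occ <- as.logical(grid$occupancy)
  if (any(occ[source])) stop("source voxel is occupied")
  dims <- grid$dims
  free <- which(!occ)
  rank <- integer(length(occ))
  rank[free] <- seq_along(free)
  idx <- arrayInd(free, dims)

  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (metric == "bfs6") offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  # only "positive" offsets so each undirected edge is built once
  pos <- offs[, 1] * 100 + offs[, 2] * 10 + offs[, 3] > 0
  offs <- offs[pos, , drop = FALSE]

  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(idx, 2L, offs[r, ], "+")
    inb <- nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1 &
      nb[, 1] <= dims[1] & nb[, 2] <= dims[2] & nb[, 3] <= dims[3]
    lin_nb <- .linear_index(nb[inb, , drop = FALSE], dims)
    ok <- !occ[lin_nb]
    from <- c(from, rank[free[inb]][ok])
    to <- c(to, rank[lin_nb][ok])
    w <- c(w, rep(sqrt(sum(offs[r, ]^2)) * grid$voxel_size, sum(ok)))
  }
  g <- igraph::make_graph(as.vector(rbind(from, to)), n = length(free),
                          directed = FALSE)
  d <- matrix(Inf, length(source), length(targets))
  okt <- rank[targets] != 0  # occupied targets stay unreachable
  if (any(okt))
    d[, okt] <- as.matrix(igraph::distances(g, v = rank[source],
                                            to = rank[targets][okt],
                                            weights = w))
  if (length(source) == 1L) as.numeric(d) else d
}

#' Oracle SASD for one residue pair
#'
#' Reference re-computation of the pair distance using [grid_oracle()]:
#' the minimum over start-voxel combinations of the CA connection costs plus
#' the exact grid path length. Used to cross-check [compute_sasd()].
#'
#' @param grid An `xl_grid`.
#' @param access An `xl_access` on the same grid.
#' @param id_a,id_b Target ids (`"chain:resno"`).
#' @param metric As in [grid_oracle()].
#' @return Distance in Angstrom, or `Inf` when no solvent path exists.
#' @export
sasd_oracle <- function(grid, access, id_a, id_b,
                        metric = c("dijkstra26", "bfs6")) {
  metric <- match.arg(metric)
  sa <- access$start_voxels[[id_a]]
  sb <- access$start_voxels[[id_b]]
  if (!length(sa) || !length(sb)) return(Inf)
  ca_a <- access$ca_xyz[[id_a]]
  ca_b <- access$ca_xyz[[id_b]]
  xa <- .voxel_center(arrayInd(sa, grid$dims), grid$origin, grid$voxel_size)
  xb <- .voxel_center(arrayInd(sb, grid$dims), grid$origin, grid$voxel_size)
  enter <- sqrt(colSums((t(xa) - ca_a)^2))
  exit <- sqrt(colSums((t(xb) - ca_b)^2))
  d <- grid_oracle(grid, sa, sb, metric = metric)
  d <- matrix(d, nrow = length(sa))
  min(sweep(sweep(d, 1L, enter, "+"), 2L, exit, "+"))
}
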