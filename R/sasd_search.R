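# Shortest solvent-accessible surface distances between lysines/N-termini.
#
# The distance of a pair (i, j) is
#   min over start voxels s_i, s_j of
#     |CA_i - c(s_i)|  +  grid path length s_i -> s_j  +  |c(s_j) - CA_j|
# with grid paths confined to unoccupied voxels. One multi-seeded search per
# source residue covers all its partners: each of i's start voxels is seeded
# with its Euclidean CA connection as initial cost, so the searched field
# already contains the inner minimum.

.default_metric <- c("dijkstra26", "bfs6")

.targets_needed <- function(access, pairs) {
  t <- access$targets
  if (identical(pairs, "all")) {
    if (nrow(t) < 2) stop("need at least two target residues")
    idx <- t(utils::combn(seq_len(nrow(t)), 2L))
    data.frame(i = idx[, 1L], j = idx[, 2L])
  } else {
    pairs <- as.data.frame(pairs)
    id_a <- paste(pairs$chain_a, pairs$res_a, sep = ":")
    id_b <- paste(pairs$chain_b, pairs$res_b, sep = ":")
    i <- match(id_a, t$id)
    j <- match(id_b, t$id)
    bad <- c(id_a[is.na(i)], id_b[is.na(j)])
    if (length(bad))
      stop("pair references residue(s) not among lysines/N-termini: ",
           paste(unique(bad), collapse = ", "))
    swap <- i > j
    data.frame(i = ifelse(swap, j, i), j = ifelse(swap, i, j))
  }
}

#' Compute solvent accessible surface distances
#'
#' Runs the grid shortest-path search between every requested pair of
#' lysine/N-terminus targets. Pairs with a non-accessible endpoint get status
#' `"nonaccessible_endpoint"`; accessible pairs with no connecting solvent
#' path (or beyond `max_distance`) get `"no_path"`; the rest are `"measured"`.
#'
#' @param grid Grid from [build_grid()].
#' @param access Accessibility map from [find_accessible_residues()] on the
#'   same grid.
#' @param pairs `"all"` for every unordered target pair, or a data.frame with
#'   columns chain_a, res_a, chain_b, res_b.
#' @param max_distance Distances above this are reported as `no_path`
#'   (default `Inf`, i.e. no maximum).
#' @param metric `"dijkstra26"` (default): 26-neighbour moves with Euclidean
#'   step costs; `"bfs6"`: axis moves only, uniform cost, for strict
#'   layer-by-layer breadth-first emulation.
#' @param keep_paths Record the voxel path of each measured pair (needed by
#'   [write_sasd_outputs()]).
#' @return Object of class `xl_sasd`: list with `pairs` (data.frame: id_a,
#'   id_b, chain/res columns, status, distance), `paths` (per pair, matrix of
#'   xyz points CA -> voxels -> CA, when kept), `targets`, `voxel_size`,
#'   `metric`, `max_distance`.
#' @export
compute_sasd <- function(grid, access, pairs = "all", max_distance = Inf,
                         metric = .default_metric, keep_paths = FALSE) {
  metric <- match.arg(metric, .default_metric)
  stopifnot(identical(access$dims, grid$dims))
  t <- access$targets
  want <- .targets_needed(access, pairs)
  # one row per unordered pair, computed from the lower-index endpoint
  want <- unique(want)

  n <- nrow(want)
  status <- character(n)
  distance <- rep(NA_real_, n)
  paths <- if (keep_paths) vector("list", n) else NULL

  occ <- as.logical(grid$occupancy)
  for (src in sort(unique(want$i))) {
    rows <- which(want$i == src)
    js <- want$j[rows]
    if (!t$accessible[src]) {
      status[rows] <- "nonaccessible_endpoint"
      next
    }
    acc_j <- t$accessible[js]
    status[rows[!acc_j]] <- "nonaccessible_endpoint"
    rows <- rows[acc_j]
    js <- js[acc_j]
    if (!length(rows)) next

    seeds <- access$start_voxels[[src]]
    seed_xyz <- .voxel_center(arrayInd(seeds, grid$dims), grid$origin,
                              grid$voxel_size)
    ca_src <- access$ca_xyz[[src]]
    seed_costs <- sqrt(colSums((t(seed_xyz) - ca_src)^2))
    stop_at <- unique(unlist(access$start_voxels[js]))
    res <- .grid_search_cpp(occ, grid$dims, seeds, seed_costs,
                            grid$voxel_size, metric == "dijkstra26", stop_at)

    for (rix in seq_along(rows)) {
      jj <- js[rix]
      sv <- access$start_voxels[[jj]]
      sv_xyz <- .voxel_center(arrayInd(sv, grid$dims), grid$origin,
                              grid$voxel_size)
      ca_j <- access$ca_xyz[[jj]]
      exit_cost <- sqrt(colSums((t(sv_xyz) - ca_j)^2))
      total <- res$dist[sv] + exit_cost
      best <- which.min(total)
      d <- total[best]
      if (!length(d) || !is.finite(d) || d > max_distance) {
        status[rows[rix]] <- "no_path"
        next
      }
      status[rows[rix]] <- "measured"
      distance[rows[rix]] <- d
      if (keep_paths) {
        vox_path <- sv[best]
        repeat {
          p <- res$pred[vox_path[1L]]
          if (is.na(p)) break
          vox_path <- c(p, vox_path)
        }
        pts <- .voxel_center(arrayInd(vox_path, grid$dims), grid$origin,
                             grid$voxel_size)
        paths[[rows[rix]]] <- rbind(ca_src, pts, ca_j, deparse.level = 0)
      }
    }
  }

  out <- data.frame(
    id_a = t$id[want$i], id_b = t$id[want$j],
    chain_a = t$chain[want$i], res_a = t$resno[want$i],
    chain_b = t$chain[want$j], res_b = t$resno[want$j],
    status = status, distance = distance, stringsAsFactors = FALSE
  )
  if (keep_paths) names(paths) <- paste(out$id_a, out$id_b, sep = "-")
  structure(list(pairs = out, paths = paths, targets = t,
                 voxel_size = grid$voxel_size, metric = metric,
                 max_distance = max_distance),
            class = "xl_sasd")
}

#' @export
print.xl_sasd <- function(x, ...) {
  s <- table(factor(x$pairs$status,
                    levels = c("measured", "nonaccessible_endpoint", "no_path")))
  cat(sprintf(
    "xl_sasd (%s, %g A voxels): %d pairs - %d measured, %d nonaccessible, %d no path\n",
    x$metric, x$voxel_size, nrow(x$pairs), s[["measured"]],
    s[["nonaccessible_endpoint"]], s[["no_path"]]))
  invisible(x)
}

#' Straight-line Calpha-Calpha distances between crosslinkable residues
#'
#' @param structure An [xl_structure()].
#' @param surface_only When TRUE, pairs involving a residue that is not
#'   solvent accessible (per `access`) are flagged `nonaccessible_endpoint`
#'   instead of measured.
#' @param access Required when `surface_only = TRUE`: an
#'   [find_accessible_residues()] result for the structure.
#' @param pairs `"all"` or a data.frame as in [compute_sasd()].
#' @return An object of class `xl_sasd` (same layout; `metric` records the
#'   Euclidean mode) so it can be passed to the scoring functions.
#' @export
euclidean_distances <- function(structure, surface_only = FALSE, access = NULL,
                                pairs = "all") {
  targets <- crosslinkable_residues(structure)
  targets$id <- paste(targets$chain, targets$resno, sep = ":")
  a <- structure$atoms
  ca_list <- lapply(seq_len(nrow(targets)), function(i) {
    sel <- a$chain == targets$chain[i] & a$resno == targets$resno[i] &
      a$name == "CA"
    if (!any(sel)) return(NULL)
    as.numeric(a[which(sel)[1L], c("x", "y", "z")])
  })
  has_ca <- !vapply(ca_list, is.null, logical(1))
  if (any(!has_ca))
    warning("skipping residue(s) without CA: ",
            paste(targets$id[!has_ca], collapse = ", "))
  targets <- targets[has_ca, , drop = FALSE]
  ca <- do.call(rbind, ca_list[has_ca])

  if (surface_only) {
    if (is.null(access)) stop("surface_only = TRUE requires an access map")
    acc <- access$targets$accessible[match(targets$id, access$targets$id)]
    acc[is.na(acc)] <- FALSE
  } else {
    acc <- rep(TRUE, nrow(targets))
  }
  targets$accessible <- acc
  targets$evaluable <- TRUE

  fake_access <- list(targets = targets)
  want <- .targets_needed(fake_access, pairs)
  want <- unique(want)
  d <- sqrt(rowSums((ca[want$i, , drop = FALSE] -
                       ca[want$j, , drop = FALSE])^2))
  ok <- acc[want$i] & acc[want$j]
  out <- data.frame(
    id_a = targets$id[want$i], id_b = targets$id[want$j],
    chain_a = targets$chain[want$i], res_a = targets$resno[want$i],
    chain_b = targets$chain[want$j], res_b = targets$resno[want$j],
    status = ifelse(ok, "measured", "nonaccessible_endpoint"),
    distance = ifelse(ok, d, NA_real_), stringsAsFactors = FALSE
  )
  structure(list(pairs = out, paths = NULL, targets = targets,
                 voxel_size = NA_real_,
                 metric = if (surface_only) "euclidean_surface" else "euclidean_all",
                 max_distance = Inf),
            class = "xl_sasd")
}

#' Write SASD results to a distance list and a path PDB
#'
#' The list file is tab-separated (`#`-prefixed provenance header, then
#' chain_a res_a chain_b res_b status distance) with distances to 2 decimals.
#' The path file is a PDB with one pseudo-atom chain per measured pair tracing
#' CA -> surface voxels -> CA; pairs without a path emit no chain.
#'
#' @param result An `xl_sasd` computed with `keep_paths = TRUE` if
#'   `paths_path` is given.
#' @param list_path Output path for the distance list (TSV).
#' @param paths_path Optional output path for the path pseudo-atom PDB.
#' @param header Extra `#` header lines to prepend.
#' @return Invisibly, `list_path`.
#' @export
write_sasd_outputs <- function(result, list_path, paths_path = NULL,
                               header = character(0)) {
  p <- result$pairs
  if (!nrow(p)) stop("empty SASD result")
  con <- file(list_path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c(sprintf("# xlwalk %s sasd list; voxel_size=%s; metric=%s",
                       as.character(utils::packageVersion("xlwalk")),
                       format(result$voxel_size), result$metric),
               header), con)
  writeLines(paste("chain_a", "res_a", "chain_b", "res_b", "status",
                   "sasd_A", sep = "\t"), con)
  writeLines(paste(p$chain_a, p$res_a, p$chain_b, p$res_b, p$status,
                   ifelse(is.na(p$distance), "NA",
                          sprintf("%.2f", p$distance)), sep = "\t"), con)

  if (!is.null(paths_path)) {
    if (is.null(result$paths))
      stop("result has no paths; rerun compute_sasd(keep_paths = TRUE)")
    chains <- c(LETTERS, letters, 0:9)
    measured <- which(p$status == "measured")
    xyz <- NULL; chain <- NULL; resno <- NULL
    for (k in seq_along(measured)) {
      pt <- result$paths[[measured[k]]]
      xyz <- rbind(xyz, pt)
      chain <- c(chain, rep(chains[(k - 1L) %% length(chains) + 1L], nrow(pt)))
      resno <- c(resno, seq_len(nrow(pt)))  # one residue per path point
    }
    if (is.null(xyz)) {
      writeLines("END", paths_path)
    } else {
      n_at <- nrow(xyz)
      bio3d::write.pdb(file = paths_path, type = rep("ATOM", n_at),
                       eleno = seq_len(n_at), elety = rep("C", n_at),
                       resid = rep("PTH", n_at), chain = chain, resno = resno,
                       xyz = as.numeric(t(xyz)), o = rep(1, n_at),
                       b = rep(0, n_at), elesy = rep("C", n_at))
    }
  }
  invisible(list_path)
}

#' Read back a SASD list written by [write_sasd_outputs()]
#'
#' @param file Path to the TSV list.
#' @return data.frame with the pair, status and distance columns.
#' @export
read_sasd_list <- function(file) {
  utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
}

#' Extract a named distance lookup from an `xl_sasd`
#'
#' Names are canonical pair keys (`chain:res-chain:res`, endpoints ordered
#' lexicographically by chain then residue number) so lookups are independent
#' of endpoint order.
#'
#' @param result An `xl_sasd`.
#' @return Named numeric vector, NA where not measured.
#' @keywords internal
sasd_lookup <- function(result) {
  p <- result$pairs
  canon <- .canonical_pairs(p$chain_a, p$res_a, p$chain_b, p$res_b)
  stats::setNames(p$distance,
                  paste(paste(canon$chain_a, canon$res_a, sep = ":"),
                        paste(canon$chain_b, canon$res_b, sep = ":"),
                        sep = "-"))
}
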