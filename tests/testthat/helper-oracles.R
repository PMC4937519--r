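# Independent reference implementations and tiny builders used across tests.
# These deliberately avoid the package's production code paths.

# hand-rolled Kabsch superposition RMSD (oracle for calpha_rmsd)
naive_rmsd <- function(a, b) {
  ca <- sweep(a, 2, colMeans(a))
  cb <- sweep(b, 2, colMeans(b))
  s <- svd(t(cb) %*% ca)
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((cb %*% rot - ca)^2)))
}

# one PDB ATOM line, fixed-column format
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, altloc = " ", element = NULL) {
  if (is.null(element)) element <- substr(trimws(name), 1, 1)
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, altloc, resname, chain, resno, x, y, z, occ, 0,
          element)
}

# atom-table row for building xl_structure objects directly
atom_df <- function(serial, name, element, chain, resno, resname, xyz,
                    occ = 1, altloc = "") {
  data.frame(serial = serial, name = name, altloc = altloc, resname = resname,
             chain = chain, resno = resno, x = xyz[1], y = xyz[2], z = xyz[3],
             occupancy = occ, element = element, record = "ATOM",
             stringsAsFactors = FALSE)
}

# a minimal lysine (full side chain along +dir); independent of the package's
# internal fixture geometry helpers
lys_df <- function(ca, dir = c(0, 0, 1), chain = "A", resno = 1L,
                   serial0 = 0L, side_chain = TRUE) {
  dir <- dir / sqrt(sum(dir^2))
  ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * dir) * dir
  e1 <- e1 / sqrt(sum(e1^2))
  rows <- list(
    atom_df(serial0 + 1, "N", "N", chain, resno, "LYS", ca - 1.46 * e1),
    atom_df(serial0 + 2, "CA", "C", chain, resno, "LYS", ca),
    atom_df(serial0 + 3, "C", "C", chain, resno, "LYS", ca + 1.53 * e1),
    atom_df(serial0 + 4, "O", "O", chain, resno, "LYS",
            ca + 1.53 * e1 + 1.23 * dir)
  )
  if (side_chain) {
    sc <- list(c("CB", 1.5), c("CG", 2.8), c("CD", 4.1), c("CE", 5.4),
               c("NZ", 6.4))
    for (i in seq_along(sc)) {
      rows <- c(rows, list(atom_df(serial0 + 4 + i, sc[[i]][1],
                                   substr(sc[[i]][1], 1, 1), chain, resno,
                                   "LYS", ca + as.numeric(sc[[i]][2]) * dir)))
    }
  }
  do.call(rbind, rows)
}

# a bare single-atom "lysine" (CA only) -- exercises the CA fallback
bare_lys_df <- function(ca, chain = "A", resno = 1L, serial = 1L) {
  atom_df(serial, "CA", "C", chain, resno, "LYS", ca)
}

# named pair -> distance lookup (test-side mirror of the internal helper)
sasd_lookup_test <- function(res) {
  stats::setNames(res$pairs$distance,
                  paste(res$pairs$id_a, res$pairs$id_b, sep = "-"))
}

# a fake distance map shaped like compute_sasd() output, for scoring tests
fake_sasd <- function(df, metric = "sasd") {
  stopifnot(all(c("chain_a", "res_a", "chain_b", "res_b", "distance") %in%
                  names(df)))
  df$id_a <- paste(df$chain_a, df$res_a, sep = ":")
  df$id_b <- paste(df$chain_b, df$res_b, sep = ":")
  if (is.null(df$status))
    df$status <- ifelse(is.na(df$distance), "nonaccessible_endpoint",
                        "measured")
  structure(list(pairs = df, paths = NULL, targets = NULL, voxel_size = 1,
                 metric = metric, max_distance = Inf),
            class = "xl_sasd")
}

# random occupancy grid shaped like build_grid() output
random_grid <- function(dims = c(20, 20, 20), fill = 0.3, seed = 1,
                        voxel_size = 1) {
  set.seed(seed)
  occ <- array(stats::runif(prod(dims)) < fill, dim = dims)
  structure(list(origin = c(0, 0, 0), voxel_size = voxel_size,
                 dims = as.integer(dims), occupancy = occ, padding = 4,
                 probe_increment = 0.7),
            class = "xl_grid")
}

# tiny perturbed ensemble scored with Euclidean distances (fast, no grids);
# returns list(tab, rmsds, theo, dist, cfg, truth_sigma)
euclid_benchmark <- function(n_models = 30, n_res = 8, sigma_max = 10,
                             seed = 7) {
  fx <- make_fixture("perturbed_ensemble", n_models = n_models,
                     n_residues = n_res, sigma_max = sigma_max, seed = seed)
  dist <- compute_model_distances(fx$models, distance_mode = "euclidean_all")
  ref_d <- euclidean_distances(fx$structure)
  theo <- make_theoretical_dataset(ref_d, cutoff = 33)
  fit <- fit_sasd_distribution(
    ref_d$pairs$distance[ref_d$pairs$status == "measured"], 33)
  cfg <- scoring_config(distribution = fit, distance_mode = "euclidean_all")
  rmsds <- vapply(fx$models, calpha_rmsd, numeric(1),
                  reference = fx$structure)
  list(models = fx$models, reference = fx$structure, dist = dist, theo = theo,
       cfg = cfg, rmsds = rmsds, truth_sigma = fx$truth$sigma)
}
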