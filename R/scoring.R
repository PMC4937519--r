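# MNXL and the comparison scores.
#
# Each crosslink of the MS dataset, looked up on a model's distance map, is
# classified as matched (a distance exists) or non-accessible (no distance:
# buried endpoint or no solvent path). Matched crosslinks at or below the
# maximum-bound are rewarded with the normal density fitted to reference
# SASDs; above it they take a flat penalty, as does each non-accessible
# crosslink. Raw MNXL is the sum over the dataset; higher is better.

#' Scoring configuration
#'
#' @param mu,sigma Mean and standard deviation (Angstrom) of the matched-
#'   crosslink SASD distribution; alternatively supply `distribution`.
#' @param distribution A `sasd_normal` from [fit_sasd_distribution()].
#' @param cutoff Maximum-bound in Angstrom (default 33). Distances exactly at
#'   the cutoff count as satisfied.
#' @param penalty_violation Flat score for a matched crosslink above the
#'   cutoff (default -0.1).
#' @param penalty_nonaccessible Flat score per non-accessible crosslink
#'   (default -0.1).
#' @param distance_mode How model distances were computed: `"sasd"`,
#'   `"euclidean_surface"` or `"euclidean_all"` (in the latter the
#'   non-accessible category is empty by construction).
#' @param density Reward function for satisfied crosslinks,
#'   `function(distance, mu, sigma)`; defaults to the plain normal density
#'   [stats::dnorm()]. Swap in a log-density here if preferred.
#' @return Object of class `mnxl_config`.
#' @export
scoring_config <- function(mu = NULL, sigma = NULL, distribution = NULL,
                           cutoff = 33, penalty_violation = -0.1,
                           penalty_nonaccessible = -0.1,
                           distance_mode = c("sasd", "euclidean_surface",
                                             "euclidean_all"),
                           density = function(d, mu, sigma)
                             stats::dnorm(d, mu, sigma)) {
  distance_mode <- match.arg(distance_mode)
  if (!is.null(distribution)) {
    stopifnot(inherits(distribution, "sasd_normal"))
    mu <- distribution$mu
    sigma <- distribution$sigma
  }
  if (is.null(mu) || is.null(sigma))
    stop("supply mu and sigma (or a fitted distribution)")
  if (sigma <= 0) stop("sigma must be > 0")
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (penalty_violation > 0 || penalty_nonaccessible > 0)
    stop("penalties must be <= 0")
  structure(list(mu = mu, sigma = sigma, cutoff = cutoff,
                 penalty_violation = penalty_violation,
                 penalty_nonaccessible = penalty_nonaccessible,
                 distance_mode = distance_mode, density = density),
            class = "mnxl_config")
}

#' @export
print.mnxl_config <- function(x, ...) {
  cat(sprintf(
    "mnxl_config: N(%.2f, %.2f^2), cutoff %g A, penalties %g/%g, mode %s\n",
    x$mu, x$sigma, x$cutoff, x$penalty_violation, x$penalty_nonaccessible,
    x$distance_mode))
  invisible(x)
}

#' Classify the crosslinks of an MS dataset on one model
#'
#' @param dataset An [xl_dataset()] of observed (or theoretical) crosslinks.
#' @param distances An `xl_sasd` for the model, from [compute_sasd()] or
#'   [euclidean_distances()], covering every dataset pair.
#' @param config An [scoring_config()].
#' @return Object of class `xl_classification`: list of data.frames
#'   `matched_ok`, `matched_violating` (each with pair ids and distance) and
#'   `nonaccessible` (pair ids); the three partition the dataset.
#' @export
classify_crosslinks <- function(dataset, distances, config) {
  ds <- as.data.frame(dataset)
  key <- paste(paste(ds$chain_a, ds$res_a, sep = ":"),
               paste(ds$chain_b, ds$res_b, sep = ":"), sep = "-")
  map <- sasd_lookup(distances)
  hit <- match(key, names(map))
  if (anyNA(hit))
    stop("crosslink pair(s) absent from the model distance map: ",
         paste(key[is.na(hit)], collapse = ", "),
         " (models and dataset must share residue numbering)")
  d <- unname(map[hit])
  measured <- !is.na(d)
  ok <- measured & d <= config$cutoff
  viol <- measured & d > config$cutoff
  base <- data.frame(pair = key, distance = d, stringsAsFactors = FALSE)
  structure(list(
    matched_ok = base[ok, , drop = FALSE],
    matched_violating = base[viol, , drop = FALSE],
    nonaccessible = base[!measured, c("pair"), drop = FALSE]
  ), class = "xl_classification")
}

#' @export
print.xl_classification <- function(x, ...) {
  cat(sprintf("xl_classification: %d satisfied, %d violating, %d non-accessible\n",
              nrow(x$matched_ok), nrow(x$matched_violating),
              nrow(x$nonaccessible)))
  invisible(x)
}

#' Score of a single matched crosslink
#'
#' Normal density at the distance when at or below the cutoff, flat violation
#' penalty above it.
#'
#' @param distance Distance(s) in Angstrom (vectorized).
#' @param config An [scoring_config()].
#' @return Numeric score(s).
#' @export
#' @examples
#' cfg <- scoring_config(mu = 20, sigma = 5)
#' score_matched(20, cfg)  # 1 / (5 * sqrt(2 * pi))
#' score_matched(40, cfg)  # -0.1
score_matched <- function(distance, config) {
  stopifnot(all(distance > 0))
  ifelse(distance <= config$cutoff,
         config$density(distance, config$mu, config$sigma),
         config$penalty_violation)
}

#' Raw MNXL score of a model
#'
#' Sum of [score_matched()] over all matched crosslinks (satisfied and
#' violating) plus the flat penalty for each non-accessible crosslink.
#' Higher is better; crosslinkable pairs absent from the MS dataset
#' contribute nothing.
#'
#' @param classification An [classify_crosslinks()] result.
#' @param config An [scoring_config()].
#' @return Raw MNXL (numeric scalar).
#' @export
score_mnxl <- function(classification, config) {
  s <- 0
  if (nrow(classification$matched_ok))
    s <- s + sum(config$density(classification$matched_ok$distance,
                                config$mu, config$sigma))
  s + config$penalty_violation * nrow(classification$matched_violating) +
    config$penalty_nonaccessible * nrow(classification$nonaccessible)
}

#' Number of violations
#'
#' Count of crosslinks whose model distance exceeds the cutoff. Lower is
#' better.
#' @inheritParams score_mnxl
#' @return Integer.
#' @export
score_nov <- function(classification) {
  nrow(classification$matched_violating)
}

#' Sum of violation distances
#'
#' Total excess distance over the cutoff across violating crosslinks
#' (Angstrom). Lower is better.
#' @inheritParams score_mnxl
#' @export
score_sovd <- function(classification, config) {
  v <- classification$matched_violating$distance
  if (!length(v)) return(0)
  sum(v - config$cutoff)
}

#' Number of violations plus non-accessible crosslinks
#'
#' @inheritParams score_mnxl
#' @return Integer; lower is better.
#' @export
score_nov_nonacc <- function(classification) {
  nrow(classification$matched_violating) + nrow(classification$nonaccessible)
}

#' Min-max normalize an ensemble of raw scores
#'
#' Maps the best model to 0 and the worst to 1; an all-equal ensemble maps to
#' all zeros.
#'
#' @param raw Numeric vector of raw scores, one per model.
#' @param orientation `"higher_better"` (MNXL) or `"lower_better"` (NoV,
#'   SoVD).
#' @return Numeric vector in `[0, 1]`.
#' @export
#' @examples
#' normalize_ensemble(c(5, 3, 1), "higher_better")  # 0, 0.5, 1
normalize_ensemble <- function(raw,
                               orientation = c("higher_better", "lower_better")) {
  orientation <- match.arg(orientation)
  if (!length(raw)) stop("empty ensemble")
  x <- if (orientation == "higher_better") -raw else raw
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Score an ensemble of models against a crosslink dataset
#'
#' Convenience driver: classifies the dataset on each model's distance map and
#' tabulates raw MNXL, NoV, SoVD, NoV+non-accessible, category counts and the
#' ensemble-normalized MNXL.
#'
#' @param distances List of `xl_sasd` objects, one per model (see
#'   [compute_model_distances()]).
#' @param dataset An [xl_dataset()].
#' @param config An [scoring_config()].
#' @return data.frame, one row per model, with attribute
#'   `"classifications"` (the per-model [classify_crosslinks()] results).
#' @export
score_models <- function(distances, dataset, config) {
  cls <- lapply(distances, classify_crosslinks, dataset = dataset,
                config = config)
  out <- data.frame(
    model = if (!is.null(names(distances))) names(distances)
            else sprintf("model_%03d", seq_along(distances)),
    raw_mnxl = vapply(cls, score_mnxl, numeric(1), config = config),
    nov = vapply(cls, score_nov, integer(1)),
    sovd = vapply(cls, score_sovd, numeric(1), config = config),
    nov_nonacc = vapply(cls, score_nov_nonacc, integer(1)),
    matched_count = vapply(cls, function(x)
      nrow(x$matched_ok) + nrow(x$matched_violating), integer(1)),
    violating_count = vapply(cls, function(x)
      nrow(x$matched_violating), integer(1)),
    nonaccessible_count = vapply(cls, function(x)
      nrow(x$nonaccessible), integer(1)),
    stringsAsFactors = FALSE
  )
  out$mnxl_norm <- normalize_ensemble(out$raw_mnxl, "higher_better")
  attr(out, "classifications") <- cls
  out
}

#' Compute per-model distance maps for a crosslink dataset
#'
#' For each model structure, builds the grid, runs the accessibility test and
#' computes the distances the dataset needs, in the configured distance mode.
#'
#' @param models List of [xl_structure()] objects (or a character vector of
#'   PDB paths).
#' @param dataset Optional [xl_dataset()]; when given, only its pairs are
#'   computed, otherwise all target pairs.
#' @param distance_mode As in [scoring_config()].
#' @param voxel_size,vdw,probe_increment Grid parameters, see [build_grid()].
#' @param max_distance Passed to [compute_sasd()].
#' @return Named list of `xl_sasd` objects.
#' @export
compute_model_distances <- function(models, dataset = NULL,
                                    distance_mode = "sasd", voxel_size = 1,
                                    vdw = vdw_table(),
                                    probe_increment = water_probe_increment(),
                                    max_distance = Inf) {
  if (is.character(models)) {
    nm <- basename(models)
    models <- lapply(models, read_structure)
    names(models) <- nm
  }
  pairs <- if (is.null(dataset)) "all" else as.data.frame(dataset)
  res <- lapply(models, function(m) {
    if (distance_mode == "euclidean_all") {
      euclidean_distances(m, surface_only = FALSE, pairs = pairs)
    } else {
      g <- build_grid(m, voxel_size = voxel_size, vdw = vdw,
                      probe_increment = probe_increment)
      acc <- find_accessible_residues(g, m, vdw = vdw,
                                      probe_increment = probe_increment)
      if (distance_mode == "euclidean_surface") {
        euclidean_distances(m, surface_only = TRUE, access = acc,
                            pairs = pairs)
      } else {
        compute_sasd(g, acc, pairs = pairs, max_distance = max_distance)
      }
    }
  })
  if (is.null(names(res)) || any(names(res) == ""))
    names(res) <- sprintf("model_%03d", seq_along(res))
  res
}
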