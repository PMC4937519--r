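# Assessment of scoring functions against model quality: Calpha-RMSD after
# optimal superposition, Pearson correlation of the normalized score with
# RMSD, top-k precision with resampling over rank ties, bootstrap
# crosslink-recovery curves, and the maximum-bound (cutoff) scan.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.shared_ca <- function(model, reference) {
  am <- model$atoms
  ar <- reference$atoms
  cm <- am[am$name == "CA", , drop = FALSE]
  cr <- ar[ar$name == "CA", , drop = FALSE]
  km <- paste(cm$chain, cm$resno)
  kr <- paste(cr$chain, cr$resno)
  shared <- intersect(km, kr)
  list(
    model = as.matrix(cm[match(shared, km), c("x", "y", "z")]),
    ref = as.matrix(cr[match(shared, kr), c("x", "y", "z")]),
    n = length(shared)
  )
}

#' Calpha RMSD between a model and a reference after superposition
#'
#' Root-mean-square deviation over the shared (chain, residue number) Calpha
#' atoms after optimal rigid-body superposition (Kabsch, via
#' [bio3d::fit.xyz()] machinery).
#'
#' @param model,reference [xl_structure()] objects sharing residue numbering.
#' @return RMSD in Angstrom.
#' @export
calpha_rmsd <- function(model, reference) {
  s <- .shared_ca(model, reference)
  if (s$n < 3) stop("need at least 3 shared Calpha atoms, found ", s$n)
  xyz_m <- as.numeric(t(s$model))
  xyz_r <- as.numeric(t(s$ref))
  idx <- seq_along(xyz_r)
  fitted <- bio3d::fit.xyz(fixed = xyz_r, mobile = xyz_m,
                           fixed.inds = idx, mobile.inds = idx)
  # rmsd computed here at full precision (bio3d::rmsd rounds to 3 decimals)
  sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) - s$ref)^2)))
}

#' Pearson correlation between scores and RMSDs
#'
#' @param scores,rmsds Numeric vectors of equal length (>= 3).
#' @return The product-moment coefficient, or NA (with a warning) when either
#'   vector has zero variance.
#' @export
pearson <- function(scores, rmsds) {
  stopifnot(length(scores) == length(rmsds))
  if (length(scores) < 3) stop("need at least 3 models")
  if (stats::sd(scores) == 0 || stats::sd(rmsds) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(scores, rmsds)
}

#' Top-k precision with resampling over rank ties
#'
#' Models are ranked ascending by normalized score (0 = best). Precision is
#' TP / (TP + FP) where a true positive is a top-`k` model with RMSD at or
#' below `rmsd_cut`. When the k-th rank boundary falls inside a cluster of
#' tied scores (equal within `tie_tol`), the remaining slots are filled by
#' uniform sampling without replacement from the cluster and the precision
#' averaged over `resamples` draws; without a boundary tie the result is
#' deterministic and `resamples` is irrelevant.
#'
#' @param scores Normalized scores (lower = better).
#' @param rmsds Calpha-RMSDs (Angstrom), same length.
#' @param k Number of top-ranked models considered (default 20).
#' @param rmsd_cut RMSD threshold for a true positive (default 4).
#' @param resamples Number of tie resamples (default 1000).
#' @param seed Optional seed for the tie resampling.
#' @param tie_tol Scores within this of the boundary score form one tie
#'   cluster (default 1e-9).
#' @return Mean precision in `[0, 1]`.
#' @export
precision_top_k <- function(scores, rmsds, k = 20, rmsd_cut = 4,
                            resamples = 1000, seed = NULL, tie_tol = 1e-9) {
  n <- length(scores)
  stopifnot(length(rmsds) == n)
  if (n < k) stop("need at least k = ", k, " models, got ", n)
  tp <- rmsds <= rmsd_cut
  boundary <- sort(scores, partial = k)[k]
  better <- scores < boundary - tie_tol
  cluster <- abs(scores - boundary) <= tie_tol
  slots <- k - sum(better)
  if (sum(cluster) == slots) {
    return(sum(tp[better | cluster]) / k)
  }
  base_tp <- sum(tp[better])
  cluster_tp <- tp[cluster]
  nc <- length(cluster_tp)
  .with_seed(seed, {
    mean(vapply(seq_len(resamples), function(i) {
      (base_tp + sum(cluster_tp[sample.int(nc, slots)])) / k
    }, numeric(1)))
  })
}

#' Theoretical crosslink dataset from a reference structure
#'
#' All lysine/N-terminus pairs whose SASD on the reference is below the
#' cutoff; this emulates a complete (100% recovery) crosslinking experiment.
#'
#' @param reference An [xl_structure()], or a precomputed `xl_sasd` over all
#'   pairs of the reference.
#' @param cutoff Inclusion bound in Angstrom (default 33; pairs with SASD
#'   strictly below it are included).
#' @param ... Grid parameters forwarded to [build_grid()] when `reference` is
#'   a structure.
#' @return An [xl_dataset()] tagged "theoretical" (possibly empty).
#' @export
make_theoretical_dataset <- function(reference, cutoff = 33, ...) {
  sasd <- if (inherits(reference, "xl_sasd")) reference else {
    g <- build_grid(reference, ...)
    acc <- find_accessible_residues(g, reference)
    compute_sasd(g, acc, pairs = "all")
  }
  p <- sasd$pairs
  keep <- p$status == "measured" & p$distance < cutoff
  recs <- p[keep, c("chain_a", "res_a", "chain_b", "res_b"), drop = FALSE]
  rownames(recs) <- NULL
  xl_dataset(recs, provenance = "theoretical")
}

# per-model x per-crosslink MNXL contribution matrix; bootstrap subset scores
# are then plain row sums over the drawn columns
.mnxl_terms <- function(distances, dataset, config) {
  ds <- as.data.frame(dataset)
  key <- paste(paste(ds$chain_a, ds$res_a, sep = ":"),
               paste(ds$chain_b, ds$res_b, sep = ":"), sep = "-")
  terms <- vapply(distances, function(dd) {
    map <- sasd_lookup(dd)
    hit <- match(key, names(map))
    if (anyNA(hit))
      stop("crosslink pair(s) absent from a model distance map: ",
           paste(key[is.na(hit)], collapse = ", "))
    d <- unname(map[hit])
    out <- numeric(length(d))
    meas <- !is.na(d)
    out[meas & d <= config$cutoff] <-
      config$density(d[meas & d <= config$cutoff], config$mu, config$sigma)
    out[meas & d > config$cutoff] <- config$penalty_violation
    out[!meas] <- config$penalty_nonaccessible
    out
  }, numeric(length(key)))
  t(matrix(terms, nrow = length(key)))  # models x crosslinks
}

#' Bootstrap crosslink-recovery curve
#'
#' For each recovery percentage, draws `n_boot` uniform subsets (without
#' replacement, size `round(p * N / 100)`, minimum 1) of the theoretical
#' crosslink set, scores every model with MNXL on each subset, and reports the
#' mean Pearson correlation with RMSD and the mean top-k precision across
#' subsets.
#'
#' @param theoretical An [xl_dataset()] (typically from
#'   [make_theoretical_dataset()]).
#' @param distances Per-model distance maps covering all theoretical pairs
#'   (see [compute_model_distances()]).
#' @param rmsds Per-model Calpha-RMSD to the reference.
#' @param config An [scoring_config()].
#' @param percent_ladder Recovery percentages (default 90..1 as commonly
#'   scanned).
#' @param n_boot Bootstrap sets per percentage (default 1000).
#' @param seed Seed making the whole curve reproducible.
#' @param k,rmsd_cut,resamples Passed to [precision_top_k()] (fewer tie
#'   resamples than the headline default keep the inner loop affordable).
#' @return Object of class `recovery_curve`: data.frame with percent,
#'   subset_size, mean_correlation, mean_precision, n_boot.
#' @export
bootstrap_recovery <- function(theoretical, distances, rmsds, config,
                               percent_ladder = c(90, 80, 70, 60, 50, 40, 30,
                                                  20, 10, 5, 1),
                               n_boot = 1000, seed = NULL, k = 20,
                               rmsd_cut = 4, resamples = 100) {
  N <- nrow(theoretical)
  if (!N) stop("theoretical dataset is empty")
  stopifnot(length(rmsds) == length(distances))
  terms <- .mnxl_terms(distances, theoretical, config)
  .with_seed(seed, {
    rows <- lapply(percent_ladder, function(p) {
      size <- max(1L, as.integer(floor(p * N / 100 + 0.5)))
      cors <- numeric(n_boot)
      precs <- numeric(n_boot)
      for (b in seq_len(n_boot)) {
        sub <- sample.int(N, size)
        raw <- rowSums(terms[, sub, drop = FALSE])
        norm <- normalize_ensemble(raw, "higher_better")
        cors[b] <- if (stats::sd(norm) == 0 || stats::sd(rmsds) == 0)
          NA_real_ else stats::cor(norm, rmsds)
        precs[b] <- precision_top_k(norm, rmsds, k = k, rmsd_cut = rmsd_cut,
                                    resamples = resamples)
      }
      data.frame(percent = p, subset_size = size,
                 mean_correlation = mean(cors, na.rm = TRUE),
                 mean_precision = mean(precs), n_boot = n_boot)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("recovery_curve", "data.frame")
    out
  })
}

#' Scan the maximum-bound cutoff
#'
#' Re-scores the ensemble with MNXL at each candidate cutoff (distances are
#' computed once; only the classification changes) and tabulates the Pearson
#' correlation with RMSD and the top-k precision per cutoff.
#'
#' @param distances Per-model distance maps (all pairs of the dataset).
#' @param dataset An [xl_dataset()].
#' @param rmsds Per-model Calpha-RMSD to the reference.
#' @param config Baseline [scoring_config()]; its cutoff is replaced by each
#'   scanned value.
#' @param cutoffs Cutoff ladder in Angstrom (default 20..80).
#' @param refit When TRUE, mu/sigma are refitted at each cutoff from
#'   `refit_values` (reference SASDs at or below the cutoff); when FALSE
#'   (default) the distribution is held fixed.
#' @param refit_values Numeric SASD vector used when `refit = TRUE`.
#' @param k,rmsd_cut,resamples,seed Passed to [precision_top_k()].
#' @return data.frame with cutoff, correlation, precision.
#' @export
cutoff_scan <- function(distances, dataset, rmsds, config,
                        cutoffs = seq(20, 80, by = 1), refit = FALSE,
                        refit_values = NULL, k = 20, rmsd_cut = 4,
                        resamples = 1000, seed = NULL) {
  if (length(distances) < 3) stop("need at least 3 models")
  if (refit && is.null(refit_values))
    stop("refit = TRUE requires refit_values")
  rows <- lapply(cutoffs, function(ct) {
    cfg <- config
    cfg$cutoff <- ct
    if (refit) {
      fit <- fit_sasd_distribution(refit_values, fit_cutoff = ct)
      cfg$mu <- fit$mu
      cfg$sigma <- fit$sigma
    }
    raw <- vapply(distances, function(dd)
      score_mnxl(classify_crosslinks(dataset, dd, cfg), cfg), numeric(1))
    norm <- normalize_ensemble(raw, "higher_better")
    r <- if (stats::sd(norm) == 0 || stats::sd(rmsds) == 0) NA_real_
         else stats::cor(norm, rmsds)
    data.frame(cutoff = ct, correlation = r,
               precision = precision_top_k(norm, rmsds, k = k,
                                           rmsd_cut = rmsd_cut,
                                           resamples = resamples, seed = seed))
  })
  do.call(rbind, rows)
}

#' Evaluate one scoring function over an ensemble
#'
#' @param scores Raw scores, one per model.
#' @param rmsds Calpha-RMSDs, one per model.
#' @param orientation Score orientation, see [normalize_ensemble()].
#' @param k,rmsd_cut,resamples,seed Passed to [precision_top_k()].
#' @return List with per-model table (`models`: normalized score, rmsd),
#'   `correlation`, `precision`, and `best_separated` (whether the best
#'   model's raw score sits more than 2 ensemble standard deviations from the
#'   ensemble mean, a diagnostic for an ideal scoring function).
#' @export
evaluate_scores <- function(scores, rmsds,
                            orientation = c("higher_better", "lower_better"),
                            k = 20, rmsd_cut = 4, resamples = 1000,
                            seed = NULL) {
  orientation <- match.arg(orientation)
  norm <- normalize_ensemble(scores, orientation)
  r <- pearson(norm, rmsds)
  prec <- precision_top_k(norm, rmsds, k = k, rmsd_cut = rmsd_cut,
                          resamples = resamples, seed = seed)
  oriented <- if (orientation == "higher_better") scores else -scores
  sep <- if (stats::sd(oriented) > 0)
    (max(oriented) - mean(oriented)) / stats::sd(oriented) > 2 else FALSE
  list(models = data.frame(score_norm = norm, rmsd = rmsds),
       correlation = r, precision = prec, best_separated = sep)
}
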