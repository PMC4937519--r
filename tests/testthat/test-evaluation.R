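test_that("Calpha RMSD is zero for identity and rigid translation", {
  fx <- make_fixture("helix", n_residues = 12)
  s <- fx$structure
  expect_equal(calpha_rmsd(s, s), 0, tolerance = 1e-9)
  a <- s$atoms
  a[, c("x", "y", "z")] <- a[, c("x", "y", "z")] + 5
  expect_equal(calpha_rmsd(xl_structure(a), s), 0, tolerance = 1e-6)
})

test_that("Calpha RMSD matches an independent Kabsch implementation", {
  fx <- make_fixture("helix", n_residues = 10)
  ref <- fx$structure
  a <- ref$atoms
  ca_rows <- which(a$name == "CA")
  a[ca_rows[4], c("x", "y", "z")] <- a[ca_rows[4], c("x", "y", "z")] + 2
  model <- xl_structure(a)
  got <- calpha_rmsd(model, ref)
  want <- naive_rmsd(as.matrix(a[ca_rows, c("x", "y", "z")]),
                     as.matrix(ref$atoms[ca_rows, c("x", "y", "z")]))
  expect_equal(got, want, tolerance = 1e-6)
  expect_gt(got, 0)
  # fewer than 3 shared CAs errors
  tiny <- xl_structure(a[a$resno <= 2, , drop = FALSE])
  expect_error(calpha_rmsd(tiny, tiny), "at least 3")
})

test_that("pearson handles perfect, inverted and degenerate inputs", {
  r <- c(1, 3, 7, 9, 15)
  expect_equal(pearson(r, r), 1.0)
  expect_equal(pearson(-r, r), -1.0)
  expect_warning(p0 <- pearson(rep(1, 5), r), "zero variance")
  expect_true(is.na(p0))
  # fixed 5-point table against the textbook formula
  x <- c(0.1, 0.4, 0.2, 0.9, 0.6)
  y <- c(2, 5, 3, 11, 8)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson(x, y), num / den)
})

test_that("top-k precision is deterministic without ties and counts TPs", {
  n <- 40
  scores <- seq(0, 1, length.out = n)
  rmsds <- c(rep(2, 20), rep(10, 20))      # top-20 all true positives
  expect_equal(precision_top_k(scores, rmsds), 1.0)
  rmsds2 <- c(rep(c(2, 10), 10), rep(10, 20))  # half the top-20
  expect_equal(precision_top_k(scores, rmsds2), 0.5)
  # no ties -> resample count is irrelevant
  expect_identical(precision_top_k(scores, rmsds2, resamples = 1),
                   precision_top_k(scores, rmsds2, resamples = 500))
  expect_error(precision_top_k(scores[1:10], rmsds[1:10]), "at least k")
})

test_that("boundary ties are resampled toward the hypergeometric expectation", {
  # 30 models tied at the best score, 15 of them true positives, k = 20
  scores <- c(rep(0, 30), seq(0.1, 1, length.out = 10))
  rmsds <- c(rep(c(2, 10), 15), rep(10, 10))
  p <- precision_top_k(scores, rmsds, k = 20, resamples = 2000, seed = 5)
  expect_equal(p, 20 * (15 / 30) / 20, tolerance = 0.03)
  # reproducible from the seed
  expect_identical(p, precision_top_k(scores, rmsds, k = 20,
                                      resamples = 2000, seed = 5))
})

test_that("theoretical datasets include only measured pairs under the cutoff", {
  fx <- make_fixture("free_pair", separation = 10)
  ds <- make_theoretical_dataset(fx$structure, cutoff = 33)
  expect_equal(nrow(ds), 1)
  expect_identical(attr(ds, "provenance"), "theoretical")

  wall <- make_fixture("wall", separation = 16)  # SASD detours past 33
  g <- build_grid(wall$structure)
  acc <- find_accessible_residues(g, wall$structure)
  sasd <- compute_sasd(g, acc)
  d <- sasd$pairs$distance[sasd$pairs$status == "measured"]
  expect_true(all(d > 33))
  expect_equal(nrow(make_theoretical_dataset(sasd, cutoff = 33)), 0)
  # with no bound, every accessible measured pair is included
  expect_equal(nrow(make_theoretical_dataset(sasd, cutoff = Inf)),
               sum(sasd$pairs$status == "measured"))

  buried <- make_fixture("buried")
  ds_b <- make_theoretical_dataset(buried$structure, cutoff = 33)
  expect_false(any(ds_b$res_a == 1 | ds_b$res_b == 1))
})

test_that("bootstrap subset sizes follow the rounding rule with floor one", {
  bm <- euclid_benchmark(n_models = 25, n_res = 6, sigma_max = 8, seed = 3)
  N <- nrow(bm$theo)
  curve <- bootstrap_recovery(bm$theo, bm$dist, bm$rmsds, bm$cfg,
                              percent_ladder = c(100, 20, 1), n_boot = 5,
                              seed = 1, k = 20, resamples = 20)
  expect_equal(curve$subset_size,
               pmax(1, as.integer(floor(c(100, 20, 1) * N / 100 + 0.5))))
  # p = 100: every subset is the full set, so the curve point equals the
  # full-data evaluation
  tab <- score_models(bm$dist, bm$theo, bm$cfg)
  full_r <- pearson(tab$mnxl_norm, bm$rmsds)
  expect_equal(curve$mean_correlation[1], full_r, tolerance = 1e-9)
})

test_that("bootstrap curves are bit-reproducible from the seed", {
  bm <- euclid_benchmark(n_models = 25, n_res = 6, sigma_max = 8, seed = 3)
  c1 <- bootstrap_recovery(bm$theo, bm$dist, bm$rmsds, bm$cfg,
                           percent_ladder = c(50, 10), n_boot = 25, seed = 42,
                           resamples = 20)
  c2 <- bootstrap_recovery(bm$theo, bm$dist, bm$rmsds, bm$cfg,
                           percent_ladder = c(50, 10), n_boot = 25, seed = 42,
                           resamples = 20)
  expect_identical(c1, c2)
})

test_that("a one-point cutoff scan equals direct evaluation at that cutoff", {
  bm <- euclid_benchmark(n_models = 25, n_res = 6, sigma_max = 8, seed = 3)
  scan <- cutoff_scan(bm$dist, bm$theo, bm$rmsds, bm$cfg, cutoffs = 33,
                      seed = 2)
  tab <- score_models(bm$dist, bm$theo, bm$cfg)
  expect_equal(scan$correlation, pearson(tab$mnxl_norm, bm$rmsds))
  expect_equal(scan$precision,
               precision_top_k(tab$mnxl_norm, bm$rmsds, seed = 2))
  # refitting at the scanned cutoff uses only reference values below it
  ref_vals <- c(10, 20, 30, 44, 60)
  scan_fit <- cutoff_scan(bm$dist, bm$theo, bm$rmsds, bm$cfg,
                          cutoffs = c(33, 50), refit = TRUE,
                          refit_values = ref_vals, seed = 2)
  expect_equal(nrow(scan_fit), 2)
  expect_error(cutoff_scan(bm$dist, bm$theo, bm$rmsds, bm$cfg, cutoffs = 33,
                           refit = TRUE), "refit_values")
})

test_that("the scan is flat when no classification can change", {
  # all distances well under every scanned cutoff -> same classification
  set.seed(8)
  maps <- lapply(1:25, function(i) fake_sasd(data.frame(
    chain_a = "A", res_a = c(1, 3, 5), chain_b = "A", res_b = c(2, 4, 6),
    distance = runif(3, 5, 15))))
  ds <- xl_dataset(data.frame(chain_a = "A", res_a = c(1, 3, 5),
                              chain_b = "A", res_b = c(2, 4, 6)))
  cfg <- scoring_config(mu = 20, sigma = 5)
  rmsds <- seq(1, 12, length.out = 25)
  scan <- cutoff_scan(maps, ds, rmsds, cfg, cutoffs = c(20, 40, 60), seed = 1)
  expect_equal(scan$correlation, rep(scan$correlation[1], 3))
  expect_equal(scan$precision, rep(scan$precision[1], 3))
})

test_that("the scan reacts between cutoffs that straddle the violations", {
  # violations concentrated at 30-36 A: scanning 30 vs 36 must differ
  set.seed(9)
  rmsds <- seq(0.5, 14, length.out = 25)
  maps <- lapply(seq_len(25), function(i) fake_sasd(data.frame(
    chain_a = "A", res_a = c(1, 3, 5), chain_b = "A", res_b = c(2, 4, 6),
    distance = c(20, 30 + 6 * (i - 1) / 24, 25))))
  ds <- xl_dataset(data.frame(chain_a = "A", res_a = c(1, 3, 5),
                              chain_b = "A", res_b = c(2, 4, 6)))
  cfg <- scoring_config(mu = 20, sigma = 5)
  scan <- cutoff_scan(maps, ds, rmsds, cfg, cutoffs = c(30, 36), seed = 1)
  expect_false(isTRUE(all.equal(scan$correlation[1], scan$correlation[2])))
})

test_that("evaluate_scores summarizes an oriented ensemble", {
  rmsds <- seq(0.5, 12, length.out = 30)
  ev <- evaluate_scores(-rmsds, rmsds, "higher_better", k = 20, seed = 1)
  expect_equal(ev$correlation, 1.0)
  tp <- sum(rmsds[order(rmsds)][1:20] <= 4)
  expect_equal(ev$precision, tp / 20)
})
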