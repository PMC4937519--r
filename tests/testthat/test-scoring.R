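make_cfg <- function(...) scoring_config(mu = 20, sigma = 5, ...)

three_link_map <- function() {
  fake_sasd(data.frame(
    chain_a = "A", res_a = c(1, 3, 5), chain_b = "A", res_b = c(2, 4, 6),
    distance = c(20, 40, NA), stringsAsFactors = FALSE))
}

three_link_dataset <- function() {
  xl_dataset(data.frame(chain_a = "A", res_a = c(1, 3, 5),
                        chain_b = "A", res_b = c(2, 4, 6)))
}

test_that("crosslinks partition into matched, violating and non-accessible", {
  cls <- classify_crosslinks(three_link_dataset(), three_link_map(),
                             make_cfg())
  expect_equal(cls$matched_ok$pair, "A:1-A:2")
  expect_equal(cls$matched_violating$pair, "A:3-A:4")
  expect_equal(cls$nonaccessible$pair, "A:5-A:6")
  n <- nrow(cls$matched_ok) + nrow(cls$matched_violating) +
    nrow(cls$nonaccessible)
  expect_equal(n, 3)
})

test_that("a distance exactly at the cutoff counts as satisfied", {
  map <- fake_sasd(data.frame(chain_a = "A", res_a = 1, chain_b = "A",
                              res_b = 2, distance = 33))
  ds <- xl_dataset(data.frame(chain_a = "A", res_a = 1, chain_b = "A",
                              res_b = 2))
  cls <- classify_crosslinks(ds, map, make_cfg())
  expect_equal(nrow(cls$matched_ok), 1)
  expect_equal(nrow(cls$matched_violating), 0)
})

test_that("a dataset pair missing from the distance map is an error", {
  ds <- xl_dataset(data.frame(chain_a = "A", res_a = 1, chain_b = "A",
                              res_b = 99))
  expect_error(classify_crosslinks(ds, three_link_map(), make_cfg()),
               "A:1-A:99")
})

test_that("score_matched is the normal density below the cutoff, flat above", {
  cfg <- make_cfg()
  expect_equal(score_matched(20, cfg), 1 / (5 * sqrt(2 * pi)))
  expect_equal(score_matched(20, cfg), 0.0798, tolerance = 1e-3)
  expect_equal(score_matched(40, cfg), -0.1)
  expect_equal(score_matched(33, cfg), dnorm(33, 20, 5))
  # symmetric about mu within the satisfied region
  expect_equal(score_matched(15, cfg), score_matched(25, cfg))
  expect_gt(score_matched(20, cfg), score_matched(25, cfg))
})

test_that("raw MNXL totals density rewards and flat penalties", {
  cfg <- make_cfg()
  cls <- classify_crosslinks(three_link_dataset(), three_link_map(), cfg)
  expect_equal(score_mnxl(cls, cfg), dnorm(20, 20, 5) - 0.1 - 0.1)
  expect_equal(score_mnxl(cls, cfg), -0.1202, tolerance = 1e-3)

  empty <- classify_crosslinks(
    xl_dataset(data.frame(chain_a = character(0), res_a = integer(0),
                          chain_b = character(0), res_b = integer(0))),
    three_link_map(), cfg)
  expect_equal(score_mnxl(empty, cfg), 0)

  all_na <- fake_sasd(data.frame(chain_a = "A", res_a = 1:4, chain_b = "A",
                                 res_b = 11:14, distance = NA_real_))
  ds <- xl_dataset(data.frame(chain_a = "A", res_a = 1:4, chain_b = "A",
                              res_b = 11:14))
  expect_equal(score_mnxl(classify_crosslinks(ds, all_na, cfg), cfg),
               -0.1 * 4)
})

test_that("NoV, SoVD and NoV+nonaccessible match hand sums", {
  cfg <- make_cfg()
  map <- fake_sasd(data.frame(
    chain_a = "A", res_a = c(1, 3, 5, 7, 9), chain_b = "A",
    res_b = c(2, 4, 6, 8, 10), distance = c(40, 50, 10, NA, NA)))
  ds <- xl_dataset(data.frame(chain_a = "A", res_a = c(1, 3, 5, 7, 9),
                              chain_b = "A", res_b = c(2, 4, 6, 8, 10)))
  cls <- classify_crosslinks(ds, map, cfg)
  expect_equal(score_nov(cls), 2)
  expect_equal(score_sovd(cls, cfg), (40 - 33) + (50 - 33))
  expect_equal(score_nov_nonacc(cls), 2 + 2)

  none <- classify_crosslinks(
    xl_dataset(data.frame(chain_a = "A", res_a = 5, chain_b = "A", res_b = 6)),
    map, cfg)
  expect_equal(score_nov(none), 0)
  expect_equal(score_sovd(none, cfg), 0)
})

test_that("SoVD tends to zero as violations approach the cutoff from above", {
  cfg <- make_cfg()
  for (eps in c(1, 0.1, 0.001)) {
    map <- fake_sasd(data.frame(chain_a = "A", res_a = 1, chain_b = "A",
                                res_b = 2, distance = 33 + eps))
    ds <- xl_dataset(data.frame(chain_a = "A", res_a = 1, chain_b = "A",
                                res_b = 2))
    expect_equal(score_sovd(classify_crosslinks(ds, map, cfg), cfg), eps)
  }
})

test_that("normalization maps best to 0 and worst to 1 in both orientations", {
  expect_equal(normalize_ensemble(c(5, 3, 1), "higher_better"), c(0, 0.5, 1))
  expect_equal(normalize_ensemble(c(0, 2, 4), "lower_better"), c(0, 0.5, 1))
  expect_equal(normalize_ensemble(7, "higher_better"), 0)
  expect_equal(normalize_ensemble(c(2, 2, 2), "lower_better"), c(0, 0, 0))
})

test_that("crossing the cutoff never improves MNXL nor NoV/SoVD", {
  cfg <- make_cfg()
  ds <- three_link_dataset()
  base <- three_link_map()
  for (d_new in c(34, 45, 80)) {
    moved <- base
    moved$pairs$distance[1] <- d_new  # was 20 (satisfied)
    cls0 <- classify_crosslinks(ds, base, cfg)
    cls1 <- classify_crosslinks(ds, fake_sasd(moved$pairs), cfg)
    expect_lte(score_mnxl(cls1, cfg), score_mnxl(cls0, cfg))
    expect_gte(score_nov(cls1), score_nov(cls0))
    expect_gte(score_sovd(cls1, cfg), score_sovd(cls0, cfg))
  }
})

test_that("MNXL is invariant to crosslink order", {
  cfg <- make_cfg()
  df <- data.frame(chain_a = "A", res_a = c(1, 3, 5, 7),
                   chain_b = "A", res_b = c(2, 4, 6, 8),
                   distance = c(18, 25, 40, NA))
  ds1 <- xl_dataset(df[, 1:4])
  ds2 <- xl_dataset(df[c(3, 1, 4, 2), 1:4])
  map <- fake_sasd(df)
  expect_equal(score_mnxl(classify_crosslinks(ds1, map, cfg), cfg),
               score_mnxl(classify_crosslinks(ds2, map, cfg), cfg))
})

test_that("euclidean_all mode never produces non-accessible crosslinks", {
  fx <- make_fixture("buried")
  dist <- compute_model_distances(list(m = fx$structure),
                                  distance_mode = "euclidean_all")
  ds <- xl_dataset(data.frame(chain_a = "A", res_a = 1, chain_b = "A",
                              res_b = 5))
  cfg <- make_cfg(distance_mode = "euclidean_all")
  cls <- classify_crosslinks(ds, dist[[1]], cfg)
  expect_equal(nrow(cls$nonaccessible), 0)
})

test_that("scoring_config validates its parameters", {
  expect_error(scoring_config(mu = 20, sigma = 0), "sigma")
  expect_error(scoring_config(mu = 20, sigma = 5, cutoff = -1), "cutoff")
  expect_error(scoring_config(mu = 20, sigma = 5, penalty_violation = 0.1),
               "penalties")
  expect_error(scoring_config(), "mu and sigma")
  fit <- fit_sasd_distribution(c(10, 20, 30))
  cfg <- scoring_config(distribution = fit)
  expect_equal(cfg$mu, 20)
})

test_that("score_models tabulates an ensemble with normalized MNXL", {
  cfg <- make_cfg()
  ds <- three_link_dataset()
  maps <- list(
    good = three_link_map(),
    bad = fake_sasd(data.frame(chain_a = "A", res_a = c(1, 3, 5),
                               chain_b = "A", res_b = c(2, 4, 6),
                               distance = c(50, 60, NA)))
  )
  tab <- score_models(maps, ds, cfg)
  expect_equal(tab$model, c("good", "bad"))
  expect_gt(tab$raw_mnxl[1], tab$raw_mnxl[2])
  expect_equal(tab$mnxl_norm, c(0, 1))
  expect_equal(tab$nov, c(1L, 2L))
  expect_equal(tab$nonaccessible_count, c(1L, 1L))
})
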