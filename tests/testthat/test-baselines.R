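test_that("build_baseline keeps raw in-bin values and rejects thin bins", {
  set.seed(3)
  plants <- data.frame(plant_id = paste0("p", 1:15),
                       elevation_m = c(runif(10, 4000, 5000),
                                       runif(5, 3000, 4000)),
                       d13C = rnorm(15, -26), d15N = rnorm(15, 7))
  b <- build_baseline(plants, c(4000, 5000))
  in_bin <- plants$elevation_m >= 4000 & plants$elevation_m < 5000
  expect_equal(b$n, sum(in_bin))
  expect_equal(sort(b$d15N), sort(plants$d15N[in_bin]))
  expect_equal(b$d15N_mean, mean(plants$d15N[in_bin]), tolerance = 1e-12)
  expect_error(build_baseline(plants[1, ], c(4000, 5000)), "insufficient")
})

test_that("two-source split is the global optimum of the within-SS objective", {
  # exhaustive oracle over all 2-subsets (not assuming contiguity)
  best_split_ss <- function(x) {
    n <- length(x); best <- Inf
    for (mask in 1:(2^n - 2)) {
      idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
      if (length(idx) < 2 || n - length(idx) < 2) next
      g1 <- x[idx]; g2 <- x[-idx]
      ss <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
      best <- min(best, ss)
    }
    best
  }
  set.seed(7)
  for (rep in 1:5) {
    x <- c(rnorm(5, -26, 1), rnorm(5, -13, 1))
    b <- baseline_from(rnorm(10, 6), d13C = x)
    s <- split_two_sources(b)
    ss <- sum((s$source1$d13C - s$source1$d13C_mean)^2) +
      sum((s$source2$d13C - s$source2$d13C_mean)^2)
    expect_equal(ss, best_split_ss(x), tolerance = 1e-10)
    # union preserved, source1 is the 13C-depleted group
    expect_setequal(c(s$source1$d13C, s$source2$d13C), x)
    expect_lt(s$source1$d13C_mean, s$source2$d13C_mean)
  }
})

test_that("a clear mixture is recovered exactly and order does not matter", {
  set.seed(11)
  c3 <- rnorm(10, -26, 1); c4 <- rnorm(10, -13, 1)
  x <- c(c3, c4)
  for (ord in list(seq_along(x), sample(seq_along(x)))) {
    b <- baseline_from(rnorm(20, 6), d13C = x[ord])
    s <- split_two_sources(b)
    expect_setequal(s$source1$d13C, c3)
    expect_setequal(s$source2$d13C, c4)
  }
  # obvious 4-point partition
  b4 <- baseline_from(rnorm(4, 6), d13C = c(-27, -25, -14, -12))
  s4 <- split_two_sources(b4)
  expect_setequal(s4$source1$d13C, c(-27, -25))
  expect_setequal(s4$source2$d13C, c(-14, -12))
})

test_that("unimodal input splits mechanically but warns about bimodality", {
  set.seed(13)
  b <- baseline_from(rnorm(20, 6), d13C = rnorm(20, -26, 1))
  expect_warning(split_two_sources(b), "bimodal")
  expect_error(split_two_sources(baseline_from(c(1, 2, 3), d13C = c(-26, -25, -24))),
               "at least 4")
})

test_that("the default site mapping resolves models and baselines as designed", {
  set.seed(17)
  plants <- simulate_plants(seed = 17)
  r2 <- map_site_to_baseline("Site 2", plants)
  expect_equal(r2$model, "twoBaselinesFull")
  expect_equal(r2$baselines$source1$bin_label, "3000-4000")
  expect_lt(r2$baselines$source1$d13C_mean, r2$baselines$source2$d13C_mean)

  r5 <- map_site_to_baseline("Site 5", plants)
  expect_equal(r5$model, "oneBaseline")
  expect_equal(r5$baselines[[1]]$bin_label, "> 4000")
  # "> 4000" pools the 4000-5000 and top bins
  n_hi <- sum(plants$elevation_m >= 4000)
  expect_equal(r5$baselines[[1]]$n, n_hi)

  r7 <- map_site_to_baseline("Site 7", plants)
  expect_equal(r7$model, "individualOneBaseline")

  # the alternative top-bin-only mapping is expressible in config
  alt <- default_baseline_mapping()
  alt$`Site 7`$bins <- "> 5000"
  r7b <- map_site_to_baseline("Site 7", plants, alt)
  expect_equal(r7b$baselines[[1]]$n, sum(plants$elevation_m >= 5000))

  expect_error(map_site_to_baseline("Site 99", plants), "no baseline mapping")
})

test_that("a manual source column overrides the automatic split", {
  plants <- data.frame(plant_id = paste0("p", 1:6),
                       elevation_m = 3500,
                       d13C = c(-26, -25, -24, -14, -13, -12),
                       d15N = c(6, 7, 8, 5, 6, 7),
                       source = rep(c("C3", "CAM"), each = 3))
  r <- map_site_to_baseline("Site 2", plants)
  expect_equal(r$baselines$source1$n, 3)
  expect_equal(r$baselines$source1$source_label, "C3")
})
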