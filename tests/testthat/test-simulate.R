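test_that("simulated consumers match the site specifications", {
  x <- simulate_sites(seed = 1)
  specs <- phyllotis_sites()
  expect_equal(nrow(x), sum(specs$n))
  expect_equal(as.integer(table(x$site_id)[specs$site_id]), specs$n)
  # sample moments converge to spec moments (3 SE tolerance per variable)
  for (i in which(specs$n >= 4)) {
    s <- specs[i, ]
    v <- x[x$site_id == s$site_id, ]
    expect_lt(abs(mean(v$d15N) - s$d15N_mean), 3 * s$d15N_sd / sqrt(s$n) + 1e-9)
    expect_lt(abs(mean(v$d13C) - s$d13C_mean), 3 * s$d13C_sd / sqrt(s$n) + 1e-9)
  }
  # C:N honours the truncation range
  expect_true(all(x$cn_ratio >= 3.0 & x$cn_ratio <= 6.0))
  # single-animal site reproduces its means exactly (SD treated as 0)
  summit <- x[x$site_id == "Site 7", ]
  expect_equal(summit$d15N, specs$d15N_mean[7])
})

test_that("generators are pure functions of (spec, seed)", {
  expect_identical(simulate_sites(seed = 9), simulate_sites(seed = 9))
  expect_false(identical(simulate_sites(seed = 9), simulate_sites(seed = 10)))
  expect_identical(simulate_plants(seed = 3), simulate_plants(seed = 3))
})

test_that("zero-SD site specs give constant values", {
  spec <- phyllotis_sites()[1, ]
  spec$d15N_sd <- 0; spec$d13C_sd <- 0; spec$d34S_sd <- 0; spec$cn_sd <- 0
  x <- simulate_sites(spec, seed = 2)
  expect_equal(unique(x$d15N), spec$d15N_mean)
  expect_equal(unique(x$cn_ratio), spec$cn_mean)
})

test_that("plant mixtures are bimodal where specified and labelled for oracles", {
  p <- simulate_plants(seed = 4)
  mid <- p[p$elevation_m >= 3000 & p$elevation_m < 4000, ]
  expect_setequal(unique(mid$component), c(1, 2))
  # the two generating components are far apart in d13C
  expect_lt(max(mid$d13C[mid$component == 1]),
            min(mid$d13C[mid$component == 2]))
  # a single-component bin is unimodal
  hi <- p[p$elevation_m >= 4000 & p$elevation_m < 5000, ]
  expect_equal(unique(hi$component), 1)
  # degenerate n = 0 propagates to the insufficient-baseline error downstream
  spec0 <- default_plant_specs()[3]
  spec0[[1]]$n <- 0
  p0 <- simulate_plants(spec0, seed = 1)
  expect_equal(nrow(p0), 0)
  expect_error(build_baseline(p0, c(4000, 5000)), "insufficient")
  # invalid weights rejected
  badspec <- default_plant_specs()[2]
  badspec[[1]]$components$weight <- c(0.7, 0.7)
  expect_error(simulate_plants(badspec, seed = 1), "sum to 1")
})

test_that("known-TP consumers follow the inverted TP equation", {
  b <- baseline_from(rnorm(20, 5, 1))
  # sigma = 0 at TP 1: consumers equal the baseline mean exactly
  sim0 <- simulate_consumers_known_tp(1, b, n_consumers = 5,
                                      sigma_consumer = 0, seed = 6)
  expect_equal(sim0$consumers$d15N, rep(b$d15N_mean, 5))
  # alpha = 1 tracks source1 only
  s1 <- baseline_from(rnorm(10, 3, 0.5), d13C = rnorm(10, -26, 0.5))
  s2 <- baseline_from(rnorm(10, 9, 0.5), d13C = rnorm(10, -13, 0.5))
  sim1 <- simulate_consumers_known_tp(2, list(source1 = s1, source2 = s2),
                                      n_consumers = 6, sigma_consumer = 0,
                                      alpha_true = 1, seed = 7)
  tdf <- tdf_liver()
  expect_equal(unique(sim1$consumers$d15N), s1$d15N_mean + tdf$d15N_mean)
  expect_equal(unique(sim1$consumers$d13C), s1$d13C_mean + tdf$d13C_mean)
  expect_equal(sim1$truth$tp_true, 2)
})

test_that("the fixture bundle is reproducible and passes its own validation", {
  d1 <- tempfile(); d2 <- tempfile()
  b1 <- make_fixture_bundle(d1, seed = 42)
  b2 <- make_fixture_bundle(d2, seed = 42)
  expect_identical(readLines(b1$consumers), readLines(b2$consumers))
  expect_identical(readLines(b1$plants), readLines(b2$plants))
  x <- read_samples(b1$consumers)
  expect_equal(nrow(x), 41)
  # site means differ by construction, so elevational bins separate
  x$d13C_corrected <- lipid_correct(x$d13C, x$cn_ratio)
  keep <- x$site_id %in% names(which(table(x$site_id) >= 2))
  D <- euclidean_distances(as.matrix(
    x[keep, c("d13C_corrected", "d15N", "d34S")]))
  r <- permanova(D, assign_bin(x$elevation_m[keep]), n_perm = 999, seed = 1)
  expect_lte(r$p_perm, 0.01)
})
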