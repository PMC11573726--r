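test_that("euclidean distances match a brute-force double loop", {
  expect_equal(as.matrix(euclidean_distances(rbind(c(0, 0, 0),
                                                   c(3, 4, 0))))[1, 2], 5)
  set.seed(51)
  x <- matrix(rnorm(18), 6, 3)
  D <- as.matrix(euclidean_distances(x))
  for (i in 1:6) for (j in 1:6) {
    expect_equal(D[i, j], sqrt(sum((x[i, ] - x[j, ])^2)), tolerance = 1e-12)
  }
  expect_equal(D[2, 2], 0)
  xm <- x; xm[3, 2] <- NA
  rownames(xm) <- paste0("s", 1:6)
  expect_error(euclidean_distances(xm), "s3")
})

test_that("well-separated clusters give perfect LOO and the permutation lower bound", {
  cl <- make_clusters(k = 4, n_per = 8, sep = 12, sd = 0.3, seed = 52)
  fit <- cap(cl$x, cl$groups)
  loo <- cap_loo(cl$x, cl$groups, fit$m)
  expect_equal(loo$overall_percent, 100)
  expect_equal(unname(loo$percent_correct), rep(100, 4))
  expect_equal(unname(rowSums(loo$counts)), rep(8, 4))
  tst <- cap_permutation_test(cl$x, cl$groups, fit$m, n_perm = 999, seed = 1)
  expect_equal(tst$p_perm, 1 / 1000)
  # with full-rank axes the trace approaches g - 1
  f3 <- cap(cl$x, cl$groups, m = 3)
  expect_gt(f3$trace, 2.9)
  expect_lte(f3$trace, 3)
  expect_true(all(f3$sq_corr >= 0 & f3$sq_corr <= 1))
})

test_that("add-a-point projection reproduces training coordinates to 1e-8", {
  set.seed(53)
  x <- matrix(rnorm(45), 15, 3)
  g <- rep(c("a", "b", "c"), each = 5)
  fit <- cap(x, g, m = 2)
  pr <- predict(fit, x)
  for (i in 1:15) {
    z <- as.numeric(pr[i, paste0("cap", seq_len(ncol(fit$scores)))])
    expect_lt(max(abs(z - fit$scores[i, ])), 1e-8)
  }
})

test_that("full-rank CAP classification equals classical LDA under equal priors", {
  skip_if_not_installed("MASS")
  set.seed(54)
  x <- matrix(rnorm(90), 30, 3)
  x[11:20, 1] <- x[11:20, 1] + 2
  x[21:30, 2] <- x[21:30, 2] + 2
  g <- rep(c("a", "b", "c"), each = 10)
  fit <- cap(x, g, m = 3)
  pred_cap <- predict(fit, x)$predicted
  ld <- MASS::lda(x, grouping = g, prior = rep(1 / 3, 3))
  pred_lda <- as.character(predict(ld, x)$class)
  expect_equal(pred_cap, pred_lda)
})

test_that("the trace is invariant to co-permutation of distances and labels", {
  set.seed(55)
  cl <- make_clusters(k = 3, n_per = 6, sep = 4, sd = 1, seed = 55)
  D <- as.matrix(euclidean_distances(cl$x))
  f1 <- cap(D, cl$groups, m = 2)
  perm <- sample(nrow(D))
  f2 <- cap(D[perm, perm], cl$groups[perm], m = 2)
  expect_equal(f1$trace, f2$trace, tolerance = 1e-9)
})

test_that("random labels give small traces and approximately uniform p-values", {
  set.seed(56)
  ps <- replicate(60, {
    x <- matrix(rnorm(48), 16, 3)
    g <- sample(rep(c("a", "b"), each = 8))
    cap_permutation_test(x, g, m = 2, n_perm = 99,
                         seed = sample.int(1e6, 1))$p_perm
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_gt(min(ps), 0.005)
})

test_that("duplicated clusters under two labels classify at chance", {
  set.seed(57)
  core <- matrix(rnorm(30, sd = 0.5), 10, 3)
  x <- rbind(core, core + matrix(rnorm(30, sd = 1e-3), 10, 3))
  g <- rep(c("a", "b"), each = 10)
  loo <- cap_loo(x, g, m = 2)
  expect_lt(loo$overall_percent, 75)
})

test_that("assignment of new samples is self-consistent and ties are flagged", {
  cl <- make_clusters(k = 3, n_per = 6, sep = 10, sd = 0.2, seed = 58)
  fit <- cap(cl$x, cl$groups, m = 2)
  # a training point re-projected lands in its own group
  pr <- predict(fit, cl$x[7, ])
  expect_equal(pr$predicted, cl$groups[7])
  expect_false(pr$tie)
  # a deliberately equidistant point breaks ties to the first label
  mid <- colMeans(rbind(cl$x[1, ], cl$x[7, ]))
  sym <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(2, 2, 0))
  gsym <- c("a", "a", "b", "b")
  fsym <- cap(sym, gsym, m = 1)
  tie_point <- c(1, 1, 0)
  psym <- predict(fsym, tie_point)
  expect_true(psym$tie)
  expect_equal(psym$predicted, "a")
  expect_error(predict(fit, c(1, 2)), "columns")
})

test_that("a summit-like sample inside a training cluster is assigned to it", {
  cl <- make_clusters(k = 4, n_per = 8, sep = 12, sd = 0.4, seed = 59)
  fit <- cap(cl$x, cl$groups)
  center_c <- colMeans(cl$x[cl$groups == "C", ])
  pr <- predict(fit, center_c + rnorm(3, sd = 0.1))
  expect_equal(pr$predicted, "C")
})

test_that("m selection maximises LOO success with smallest-m tie-breaking", {
  cl <- make_clusters(k = 3, n_per = 7, sep = 10, sd = 0.3, seed = 60)
  fit <- cap(cl$x, cl$groups)
  prof <- fit$loo_profile
  expect_equal(unname(prof[fit$m]), max(prof))
  if (fit$m > 1) expect_true(all(prof[seq_len(fit$m - 1)] < prof[fit$m]))
})
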