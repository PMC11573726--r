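# Gower-centered squared-distance matrix and its eigen-decomposition.
# Returns eigenvectors/values of positive axes plus diag(G) for the
# add-a-point projection.
pcoa_decompose <- function(d2, tol = 1e-9) {
  n <- nrow(d2)
  # double centering G = -1/2 C d2 C via sequential row/column sweeps
  G <- -0.5 * d2
  G <- sweep(G, 1, rowMeans(G))
  G <- sweep(G, 2, colMeans(G))
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  pos <- e$values > tol * max(abs(e$values), 1e-300)
  if (!any(pos)) stop("degenerate distance matrix: no positive PCoA axes",
                      call. = FALSE)
  if (any(e$values < -tol * max(abs(e$values)))) {
    warning("negative PCoA eigenvalues dropped (non-Euclidean input)",
            call. = FALSE)
  }
  list(values = e$values[pos], vectors = e$vectors[, pos, drop = FALSE],
       diagG = diag(G))
}

# U-scale (orthonormal) coordinates of a new point from its squared
# distances to the training points: u = -1/2 L^{-1} U' (d2new - diag(G)).
pcoa_project <- function(dec, d2_new) {
  as.numeric(-0.5 * (t(dec$vectors) %*% (d2_new - dec$diagG)) / dec$values)
}

# canonical analysis of orthonormal PCo axes against group indicators
canonical_axes <- function(U_m, groups) {
  f <- factor(groups)
  g <- nlevels(f)
  idx <- split(seq_len(nrow(U_m)), f)
  # H U_m: replace each row by its group mean
  HU <- U_m
  for (i in idx) HU[i, ] <- matrix(colMeans(U_m[i, , drop = FALSE]),
                                   nrow = length(i), ncol = ncol(U_m),
                                   byrow = TRUE)
  M <- crossprod(U_m, HU)
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  a <- min(ncol(U_m), g - 1)
  keep <- seq_len(a)
  sq_corr <- pmin(pmax(e$values[keep], 0), 1)
  E <- e$vectors[, keep, drop = FALSE]
  Zraw <- U_m %*% E
  # pooled within-group SD per canonical axis (unit within-group variance
  # scaling makes nearest-centroid equal classical LDA on full-rank input)
  w <- vapply(seq_len(a), function(k) {
    ss <- 0
    for (i in idx) {
      z <- Zraw[i, k]
      ss <- ss + sum((z - mean(z))^2)
    }
    sqrt(ss / (nrow(U_m) - g))
  }, numeric(1))
  w[w < 1e-12] <- 1
  Z <- sweep(Zraw, 2, w, "/")
  centroids <- do.call(rbind, lapply(idx, function(i) {
    colMeans(Z[i, , drop = FALSE])
  }))
  rownames(centroids) <- names(idx)
  list(E = E, w = w, scores = Z, centroids = centroids,
       sq_corr = sq_corr, trace = sum(sq_corr), levels = levels(f))
}

classify_nearest <- function(z, centroids, tol = 1e-9) {
  d <- sqrt(rowSums(sweep(centroids, 2, z)^2))
  best <- min(d)
  cand <- which(d <= best + tol)
  list(group = rownames(centroids)[cand[1]], tie = length(cand) > 1,
       distances = d)
}

#' Canonical analysis of principal coordinates (CAP)
#'
#' A distance-based discriminant analysis: the distance matrix is embedded by
#' principal coordinates analysis (Gower centering and
#' eigen-decomposition), the first `m` orthonormal PCo axes are related to
#' the group indicators by canonical correlation analysis, and the trace
#' statistic (sum of squared canonical correlations) measures group
#' separation.  When `m` is not given it is chosen to maximise leave-one-out
#' classification success over `1..min(N-2, 20)` available axes, smallest
#' `m` on ties.
#'
#' Canonical scores are scaled to unit pooled within-group variance, so
#' nearest-centroid classification on full-rank Euclidean input coincides
#' with classical linear discriminant assignment under equal priors.
#'
#' @param x N x p data matrix (rows = samples; for isotope data the columns
#'   are lipid-corrected \eqn{\delta^{13}}C, \eqn{\delta^{15}}N,
#'   \eqn{\delta^{34}}S), or a `dist`/symmetric distance matrix.
#' @param groups Group labels (length N, >= 2 groups, N > number of groups).
#' @param m Number of PCo axes to retain; `NULL` to choose by LOO.
#' @return Object of class `"cap"` with eigenvalues, `m`, squared canonical
#'   correlations, `trace`, canonical scores, group centroids, and the LOO
#'   success profile when `m` was selected automatically.
#' @references Anderson, M.J. and Willis, T.J. (2003) Canonical analysis of
#'   principal coordinates: a useful method of constrained ordination for
#'   ecology. Ecology 84, 511-525.
#' @export
cap <- function(x, groups, m = NULL) {
  if (inherits(x, "dist")) {
    d2 <- as.matrix(x)^2
    data <- NULL
  } else if (is.matrix(x) && nrow(x) == ncol(x) && nrow(x) > 3 &&
             isSymmetric(unname(x)) && all(diag(x) == 0)) {
    d2 <- x^2
    data <- NULL
  } else {
    x <- as.matrix(x)
    data <- x
    d2 <- as.matrix(euclidean_distances(x))^2
  }
  groups <- as.character(groups)
  N <- nrow(d2)
  stopifnot(length(groups) == N)
  g <- length(unique(groups))
  if (g < 2) stop("need at least 2 groups", call. = FALSE)
  if (N <= g) stop("need more samples than groups", call. = FALSE)
  dec <- pcoa_decompose(d2)
  mmax <- min(N - 2, 20, length(dec$values))
  loo_profile <- NULL
  if (is.null(m)) {
    preds <- cap_loo_engine(d2, groups, seq_len(mmax))
    loo_profile <- colMeans(preds == groups)
    m <- which.max(loo_profile)   # which.max takes the first (smallest) tie
  }
  m <- as.integer(m)
  if (m < 1 || m > length(dec$values)) {
    stop("m must be between 1 and the number of positive PCoA axes (",
         length(dec$values), ")", call. = FALSE)
  }
  U_m <- dec$vectors[, seq_len(m), drop = FALSE]
  can <- canonical_axes(U_m, groups)
  structure(list(eigenvalues = dec$values, diagG = dec$diagG,
                 vectors = dec$vectors, m = m, data = data, d2 = d2,
                 groups = groups, sq_corr = can$sq_corr, trace = can$trace,
                 E = can$E, w = can$w, scores = can$scores,
                 centroids = can$centroids, levels = can$levels,
                 loo_profile = loo_profile),
            class = "cap")
}

#' @export
print.cap <- function(x, ...) {
  cat(sprintf("CAP: %d samples, %d groups, m = %d PCo axes\n",
              nrow(x$scores), nrow(x$centroids), x$m))
  cat(sprintf("  trace = %.4g; squared canonical correlations: %s\n",
              x$trace, paste(sprintf("%.3f", x$sq_corr), collapse = ", ")))
  invisible(x)
}

#' @export
summary.cap <- function(object, ...) {
  list(m = object$m, trace = object$trace, sq_corr = object$sq_corr,
       eigenvalues = object$eigenvalues, centroids = object$centroids,
       loo_profile = object$loo_profile)
}

# LOO predictions from the squared-distance matrix, for several candidate m
cap_loo_engine <- function(d2, groups, m_values) {
  N <- nrow(d2)
  preds <- matrix(NA_character_, N, length(m_values))
  for (i in seq_len(N)) {
    sub <- d2[-i, -i, drop = FALSE]
    gsub <- groups[-i]
    if (length(unique(gsub)) < 2) stop("a fold removed an entire group",
                                       call. = FALSE)
    dec <- pcoa_decompose(sub)
    u_new <- pcoa_project(dec, d2[-i, i])
    for (k in seq_along(m_values)) {
      m_eff <- min(m_values[k], length(dec$values))
      can <- canonical_axes(dec$vectors[, seq_len(m_eff), drop = FALSE], gsub)
      z_new <- as.numeric(u_new[seq_len(m_eff)] %*% can$E) / can$w
      preds[i, k] <- classify_nearest(z_new, can$centroids)$group
    }
  }
  preds
}

#' Leave-one-out cross-validated classification for CAP
#'
#' Each sample is withheld in turn, the PCoA/canonical model refit on the
#' remaining samples with the same number of axes `m`, the held-out sample
#' projected into the reduced PCo space by the Gower add-a-point formula and
#' assigned to the nearest group centroid in canonical coordinates.
#'
#' @param x Data matrix or distance matrix (as in [cap()]).
#' @param groups Group labels.
#' @param m Number of PCo axes (e.g. from a fitted [cap()] model).
#' @return Object of class `"cap_confusion"`: `counts` (rows = true group,
#'   cols = predicted), `percent_correct` per true group (rounded to
#'   integer), `overall_percent`, and the per-sample `predicted` labels.
#' @export
cap_loo <- function(x, groups, m) {
  d2 <- if (inherits(x, "dist")) as.matrix(x)^2 else
    as.matrix(euclidean_distances(as.matrix(x)))^2
  groups <- as.character(groups)
  pred <- cap_loo_engine(d2, groups, m)[, 1]
  labs <- sort(unique(groups))
  counts <- table(factor(groups, labs), factor(pred, labs))
  pc <- round(100 * diag(counts) / rowSums(counts))
  structure(list(counts = unclass(counts),
                 percent_correct = pc,
                 overall_percent = round(100 * mean(pred == groups)),
                 predicted = pred, truth = groups),
            class = "cap_confusion")
}

#' @export
print.cap_confusion <- function(x, ...) {
  tab <- cbind(as.data.frame.matrix(x$counts),
               `% correct` = x$percent_correct)
  print(tab)
  cat(sprintf("overall: %d%% correctly classified\n", x$overall_percent))
  invisible(x)
}

#' Permutation test of the CAP trace statistic
#'
#' Group labels are permuted and the trace (sum of squared canonical
#' correlations over the same `m` PCo axes) recomputed for each permutation;
#' \eqn{p = (\#\{trace^* \ge trace\} + 1)/(n_{perm}+1)}.
#'
#' @param x Data matrix or distance matrix.
#' @param groups Group labels.
#' @param m Number of PCo axes.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `trace`, `p_perm`, `n_perm`, `m`.
#' @export
cap_permutation_test <- function(x, groups, m, n_perm = 9999, seed = 1) {
  d2 <- if (inherits(x, "dist")) as.matrix(x)^2 else
    as.matrix(euclidean_distances(as.matrix(x)))^2
  groups <- as.character(groups)
  dec <- pcoa_decompose(d2)
  m <- min(m, length(dec$values))
  U_m <- dec$vectors[, seq_len(m), drop = FALSE]
  g <- length(unique(groups))
  trace_for <- function(lab) {
    idx <- split(seq_len(nrow(U_m)), lab)
    tr <- 0
    for (i in idx) {
      cs <- colSums(U_m[i, , drop = FALSE])
      tr <- tr + sum(cs^2) / length(i)
    }
    # tr(U' H U); with orthonormal U this equals the sum of the
    # min(m, g-1) squared canonical correlations
    tr
  }
  t_obs <- trace_for(groups)
  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    if (trace_for(sample(groups)) >= t_obs - 1e-12) count <- count + 1L
  }
  list(trace = t_obs, p_perm = (count + 1) / (n_perm + 1),
       n_perm = as.integer(n_perm), m = m)
}

#' Assign new samples to groups with a fitted CAP model
#'
#' New observations are projected into the model's principal-coordinate
#' space by the Gower add-a-point formula (from their squared distances to
#' the training samples), mapped to canonical coordinates and assigned to
#' the nearest group centroid.  Ties are broken to the lexicographically
#' first group label and flagged.
#'
#' @param object A fitted `"cap"` model built from a data matrix.
#' @param newdata Matrix (or vector) of new observations with the same
#'   columns as the training data.
#' @param ... Unused.
#' @return data.frame with `predicted`, `tie`, one column of canonical
#'   coordinates per axis (`cap1`, ...), and distances to each group
#'   centroid (`dist_<group>`).
#' @export
predict.cap <- function(object, newdata, ...) {
  if (is.null(object$data)) {
    stop("model was fitted from a distance matrix; raw training data are ",
         "needed to project new samples", call. = FALSE)
  }
  newdata <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else
    as.matrix(newdata)
  if (ncol(newdata) != ncol(object$data)) {
    stop("newdata has ", ncol(newdata), " columns; model was trained on ",
         ncol(object$data), call. = FALSE)
  }
  dec <- list(values = object$eigenvalues, vectors = object$vectors,
              diagG = object$diagG)
  out <- lapply(seq_len(nrow(newdata)), function(r) {
    d2_new <- colSums((t(object$data) - newdata[r, ])^2)
    u <- pcoa_project(dec, d2_new)
    z <- as.numeric(u[seq_len(object$m)] %*% object$E) / object$w
    cl <- classify_nearest(z, object$centroids)
    c(list(predicted = cl$group, tie = cl$tie),
      stats::setNames(as.list(z), paste0("cap", seq_along(z))),
      stats::setNames(as.list(cl$distances),
                      paste0("dist_", rownames(object$centroids))))
  })
  do.call(rbind, lapply(out, function(o) as.data.frame(o,
                                                       stringsAsFactors = FALSE)))
}

#' Ordination plot of a fitted CAP model
#'
#' @param x A `"cap"` model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cap <- function(x, ...) {
  s <- x$scores
  if (ncol(s) == 1) s <- cbind(s, 0)
  f <- factor(x$groups, levels = x$levels)
  graphics::plot(s[, 1], s[, 2], col = as.integer(f), pch = 19,
                 xlab = "CAP axis 1", ylab = "CAP axis 2", ...)
  graphics::legend("topright", legend = levels(f), col = seq_along(levels(f)),
                   pch = 19, cex = 0.8)
  invisible(x)
}
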