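#' Euclidean distance matrix on isotope values
#'
#' Distances are computed on the raw (unstandardised) per-mil values, the
#' three isotopes sharing a common scale.  Lipid-corrected
#' \eqn{\delta^{13}}C is the intended carbon variable.
#'
#' @param values N x p numeric matrix (rows = samples), no missing values.
#' @return A `dist` object.
#' @export
euclidean_distances <- function(values) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) {
    bad <- rownames(values)[apply(!is.finite(values), 1, any)]
    if (is.null(bad)) bad <- which(apply(!is.finite(values), 1, any))
    stop("missing/non-finite values for sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  stats::dist(values, method = "euclidean")
}

# within-group sum of squared distances / group sizes, from squared matrix
ss_within <- function(d2, idx_by_group) {
  s <- 0
  for (idx in idx_by_group) {
    s <- s + sum(d2[idx, idx]) / (2 * length(idx))
  }
  s
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix.
#' The pseudo-F statistic is formed from sums of squared interpoint
#' distances: \eqn{SS_{total} = \sum_{i<j} d_{ij}^2 / N}, within-group SS
#' analogously per group, and
#' \eqn{F = (SS_A/(g-1)) / (SS_W/(N-g))}.  Significance is assessed by
#' permuting raw observations (group labels) and counting permuted statistics
#' at least as large as the observed one:
#' \eqn{p = (\#\{F^* \ge F\} + 1)/(n_{perm} + 1)}.
#'
#' For univariate Euclidean data the pseudo-F is identical to the classical
#' one-way ANOVA F.
#'
#' @param D A `dist` or symmetric distance matrix.
#' @param groups Group labels, length N; each group must have n >= 2.
#' @param n_perm Number of label permutations (>= 99).
#' @param seed Integer seed for the permutation stream.
#' @return Object of class `"permanova"` with `pseudo_F`, `df_among`,
#'   `df_within`, `p_perm`, `n_perm`.
#' @export
permanova <- function(D, groups, n_perm = 9999, seed = 1) {
  d2 <- as.matrix(D)^2
  groups <- as.character(groups)
  N <- nrow(d2)
  stopifnot(length(groups) == N)
  if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop("group(s) of size 1: ", paste(names(sizes)[sizes < 2],
                                       collapse = ", "), call. = FALSE)
  }
  g <- length(sizes)
  df_among <- g - 1L
  df_within <- N - g
  ss_tot <- sum(d2) / (2 * N)
  idx <- split(seq_len(N), groups)
  ssw <- ss_within(d2, idx)
  ssa <- ss_tot - ssw
  F_obs <- if (ssw <= 0) {
    if (ssa <= 1e-12) 0 else Inf
  } else (ssa / df_among) / (ssw / df_within)
  if (ssa <= 1e-12 && ssw <= 1e-12) F_obs <- 0

  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(N)
    idx_p <- lapply(idx, function(i) perm[i])
    ssw_p <- ss_within(d2, idx_p)
    ssa_p <- ss_tot - ssw_p
    F_p <- if (ssw_p <= 0) {
      if (ssa_p <= 1e-12) 0 else Inf
    } else (ssa_p / df_among) / (ssw_p / df_within)
    if (F_p >= F_obs) count <- count + 1L
  }
  p <- (count + 1) / (n_perm + 1)
  structure(list(pseudo_F = F_obs, df_among = df_among,
                 df_within = df_within, p_perm = p,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F[%d,%d] = %.4g, p = %.4g (%d permutations)\n",
              x$df_among, x$df_within, x$pseudo_F, x$p_perm, x$n_perm))
  invisible(x)
}

#' Pairwise post hoc PERMANOVA comparisons
#'
#' For every pair of groups, a two-group PERMANOVA; the reported statistic is
#' \eqn{t = \sqrt{F}} of the two-group test.  p-values are raw permutation
#' p-values without multiplicity adjustment.
#'
#' @inheritParams permanova
#' @return data.frame with columns `group1`, `group2`, `t`, `p_perm`.
#' @export
pairwise_permanova <- function(D, groups, n_perm = 9999, seed = 1) {
  dm <- as.matrix(D)
  groups <- as.character(groups)
  labs <- sort(unique(groups))
  pairs <- utils::combn(labs, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    keep <- groups %in% c(a, b)
    r <- permanova(dm[keep, keep, drop = FALSE], groups[keep],
                   n_perm = n_perm, seed = seed + k)
    data.frame(group1 = a, group2 = b, t = sqrt(max(r$pseudo_F, 0)),
               p_perm = r$p_perm, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
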