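#' Posterior mode by kernel density
#'
#' Argmax of a Gaussian kernel density estimate (Silverman's rule-of-thumb
#' bandwidth) evaluated on a 512-point grid spanning the range of the draws.
#' Degenerate draw sets (all equal) return the common value.
#'
#' @param draws Numeric vector of pooled posterior draws (>= 1000).
#' @return The modal value.
#' @export
posterior_mode <- function(draws) {
  draws <- as.numeric(draws)
  if (length(draws) < 1000) {
    stop("posterior_mode needs at least 1000 pooled draws", call. = FALSE)
  }
  if (diff(range(draws)) == 0) return(draws[1])
  d <- stats::density(draws, bw = "nrd0", n = 512,
                      from = min(draws), to = max(draws))
  d$x[which.max(d$y)]
}

#' Central credible interval
#'
#' @param draws Numeric vector of pooled draws (>= 1000).
#' @param level Coverage level in (0, 1); default 0.95 gives the
#'   (2.5%, 97.5%) quantile interval.
#' @return Numeric `c(lo, hi)`.
#' @export
credible_interval <- function(draws, level = 0.95) {
  if (length(draws) < 1000) {
    stop("credible_interval needs at least 1000 draws", call. = FALSE)
  }
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("level must be in (0, 1)", call. = FALSE)
  }
  a <- (1 - level) / 2
  unname(stats::quantile(draws, c(a, 1 - a), names = FALSE))
}

#' Split-R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, comparing between- and within-half variances.  Values near 1
#' indicate the chains mix over the same distribution.
#'
#' @param draws An iterations x chains numeric matrix (>= 2 chains).
#' @return The split-R-hat value.
#' @export
rhat_split <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) stop("need at least 2 chains", call. = FALSE)
  n <- nrow(draws)
  half <- floor(n / 2)
  if (half < 2) stop("chains too short to split", call. = FALSE)
  splits <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j) {
    cbind(draws[1:half, j], draws[(n - half + 1):n, j])
  }))
  m <- ncol(splits); nh <- nrow(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, stats::var)
  W <- mean(vars)
  B <- nh * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((nh - 1) / nh * W + B / nh) / W)
}

#' Convergence check across monitored parameters
#'
#' @param draws_list Named list of iterations x chains matrices, one per
#'   parameter.
#' @param threshold R-hat above which a parameter is flagged.
#' @return Named numeric vector of split-R-hat values with attribute
#'   `converged` (all below `threshold`).
#' @export
convergence_check <- function(draws_list, threshold = 1.05) {
  r <- vapply(draws_list, rhat_split, numeric(1))
  structure(r, converged = all(is.finite(r) & r < threshold))
}
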