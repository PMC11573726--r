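#' Liver trophic discrimination factors
#'
#' Default diet-to-liver trophic discrimination factors (TDF, mean ± SD) for
#' laboratory mice on a single-source control diet:
#' \eqn{\Delta^{13}}C = 0.7 ± 0.3, \eqn{\Delta^{15}}N = 4.3 ± 0.2,
#' \eqn{\Delta^{34}}S = -2.1 ± 0.1 per-mil.
#'
#' @return List with `d15N_mean`, `d15N_sd`, `d13C_mean`, `d13C_sd`,
#'   `d34S_mean`, `d34S_sd`.
#' @export
tdf_liver <- function() {
  list(d15N_mean = 4.3, d15N_sd = 0.2,
       d13C_mean = 0.7, d13C_sd = 0.3,
       d34S_mean = -2.1, d34S_sd = 0.1)
}

#' Deterministic trophic-position point estimate
#'
#' \deqn{TP = \lambda + (\delta^{15}N_{consumer} - \delta^{15}N_{baseline}) / \Delta^{15}N}
#' where \eqn{\lambda} is the trophic position of the baseline taxon
#' (1 for primary producers).
#'
#' @param consumer_d15N Consumer \eqn{\delta^{15}}N (per-mil); vectorised.
#' @param baseline_d15N Baseline \eqn{\delta^{15}}N (per-mil).
#' @param tdf_d15N Nitrogen trophic discrimination factor (per-mil, non-zero).
#' @param lambda Trophic position of the baseline.
#' @return Trophic position estimate(s).
#' @export
tp_point <- function(consumer_d15N, baseline_d15N, tdf_d15N = 4.3,
                     lambda = 1) {
  if (any(tdf_d15N == 0)) stop("TDF must be non-zero", call. = FALSE)
  lambda + (consumer_d15N - baseline_d15N) / tdf_d15N
}

#' MCMC and prior configuration for trophic-position models
#'
#' Defaults for the population models follow common practice for this model
#' family: 3 chains, 1000 adaptive iterations, 20,000 sampling iterations,
#' 1000 burn-in, thinning 10.  The individual-level model defaults to 16
#' chains, 1000 warm-up iterations and 10,000 kept samples pooled across
#' chains (625 per chain, no thinning); pass
#' `tp_config(model = "individualOneBaseline")` to get them.
#'
#' @param model Model kind the configuration is intended for.
#' @param lambda Trophic position of the baseline (default 1).
#' @param tp_prior Bounds of the uniform TP prior; default
#'   `c(lambda - 0.5, 10)` is permissive (covers sub-baseline consumers) but
#'   bounded for sampler stability.
#' @param n_chains,n_adapt,n_iter,n_burnin,thin MCMC controls; `n_iter` is
#'   pre-thinning sampling iterations per chain.
#' @param seed Integer seed fanned out to per-chain RNG streams.
#' @param sigma_prior_scale Scale of the half-Cauchy priors on residual SDs.
#' @param allow_nonconverged If `FALSE` (default), R-hat >= 1.1 on any
#'   monitored parameter is an error.
#' @return List of class `"tp_config"`.
#' @export
tp_config <- function(model = "oneBaseline", lambda = 1, tp_prior = NULL,
                      n_chains = NULL, n_adapt = 1000, n_iter = NULL,
                      n_burnin = 1000, thin = NULL, seed = 1,
                      sigma_prior_scale = 3, allow_nonconverged = FALSE) {
  individual <- identical(model, "individualOneBaseline")
  if (is.null(n_chains)) n_chains <- if (individual) 16L else 3L
  if (is.null(n_iter)) n_iter <- if (individual) 625L else 20000L
  if (is.null(thin)) thin <- if (individual) 1L else 10L
  if (is.null(tp_prior)) tp_prior <- c(lambda - 0.5, 10)
  stopifnot(lambda >= 1, tp_prior[1] >= 0, tp_prior[1] < tp_prior[2],
            n_chains >= 2, n_iter >= thin, thin >= 1)
  structure(list(model = model, lambda = lambda, tp_prior = tp_prior,
                 n_chains = as.integer(n_chains), n_adapt = as.integer(n_adapt),
                 n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
                 thin = as.integer(thin), seed = as.integer(seed),
                 sigma_prior_scale = sigma_prior_scale,
                 allow_nonconverged = isTRUE(allow_nonconverged)),
            class = "tp_config")
}

# run a JAGS model and return per-parameter iterations x chains matrices;
# param_inits are data-informed starting values so the sampler can evaluate
# the likelihood even under near-degenerate (tight-prior) configurations
run_jags <- function(model_string, data, monitor, cfg, param_inits = list()) {
  inits <- lapply(seq_len(cfg$n_chains), function(ch) {
    c(param_inits,
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = (cfg$seed %% 100000L) * 20L + ch))
  })
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = cfg$n_chains,
                          n.adapt = cfg$n_adapt, quiet = TRUE)
  if (cfg$n_burnin > 0) stats::update(jm, n.iter = cfg$n_burnin,
                                      progress.bar = "none")
  samp <- rjags::coda.samples(jm, variable.names = monitor,
                              n.iter = cfg$n_iter, thin = cfg$thin,
                              progress.bar = "none")
  vars <- colnames(samp[[1]])
  out <- lapply(vars, function(v) {
    do.call(cbind, lapply(samp, function(ch) as.numeric(ch[, v])))
  })
  names(out) <- vars
  out
}

clamp_tp <- function(tp, lo, hi) {
  pad <- 0.02 * (hi - lo)
  min(max(tp, lo + pad), hi - pad)
}

jags_model_one_baseline <- "
model {
  for (i in 1:Nb) { b[i] ~ dnorm(mu_b, tau_b) }
  for (j in 1:Nc) { y[j] ~ dnorm(mu_b + tdf * (TP - lambda), tau_c) }
  mu_b ~ dnorm(b_center, 0.01)
  sigma_b ~ dt(0, sigma_prec, 1) T(0,)
  sigma_c ~ dt(0, sigma_prec, 1) T(0,)
  tau_b <- pow(sigma_b, -2)
  tau_c <- pow(sigma_c, -2)
  tdf ~ dnorm(tdf_mean, pow(tdf_sd, -2))
  TP ~ dunif(tp_lo, tp_hi)
}"

jags_model_two_baselines_full <- "
model {
  for (i in 1:N1) {
    bN1[i] ~ dnorm(mu_N1, pow(sigma_N1, -2))
    bC1[i] ~ dnorm(mu_C1, pow(sigma_C1, -2))
  }
  for (i in 1:N2) {
    bN2[i] ~ dnorm(mu_N2, pow(sigma_N2, -2))
    bC2[i] ~ dnorm(mu_C2, pow(sigma_C2, -2))
  }
  for (j in 1:Nc) {
    yN[j] ~ dnorm(alpha * mu_N1 + (1 - alpha) * mu_N2
                  + tdfN * (TP - lambda), pow(sigma_cN, -2))
    yC[j] ~ dnorm(alpha * mu_C1 + (1 - alpha) * mu_C2
                  + tdfC * (TP - lambda), pow(sigma_cC, -2))
  }
  mu_N1 ~ dnorm(cN1, 0.01)
  mu_N2 ~ dnorm(cN2, 0.01)
  mu_C1 ~ dnorm(cC1, 0.01)
  mu_C2 ~ dnorm(cC2, 0.01)
  sigma_N1 ~ dt(0, sigma_prec, 1) T(0,)
  sigma_N2 ~ dt(0, sigma_prec, 1) T(0,)
  sigma_C1 ~ dt(0, sigma_prec, 1) T(0,)
  sigma_C2 ~ dt(0, sigma_prec, 1) T(0,)
  sigma_cN ~ dt(0, sigma_prec, 1) T(0,)
  sigma_cC ~ dt(0, sigma_prec, 1) T(0,)
  tdfN ~ dnorm(tdfN_mean, pow(tdfN_sd, -2))
  tdfC ~ dnorm(tdfC_mean, pow(tdfC_sd, -2))
  alpha ~ dunif(0, 1)
  TP ~ dunif(tp_lo, tp_hi)
}"

# the baseline-SD prior is Cauchy(location = plant sample SD, scale)
# truncated to [0, Inf); it is sampled through its inverse CDF
# (sigma = loc + scale * tan(pi * (u - 1/2)), u uniform on the truncated
# quantile range) because slice-sampling the heavy Cauchy tail directly
# mixes poorly when a single observation leaves sigma prior-dominated
jags_model_individual <- "
model {
  mu_b ~ dnorm(b_mean, pow(b_sd, -2))
  u ~ dunif(u_lo, 1)
  sigma_b <- sigma_loc + sigma_scale * tan(3.14159265358979 * (u - 0.5))
  y ~ dnorm(mu_b + tdf * (TP - lambda), pow(sigma_b, -2))
  tdf ~ dnorm(tdf_mean, pow(tdf_sd, -2))
  TP ~ dunif(tp_lo, tp_hi)
}"

#' Fit a Bayesian trophic-position model
#'
#' Three model kinds are supported.
#'
#' `"oneBaseline"` (population): plant baseline \eqn{\delta^{15}}N
#' observations are Normal(\eqn{\mu_b, \sigma_b}); consumer
#' \eqn{\delta^{15}}N observations are
#' Normal(\eqn{\mu_b + \Delta^{15}N (TP - \lambda), \sigma_c});
#' \eqn{\Delta^{15}N} has an informative Normal prior from the TDF set; TP is
#' uniform over `cfg$tp_prior`; residual SDs have half-Cauchy priors.
#'
#' `"twoBaselinesFull"` (population, two sources): consumer
#' \eqn{\delta^{15}}N and lipid-corrected \eqn{\delta^{13}}C are both
#' modelled, with source means mixed by a diet proportion
#' \eqn{\alpha \sim U(0,1)} (\eqn{\alpha} = proportion from `source1`, the
#' 13C-depleted C3 source) and both elements shifted by their TDFs times
#' \eqn{(TP - \lambda)}.
#'
#' `"individualOneBaseline"`: for a single consumer value; the baseline mean
#' has a Normal prior at the plant sample mean with the plant sample SD, the
#' baseline SD a Cauchy prior located at the plant sample SD (scale 3)
#' truncated to \eqn{[0, \infty)}, and the single observation is Normal
#' around \eqn{\mu_b + \Delta^{15}N (TP - \lambda)} with that SD.
#'
#' @param consumers For the one-baseline models, a numeric vector of consumer
#'   \eqn{\delta^{15}}N values (exactly one for the individual model).  For
#'   `"twoBaselinesFull"`, a data.frame or list with elements `d15N` and
#'   `d13C` (lipid-corrected).
#' @param baseline A `"baseline"` object, or for `"twoBaselinesFull"` a list
#'   of two (`source1`, `source2`, e.g. from [split_two_sources()]).
#' @param model Model kind.
#' @param tdf TDF set, see [tdf_liver()].
#' @param cfg A [tp_config()]; default configuration for the chosen model.
#' @return Object of class `"tp_fit"`: posterior draws, summaries
#'   (mode, mean, SD, 95% credible interval), split-R-hat per parameter and
#'   a convergence flag.
#' @seealso [tp_point()], [posterior_mode()], [credible_interval()]
#' @export
fit_tp <- function(consumers, baseline,
                   model = c("oneBaseline", "twoBaselinesFull",
                             "individualOneBaseline"),
                   tdf = tdf_liver(), cfg = NULL) {
  model <- match.arg(model)
  if (is.null(cfg)) cfg <- tp_config(model = model)
  sp <- 1 / cfg$sigma_prior_scale^2

  if (model == "oneBaseline") {
    consumers <- as.numeric(consumers)
    if (length(consumers) < 1) stop("no consumer values", call. = FALSE)
    stopifnot(inherits(baseline, "baseline"), baseline$n >= 2)
    data <- list(b = baseline$d15N, Nb = baseline$n,
                 y = consumers, Nc = length(consumers),
                 b_center = baseline$d15N_mean,
                 tdf_mean = tdf$d15N_mean, tdf_sd = tdf$d15N_sd,
                 lambda = cfg$lambda, tp_lo = cfg$tp_prior[1],
                 tp_hi = cfg$tp_prior[2], sigma_prec = sp)
    inits <- list(
      TP = clamp_tp(tp_point(mean(consumers), baseline$d15N_mean,
                             tdf$d15N_mean, cfg$lambda),
                    cfg$tp_prior[1], cfg$tp_prior[2]),
      mu_b = baseline$d15N_mean,
      sigma_b = max(baseline$d15N_sd, 1e-3),
      sigma_c = max(stats::sd(consumers), 1e-3),
      tdf = tdf$d15N_mean)
    if (is.na(inits$sigma_c)) inits$sigma_c <- 1e-3
    draws <- run_jags(jags_model_one_baseline, data,
                      c("TP", "mu_b", "sigma_b", "sigma_c", "tdf"), cfg,
                      inits)
  } else if (model == "twoBaselinesFull") {
    yN <- as.numeric(consumers$d15N); yC <- as.numeric(consumers$d13C)
    if (length(yN) < 1 || length(yN) != length(yC)) {
      stop("consumers must supply matching d15N and d13C vectors",
           call. = FALSE)
    }
    s1 <- baseline$source1; s2 <- baseline$source2
    stopifnot(inherits(s1, "baseline"), inherits(s2, "baseline"),
              s1$n >= 2, s2$n >= 2)
    data <- list(bN1 = s1$d15N, bC1 = s1$d13C, N1 = s1$n,
                 bN2 = s2$d15N, bC2 = s2$d13C, N2 = s2$n,
                 yN = yN, yC = yC, Nc = length(yN),
                 cN1 = s1$d15N_mean, cN2 = s2$d15N_mean,
                 cC1 = s1$d13C_mean, cC2 = s2$d13C_mean,
                 tdfN_mean = tdf$d15N_mean, tdfN_sd = tdf$d15N_sd,
                 tdfC_mean = tdf$d13C_mean, tdfC_sd = tdf$d13C_sd,
                 lambda = cfg$lambda, tp_lo = cfg$tp_prior[1],
                 tp_hi = cfg$tp_prior[2], sigma_prec = sp)
    sd0 <- function(v) { s <- stats::sd(v); if (is.na(s) || s < 1e-3) 1e-3 else s }
    inits <- list(
      TP = clamp_tp(tp_point(mean(yN), (s1$d15N_mean + s2$d15N_mean) / 2,
                             tdf$d15N_mean, cfg$lambda),
                    cfg$tp_prior[1], cfg$tp_prior[2]),
      alpha = 0.5,
      mu_N1 = s1$d15N_mean, mu_N2 = s2$d15N_mean,
      mu_C1 = s1$d13C_mean, mu_C2 = s2$d13C_mean,
      sigma_N1 = sd0(s1$d15N), sigma_N2 = sd0(s2$d15N),
      sigma_C1 = sd0(s1$d13C), sigma_C2 = sd0(s2$d13C),
      sigma_cN = sd0(yN), sigma_cC = sd0(yC),
      tdfN = tdf$d15N_mean, tdfC = tdf$d13C_mean)
    draws <- run_jags(jags_model_two_baselines_full, data,
                      c("TP", "alpha", "mu_N1", "mu_N2", "mu_C1", "mu_C2",
                        "sigma_cN", "sigma_cC"), cfg, inits)
  } else {
    consumers <- as.numeric(consumers)
    if (length(consumers) != 1) {
      stop("the individual model takes exactly one consumer value; ",
           "use the population model for groups", call. = FALSE)
    }
    stopifnot(inherits(baseline, "baseline"), baseline$n >= 2)
    if (is.null(cfg$model) || cfg$model != "individualOneBaseline") {
      cfg <- tp_config(model = "individualOneBaseline", lambda = cfg$lambda,
                       tp_prior = cfg$tp_prior, seed = cfg$seed,
                       sigma_prior_scale = cfg$sigma_prior_scale,
                       allow_nonconverged = cfg$allow_nonconverged)
    }
    loc <- baseline$d15N_sd
    scl <- cfg$sigma_prior_scale
    u_lo <- 0.5 + atan((0 - loc) / scl) / pi
    sigma_init <- max(loc, 1e-3)
    data <- list(y = consumers, b_mean = baseline$d15N_mean,
                 b_sd = baseline$d15N_sd,
                 tdf_mean = tdf$d15N_mean, tdf_sd = tdf$d15N_sd,
                 lambda = cfg$lambda, tp_lo = cfg$tp_prior[1],
                 tp_hi = cfg$tp_prior[2], sigma_loc = loc,
                 sigma_scale = scl, u_lo = u_lo)
    inits <- list(
      TP = clamp_tp(tp_point(consumers, baseline$d15N_mean, tdf$d15N_mean,
                             cfg$lambda), cfg$tp_prior[1], cfg$tp_prior[2]),
      mu_b = baseline$d15N_mean,
      u = min(max(0.5 + atan((sigma_init - loc) / scl) / pi,
                  u_lo + 1e-6), 1 - 1e-6),
      tdf = tdf$d15N_mean)
    draws <- run_jags(jags_model_individual, data,
                      c("TP", "mu_b", "sigma_b", "tdf"), cfg, inits)
  }

  rhat <- convergence_check(draws)
  converged <- attr(rhat, "converged")
  if (any(rhat >= 1.1) && !cfg$allow_nonconverged) {
    stop("MCMC did not converge (split-R-hat >= 1.1 for: ",
         paste(names(rhat)[rhat >= 1.1], collapse = ", "),
         "); increase iterations or set allow_nonconverged", call. = FALSE)
  }
  summarise_param <- function(v) {
    pooled <- as.numeric(draws[[v]])
    ci <- credible_interval(pooled)
    mo <- posterior_mode(pooled)
    c(mode = mo, mean = mean(pooled), sd = stats::sd(pooled),
      lo = ci[1], hi = ci[2])
  }
  params <- intersect(c("TP", "alpha"), names(draws))
  summary <- t(vapply(params, summarise_param, numeric(5)))
  structure(list(model = model, draws = draws, summary = summary,
                 rhat = rhat, converged = converged, cfg = cfg, tdf = tdf,
                 n_consumers = if (model == "twoBaselinesFull")
                   length(data$yN) else length(consumers),
                 n_draws = length(as.numeric(draws[["TP"]]))),
            class = "tp_fit")
}

#' @export
print.tp_fit <- function(x, ...) {
  cat("Bayesian trophic-position model (", x$model, ")\n", sep = "")
  cat(sprintf("  consumers: %d, pooled draws: %d, chains: %d\n",
              x$n_consumers, x$n_draws, x$cfg$n_chains))
  s <- x$summary
  for (p in rownames(s)) {
    cat(sprintf("  %-5s mode %.2f, mean %.2f ± %.2f, 95%% CI (%.2f, %.2f)\n",
                p, s[p, "mode"], s[p, "mean"], s[p, "sd"],
                s[p, "lo"], s[p, "hi"]))
  }
  cat(sprintf("  max split-R-hat %.3f (%s)\n", max(x$rhat),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.tp_fit <- function(object, ...) {
  out <- as.data.frame(object$summary)
  out$rhat <- object$rhat[rownames(out)]
  out
}

#' @export
coef.tp_fit <- function(object, ...) {
  stats::setNames(object$summary[, "mode"], rownames(object$summary))
}

#' Posterior density plot for a trophic-position fit
#'
#' @param x A `"tp_fit"`.
#' @param parameter Parameter to plot (`"TP"` or, for the two-source model,
#'   `"alpha"`).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tp_fit <- function(x, parameter = "TP", ...) {
  pooled <- as.numeric(x$draws[[parameter]])
  d <- stats::density(pooled)
  graphics::plot(d, main = paste("Posterior of", parameter),
                 xlab = parameter, ...)
  graphics::abline(v = x$summary[parameter, "mode"], lty = 2)
  invisible(x)
}
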