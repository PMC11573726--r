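#' Simulate per-individual consumer isotope data from site specifications
#'
#' Draws one row per animal from independent Normals per variable, except
#' that bulk \eqn{\delta^{13}}C and C:N are drawn jointly with a (default
#' negative) correlation, emulating the within-site lipid-content effect.
#' C:N is truncated to `cn_range` by rejection of the joint draw, so the
#' coupling is preserved.  Single-animal sites (SD columns `NA`) reproduce
#' their means exactly.
#'
#' @param specs Site specification table shaped like [phyllotis_sites()]
#'   (the default), with per-site n, means and SDs.
#' @param seed Integer seed; the generator is a pure function of
#'   `(specs, seed)`.
#' @param cn_range Admissible C:N interval.
#' @param cn_d13C_cor Correlation between the C:N and bulk
#'   \eqn{\delta^{13}}C draws within a site.
#' @return Consumer data.frame with columns `sample_id`, `site_id`,
#'   `elevation_m`, `d13C`, `d15N`, `d34S`, `cn_ratio`.
#' @export
simulate_sites <- function(specs = phyllotis_sites(), seed = 1,
                           cn_range = c(3.0, 6.0), cn_d13C_cor = -0.3) {
  stopifnot(all(specs$n >= 1))
  set.seed(seed)
  r <- cn_d13C_cor
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    s <- specs[i, ]
    sdz <- function(v) if (is.na(v)) 0 else v
    n <- s$n
    cn <- numeric(n); d13C <- numeric(n)
    for (k in seq_len(n)) {
      repeat {
        z1 <- stats::rnorm(1)
        z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(1)
        cn_k <- s$cn_mean + sdz(s$cn_sd) * z1
        if (cn_k >= cn_range[1] && cn_k <= cn_range[2]) break
      }
      cn[k] <- cn_k
      d13C[k] <- s$d13C_mean + sdz(s$d13C_sd) * z2
    }
    data.frame(
      sample_id = sprintf("%s-%02d", gsub("\\s+", "", s$site_id), seq_len(n)),
      site_id = s$site_id,
      elevation_m = s$elevation_m,
      d13C = d13C,
      d15N = stats::rnorm(n, s$d15N_mean, sdz(s$d15N_sd)),
      d34S = stats::rnorm(n, s$d34S_mean, sdz(s$d34S_sd)),
      cn_ratio = cn,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Default plant baseline specifications by elevational bin
#'
#' Synthetic stand-ins for regional plant survey data, chosen to match the
#' qualitative elevational structure of Andean primary producers: a
#' C4/CAM-dominated low-elevation flora, a bimodal C3 + C4/CAM mixture at
#' mid elevations (distinct \eqn{\delta^{13}}C modes near -26 and -13
#' per-mil), and a 15N-depleted all-C3 flora above 4000 m.
#'
#' @return List of per-bin specs; each has `bin`, `lower_m`, `upper_m`, `n`
#'   and a `components` data.frame (`weight`, `d13C_mean`, `d13C_sd`,
#'   `d15N_mean`, `d15N_sd`).
#' @export
default_plant_specs <- function() {
  comp <- function(...) data.frame(..., stringsAsFactors = FALSE)
  list(
    list(bin = "2000-3000", lower_m = 2000, upper_m = 3000, n = 20,
         components = comp(weight = 1, d13C_mean = -16, d13C_sd = 4,
                           d15N_mean = 5.0, d15N_sd = 2.0)),
    list(bin = "3000-4000", lower_m = 3000, upper_m = 4000, n = 30,
         components = comp(weight = c(0.5, 0.5),
                           d13C_mean = c(-26, -13), d13C_sd = c(1.5, 1.5),
                           d15N_mean = c(6.2, 6.2), d15N_sd = c(1.5, 1.5))),
    list(bin = "4000-5000", lower_m = 4000, upper_m = 5000, n = 25,
         components = comp(weight = 1, d13C_mean = -26, d13C_sd = 1.5,
                           d15N_mean = 1.8, d15N_sd = 1.5)),
    list(bin = "> 5000", lower_m = 5000, upper_m = 5500, n = 8,
         components = comp(weight = 1, d13C_mean = -26.5, d13C_sd = 1.5,
                           d15N_mean = 1.6, d15N_sd = 1.5))
  )
}

#' Simulate a plant baseline table
#'
#' Draws plant samples per elevational bin from (possibly multi-component)
#' Gaussian mixtures of \eqn{(\delta^{13}C, \delta^{15}N)}; elevations are
#' uniform within the bin.  The generating component label is retained in a
#' `component` column for oracle checks of two-source splitting.
#'
#' @param specs As [default_plant_specs()].
#' @param seed Integer seed.
#' @return Plant data.frame with `plant_id`, `elevation_m`, `d13C`, `d15N`,
#'   `component`.
#' @export
simulate_plants <- function(specs = default_plant_specs(), seed = 1) {
  set.seed(seed)
  rows <- lapply(specs, function(s) {
    if (abs(sum(s$components$weight) - 1) > 1e-9) {
      stop("component weights must sum to 1 in bin '", s$bin, "'",
           call. = FALSE)
    }
    n <- s$n
    if (n == 0) {
      return(data.frame(plant_id = character(0), elevation_m = numeric(0),
                        d13C = numeric(0), d15N = numeric(0),
                        component = integer(0), stringsAsFactors = FALSE))
    }
    k <- sample.int(nrow(s$components), n, replace = TRUE,
                    prob = s$components$weight)
    data.frame(
      plant_id = sprintf("P%s-%02d", gsub("[^0-9><]", "", s$bin), seq_len(n)),
      elevation_m = stats::runif(n, s$lower_m, min(s$upper_m, 9000)),
      d13C = stats::rnorm(n, s$components$d13C_mean[k],
                          s$components$d13C_sd[k]),
      d15N = stats::rnorm(n, s$components$d15N_mean[k],
                          s$components$d15N_sd[k]),
      component = k,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Simulate consumers at known trophic position
#'
#' Inverts the trophic-position equation: consumer
#' \eqn{\delta^{15}N = \mu_{baseline} + \Delta^{15}N (TP_{true} - \lambda) +
#' \epsilon}, \eqn{\epsilon \sim N(0, \sigma_{consumer})}.  With a two-source
#' baseline and a mixing proportion `alpha_true`, both elements are
#' generated (\eqn{\delta^{13}}C uses the carbon TDF).  The truth record is
#' returned alongside the data for parameter-recovery studies.
#'
#' @param tp_true True trophic position (>= 1).
#' @param baseline A `"baseline"` object, or a list of two (`source1`,
#'   `source2`) for the two-source generator.
#' @param n_consumers Number of consumers.
#' @param sigma_consumer Residual SD of consumer values (per-mil).
#' @param alpha_true Diet proportion from `source1` (two-source only).
#' @param tdf TDF set ([tdf_liver()]).
#' @param lambda Baseline trophic position.
#' @param seed Integer seed.
#' @return List with `consumers` (data.frame with `d15N` and, for two
#'   sources, `d13C`) and `truth` (the generating parameters).
#' @export
simulate_consumers_known_tp <- function(tp_true, baseline, n_consumers = 8,
                                        sigma_consumer = 0.5,
                                        alpha_true = NULL, tdf = tdf_liver(),
                                        lambda = 1, seed = 1) {
  stopifnot(tp_true >= 1, n_consumers >= 1, sigma_consumer >= 0)
  set.seed(seed)
  if (inherits(baseline, "baseline")) {
    mu <- baseline$d15N_mean + tdf$d15N_mean * (tp_true - lambda)
    consumers <- data.frame(
      d15N = stats::rnorm(n_consumers, mu, sigma_consumer))
  } else {
    stopifnot(!is.null(alpha_true), alpha_true >= 0, alpha_true <= 1)
    s1 <- baseline$source1; s2 <- baseline$source2
    muN <- alpha_true * s1$d15N_mean + (1 - alpha_true) * s2$d15N_mean +
      tdf$d15N_mean * (tp_true - lambda)
    muC <- alpha_true * s1$d13C_mean + (1 - alpha_true) * s2$d13C_mean +
      tdf$d13C_mean * (tp_true - lambda)
    consumers <- data.frame(
      d15N = stats::rnorm(n_consumers, muN, sigma_consumer),
      d13C = stats::rnorm(n_consumers, muC, sigma_consumer))
  }
  list(consumers = consumers,
       truth = list(tp_true = tp_true, alpha_true = alpha_true,
                    sigma_consumer = sigma_consumer, lambda = lambda,
                    n_consumers = n_consumers, seed = seed))
}

#' Generate a complete small fixture dataset
#'
#' Writes a consumer CSV (default site specifications), a plant CSV
#' (default baseline specifications) and a YAML run configuration into a
#' directory, so the full pipeline can run end-to-end with no external
#' data.  Identical `(seed)` gives byte-identical bundles.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Named list of the written paths (`consumers`, `plants`,
#'   `config`).
#' @export
make_fixture_bundle <- function(dir = tempfile("isoelev_fixture"), seed = 42) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  consumers <- simulate_sites(seed = seed)
  plants <- simulate_plants(seed = seed + 1L)
  p_cons <- file.path(dir, "consumers.csv")
  p_plants <- file.path(dir, "plants.csv")
  p_cfg <- file.path(dir, "config.yaml")
  write_samples(consumers, p_cons)
  utils::write.csv(plants, p_plants, row.names = FALSE, quote = FALSE)
  cfg <- list(consumers = p_cons, plants = p_plants, seed = seed,
              lipid_coeffs = "liver", n_perm = 999,
              mcmc = list(n_iter = 4000, n_burnin = 500, thin = 2,
                          n_adapt = 500))
  yaml::write_yaml(cfg, p_cfg)
  list(consumers = p_cons, plants = p_plants, config = p_cfg)
}
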