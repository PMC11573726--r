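# shared fixtures built in code

# well-separated Gaussian clusters in 3-D
make_clusters <- function(k = 4, n_per = 8, sep = 10, sd = 0.3, seed = 1) {
  set.seed(seed)
  centers <- sep * diag(1, k, 3)
  if (k > 3) centers[4, ] <- c(sep, sep, sep) / sqrt(3)
  x <- centers[rep(seq_len(k), each = n_per), , drop = FALSE] +
    matrix(rnorm(k * n_per * 3, sd = sd), k * n_per, 3)
  list(x = x, groups = rep(LETTERS[seq_len(k)], each = n_per))
}

# light MCMC settings for tests (population models)
light_cfg <- function(seed = 1, ...) {
  tp_config(seed = seed, n_adapt = 500, n_iter = 4000, n_burnin = 500,
            thin = 2, ...)
}

# light settings for the individual model: 4 chains x 500 kept
light_ind_cfg <- function(seed = 1, ...) {
  tp_config(model = "individualOneBaseline", seed = seed, n_adapt = 500,
            n_chains = 4, n_iter = 500, n_burnin = 500, thin = 1, ...)
}

# a baseline object built directly from values
baseline_from <- function(d15N, d13C = rep(-26, length(d15N)),
                          label = "test") {
  plants <- data.frame(plant_id = paste0("p", seq_along(d15N)),
                       elevation_m = 4500, d13C = d13C, d15N = d15N)
  build_baseline(plants, c(4000, 5000), label = label)
}

# small consumer CSV on disk
write_consumer_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
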