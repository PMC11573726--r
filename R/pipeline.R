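verr <- function(...) {
  stop(structure(class = c("isoelev_validation", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Assemble a run configuration
#'
#' Collects all analysis constants in one validated list: input paths (or
#' `NULL` to simulate), bin definitions, lipid coefficient set, TDFs,
#' site-to-baseline mapping, MCMC settings, permutation count, seed and
#' output directory.  Unspecified fields take the package defaults.
#'
#' @param ... Fields overriding the defaults (`consumers`, `plants`, `bins`,
#'   `lipid_coeffs`, `tdf`, `mapping`, `mcmc`, `n_perm`, `seed`, `out_dir`,
#'   `allow_nonconverged`).
#' @return List of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- list(consumers = NULL, plants = NULL, bins = elevation_bins(),
              lipid_coeffs = "liver", tdf = tdf_liver(),
              mapping = default_baseline_mapping(),
              mcmc = list(), n_perm = 9999, seed = 1, out_dir = NULL,
              allow_nonconverged = FALSE)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) verr("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (is.data.frame(cfg$bins)) validate_bins(cfg$bins)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Configuration file; format chosen by extension.
#' @return List of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) verr("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$bins)) raw$bins <- as.data.frame(raw$bins)
  do.call(run_config, raw)
}

# per-stage seed fan-out: independent substreams from one global seed
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 101L + stage * 7919L) %% 2147483629L
}

fmt_num <- function(x, digits = 4) round(x, digits)

#' Run the full stable-isotope analysis pipeline
#'
#' Orchestrates: read (or simulate) consumers, lipid-correct
#' \eqn{\delta^{13}}C, site summaries, plant baselines per elevational bin,
#' Bayesian trophic-position models per site (per the baseline mapping),
#' among-site PERMANOVA with pairwise post hoc tests, CAP assignment to
#' elevational zones with leave-one-out cross-validation, and projection of
#' single-animal sites into the CAP space.  Writes report tables
#' (`site_summary.tsv`, `tp_estimates.tsv`, `permanova.json`,
#' `cap_summary.json`, `confusion.tsv`, `assignments.tsv`, `run_log.txt`)
#' into the output directory.  The global seed is fanned out to per-stage
#' substreams, so a rerun under the same configuration is byte-identical.
#'
#' @param config A [run_config()] (or path read via [read_run_config()]).
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  if (is.null(config$out_dir)) verr("config must name an output directory")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)

  # stage: consumers
  consumers <- tryCatch({
    if (is.null(config$consumers)) {
      simulate_sites(seed = stage_seed(seed, 1L))
    } else if (is.character(config$consumers)) {
      read_samples(config$consumers)
    } else config$consumers
  }, error = function(e) verr("stage consumers: ", conditionMessage(e)))
  consumers$d13C_corrected <- lipid_correct(consumers$d13C,
                                            consumers$cn_ratio,
                                            config$lipid_coeffs)
  consumers$bin <- assign_bin(consumers$elevation_m, config$bins)

  # fail fast: every site must be mapped before any model runs
  sites <- unique(consumers$site_id)
  unmapped <- setdiff(sites, names(config$mapping))
  if (length(unmapped)) verr("stage mapping: unmapped site(s): ",
                             paste(unmapped, collapse = ", "))
  bad_sites <- setdiff(names(config$mapping), sites)
  if (length(bad_sites)) verr("stage mapping: mapping names unknown site(s): ",
                              paste(bad_sites, collapse = ", "))

  # stage: site summary
  summary <- summarize_sites(consumers, config$lipid_coeffs)
  write_site_summary(summary, file.path(config$out_dir, "site_summary.tsv"))

  # stage: plants
  plants <- tryCatch({
    if (is.null(config$plants)) {
      simulate_plants(seed = stage_seed(seed, 2L))
    } else if (is.character(config$plants)) {
      read_plants(config$plants)
    } else config$plants
  }, error = function(e) verr("stage plants: ", conditionMessage(e)))

  # stage: trophic-position models
  mcmc_over <- config$mcmc
  tp_rows <- list(); tp_fits <- list()
  for (k in seq_along(sites)) {
    sid <- sites[k]
    res <- map_site_to_baseline(sid, plants, config$mapping, config$bins)
    sub <- consumers[consumers$site_id == sid, ]
    cfg_args <- c(list(model = if (res$model == "individualOneBaseline")
      "individualOneBaseline" else "oneBaseline",
      seed = stage_seed(seed, 10L + k),
      allow_nonconverged = isTRUE(config$allow_nonconverged)),
      mcmc_over)
    cfg_args$model <- res$model
    tpcfg <- do.call(tp_config, cfg_args)
    fit <- switch(res$model,
      oneBaseline = fit_tp(sub$d15N, res$baselines[[1]], "oneBaseline",
                           config$tdf, tpcfg),
      twoBaselinesFull = fit_tp(
        list(d15N = sub$d15N, d13C = sub$d13C_corrected),
        res$baselines, "twoBaselinesFull", config$tdf, tpcfg),
      individualOneBaseline = fit_tp(sub$d15N, res$baselines[[1]],
                                     "individualOneBaseline", config$tdf,
                                     tpcfg),
      verr("stage tp: unknown model kind '", res$model, "'"))
    s <- fit$summary["TP", ]
    tp_rows[[sid]] <- data.frame(
      site = sid, model = res$model,
      baseline = paste(vapply(fit_baselines(res), `[[`, character(1),
                              "bin_label"), collapse = " + "),
      mode = s[["mode"]], ci_lo = s[["lo"]], ci_hi = s[["hi"]],
      mean = s[["mean"]], sd = s[["sd"]],
      alpha_mode = if ("alpha" %in% rownames(fit$summary))
        fit$summary["alpha", "mode"] else NA_real_,
      max_rhat = max(fit$rhat), converged = fit$converged,
      stringsAsFactors = FALSE)
    tp_fits[[sid]] <- fit
  }
  tp_tab <- do.call(rbind, tp_rows)
  rownames(tp_tab) <- NULL
  tp_out <- tp_tab
  for (col in c("mode", "ci_lo", "ci_hi", "mean", "sd", "alpha_mode")) {
    tp_out[[col]] <- round(tp_out[[col]], 1)
  }
  tp_out$max_rhat <- round(tp_tab$max_rhat, 3)
  utils::write.table(tp_out, file.path(config$out_dir, "tp_estimates.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(tp_tab, file.path(config$out_dir, "tp_estimates.json"),
                       digits = NA, auto_unbox = TRUE)

  # stage: PERMANOVA among sites (multi-animal sites only)
  keep <- consumers$site_id %in% names(which(table(consumers$site_id) >= 2))
  vars <- as.matrix(consumers[keep, c("d13C_corrected", "d15N", "d34S")])
  D <- euclidean_distances(vars)
  pa <- permanova(D, consumers$site_id[keep], n_perm = config$n_perm,
                  seed = stage_seed(seed, 3L))
  pw <- pairwise_permanova(D, consumers$site_id[keep],
                           n_perm = config$n_perm,
                           seed = stage_seed(seed, 4L))
  jsonlite::write_json(
    list(pseudo_F = pa$pseudo_F, df_among = pa$df_among,
         df_within = pa$df_within, p_perm = pa$p_perm, n_perm = pa$n_perm,
         pairwise = pw),
    file.path(config$out_dir, "permanova.json"), digits = NA,
    auto_unbox = TRUE)

  # stage: CAP by elevational bin; single-animal sites held out and assigned
  held_out <- consumers$site_id %in% names(which(table(consumers$site_id) < 2))
  train <- consumers[!held_out, ]
  cap_vars <- as.matrix(train[, c("d13C_corrected", "d15N", "d34S")])
  cap_fit <- cap(cap_vars, train$bin)
  cap_p <- cap_permutation_test(cap_vars, train$bin, cap_fit$m,
                                n_perm = config$n_perm,
                                seed = stage_seed(seed, 5L))
  loo <- cap_loo(cap_vars, train$bin, cap_fit$m)
  jsonlite::write_json(
    list(trace = cap_fit$trace, p_perm = cap_p$p_perm, m = cap_fit$m,
         n_perm = cap_p$n_perm, sq_corr = cap_fit$sq_corr,
         eigenvalues = cap_fit$eigenvalues,
         overall_percent = loo$overall_percent),
    file.path(config$out_dir, "cap_summary.json"), digits = NA,
    auto_unbox = TRUE)
  conf <- cbind(data.frame(true_bin = rownames(loo$counts)),
                as.data.frame.matrix(loo$counts),
                `percent_correct` = loo$percent_correct)
  utils::write.table(conf, file.path(config$out_dir, "confusion.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  assignments <- data.frame(sample_id = train$sample_id,
                            site_id = train$site_id, bin = train$bin,
                            predicted_bin = loo$predicted,
                            held_out = FALSE, stringsAsFactors = FALSE)
  if (any(held_out)) {
    ho <- consumers[held_out, ]
    pr <- predict(cap_fit,
                  as.matrix(ho[, c("d13C_corrected", "d15N", "d34S")]))
    assignments <- rbind(assignments, data.frame(
      sample_id = ho$sample_id, site_id = ho$site_id, bin = ho$bin,
      predicted_bin = pr$predicted, held_out = TRUE,
      stringsAsFactors = FALSE))
  }
  utils::write.table(assignments,
                     file.path(config$out_dir, "assignments.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  writeLines(c(
    paste0("isoelev ", as.character(utils::packageVersion("isoelev"))),
    paste0("seed: ", seed),
    paste0("n_consumers: ", nrow(consumers)),
    paste0("n_plants: ", nrow(plants)),
    paste0("max_rhat: ", round(max(tp_tab$max_rhat), 4)),
    paste0("all_converged: ", all(tp_tab$converged))
  ), file.path(config$out_dir, "run_log.txt"))

  invisible(list(consumers = consumers, summary = summary, plants = plants,
                 tp = tp_tab, tp_fits = tp_fits, permanova = pa,
                 pairwise = pw, cap = cap_fit, cap_test = cap_p, loo = loo,
                 assignments = assignments, config = config))
}

fit_baselines <- function(res) {
  b <- res$baselines
  if (inherits(b, "baseline")) list(b) else b
}

#' Command-line entry point
#'
#' Thin argument-parsing wrapper over the package's functions.  Subcommands:
#' `simulate` (write a fixture bundle), `run` (full pipeline), `correct`
#' (lipid-correct a consumer CSV), `summarize` (site summary TSV), `tp`
#' (trophic-position model for one site), `permanova` and `cap` (among-site
#' tests).  Returns an exit code instead of quitting: 0 success, 2
#' validation/usage error, 1 runtime error.
#'
#' @param argv Character vector of arguments (e.g. `commandArgs(TRUE)`).
#' @return Integer exit code.
#' @export
cli <- function(argv = character()) {
  usage <- function() {
    message("usage: isoelev <simulate|run|correct|summarize|tp|permanova|cap>",
            " [--config FILE] [--in FILE] [--plants FILE] [--site ID]",
            " [--model KIND] [--seed N] [--n-perm N] [--out PATH]",
            " [--allow-nonconverged]")
    2L
  }
  if (length(argv) < 1) return(usage())
  sub <- argv[1]
  args <- argv[-1]
  opts <- list(seed = 1L, n_perm = 999L, allow_nonconverged = FALSE)
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    take <- function() {
      if (i + 1 > length(args)) verr("flag ", a, " needs a value")
      args[i + 1]
    }
    consumed <- 2
    switch(a,
      "--config" = opts$config <- take(),
      "--in" = opts$input <- take(),
      "--plants" = opts$plants <- take(),
      "--site" = opts$site <- take(),
      "--model" = opts$model <- take(),
      "--seed" = opts$seed <- as.integer(take()),
      "--n-perm" = opts$n_perm <- as.integer(take()),
      "--out" = opts$out <- take(),
      "--allow-nonconverged" = { opts$allow_nonconverged <- TRUE
        consumed <- 1 },
      return(usage())
    )
    i <- i + consumed
  }
  run <- function() {
    switch(sub,
      simulate = {
        if (is.null(opts$out)) verr("simulate needs --out DIR")
        b <- make_fixture_bundle(opts$out, seed = opts$seed)
        message("wrote ", paste(unlist(b), collapse = ", "))
      },
      run = {
        cfg <- if (!is.null(opts$config)) read_run_config(opts$config) else
          run_config()
        cfg$seed <- opts$seed
        cfg$allow_nonconverged <- opts$allow_nonconverged
        if (!is.null(opts$out)) cfg$out_dir <- opts$out
        run_pipeline(cfg)
        message("pipeline complete: ", cfg$out_dir)
      },
      correct = {
        if (is.null(opts$input) || is.null(opts$out))
          verr("correct needs --in CSV and --out CSV")
        x <- read_samples(opts$input)
        x$d13C_corrected <- lipid_correct(x$d13C, x$cn_ratio)
        write_samples(x, opts$out)
      },
      summarize = {
        if (is.null(opts$input) || is.null(opts$out))
          verr("summarize needs --in CSV and --out TSV")
        write_site_summary(summarize_sites(read_samples(opts$input)),
                           opts$out)
      },
      tp = {
        if (is.null(opts$input) || is.null(opts$plants) ||
            is.null(opts$site))
          verr("tp needs --in CSV, --plants CSV and --site ID")
        x <- read_samples(opts$input)
        sub_x <- x[x$site_id == opts$site, ]
        if (nrow(sub_x) == 0) verr("no rows for site ", opts$site)
        model <- if (!is.null(opts$model)) opts$model else "oneBaseline"
        if (model %in% c("individual", "individualOneBaseline")) {
          model <- "individualOneBaseline"
          if (nrow(sub_x) != 1)
            verr("the individual model takes exactly one consumer row; ",
                 "site ", opts$site, " has ", nrow(sub_x),
                 " (use the population model)")
        }
        plants <- read_plants(opts$plants)
        res <- map_site_to_baseline(opts$site, plants)
        fit <- fit_tp(sub_x$d15N, res$baselines[[1]], model,
                      cfg = tp_config(model = model, seed = opts$seed,
                        allow_nonconverged = opts$allow_nonconverged))
        out <- as.list(fit$summary["TP", ])
        out$rhat_max <- max(fit$rhat)
        if (!is.null(opts$out)) {
          jsonlite::write_json(out, opts$out, digits = NA, auto_unbox = TRUE)
        } else message(paste(names(out), round(unlist(out), 3),
                             sep = "=", collapse = " "))
      },
      permanova = {
        if (is.null(opts$input)) verr("permanova needs --in CSV")
        x <- read_samples(opts$input)
        x$d13C_corrected <- lipid_correct(x$d13C, x$cn_ratio)
        keep <- x$site_id %in% names(which(table(x$site_id) >= 2))
        D <- euclidean_distances(
          as.matrix(x[keep, c("d13C_corrected", "d15N", "d34S")]))
        r <- permanova(D, x$site_id[keep], n_perm = opts$n_perm,
                       seed = opts$seed)
        out <- list(pseudo_F = r$pseudo_F, df_among = r$df_among,
                    df_within = r$df_within, p_perm = r$p_perm,
                    n_perm = r$n_perm)
        if (!is.null(opts$out)) {
          jsonlite::write_json(out, opts$out, digits = NA, auto_unbox = TRUE)
        } else print(r)
      },
      cap = {
        if (is.null(opts$input)) verr("cap needs --in CSV")
        x <- read_samples(opts$input)
        x$d13C_corrected <- lipid_correct(x$d13C, x$cn_ratio)
        x$bin <- assign_bin(x$elevation_m)
        keep <- x$bin %in% names(which(table(x$bin) >= 2))
        v <- as.matrix(x[keep, c("d13C_corrected", "d15N", "d34S")])
        fit <- cap(v, x$bin[keep])
        tst <- cap_permutation_test(v, x$bin[keep], fit$m,
                                    n_perm = opts$n_perm, seed = opts$seed)
        out <- list(trace = fit$trace, p_perm = tst$p_perm, m = fit$m,
                    n_perm = tst$n_perm)
        if (!is.null(opts$out)) {
          jsonlite::write_json(out, opts$out, digits = NA, auto_unbox = TRUE)
        } else print(fit)
      },
      return(usage())
    )
    0L
  }
  tryCatch(run(),
           isoelev_validation = function(e) {
             message("error: ", conditionMessage(e)); 2L
           },
           error = function(e) {
             msg <- conditionMessage(e)
             input_like <- grepl(
               "file not found|missing required column|validation failed|needs",
               msg)
             message("error: ", msg)
             if (input_like) 2L else 1L
           })
}
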