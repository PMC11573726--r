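#' Default elevational bins
#'
#' Half-open 1000 m capture-elevation bins: \[2000, 3000), \[3000, 4000),
#' \[4000, 5000) and \[5000, Inf).  A boundary elevation belongs to the bin
#' whose lower bound it equals.
#'
#' @param lower Lower edges (m a.s.l.) of all bins but the open top bin.
#' @param top_label Label used for the unbounded top bin.
#' @return A data.frame with columns `label`, `lower_m`, `upper_m`.
#' @export
elevation_bins <- function(lower = c(2000, 3000, 4000, 5000),
                           top_label = "> 5000") {
  stopifnot(length(lower) >= 1, !is.unsorted(lower, strictly = TRUE))
  upper <- c(lower[-1], Inf)
  label <- ifelse(is.finite(upper), paste0(lower, "-", upper), top_label)
  data.frame(label = label, lower_m = lower, upper_m = upper,
             stringsAsFactors = FALSE)
}

#' Assign an elevation to a bin
#'
#' @param elevation_m Elevation(s) in m a.s.l.
#' @param bins Bin table as returned by [elevation_bins()].
#' @return Character vector of bin labels.
#' @export
assign_bin <- function(elevation_m, bins = elevation_bins()) {
  validate_bins(bins)
  idx <- vapply(elevation_m, function(e) {
    i <- which(e >= bins$lower_m & e < bins$upper_m)
    if (length(i) != 1L) {
      stop("elevation ", e, " m falls outside all bins", call. = FALSE)
    }
    i
  }, integer(1))
  bins$label[idx]
}

validate_bins <- function(bins) {
  stopifnot(is.data.frame(bins),
            all(c("label", "lower_m", "upper_m") %in% names(bins)))
  if (any(bins$lower_m >= bins$upper_m)) {
    stop("each bin must have lower_m < upper_m", call. = FALSE)
  }
  o <- order(bins$lower_m)
  lo <- bins$lower_m[o]; up <- bins$upper_m[o]
  if (any(up[-length(up)] > lo[-1])) {
    stop("bins overlap", call. = FALSE)
  }
  invisible(bins)
}

required_sample_cols <- c("sample_id", "site_id", "elevation_m",
                          "d13C", "d15N", "d34S")

#' Read a consumer isotope table from CSV
#'
#' One row per animal with identifiers, capture elevation, the three isotope
#' values and either a `cn_ratio` column or `percent_C` + `percent_N` columns
#' from which the C:N mass ratio is computed.  Rows violating the data
#' invariants (isotope values within \eqn{\pm 60} per-mil, elevation within
#' 0--9000 m, C:N > 0) are reported with their `sample_id`.
#'
#' @param path CSV file with header; `""`/`"NA"` are missing.
#' @param schema Optional named character vector mapping the canonical column
#'   names (`sample_id`, `site_id`, `elevation_m`, `d13C`, `d15N`, `d34S`,
#'   `percent_C`, `percent_N`, `cn_ratio`) to the names used in the file.
#' @return A data.frame of validated samples with a `cn_ratio` column filled.
#' @export
read_samples <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      j <- match(schema[[canon]], names(raw))
      if (!is.na(j)) names(raw)[j] <- canon
    }
  }
  missing_cols <- setdiff(required_sample_cols, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  has_cn <- "cn_ratio" %in% names(raw)
  has_pc <- all(c("percent_C", "percent_N") %in% names(raw))
  if (!has_cn && !has_pc) {
    stop("need either a cn_ratio column or percent_C and percent_N columns",
         call. = FALSE)
  }
  num_cols <- intersect(c("elevation_m", "d13C", "d15N", "d34S",
                          "percent_C", "percent_N", "cn_ratio"), names(raw))
  for (col in num_cols) {
    if (!is.numeric(raw[[col]])) {
      bad <- which(!is.na(raw[[col]]) &
                     is.na(suppressWarnings(as.numeric(raw[[col]]))))
      if (length(bad)) {
        stop("non-numeric value in column '", col, "' at row(s) ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      raw[[col]] <- as.numeric(raw[[col]])
    }
  }
  if (!has_cn) raw$cn_ratio <- NA_real_
  fill <- is.na(raw$cn_ratio)
  if (any(fill)) {
    if (!has_pc) {
      stop("cn_ratio missing and no percent_C/percent_N to compute it for ",
           "sample(s): ", paste(raw$sample_id[fill], collapse = ", "),
           call. = FALSE)
    }
    zeroN <- fill & (is.na(raw$percent_N) | raw$percent_N == 0)
    if (any(zeroN)) {
      stop("percent_N is zero or missing (C:N undefined) for sample(s): ",
           paste(raw$sample_id[zeroN], collapse = ", "), call. = FALSE)
    }
    raw$cn_ratio[fill] <- raw$percent_C[fill] / raw$percent_N[fill]
  }
  validate_samples(raw)
  raw
}

validate_samples <- function(x) {
  bad <- function(cond) x$sample_id[which(cond)]
  problems <- character(0)
  iso <- c("d13C", "d15N", "d34S")
  for (col in iso) {
    b <- bad(!is.finite(x[[col]]) | abs(x[[col]]) > 60)
    if (length(b)) problems <- c(problems, paste0(
      col, " outside [-60, 60] or missing: ", paste(b, collapse = ", ")))
  }
  b <- bad(!is.finite(x$elevation_m) | x$elevation_m < 0 | x$elevation_m > 9000)
  if (length(b)) problems <- c(problems,
    paste0("elevation_m outside [0, 9000]: ", paste(b, collapse = ", ")))
  b <- bad(!is.finite(x$cn_ratio) | x$cn_ratio <= 0)
  if (length(b)) problems <- c(problems,
    paste0("cn_ratio not positive: ", paste(b, collapse = ", ")))
  if (all(c("percent_C", "percent_N") %in% names(x))) {
    ok <- !is.na(x$percent_C) & !is.na(x$percent_N) & x$percent_N != 0
    b <- bad(ok & abs(x$cn_ratio - x$percent_C / x$percent_N) > 1e-9)
    if (length(b)) problems <- c(problems,
      paste0("cn_ratio inconsistent with percent_C/percent_N: ",
             paste(b, collapse = ", ")))
  }
  if (length(problems)) {
    stop("sample validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(x)
}

#' Write a consumer table to CSV
#'
#' Inverse of [read_samples()]; `read_samples(write_samples(x, f))`
#' round-trips valid data.
#'
#' @param x Sample data.frame.
#' @param path Output CSV path.
#' @export
write_samples <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Per-site summary statistics
#'
#' n, mean and sample SD (n-1 denominator) of each isotope (bulk and
#' lipid-corrected \eqn{\delta^{13}}C, \eqn{\delta^{15}}N,
#' \eqn{\delta^{34}}S) and of the C:N ratio, per site, ordered by elevation.
#' SDs are `NA` for single-animal sites.  The lipid correction is applied per
#' individual before summarising if a `d13C_corrected` column is not present.
#'
#' @param samples Validated sample data.frame (see [read_samples()]).
#' @param coeffs Lipid coefficient set for on-the-fly correction.
#' @return A data.frame shaped like [phyllotis_sites()].
#' @export
summarize_sites <- function(samples, coeffs = "liver") {
  stopifnot(nrow(samples) >= 1)
  if (!"d13C_corrected" %in% names(samples)) {
    samples$d13C_corrected <- lipid_correct(samples$d13C, samples$cn_ratio,
                                            coeffs)
  }
  sd_or_na <- function(v) if (length(v) >= 2) stats::sd(v) else NA_real_
  out <- do.call(rbind, lapply(split(samples, samples$site_id), function(s) {
    data.frame(
      site_id = s$site_id[1],
      elevation_m = mean(s$elevation_m),
      n = nrow(s),
      d13C_mean = mean(s$d13C),          d13C_sd = sd_or_na(s$d13C),
      d13C_corr_mean = mean(s$d13C_corrected),
      d13C_corr_sd = sd_or_na(s$d13C_corrected),
      d15N_mean = mean(s$d15N),          d15N_sd = sd_or_na(s$d15N),
      d34S_mean = mean(s$d34S),          d34S_sd = sd_or_na(s$d34S),
      cn_mean = mean(s$cn_ratio),        cn_sd = sd_or_na(s$cn_ratio),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(out$elevation_m), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a site summary as a report TSV
#'
#' Values rounded to 1 decimal per-mil; single-animal SDs rendered as
#' an em-dash placeholder.
#'
#' @param summary Output of [summarize_sites()].
#' @param path Output TSV path.
#' @export
write_site_summary <- function(summary, path) {
  fmt <- function(m, s) ifelse(is.na(s),
                               paste0(round(m, 1), " (-)"),
                               paste0(round(m, 1), " (±", round(s, 1), ")"))
  tab <- data.frame(
    site = summary$site_id,
    elevation_m = summary$elevation_m,
    n = summary$n,
    d13C = fmt(summary$d13C_mean, summary$d13C_sd),
    d13C_lipid_corrected = fmt(summary$d13C_corr_mean, summary$d13C_corr_sd),
    d15N = fmt(summary$d15N_mean, summary$d15N_sd),
    d34S = fmt(summary$d34S_mean, summary$d34S_sd),
    CN = fmt(summary$cn_mean, summary$cn_sd),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
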