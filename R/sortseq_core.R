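#' Convert per-bin read counts to estimated cell counts
#'
#' Within each bin, a variant's reads are normalised by the bin's total reads
#' and the fraction is multiplied by the number of cells sorted into that
#' bin. Column sums of the result therefore equal `cells_sorted` for every
#' bin that received reads.
#'
#' @param counts Integer matrix, variants x bins (as from
#'   [demultiplex_and_count()]).
#' @param manifest A [bin_manifest()] supplying `cells_sorted`.
#' @return Numeric matrix of estimated cells, same dimensions as `counts`.
#' @export
counts_to_cells <- function(counts, manifest) {
  counts <- as.matrix(counts)
  if (ncol(counts) != nrow(manifest))
    stop("counts has ", ncol(counts), " bins but manifest has ", nrow(manifest))
  tot <- colSums(counts)
  bad <- tot > 0 & manifest$cells_sorted == 0
  if (any(bad))
    stop("bin(s) with reads but cells_sorted = 0: ",
         paste(manifest$bin[bad], collapse = ", "))
  frac <- sweep(counts, 2, ifelse(tot > 0, tot, 1), "/")
  frac[, tot == 0] <- 0
  sweep(frac, 2, manifest$cells_sorted, "*")
}

#' Per-variant occupancy statistics
#'
#' @param cells Numeric matrix of estimated cells, variants x bins.
#' @return Tibble with `variant`, `cps` (total estimated cells per sequence)
#'   and `bins_occupied`.
#' @export
variant_stats <- function(cells) {
  tibble::tibble(
    variant = rownames(cells) %||% as.character(seq_len(nrow(cells))),
    cps = unname(rowSums(cells)),
    bins_occupied = unname(rowSums(cells > 0))
  )
}

#' Minimum-sampling filters
#'
#' Removes variants observed in fewer than `min_bins` bins or with fewer than
#' `min_cps` estimated cells per sequence (CPS). Both bounds are inclusive on
#' the keep side ("less than" removes), so a variant with exactly
#' `min_cps` cells in exactly `min_bins` bins is kept.
#'
#' @param cells Numeric matrix of estimated cells, variants x bins.
#' @param min_bins Minimum occupied bins (default 2).
#' @param min_cps Minimum cells per sequence (default 20).
#' @return List with `kept` (submatrix of `cells`) and `removed` (tibble of
#'   `variant`, `cps`, `bins_occupied`, `reason`; reasons `"bins"`, `"cps"`
#'   or `"bins;cps"`).
#' @export
filter_variants <- function(cells, min_bins = 2, min_cps = 20) {
  st <- variant_stats(cells)
  fail_bins <- st$bins_occupied < min_bins
  fail_cps <- st$cps < min_cps
  keep <- !fail_bins & !fail_cps
  reason <- character(nrow(st))
  reason[fail_bins] <- "bins"
  reason[fail_cps] <- "cps"
  reason[fail_bins & fail_cps] <- "bins;cps"
  removed <- st[!keep, ]
  removed$reason <- reason[!keep]
  list(kept = cells[keep, , drop = FALSE], removed = removed)
}

#' Replicate-concordance gate
#'
#' Percent error of a statistic across replicates is the sample standard
#' deviation divided by the mean, times 100. A variant passes when its
#' percent error in mean fluorescence and in CV-squared both stay at or below
#' their thresholds (`rule = "either"`: exceeding either one fails the
#' variant; `rule = "both"`: a variant fails only when both are exceeded).
#' Variants present in fewer than two replicates are removed.
#'
#' @param fits Data frame with columns `variant`, `replicate`, `mean`, `cv2`
#'   (one row per variant per replicate, e.g. stacked [fit_gamma_all()]
#'   tables).
#' @param max_err_mean Threshold (percent) on the mean's error (default 30).
#' @param max_err_cv2 Threshold (percent) on CV-squared's error (default 40).
#' @param rule `"either"` (default) or `"both"`; see above.
#' @return List with `kept` and `removed` tibbles (`variant`,
#'   `err_mean`, `err_cv2`, `n_replicates`; `removed` adds `reason`).
#' @export
replicate_gate <- function(fits, max_err_mean = 30, max_err_cv2 = 40,
                           rule = c("either", "both")) {
  rule <- match.arg(rule)
  stopifnot(all(c("variant", "replicate", "mean", "cv2") %in% names(fits)))
  pct_err <- function(x) if (length(x) < 2) NA_real_ else
    100 * stats::sd(x) / base::mean(x)
  sp <- split(fits, fits$variant)
  st <- tibble::tibble(
    variant = names(sp),
    n_replicates = unname(vapply(sp, nrow, integer(1))),
    err_mean = unname(vapply(sp, function(d) pct_err(d$mean), numeric(1))),
    err_cv2 = unname(vapply(sp, function(d) pct_err(d$cv2), numeric(1)))
  )
  single <- st$n_replicates < 2
  over_m <- !single & st$err_mean > max_err_mean
  over_c <- !single & st$err_cv2 > max_err_cv2
  fail_err <- if (rule == "either") over_m | over_c else over_m & over_c
  keep <- !single & !fail_err
  reason <- character(nrow(st))
  reason[single] <- "single_replicate"
  reason[over_m & !single] <- "err_mean"
  reason[over_c & !single] <- "err_cv2"
  reason[over_m & over_c] <- "err_mean;err_cv2"
  if (rule == "both") reason[fail_err] <- "err_mean;err_cv2"
  removed <- st[!keep, ]
  removed$reason <- reason[!keep]
  list(kept = st[keep, ], removed = removed)
}

#' Regress a distribution statistic on a codon metric
#'
#' Ordinary least squares of a fitted distribution statistic (mean, variance
#' or CV-squared) on a per-variant sequence metric; reports the slope, R-squared
#' and the two-sided p-value for the slope.
#'
#' @param records Data frame with one row per variant containing both the
#'   statistic and the metric columns.
#' @param metric Name of the predictor column (e.g. `"tai"`).
#' @param response Name of the response column (default `"mean"`).
#' @return One-row tibble: `metric`, `response`, `n`, `slope`, `r_squared`,
#'   `p_value`.
#' @export
associate_metrics <- function(records, metric, response = "mean") {
  stopifnot(metric %in% names(records), response %in% names(records))
  d <- records[is.finite(records[[metric]]) & is.finite(records[[response]]), ]
  if (nrow(d) < 3) stop("need at least 3 records for regression, have ", nrow(d))
  fit <- stats::lm(d[[response]] ~ d[[metric]])
  sm <- summary(fit)
  tibble::tibble(
    metric = metric, response = response, n = nrow(d),
    slope = unname(coef(fit)[2]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2, 4]
  )
}
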