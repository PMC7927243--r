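make_manifest <- function(n_bins = 4, cells = rep(1000, n_bins), lo = 10) {
  edges <- exp(seq(log(lo), log(lo * 2^n_bins), length.out = n_bins + 1))
  bin_manifest_from_edges(edges, make_barcodes(n_bins, seed = 5), cells)
}

test_that("bin manifest validates its design invariants", {
  m <- make_manifest(4)
  expect_s3_class(m, "bin_manifest")
  expect_equal(nrow(m), 4)

  bc <- make_barcodes(3, seed = 5)
  expect_error(bin_manifest(c(1, 2, 4), c(2, 4, 8), c(bc[1], bc[1], bc[2]),
                            rep(1, 3)), "duplicate")
  expect_error(bin_manifest(c(1, 3), c(2, 6), bc[1:2], rep(1, 2)),
               "contiguous")
  expect_error(bin_manifest(c(1, 2), c(2, 8), bc[1:2], rep(1, 2),
                            spacing = "log"), "constant")
  expect_error(bin_manifest(1, 2, "ACGT", 1), "9 bases")
})

test_that("manifest files round-trip through TSV and YAML", {
  m <- make_manifest(3)
  tsv <- tempfile(fileext = ".tsv")
  write_bin_manifest(m, tsv)
  m2 <- read_bin_manifest(tsv)
  expect_equal(as.data.frame(m2), as.data.frame(m), tolerance = 1e-12)
  expect_equal(attr(m2, "spacing"), "log")

  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(spacing = "log", bins = lapply(seq_len(nrow(m)),
    function(i) as.list(as.data.frame(m)[i, c("lower", "upper", "barcode",
                                              "cells_sorted")]))), yml)
  m3 <- read_bin_manifest(yml)
  expect_equal(m3$barcode, m$barcode)
  expect_equal(m3$lower, m$lower, tolerance = 1e-9)
})

test_that("demultiplexing assigns perfect reads and logs discards", {
  m <- make_manifest(2)
  lay <- read_layout()
  v1 <- strrep("ACGT", 6)
  v2 <- strrep("GGCA", 6)
  mk <- function(v, b) paste0(lay$flank5, v, lay$flank3, m$barcode[b])
  reads <- c(mk(v1, 1), mk(v1, 2), mk(v2, 1), mk(v2, 2))
  dm <- demultiplex_and_count(reads, m, lay)
  expect_equal(unname(colSums(dm$counts)), c(2, 2))
  expect_equal(unname(dm$counts[v1, ]), c(1, 1))
  expect_equal(sum(dm$discards), 0)

  bad <- c(mk(v1, 1), paste0(lay$flank5, v1, lay$flank3, "AAAAAAAAA"),
           paste0("T", substr(mk(v1, 1), 1, 56)),      # shifted frame
           sub("ACGT", "ANGT", mk(v1, 1)), "ACGT")     # ambiguous / truncated
  dm2 <- demultiplex_and_count(bad, m, lay)
  expect_equal(sum(dm2$counts), 1)
  expect_equal(unname(dm2$discards["unmatched_barcode"]), 1)
  expect_equal(unname(dm2$discards["flank_mismatch"]), 1)
  expect_equal(unname(dm2$discards["ambiguous_base"]), 1)
  expect_equal(unname(dm2$discards["truncated"]), 1)

  # one-mismatch barcode rescue is opt-in
  near <- paste0(lay$flank5, v1, lay$flank3,
                 sub("^.", ifelse(substr(m$barcode[1], 1, 1) == "A", "C", "A"),
                     m$barcode[1]))
  expect_equal(sum(demultiplex_and_count(near, m, lay)$counts), 0)
  expect_equal(sum(demultiplex_and_count(near, m, lay,
                                         max_barcode_mismatch = 1)$counts), 1)
})

test_that("cell-count normalisation conserves bin totals", {
  m <- make_manifest(2, cells = c(1000, 500))
  counts <- matrix(c(10, 90, 0, 0), nrow = 2,
                   dimnames = list(c("v1", "v2"), 1:2))
  cells <- counts_to_cells(counts, m)
  expect_equal(cells["v1", 1], 100) # 10/100 reads of 1000 cells
  expect_equal(unname(cells[, 2]), c(0, 0))

  # random matrices: column sums equal cells_sorted; entries match a loop oracle
  for (seed in 1:5) {
    cm <- withr::with_seed(seed, matrix(rpois(12, 40), nrow = 3,
                                        dimnames = list(paste0("v", 1:3), 1:4)))
    mm <- make_manifest(4, cells = c(100, 200, 300, 400))
    cc <- counts_to_cells(cm, mm)
    expect_equal(unname(colSums(cc)), mm$cells_sorted, tolerance = 1e-9)
    for (b in 1:4) for (v in 1:3)
      expect_equal(cc[v, b], cm[v, b] / sum(cm[, b]) * mm$cells_sorted[b])
  }

  m0 <- make_manifest(2, cells = c(1000, 0))
  expect_error(counts_to_cells(matrix(1, 1, 2), m0), "cells_sorted = 0")
})

test_that("minimum-bin and CPS filters apply inclusively and commute", {
  cells <- rbind(
    one_bin = c(50, 0, 0),
    low_cps = c(10, 9, 0),
    boundary = c(10, 10, 0),
    good = c(40, 30, 30))
  flt <- filter_variants(cells, min_bins = 2, min_cps = 20)
  expect_setequal(rownames(flt$kept), c("boundary", "good"))
  expect_equal(flt$removed$reason[flt$removed$variant == "one_bin"], "bins")
  expect_equal(flt$removed$reason[flt$removed$variant == "low_cps"], "cps")

  # order independence / idempotence: bins-then-cps == cps-then-bins == joint
  a <- filter_variants(filter_variants(cells, min_bins = 2, min_cps = 0)$kept,
                       min_bins = 0, min_cps = 20)$kept
  b <- filter_variants(filter_variants(cells, min_bins = 0, min_cps = 20)$kept,
                       min_bins = 2, min_cps = 0)$kept
  expect_identical(a, b)
  expect_identical(a, flt$kept)
  expect_identical(filter_variants(flt$kept)$kept, flt$kept)
})

test_that("gamma fits satisfy the moment identities and recover truth", {
  m20 <- bin_manifest_from_edges(
    exp(seq(log(5), log(5000), length.out = 21)),
    make_barcodes(20, seed = 2), rep(0, 20))
  x <- withr::with_seed(11, rgamma(50000, shape = 3, scale = 50))
  counts <- tabulate(findInterval(x, m20$lower, rightmost.closed = FALSE), 20)
  fit <- fit_gamma(counts, m20)
  expect_true(fit$converged)
  expect_lt(abs(fit$alpha - 3) / 3, 0.05)
  expect_lt(abs(fit$mean - 150) / 150, 0.02)

  # Eqs.-of-moment identities hold exactly for the emitted parameters
  expect_equal(fit$mean, fit$alpha * fit$beta, tolerance = 1e-12)
  expect_equal(fit$variance, fit$alpha * fit$beta^2, tolerance = 1e-12)
  expect_equal(fit$cv2, 1 / fit$alpha, tolerance = 1e-12)
  expect_equal(fit$variance / fit$mean^2, fit$cv2, tolerance = 1e-9)

  expect_error(fit_gamma(c(100, 0, 0, rep(0, 17)), m20), "at least 2 bins")
})

test_that("fit_gamma_all flags unfittable variants instead of aborting", {
  m <- make_manifest(4)
  cells <- rbind(ok = c(10, 20, 10, 0), onebin = c(40, 0, 0, 0))
  fits <- fit_gamma_all(cells, m)
  expect_equal(nrow(fits), 2)
  expect_true(fits$converged[fits$variant == "ok"])
  expect_false(fits$converged[fits$variant == "onebin"])
})

test_that("replicate gate computes percent error as sd/mean and applies thresholds", {
  mk <- function(v, means, cv2s) tibble::tibble(
    variant = v, replicate = seq_along(means), mean = means, cv2 = cv2s)
  fits <- rbind(
    mk("same", c(100, 100, 100), c(0.2, 0.2, 0.2)),
    mk("noisy_mean", c(100, 100, 200), c(0.2, 0.2, 0.2)),
    mk("boundary", c(100, 100 * (1 + 0.29 * sqrt(2)), 100)[1:2], c(0.2, 0.2)),
    mk("single", 100, 0.2))
  gate <- replicate_gate(fits)
  expect_true("same" %in% gate$kept$variant)
  expect_equal(gate$kept$err_mean[gate$kept$variant == "same"], 0)

  nm <- gate$removed[gate$removed$variant == "noisy_mean", ]
  expect_equal(nm$err_mean, 100 * sd(c(100, 100, 200)) / mean(c(100, 100, 200)),
               tolerance = 1e-12)
  expect_gt(nm$err_mean, 43)
  expect_equal(nm$reason, "err_mean")

  # 29%-ish mean error and low cv2 error stays in ("above 30%" is strict)
  expect_true("boundary" %in% gate$kept$variant)
  expect_equal(gate$removed$reason[gate$removed$variant == "single"],
               "single_replicate")

  # under the conjunctive reading, a variant must exceed both to be removed
  gate2 <- replicate_gate(fits, rule = "both")
  expect_true("noisy_mean" %in% gate2$kept$variant)
})

test_that("metric association reports OLS slope, R2 and p", {
  d <- tibble::tibble(tai = 1:10 / 10, mean = 3 + 2 * (1:10 / 10))
  r <- suppressWarnings(associate_metrics(d, "tai", "mean")) # exact fit
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_equal(r$slope, 2, tolerance = 1e-9)

  # textbook 5-point case against the closed-form normal equations
  d5 <- tibble::tibble(x = c(1, 2, 3, 4, 5), y = c(2, 4, 5, 4, 5))
  r5 <- associate_metrics(d5, "x", "y")
  sxy <- sum((d5$x - 3) * (d5$y - 4)); sxx <- sum((d5$x - 3)^2)
  expect_equal(r5$slope, sxy / sxx, tolerance = 1e-12)
  expect_equal(r5$r_squared, sxy^2 / (sxx * sum((d5$y - 4)^2)),
               tolerance = 1e-12)

  # permuted metric carries no signal
  dperm <- withr::with_seed(3, tibble::tibble(x = runif(200),
                                              y = sample(runif(200))))
  expect_lt(associate_metrics(dperm, "x", "y")$r_squared, 0.05)

  expect_error(associate_metrics(d5[1:2, ], "x", "y"), "at least 3")
})
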