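#' Construct a bin manifest
#'
#' The manifest records the sorting design: for each fluorescence bin its
#' lower/upper gate (arbitrary fluorescence units), the 9-base sequencing
#' barcode identifying the bin, and the number of cells the sorter deposited
#' in it. Bins must be contiguous and strictly increasing; under `"log"`
#' spacing the upper/lower ratio must be constant across bins.
#'
#' @param lower,upper Numeric vectors of bin bounds (upper\[i\] == lower\[i+1\]).
#' @param barcode Character vector of pairwise-distinct 9-base barcodes.
#' @param cells_sorted Non-negative integer vector, cells sorted per bin.
#' @param spacing `"log"` or `"linear"`.
#' @return A `bin_manifest` tibble with columns `bin`, `lower`, `upper`,
#'   `barcode`, `cells_sorted` and a `spacing` attribute.
#' @export
bin_manifest <- function(lower, upper, barcode, cells_sorted,
                         spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  n <- length(lower)
  stopifnot(length(upper) == n, length(barcode) == n, length(cells_sorted) == n)
  if (any(upper <= lower)) stop("bin bounds must be strictly increasing")
  if (n > 1 && any(abs(upper[-n] - lower[-1]) > 1e-8 * upper[-n]))
    stop("bins must be contiguous: upper[i] must equal lower[i+1]")
  if (spacing == "log") {
    if (any(lower <= 0)) stop("log-spaced bins need positive bounds")
    r <- upper / lower
    if (max(r) / min(r) > 1 + 1e-6)
      stop("log spacing requires a constant upper/lower ratio across bins")
  }
  barcode <- toupper(barcode)
  if (any(nchar(barcode) != 9)) stop("barcodes must be 9 bases")
  if (anyDuplicated(barcode)) stop("duplicate bin barcodes in manifest")
  if (!is_count(cells_sorted)) stop("cells_sorted must be non-negative integers")
  out <- tibble::tibble(bin = seq_len(n), lower = lower, upper = upper,
                        barcode = barcode, cells_sorted = as.numeric(cells_sorted))
  attr(out, "spacing") <- spacing
  class(out) <- c("bin_manifest", class(out))
  out
}

#' Build a manifest from a vector of bin edges
#'
#' @param edges Numeric vector of n_bins + 1 increasing edges.
#' @inheritParams bin_manifest
#' @export
bin_manifest_from_edges <- function(edges, barcode, cells_sorted,
                                    spacing = c("log", "linear")) {
  k <- length(edges) - 1
  bin_manifest(edges[seq_len(k)], edges[-1], barcode, cells_sorted, spacing)
}

#' Read / write a bin manifest file
#'
#' Tab-separated (`bin`, `lower`, `upper`, `barcode`, `cells_sorted`, with the
#' spacing on a `# spacing:` comment line) or YAML (`spacing:` plus a `bins:`
#' list with the same fields). Format chosen by file extension
#' (`.yml`/`.yaml` vs anything else).
#'
#' @param path File path.
#' @return A `bin_manifest` (reader) or `path` invisibly (writer).
#' @export
read_bin_manifest <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    b <- do.call(rbind, lapply(y$bins, as.data.frame))
    return(bin_manifest(b$lower, b$upper, b$barcode, b$cells_sorted,
                        spacing = y$spacing %||% "log"))
  }
  first <- readLines(path, n = 1)
  spacing <- if (grepl("^#\\s*spacing:", first))
    sub("^#\\s*spacing:\\s*", "", first) else "log"
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  bin_manifest(tab$lower, tab$upper, tab$barcode, tab$cells_sorted, spacing)
}

#' @rdname read_bin_manifest
#' @param manifest A `bin_manifest`.
#' @export
write_bin_manifest <- function(manifest, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# spacing: ", attr(manifest, "spacing")), con)
  utils::write.table(as.data.frame(manifest), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
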