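# Plain-text readers for user-supplied weight tables. All files are
# tab-separated with a header row; schemas documented per reader.

#' Read a CAI weight table
#'
#' Two tab-separated columns: `codon`, `w` (relative adaptiveness in (0, 1]).
#'
#' @param path File path.
#' @return Named numeric vector, codon -> w.
#' @export
read_cai_weights <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("codon", "w") %in% names(tab)))
  w <- setNames(tab$w, as_codons(tab$codon))
  if (any(w <= 0 | w > 1)) stop("CAI weights must lie in (0, 1]")
  w
}

#' Read a tAI source table (tRNA gene copy numbers and wobble constraints)
#'
#' Tab-separated columns: `codon`, `anticodon` (optional, informational),
#' `tgcn` (gene copy number of the isoacceptor), `s` (selective constraint
#' in \[0,1\]); one row per (codon, isoacceptor) pairing.
#'
#' @param path File path.
#' @return Data frame suitable for [build_tai_weights()].
#' @export
read_tai_source <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("codon", "tgcn", "s") %in% names(tab)))
  tab
}

#' Read nTE source tables (transcript abundances and codon counts)
#'
#' `abundance_path`: columns `gene`, `abundance`. `counts_path`: a codon-by-
#' gene matrix, first column `codon`, remaining columns one per gene.
#'
#' @param abundance_path,counts_path File paths.
#' @return List with `abundance` (named vector) and `codon_counts` (matrix)
#'   ready for [build_nte_weights()].
#' @export
read_nte_source <- function(abundance_path, counts_path) {
  ab <- utils::read.delim(abundance_path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "abundance") %in% names(ab)))
  cc <- utils::read.delim(counts_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  stopifnot(names(cc)[1] == "codon")
  m <- as.matrix(cc[, -1, drop = FALSE])
  rownames(m) <- as_codons(cc$codon)
  list(abundance = setNames(ab$abundance, ab$gene), codon_counts = m)
}

#' Packaged synthetic example weight sources
#'
#' Paths to the synthetic example tables shipped under `extdata`. These are
#' *synthetic* tables generated to demonstrate the file schemas and exercise
#' the weight builders; they are not measured E. coli tRNA gene copy numbers
#' or transcript abundances. Substitute organism-specific tables for real
#' analyses.
#'
#' @param which One of `"tai"`, `"nte_abundance"`, `"nte_counts"`.
#' @return File path.
#' @export
synthetic_weight_path <- function(which = c("tai", "nte_abundance", "nte_counts")) {
  which <- match.arg(which)
  fn <- switch(which,
    tai = "tai_source_synthetic.tsv",
    nte_abundance = "nte_abundance_synthetic.tsv",
    nte_counts = "nte_codon_counts_synthetic.tsv")
  system.file("extdata", fn, package = "sortnoise", mustWork = TRUE)
}

#' Write a variant score/statistics table as tab-separated text
#'
#' @param tab Data frame or tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
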