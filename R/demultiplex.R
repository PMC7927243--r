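#' Amplicon read layout
#'
#' Reads are laid out as: 5' flank, variable region, 3' flank, bin index.
#' The flanks are the fixed primer-derived sequence on either side of the
#' synonymous-codon variable region; the 9-base index at the read's 3' end
#' identifies the sorting bin.
#'
#' @param flank5,flank3 Fixed flanking sequences (uppercase DNA).
#' @param var_width Width of the variable region in bases (24 = 8 codons).
#' @param index_width Width of the bin index (9).
#' @return A `read_layout` list.
#' @export
read_layout <- function(flank5 = "ACACGACGCTCT", flank3 = "AGATCGGAAGAG",
                        var_width = 24L, index_width = 9L) {
  structure(list(flank5 = toupper(flank5), flank3 = toupper(flank3),
                 var_width = as.integer(var_width),
                 index_width = as.integer(index_width)),
            class = "read_layout")
}

layout_width <- function(layout) {
  nchar(layout$flank5) + layout$var_width + nchar(layout$flank3) +
    layout$index_width
}

#' Demultiplex barcoded reads into per-variant, per-bin counts
#'
#' Each read is located against the fixed layout: the flanks must match
#' exactly (an indel or heavily mutated flank shifts the frame and the read
#' is discarded), the variable region must be unambiguous ACGT, and the
#' 9-base index must match a manifest barcode (exactly, or within
#' `max_barcode_mismatch` substitutions). Every read is either assigned to
#' exactly one bin or discarded with a reason.
#'
#' @param reads FASTQ file path(s) (plain or gzipped), a `DNAStringSet`, or a
#'   character vector of read sequences.
#' @param manifest A [bin_manifest()].
#' @param layout A [read_layout()].
#' @param max_barcode_mismatch Allowed substitutions in the bin index
#'   (default 0 = exact).
#' @return List with `counts` (integer matrix, variants x bins) and
#'   `discards` (named integer vector of reads dropped per reason:
#'   `truncated`, `flank_mismatch`, `ambiguous_base`, `unmatched_barcode`).
#' @export
demultiplex_and_count <- function(reads, manifest, layout = read_layout(),
                                  max_barcode_mismatch = 0L) {
  if (is.character(reads) && length(reads) >= 1 && file.exists(reads[1])) {
    reads <- unlist(lapply(reads, function(p)
      as.character(Biostrings::readDNAStringSet(p, format = "fastq"))))
  } else if (methods::is(reads, "DNAStringSet")) {
    reads <- as.character(reads)
  }
  reads <- toupper(reads)
  n_f5 <- nchar(layout$flank5)
  n_f3 <- nchar(layout$flank3)
  width <- layout_width(layout)

  discards <- c(truncated = 0L, flank_mismatch = 0L, ambiguous_base = 0L,
                unmatched_barcode = 0L)

  ok <- nchar(reads) >= width
  discards["truncated"] <- sum(!ok)
  reads <- reads[ok]

  f5 <- substr(reads, 1L, n_f5)
  var_at <- n_f5 + 1L
  var <- substr(reads, var_at, var_at + layout$var_width - 1L)
  f3_at <- var_at + layout$var_width
  f3 <- substr(reads, f3_at, f3_at + n_f3 - 1L)
  idx_at <- f3_at + n_f3
  idx <- substr(reads, idx_at, idx_at + layout$index_width - 1L)

  flank_ok <- f5 == layout$flank5 & f3 == layout$flank3
  discards["flank_mismatch"] <- sum(!flank_ok)
  var <- var[flank_ok]; idx <- idx[flank_ok]

  clean <- !grepl("[^ACGT]", var)
  discards["ambiguous_base"] <- sum(!clean)
  var <- var[clean]; idx <- idx[clean]

  bin <- match(idx, manifest$barcode)
  if (max_barcode_mismatch > 0 && anyNA(bin)) {
    unm <- which(is.na(bin))
    bcs <- strsplit(manifest$barcode, "")
    for (i in unm) {
      q <- strsplit(idx[i], "")[[1]]
      if (length(q) != length(bcs[[1]])) next
      d <- vapply(bcs, function(b) sum(b != q), integer(1))
      hit <- which(d <= max_barcode_mismatch)
      if (length(hit) == 1) bin[i] <- hit
    }
  }
  matched <- !is.na(bin)
  discards["unmatched_barcode"] <- sum(!matched)
  var <- var[matched]; bin <- bin[matched]

  counts <- table(factor(var), factor(bin, levels = manifest$bin))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   ncol = nrow(manifest),
                   dimnames = list(rownames(counts), manifest$bin))
  list(counts = counts, discards = discards)
}
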