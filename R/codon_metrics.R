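#' Split a nucleotide sequence into codons
#'
#' Normalises case and RNA (`U`) to DNA (`T`), then splits the sequence into
#' consecutive trinucleotides. Input may already be a vector of codons.
#'
#' @param x A single string whose length is a multiple of 3, or a character
#'   vector of 3-base codons.
#' @return Character vector of uppercase DNA codons.
#' @export
as_codons <- function(x) {
  if (length(x) == 0) stop("empty sequence")
  x <- chartr("u", "t", tolower(x))
  x <- toupper(x)
  if (length(x) == 1 && nchar(x) != 3) {
    if (nchar(x) %% 3 != 0)
      stop("sequence length ", nchar(x), " is not a multiple of 3")
    x <- substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  }
  if (any(nchar(x) != 3))
    stop("codons must be exactly 3 bases: ", paste(x[nchar(x) != 3], collapse = ", "))
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop("non-ACGT characters in codon(s): ", paste(unique(x[bad]), collapse = ", "))
  x
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Shared scorer: geometric mean of per-codon weights, log-space.
score_geomean <- function(seq, weights, what) {
  codons <- as_codons(seq)
  if (any(codons %in% STOP_CODONS))
    stop("stop codon(s) in sequence: ",
         paste(unique(codons[codons %in% STOP_CODONS]), collapse = ", "),
         "; stop codons carry no ", what, " weight")
  missing <- setdiff(unique(codons), names(weights))
  if (length(missing))
    stop("no ", what, " weight for codon(s): ", paste(missing, collapse = ", "))
  w <- weights[codons]
  if (any(!is.finite(w)) || any(w <= 0))
    stop(what, " weights must be finite and positive")
  geomean(w)
}

#' Codon Adaptation Index of a sequence
#'
#' CAI is the geometric mean of per-codon relative adaptiveness weights
#' \eqn{w_k}: \eqn{CAI = (\prod_k w_k)^{1/L}} over the \eqn{L} codons.
#'
#' @param seq Sequence (string or codon vector); see [as_codons()].
#' @param weights Named numeric vector, codon -> w in (0, 1].
#' @return CAI score in (0, 1].
#' @seealso [cai_weights_ecoli()] for the packaged E. coli weight set.
#' @export
#' @examples
#' compute_cai("AAAAAC", cai_weights_ecoli())
compute_cai <- function(seq, weights) score_geomean(seq, weights, "CAI")

#' tRNA Adaptation Index of a sequence
#'
#' Geometric mean of tAI codon weights built by [build_tai_weights()].
#'
#' @inheritParams compute_cai
#' @param weights Named numeric vector, codon -> tAI weight \eqn{w_i}.
#' @return TAI score in (0, 1].
#' @export
compute_tai <- function(seq, weights) score_geomean(seq, weights, "TAI")

#' Normalized Translation Efficiency of a sequence
#'
#' Geometric mean of nTE codon weights built by [build_nte_weights()].
#'
#' @inheritParams compute_cai
#' @param weights Named numeric vector, codon -> nTE weight.
#' @return nTE score in (0, 1].
#' @export
compute_nte <- function(seq, weights) score_geomean(seq, weights, "nTE")

#' Build tAI codon weights from tRNA gene copy numbers
#'
#' For each codon \eqn{i} the absolute adaptiveness is
#' \eqn{W_i = \sum_j (1 - s_{ij})\, tGCN_{ij}} over the tRNA isoacceptors
#' \eqn{j} that read it, where \eqn{tGCN_{ij}} is the gene copy number of the
#' isoacceptor and \eqn{s_{ij} \in [0,1]} the selective constraint on the
#' codon-anticodon coupling. Weights are \eqn{w_i = W_i / W_{max}}; codons
#' with \eqn{W_i = 0} (no cognate tRNA gene) receive the geometric mean of
#' the nonzero weights.
#'
#' @param src Data frame with columns `codon`, `tgcn` (non-negative integer)
#'   and `s` (in \[0,1\]); one row per (codon, isoacceptor) pair. Extra
#'   columns (e.g. `anticodon`) are ignored.
#' @return Named numeric vector of weights in (0, 1], one per codon in `src`.
#' @export
build_tai_weights <- function(src) {
  src <- as.data.frame(src)
  stopifnot(all(c("codon", "tgcn", "s") %in% names(src)))
  codon <- as_codons(as.character(src$codon))
  if (!is_count(src$tgcn)) stop("tgcn must be non-negative integers")
  if (!is.numeric(src$s) || any(src$s < 0 | src$s > 1))
    stop("s must lie in [0, 1]")
  W <- tapply((1 - src$s) * src$tgcn, codon, sum)
  W <- setNames(as.numeric(W), names(W))
  if (all(W == 0)) stop("all W_i are zero; w_mean is undefined")
  w <- W / max(W)
  w_mean <- geomean(w[W != 0])
  w[W == 0] <- w_mean
  w
}

#' Build nTE codon weights from tRNA supply and codon demand
#'
#' Codon demand is \eqn{U_i = \sum_j a_j c_{ij}} (transcript abundance
#' \eqn{a_j} of gene \eqn{j} times the count \eqn{c_{ij}} of codon \eqn{i} in
#' that gene), normalised to \eqn{cu_i = U_i / U_{max}}. Supply over demand,
#' \eqn{nTE'_i = w_i / cu_i} with \eqn{w_i} the tAI weight, is renormalised so
#' the maximum weight is 1.
#'
#' @param abundance Named numeric vector: gene -> transcript abundance (>= 0).
#' @param codon_counts Numeric matrix of codon counts, rows = codons,
#'   columns = genes (names must cover `names(abundance)`).
#' @param tai_w Named numeric vector of tAI weights (see
#'   [build_tai_weights()]); weights are produced for these codons.
#' @return Named numeric vector of nTE weights in (0, 1].
#' @export
build_nte_weights <- function(abundance, codon_counts, tai_w) {
  stopifnot(is.numeric(abundance), all(abundance >= 0))
  codon_counts <- as.matrix(codon_counts)
  if (!is_count(codon_counts)) stop("codon_counts must be non-negative integers")
  genes <- names(abundance)
  if (is.null(genes) || !all(genes %in% colnames(codon_counts)))
    stop("every gene in `abundance` needs a column in `codon_counts`")
  rownames(codon_counts) <- as_codons(rownames(codon_counts))
  U <- as.numeric(codon_counts[, genes, drop = FALSE] %*% abundance)
  names(U) <- rownames(codon_counts)
  if (max(U) <= 0) stop("U_max must be positive")
  cu <- U / max(U)
  codons <- names(tai_w)
  missing <- setdiff(codons, names(cu))
  if (length(missing))
    stop("no codon usage for codon(s): ", paste(missing, collapse = ", "))
  if (any(cu[codons] == 0))
    stop("cu_i = 0 for codon(s) with a tAI weight: ",
         paste(codons[cu[codons] == 0], collapse = ", "),
         "; nTE'_i = w_i/cu_i is undefined")
  nte_raw <- tai_w / cu[codons]
  nte_raw / max(nte_raw)
}

#' GC content of a sequence
#'
#' @inheritParams compute_cai
#' @return Fraction of G or C bases, in \[0, 1\].
#' @export
gc_content <- function(seq) {
  codons <- as_codons(seq)
  bases <- strsplit(paste(codons, collapse = ""), "")[[1]]
  mean(bases %in% c("G", "C"))
}

#' Mean-centred mRNA folding free energies
#'
#' Each variant's folding free energy is expressed relative to the library
#' mean: \eqn{\Delta\Delta G_v = \Delta G_v - \overline{\Delta G}}. The
#' package consumes precomputed free energies (kcal/mol); it does not fold
#' RNA itself.
#'
#' @param dg Named numeric vector: variant -> free energy of folding.
#' @return Named numeric vector of the same length, summing to zero.
#' @export
compute_ddG <- function(dg) {
  if (length(dg) == 0) stop("empty free-energy input")
  if (any(!is.finite(dg))) stop("non-finite free energy value(s)")
  dg - mean(dg)
}

#' E. coli CAI relative-adaptiveness weights
#'
#' The classic E. coli codon relative-adaptiveness table, taken at runtime
#' from `seqinr::caitab` (column `ec`). Stop codons are dropped.
#'
#' @return Named numeric vector, codon -> w in (0, 1].
#' @export
cai_weights_ecoli <- function() {
  caitab <- NULL # silence R CMD check; filled by data()
  utils::data("caitab", package = "seqinr", envir = environment())
  w <- setNames(caitab$ec, toupper(rownames(caitab)))
  w <- w[!names(w) %in% STOP_CODONS]
  w[w > 0]
}

#' Score a set of variant sequences with all codon metrics
#'
#' @param seqs Named character vector of nucleotide sequences (e.g. the
#'   24-base variable regions); names are variant ids (defaults to the
#'   sequences themselves).
#' @param cai_w,tai_w,nte_w Named weight vectors; any may be `NULL` to skip
#'   that metric.
#' @param dg Optional named numeric vector of folding free energies; variants
#'   present are mean-centred into a `ddg` column.
#' @return Tibble with columns `variant`, `cai`, `tai`, `nte`, `gc`, `ddg`.
#' @export
score_variants <- function(seqs, cai_w = cai_weights_ecoli(), tai_w = NULL,
                           nte_w = NULL, dg = NULL) {
  ids <- names(seqs) %||% unname(seqs)
  score_all <- function(w, f) {
    if (is.null(w)) return(rep(NA_real_, length(seqs)))
    vapply(seqs, f, numeric(1), weights = w, USE.NAMES = FALSE)
  }
  out <- tibble::tibble(
    variant = ids,
    cai = score_all(cai_w, compute_cai),
    tai = score_all(tai_w, compute_tai),
    nte = score_all(nte_w, compute_nte),
    gc  = vapply(seqs, gc_content, numeric(1), USE.NAMES = FALSE),
    ddg = NA_real_
  )
  if (!is.null(dg)) {
    ddg <- compute_ddG(dg)
    out$ddg <- unname(ddg[match(out$variant, names(ddg))])
  }
  out
}

#' Score every CDS in a FASTA file (genome-scan mode)
#'
#' Reads coding sequences from a FASTA file and scores each with all codons
#' in the gene. A trailing stop codon, if present, is trimmed before scoring.
#'
#' @param fasta Path to a (multi-)FASTA file of CDSs.
#' @inheritParams score_variants
#' @return Tibble as from [score_variants()], one row per CDS.
#' @export
genome_scan <- function(fasta, cai_w = cai_weights_ecoli(), tai_w = NULL,
                        nte_w = NULL) {
  cds <- Biostrings::readDNAStringSet(fasta)
  seqs <- as.character(cds)
  last <- substring(seqs, nchar(seqs) - 2, nchar(seqs))
  seqs <- ifelse(toupper(last) %in% STOP_CODONS,
                 substring(seqs, 1, nchar(seqs) - 3), seqs)
  names(seqs) <- names(cds)
  score_variants(seqs, cai_w = cai_w, tai_w = tai_w, nte_w = nte_w)
}
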