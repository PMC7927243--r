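# Ground-truthed generator for the full Sort-seq process: a synonymous-codon
# library with Gamma-distributed single-cell fluorescence, multinomial FACS
# into log-spaced bins, and barcoded amplicon reads with substitution errors.

#' Synonymous codon table
#'
#' DNA codons per amino acid (one-letter code), from the standard genetic
#' code; stop codons excluded.
#'
#' @return Named list: amino acid -> character vector of codons.
#' @export
aa_codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  gc <- gc[gc != "*"]
  split(names(gc), unname(gc))
}

#' Simulation configuration
#'
#' Defaults mirror a realistic Sort-seq experiment on a synonymous-codon GFP
#' library: 20 log-spaced bins, about 2.16 million sorted cells, roughly 2
#' sequencing reads per sorted cell, and a broad (log-normal) spread of
#' pre-sort variant abundances so that cells-per-sequence varies over orders
#' of magnitude. The default peptide `"VKGEDAFT"` has a synonymous space of
#' exactly 4096 sequences (4*2*4*2*2*4*2*4).
#'
#' @param seed Integer seed; mandatory — every stochastic stage derives its
#'   stream from it.
#' @param n_variants Library members to simulate.
#' @param peptide 8-residue peptide encoded by the variable region.
#' @param alpha_range Range of true Gamma shapes (uniform draw).
#' @param mean_range Range of true mean fluorescence (log-uniform draw);
#'   scale is `mean/alpha`.
#' @param abundance_sdlog Log-normal sdlog of pre-sort variant abundance.
#' @param cells_total Total cells sorted across all bins.
#' @param n_bins Number of sorting bins.
#' @param spacing Bin-edge spacing, `"log"` or `"linear"`.
#' @param bin_quantiles Pooled-library quantiles the outer gates are set at.
#' @param reads_per_bin Sequencing reads drawn from each bin.
#' @param error_rate Per-base substitution error rate of sequencing.
#' @param n_replicates Independent sort + sequencing replicates.
#' @param fluor_model `"gamma"` (matches the fitting model) or `"lognormal"`
#'   (model-mismatch stress test; same mean and CV² per variant).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed, n_variants = 100, peptide = "VKGEDAFT",
                       alpha_range = c(1, 10), mean_range = c(100, 10000),
                       abundance_sdlog = 1.5, cells_total = 2.16e6,
                       n_bins = 20, spacing = c("log", "linear"),
                       bin_quantiles = c(0.001, 0.999),
                       reads_per_bin = 195000, error_rate = 0.001,
                       n_replicates = 3,
                       fluor_model = c("gamma", "lognormal")) {
  if (missing(seed)) stop("`seed` is mandatory")
  spacing <- match.arg(spacing)
  fluor_model <- match.arg(fluor_model)
  stopifnot(n_variants >= 1, cells_total >= 1, n_bins >= 2,
            reads_per_bin >= 1, error_rate >= 0, error_rate < 1,
            n_replicates >= 1, all(alpha_range > 0), all(mean_range > 0))
  aa <- aa_codon_table()
  pep <- strsplit(toupper(peptide), "")[[1]]
  if (!all(pep %in% names(aa)))
    stop("peptide contains residues without (sense) codons: ",
         paste(setdiff(pep, names(aa)), collapse = ", "))
  structure(list(
    seed = as.integer(seed), n_variants = as.integer(n_variants),
    peptide = paste(pep, collapse = ""), alpha_range = alpha_range,
    mean_range = mean_range, abundance_sdlog = abundance_sdlog,
    cells_total = cells_total, n_bins = as.integer(n_bins), spacing = spacing,
    bin_quantiles = bin_quantiles, reads_per_bin = reads_per_bin,
    error_rate = error_rate, n_replicates = as.integer(n_replicates),
    fluor_model = fluor_model
  ), class = "sim_config")
}

#' Generate a ground-truthed synonymous library
#'
#' Samples `n_variants` distinct synonymous codon combinations of the
#' configured peptide and assigns each a true Gamma law (shape uniform in
#' `alpha_range`, mean log-uniform in `mean_range`, scale = mean/shape) and a
#' pre-sort abundance (log-normal, normalised to sum to 1).
#'
#' @param cfg A [sim_config()].
#' @return Tibble: `variant` (24-base sequence), `alpha`, `beta`,
#'   `true_mean`, `true_cv2`, `abundance`.
#' @export
make_library <- function(cfg) {
  aa <- aa_codon_table()
  pos <- aa[strsplit(cfg$peptide, "")[[1]]]
  space <- prod(lengths(pos))
  if (cfg$n_variants > space)
    stop("peptide ", cfg$peptide, " has only ", space,
         " synonymous sequences; cannot draw ", cfg$n_variants)
  withr::with_seed(cfg$seed, {
    if (space <= 65536) {
      all_seqs <- do.call(paste0, expand.grid(pos, stringsAsFactors = FALSE))
      seqs <- sample(all_seqs, cfg$n_variants)
    } else {
      seqs <- character(0)
      while (length(seqs) < cfg$n_variants) {
        draw <- do.call(paste0, lapply(pos, sample,
                                       size = 2 * cfg$n_variants, replace = TRUE))
        seqs <- head(unique(c(seqs, draw)), cfg$n_variants)
      }
    }
    alpha <- runif(cfg$n_variants, cfg$alpha_range[1], cfg$alpha_range[2])
    m <- exp(runif(cfg$n_variants, log(cfg$mean_range[1]), log(cfg$mean_range[2])))
    ab <- rlnorm(cfg$n_variants, 0, cfg$abundance_sdlog)
  })
  tibble::tibble(variant = seqs, alpha = alpha, beta = m / alpha,
                 true_mean = m, true_cv2 = 1 / alpha, abundance = ab / sum(ab))
}

# Quantile of the library's pooled fluorescence mixture (deterministic).
mixture_quantile <- function(lib, q) {
  cdf <- function(x) sum(lib$abundance * pgamma(x, shape = lib$alpha,
                                                scale = lib$beta))
  lo <- min(qgamma(1e-6, shape = lib$alpha, scale = lib$beta))
  hi <- max(qgamma(1 - 1e-9, shape = lib$alpha, scale = lib$beta))
  vapply(q, function(qq)
    uniroot(function(x) cdf(x) - qq, c(max(lo, 1e-12), hi))$root, numeric(1))
}

#' Deterministic bin barcodes
#'
#' 9-base barcodes with pairwise Hamming distance >= 3, drawn greedily from a
#' seeded random stream (bit-reproducible for a given `n` and `seed`).
#'
#' @param n Number of barcodes.
#' @param seed Integer seed.
#' @return Character vector of `n` barcodes.
#' @export
make_barcodes <- function(n, seed = 1L) {
  withr::with_seed(seed, {
    out <- character(0)
    while (length(out) < n) {
      cand <- paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE),
                    collapse = "")
      ok <- all(vapply(out, function(b)
        sum(strsplit(b, "")[[1]] != strsplit(cand, "")[[1]]) >= 3, logical(1)))
      if (ok) out <- c(out, cand)
    }
    out
  })
}

#' Simulate FACS sorting of the library into bins
#'
#' Gates are log-spaced (or linear) between the configured pooled-library
#' quantiles. Each variant's cells are multinomially distributed over the
#' bins with probabilities equal to its fluorescence law's probability mass
#' in each bin; cells falling outside the outer gates are not sorted. Under
#' the `"lognormal"` fluorescence model the per-bin mass uses a log-normal
#' with the variant's true mean and CV².
#'
#' @param lib Library tibble from [make_library()].
#' @param cfg A [sim_config()].
#' @param replicate Replicate index (shifts the random stream; gates and
#'   barcodes are shared across replicates, as on a sorter).
#' @return List (class `sortseq_sim`): `manifest` (a [bin_manifest()] with
#'   `cells_sorted` filled in), `cells` (true variants x bins cell counts),
#'   `lib`, `edges`.
#' @export
simulate_sort <- function(lib, cfg, replicate = 1L) {
  gates <- mixture_quantile(lib, cfg$bin_quantiles)
  edges <- if (cfg$spacing == "log")
    exp(seq(log(gates[1]), log(gates[2]), length.out = cfg$n_bins + 1))
  else seq(gates[1], gates[2], length.out = cfg$n_bins + 1)

  bin_mass <- function(a, b, m, v) {
    if (cfg$fluor_model == "gamma") {
      p <- pgamma(edges, shape = a, scale = b)
    } else {
      sdl <- sqrt(log1p(v / m^2))
      p <- stats::plnorm(edges, meanlog = log(m) - sdl^2 / 2, sdlog = sdl)
    }
    diff(p)
  }

  n_var <- nrow(lib)
  cells <- withr::with_seed(cfg$seed + 1000L * as.integer(replicate) + 1L, {
    per_variant <- as.vector(rmultinom(1, cfg$cells_total, lib$abundance))
    t(vapply(seq_len(n_var), function(i) {
      p <- bin_mass(lib$alpha[i], lib$beta[i], lib$true_mean[i],
                    lib$true_mean[i]^2 * lib$true_cv2[i])
      p_out <- max(0, 1 - sum(p))
      draw <- as.vector(rmultinom(1, per_variant[i], c(p, p_out)))
      draw[seq_len(cfg$n_bins)]
    }, numeric(cfg$n_bins)))
  })
  rownames(cells) <- lib$variant
  manifest <- bin_manifest_from_edges(
    edges, make_barcodes(cfg$n_bins, seed = cfg$seed),
    colSums(cells), spacing = cfg$spacing)
  colnames(cells) <- manifest$bin
  structure(list(manifest = manifest, cells = cells, lib = lib,
                 edges = edges), class = "sortseq_sim")
}

#' Simulate barcoded sequencing reads from sorted bins
#'
#' From each bin, `reads_per_bin` reads are drawn multinomially in proportion
#' to the bin's cell composition (uniform amplification). Each read is laid
#' out per [read_layout()] (5' flank, 24-base variable region, 3' flank,
#' 9-base bin index) and per-base substitution errors are applied at the
#' configured rate.
#'
#' @param sim A `sortseq_sim` from [simulate_sort()].
#' @param cfg A [sim_config()].
#' @param replicate Replicate index (shifts the random stream).
#' @param layout A [read_layout()].
#' @return List: `reads` (character vector of read sequences),
#'   `read_counts` (error-free variants x bins read composition matrix),
#'   `layout`.
#' @export
simulate_reads <- function(sim, cfg, replicate = 1L, layout = read_layout()) {
  cells <- sim$cells
  manifest <- sim$manifest
  n_var <- nrow(cells)
  withr::with_seed(cfg$seed + 1000L * as.integer(replicate) + 2L, {
    read_counts <- vapply(seq_len(nrow(manifest)), function(b) {
      tot <- sum(cells[, b])
      if (tot == 0) return(integer(n_var))
      as.vector(rmultinom(1, cfg$reads_per_bin, cells[, b] / tot))
    }, integer(n_var))
    dimnames(read_counts) <- dimnames(cells)

    var_idx <- rep(rep(seq_len(n_var), ncol(read_counts)), as.vector(read_counts))
    bin_idx <- rep(rep(seq_len(ncol(read_counts)), each = n_var),
                   as.vector(read_counts))
    reads <- paste0(layout$flank5, rownames(cells)[var_idx], layout$flank3,
                    manifest$barcode[bin_idx])
    if (cfg$error_rate > 0 && length(reads) > 0) {
      width <- layout_width(layout)
      chars <- matrix(unlist(strsplit(reads, ""), use.names = FALSE),
                      ncol = width, byrow = TRUE)
      hit <- which(matrix(runif(length(chars)) < cfg$error_rate,
                          ncol = width))
      if (length(hit)) {
        bases <- c("A", "C", "G", "T")
        # substitute with one of the three other bases, uniformly
        repl <- vapply(chars[hit], function(ch)
          sample(setdiff(bases, ch), 1), character(1))
        chars[hit] <- repl
        reads <- do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
      }
    }
  })
  list(reads = reads, read_counts = read_counts, layout = layout)
}

#' Write reads as FASTQ
#'
#' Plain four-line-per-record FASTQ with constant placeholder qualities
#' (simulated reads carry no quality model).
#'
#' @param reads Character vector of read sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (length(reads) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  ids <- sprintf("@read%d", seq_along(reads))
  qual <- vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), character(1))
  writeLines(rbind(ids, reads, "+", qual), path)
  invisible(path)
}

#' Write the simulation ground truth as tab-separated text
#'
#' @param sim A `sortseq_sim`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(sim, path) {
  tab <- cbind(as.data.frame(sim$lib),
               as.data.frame(sim$cells, check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
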