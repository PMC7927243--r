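#' Run the full Sort-seq pipeline on a simulated library
#'
#' Wires every stage end to end: library generation, per-replicate sorting
#' and sequencing, demultiplexing, cell-count normalisation, the minimum-bin
#' and minimum-CPS filters, Gamma fitting, the replicate-concordance gate,
#' codon-metric scoring, and metric-vs-statistic regressions. Each stage is
#' also exported on its own so persisted intermediate files can be re-run
#' independently.
#'
#' @param cfg A [sim_config()]; its seed drives every stochastic stage.
#' @param min_bins,min_cps Minimum-sampling filter thresholds
#'   (see [filter_variants()]).
#' @param max_err_mean,max_err_cv2,rule Replicate gate settings
#'   (see [replicate_gate()]).
#' @param cai_w,tai_w,nte_w Codon weight vectors used for scoring; the
#'   defaults use the packaged E. coli CAI table and the synthetic example
#'   tAI/nTE tables.
#' @param outdir Optional directory; when given, the variant table,
#'   regression table, QC summary and run manifest are written there.
#' @return List: `variant_table` (one row per variant passing all gates,
#'   with replicate-averaged statistics and metric scores), `fits` (all
#'   per-replicate fits), `regressions`, `qc_summary`, `discards`,
#'   `run_manifest`.
#' @export
run_all <- function(cfg, min_bins = 2, min_cps = 20, max_err_mean = 30,
                    max_err_cv2 = 40, rule = "either",
                    cai_w = cai_weights_ecoli(),
                    tai_w = build_tai_weights(read_tai_source(synthetic_weight_path("tai"))),
                    nte_w = local({
                      src <- read_nte_source(synthetic_weight_path("nte_abundance"),
                                             synthetic_weight_path("nte_counts"))
                      build_nte_weights(src$abundance, src$codon_counts, tai_w)
                    }),
                    outdir = NULL) {
  lib <- make_library(cfg)
  detected <- character(0)
  discards <- NULL
  all_fits <- NULL
  rep_summary <- list()
  for (r in seq_len(cfg$n_replicates)) {
    sim <- simulate_sort(lib, cfg, replicate = r)
    rd <- simulate_reads(sim, cfg, replicate = r)
    dm <- demultiplex_and_count(rd$reads, sim$manifest, rd$layout)
    detected <- union(detected, rownames(dm$counts))
    discards <- if (is.null(discards)) dm$discards else discards + dm$discards
    cells <- counts_to_cells(dm$counts, sim$manifest)
    flt <- filter_variants(cells, min_bins = min_bins, min_cps = min_cps)
    fits <- fit_gamma_all(flt$kept, sim$manifest)
    n_unconverged <- sum(!fits$converged)
    fits <- fits[fits$converged, ]
    fits$replicate <- r
    all_fits <- rbind(all_fits, fits)
    rep_summary[[r]] <- tibble::tibble(
      replicate = r, n_detected = nrow(dm$counts),
      n_filtered_bins = sum(grepl("bins", flt$removed$reason)),
      n_filtered_cps = sum(grepl("cps", flt$removed$reason)),
      n_unconverged = n_unconverged, n_fit = nrow(fits))
  }

  gate <- replicate_gate(all_fits, max_err_mean = max_err_mean,
                         max_err_cv2 = max_err_cv2, rule = rule)
  kept_ids <- gate$kept$variant
  agg <- function(col) vapply(kept_ids, function(v)
    mean(all_fits[[col]][all_fits$variant == v]), numeric(1))
  variant_table <- tibble::tibble(
    variant = kept_ids,
    alpha = agg("alpha"), beta = agg("beta"), mean = agg("mean"),
    variance = agg("variance"), cv2 = agg("cv2"), cps = agg("cps"),
    bins_occupied = agg("bins_occupied"),
    err_mean = gate$kept$err_mean, err_cv2 = gate$kept$err_cv2)
  scores <- score_variants(setNames(kept_ids, kept_ids), cai_w = cai_w,
                           tai_w = tai_w, nte_w = nte_w)
  variant_table <- merge(variant_table, scores, by = "variant", sort = TRUE)
  variant_table <- tibble::as_tibble(variant_table)

  # ground truth carried along for validation studies
  variant_table <- merge(variant_table,
                         lib[, c("variant", "true_mean", "true_cv2")],
                         by = "variant", all.x = TRUE, sort = TRUE)
  variant_table <- tibble::as_tibble(variant_table)

  regressions <- NULL
  if (nrow(variant_table) >= 3) {
    for (metric in c("cai", "tai", "nte", "gc")) {
      for (response in c("mean", "variance", "cv2")) {
        reg <- tryCatch(associate_metrics(variant_table, metric, response),
                        error = function(e) NULL)
        regressions <- rbind(regressions, reg)
      }
    }
  }

  n_gate_input <- length(unique(all_fits$variant))
  qc_summary <- list(
    n_detected = length(detected),
    n_filtered_out = length(detected) - n_gate_input,
    n_gate_input = n_gate_input,
    n_gate_removed = nrow(gate$removed),
    n_kept = nrow(gate$kept),
    per_replicate = do.call(rbind, rep_summary))
  run_manifest <- list(
    package = "sortnoise",
    version = as.character(utils::packageVersion("sortnoise")),
    seed = cfg$seed,
    config = unclass(cfg),
    thresholds = list(min_bins = min_bins, min_cps = min_cps,
                      max_err_mean = max_err_mean, max_err_cv2 = max_err_cv2,
                      gate_rule = rule))

  out <- list(variant_table = variant_table, fits = all_fits,
              regressions = regressions, qc_summary = qc_summary,
              discards = discards, gate = gate, run_manifest = run_manifest)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_variant_table(variant_table, file.path(outdir, "variant_table.tsv"))
    if (!is.null(regressions))
      write_variant_table(regressions, file.path(outdir, "regressions.tsv"))
    yaml::write_yaml(qc_summary[names(qc_summary) != "per_replicate"],
                     file.path(outdir, "qc_summary.yaml"))
    write_variant_table(qc_summary$per_replicate,
                        file.path(outdir, "qc_per_replicate.tsv"))
    yaml::write_yaml(run_manifest, file.path(outdir, "run_manifest.yaml"))
  }
  out
}
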