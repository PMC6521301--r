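#' Plot the integer distribution of a risk score
#'
#' Bar chart of score counts, annotated with the number of scored
#' participants, in the style of the published score-distribution
#' figures.
#'
#' @param grs A `grs_vector` from [compute_grs()].
#' @param path Optional file path; when given the figure is saved there
#'   (format from the extension) and the path returned invisibly.
#' @return A ggplot object (or `path` invisibly when saving).
#' @export
plot_grs_distribution <- function(grs, path = NULL) {
  h <- grs_distribution(grs)
  n <- attr(h, "n")
  p <- ggplot2::ggplot(h, ggplot2::aes(x = score, y = count)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(
      x = "Genetic risk score",
      y = "Number of participants",
      title = sprintf("GRS distribution, %s panel (n = %d)",
                      attr(grs, "panel_name"), n)) +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 7, height = 4.5, dpi = 150)
    return(invisible(path))
  }
  p
}

utils::globalVariables(c("score", "count"))

pipeline_defaults <- function() {
  list(simulation = list(),      # passed to simulation_config()
       genotypes = NULL,         # or: paths to existing data
       genotype_format = "vcf",
       phenotypes = NULL,
       panel = "all",
       entry_p = 0.15, stay_p = 0.15,
       retrench_step = 10L, retrench_min_n = 30L,
       reference_maf = NULL,     # data.frame or CSV path rsid,maf[,n]
       reference_n = NULL,
       plots = TRUE,
       out_dir = NULL,
       seed = 1L)
}

#' Run the full risk-score pipeline
#'
#' Orchestrates the end-to-end analysis: cohort simulation (or
#' ingestion of genotype/phenotype files), per-SNP QC, responder
#' classification, odds-ratio-directed weight estimation, full-panel and
#' seven-SNP replication scores, covariate-adjusted variance-explained
#' fits, bidirectional stepwise SNP selection, the refined-panel refit,
#' and the extreme-response retrenchment sweep. Every artifact is
#' written under `out_dir` and catalogued in a manifest; the run is
#' fully determined by the config and its seed.
#'
#' @param config A named list overriding the pipeline defaults, or the
#'   path to a YAML file with the same keys. Exactly one of a
#'   `simulation` config (list of [simulation_config()] arguments) or
#'   input paths (`genotypes` + `phenotypes`) must be supplied;
#'   an empty `simulation` list means "simulate with defaults". Other
#'   keys: `panel`, `entry_p`, `stay_p`, `retrench_step`,
#'   `retrench_min_n`, `reference_maf`, `reference_n`, `plots`,
#'   `out_dir` (required), `seed`.
#' @return The run manifest (invisibly): list with `config`, `summary`
#'   and `artifacts` (named file paths). The summary JSON holds the
#'   cohort size, percent non-responders, HWE failures, panel sizes and
#'   the percent variance explained by the full, replication and refined
#'   panels.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipeline_defaults(), config)
  if (is.null(cfg$out_dir)) stop("config must set out_dir")
  simulate <- is.null(cfg$genotypes)
  if (!simulate && is.null(cfg$phenotypes))
    stop("supply both genotypes and phenotypes, or neither (to simulate)")
  if (!simulate && length(cfg$simulation))
    stop("supply either input paths or a simulation config, not both")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- ingest or simulate ----------------------------------------------
  if (simulate) {
    sim_args <- cfg$simulation
    sim_args$seed <- cfg$seed
    sim_cfg <- stage("simulate", do.call(simulation_config, sim_args))
    cohort <- stage("simulate", simulate_cohort(sim_cfg))
    gm <- cohort$genotypes
    pheno_raw <- cohort$phenotypes
    art$cohort <- write_cohort(cohort, file.path(cfg$out_dir, "cohort"))
  } else {
    gm <- stage("ingest", read_genotypes(cfg$genotypes,
                                         cfg$genotype_format))
    pheno_raw <- stage("ingest", read.csv(cfg$phenotypes,
                                          stringsAsFactors = FALSE))
  }

  # --- QC ---------------------------------------------------------------
  qc <- stage("qc", qc_report(gm))
  art$qc <- file.path(cfg$out_dir, "qc_report.tsv")
  write.table(qc, art$qc, sep = "\t", quote = FALSE, row.names = FALSE)
  hwe_failures <- qc$rsid[!is.na(qc$in_hwe) & !qc$in_hwe]
  if (!is.null(cfg$reference_maf)) {
    ref <- cfg$reference_maf
    if (is.character(ref)) ref <- read.csv(ref, stringsAsFactors = FALSE)
    cmp <- stage("qc", maf_comparison(gm, ref, cfg$reference_n))
    art$maf_comparison <- file.path(cfg$out_dir, "maf_comparison.tsv")
    write.table(cmp, art$maf_comparison, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  # --- classification ---------------------------------------------------
  pheno <- stage("classify", classify_responders(pheno_raw))
  cls <- attr(pheno, "summary")
  art$phenotypes <- file.path(cfg$out_dir, "phenotypes_classified.csv")
  write.csv(pheno, art$phenotypes, row.names = FALSE, quote = FALSE)
  desc <- stage("classify", descriptive_table(pheno))
  art$descriptives <- file.path(cfg$out_dir, "descriptive_table.tsv")
  write.table(desc, art$descriptives, sep = "\t", quote = FALSE,
              row.names = FALSE)

  # --- weights and scores ----------------------------------------------
  weights <- stage("weights", compute_weights(gm, pheno))
  art$weights <- file.path(cfg$out_dir, "weights.tsv")
  write.table(weights, art$weights, sep = "\t", quote = FALSE,
              row.names = FALSE)
  panel <- cfg$panel
  if (identical(panel, "replication_7")) panel <- replication_panel()
  grs_full <- stage("score", compute_grs(gm, weights, panel = panel))
  art$grs_full <- file.path(cfg$out_dir, "grs_full.csv")
  write.csv(grs_full, art$grs_full, row.names = FALSE, quote = FALSE)
  fit_full <- stage("fit", fit_grs_model(pheno, grs_full))

  repl_available <- all(replication_panel() %in% gm$snps$rsid)
  fit_repl <- NULL
  if (repl_available) {
    grs_repl <- stage("score", replication_panel_grs(gm, weights))
    art$grs_replication <- file.path(cfg$out_dir, "grs_replication.csv")
    write.csv(grs_repl, art$grs_replication, row.names = FALSE,
              quote = FALSE)
    fit_repl <- stage("fit", fit_grs_model(pheno, grs_repl))
  }

  # --- stepwise refinement ---------------------------------------------
  sw <- stage("stepwise", stepwise_select(pheno, gm,
                                          entry_p = cfg$entry_p,
                                          stay_p = cfg$stay_p))
  art$stepwise_log <- file.path(cfg$out_dir, "stepwise_log.tsv")
  write.table(sw$log, art$stepwise_log, sep = "\t", quote = FALSE,
              row.names = FALSE)
  fit_refined <- NULL
  grs_refined <- NULL
  if (length(sw$selected)) {
    grs_refined <- stage("score", compute_grs(
      gm, weights, panel = sw$selected,
      panel_name = paste0("refined_", length(sw$selected))))
    art$grs_refined <- file.path(cfg$out_dir, "grs_refined.csv")
    write.csv(grs_refined, art$grs_refined, row.names = FALSE,
              quote = FALSE)
    fit_refined <- stage("fit", fit_grs_model(pheno, grs_refined))
  }

  # --- retrenchment -----------------------------------------------------
  retro <- NULL
  if (!is.null(grs_refined)) {
    retro <- stage("retrench", retrench_and_refit(
      pheno, grs_refined, step = cfg$retrench_step,
      min_n = cfg$retrench_min_n))
    art$retrenchment <- file.path(cfg$out_dir, "retrenchment.tsv")
    write.table(retro, art$retrenchment, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  # --- figures ----------------------------------------------------------
  if (isTRUE(cfg$plots)) {
    art$fig_grs_full <- file.path(cfg$out_dir, "grs_distribution_full.png")
    stage("plot", plot_grs_distribution(grs_full, art$fig_grs_full))
    if (!is.null(grs_refined)) {
      art$fig_grs_refined <- file.path(cfg$out_dir,
                                       "grs_distribution_refined.png")
      stage("plot", plot_grs_distribution(grs_refined,
                                          art$fig_grs_refined))
    }
  }

  # --- summary and manifest --------------------------------------------
  pct <- function(f) if (is.null(f)) NULL else f$grs_percent_variance
  pval <- function(f) if (is.null(f)) NULL else f$grs_p
  summary <- list(
    n_participants = nrow(pheno),
    n_snps = nrow(gm$snps),
    n_responders = cls$n_responders,
    n_non_responders = cls$n_non_responders,
    percent_non_responders = cls$percent_non_responders,
    hwe_failures = as.list(hwe_failures),
    panel_sizes = list(full = length(attr(grs_full, "rsids")),
                       replication = if (repl_available) 7L else NULL,
                       refined = length(sw$selected)),
    grs_percent_variance = list(full = pct(fit_full),
                                replication = pct(fit_repl),
                                refined = pct(fit_refined)),
    grs_p = list(full = pval(fit_full),
                 replication = pval(fit_repl),
                 refined = pval(fit_refined)),
    selected_snps = as.list(sw$selected),
    retrenchment_table = if (!is.null(retro))
      basename(art$retrenchment) else NULL,
    seed = cfg$seed)
  art$summary <- file.path(cfg$out_dir, "summary.json")
  art$manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(summary, art$summary, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  manifest <- list(config = cfg[setdiff(names(cfg), "reference_maf")],
                   summary = summary,
                   artifacts = lapply(art, as.character))
  jsonlite::write_json(manifest, art$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(manifest)
}
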