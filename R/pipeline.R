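# Orchestration: one seeded configuration object drives simulation, the flow
# pipeline, the single-cell pipeline and the pooling calculation, collecting
# every count and p-value into a single summary bundle.

#' Pipeline run configuration
#'
#' Bundles the per-stage configurations with a master seed; per-stage seeds
#' are derived from it by the package's documented substream rule, so stages
#' can be regenerated independently.
#'
#' @param seed Master seed.
#' @param stages Character subset of `c("flow", "scrna", "libprep")`.
#' @param cohort A [cohort_config()] (seed defaults to the master seed).
#' @param counts A [counts_config()].
#' @param imputation An [imputation_config()].
#' @param outlier An [outlier_rule()].
#' @param qc_thresholds A [cell_qc_thresholds()]; scale `min_genes`/`max_genes`
#'   down alongside `counts$n_genes` when simulating small fixtures.
#' @param min_cells_per_cycle Cycle-cutoff for [cycle_dynamics()].
#' @param distribution_expected Expectation for [subpop_distribution()].
#' @param hub_params Hub planting plan for [simulate_geneset_scores()];
#'   NULL plants a default two-method, two-gene-set design on two strongly
#'   planted DEGs at Spearman rho 0.4.
#' @param libprep_n_samples Synthetic fragment-analyzer samples (default 54).
#' @return List of class `ctc_run_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c("flow", "scrna", "libprep"),
                            cohort = cohort_config(seed = seed),
                            counts = counts_config(seed = derive_seed(seed, "counts")),
                            imputation = imputation_config(seed = derive_seed(seed, "impute")),
                            outlier = outlier_rule(),
                            qc_thresholds = cell_qc_thresholds(),
                            min_cells_per_cycle = 5L,
                            distribution_expected = "overall_proportions",
                            hub_params = NULL,
                            libprep_n_samples = 54L) {
  stages <- match.arg(stages, c("flow", "scrna", "libprep"), several.ok = TRUE)
  structure(list(seed = as.integer(seed), stages = stages, cohort = cohort,
                 counts = counts, imputation = imputation, outlier = outlier,
                 qc_thresholds = qc_thresholds,
                 min_cells_per_cycle = as.integer(min_cells_per_cycle),
                 distribution_expected = distribution_expected,
                 hub_params = hub_params,
                 libprep_n_samples = as.integer(libprep_n_samples)),
            class = "ctc_run_config")
}

default_hub_params <- function(fixture) {
  lfc <- fixture$true_degs
  genes <- names(sort(abs(lfc[lfc != 0]), decreasing = TRUE))[1:2]
  list(methods = c("methodA", "methodB"),
       genesets = c("SET1", "SET2"),
       plan = data.frame(
         gene = rep(genes, each = 2),
         geneset = rep(c("SET1", "SET2"), each = 2),
         method = rep(c("methodA", "methodB"), times = 2),
         rho = 0.4, stringsAsFactors = FALSE))
}

#' Run the configured pipeline end to end
#'
#' Fixed stage order: simulate, control QC, normalize, exclude unknown
#' outcomes, impute, outlier-filter, threshold, classify, distribution,
#' group comparisons, cycle dynamics, CTC counts; then single-cell QC,
#' normalization, composition tests, differential expression, ranking,
#' gene-set scores and the hub filter; then the pooling plan. The summary
#' carries every count and p-value keyed by the stage that produced it.
#'
#' @param config A [pipeline_config()].
#' @return List of class `ctc_run_bundle`: stage outputs plus `summary`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "ctc_run_config"))
  bundle <- list(config = config, summary = list(seed = config$seed))

  if ("flow" %in% config$stages) {
    skeleton <- simulate_cohort(config$cohort)
    events <- simulate_flow_events(skeleton, config$cohort)
    ctrl <- summarize_controls(events)
    normalized <- normalize_events(events, ctrl)
    excl <- exclude_unknown_response(normalized)
    ev <- excl$events
    imp_logs <- list()
    for (ch in c("EpCAM", "PSMA")) {
      imp <- impute_negative_mfi(ev, ch, config$imputation)
      ev <- imp$events
      imp_logs[[ch]] <- imp$log
    }
    filt <- filter_outliers(ev, config$outlier)
    retained <- filt$events
    thr <- derive_thresholds(retained)
    classified <- classify_events(retained, thr)
    dist <- subpop_distribution(classified, config$distribution_expected)
    cmp <- lapply(c(EpCAM = "EpCAM", PSMA = "PSMA"),
                  function(ch) compare_groups_mfi(retained, ch))
    dyn <- lapply(c(EpCAM = "EpCAM", PSMA = "PSMA"), function(ch)
      cycle_dynamics(retained, ch, config$min_cells_per_cycle))
    cnt <- ctc_count_stats(retained)

    bundle$flow <- list(skeleton = skeleton, events = events,
                        controls = ctrl, normalized = normalized,
                        exclusion_log = excl$exclusion_log,
                        imputation_logs = imp_logs, outliers_removed = filt$removed,
                        retained = retained, thresholds = thr,
                        classified = classified, distribution = dist,
                        comparisons = cmp, dynamics = dyn, ctc_counts = cnt)
    nbg <- function(ch) cmp[[ch]]$test$p_value
    bundle$summary$flow <- list(
      n_events_simulated = sum(!events$is_control),
      n_sessions = nrow(ctrl$summaries),
      n_excluded_unknown = sum(excl$exclusion_log$n_excluded),
      n_imputed = sum(vapply(imp_logs, nrow, 0L)),
      n_outliers_removed = nrow(filt$removed),
      n_retained = sum(!retained$is_control),
      thresholds = as.list(thr$thresholds),
      n_double_negative = dist$n_double_negative,
      subpop_counts = dist$table[, c("subpop", "responder_n", "nonresponder_n")],
      epcam_between_group_p = nbg("EpCAM"),
      psma_between_group_p = nbg("PSMA"),
      ctc_count_p = cnt$test$p_value,
      ctc_count_median_responder = cnt$responder$median,
      ctc_count_median_nonresponder = cnt$nonresponder$median,
      dynamics = lapply(dyn, function(d)
        d[, c("group", "cycle", "n", "median_mfi", "p_vs_baseline",
              "p_between_groups")]))
  }

  if ("scrna" %in% config$stages) {
    fixture <- simulate_counts(config$counts)
    qc <- qc_filter_cells(fixture$counts, fixture$mt_genes, config$qc_thresholds)
    kept <- qc$kept_cells
    counts_kept <- fixture$counts[, kept, drop = FALSE]
    meta_kept <- fixture$cell_meta[match(kept, fixture$cell_meta$cell_id), ]
    norm <- lognormalize(counts_kept)
    comp <- lapply(c(response = "response", cycle = "cycle",
                     treatment_type = "treatment_type"),
                   function(v) composition_association(meta_kept$true_cluster,
                                                       meta_kept[[v]]))
    dge <- dge_wilcoxon(norm, meta_kept$true_cluster)
    ranked <- filter_and_rank_degs(dge)
    hub_params <- if (is.null(config$hub_params)) default_hub_params(fixture)
                  else config$hub_params
    scores_all <- simulate_geneset_scores(fixture, hub_params)
    scores <- lapply(scores_all, function(m) m[kept, , drop = FALSE])
    cand <- unique(hub_params$plan$gene)
    hub_rec <- hub_correlations(norm, scores, candidate_genes = cand)
    hubs <- filter_hub_genes(hub_rec, ranked$significant)

    bundle$scrna <- list(fixture = fixture, qc = qc, norm_dim = dim(norm),
                         composition = comp, dge = dge, ranked = ranked,
                         scores = scores, hub_records = hubs$records,
                         hubs = hubs$hubs)
    bundle$summary$scrna <- list(
      n_cells_simulated = ncol(fixture$counts),
      n_cells_kept = length(kept),
      n_cells_removed = ncol(fixture$counts) - length(kept),
      composition_p = lapply(comp, function(x)
        if (is.null(x$test)) NA_real_ else x$test$p_value),
      n_genes_tested = nrow(dge),
      n_significant_unfiltered = sum(dge$p_adj < 0.05),
      n_significant_degs = length(ranked$significant),
      n_up = ranked$n_up, n_down = ranked$n_down,
      top_genes = ranked$top$gene,
      n_hub_genes = length(hubs$hubs), hub_genes = hubs$hubs)
  }

  if ("libprep" %in% config$stages) {
    libs <- with_seed(derive_seed(config$seed, "pipeline"), data.frame(
      sample_id = sprintf("LIB%02d", seq_len(config$libprep_n_samples)),
      conc_ng_per_ul = stats::rlnorm(config$libprep_n_samples,
                                     log(2.2), 0.8),
      avg_fragment_bp = stats::rnorm(config$libprep_n_samples, 480, 60),
      stringsAsFactors = FALSE))
    pool <- plan_pooling(libs)
    bundle$libprep <- list(samples = libs, pooling = pool)
    bundle$summary$libprep <- list(
      n_samples = nrow(libs),
      median_molarity_nM = pool$median_molarity_nM,
      n_discarded = sum(!pool$plan$keep),
      target_fmol = pool$target_fmol)
  }

  class(bundle) <- "ctc_run_bundle"
  bundle
}

#' Write a human-readable run report
#'
#' Deterministic text report plus CSV tables (classification, dynamics,
#' differential expression, pooling plan) and the summary as JSON.
#'
#' @param bundle A [run_pipeline()] bundle.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ctc_run_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  put <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  lines <- c("CTC pipeline run report", sprintf("seed: %d", bundle$config$seed), "")
  s <- bundle$summary
  if (!is.null(bundle$flow)) {
    f <- s$flow
    lines <- c(lines, "== Flow cytometry ==",
      sprintf("events simulated: %d; retained after QC/filters: %d",
              f$n_events_simulated, f$n_retained),
      sprintf("excluded (unknown outcome): %d; imputed: %d; outliers removed: %d",
              f$n_excluded_unknown, f$n_imputed, f$n_outliers_removed),
      sprintf("thresholds: EpCAM %.4g, PSMA %.4g",
              f$thresholds$EpCAM, f$thresholds$PSMA),
      sprintf("CTC counts: Responder median %.3g, Nonresponder median %.3g, p = %.3g",
              f$ctc_count_median_responder, f$ctc_count_median_nonresponder,
              f$ctc_count_p),
      sprintf("pooled between-group p: EpCAM %.3g, PSMA %.3g",
              f$epcam_between_group_p, f$psma_between_group_p), "")
    put(bundle$flow$classified, "classification.csv")
    put(do.call(rbind, bundle$flow$dynamics), "dynamics.csv")
    put(bundle$flow$normalized, "normalized_events.csv")
  } else lines <- c(lines, "== Flow cytometry ==", "not computed", "")
  if (!is.null(bundle$scrna)) {
    c2 <- s$scrna
    lines <- c(lines, "== Single-cell RNA-seq ==",
      sprintf("cells: %d simulated, %d kept after QC",
              c2$n_cells_simulated, c2$n_cells_kept),
      sprintf("DEGs: %d significant (of %d tested), %d up / %d down",
              c2$n_significant_degs, c2$n_genes_tested, c2$n_up, c2$n_down),
      sprintf("hub genes: %s",
              if (length(c2$hub_genes)) paste(c2$hub_genes, collapse = ", ")
              else "none"), "")
    put(bundle$scrna$dge, "dge.csv")
    put(bundle$scrna$qc$qc, "cell_qc.csv")
    put(bundle$scrna$hub_records, "hub_records.csv")
  } else lines <- c(lines, "== Single-cell RNA-seq ==", "not computed", "")
  if (!is.null(bundle$libprep)) {
    lines <- c(lines, "== Library pooling ==",
      sprintf("median molarity: %.3g nM; %d of %d samples discarded (< 1 nM)",
              s$libprep$median_molarity_nM, s$libprep$n_discarded,
              s$libprep$n_samples), "")
    put(bundle$libprep$pooling$plan, "pooling_plan.csv")
  } else lines <- c(lines, "== Library pooling ==", "not computed", "")
  rp <- file.path(dir, "report.txt")
  writeLines(lines, rp)
  sj <- file.path(dir, "summary.json")
  jsonlite::write_json(bundle$summary, sj, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(c(paths, rp, sj))
}

# YAML round-trip ---------------------------------------------------------------

#' Serialize / restore a run configuration as YAML
#'
#' The YAML file round-trips losslessly back into an identical
#' `ctc_run_config` (constructors are re-applied on read).
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_run_config` returns the restored `ctc_run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "ctc_run_config"))
  x <- unclass(config)
  x$cohort <- unclass(x$cohort)
  x$cohort$marker_medians <- as.list(x$cohort$marker_medians)
  # yaml drops names on named atomic vectors; serialize them as maps
  for (f in c("group_ctc_count_medians", "control_raw_medians",
              "cycle4_group_totals"))
    x$cohort[[f]] <- as.list(x$cohort[[f]])
  x$counts <- unclass(x$counts)
  x$imputation <- unclass(x$imputation)
  x$outlier <- unclass(x$outlier)
  x$qc_thresholds <- unclass(x$qc_thresholds)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  co <- x$cohort
  co$marker_medians <- as.data.frame(co$marker_medians,
                                     stringsAsFactors = FALSE)
  co$group_ctc_count_medians <- unlist(co$group_ctc_count_medians)
  co$control_raw_medians <- unlist(co$control_raw_medians)
  co$cycle4_group_totals <- unlist(co$cycle4_group_totals)
  cohort <- do.call(cohort_config, co)
  counts <- do.call(counts_config, x$counts)
  imputation <- do.call(imputation_config, x$imputation)
  outlier <- do.call(outlier_rule, x$outlier)
  qc <- do.call(cell_qc_thresholds, x$qc_thresholds)
  pipeline_config(seed = x$seed, stages = x$stages, cohort = cohort,
                  counts = counts, imputation = imputation, outlier = outlier,
                  qc_thresholds = qc,
                  min_cells_per_cycle = x$min_cells_per_cycle,
                  distribution_expected = x$distribution_expected,
                  hub_params = x$hub_params,
                  libprep_n_samples = x$libprep_n_samples)
}
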