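# Synthetic cohort generators. Every stage of the flow and single-cell
# pipelines is exercised on seeded simulations that emulate the structure of
# an index-sorted CTC study: paired sort sessions with control wells,
# per-cycle marker medians, dispersed per-sample CTC counts, and Smart-seq2
# depth count matrices with planted clusters and differential genes.

#' Default planted per-cycle marker medians
#'
#' Normalized (control-relative) median MFI per response group, treatment
#' cycle and channel. Cycles 0-3 use the study's printed medians where
#' available; the remaining cells are flat or interpolated continuations of
#' the printed trajectories. Cycle 4 reuses the cycle-3 medians (cycle-4
#' samples are planted nearly empty so the cycle-cutoff rule is exercised).
#'
#' @return A data.frame with columns `group`, `cycle`, `channel`, `median`.
#' @export
default_marker_medians <- function() {
  g <- function(group, channel, meds)
    data.frame(group = group, cycle = 0:4, channel = channel, median = meds)
  rbind(
    g("Responder",    "EpCAM", c(0.3299, 0.0992, 0.3000, 0.3000, 0.3000)),
    g("Nonresponder", "EpCAM", c(0.8258, 0.8849, 0.2872, 0.2706, 0.2706)),
    g("Responder",    "PSMA",  c(0.1920, 0.1181, 0.0453, 0.0186, 0.0186)),
    g("Nonresponder", "PSMA",  c(0.0683, 0.0883, 0.0500, 0.0200, 0.0200)))
}

#' Flow-cohort simulation configuration
#'
#' Collects the knobs of the synthetic flow cohort. Defaults are the study
#' conditions: group CTC-count medians 2 (Responder) and 8 (Nonresponder),
#' planted marker medians from [default_marker_medians()], multiplicative
#' per-session batch factors, lognormal within-sample MFI noise, and a
#' half-normal detection-floor subtraction producing occasional negative MFIs.
#'
#' @param n_patients_per_group Patients per response group (default 10).
#' @param cycles Ascending integer treatment cycles starting at 0.
#' @param ctc_count_dispersion Negative-binomial size for per-sample CTC counts.
#' @param group_ctc_count_medians Named target medians of sorted CTCs per sample.
#' @param marker_medians Planted medians, as from [default_marker_medians()].
#' @param log_mfi_sd Within-sample lognormal noise (sd on the natural-log scale).
#' @param session_batch_sd Lognormal sd of the per-session per-channel batch factor.
#' @param detection_floor Scale (sd) of the half-normal baseline-subtraction
#'   term, in raw MFI units; 0 disables it (no negative MFIs).
#' @param unknown_response_fraction Fraction of extra patients whose treatment
#'   outcome is recorded as Unknown (excluded downstream).
#' @param control_raw_medians Raw control-line median MFI per channel.
#' @param control_events_per_session Control events recorded per sort session.
#' @param cycle4_group_totals Total planted CTCs per group at cycles >= 4
#'   (default 3 Responder, 0 Nonresponder, reproducing the sparse tail that
#'   motivates the cycle cutoff).
#' @param seed Master seed; all stage streams derive from it.
#' @return A validated list of class `ctc_cohort_config`.
#' @export
cohort_config <- function(n_patients_per_group = 10L,
                          cycles = 0:4,
                          ctc_count_dispersion = 2,
                          group_ctc_count_medians = c(Responder = 2, Nonresponder = 8),
                          marker_medians = default_marker_medians(),
                          log_mfi_sd = 0.25,
                          session_batch_sd = 0.15,
                          detection_floor = 0.5,
                          unknown_response_fraction = 0.1,
                          control_raw_medians = c(EpCAM = 50, PSMA = 50),
                          control_events_per_session = 30L,
                          cycle4_group_totals = c(Responder = 3L, Nonresponder = 0L),
                          seed = 1L) {
  if (n_patients_per_group < 1) stop("n_patients_per_group must be positive", call. = FALSE)
  cycles <- as.integer(cycles)
  if (length(cycles) == 0 || cycles[1] != 0L || is.unsorted(cycles, strictly = TRUE))
    stop("cycles must be ascending integers starting at 0", call. = FALSE)
  if (ctc_count_dispersion <= 0) stop("ctc_count_dispersion must be positive", call. = FALSE)
  if (any(group_ctc_count_medians <= 0) || any(marker_medians$median <= 0) ||
      any(control_raw_medians <= 0))
    stop("all medians must be strictly positive", call. = FALSE)
  if (log_mfi_sd <= 0) stop("log_mfi_sd must be positive", call. = FALSE)
  if (session_batch_sd < 0 || detection_floor < 0)
    stop("session_batch_sd and detection_floor must be >= 0", call. = FALSE)
  if (unknown_response_fraction < 0 || unknown_response_fraction >= 1)
    stop("unknown_response_fraction must lie in [0, 1)", call. = FALSE)
  out <- list(n_patients_per_group = as.integer(n_patients_per_group),
              cycles = cycles,
              ctc_count_dispersion = ctc_count_dispersion,
              group_ctc_count_medians = group_ctc_count_medians,
              marker_medians = marker_medians,
              log_mfi_sd = log_mfi_sd,
              session_batch_sd = session_batch_sd,
              detection_floor = detection_floor,
              unknown_response_fraction = unknown_response_fraction,
              control_raw_medians = control_raw_medians,
              control_events_per_session = as.integer(control_events_per_session),
              cycle4_group_totals = cycle4_group_totals,
              seed = as.integer(seed))
  class(out) <- "ctc_cohort_config"
  out
}

# Negative-binomial mean calibrated so that median(max(1, NB(size, mu)))
# equals the target median: the valid mu interval is located on a grid and
# its midpoint returned.
calibrate_nb_mu <- function(target_median, size) {
  grid <- seq(0.05, max(10, 6 * target_median), by = 0.05)
  med <- pmax(1, stats::qnbinom(0.5, size = size, mu = grid))
  hit <- grid[med == target_median]
  if (length(hit) == 0) stop("cannot calibrate NB mean for median ", target_median,
                             call. = FALSE)
  stats::median(hit)
}

#' Simulate a cohort skeleton
#'
#' Builds the sampling design: patients per group (plus a configurable
#' fraction with Unknown outcome), one sample per patient and cycle, sort
#' sessions pairing one Responder with one Nonresponder sample plus a control
#' well, and per-sample planned CTC counts drawn from a dispersed count
#' distribution centered on the group median. Cycles >= 4 are planted nearly
#' empty per `cycle4_group_totals`.
#'
#' @param config A [cohort_config()].
#' @return List of class `ctc_cohort_skeleton` with data.frames `patients`,
#'   `samples` and `sessions`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "ctc_cohort_config"))
  with_seed(derive_seed(config$seed, "cohort"), {
    npg <- config$n_patients_per_group
    n_unknown <- ceiling(config$unknown_response_fraction * 2 * npg)
    patients <- data.frame(
      patient_id = c(sprintf("R%02d", seq_len(npg)),
                     sprintf("N%02d", seq_len(npg)),
                     if (n_unknown > 0) sprintf("U%02d", seq_len(n_unknown))),
      response = c(rep("Responder", npg), rep("Nonresponder", npg),
                   rep("Unknown", n_unknown)),
      stringsAsFactors = FALSE)
    # Unknown patients still belong to a (hidden) biological group
    patients$hidden_group <- patients$response
    if (n_unknown > 0)
      patients$hidden_group[patients$response == "Unknown"] <-
        sample(c("Responder", "Nonresponder"), n_unknown, replace = TRUE)

    mus <- vapply(c(Responder = "Responder", Nonresponder = "Nonresponder"),
                  function(g) calibrate_nb_mu(config$group_ctc_count_medians[[g]],
                                              config$ctc_count_dispersion),
                  numeric(1))

    samples <- NULL; sessions <- NULL
    for (cy in config$cycles) {
      if (cy >= 4L) {
        # sparse planted tail: a few single-cell Responder samples only
        totals <- config$cycle4_group_totals
        sm <- NULL
        for (g in names(totals)) {
          k <- as.integer(totals[[g]])
          if (k <= 0) next
          pids <- patients$patient_id[patients$hidden_group == g &
                                      patients$response != "Unknown"][seq_len(k)]
          sm <- rbind(sm, data.frame(patient_id = pids, cycle = cy,
                                     planned_ctc_count = 1L,
                                     stringsAsFactors = FALSE))
        }
        if (is.null(sm)) next
        cyc_samples <- merge(sm, patients, by = "patient_id")
      } else {
        cyc_samples <- patients
        cyc_samples$cycle <- cy
        cyc_samples$planned_ctc_count <- pmax(1L, stats::rnbinom(
          nrow(cyc_samples), size = config$ctc_count_dispersion,
          mu = mus[cyc_samples$hidden_group]))
      }
      # random Responder/Nonresponder pairing into sessions, one control each
      resample <- function(v) v[sample.int(length(v))]
      resp <- resample(which(cyc_samples$hidden_group == "Responder"))
      nonr <- resample(which(cyc_samples$hidden_group == "Nonresponder"))
      npair <- max(length(resp), length(nonr))
      sess_ids <- sprintf("S_c%d_%02d", cy, seq_len(max(npair, 1L)))
      cyc_samples$session_id <- NA_character_
      if (length(resp)) cyc_samples$session_id[resp] <- sess_ids[seq_along(resp)]
      if (length(nonr)) cyc_samples$session_id[nonr] <- sess_ids[seq_along(nonr)]
      used <- sort(unique(stats::na.omit(cyc_samples$session_id)))
      sessions <- rbind(sessions, data.frame(session_id = used, cycle = cy,
                                             stringsAsFactors = FALSE))
      cyc_samples$sample_id <- paste0(cyc_samples$patient_id, "_c", cy)
      samples <- rbind(samples, cyc_samples[, c("sample_id", "patient_id",
                                                "session_id", "cycle", "response",
                                                "hidden_group",
                                                "planned_ctc_count")])
    }
    rownames(samples) <- NULL
    out <- list(patients = patients, samples = samples, sessions = sessions,
                config = config)
    class(out) <- "ctc_cohort_skeleton"
    out
  })
}

#' Simulate flow-cytometry events for a cohort skeleton
#'
#' Draws raw per-channel MFIs: planted normalized median x raw control median
#' x per-session per-channel batch factor x lognormal cell noise, then
#' subtracts a half-normal detection-floor term (raw units), which produces
#' occasional negative values for dim cells. Control wells are drawn around
#' the raw control median under the same session factor (no floor
#' subtraction; the control line is bright).
#'
#' @param skeleton From [simulate_cohort()].
#' @param config The same [cohort_config()]; defaults to the skeleton's.
#' @return A data.frame of events: `event_id`, `patient_id`, `sample_id`,
#'   `session_id`, `cycle`, `response`, `epcam_mfi`, `psma_mfi`, `is_control`.
#' @export
simulate_flow_events <- function(skeleton, config = skeleton$config) {
  stopifnot(inherits(skeleton, "ctc_cohort_skeleton"))
  channels <- c("EpCAM", "PSMA")
  mm <- config$marker_medians
  with_seed(derive_seed(config$seed, "flow"), {
    sess <- skeleton$sessions
    batch <- matrix(stats::rlnorm(nrow(sess) * 2, 0, config$session_batch_sd),
                    nrow(sess), 2, dimnames = list(sess$session_id, channels))
    rows <- vector("list", nrow(sess) + nrow(skeleton$samples))
    ri <- 0L
    for (i in seq_len(nrow(sess))) {
      n <- config$control_events_per_session
      vals <- sapply(channels, function(ch)
        config$control_raw_medians[[ch]] * batch[i, ch] *
          stats::rlnorm(n, 0, config$log_mfi_sd))
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        event_id = sprintf("%s_ctrl_%03d", sess$session_id[i], seq_len(n)),
        patient_id = NA_character_, sample_id = NA_character_,
        session_id = sess$session_id[i], cycle = sess$cycle[i],
        response = NA_character_,
        epcam_mfi = vals[, "EpCAM"], psma_mfi = vals[, "PSMA"],
        is_control = TRUE, stringsAsFactors = FALSE)
    }
    for (j in seq_len(nrow(skeleton$samples))) {
      sm <- skeleton$samples[j, ]
      n <- sm$planned_ctc_count
      vals <- sapply(channels, function(ch) {
        med <- mm$median[mm$group == sm$hidden_group & mm$cycle == sm$cycle &
                         mm$channel == ch]
        if (length(med) != 1)
          stop("no planted median for ", sm$hidden_group, " cycle ", sm$cycle,
               " ", ch, call. = FALSE)
        raw <- med * config$control_raw_medians[[ch]] * batch[sm$session_id, ch] *
          stats::rlnorm(n, 0, config$log_mfi_sd)
        if (config$detection_floor > 0)
          raw <- raw - abs(stats::rnorm(n, 0, config$detection_floor))
        raw
      })
      vals <- matrix(vals, nrow = n, dimnames = list(NULL, channels))
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        event_id = sprintf("%s_ev%03d", sm$sample_id, seq_len(n)),
        patient_id = sm$patient_id, sample_id = sm$sample_id,
        session_id = sm$session_id, cycle = sm$cycle, response = sm$response,
        epcam_mfi = vals[, "EpCAM"], psma_mfi = vals[, "PSMA"],
        is_control = FALSE, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows[seq_len(ri)])
    rownames(out) <- NULL
    out
  })
}

# Single-cell count fixture ----------------------------------------------------

#' Single-cell count simulation configuration
#'
#' Negative-binomial count matrix with two planted cell clusters, planted
#' log2 fold changes on a subset of moderately expressed genes, mitochondrial
#' genes, and planted low-quality cells (shallow libraries, high mitochondrial
#' fraction) so QC filters are exercised on both sides of their thresholds.
#'
#' @param n_genes Total genes (default 2000, of which `n_mt_genes` mitochondrial).
#' @param cells_per_cluster Cells per planted cluster (default 60).
#' @param n_deg Number of planted differential genes (default 100).
#' @param lfc_magnitude Planted |log2FC| (default 1.5).
#' @param frac_up Fraction of planted DEGs up in cluster 0 (default 0.85).
#' @param nb_size Gene-level negative-binomial size (default 5).
#' @param base_meanlog,base_sdlog Lognormal parameters of gene base means.
#' @param min_deg_base_mean Planting floor: DEGs drawn among genes whose base
#'   mean is at least this (default 5), keeping planted effects within the
#'   power of a rank test at this depth.
#' @param n_mt_genes Mitochondrial genes (default 50).
#' @param depth_meanlog,depth_sdlog Lognormal per-cell target depth.
#' @param frac_low_depth,frac_high_mt Fractions of planted low-quality cells.
#' @param seed Master seed.
#' @return A list of class `ctc_counts_config`.
#' @export
counts_config <- function(n_genes = 2000L, cells_per_cluster = 60L,
                          n_deg = 100L, lfc_magnitude = 1.5, frac_up = 0.85,
                          nb_size = 5, base_meanlog = 1.0, base_sdlog = 1.2,
                          min_deg_base_mean = 5, n_mt_genes = 50L,
                          depth_meanlog = log(2e4), depth_sdlog = 0.35,
                          frac_low_depth = 0.08, frac_high_mt = 0.08,
                          seed = 1L) {
  if (cells_per_cluster < 2) stop("need at least 2 cells per cluster", call. = FALSE)
  if (n_deg > n_genes - n_mt_genes) stop("too many planted DEGs", call. = FALSE)
  out <- as.list(environment())
  out[c("n_genes", "cells_per_cluster", "n_deg", "n_mt_genes", "seed")] <-
    lapply(out[c("n_genes", "cells_per_cluster", "n_deg", "n_mt_genes", "seed")],
           as.integer)
  class(out) <- "ctc_counts_config"
  out
}

#' Simulate a single-cell count fixture
#'
#' @param config A [counts_config()].
#' @return List of class `ctc_count_fixture`: `counts` (genes x cells integer
#'   matrix), `cell_meta` (response, cycle, treatment_type, true_cluster,
#'   planted_low_depth, planted_high_mt), `mt_genes`, `true_degs` (named
#'   planted log2FC vector, 0 for null genes).
#' @export
simulate_counts <- function(config = counts_config()) {
  stopifnot(inherits(config, "ctc_counts_config"))
  with_seed(derive_seed(config$seed, "counts"), {
    ng <- config$n_genes; nc <- 2L * config$cells_per_cluster
    mt_genes <- sprintf("MT-G%02d", seq_len(config$n_mt_genes))
    genes <- c(sprintf("GENE%04d", seq_len(ng - config$n_mt_genes)), mt_genes)
    base_mean <- stats::rlnorm(ng, config$base_meanlog, config$base_sdlog)
    names(base_mean) <- genes
    # mitochondrial block pinned to a healthy ~6% share of reads
    mt_idx <- which(genes %in% mt_genes)
    base_mean[mt_idx] <- sum(base_mean[-mt_idx]) * 0.06 / config$n_mt_genes

    eligible <- setdiff(which(base_mean >= config$min_deg_base_mean), mt_idx)
    if (length(eligible) < config$n_deg)
      stop("not enough well-expressed genes to plant DEGs", call. = FALSE)
    deg_idx <- sample(eligible, config$n_deg)
    n_up <- round(config$frac_up * config$n_deg)
    lfc <- rep(0, ng); names(lfc) <- genes
    lfc[deg_idx] <- config$lfc_magnitude *
      c(rep(1, n_up), rep(-1, config$n_deg - n_up))

    cluster <- rep(c(0L, 1L), each = config$cells_per_cluster)
    low_depth <- rep(FALSE, nc); high_mt <- rep(FALSE, nc)
    low_depth[sample(nc, round(config$frac_low_depth * nc))] <- TRUE
    high_mt[sample(nc, round(config$frac_high_mt * nc))] <- TRUE

    counts <- matrix(0L, ng, nc, dimnames = list(genes, sprintf("cell%03d", seq_len(nc))))
    depth <- exp(stats::rnorm(nc, config$depth_meanlog, config$depth_sdlog))
    depth[low_depth] <- stats::runif(sum(low_depth), 1500, 3500)
    for (j in seq_len(nc)) {
      mu_g <- base_mean
      # planted fold change expressed in cluster 0 relative to cluster 1
      if (cluster[j] == 0L) mu_g[deg_idx] <- mu_g[deg_idx] * 2^lfc[deg_idx]
      if (high_mt[j]) mu_g[mt_idx] <- mu_g[mt_idx] * 80  # pushes MT share > 0.75
      mu_g <- mu_g / sum(mu_g) * depth[j]
      counts[, j] <- stats::rnbinom(ng, size = config$nb_size, mu = mu_g)
    }
    cell_meta <- data.frame(
      cell_id = colnames(counts),
      response = sample(c("Responder", "Nonresponder"), nc, replace = TRUE),
      cycle = sample(0:3, nc, replace = TRUE),
      treatment_type = sample(c("NT", "L", "AL"), nc, replace = TRUE),
      true_cluster = cluster,
      planted_low_depth = low_depth,
      planted_high_mt = high_mt,
      stringsAsFactors = FALSE)
    out <- list(counts = counts, cell_meta = cell_meta, mt_genes = mt_genes,
                true_degs = lfc, config = config)
    class(out) <- "ctc_count_fixture"
    out
  })
}

#' Simulate per-method gene-set score matrices
#'
#' Stand-in for per-cell gene-set enrichment scoring: for each planted hub
#' assignment (gene, gene set, method, target Spearman rho) the score column
#' is built by a Gaussian-copula construction on the midranks of that gene's
#' log-normalized expression, so the population Spearman correlation equals
#' the target. `rho = 1` returns the expression itself (a monotone
#' transform). Gene sets without a planted gene are pure noise.
#'
#' @param fixture A [simulate_counts()] fixture.
#' @param hub_params List with `methods` (>= 2 labels), `genesets` (ids),
#'   and `plan`: a data.frame (`gene`, `geneset`, `method`, `rho`).
#' @param seed Seed for the score noise (default: fixture seed).
#' @return Named list (per method) of cells x genesets score matrices.
#' @export
simulate_geneset_scores <- function(fixture, hub_params, seed = fixture$config$seed) {
  stopifnot(inherits(fixture, "ctc_count_fixture"))
  if (length(hub_params$methods) < 2)
    stop("need at least 2 scoring methods", call. = FALSE)
  plan <- hub_params$plan
  if (!is.null(plan)) {
    if (!all(plan$gene %in% rownames(fixture$counts)))
      stop("planted hub genes must exist in the fixture", call. = FALSE)
    if (anyDuplicated(plan[, c("geneset", "method")]))
      stop("each (geneset, method) column can carry only one planted gene",
           call. = FALSE)
  }
  norm <- lognormalize(fixture$counts)
  nc <- ncol(norm)
  with_seed(derive_seed(seed, "scores"), {
    out <- lapply(hub_params$methods, function(meth) {
      m <- matrix(stats::rnorm(nc * length(hub_params$genesets)), nc,
                  dimnames = list(colnames(norm), hub_params$genesets))
      if (!is.null(plan)) {
        sel <- plan[plan$method == meth, , drop = FALSE]
        for (k in seq_len(nrow(sel))) {
          x <- norm[sel$gene[k], ]
          rho_s <- sel$rho[k]
          if (rho_s >= 1) {
            m[, sel$geneset[k]] <- x
          } else {
            zx <- stats::qnorm((rank(x) - 0.5) / nc)
            rho_p <- 2 * sin(pi * rho_s / 6)   # Spearman -> Pearson (copula)
            m[, sel$geneset[k]] <- rho_p * zx +
              sqrt(1 - rho_p^2) * stats::rnorm(nc)
          }
        }
      }
      m
    })
    names(out) <- hub_params$methods
    out
  })
}
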