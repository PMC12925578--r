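# Flow-cytometry MFI pipeline: control QC, session-matched normalization,
# negative-MFI imputation, robust outlier filtering, minimum-median
# subpopulation thresholds, and nonparametric group/cycle comparisons.

.chan_col <- c(EpCAM = "epcam_mfi", PSMA = "psma_mfi")

chan_column <- function(channel) {
  channel <- match.arg(channel, names(.chan_col))
  .chan_col[[channel]]
}

check_events <- function(events) {
  need <- c("event_id", "sample_id", "session_id", "cycle", "response",
            "epcam_mfi", "psma_mfi", "is_control")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("event table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  invisible(events)
}

# Control QC ------------------------------------------------------------------

#' Summarize control wells per sort session
#'
#' Deduplicates control entries, computes per-session per-channel control
#' medians, and the cross-session grand median / MAD / MADM QC statistics.
#' Optionally compares per-session control medians between two session groups
#' with a Mann-Whitney U test (e.g. early vs late sessions).
#'
#' @param events Event table containing control rows (`is_control == TRUE`).
#' @param scale_constant MAD scale constant (default 1, descriptive).
#' @param session_groups Optional named vector mapping session ids to one of
#'   exactly two group labels; adds a per-channel `comparison`.
#' @return List: `summaries` (per-session data.frame with `session_id`,
#'   `epcam_median`, `psma_median`, `n_events`), `robust` (per-channel
#'   [robust_summaries()]), optional `comparison`.
#' @export
summarize_controls <- function(events, scale_constant = 1.0,
                               session_groups = NULL) {
  check_events(events)
  ctrl <- events[events$is_control, , drop = FALSE]
  if (nrow(ctrl) == 0) stop("no control events", call. = FALSE)
  dup <- duplicated(ctrl[, c("session_id", "epcam_mfi", "psma_mfi")])
  ctrl <- ctrl[!dup, , drop = FALSE]
  sp <- split(ctrl, ctrl$session_id)
  summaries <- data.frame(
    session_id = names(sp),
    epcam_median = vapply(sp, function(d) stats::median(d$epcam_mfi), 0),
    psma_median = vapply(sp, function(d) stats::median(d$psma_mfi), 0),
    n_events = vapply(sp, nrow, 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  robust <- list(
    EpCAM = robust_summaries(lapply(sp, `[[`, "epcam_mfi"), scale_constant),
    PSMA = robust_summaries(lapply(sp, `[[`, "psma_mfi"), scale_constant))
  out <- list(summaries = summaries, robust = robust,
              n_duplicates_removed = sum(dup))
  if (!is.null(session_groups)) {
    g <- session_groups[summaries$session_id]
    lev <- unique(stats::na.omit(g))
    if (length(lev) != 2) stop("session_groups must define exactly 2 groups",
                               call. = FALSE)
    out$comparison <- lapply(c(EpCAM = "epcam_median", PSMA = "psma_median"),
      function(col) mann_whitney_u(summaries[[col]][g == lev[1]],
                                   summaries[[col]][g == lev[2]]))
  }
  out
}

# Normalization ----------------------------------------------------------------

#' Normalize event MFIs by session-matched control medians
#'
#' Divides each non-control event's channel MFI by that session's control
#' median for the same channel, cancelling the multiplicative sort-to-sort
#' batch factor. Control rows pass through untouched; negative raw values
#' keep their sign (the divisor is positive).
#'
#' @param events Event table.
#' @param control A [summarize_controls()] result (or its `summaries` frame).
#' @return The event table with normalized `epcam_mfi` / `psma_mfi`.
#' @export
normalize_events <- function(events, control) {
  check_events(events)
  summaries <- if (is.data.frame(control)) control else control$summaries
  idx <- match(events$session_id, summaries$session_id)
  need <- !events$is_control
  missing_sess <- unique(events$session_id[need & is.na(idx)])
  if (length(missing_sess))
    stop("no control summary for session(s): ",
         paste(missing_sess, collapse = ", "), call. = FALSE)
  out <- events
  out$epcam_mfi[need] <- events$epcam_mfi[need] / summaries$epcam_median[idx[need]]
  out$psma_mfi[need] <- events$psma_mfi[need] / summaries$psma_median[idx[need]]
  out
}

#' Exclude events from patients with unknown treatment outcome
#'
#' @param events Event table.
#' @return List: `events` (only Responder/Nonresponder non-control events,
#'   controls retained), `exclusion_log` (per-patient excluded event counts).
#' @export
exclude_unknown_response <- function(events) {
  check_events(events)
  drop <- !events$is_control & !(events$response %in% c("Responder", "Nonresponder"))
  log <- data.frame()
  if (any(drop)) {
    tab <- table(events$patient_id[drop], useNA = "ifany")
    log <- data.frame(patient_id = names(tab), n_excluded = as.integer(tab),
                      stringsAsFactors = FALSE)
  }
  kept <- events[!drop, , drop = FALSE]
  if (!any(!kept$is_control))
    warning("no events with known treatment outcome remain")
  list(events = kept, exclusion_log = log)
}

# Imputation -------------------------------------------------------------------

#' Imputation configuration for negative MFI artifacts
#'
#' @param draw_set_size Size of the channel-specific drawing set built from
#'   the lowest strictly positive normalized values (default 10).
#' @param n_draws Values drawn per imputation; their mean is the imputed
#'   value (default 2).
#' @param seed Seed for the draws.
#' @param with_replacement Draw with replacement within one imputation
#'   (default FALSE: the drawn members are distinct).
#' @return List of class `ctc_imputation_config`.
#' @export
imputation_config <- function(draw_set_size = 10L, n_draws = 2L, seed = 1L,
                              with_replacement = FALSE) {
  if (!with_replacement && draw_set_size < n_draws)
    stop("draw_set_size must be >= n_draws", call. = FALSE)
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  out <- list(draw_set_size = as.integer(draw_set_size),
              n_draws = as.integer(n_draws), seed = as.integer(seed),
              with_replacement = with_replacement)
  class(out) <- "ctc_imputation_config"
  out
}

#' Impute negative and zero MFI values
#'
#' Negative MFIs are artifacts of instrument baseline subtraction. Per
#' channel, a drawing set of the `draw_set_size` lowest strictly positive
#' normalized values (dataset-wide, non-control events) is built; each value
#' <= 0 is replaced, independently, by the mean of `n_draws` values sampled
#' from that set, keeping imputed values near the detection baseline while
#' avoiding duplicated values.
#'
#' @param events Normalized event table.
#' @param channel `"EpCAM"` or `"PSMA"`.
#' @param cfg An [imputation_config()].
#' @return List: `events` (imputed), `log` (event_id, original value, drawn
#'   members, imputed value).
#' @export
impute_negative_mfi <- function(events, channel, cfg = imputation_config()) {
  check_events(events)
  col <- chan_column(channel)
  need <- !events$is_control
  vals <- events[[col]][need]
  pos <- sort(vals[vals > 0])
  if (length(pos) < cfg$draw_set_size)
    stop("fewer than ", cfg$draw_set_size, " positive values on ", channel,
         call. = FALSE)
  draw_set <- pos[seq_len(cfg$draw_set_size)]
  target <- which(need)[vals <= 0]
  log <- data.frame()
  out <- events
  if (length(target)) {
    with_seed(cfg$seed, {
      drawn <- lapply(target, function(i)
        sample(draw_set, cfg$n_draws, replace = cfg$with_replacement))
      imputed <- vapply(drawn, mean, 0)
      log <- data.frame(event_id = events$event_id[target],
                        channel = channel,
                        original = events[[col]][target],
                        drawn = vapply(drawn, paste, "", collapse = ";"),
                        imputed = imputed, stringsAsFactors = FALSE)
      out[[col]][target] <- imputed
    })
  }
  list(events = out, log = log, draw_set = draw_set)
}

# Outlier filtering ------------------------------------------------------------

#' Outlier filtering rule
#'
#' @param k Multiplier on the MAD (default 3).
#' @param transform `"log10"` (default) or `"identity"` applied per channel
#'   before computing median and MAD.
#' @param scale_constant MAD scale constant (default 1.4826, normal-consistent).
#' @return List of class `ctc_outlier_rule`.
#' @export
outlier_rule <- function(k = 3.0, transform = c("log10", "identity"),
                         scale_constant = 1.4826) {
  transform <- match.arg(transform)
  if (k <= 0) stop("k must be positive", call. = FALSE)
  structure(list(k = k, transform = transform, scale_constant = scale_constant),
            class = "ctc_outlier_rule")
}

#' Remove events with exceptionally high or low MFI values
#'
#' Per channel (after imputation), events with transformed MFI farther than
#' `k x MAD` from the channel median are flagged; an event is removed if
#' flagged on either channel. If the MAD is zero (all values identical)
#' nothing is removed.
#'
#' @param events Imputed event table (all non-control MFIs must be positive
#'   when `transform = "log10"`).
#' @param rule An [outlier_rule()].
#' @return List: `events` (retained), `removed` (with per-channel reasons).
#' @export
filter_outliers <- function(events, rule = outlier_rule()) {
  check_events(events)
  need <- !events$is_control
  flag <- matrix(FALSE, nrow(events), 2,
                 dimnames = list(NULL, names(.chan_col)))
  for (ch in names(.chan_col)) {
    v <- events[[.chan_col[[ch]]]][need]
    if (rule$transform == "log10") {
      if (any(v <= 0)) stop("non-positive ", ch,
                            " values: impute before filtering", call. = FALSE)
      t <- log10(v)
    } else t <- v
    med <- stats::median(t)
    mad <- rule$scale_constant * stats::median(abs(t - med))
    if (mad > 0) flag[which(need)[abs(t - med) > rule$k * mad], ch] <- TRUE
  }
  rm_idx <- which(flag[, 1] | flag[, 2])
  removed <- events[rm_idx, , drop = FALSE]
  if (length(rm_idx)) {
    removed$reason <- apply(flag[rm_idx, , drop = FALSE], 1, function(f)
      paste(names(.chan_col)[f], collapse = "+"))
  }
  list(events = events[setdiff(seq_len(nrow(events)), rm_idx), , drop = FALSE],
       removed = removed)
}

# Thresholding and classification ----------------------------------------------

#' Derive subpopulation thresholds from minimum per-sample medians
#'
#' Per channel, the threshold is the minimum over retained samples of the
#' per-sample median normalized MFI, mirroring a single gating line per
#' channel below every sample's typical level.
#'
#' @param events Retained (filtered) non-control event table.
#' @return List of class `ctc_thresholds`: `thresholds` (named per channel),
#'   `provenance` (which sample supplied each minimum).
#' @export
derive_thresholds <- function(events) {
  check_events(events)
  ev <- events[!events$is_control, , drop = FALSE]
  if (nrow(ev) == 0) stop("no events to derive thresholds from", call. = FALSE)
  prov <- NULL
  thr <- vapply(names(.chan_col), function(ch) {
    meds <- tapply(ev[[.chan_col[[ch]]]], ev$sample_id, stats::median)
    i <- which.min(meds)
    prov <<- rbind(prov, data.frame(channel = ch, sample_id = names(meds)[i],
                                    n_samples = length(meds),
                                    stringsAsFactors = FALSE))
    meds[[i]]
  }, 0)
  structure(list(thresholds = thr, provenance = prov), class = "ctc_thresholds")
}

#' Classify events into EpCAM/PSMA subpopulations
#'
#' A channel is positive iff its normalized MFI is greater than or equal to
#' the channel threshold (boundary counts as positive). The four labels form
#' a complete disjoint partition.
#'
#' @param events Event table.
#' @param thresholds A [derive_thresholds()] result (or named numeric vector).
#' @return The non-control events with an added `subpop` column, one of
#'   `"EpCAM+PSMA-"`, `"EpCAM+PSMA+"`, `"EpCAM-PSMA+"`, `"EpCAM-PSMA-"`.
#' @export
classify_events <- function(events, thresholds) {
  check_events(events)
  thr <- if (inherits(thresholds, "ctc_thresholds")) thresholds$thresholds
         else thresholds
  ev <- events[!events$is_control, , drop = FALSE]
  ep <- ev$epcam_mfi >= thr[["EpCAM"]]
  ps <- ev$psma_mfi >= thr[["PSMA"]]
  ev$subpop <- paste0(ifelse(ep, "EpCAM+", "EpCAM-"),
                      ifelse(ps, "PSMA+", "PSMA-"))
  ev
}

#' Subpopulation distribution between response groups
#'
#' Raw counts and within-subpopulation percentages of Responder vs
#' Nonresponder events for the three marker-positive subpopulations, each
#' with a chi-squared goodness-of-fit test of the split against either the
#' overall group proportions (default, accounts for unequal group sizes) or
#' an equal split. Double-negative events are excluded and reported.
#'
#' @param classified Output of [classify_events()].
#' @param expected `"overall_proportions"` (default) or `"equal"`.
#' @return List: `table` (subpop x group counts and percentages), `tests`
#'   (per subpop, `ctc_test` or NULL when empty), `n_double_negative`.
#' @export
subpop_distribution <- function(classified,
                                expected = c("overall_proportions", "equal")) {
  expected <- match.arg(expected)
  if (nrow(classified) == 0) stop("no labeled events", call. = FALSE)
  groups <- c("Responder", "Nonresponder")
  pos <- c("EpCAM+PSMA-", "EpCAM+PSMA+", "EpCAM-PSMA+")
  dn <- sum(classified$subpop == "EpCAM-PSMA-")
  ev <- classified[classified$subpop != "EpCAM-PSMA-", , drop = FALSE]
  overall <- prop.table(table(factor(ev$response, groups)))
  tab <- NULL; tests <- list()
  for (sp in pos) {
    cnt <- table(factor(ev$response[ev$subpop == sp], groups))
    total <- sum(cnt)
    tab <- rbind(tab, data.frame(
      subpop = sp, responder_n = cnt[["Responder"]],
      nonresponder_n = cnt[["Nonresponder"]],
      responder_pct = if (total) 100 * cnt[["Responder"]] / total else NA_real_,
      nonresponder_pct = if (total) 100 * cnt[["Nonresponder"]] / total else NA_real_,
      stringsAsFactors = FALSE))
    tests[[sp]] <- if (total == 0) NULL else chi_squared_gof(
      as.integer(cnt),
      if (expected == "equal") c(0.5, 0.5) else as.numeric(overall))
  }
  list(table = tab, tests = tests, n_double_negative = dn, expected = expected)
}

# Group and cycle comparisons --------------------------------------------------

#' Compare pooled-cycle marker levels between response groups
#'
#' @param events Retained non-control event table.
#' @param channel `"EpCAM"` or `"PSMA"`.
#' @return List: per-group `n`, `median`, `log10_median`, and a two-sided
#'   Mann-Whitney `test`.
#' @export
compare_groups_mfi <- function(events, channel) {
  col <- chan_column(channel)
  ev <- events[!events$is_control, , drop = FALSE]
  x <- ev[[col]][ev$response == "Responder"]
  y <- ev[[col]][ev$response == "Nonresponder"]
  if (!length(x) || !length(y)) stop("both response groups must be non-empty",
                                     call. = FALSE)
  med <- function(v) stats::median(v)
  list(channel = channel,
       responder = list(n = length(x), median = med(x),
                        log10_median = log10(med(x))),
       nonresponder = list(n = length(y), median = med(y),
                           log10_median = log10(med(y))),
       test = mann_whitney_u(x, y))
}

#' Per-cycle marker dynamics
#'
#' Drops cycles where either response group has fewer than
#' `min_cells_per_cycle` cells (the sparse-tail cutoff), then tests, on
#' log-transformed values, each group's cycle against its baseline (cycle 0)
#' and the two groups against each other within each retained cycle.
#'
#' @param events Retained non-control event table (positive MFIs).
#' @param channel `"EpCAM"` or `"PSMA"`.
#' @param min_cells_per_cycle Minimum cells per group per cycle (default 5).
#' @return data.frame with `group`, `cycle`, `channel`, `n`, `median_mfi`,
#'   `log10_median`, `p_vs_baseline` (NA at cycle 0), `p_between_groups`.
#' @export
cycle_dynamics <- function(events, channel, min_cells_per_cycle = 5L) {
  col <- chan_column(channel)
  ev <- events[!events$is_control, , drop = FALSE]
  groups <- c("Responder", "Nonresponder")
  cyc <- sort(unique(ev$cycle))
  if (!0L %in% cyc) stop("baseline (cycle 0) missing", call. = FALSE)
  nmat <- sapply(groups, function(g) sapply(cyc, function(cc)
    sum(ev$response == g & ev$cycle == cc)))
  keep_cyc <- cyc[apply(nmat >= min_cells_per_cycle, 1, all)]
  if (!0L %in% keep_cyc)
    stop("baseline has fewer than min_cells_per_cycle cells", call. = FALSE)
  base <- lapply(groups, function(g)
    log10(ev[[col]][ev$response == g & ev$cycle == 0L]))
  names(base) <- groups
  rows <- NULL
  for (cc in keep_cyc) {
    vals <- lapply(groups, function(g)
      log10(ev[[col]][ev$response == g & ev$cycle == cc]))
    names(vals) <- groups
    p_bg <- mann_whitney_u(vals$Responder, vals$Nonresponder)$p_value
    for (g in groups) {
      v <- vals[[g]]
      rows <- rbind(rows, data.frame(
        group = g, cycle = cc, channel = channel, n = length(v),
        median_mfi = stats::median(10^v), log10_median = stats::median(v),
        p_vs_baseline = if (cc == 0L) NA_real_ else
          mann_whitney_u(v, base[[g]])$p_value,
        p_between_groups = p_bg, stringsAsFactors = FALSE))
    }
  }
  rownames(rows) <- NULL
  rows
}

#' Per-sample CTC counts and group comparison
#'
#' Counts retained events per sample, summarizes medians and ranges per
#' response group, and compares the per-sample counts with a Mann-Whitney
#' U test.
#'
#' @param events Retained non-control event table.
#' @return List: `per_sample` data.frame, per-group `median`, `range`, `n`,
#'   and `test`.
#' @export
ctc_count_stats <- function(events) {
  ev <- events[!events$is_control, , drop = FALSE]
  per_sample <- as.data.frame(table(sample_id = ev$sample_id),
                              stringsAsFactors = FALSE)
  names(per_sample)[2] <- "n_ctc"
  per_sample$response <- ev$response[match(per_sample$sample_id, ev$sample_id)]
  out <- list(per_sample = per_sample)
  for (g in c("Responder", "Nonresponder")) {
    v <- per_sample$n_ctc[per_sample$response == g]
    if (!length(v)) stop("group without samples: ", g, call. = FALSE)
    out[[tolower(g)]] <- list(n = length(v), median = stats::median(v),
                              range = range(v))
  }
  out$test <- mann_whitney_u(
    per_sample$n_ctc[per_sample$response == "Responder"],
    per_sample$n_ctc[per_sample$response == "Nonresponder"])
  out
}

# CSV dialect ------------------------------------------------------------------

#' Write / read the flow event CSV dialect
#'
#' One row per event with the documented columns (`event_id`, `patient_id`,
#' `sample_id`, `session_id`, `cycle`, `response`, `epcam_mfi`, `psma_mfi`,
#' `is_control`); controls are flagged by column, not kept in a separate file.
#'
#' @param events Event table.
#' @param path File path.
#' @return `read_flow_events` returns the event data.frame.
#' @export
write_flow_events <- function(events, path) {
  check_events(events)
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flow_events
#' @export
read_flow_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  ev$is_control <- as.logical(ev$is_control)
  check_events(ev)
}
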