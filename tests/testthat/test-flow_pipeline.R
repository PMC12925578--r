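test_that("control summaries deduplicate and report robust QC statistics", {
  ctrl <- rbind(make_events(c(1, 2, 3), c(2, 4, 6), session_id = "S1",
                            is_control = TRUE, id_prefix = "a"),
                make_events(c(2, 3, 4), c(1, 2, 3), session_id = "S2",
                            is_control = TRUE, id_prefix = "b"))
  s <- summarize_controls(ctrl)
  expect_equal(s$summaries$epcam_median[s$summaries$session_id == "S1"], 2)
  expect_equal(s$robust$EpCAM$grand_median, 2.5)

  # duplicated control rows are removed before summarizing
  dup <- rbind(ctrl, ctrl[1:2, ])
  s2 <- summarize_controls(dup)
  expect_equal(s2$n_duplicates_removed, 2L)
  expect_equal(s2$summaries$n_events, s$summaries$n_events)

  # two identical control batches compare with p = 1
  many <- do.call(rbind, lapply(1:8, function(i)
    make_events(rep(i, 2), rep(i, 2), session_id = sprintf("S%02d", i),
                is_control = TRUE, id_prefix = paste0("s", i))))
  grp <- setNames(rep(c("A", "B"), 4), sprintf("S%02d", 1:8))
  cmp <- summarize_controls(many, session_groups = grp)$comparison
  expect_gt(cmp$EpCAM$p_value, 0.5)
  expect_error(summarize_controls(make_events(1, 1)), "no control")
})

test_that("normalization divides by session-matched control medians", {
  ev <- make_events(2.0, 0.5, session_id = "S1")
  ctrl <- data.frame(session_id = "S1", epcam_median = 4.0, psma_median = 0.25,
                     n_events = 10)
  nm <- normalize_events(ev, ctrl)
  expect_equal(nm$epcam_mfi, 0.5)
  expect_equal(nm$psma_mfi, 2.0)

  ident <- normalize_events(ev, data.frame(session_id = "S1", epcam_median = 1,
                                           psma_median = 1, n_events = 1))
  expect_equal(ident$epcam_mfi, ev$epcam_mfi)
  # sign of negative raw values is preserved
  neg <- make_events(-0.3, 1, session_id = "S1")
  expect_lt(normalize_events(neg, ctrl)$epcam_mfi, 0)
  expect_error(normalize_events(make_events(1, 1, session_id = "S9"), ctrl),
               "S9")
})

test_that("unknown-outcome exclusion is exact bookkeeping", {
  ev <- rbind(make_events(1:3, 1:3, response = "Responder", patient_id = "P1"),
              make_events(1:5, 1:5, response = "Unknown", patient_id = "P9",
                          id_prefix = "u"))
  r <- exclude_unknown_response(ev)
  expect_equal(nrow(r$events), nrow(ev) - 5)
  expect_equal(r$exclusion_log$n_excluded, 5L)
  expect_equal(nrow(exclude_unknown_response(ev[1:3, ])$exclusion_log), 0)
  expect_warning(exclude_unknown_response(ev[4:8, ]), "no events")
})

test_that("imputation draws pair means from the ten lowest positive values", {
  pos <- c(0.01, 0.02, 0.05, 0.08, 0.1, 0.12, 0.2, 0.3, 0.4, 0.55,
           1, 2, 3, 4, 5)
  ev <- make_events(c(pos, -0.5, 0, -0.1), rep(1, 18))
  cfg <- imputation_config(seed = 7)
  r <- impute_negative_mfi(ev, "EpCAM", cfg)
  set10 <- sort(pos)[1:10]
  pair_means <- apply(utils::combn(set10, 2), 2, mean)
  imputed <- r$log$imputed
  expect_equal(nrow(r$log), 3)
  for (v in imputed) expect_true(any(abs(pair_means - v) < 1e-12))
  expect_true(all(imputed >= min(set10) & imputed <= max(set10)))
  # strictly positive values never change
  expect_equal(r$events$epcam_mfi[1:15], ev$epcam_mfi[1:15])
  # reproducible under the same seed
  expect_identical(impute_negative_mfi(ev, "EpCAM", cfg)$events, r$events)
  # identity when nothing to impute
  clean <- make_events(pos, rep(1, 15))
  expect_identical(impute_negative_mfi(clean, "EpCAM", cfg)$events, clean)
  expect_error(impute_negative_mfi(make_events(1:5, 1:5), "EpCAM", cfg),
               "fewer than 10")
})

test_that("outlier filter flags log-scale deviations beyond k MADs", {
  ev <- make_events(rep(2, 10), rep(2, 10))
  expect_equal(nrow(filter_outliers(ev)$removed), 0)  # MAD = 0: retain all

  v <- c(0.9, 1, 1.1, 1.05, 0.95, 1.2, 0.85, 1, 1e6)
  ev2 <- make_events(v, rep(1, 9))
  r <- filter_outliers(ev2)
  expect_equal(r$removed$event_id, "ev9")
  expect_equal(r$removed$reason, "EpCAM")

  # increasing k never removes more events
  n_removed <- vapply(c(2, 3, 5, 10), function(k)
    nrow(filter_outliers(ev2, outlier_rule(k = k))$removed), 0L)
  expect_false(is.unsorted(rev(n_removed)))
  expect_error(filter_outliers(make_events(c(1, -1), c(1, 1))), "impute")
})

test_that("thresholds are minima of per-sample medians", {
  ev <- rbind(make_events(c(0.5, 0.5), c(1, 1), sample_id = "A"),
              make_events(c(0.2, 0.2), c(2, 2), sample_id = "B", id_prefix = "b"),
              make_events(c(0.9, 0.9), c(3, 3), sample_id = "C", id_prefix = "c"))
  thr <- derive_thresholds(ev)
  expect_equal(unname(thr$thresholds["EpCAM"]), 0.2)
  expect_equal(thr$provenance$sample_id[thr$provenance$channel == "EpCAM"], "B")

  single <- make_events(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(derive_thresholds(single)$thresholds), c(2, 5))

  # adding a sample with a higher median never raises the threshold
  more <- rbind(ev, make_events(c(5, 5), c(5, 5), sample_id = "D", id_prefix = "d"))
  expect_lte(derive_thresholds(more)$thresholds[["EpCAM"]],
             thr$thresholds[["EpCAM"]])
})

test_that("classification is a complete disjoint partition with >= boundary", {
  thr <- c(EpCAM = 0.2, PSMA = 0.2)
  ev <- make_events(0.3, 0.1)
  expect_equal(classify_events(ev, thr)$subpop, "EpCAM+PSMA-")
  expect_equal(classify_events(make_events(0.2, 0.2), thr)$subpop,
               "EpCAM+PSMA+")

  set.seed(6)
  big <- make_events(runif(200), runif(200))
  cl <- classify_events(big, thr)
  expect_equal(sum(table(cl$subpop)), 200)
  expect_length(unique(cl$subpop), 4)
})

test_that("subpopulation distribution tests match the goodness-of-fit stats", {
  ev <- rbind(
    make_events(rep(1, 10), rep(0, 10), response = "Responder"),
    make_events(rep(1, 10), rep(0, 10), response = "Nonresponder", id_prefix = "n"),
    make_events(rep(1, 15), rep(1, 15), response = "Responder", id_prefix = "p"),
    make_events(rep(1, 5), rep(1, 5), response = "Nonresponder", id_prefix = "q"))
  cl <- classify_events(ev, c(EpCAM = 0.5, PSMA = 0.5))
  d <- subpop_distribution(cl, expected = "equal")
  expect_equal(d$tests[["EpCAM+PSMA-"]]$p_value, 1)
  expect_equal(d$tests[["EpCAM+PSMA+"]]$statistic, 5.0)
  pct <- d$table$responder_pct + d$table$nonresponder_pct
  expect_equal(pct[!is.na(pct)], rep(100, sum(!is.na(pct))))
})

test_that("group comparison reports log10 medians consistently", {
  set.seed(10)
  ev <- rbind(make_events(rlnorm(30), rlnorm(30), response = "Responder"),
              make_events(rlnorm(30), rlnorm(30), response = "Nonresponder",
                          id_prefix = "n"))
  r <- compare_groups_mfi(ev, "EpCAM")
  expect_equal(r$responder$log10_median, log10(r$responder$median))
  expect_gt(r$test$p_value, 0.05)   # identical distributions
  expect_error(compare_groups_mfi(ev[ev$response == "Responder", ], "EpCAM"),
               "non-empty")
})

test_that("cycle dynamics applies the sparse-cycle cutoff", {
  mk <- function(n, cy, g, pre) make_events(rlnorm(n), rlnorm(n), cycle = cy,
                                            response = g, id_prefix = pre,
                                            sample_id = paste0(pre, cy))
  set.seed(11)
  ev <- rbind(mk(20, 0, "Responder", "r0"), mk(20, 0, "Nonresponder", "n0"),
              mk(20, 1, "Responder", "r1"), mk(20, 1, "Nonresponder", "n1"),
              mk(3, 4, "Responder", "r4"))   # cycle 4: 3 vs 0 cells
  d <- cycle_dynamics(ev, "EpCAM", min_cells_per_cycle = 5)
  expect_setequal(unique(d$cycle), c(0, 1))
  expect_true(all(is.na(d$p_vs_baseline[d$cycle == 0])))
  expect_false(any(is.na(d$p_vs_baseline[d$cycle == 1])))
  expect_error(cycle_dynamics(ev[ev$cycle != 0, ], "EpCAM"), "baseline")
})

test_that("CTC count statistics summarize per-sample counts", {
  ev <- rbind(make_events(rep(1, 1), rep(1, 1), sample_id = "A"),
              make_events(rep(1, 2), rep(1, 2), sample_id = "B", id_prefix = "b"),
              make_events(rep(1, 24), rep(1, 24), sample_id = "C", id_prefix = "c"),
              make_events(rep(1, 4), rep(1, 4), sample_id = "D", id_prefix = "d",
                          response = "Nonresponder"))
  r <- ctc_count_stats(ev)
  expect_equal(r$responder$median, 2)
  expect_equal(r$responder$range, c(1, 24))
  expect_equal(r$nonresponder$median, 4)
  expect_identical(r$test$method, "exact")   # tiny samples use enumeration
})

test_that("normalization exactly cancels a multiplicative session factor", {
  cfg <- cohort_config(n_patients_per_group = 4, cycles = 0:1,
                       detection_floor = 0, seed = 21)
  ev <- simulate_flow_events(simulate_cohort(cfg), cfg)
  norm1 <- normalize_events(ev, summarize_controls(ev))
  scaled <- ev
  s1 <- scaled$session_id == scaled$session_id[1]
  scaled$epcam_mfi[s1] <- scaled$epcam_mfi[s1] * 7
  scaled$psma_mfi[s1] <- scaled$psma_mfi[s1] * 0.3
  norm2 <- normalize_events(scaled, summarize_controls(scaled))
  expect_equal(norm2$epcam_mfi[!norm2$is_control],
               norm1$epcam_mfi[!norm1$is_control], tolerance = 1e-12)
})

test_that("flow event CSV dialect round-trips", {
  cfg <- cohort_config(n_patients_per_group = 2, cycles = 0:1, seed = 2)
  ev <- simulate_flow_events(simulate_cohort(cfg), cfg)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_flow_events(ev, path)
  back <- read_flow_events(path)
  expect_equal(back$epcam_mfi, ev$epcam_mfi, tolerance = 1e-12)
  expect_identical(back$is_control, ev$is_control)
})
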