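test_that("QC removal reasons follow the strict-inequality rule", {
  # hand-built matrix: one clear failure per reason plus a clean cell
  genes <- c(sprintf("G%04d", 1:2100), "MT-A", "MT-B")
  mt <- c("MT-A", "MT-B")
  m <- matrix(0L, length(genes), 4,
              dimnames = list(genes, paste0("c", 1:4)))
  m[1:1500, 1] <- 4L                      # clean: 6000 counts, 1500 genes
  m[1:1200, 2] <- 3L; m[1, 2] <- 3L       # low counts: 3600 total
  m[1:500, 3] <- 20L                      # low genes: 500 detected
  m[1:1200, 4] <- 2L; m["MT-A", 4] <- 8000L  # mt fraction >> 0.75
  qc <- qc_filter_cells(m, mt)
  expect_equal(qc$qc$reasons, c("", "low_counts", "low_genes", "high_mt"))
  expect_equal(qc$kept_cells, "c1")
  expect_error(qc_filter_cells(m, c("NOPE")), "subset")
  expect_error(qc_filter_cells(m[, 0], mt), "empty")
})

test_that("log-normalization is depth-invariant and maps zero to zero", {
  m <- matrix(c(0, 5, 5, 2, 8, 0), 3, 2,
              dimnames = list(c("a", "b", "c"), c("x", "y")))
  nm <- lognormalize(m)
  expect_equal(nm["a", "x"], 0)
  expect_equal(nm["b", "x"], nm["c", "x"])      # equal counts, equal values
  expect_equal(lognormalize(m * 2)[, "y"], nm[, "y"])  # doubling a cell: no-op
  m0 <- m; m0[, 1] <- 0
  expect_error(lognormalize(m0), "zero-total")
  # sparse input gives the same result
  expect_equal(lognormalize(Matrix::Matrix(m, sparse = TRUE)), nm)
})

test_that("composition association matches hand computation", {
  cl <- rep(c(0, 1), each = 20)
  confounded <- rep(c("A", "B"), each = 20)
  r <- composition_association(cl, confounded)
  expect_equal(r$test$statistic, 40)            # all expected cells 10
  r2 <- composition_association(confounded, cl) # transposed table
  expect_equal(r2$test$statistic, r$test$statistic)
  skip <- composition_association(rep(0, 10), rep(c("A", "B"), 5))
  expect_null(skip$test)
  expect_match(skip$note, "degenerate")
})

test_that("null calibration of composition tests", {
  set.seed(17)
  ps <- replicate(200, {
    cl <- sample(c(0, 1), 60, TRUE)
    cov <- sample(c("A", "B"), 60, TRUE)
    r <- composition_association(cl, cov)
    if (is.null(r$test)) NA_real_ else r$test$p_value
  })
  expect_lt(mean(ps < 0.05, na.rm = TRUE), 0.12)
})

test_that("Wilcoxon DGE records obey their definitions", {
  set.seed(23)
  n <- 40
  m <- rbind(flat = rep(2, 2 * n),
             up = c(rnorm(n, 4, 0.3), rnorm(n, 1, 0.3)),
             noise = rnorm(2 * n, 2, 0.5))
  colnames(m) <- paste0("c", seq_len(2 * n))
  cl <- rep(c(0, 1), each = n)
  dge <- dge_wilcoxon(m, cl)
  flat <- dge[dge$gene == "flat", ]
  expect_equal(flat$log2fc, 0, tolerance = 1e-9)
  expect_false(flat$significant)
  expect_equal(dge$p_adj, pmin(1, dge$p_raw * nrow(m)))
  expect_true(dge$significant[dge$gene == "up"])
  expect_error(dge_wilcoxon(m, rep(0, 2 * n)), "two levels")
})

test_that("a single planted two-fold-squared effect is recovered accurately", {
  # one gene at log2FC = 2, everything else null: estimate within +/- 0.5
  hits <- vapply(1:10, function(s) {
    cfg <- counts_config(n_deg = 1, lfc_magnitude = 2, frac_up = 1, seed = s)
    fx <- simulate_counts(cfg)
    qc <- qc_filter_cells(fx$counts, fx$mt_genes)
    norm <- lognormalize(fx$counts[, qc$kept_cells])
    cl <- fx$cell_meta$true_cluster[match(qc$kept_cells, fx$cell_meta$cell_id)]
    dge <- dge_wilcoxon(norm, cl)
    g <- names(which(fx$true_degs != 0))
    rec <- dge[dge$gene == g, ]
    abs(rec$log2fc - 2) <= 0.5 && rec$significant
  }, NA)
  expect_gte(mean(hits), 0.9)
})

test_that("DEG filtering and ranking equal an independent re-scan", {
  set.seed(29)
  rec <- data.frame(gene = sprintf("g%03d", 1:200),
                    log2fc = rnorm(200, 0, 1.2),
                    p_raw = runif(200)^3, stringsAsFactors = FALSE)
  rec$p_adj <- pmin(1, rec$p_raw * 200)
  r <- filter_and_rank_degs(rec)
  # brute-force scan oracle
  sig <- character(); best <- -Inf; best_gene <- NA
  for (i in 1:200) {
    if (rec$p_adj[i] < 0.05 && abs(rec$log2fc[i]) >= 1) {
      sig <- c(sig, rec$gene[i])
      score <- abs(rec$log2fc[i] * -log10(max(rec$p_adj[i], 1e-300)))
      if (score > best) { best <- score; best_gene <- rec$gene[i] }
    }
  }
  expect_setequal(r$significant, sig)
  expect_equal(r$ranked$gene[1], best_gene)
  expect_equal(r$n_up + r$n_down, length(sig))

  expect_false("x" %in% filter_and_rank_degs(
    data.frame(gene = "x", log2fc = 0.9, p_raw = 1e-5, p_adj = 0.001))$significant)
  one <- filter_and_rank_degs(
    data.frame(gene = "y", log2fc = 2, p_raw = 1e-4, p_adj = 0.01))
  expect_equal(one$ranked$rank_score, 4.0)
})

test_that("hub correlations validate cells and detect monotone scores", {
  set.seed(31)
  norm <- matrix(rlnorm(300), 3, 100,
                 dimnames = list(c("g1", "g2", "g3"), sprintf("c%03d", 1:100)))
  sc <- matrix(rnorm(200), 100, 2,
               dimnames = list(colnames(norm), c("GS1", "GS2")))
  sc[, "GS1"] <- norm["g1", ]^2        # monotone transform of g1 (positive vals)
  rec <- hub_correlations(norm, list(m1 = sc, m2 = sc))
  r11 <- rec[rec$gene == "g1" & rec$geneset == "GS1" & rec$method == "m1", ]
  expect_equal(r11$rho, 1)
  bad <- list(m1 = sc, m2 = sc[rev(seq_len(100)), ])
  expect_error(hub_correlations(norm, bad), "mismatch")
  expect_error(hub_correlations(norm, list(only = sc)), "2 methods")
})

test_that("hub filter applies the three-criterion rule order-invariantly", {
  rec <- data.frame(
    gene = c("A", "A", "B", "B", "C", "C"),
    geneset = "GS",
    method = rep(c("m1", "m2"), 3),
    rho = c(0.25, 0.30, 0.25, 0.05, 0.4, 0.5),
    p_spearman = c(0.01, 0.001, 0.01, 0.6, 1e-4, 1e-4),
    stringsAsFactors = FALSE)
  degs <- c("A", "B")
  r <- filter_hub_genes(rec, degs)
  expect_equal(r$hubs, "A")             # B: one method; C: not a DEG
  shuffled <- rec[sample(nrow(rec)), ]
  expect_equal(filter_hub_genes(shuffled, degs)$hubs, r$hubs)
  # same gene passing in two gene sets but one method each is not a hub
  split_rec <- data.frame(gene = "D", geneset = c("GS1", "GS2"),
                          method = c("m1", "m2"), rho = 0.5,
                          p_spearman = 1e-5, stringsAsFactors = FALSE)
  expect_length(filter_hub_genes(split_rec, "D")$hubs, 0)
})

test_that("MTX sidecar round-trip preserves counts and metadata", {
  fx <- simulate_counts(counts_config(n_genes = 80, cells_per_cluster = 5,
                                      n_deg = 5, n_mt_genes = 4, seed = 12))
  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE))
  write_counts_mtx(fx$counts, dir, fx$cell_meta)
  back <- read_counts_mtx(dir)
  expect_equal(as.matrix(back$counts), fx$counts)
  expect_equal(back$cell_meta$cell_id, fx$cell_meta$cell_id)
})
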