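# Single-cell downstream computations: per-cell QC filters, depth
# log-normalization, cluster-composition association, Wilcoxon differential
# expression with Bonferroni and fold-change filtering, DEG ranking, and the
# hub-gene correlation filter against per-cell gene-set scores.

#' Cell QC thresholds
#'
#' Defaults retain cells with >= 4,000 total counts, 1,000-7,800 detected
#' genes and <= 75% mitochondrial reads (removal uses strict inequalities, so
#' boundary cells are kept). The lenient mitochondrial cutoff reflects
#' sorted, irradiated CTCs profiled with a full-length plate protocol, where
#' high MT fractions are common in intact cells.
#'
#' @param min_counts,min_genes,max_genes,max_mt_fraction Threshold values.
#' @return List of class `ctc_qc_thresholds`.
#' @export
cell_qc_thresholds <- function(min_counts = 4000L, min_genes = 1000L,
                               max_genes = 7800L, max_mt_fraction = 0.75) {
  if (min_genes >= max_genes) stop("min_genes must be < max_genes", call. = FALSE)
  if (max_mt_fraction <= 0 || max_mt_fraction > 1)
    stop("max_mt_fraction must lie in (0, 1]", call. = FALSE)
  structure(list(min_counts = as.integer(min_counts),
                 min_genes = as.integer(min_genes),
                 max_genes = as.integer(max_genes),
                 max_mt_fraction = max_mt_fraction),
            class = "ctc_qc_thresholds")
}

#' Filter cells on counts, detected genes and mitochondrial fraction
#'
#' A cell is removed iff `total_counts < min_counts` OR
#' `genes_detected < min_genes` OR `genes_detected > max_genes` OR
#' `mt_fraction > max_mt_fraction`; values exactly at a threshold are
#' retained. The mitochondrial fraction is computed on raw counts.
#'
#' @param counts Genes x cells count matrix (dense or sparse).
#' @param mt_genes Character vector of mitochondrial gene ids (subset of
#'   `rownames(counts)`).
#' @param thresholds A [cell_qc_thresholds()].
#' @return List: `kept_cells` (ids), `qc` (per-cell data.frame with
#'   `total_counts`, `genes_detected`, `mt_fraction`, `keep`, `reasons`).
#' @export
qc_filter_cells <- function(counts, mt_genes, thresholds = cell_qc_thresholds()) {
  if (length(counts) == 0 || ncol(counts) == 0)
    stop("empty count matrix", call. = FALSE)
  if (!all(mt_genes %in% rownames(counts)))
    stop("mt_genes must be a subset of the matrix genes", call. = FALSE)
  total <- Matrix::colSums(counts)
  detected <- Matrix::colSums(counts > 0)
  mt <- if (length(mt_genes))
    Matrix::colSums(counts[mt_genes, , drop = FALSE]) / pmax(total, 1)
  else rep(0, ncol(counts))
  reasons <- vapply(seq_len(ncol(counts)), function(j) {
    r <- c(if (total[j] < thresholds$min_counts) "low_counts",
           if (detected[j] < thresholds$min_genes) "low_genes",
           if (detected[j] > thresholds$max_genes) "high_genes",
           if (mt[j] > thresholds$max_mt_fraction) "high_mt")
    paste(r, collapse = "+")
  }, "")
  qc <- data.frame(cell_id = colnames(counts), total_counts = as.numeric(total),
                   genes_detected = as.integer(detected),
                   mt_fraction = as.numeric(mt),
                   keep = reasons == "", reasons = reasons,
                   stringsAsFactors = FALSE, row.names = NULL)
  list(kept_cells = qc$cell_id[qc$keep], qc = qc)
}

#' Depth log-normalization
#'
#' Per cell: `ln(1 + scale * count / cell_total)`. A plain plumbing transform
#' standing upstream of rank-based testing; it removes library depth and
#' nothing else.
#'
#' @param counts Genes x cells non-negative count matrix.
#' @param scale Scale factor (default 1e4).
#' @return Dense numeric matrix of the same shape.
#' @export
lognormalize <- function(counts, scale = 1e4) {
  total <- Matrix::colSums(counts)
  if (any(total == 0)) stop("zero-total cell(s): run QC first", call. = FALSE)
  m <- as.matrix(counts)
  log1p(scale * sweep(m, 2, total, "/"))
}

#' Association between cluster membership and a per-cell covariate
#'
#' Builds the cluster x covariate contingency table and runs the chi-squared
#' test of independence. Degenerate margins (a cluster or level with zero
#' cells, or fewer than two levels) skip the test with a notice.
#'
#' @param cluster_labels Per-cell cluster labels.
#' @param covariate Per-cell covariate (response, cycle, treatment type, ...).
#' @return List: `table`, `test` (`ctc_test` or NULL), `note`.
#' @export
composition_association <- function(cluster_labels, covariate) {
  tab <- table(cluster = cluster_labels, covariate = covariate)
  if (nrow(tab) < 2 || ncol(tab) < 2 || any(rowSums(tab) == 0) ||
      any(colSums(tab) == 0))
    return(list(table = tab, test = NULL,
                note = "skipped: degenerate margins"))
  list(table = tab, test = chi_squared_independence(tab), note = NULL)
}

#' Wilcoxon differential expression between two clusters
#'
#' Per gene: two-sided Mann-Whitney p on log-normalized values, Bonferroni
#' adjustment with `m` = genes tested, and a fold change computed as the
#' log2 ratio of cluster means of the back-transformed expression
#' (`expm1`) with pseudocount `eps`. Significance requires adjusted
#' p < `alpha` and `|log2fc| >= lfc_cutoff`; the ranking score is
#' `log2fc * (-log10 max(p_adj, p_floor))`.
#'
#' @param norm Log-normalized genes x cells matrix.
#' @param cluster_labels Per-cell labels with exactly two levels; the first
#'   sorted level is "cluster 0" (fold changes are cluster 0 over cluster 1).
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @param lfc_cutoff Minimum |log2fc| (default 1, i.e. two-fold).
#' @param eps Fold-change pseudocount (default 1e-9).
#' @param p_floor Floor on the adjusted p inside the ranking score
#'   (default 1e-300).
#' @return data.frame: `gene`, `log2fc`, `p_raw`, `p_adj`, `significant`,
#'   `rank_score`.
#' @export
dge_wilcoxon <- function(norm, cluster_labels, alpha = 0.05, lfc_cutoff = 1,
                         eps = 1e-9, p_floor = 1e-300) {
  lev <- sort(unique(cluster_labels))
  if (length(lev) != 2) stop("cluster_labels must have exactly two levels",
                             call. = FALSE)
  i0 <- which(cluster_labels == lev[1]); i1 <- which(cluster_labels == lev[2])
  if (length(i0) < 3 || length(i1) < 3)
    stop("each cluster needs at least 3 cells", call. = FALSE)
  m <- as.matrix(norm)
  genes <- rownames(m)
  p_raw <- vapply(seq_len(nrow(m)), function(g)
    mann_whitney_u(m[g, i0], m[g, i1])$p_value, 0)
  lfc <- log2((rowMeans(expm1(m[, i0, drop = FALSE])) + eps) /
              (rowMeans(expm1(m[, i1, drop = FALSE])) + eps))
  p_adj <- bonferroni_adjust(p_raw, nrow(m))
  data.frame(gene = genes, log2fc = unname(lfc), p_raw = p_raw, p_adj = p_adj,
             significant = p_adj < alpha & abs(lfc) >= lfc_cutoff,
             rank_score = unname(lfc) * -log10(pmax(p_adj, p_floor)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter and rank differential-expression records
#'
#' Applies the significance rule (adjusted p < `alpha` and
#' `|log2fc| >= lfc_cutoff`), recomputes ranking scores with the p-floor, and
#' sorts by absolute ranking score.
#'
#' @param records Output of [dge_wilcoxon()].
#' @param alpha,lfc_cutoff,p_floor As in [dge_wilcoxon()].
#' @param top_k Rows in the display subset (default 15).
#' @return List: `significant` (gene ids), `ranked` (sorted data.frame),
#'   `top` (head of `ranked`), `n_up`, `n_down`.
#' @export
filter_and_rank_degs <- function(records, alpha = 0.05, lfc_cutoff = 1,
                                 p_floor = 1e-300, top_k = 15L) {
  sig <- records$p_adj < alpha & abs(records$log2fc) >= lfc_cutoff
  records$significant <- sig
  records$rank_score <- records$log2fc * -log10(pmax(records$p_adj, p_floor))
  ranked <- records[sig, , drop = FALSE]
  ranked <- ranked[order(-abs(ranked$rank_score)), , drop = FALSE]
  rownames(ranked) <- NULL
  list(significant = ranked$gene, ranked = ranked,
       top = utils::head(ranked, top_k),
       n_up = sum(ranked$log2fc > 0), n_down = sum(ranked$log2fc < 0))
}

#' Spearman correlations between gene expression and gene-set scores
#'
#' For every (candidate gene, gene set, scoring method), the Spearman
#' correlation between the gene's log-normalized expression and the
#' per-cell gene-set score.
#'
#' @param norm Log-normalized genes x cells matrix.
#' @param score_matrices Named list (>= 2 methods) of cells x gene-sets score
#'   matrices sharing the cell set (columns of `norm`).
#' @param candidate_genes Genes to correlate (default: all rows of `norm`).
#' @param rho_min,alpha Per-method pass rule: `rho >= rho_min` and
#'   `p < alpha` (defaults 0.2 and 0.05).
#' @return data.frame: `gene`, `geneset`, `method`, `rho`, `p_spearman`,
#'   `passes_method`.
#' @export
hub_correlations <- function(norm, score_matrices,
                             candidate_genes = rownames(norm),
                             rho_min = 0.2, alpha = 0.05) {
  if (length(score_matrices) < 2)
    stop("need score matrices from at least 2 methods", call. = FALSE)
  cells <- colnames(norm)
  for (meth in names(score_matrices)) {
    if (!identical(rownames(score_matrices[[meth]]), cells))
      stop("cell-set mismatch between scores (", meth,
           ") and expression matrix", call. = FALSE)
  }
  rows <- list(); i <- 0L
  for (meth in names(score_matrices)) {
    sm <- score_matrices[[meth]]
    for (gs in colnames(sm)) {
      for (g in candidate_genes) {
        sc <- spearman_corr(norm[g, ], sm[, gs])
        i <- i + 1L
        rows[[i]] <- data.frame(gene = g, geneset = gs, method = meth,
                                rho = sc$rho, p_spearman = sc$p_value,
                                stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$passes_method <- out$rho >= rho_min & out$p_spearman < alpha
  rownames(out) <- NULL
  out
}

#' Hub-gene filter
#'
#' A gene is a hub iff, for some gene set, the per-method rule
#' (`rho >= rho_min` and Spearman p < `alpha`) holds in at least
#' `min_methods` distinct methods, and the gene is a significant DEG.
#' Invariant to record and method ordering.
#'
#' @param hub_records Output of [hub_correlations()].
#' @param significant_deg_set Character vector of significant DEG ids.
#' @param min_methods Methods required (default 2).
#' @param rho_min,alpha Per-method rule, re-applied if `passes_method` absent.
#' @return List: `hubs` (sorted gene ids), `records` (with `is_hub`).
#' @export
filter_hub_genes <- function(hub_records, significant_deg_set,
                             min_methods = 2L, rho_min = 0.2, alpha = 0.05) {
  rec <- hub_records
  if (is.null(rec$passes_method))
    rec$passes_method <- rec$rho >= rho_min & rec$p_spearman < alpha
  pass <- rec[rec$passes_method, , drop = FALSE]
  key <- paste(pass$gene, pass$geneset, sep = "\r")
  n_meth <- tapply(pass$method, key, function(m) length(unique(m)))
  hub_keys <- names(n_meth)[n_meth >= min_methods]
  hub_genes <- unique(sub("\r.*$", "", hub_keys))
  hubs <- sort(intersect(hub_genes, significant_deg_set))
  rec$is_hub <- rec$gene %in% hubs
  list(hubs = hubs, records = rec)
}

# MTX + sidecar IO -------------------------------------------------------------

#' Write / read a count matrix as MatrixMarket with TSV sidecars
#'
#' Writes `matrix.mtx`, `genes.tsv`, `cells.tsv` and optionally
#' `cell_meta.csv` under `dir`.
#'
#' @param counts Genes x cells count matrix.
#' @param dir Output directory (created if needed).
#' @param cell_meta Optional per-cell metadata data.frame.
#' @return `read_counts_mtx` returns a list with `counts` (dgCMatrix) and
#'   `cell_meta` (or NULL).
#' @export
write_counts_mtx <- function(counts, dir, cell_meta = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- methods::as(methods::as(Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                                "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "cells.tsv"))
  if (!is.null(cell_meta))
    utils::write.csv(cell_meta, file.path(dir, "cell_meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  counts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  counts <- methods::as(counts, "CsparseMatrix")
  dimnames(counts) <- list(readLines(file.path(dir, "genes.tsv")),
                           readLines(file.path(dir, "cells.tsv")))
  meta_path <- file.path(dir, "cell_meta.csv")
  meta <- if (file.exists(meta_path))
    utils::read.csv(meta_path, stringsAsFactors = FALSE) else NULL
  list(counts = counts, cell_meta = meta)
}
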