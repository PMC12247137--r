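# Two-sided Wilcoxon rank-sum p-value.
# Exact enumeration of the rank-sum null (over all C(n, n_a) group
# assignments of the observed mid-ranks) when both groups have <= `exact_max`
# observations; tie-corrected normal approximation (no continuity correction)
# otherwise. Mid-ranks make the exact path valid under ties.
rank_sum_p <- function(a, b, exact_max = 8) {
  n_a <- length(a)
  n_b <- length(b)
  n <- n_a + n_b
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n_a)])
  mu <- n_a * (n + 1) / 2

  if (n_a <= exact_max && n_b <= exact_max) {
    idx <- combn(n, n_a)
    ws <- colSums(matrix(r[idx], nrow = n_a))
    p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
    return(min(1, p))
  }
  tie_tab <- table(r)
  sigma2 <- n_a * n_b / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - mu) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test on depth-normalized expression
#' (counts per 10k), with the conventional single-cell marker filters: a gene
#' "passes" when `p < p_threshold`, `log2 fold change > logfc_threshold`, and
#' the larger of the two detection fractions exceeds `min_pct`. The fold
#' change is `log2((mean_A + eps) / (mean_B + eps))` on linear normalized
#' expression with a small pseudocount so zero-mean genes are well defined.
#' Benjamini-Hochberg q-values are reported as an extra column; the pass flag
#' deliberately uses raw p-values.
#'
#' @param x A [umi_counts()] object (typically post-[qc_filter()]).
#' @param cells_a,cells_b Character vectors of cell barcodes (non-empty,
#'   disjoint).
#' @param p_threshold,logfc_threshold,min_pct Pass-filter thresholds
#'   (defaults 0.05, 0.25, 0.1).
#' @param two_sided_lfc If TRUE the fold-change filter uses `|log2FC|`
#'   (absolute-value mode); default FALSE keeps the positive-only reading.
#' @param eps Pseudocount for the fold-change ratio.
#' @param exact_max Largest group size for exact enumeration of the rank-sum
#'   null (default 8).
#' @return A `deg_tbl` tibble: `gene`, `log2fc`, `p`, `q`, `pct_1`, `pct_2`,
#'   `passes`, sorted by `p`. Group sizes are attached as attributes.
#' @examples
#' sim <- simulate_umi_counts(transcriptome_sim_config(n_cells_per_sample = 60,
#'                                                     n_genes = 200))
#' ct <- sim$counts$cells
#' de <- wilcoxon_de(sim$counts,
#'                   ct$cell[ct$condition == "CCI"],
#'                   ct$cell[ct$condition == "control"])
#' head(de)
#' @export
wilcoxon_de <- function(x, cells_a, cells_b,
                        p_threshold = 0.05,
                        logfc_threshold = 0.25,
                        min_pct = 0.1,
                        two_sided_lfc = FALSE,
                        eps = 1e-9,
                        exact_max = 8) {
  stopifnot(inherits(x, "umi_counts"))
  if (length(cells_a) == 0 || length(cells_b) == 0) {
    data_error("both cell groups must be non-empty.")
  }
  if (length(intersect(cells_a, cells_b))) data_error("cell groups overlap.")
  missing <- setdiff(c(cells_a, cells_b), colnames(x$counts))
  if (length(missing)) data_error("unknown cells: %s", paste(utils::head(missing, 5), collapse = ", "))

  norm <- normalize_cp10k(x)
  ma <- as.matrix(norm[, cells_a, drop = FALSE])
  mb <- as.matrix(norm[, cells_b, drop = FALSE])
  raw_a <- x$counts[, cells_a, drop = FALSE]
  raw_b <- x$counts[, cells_b, drop = FALSE]

  mean_a <- rowMeans(ma)
  mean_b <- rowMeans(mb)
  log2fc <- log2((mean_a + eps) / (mean_b + eps))
  pct_1 <- Matrix::rowSums(raw_a > 0) / length(cells_a)
  pct_2 <- Matrix::rowSums(raw_b > 0) / length(cells_b)

  p <- vapply(seq_len(nrow(ma)), function(i) {
    rank_sum_p(ma[i, ], mb[i, ], exact_max = exact_max)
  }, numeric(1))

  lfc_stat <- if (two_sided_lfc) abs(log2fc) else log2fc
  out <- tibble(
    gene = rownames(norm),
    log2fc = unname(log2fc),
    p = p,
    q = p.adjust(p, method = "BH"),
    pct_1 = unname(pct_1),
    pct_2 = unname(pct_2),
    passes = p < p_threshold & lfc_stat > logfc_threshold &
      pmax(pct_1, pct_2) > min_pct
  ) |>
    dplyr::arrange(.data$p, dplyr::desc(abs(.data$log2fc)))
  structure(out, n_a = length(cells_a), n_b = length(cells_b),
            thresholds = c(p = p_threshold, log2fc = logfc_threshold,
                           min_pct = min_pct),
            class = c("deg_tbl", class(out)))
}

#' Positive cluster markers (each cluster vs all remaining cells)
#'
#' For every cluster, runs [wilcoxon_de()] of the cluster against all other
#' cells and retains only positively enriched genes
#' (`log2fc > logfc_threshold`, default 0.1) — the "only positive" marker
#' convention.
#'
#' @param x A [umi_counts()] object.
#' @param labels Cluster label per cell: either a vector aligned with
#'   `x$cells`, or the name of a column in `x$cells`.
#' @param logfc_threshold Positive log2 fold-change cutoff (default 0.1).
#' @param ... Passed to [wilcoxon_de()].
#' @return Tibble of per-cluster marker rows with a `cluster` column.
#' @export
positive_markers <- function(x, labels, logfc_threshold = 0.1, ...) {
  stopifnot(inherits(x, "umi_counts"))
  if (length(labels) == 1 && labels %in% names(x$cells)) {
    labels <- x$cells[[labels]]
  }
  if (length(labels) != ncol(x$counts)) {
    config_error("`labels` must supply one cluster label per cell.")
  }
  clusters <- unique(labels)
  if (length(clusters) < 2) config_error("need >= 2 clusters.")
  purrr::map_dfr(clusters, function(cl) {
    in_cl <- x$cells$cell[labels == cl]
    rest <- x$cells$cell[labels != cl]
    if (length(in_cl) == 1) {
      warn(sprintf("cluster '%s' has a single cell; approximate test only.", cl))
    }
    wilcoxon_de(x, in_cl, rest, logfc_threshold = logfc_threshold, ...) |>
      dplyr::filter(.data$log2fc > logfc_threshold) |>
      dplyr::mutate(cluster = as.character(cl), .before = 1)
  })
}

#' Condition differential expression within neuron classes
#'
#' Runs [wilcoxon_de()] between two conditions (e.g., CCI vs control or AEW
#' vs control) separately within each neuron class; classes missing either
#' condition are skipped with a warning. The resulting per-class gene lists
#' are the inputs a downstream enrichment analysis would consume.
#'
#' @param x A [umi_counts()] whose cell table has a `condition` column.
#' @param class_labels Class per cell: vector aligned with `x$cells` or the
#'   name of a column in `x$cells`.
#' @param conditions Length-2 character vector `c(test, reference)`.
#' @param ... Passed to [wilcoxon_de()].
#' @return Tibble of `deg_tbl` rows with `class`, `condition` columns.
#' @export
condition_deg <- function(x, class_labels,
                          conditions = c("CCI", "control"), ...) {
  stopifnot(inherits(x, "umi_counts"))
  if (!"condition" %in% names(x$cells)) data_error("cells lack a `condition` column.")
  if (length(conditions) != 2) config_error("`conditions` must have length 2.")
  if (length(class_labels) == 1 && class_labels %in% names(x$cells)) {
    class_labels <- x$cells[[class_labels]]
  }
  if (length(class_labels) != ncol(x$counts)) {
    config_error("`class_labels` must supply one class per cell.")
  }
  purrr::map_dfr(unique(class_labels), function(cl) {
    in_cl <- class_labels == cl
    cells_a <- x$cells$cell[in_cl & x$cells$condition == conditions[1]]
    cells_b <- x$cells$cell[in_cl & x$cells$condition == conditions[2]]
    if (length(cells_a) == 0 || length(cells_b) == 0) {
      warn(sprintf("class '%s' lacks cells in one condition; skipped.", cl))
      return(tibble())
    }
    wilcoxon_de(x, cells_a, cells_b, ...) |>
      dplyr::mutate(class = as.character(cl),
                    condition = paste(conditions, collapse = "_vs_"),
                    .before = 1)
  })
}
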