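#' Quality-control filtering of cells
#'
#' Retains cells with more than `min_genes` detected genes (strict) and a
#' mitochondrial UMI rate below `max_mito_rate` (strict), then removes
#' mitochondrial gene rows from the retained matrix. Cells at exactly the
#' boundary (500 genes, 20 percent mito) are dropped. If no gene carries a
#' mito flag, a warning is issued and every mito rate is treated as 0.
#'
#' @param x A [umi_counts()] object.
#' @param min_genes Minimum detected genes, exclusive (default 500).
#' @param max_mito_rate Maximum mitochondrial UMI fraction, exclusive
#'   (default 0.20).
#' @return A list:
#'   \describe{
#'     \item{counts}{Filtered [umi_counts()] (cells retained, mito rows
#'       removed).}
#'     \item{report}{Per-cell tibble: `cell`, `n_genes`, `mito_rate`,
#'       `retained`; totals before/after in `attr(report, "totals")`.}
#'   }
#' @examples
#' sim <- simulate_umi_counts(transcriptome_sim_config(n_cells_per_sample = 50))
#' qc <- qc_filter(sim$counts)
#' attr(qc$report, "totals")
#' @export
qc_filter <- function(x, min_genes = 500, max_mito_rate = 0.20) {
  stopifnot(inherits(x, "umi_counts"))
  m <- x$counts
  n_genes_per_cell <- Matrix::colSums(m > 0)
  total <- Matrix::colSums(m)
  if (!any(x$genes$mito)) {
    warn("no mitochondrial annotation found; mito rates treated as 0.")
    mito_rate <- rep(0, ncol(m))
  } else {
    mito_umi <- Matrix::colSums(m[x$genes$mito, , drop = FALSE])
    mito_rate <- ifelse(total > 0, mito_umi / total, 0)
  }
  retained <- n_genes_per_cell > min_genes & mito_rate < max_mito_rate
  report <- tibble(cell = colnames(m),
                   n_genes = as.integer(n_genes_per_cell),
                   mito_rate = unname(mito_rate),
                   retained = unname(retained))
  attr(report, "totals") <- c(before = ncol(m), after = sum(retained))

  keep_genes <- !x$genes$mito
  filtered <- umi_counts(m[keep_genes, retained, drop = FALSE],
                         genes = x$genes[keep_genes, ],
                         cells = x$cells[retained, ])
  list(counts = filtered, report = report)
}

# threshold machinery: the "maximum" level of a gene is the mean of its three
# largest per-cell values (zero-padded below 3 cells); the threshold is
# `threshold_frac` of that, and a cell is positive strictly above it
top3_threshold <- function(values, threshold_frac = 0.05) {
  padded <- c(values, numeric(max(0, 3 - length(values))))
  max_level <- mean(sort(padded, decreasing = TRUE)[1:3])
  c(max_level = max_level, threshold = threshold_frac * max_level)
}

#' Positivity of one gene across cells
#'
#' Implements the fraction-of-positive-cells thresholding rule: the gene's
#' "maximum" level is the average of its top three per-cell expression values
#' (zeros included when fewer than three cells are nonzero), the positivity
#' threshold is 5 percent of that maximum, and a cell is positive when its
#' expression is strictly greater than the threshold. An all-zero gene
#' therefore has threshold 0 and fraction 0.
#'
#' @param values Numeric expression values across at least 3 cells (any
#'   per-gene scale; the rule is invariant to rescaling one gene).
#' @param threshold_frac Fraction of the maximum level used as threshold
#'   (default 0.05).
#' @return One-row tibble: `max_level`, `threshold`, `n_positive`, `n_cells`,
#'   `fraction`.
#' @examples
#' gene_positivity(c(10, 8, 6, 0.2, 0)) # threshold 0.4, fraction 0.6
#' @export
gene_positivity <- function(values, threshold_frac = 0.05) {
  if (length(values) < 3) data_error("gene positivity needs >= 3 cells.")
  if (any(values < 0)) data_error("expression values must be nonnegative.")
  check_number(threshold_frac, "threshold_frac", min = 0, strict = TRUE)
  th <- top3_threshold(values, threshold_frac)
  n_pos <- sum(values > th[["threshold"]])
  tibble(max_level = th[["max_level"]], threshold = th[["threshold"]],
         n_positive = n_pos, n_cells = length(values),
         fraction = n_pos / length(values))
}

# expression matrix on the requested scale for a set of genes (genes x cells)
expression_for <- function(x, genes = NULL, scale = c("cp10k", "counts")) {
  scale <- match.arg(scale)
  genes <- genes %||% x$genes$gene
  missing <- setdiff(genes, x$genes$gene)
  if (length(missing)) {
    config_error("marker genes missing from the matrix: %s",
                 paste(missing, collapse = ", "))
  }
  m <- if (scale == "cp10k") normalize_cp10k(x) else x$counts
  m[genes, , drop = FALSE]
}

#' Positivity table for a set of genes
#'
#' Applies [gene_positivity()] to each requested gene on depth-normalized
#' expression (counts per 10k by default; the rule itself is scale-invariant
#' per gene, so the normalization only matters through between-cell depth
#' differences).
#'
#' @param x A [umi_counts()] object.
#' @param genes Genes to score; default all.
#' @param threshold_frac Threshold as a fraction of the top-3 maximum.
#' @param scale `"cp10k"` (default) or `"counts"`.
#' @return Tibble with one row per gene: `gene`, `max_level`, `threshold`,
#'   `n_positive`, `n_cells`, `fraction`.
#' @export
positivity <- function(x, genes = NULL, threshold_frac = 0.05,
                       scale = c("cp10k", "counts")) {
  stopifnot(inherits(x, "umi_counts"))
  em <- expression_for(x, genes, scale)
  if (ncol(em) < 3) data_error("gene positivity needs >= 3 cells.")
  purrr::map_dfr(rownames(em), function(g) {
    dplyr::bind_cols(tibble(gene = g), gene_positivity(em[g, ], threshold_frac))
  })
}

#' Per-cell positivity calls for a set of genes
#'
#' @inheritParams positivity
#' @return Cells-by-genes logical matrix of positivity calls (cell barcodes as
#'   row names). Works for any number of cells; below 3 cells the top-3 mean
#'   is computed over the values padded with zeros.
#' @export
positivity_calls <- function(x, genes, threshold_frac = 0.05,
                             scale = c("cp10k", "counts")) {
  stopifnot(inherits(x, "umi_counts"))
  em <- expression_for(x, genes, scale)
  calls <- vapply(rownames(em), function(g) {
    th <- top3_threshold(em[g, ], threshold_frac)
    as.vector(em[g, ] > th[["threshold"]])
  }, logical(ncol(em)))
  calls <- matrix(calls, ncol = nrow(em),
                  dimnames = list(colnames(em), rownames(em)))
  calls
}

#' Classify neurons as itch, pain, or dual from marker positivity
#'
#' A cell positive for an itch marker (Mrgpra3 or Nmb) but no pain marker is
#' itch-related; positive for a pain marker (Tac1 or Calca) but no itch marker
#' is pain-related; positive for both kinds is dual (itch/pain); positive for
#' neither is unclassified and excluded from the class denominator.
#'
#' @param x A [umi_counts()] object containing all four markers.
#' @param itch_markers,pain_markers Marker gene names.
#' @param threshold_frac,scale Passed to [positivity_calls()].
#' @return Tibble with one row per cell: `cell`, per-marker positivity flags,
#'   and `class` (`itch`/`pain`/`itch_pain`/`unclassified`). Summarize with
#'   [class_summary()].
#' @examples
#' fx <- make_fixture_classes(c(itch_only = 4, pain_only = 2, both = 3))
#' class_summary(classify_neurons(fx))
#' @export
classify_neurons <- function(x,
                             itch_markers = c("Mrgpra3", "Nmb"),
                             pain_markers = c("Tac1", "Calca"),
                             threshold_frac = 0.05,
                             scale = c("cp10k", "counts")) {
  stopifnot(inherits(x, "umi_counts"))
  markers <- c(itch_markers, pain_markers)
  if (ncol(x$counts) == 0) {
    out <- tibble(cell = character(), class = character())
    return(out)
  }
  calls <- positivity_calls(x, markers, threshold_frac, scale)
  itch_pos <- rowSums(calls[, itch_markers, drop = FALSE]) > 0
  pain_pos <- rowSums(calls[, pain_markers, drop = FALSE]) > 0
  class <- dplyr::case_when(
    itch_pos & pain_pos ~ "itch_pain",
    itch_pos ~ "itch",
    pain_pos ~ "pain",
    .default = "unclassified"
  )
  dplyr::bind_cols(tibble(cell = rownames(calls)),
                   as_tibble(calls),
                   tibble(class = class))
}

#' Class counts and percentages over classified neurons
#'
#' Counts per class with percentages over the classified set (cells positive
#' for at least one marker), rounded half-away-from-zero to one decimal, as in
#' printed pie-chart proportions (e.g., 43.3 percent = 420/971).
#'
#' @param assignment Output of [classify_neurons()].
#' @return Tibble: `class`, `n`, `pct` for `itch`, `pain`, `itch_pain` (pct
#'   over classified cells) plus an `unclassified` row with `pct = NA`;
#'   `attr(., "n_classified")` holds the denominator.
#' @export
class_summary <- function(assignment) {
  lv <- c("itch", "pain", "itch_pain", "unclassified")
  counts <- table(factor(assignment$class, levels = lv))
  n_classified <- sum(counts[c("itch", "pain", "itch_pain")])
  out <- tibble(
    class = lv,
    n = as.integer(counts),
    pct = ifelse(lv == "unclassified", NA_real_,
                 if (n_classified > 0) {
                   round_half_up(100 * as.integer(counts) / n_classified, 1)
                 } else {
                   NA_real_
                 })
  )
  attr(out, "n_classified") <- n_classified
  out
}

#' Venn counts over marker-positivity combinations
#'
#' Counts cells in each of the `2^k - 1` non-empty positivity combinations of
#' `k` markers (exact combinations, so the counts are disjoint and sum to the
#' number of cells positive for at least one marker).
#'
#' @param x A [umi_counts()] object.
#' @param markers Marker genes (k >= 2).
#' @param threshold_frac,scale Passed to [positivity_calls()].
#' @return Tibble with one logical column per marker, a `combination` label
#'   (e.g. `"Nmb+Tac1"`), and `n`.
#' @export
marker_venn <- function(x, markers = c("Nmb", "Mrgpra3", "Tac1", "Calca"),
                        threshold_frac = 0.05,
                        scale = c("cp10k", "counts")) {
  if (length(markers) < 2) config_error("`markers` must contain >= 2 genes.")
  calls <- positivity_calls(x, markers, threshold_frac, scale)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(markers)))
  names(combos) <- markers
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  n <- vapply(seq_len(nrow(combos)), function(i) {
    want <- unlist(combos[i, ])
    sum(apply(calls, 1, function(row) all(row == want)))
  }, integer(1))
  as_tibble(combos) |>
    dplyr::mutate(
      combination = vapply(seq_len(nrow(combos)), function(i) {
        paste(markers[unlist(combos[i, ])], collapse = "+")
      }, character(1)),
      n = n
    ) |>
    dplyr::arrange(dplyr::desc(.data$n))
}
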