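#' Configure a synthetic DRG single-cell count matrix
#'
#' Builds the configuration for [simulate_umi_counts()]: negative-binomial
#' UMI counts for a panel of marker genes (itch: Mrgpra3, Nmb; pain: Tac1,
#' Calca), mitochondrial genes (`mt-` prefix) and background genes, over cells
#' with planted neuron classes and experimental conditions (control, CCI
#' nerve-injury pain model, AEW dry-skin itch model). Marker genes are highly
#' expressed only in cells of the matching planted class; condition-responsive
#' genes carry multiplicative log2 effects in the stated condition (optionally
#' restricted to one class). Per-cell library sizes vary lognormally and a
#' planted fraction of low-quality cells (shallow, mito-heavy) gives the QC
#' filter something to remove.
#'
#' The default class mix follows the control-group composition implied by
#' 971 marker-positive neurons out of 1242 (itch-only 0.338, pain-only 0.117,
#' dual 0.326, none 0.219).
#'
#' @param samples Tibble with columns `sample` and `condition`
#'   (`control`/`CCI`/`AEW`). Default one sample per condition.
#' @param n_cells_per_sample Cells simulated per sample.
#' @param n_genes Total genes including markers and mito genes.
#' @param itch_markers,pain_markers Marker gene names per class.
#' @param mito_genes Mitochondrial gene names (must carry the `mt-` prefix).
#' @param class_fractions Named fractions over
#'   `itch_only`/`pain_only`/`both`/`none`, summing to 1.
#' @param marker_on_mean,marker_off_mean NB mean of a marker gene in cells of
#'   its class vs other cells.
#' @param marker_dispersion NB size for marker genes (markers are modeled as
#'   strongly expressed with tighter dispersion than background, reflecting
#'   the on/off bimodality of subtype markers).
#' @param mito_mean NB mean per mitochondrial gene in healthy cells.
#' @param background_meanlog,background_sdlog Lognormal parameters for
#'   background gene base means.
#' @param dispersion NB size parameter (shared).
#' @param lib_size_sdlog Lognormal sd of the per-cell library-size factor.
#' @param dropout_rate Probability that any individual UMI is lost (binomial
#'   thinning on top of the NB draw).
#' @param low_quality_frac Fraction of cells planted as low-quality (library
#'   factor `low_quality_scale`, mito means times `low_quality_mito_boost`).
#' @param low_quality_scale,low_quality_mito_boost Degradation parameters.
#' @param condition_effects Tibble of planted differential expression:
#'   columns `gene`, `condition`, `log2fc`, and optional `class` (`NA` =
#'   all classes). Default plants 25 genes up (log2fc 1.5) in CCI and 25 in
#'   AEW across all classes.
#' @param seed Integer seed.
#' @return A `transcriptome_sim_config` object.
#' @seealso [simulate_umi_counts()]
#' @export
transcriptome_sim_config <- function(samples = NULL,
                                     n_cells_per_sample = 1000,
                                     n_genes = 2000,
                                     itch_markers = c("Mrgpra3", "Nmb"),
                                     pain_markers = c("Tac1", "Calca"),
                                     mito_genes = paste0("mt-", c(
                                       "Nd1", "Nd2", "Co1", "Co2", "Co3",
                                       "Atp6", "Cytb", "Nd4", "Nd5", "Rnr1")),
                                     class_fractions = c(itch_only = 0.338,
                                                         pain_only = 0.117,
                                                         both = 0.326,
                                                         none = 0.219),
                                     marker_on_mean = 50,
                                     marker_off_mean = 0.02,
                                     marker_dispersion = 8,
                                     mito_mean = 5,
                                     background_meanlog = log(0.5),
                                     background_sdlog = 1,
                                     dispersion = 2,
                                     lib_size_sdlog = 0.3,
                                     dropout_rate = 0.1,
                                     low_quality_frac = 0.05,
                                     low_quality_scale = 0.1,
                                     low_quality_mito_boost = 10,
                                     condition_effects = NULL,
                                     seed = 1L) {
  if (is.null(samples)) {
    samples <- tibble(sample = c("ctrl1", "cci1", "aew1"),
                      condition = c("control", "CCI", "AEW"))
  }
  samples <- as_tibble(samples)
  if (!all(c("sample", "condition") %in% names(samples))) {
    config_error("`samples` must have columns sample, condition.")
  }
  if (!all(samples$condition %in% c("control", "CCI", "AEW"))) {
    config_error("conditions must be control, CCI or AEW.")
  }
  check_number(n_cells_per_sample, "n_cells_per_sample", min = 1)
  check_number(n_genes, "n_genes", min = 10)
  check_number(dispersion, "dispersion", min = 0, strict = TRUE)
  check_number(marker_on_mean, "marker_on_mean", min = 0)
  check_number(dropout_rate, "dropout_rate", min = 0)
  if (dropout_rate >= 1) config_error("`dropout_rate` must be < 1.")

  cls <- c("itch_only", "pain_only", "both", "none")
  if (!setequal(names(class_fractions), cls)) {
    config_error("`class_fractions` must be named %s.", paste(cls, collapse = ", "))
  }
  class_fractions <- class_fractions[cls]
  if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-9) {
    config_error("`class_fractions` must be nonnegative and sum to 1 (within 1e-9).")
  }
  if (!all(grepl("^mt-", mito_genes))) {
    config_error("mito genes must carry the 'mt-' prefix.")
  }
  n_named <- length(itch_markers) + length(pain_markers) + length(mito_genes)
  if (n_genes <= n_named) {
    config_error("`n_genes` must exceed the %d named marker/mito genes.", n_named)
  }

  if (is.null(condition_effects)) {
    n_bg <- n_genes - n_named
    bg <- sprintf("g%04d", seq_len(n_bg))
    condition_effects <- tibble(
      gene = c(bg[seq_len(min(25, n_bg))], bg[min(25, n_bg) + seq_len(min(25, n_bg))]),
      condition = rep(c("CCI", "AEW"), each = min(25, n_bg)),
      log2fc = 1.5,
      class = NA_character_
    )
  }
  condition_effects <- as_tibble(condition_effects)
  if (nrow(condition_effects) &&
      !all(c("gene", "condition", "log2fc") %in% names(condition_effects))) {
    config_error("`condition_effects` must have columns gene, condition, log2fc.")
  }
  if (!"class" %in% names(condition_effects)) condition_effects$class <- NA_character_

  structure(
    list(samples = samples, n_cells_per_sample = as.integer(n_cells_per_sample),
         n_genes = as.integer(n_genes),
         itch_markers = itch_markers, pain_markers = pain_markers,
         mito_genes = mito_genes, class_fractions = class_fractions,
         marker_on_mean = marker_on_mean, marker_off_mean = marker_off_mean,
         marker_dispersion = marker_dispersion, mito_mean = mito_mean,
         background_meanlog = background_meanlog,
         background_sdlog = background_sdlog,
         dispersion = dispersion, lib_size_sdlog = lib_size_sdlog,
         dropout_rate = dropout_rate,
         low_quality_frac = low_quality_frac,
         low_quality_scale = low_quality_scale,
         low_quality_mito_boost = low_quality_mito_boost,
         condition_effects = condition_effects, seed = as.integer(seed)),
    class = "transcriptome_sim_config"
  )
}

#' Simulate a UMI count matrix with planted classes and condition effects
#'
#' Draws counts gene-wise from a negative binomial whose mean depends on the
#' gene's role (marker / mito / background), the cell's planted class and
#' condition, a lognormal per-cell library factor, and planted condition
#' effects, then thins each count binomially (dropout). Identical seed gives
#' an identical sparse matrix.
#'
#' @param config A [transcriptome_sim_config()].
#' @return A list with:
#'   \describe{
#'     \item{counts}{A [umi_counts()] whose cell table carries `sample`,
#'       `condition`, the planted `true_class` and `low_quality` flag.}
#'     \item{truth}{List: the cell tibble and the planted `condition_effects`
#'       table.}
#'   }
#' @export
simulate_umi_counts <- function(config) {
  stopifnot(inherits(config, "transcriptome_sim_config"))
  markers <- c(config$itch_markers, config$pain_markers)
  n_bg <- config$n_genes - length(markers) - length(config$mito_genes)
  bg_genes <- sprintf("g%04d", seq_len(n_bg))
  genes <- c(markers, config$mito_genes, bg_genes)
  role <- c(rep("itch_marker", length(config$itch_markers)),
            rep("pain_marker", length(config$pain_markers)),
            rep("mito", length(config$mito_genes)),
            rep("background", n_bg))

  bad <- setdiff(config$condition_effects$gene, genes)
  if (length(bad)) {
    config_error("condition-effect genes absent from the gene list: %s",
                 paste(bad, collapse = ", "))
  }

  with_local_seed(config$seed, {
    # cells: classes by largest remainder within each sample, then shuffled
    cells <- purrr::pmap_dfr(config$samples, function(sample, condition) {
      n <- config$n_cells_per_sample
      counts_per_class <- largest_remainder(config$class_fractions * n, n)
      class <- sample(rep(names(counts_per_class), times = counts_per_class))
      tibble(cell = sprintf("%s_c%04d", sample, seq_len(n)),
             sample = sample, condition = condition, true_class = class)
    })
    n_cells <- nrow(cells)
    cells$low_quality <- stats::runif(n_cells) < config$low_quality_frac

    base_mean <- numeric(length(genes))
    base_mean[role == "mito"] <- config$mito_mean
    base_mean[role == "background"] <-
      rlnorm(n_bg, config$background_meanlog, config$background_sdlog)

    lib <- rlnorm(n_cells, 0, config$lib_size_sdlog)
    lib[cells$low_quality] <- lib[cells$low_quality] * config$low_quality_scale

    mu <- outer(base_mean, lib)
    rownames(mu) <- genes

    itch_on <- cells$true_class %in% c("itch_only", "both")
    pain_on <- cells$true_class %in% c("pain_only", "both")
    mu[config$itch_markers, ] <- outer(
      rep(1, length(config$itch_markers)),
      ifelse(itch_on, config$marker_on_mean, config$marker_off_mean) * lib)
    mu[config$pain_markers, ] <- outer(
      rep(1, length(config$pain_markers)),
      ifelse(pain_on, config$marker_on_mean, config$marker_off_mean) * lib)
    mu[config$mito_genes, cells$low_quality] <-
      mu[config$mito_genes, cells$low_quality, drop = FALSE] * config$low_quality_mito_boost

    ce <- config$condition_effects
    for (i in seq_len(nrow(ce))) {
      hit <- cells$condition == ce$condition[i]
      if (!is.na(ce$class[i])) hit <- hit & cells$true_class == ce$class[i]
      mu[ce$gene[i], hit] <- mu[ce$gene[i], hit] * 2^ce$log2fc[i]
    }

    size <- matrix(config$dispersion, nrow = nrow(mu), ncol = ncol(mu))
    size[role %in% c("itch_marker", "pain_marker"), ] <- config$marker_dispersion
    counts <- matrix(
      rnbinom(length(mu), size = size, mu = mu),
      nrow = nrow(mu), dimnames = list(genes, cells$cell)
    )
    if (config$dropout_rate > 0) {
      pos <- counts > 0
      counts[pos] <- rbinom(sum(pos), counts[pos], 1 - config$dropout_rate)
    }

    x <- umi_counts(counts,
                    genes = tibble(gene = genes, mito = role == "mito", role = role),
                    cells = cells)
    list(counts = x,
         truth = list(cells = cells, condition_effects = ce))
  })
}

#' Build a deterministic positivity fixture with exact class counts
#'
#' Constructs a minimal count matrix in which exactly the requested numbers of
#' cells are positive for each marker combination under the top-3/5-percent
#' thresholding rule: itch-only cells express `Nmb`, pain-only cells express
#' `Tac1`, dual cells express both, and "none" cells express only a
#' housekeeping gene. Used to reproduce printed class totals (e.g., 420 itch /
#' 146 pain / 405 dual over 971 classified neurons).
#'
#' @param counts_per_class Named nonnegative counts over `itch_only`,
#'   `pain_only`, `both`, `none` (missing names default to 0).
#' @param itch_markers,pain_markers Marker names (first of each is the one
#'   expressed).
#' @return A [umi_counts()] with all four markers present (rows of zeros for
#'   the unexpressed ones) and a `true_class` cell column.
#' @examples
#' fx <- make_fixture_classes(c(itch_only = 420, pain_only = 146, both = 405))
#' dim(fx)
#' @export
make_fixture_classes <- function(counts_per_class,
                                 itch_markers = c("Mrgpra3", "Nmb"),
                                 pain_markers = c("Tac1", "Calca")) {
  cls <- c("itch_only", "pain_only", "both", "none")
  full <- setNames(rep(0L, 4), cls)
  if (length(counts_per_class)) {
    if (is.null(names(counts_per_class)) ||
        !all(names(counts_per_class) %in% cls)) {
      config_error("`counts_per_class` names must be among %s.", paste(cls, collapse = ", "))
    }
    if (any(counts_per_class < 0)) config_error("requested counts must be >= 0.")
    full[names(counts_per_class)] <- as.integer(counts_per_class)
  }
  n <- sum(full)
  genes <- c(itch_markers, pain_markers, "Actb")
  classes <- rep(cls, times = full)
  m <- matrix(0, nrow = length(genes), ncol = n,
              dimnames = list(genes, if (n) sprintf("fx_c%04d", seq_len(n)) else character()))
  if (n) {
    m[itch_markers[2], classes %in% c("itch_only", "both")] <- 100
    m[pain_markers[1], classes %in% c("pain_only", "both")] <- 100
    m["Actb", ] <- 10
  }
  umi_counts(m,
             genes = tibble(gene = genes, mito = FALSE),
             cells = tibble(cell = colnames(m) %||% character(0),
                            true_class = classes))
}
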