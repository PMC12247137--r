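write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

pipeline_manifest <- function(stage, inputs, parameters, outputs) {
  list(
    stage = stage,
    package = "drgmodal",
    version = as.character(utils::packageVersion("drgmodal")),
    inputs = inputs,
    parameters = parameters,
    outputs = outputs
  )
}

#' Run the calcium-imaging arm end to end
#'
#' Delta-F/F0 computation, activation calling, stimulus-overlap summary and a
#' peak-amplitude comparison (dual-responsive vs first-stimulus-only neurons),
#' written as CSV/JSON into an output directory together with a reproducible
#' run manifest (inputs, thresholds, package version; no timestamps, so
#' reruns are byte-identical).
#'
#' @param recording A [fluor_recording()], or the path of a trace CSV (then
#'   `epochs_yaml` is required).
#' @param out_dir Output directory (created).
#' @param epochs_yaml Epoch sidecar path when `recording` is a CSV path.
#' @param baseline_s Baseline window (s) for F0.
#' @param threshold_pct Activation threshold (percent delta-F/F0).
#' @param stim_a,stim_b Stimuli for the overlap summary; default the first two
#'   epoch labels.
#' @param write_dff Also write the full delta-F/F0 long table (can be large).
#' @param ... Passed to [call_responses()].
#' @return Invisibly, a list with `dff`, `calls`, `overlap`, `amplitude`
#'   (possibly NULL) and `manifest`.
#' @export
run_calcium_pipeline <- function(recording, out_dir,
                                 epochs_yaml = NULL,
                                 baseline_s = 60,
                                 threshold_pct = 20,
                                 stim_a = NULL, stim_b = NULL,
                                 write_dff = FALSE, ...) {
  input_desc <- if (is.character(recording)) {
    if (is.null(epochs_yaml)) data_error("`epochs_yaml` required with a CSV input.")
    paths <- c(csv = recording, yaml = epochs_yaml)
    recording <- read_recording(recording, epochs_yaml)
    as.list(paths)
  } else {
    list(recording = "<in-memory fluor_recording>")
  }
  stopifnot(inherits(recording, "fluor_recording"))
  if (nrow(recording$epochs) == 0) data_error("recording has an empty `epochs` section.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  labels <- recording$epochs$label
  stim_a <- stim_a %||% labels[1]
  stim_b <- stim_b %||% labels[2]

  dff <- compute_dff(recording, baseline_s = baseline_s)
  calls <- call_responses(dff, threshold_pct = threshold_pct, ...)
  overlap <- summarize_overlap(calls, stim_a, stim_b)

  # amplitude comparison: dual responders vs stim_a-only responders, on their
  # peak responses to stim_a
  wide <- calls |>
    dplyr::filter(.data$stimulus %in% c(stim_a, stim_b)) |>
    dplyr::select("neuron", "stimulus", "activated", "peak_dff") |>
    tidyr::pivot_wider(names_from = "stimulus",
                       values_from = c("activated", "peak_dff"))
  act_a <- wide[[paste0("activated_", stim_a)]]
  act_b <- wide[[paste0("activated_", stim_b)]]
  peaks_a <- wide[[paste0("peak_dff_", stim_a)]]
  amp <- NULL
  if (sum(act_a & act_b) >= 2 && sum(act_a & !act_b) >= 2) {
    amp <- compare_amplitudes(peaks_a[act_a & act_b], peaks_a[act_a & !act_b])
  }

  files <- c(calls = "response_calls.csv", overlap = "overlap_summary.csv",
             summary = "summary.json", manifest = "manifest.json")
  if (write_dff) {
    readr::write_csv(dff, file.path(out_dir, "dff.csv"))
    files <- c(files, dff = "dff.csv")
  }
  readr::write_csv(calls, file.path(out_dir, files[["calls"]]))
  readr::write_csv(overlap, file.path(out_dir, files[["overlap"]]))

  summary <- list(
    overlap = as.list(overlap),
    amplitude = if (!is.null(amp)) as.list(tidy(amp)) else NULL
  )
  write_json_stable(summary, file.path(out_dir, files[["summary"]]))
  manifest <- pipeline_manifest(
    "calcium",
    inputs = input_desc,
    parameters = list(baseline_s = baseline_s, threshold_pct = threshold_pct,
                      stim_a = stim_a, stim_b = stim_b),
    outputs = as.list(files)
  )
  write_json_stable(manifest, file.path(out_dir, files[["manifest"]]))

  invisible(list(dff = dff, calls = calls, overlap = overlap,
                 amplitude = amp, manifest = manifest))
}

#' Run the single-cell classification arm end to end
#'
#' QC filtering, marker positivity, itch/pain/dual classification, Venn
#' counts, and (optionally) per-class condition differential expression,
#' written as CSV/JSON with a reproducible manifest. Marker presence is
#' checked before any computation.
#'
#' @param x A [umi_counts()] object or a 10x-style directory path (see
#'   [read_counts_10x()]).
#' @param out_dir Output directory (created).
#' @param itch_markers,pain_markers Marker genes.
#' @param min_genes,max_mito_rate QC thresholds (see [qc_filter()]).
#' @param threshold_frac Positivity threshold fraction (default 0.05).
#' @param de_conditions Optional length-2 condition contrast (e.g.
#'   `c("CCI", "control")`) to run [condition_deg()] within assigned classes.
#' @return Invisibly, a list with `qc`, `positivity`, `classes`,
#'   `class_summary`, `venn`, `deg` (possibly NULL) and `manifest`.
#' @export
run_transcriptome_pipeline <- function(x, out_dir,
                                       itch_markers = c("Mrgpra3", "Nmb"),
                                       pain_markers = c("Tac1", "Calca"),
                                       min_genes = 500,
                                       max_mito_rate = 0.20,
                                       threshold_frac = 0.05,
                                       de_conditions = NULL) {
  input_desc <- if (is.character(x)) {
    path <- x
    x <- read_counts_10x(x)
    list(counts_dir = path)
  } else {
    list(counts = "<in-memory umi_counts>")
  }
  stopifnot(inherits(x, "umi_counts"))
  markers <- c(itch_markers, pain_markers)
  missing <- setdiff(markers, x$genes$gene)
  if (length(missing)) {
    config_error("marker genes missing from the matrix: %s",
                 paste(missing, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  qc <- qc_filter(x, min_genes = min_genes, max_mito_rate = max_mito_rate)
  if (sum(qc$report$retained) == 0) {
    data_error("no cells passed QC (retained 0 of %d).", nrow(qc$report))
  }
  filtered <- qc$counts
  pos <- positivity(filtered, markers, threshold_frac = threshold_frac)
  classes <- classify_neurons(filtered, itch_markers, pain_markers,
                              threshold_frac = threshold_frac)
  cls_sum <- class_summary(classes)
  venn <- marker_venn(filtered, markers, threshold_frac = threshold_frac)

  deg <- NULL
  if (!is.null(de_conditions)) {
    deg <- condition_deg(filtered, classes$class, conditions = de_conditions)
  }

  files <- c(qc = "qc_report.csv", positivity = "positivity.csv",
             classes = "class_assignments.csv",
             class_summary = "class_summary.csv", venn = "venn_counts.csv",
             summary = "summary.json", manifest = "manifest.json")
  readr::write_csv(qc$report, file.path(out_dir, files[["qc"]]))
  readr::write_csv(pos, file.path(out_dir, files[["positivity"]]))
  readr::write_csv(classes, file.path(out_dir, files[["classes"]]))
  readr::write_csv(cls_sum, file.path(out_dir, files[["class_summary"]]))
  readr::write_csv(venn, file.path(out_dir, files[["venn"]]))
  if (!is.null(deg)) {
    readr::write_csv(deg, file.path(out_dir, "condition_deg.csv"))
    files <- c(files, deg = "condition_deg.csv")
  }

  summary <- list(
    qc = as.list(attr(qc$report, "totals")),
    n_classified = attr(cls_sum, "n_classified"),
    class_summary = purrr::transpose(as.list(cls_sum))
  )
  write_json_stable(summary, file.path(out_dir, files[["summary"]]))
  manifest <- pipeline_manifest(
    "transcriptome",
    inputs = input_desc,
    parameters = list(itch_markers = itch_markers, pain_markers = pain_markers,
                      min_genes = min_genes, max_mito_rate = max_mito_rate,
                      threshold_frac = threshold_frac,
                      de_conditions = de_conditions),
    outputs = as.list(files)
  )
  write_json_stable(manifest, file.path(out_dir, files[["manifest"]]))

  invisible(list(qc = qc, positivity = pos, classes = classes,
                 class_summary = cls_sum, venn = venn, deg = deg,
                 manifest = manifest))
}
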