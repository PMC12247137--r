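#' Write / read a fluorescence recording (CSV traces + YAML epochs)
#'
#' The on-disk form is a plain CSV whose first column is time in seconds and
#' remaining columns are per-neuron traces (header row of neuron ids), plus a
#' YAML sidecar holding the frame rate and the stimulus-epoch table.
#'
#' @param recording A [fluor_recording()].
#' @param csv_path Path of the trace CSV.
#' @param yaml_path Path of the epoch/metadata YAML sidecar.
#' @return `write_recording()` returns the paths invisibly; `read_recording()`
#'   returns a [fluor_recording()].
#' @export
write_recording <- function(recording, csv_path, yaml_path) {
  stopifnot(inherits(recording, "fluor_recording"))
  readr::write_csv(recording$traces, csv_path)
  yaml::write_yaml(
    list(frame_rate = recording$frame_rate,
         epochs = purrr::transpose(as.list(recording$epochs))),
    yaml_path
  )
  invisible(c(csv = csv_path, yaml = yaml_path))
}

#' @rdname write_recording
#' @export
read_recording <- function(csv_path, yaml_path) {
  traces <- readr::read_csv(csv_path, show_col_types = FALSE)
  meta <- yaml::read_yaml(yaml_path)
  if (is.null(meta$epochs) || length(meta$epochs) == 0) {
    data_error("epoch sidecar '%s' has no `epochs` section.", yaml_path)
  }
  epochs <- purrr::map_dfr(meta$epochs, as_tibble)
  fluor_recording(traces, frame_rate = meta$frame_rate, epochs = epochs)
}

#' Write / read a UMI matrix in 10x-style triplet layout
#'
#' Writes `matrix.mtx` (Matrix Market integer triplets), `features.tsv`
#' (gene table), `barcodes.tsv` (cell ids) and `metadata.tsv` (full cell
#' table) into a directory, and reads the same layout back.
#'
#' @param x A [umi_counts()] object.
#' @param dir Directory (created if needed).
#' @return `write_counts_10x()` returns `dir` invisibly; `read_counts_10x()`
#'   returns a [umi_counts()].
#' @export
write_counts_10x <- function(x, dir) {
  stopifnot(inherits(x, "umi_counts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  readr::write_tsv(x$genes, file.path(dir, "features.tsv"))
  readr::write_tsv(tibble(cell = x$cells$cell), file.path(dir, "barcodes.tsv"),
                   col_names = FALSE)
  readr::write_tsv(x$cells, file.path(dir, "metadata.tsv"))
  invisible(dir)
}

#' @rdname write_counts_10x
#' @export
read_counts_10x <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) data_error("no matrix.mtx under '%s'.", dir)
  m <- as(Matrix::readMM(mtx), "CsparseMatrix")
  genes <- readr::read_tsv(file.path(dir, "features.tsv"), show_col_types = FALSE)
  cells <- readr::read_tsv(file.path(dir, "metadata.tsv"), show_col_types = FALSE)
  dimnames(m) <- list(genes$gene, cells$cell)
  umi_counts(m, genes = genes, cells = cells)
}
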