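# build a fluor_recording from a neurons x frames matrix
recording_from_matrix <- function(m, frame_rate = 1, epochs = NULL,
                                  ids = sprintf("n%03d", seq_len(nrow(m)))) {
  epochs <- epochs %||% tibble::tibble(label = "stim", onset = 100,
                                       offset = 110, kind = "mechanical")
  traces <- tibble::tibble(time = (seq_len(ncol(m)) - 1) / frame_rate)
  tm <- t(m)
  colnames(tm) <- ids
  fluor_recording(dplyr::bind_cols(traces, tibble::as_tibble(tm)),
                  frame_rate = frame_rate, epochs = epochs)
}

# independent brute-force rank-sum oracle: exact two-sided p over all
# assignments of the pooled mid-ranks
brute_force_rank_p <- function(a, b) {
  n_a <- length(a)
  n <- n_a + length(b)
  r <- rank(c(a, b))
  mu <- n_a * (n + 1) / 2
  w <- sum(r[seq_len(n_a)])
  ws <- apply(combn(n, n_a), 2, function(idx) sum(r[idx]))
  mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
}

# small umi_counts built by hand from a dense matrix
umi_from_dense <- function(m, mito = grepl("^mt-", rownames(m)), cells = NULL) {
  umi_counts(m,
             genes = tibble::tibble(gene = rownames(m), mito = mito),
             cells = cells %||% tibble::tibble(cell = colnames(m)))
}
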