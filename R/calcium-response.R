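#' Compute delta-F/F0 traces
#'
#' Converts raw fluorescence to fractional change,
#' `dF/F0 = (Ft - F0) / F0 * 100` (percent), where `F0` is each neuron's own
#' baseline: the mean fluorescence over the first `baseline_s` seconds of its
#' trace. The baseline window must be stimulus-free; recordings whose first
#' epoch starts inside it are rejected rather than silently re-windowed.
#'
#' @param recording A [fluor_recording()].
#' @param baseline_s Length of the baseline window in seconds (default 60).
#' @return A `dff_tbl`: long tibble with columns `neuron`, `time`, `dff`
#'   (percent). Attributes carry the per-neuron `f0` tibble, `frame_rate`,
#'   `baseline_s` and the epoch table for downstream calls.
#' @examples
#' rec <- simulate_recording(calcium_sim_config(n_neurons = 4, seed = 1))$recording
#' dff <- compute_dff(rec)
#' dplyr::filter(dff, time < 1)
#' @export
compute_dff <- function(recording, baseline_s = 60) {
  stopifnot(inherits(recording, "fluor_recording"))
  check_number(baseline_s, "baseline_s", min = 0, strict = TRUE)
  if (any(recording$epochs$onset < baseline_s)) {
    data_error("baseline window (first %g s) overlaps a stimulus epoch.", baseline_s)
  }
  tr <- recording$traces
  base_idx <- tr$time < baseline_s
  if (!any(base_idx)) data_error("no frames inside the baseline window.")

  m <- as.matrix(tr[-1])
  f0 <- colMeans(m[base_idx, , drop = FALSE])
  if (any(f0 <= 0)) data_error("F0 <= 0 for at least one neuron.")

  dff_m <- sweep(sweep(m, 2, f0, "-"), 2, f0, "/") * 100
  out <- tibble(time = tr$time) |>
    dplyr::bind_cols(as_tibble(dff_m)) |>
    tidyr::pivot_longer(-"time", names_to = "neuron", values_to = "dff") |>
    dplyr::arrange(.data$neuron, .data$time) |>
    dplyr::relocate("neuron")

  structure(
    out,
    f0 = tibble(neuron = names(f0), f0 = unname(f0)),
    frame_rate = recording$frame_rate,
    baseline_s = baseline_s,
    epochs = recording$epochs,
    class = c("dff_tbl", class(out))
  )
}

# analysis window per epoch: mechanical epochs run from onset to offset plus a
# decay margin; chemical epochs start after the post-injection exclusion and
# run to the end of the observation period
epoch_window <- function(epoch, t_max,
                         exclusion_s_after_injection,
                         observation_s_after_injection,
                         mech_decay_margin_s) {
  if (epoch$kind == "chemical") {
    c(
      start = epoch$onset + exclusion_s_after_injection,
      end = min(epoch$onset + observation_s_after_injection, t_max)
    )
  } else {
    c(start = epoch$onset, end = min(epoch$offset + mech_decay_margin_s, t_max))
  }
}

#' Call per-stimulus neuronal activation
#'
#' Applies the activation criterion to delta-F/F0 traces: a neuron is called
#' activated by a stimulus when its peak delta-F/F0 inside that stimulus's
#' analysis window reaches the threshold (default 20 percent, inclusive). For
#' mechanical epochs the window runs from onset to offset plus a decay margin;
#' for chemical epochs (injections) the first `exclusion_s_after_injection`
#' seconds are discarded to remove injection artifacts, and the window extends
#' to `observation_s_after_injection` (default 11 min) after injection.
#'
#' @param dff A `dff_tbl` from [compute_dff()].
#' @param epochs Epoch tibble; defaults to the one carried by `dff`.
#' @param threshold_pct Activation threshold in percent delta-F/F0 (inclusive).
#' @param exclusion_s_after_injection Seconds discarded after a chemical
#'   injection (default 60).
#' @param observation_s_after_injection End of the chemical analysis window,
#'   seconds after injection (default 660 = 11 min).
#' @param mech_decay_margin_s Decay margin appended to mechanical epochs (s).
#' @return A `response_calls` tibble: one row per (neuron, stimulus) with
#'   `kind`, `window_start`, `window_end`, `peak_dff` and `activated`.
#' @export
call_responses <- function(dff,
                           epochs = NULL,
                           threshold_pct = 20,
                           exclusion_s_after_injection = 60,
                           observation_s_after_injection = 660,
                           mech_decay_margin_s = 10) {
  stopifnot(inherits(dff, "dff_tbl") || all(c("neuron", "time", "dff") %in% names(dff)))
  epochs <- epochs %||% attr(dff, "epochs")
  if (is.null(epochs) || nrow(epochs) == 0) {
    data_error("no stimulus epochs supplied or attached to `dff`.")
  }
  check_number(threshold_pct, "threshold_pct", min = 0)
  t_max <- max(dff$time)

  calls <- purrr::map_dfr(seq_len(nrow(epochs)), function(i) {
    ep <- epochs[i, ]
    w <- epoch_window(ep, t_max, exclusion_s_after_injection,
                      observation_s_after_injection, mech_decay_margin_s)
    in_win <- dff$time >= w["start"] & dff$time <= w["end"]
    if (!any(in_win)) {
      data_error("epoch '%s': analysis window [%g, %g] s contains no frames.",
                 ep$label, w["start"], w["end"])
    }
    dff[in_win, ] |>
      dplyr::summarise(peak_dff = max(.data$dff), .by = "neuron") |>
      dplyr::mutate(
        stimulus = ep$label, kind = ep$kind,
        window_start = unname(w["start"]), window_end = unname(w["end"]),
        activated = .data$peak_dff >= threshold_pct
      )
  })

  out <- calls |>
    dplyr::select("neuron", "stimulus", "kind", "window_start", "window_end",
                  "peak_dff", "activated")
  structure(out, threshold_pct = threshold_pct,
            class = c("response_calls", class(out)))
}

#' Summarize the overlap of two stimulus-response populations
#'
#' Counts neurons activated by both stimuli, by only the first, and by only
#' the second; the denominator is their union (all neurons activated by at
#' least one of the two). Percentages are rounded half-away-from-zero to one
#' decimal, the convention behind printed values such as 37.4 = 198/530.
#'
#' @param calls A `response_calls` tibble from [call_responses()], or any
#'   tibble with columns `neuron`, `stimulus`, `activated`.
#' @param stim_a,stim_b Stimulus labels to compare.
#' @return One-row tibble: `n_both`, `n_only_a`, `n_only_b`, `n_union`,
#'   `pct_both`, `pct_only_a`, `pct_only_b` (one decimal) and `defined`
#'   (FALSE when the union is empty, in which case percentages are `NA`).
#'   The unrounded percentages are attached as attribute `pct_exact`.
#' @examples
#' calls <- overlap_fixture(n_both = 198, n_only_a = 293, n_only_b = 39)
#' summarize_overlap(calls, "pinch", "brush")
#' @export
summarize_overlap <- function(calls, stim_a, stim_b) {
  for (s in c(stim_a, stim_b)) {
    if (!s %in% calls$stimulus) data_error("stimulus '%s' absent from calls.", s)
  }
  wide <- calls |>
    dplyr::filter(.data$stimulus %in% c(stim_a, stim_b)) |>
    dplyr::select("neuron", "stimulus", "activated") |>
    tidyr::pivot_wider(names_from = "stimulus", values_from = "activated",
                       values_fill = FALSE)
  a <- wide[[stim_a]]
  b <- wide[[stim_b]]
  n_both <- sum(a & b)
  n_only_a <- sum(a & !b)
  n_only_b <- sum(!a & b)
  n_union <- n_both + n_only_a + n_only_b

  if (n_union == 0) {
    pct_exact <- c(both = NA_real_, only_a = NA_real_, only_b = NA_real_)
    defined <- FALSE
  } else {
    pct_exact <- 100 * c(both = n_both, only_a = n_only_a, only_b = n_only_b) / n_union
    defined <- TRUE
  }
  out <- tibble(
    stim_a = stim_a, stim_b = stim_b,
    n_both = n_both, n_only_a = n_only_a, n_only_b = n_only_b,
    n_union = n_union,
    pct_both = round_half_up(pct_exact[["both"]], 1),
    pct_only_a = round_half_up(pct_exact[["only_a"]], 1),
    pct_only_b = round_half_up(pct_exact[["only_b"]], 1),
    defined = defined
  )
  attr(out, "pct_exact") <- pct_exact
  out
}

#' Build a response-call table with given overlap counts
#'
#' Constructs a minimal `response_calls`-shaped fixture in which exactly
#' `n_both` neurons are activated by both stimuli, `n_only_a` by the first
#' only, and `n_only_b` by the second only. Useful for checking overlap
#' arithmetic against printed Venn counts.
#'
#' @param n_both,n_only_a,n_only_b Nonnegative counts.
#' @param stim_a,stim_b Stimulus labels.
#' @return A tibble with columns `neuron`, `stimulus`, `activated`.
#' @export
overlap_fixture <- function(n_both, n_only_a, n_only_b,
                            stim_a = "pinch", stim_b = "brush") {
  n <- n_both + n_only_a + n_only_b
  ids <- sprintf("n%04d", seq_len(max(n, 1)))[seq_len(n)]
  cls <- rep(c("both", "only_a", "only_b"), times = c(n_both, n_only_a, n_only_b))
  tibble(neuron = rep(ids, each = 2),
         stimulus = rep(c(stim_a, stim_b), times = n),
         activated = as.vector(rbind(cls != "only_b", cls != "only_a")))
}

#' Fraction of detectable neurons activated by a stimulus
#'
#' @param calls A `response_calls` tibble.
#' @param stimulus Stimulus label.
#' @param n_detectable Denominator: all detectable neurons in the fields of
#'   view (including constitutively fluorescent, never-activated ones); must
#'   be at least the activated count. This cannot be derived from the calls
#'   alone, so it is an explicit input.
#' @return Percent activated, rounded half-away-from-zero to one decimal.
#' @export
activated_fraction <- function(calls, stimulus, n_detectable) {
  check_number(n_detectable, "n_detectable", min = 0, strict = TRUE)
  if (!stimulus %in% calls$stimulus) data_error("stimulus '%s' absent from calls.", stimulus)
  n_act <- sum(calls$activated[calls$stimulus == stimulus])
  if (n_detectable < n_act) {
    data_error("n_detectable (%g) is smaller than the activated count (%d).",
               n_detectable, n_act)
  }
  round_half_up(100 * n_act / n_detectable, 1)
}

#' Population mean delta-F/F0 time course
#'
#' Per-frame mean and standard error of delta-F/F0 over a subset of neurons,
#' as plotted for activated populations. With a single neuron the SEM is
#' undefined; it is reported as 0 by convention and flagged.
#'
#' @param dff A `dff_tbl` from [compute_dff()].
#' @param neurons Character vector of neuron ids; default all neurons.
#' @return Tibble with `time`, `mean_dff`, `sem_dff`, `n` and `sem_defined`.
#' @export
population_mean_dff <- function(dff, neurons = NULL) {
  neurons <- neurons %||% unique(dff$neuron)
  if (length(neurons) == 0) data_error("empty neuron subset.")
  missing <- setdiff(neurons, unique(dff$neuron))
  if (length(missing)) data_error("unknown neurons: %s", paste(missing, collapse = ", "))
  dff |>
    dplyr::filter(.data$neuron %in% neurons) |>
    dplyr::summarise(
      mean_dff = mean(.data$dff),
      sem_dff = if (dplyr::n() > 1) sd(.data$dff) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(),
      .by = "time"
    ) |>
    dplyr::mutate(sem_defined = .data$n > 1)
}

#' Compare peak amplitudes between two neuron groups
#'
#' Two-sided unpaired t test on peak delta-F/F0 values (Student's
#' pooled-variance by default; Welch via `var_equal = FALSE`), reported as
#' mean plus or minus SEM per group with conventional significance stars.
#' Used for, e.g., multisensory vs single-modality amplitude comparisons.
#'
#' @param group_a,group_b Numeric vectors of peak delta-F/F0 (percent), each
#'   of length >= 2.
#' @param var_equal Assume equal variances (Student's test) if TRUE (default).
#' @return An `amplitude_comparison` object; see [tidy()] and [glance()]
#'   methods.
#' @examples
#' compare_amplitudes(c(55, 80, 62, 71), c(35, 42, 28, 49))
#' @export
compare_amplitudes <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    data_error("each group needs >= 2 observations for an unpaired t test.")
  }
  ht <- t.test(group_a, group_b, var.equal = var_equal)
  structure(
    list(
      t = unname(ht$statistic), df = unname(ht$parameter),
      p_value = ht$p.value,
      mean_a = mean(group_a), mean_b = mean(group_b),
      sem_a = sd(group_a) / sqrt(length(group_a)),
      sem_b = sd(group_b) / sqrt(length(group_b)),
      n_a = length(group_a), n_b = length(group_b),
      var_equal = var_equal,
      stars = significance_stars(ht$p.value)
    ),
    class = "amplitude_comparison"
  )
}

significance_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' @export
print.amplitude_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("Unpaired %s t test on peak dF/F0\n",
           "  group A: %.2f +/- %.2f%% (n = %d)\n",
           "  group B: %.2f +/- %.2f%% (n = %d)\n",
           "  t = %.3f, df = %.2f, p = %.4g %s\n"),
    if (x$var_equal) "Student's" else "Welch's",
    x$mean_a, x$sem_a, x$n_a, x$mean_b, x$sem_b, x$n_b,
    x$t, x$df, x$p_value, x$stars
  ))
  invisible(x)
}

#' @rdname compare_amplitudes
#' @param x An `amplitude_comparison` object.
#' @param ... Unused.
#' @export
tidy.amplitude_comparison <- function(x, ...) {
  tibble(
    estimate = x$mean_a - x$mean_b,
    mean_a = x$mean_a, mean_b = x$mean_b,
    sem_a = x$sem_a, sem_b = x$sem_b,
    statistic = x$t, df = x$df, p.value = x$p_value,
    stars = x$stars
  )
}

#' @rdname compare_amplitudes
#' @export
glance.amplitude_comparison <- function(x, ...) {
  tibble(n_a = x$n_a, n_b = x$n_b, var_equal = x$var_equal,
         statistic = x$t, p.value = x$p_value)
}
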