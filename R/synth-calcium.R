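#' Configure a synthetic calcium-imaging recording
#'
#' Builds the configuration for [simulate_recording()]: a population of DRG
#' neurons partitioned into responder classes (responding to both stimuli, to
#' one only, or to neither), imaged at a fixed frame rate while two stimulus
#' epochs are delivered. Stimulus-evoked transients follow a double-exponential
#' kernel approximating GCaMP6s kinetics, riding on a constant baseline with
#' additive Gaussian noise. The defaults reproduce the mechanical
#' (pinch/brush) study condition: 530 neurons with planted responder counts
#' 198 both / 293 pinch-only / 39 brush-only, two 10-s epochs 5 min apart.
#'
#' Multisensory ("both") neurons are planted with larger peak amplitudes than
#' single-modality neurons, mirroring the amplitude gap reported for neurons
#' responding to both a pain and an itch stimulus; the gap is planted, not
#' emergent.
#'
#' Chemical epochs (`kind == "chemical"`) model an intraplantar injection: the
#' evoked transient starts `chem_onset_delay_s` after the injection and rises
#' slowly (`chem_rise_tau`/`chem_decay_tau`), so its peak falls after the
#' 1-min post-injection exclusion window applied downstream. An optional
#' injection artifact (`artifact_dff` > 0) plants a fast spike in the first
#' seconds after injection, which the exclusion rule must discard.
#'
#' @param n_neurons Number of neurons to simulate.
#' @param frame_rate Imaging frame rate in Hz.
#' @param duration Recording length in seconds. Defaults to cover the epochs
#'   plus a 30-s tail.
#' @param baseline_level Baseline fluorescence in arbitrary units; must be > 0.
#' @param noise_sd Standard deviation of additive Gaussian noise, in the same
#'   arbitrary units as `baseline_level`.
#' @param epochs Tibble with columns `label`, `onset`, `offset` (seconds) and
#'   `kind` (`"mechanical"` or `"chemical"`). The first onset must be at least
#'   60 s so the baseline window stays stimulus-free. Defaults to two 10-s
#'   mechanical epochs (`stim_a` at 60 s, `stim_b` at 360 s).
#' @param stim_a,stim_b Labels of the two stimuli used to define responder
#'   classes.
#' @param class_fractions Named fractions (`both`, `only_a`, `only_b`, `none`)
#'   summing to 1; converted to planted counts by largest remainder.
#' @param class_counts Optional named integer vector with the same names,
#'   overriding `class_fractions` with exact planted counts (must sum to
#'   `n_neurons`).
#' @param amplitude_dff Tibble with columns `class`, `stimulus`, `amplitude`
#'   giving the target peak delta-F/F0 (percent) planted for each responder
#'   class and stimulus.
#' @param kernel_rise_tau,kernel_decay_tau Rise/decay time constants (s) of the
#'   mechanical transient kernel.
#' @param chem_rise_tau,chem_decay_tau,chem_onset_delay_s Kinetics of the
#'   sustained chemical transient.
#' @param artifact_dff Peak delta-F/F0 (percent) of the injection artifact
#'   planted in every neuron at `artifact_time_s` after a chemical epoch onset;
#'   0 disables it.
#' @param artifact_time_s Artifact onset relative to injection (must be < 60 s
#'   for the exclusion rule to see it).
#' @param seed Integer seed; the simulation is a pure function of the config.
#' @return A `calcium_sim_config` object (validated list).
#' @seealso [simulate_recording()]
#' @export
calcium_sim_config <- function(n_neurons = 530,
                               frame_rate = 5,
                               duration = NULL,
                               baseline_level = 100,
                               noise_sd = 2,
                               epochs = NULL,
                               stim_a = "pinch",
                               stim_b = "brush",
                               class_fractions = c(both = 198, only_a = 293,
                                                   only_b = 39, none = 0) / 530,
                               class_counts = NULL,
                               amplitude_dff = NULL,
                               kernel_rise_tau = 0.2,
                               kernel_decay_tau = 1.5,
                               chem_rise_tau = 30,
                               chem_decay_tau = 240,
                               chem_onset_delay_s = 30,
                               artifact_dff = 0,
                               artifact_time_s = 5,
                               seed = 1L) {
  check_number(n_neurons, "n_neurons", min = 1)
  check_number(frame_rate, "frame_rate", min = 0, strict = TRUE)
  check_number(baseline_level, "baseline_level", min = 0, strict = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(kernel_rise_tau, "kernel_rise_tau", min = 0, strict = TRUE)
  check_number(kernel_decay_tau, "kernel_decay_tau", min = 0, strict = TRUE)

  if (is.null(epochs)) {
    epochs <- tibble(
      label = c(stim_a, stim_b),
      onset = c(60, 360),
      offset = c(70, 370),
      kind = "mechanical"
    )
  }
  epochs <- as_tibble(epochs)
  need <- c("label", "onset", "offset", "kind")
  if (!all(need %in% names(epochs))) {
    config_error("`epochs` must have columns %s.", paste(need, collapse = ", "))
  }
  if (is.null(duration)) duration <- max(epochs$offset) + 30
  check_number(duration, "duration", min = 0, strict = TRUE)
  if (any(epochs$onset < 0) || any(epochs$offset > duration)) {
    config_error("all epochs must lie within [0, duration].")
  }
  if (any(epochs$offset <= epochs$onset)) {
    config_error("epoch offsets must exceed onsets.")
  }
  if (min(epochs$onset) < 60) {
    config_error("first epoch onset must be >= 60 s to keep the baseline window stimulus-free.")
  }
  if (is.unsorted(epochs$onset, strictly = TRUE)) {
    config_error("epoch onsets must be strictly increasing.")
  }

  cls <- c("both", "only_a", "only_b", "none")
  if (is.null(class_counts)) {
    if (!setequal(names(class_fractions), cls)) {
      config_error("`class_fractions` must be named %s.", paste(cls, collapse = ", "))
    }
    class_fractions <- class_fractions[cls]
    if (any(class_fractions < 0) || abs(sum(class_fractions) - 1) > 1e-9) {
      config_error("`class_fractions` must be nonnegative and sum to 1 (within 1e-9).")
    }
    class_counts <- largest_remainder(class_fractions * n_neurons, n_neurons)
  } else {
    if (!setequal(names(class_counts), cls)) {
      config_error("`class_counts` must be named %s.", paste(cls, collapse = ", "))
    }
    class_counts <- as.integer(class_counts[cls])
    names(class_counts) <- cls
    if (any(class_counts < 0) || sum(class_counts) != n_neurons) {
      config_error("`class_counts` must be nonnegative and sum to `n_neurons`.")
    }
  }

  if (is.null(amplitude_dff)) {
    amplitude_dff <- tibble(
      class = c("both", "both", "only_a", "only_b"),
      stimulus = c(stim_a, stim_b, stim_a, stim_b),
      amplitude = c(80, 60, 50, 40)
    )
  }
  amplitude_dff <- as_tibble(amplitude_dff)
  if (!all(c("class", "stimulus", "amplitude") %in% names(amplitude_dff))) {
    config_error("`amplitude_dff` must have columns class, stimulus, amplitude.")
  }

  structure(
    list(
      n_neurons = as.integer(n_neurons), frame_rate = frame_rate,
      duration = duration, baseline_level = baseline_level,
      noise_sd = noise_sd, epochs = epochs,
      stim_a = stim_a, stim_b = stim_b,
      class_counts = class_counts, amplitude_dff = amplitude_dff,
      kernel_rise_tau = kernel_rise_tau, kernel_decay_tau = kernel_decay_tau,
      chem_rise_tau = chem_rise_tau, chem_decay_tau = chem_decay_tau,
      chem_onset_delay_s = chem_onset_delay_s,
      artifact_dff = artifact_dff, artifact_time_s = artifact_time_s,
      seed = as.integer(seed)
    ),
    class = "calcium_sim_config"
  )
}

# integer apportionment: floor + distribute the remainder to largest fractions
largest_remainder <- function(x, total) {
  base <- floor(x)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(x - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  out <- as.integer(base)
  names(out) <- names(x)
  out
}

# double-exponential transient, zero before onset, normalized to peak 1 on the
# sampled grid so a planted amplitude is realized exactly in the noiseless limit
transient_kernel <- function(t, onset, rise_tau, decay_tau) {
  s <- t - onset
  k <- ifelse(s >= 0, exp(-s / decay_tau) - exp(-s / rise_tau), 0)
  m <- max(k)
  if (m <= 0) k else k / m
}

#' Simulate a fluorescence recording with known responder classes
#'
#' Draws a neurons-by-frames fluorescence matrix from a [calcium_sim_config()]:
#' `F(t) = baseline * (1 + sum of planted transients) + Gaussian noise`. Each
#' responder's transient is a double-exponential kernel scaled so that, with
#' `noise_sd = 0`, its sampled peak delta-F/F0 equals the configured amplitude
#' exactly. The output is a pure function of the config (including its seed).
#'
#' @param config A [calcium_sim_config()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{recording}{A [fluor_recording()]: wide tibble of traces (time plus
#'       one column per neuron), frame rate, and the epoch table.}
#'     \item{truth}{Tibble of planted ground truth: `neuron`, `class`,
#'       `responds_a`/`responds_b`, and the planted amplitudes
#'       `amplitude_a`/`amplitude_b` (percent delta-F/F0; `NA` for
#'       non-responders). Stimulus labels are in `attr(truth, "stimuli")`.}
#'   }
#' @examples
#' cfg <- calcium_sim_config(n_neurons = 8, seed = 42)
#' sim <- simulate_recording(cfg)
#' sim$truth
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "calcium_sim_config"))
  n <- config$n_neurons
  fr <- config$frame_rate
  n_frames <- floor(config$duration * fr)
  t <- (seq_len(n_frames) - 1) / fr
  ids <- sprintf("n%0*d", max(3L, nchar(n)), seq_len(n))

  classes <- rep(c("both", "only_a", "only_b", "none"), times = config$class_counts)

  responds <- function(class, which) {
    class == "both" | class == paste0("only_", which)
  }
  amp_lookup <- function(class, stimulus) {
    hit <- config$amplitude_dff$class == class &
      config$amplitude_dff$stimulus == stimulus
    if (any(hit)) config$amplitude_dff$amplitude[which(hit)[1]] else NA_real_
  }

  # signal matrix: frames x neurons, in units of baseline fraction
  signal <- matrix(0, nrow = n_frames, ncol = n)
  for (i in seq_len(nrow(config$epochs))) {
    ep <- config$epochs[i, ]
    which_stim <- if (ep$label == config$stim_a) "a" else
      if (ep$label == config$stim_b) "b" else NA_character_
    if (ep$kind == "chemical") {
      kern <- transient_kernel(t, ep$onset + config$chem_onset_delay_s,
                               config$chem_rise_tau, config$chem_decay_tau)
      if (config$artifact_dff > 0) {
        art <- transient_kernel(t, ep$onset + config$artifact_time_s,
                                config$kernel_rise_tau, config$kernel_decay_tau)
        signal <- signal + outer(art, rep(config$artifact_dff / 100, n))
      }
    } else {
      kern <- transient_kernel(t, ep$onset,
                               config$kernel_rise_tau, config$kernel_decay_tau)
    }
    if (is.na(which_stim)) next
    amps <- vapply(classes, function(cl) {
      if (responds(cl, which_stim)) amp_lookup(cl, ep$label) else 0
    }, numeric(1))
    amps[is.na(amps)] <- 0
    signal <- signal + outer(kern, amps / 100)
  }

  traces <- with_local_seed(config$seed, {
    config$baseline_level * (1 + signal) +
      matrix(rnorm(n_frames * n, sd = config$noise_sd), nrow = n_frames)
  })
  colnames(traces) <- ids

  truth <- tibble(
    neuron = ids,
    class = classes,
    responds_a = responds(classes, "a"),
    responds_b = responds(classes, "b"),
    amplitude_a = vapply(classes, function(cl) {
      if (responds(cl, "a")) amp_lookup(cl, config$stim_a) else NA_real_
    }, numeric(1)),
    amplitude_b = vapply(classes, function(cl) {
      if (responds(cl, "b")) amp_lookup(cl, config$stim_b) else NA_real_
    }, numeric(1))
  )
  attr(truth, "stimuli") <- c(a = config$stim_a, b = config$stim_b)

  rec <- fluor_recording(
    traces = tibble(time = t) |> dplyr::bind_cols(as_tibble(traces)),
    frame_rate = fr,
    epochs = config$epochs
  )
  list(recording = rec, truth = truth)
}

# evaluate expr under a temporary RNG state so simulation is reproducible
# without clobbering the caller's stream
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
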