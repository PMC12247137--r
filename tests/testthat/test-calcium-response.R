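test_that("dF/F0 matches the defining formula, frame by frame", {
  # constant trace: Ft = F0 everywhere
  m <- matrix(100, nrow = 1, ncol = 130)
  dff <- compute_dff(recording_from_matrix(m))
  expect_equal(dff$dff, rep(0, 130))

  # step trace: baseline 100, later frames 120 -> exactly 20%
  m2 <- matrix(100, nrow = 1, ncol = 130)
  m2[1, 101:110] <- 120
  dff2 <- compute_dff(recording_from_matrix(m2))
  expect_equal(unique(dff2$dff[101:110]), 20)

  # arbitrary traces vs an independent per-frame oracle
  set.seed(42)
  m3 <- matrix(exp(rnorm(3 * 130, log(100), 0.2)), nrow = 3)
  rec3 <- recording_from_matrix(m3)
  dff3 <- compute_dff(rec3)
  for (i in 1:3) {
    f <- m3[i, ]
    f0 <- mean(f[1:60]) # frame_rate 1 Hz: first 60 s = frames 1..60
    oracle <- (f - f0) / f0 * 100
    got <- dff3$dff[dff3$neuron == sprintf("n%03d", i)]
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("mean dF/F0 over the baseline window is zero for every neuron", {
  set.seed(7)
  for (rep in 1:5) {
    m <- matrix(exp(rnorm(4 * 200, log(80), 0.3)), nrow = 4)
    dff <- compute_dff(recording_from_matrix(m))
    base_means <- dff |>
      dplyr::filter(time < 60) |>
      dplyr::summarise(mu = mean(dff), .by = "neuron")
    expect_true(all(abs(base_means$mu) < 1e-9))
  }
})

test_that("baseline windows that overlap a stimulus are rejected", {
  m <- matrix(100, nrow = 1, ncol = 130)
  rec <- recording_from_matrix(
    m, epochs = tibble::tibble(label = "stim", onset = 70, offset = 80,
                               kind = "mechanical"))
  expect_error(compute_dff(rec, baseline_s = 80), class = "drgmodal_data_error")
})

test_that("the 20% activation boundary is inclusive", {
  m <- matrix(100, nrow = 2, ncol = 130)
  m[1, 105] <- 120.0 # peak dF/F0 exactly 20.0%
  m[2, 105] <- 119.9 # 19.9%
  calls <- call_responses(compute_dff(recording_from_matrix(m)))
  expect_true(calls$activated[calls$neuron == "n001"])
  expect_false(calls$activated[calls$neuron == "n002"])
  expect_equal(calls$peak_dff, c(20, 19.9), tolerance = 1e-12)
})

test_that("signal within 1 min of a chemical injection is excluded", {
  # 800 s recording; injection at 100 s; the only supra-threshold excursion
  # sits 30 s after injection, inside the exclusion window
  m <- matrix(100, nrow = 1, ncol = 800)
  m[1, 126:135] <- 160
  epochs <- tibble::tibble(label = "CQ", onset = 100, offset = 700,
                           kind = "chemical")
  calls <- call_responses(compute_dff(recording_from_matrix(m, epochs = epochs)))
  expect_false(calls$activated)
  expect_equal(calls$window_start, 160)

  # the same excursion after the exclusion window does activate
  m2 <- matrix(100, nrow = 1, ncol = 800)
  m2[1, 301:310] <- 160
  calls2 <- call_responses(compute_dff(recording_from_matrix(m2, epochs = epochs)))
  expect_true(calls2$activated)

  # an epoch whose window is empty after exclusion is a data error
  late <- tibble::tibble(label = "CQ", onset = 790, offset = 799,
                         kind = "chemical")
  expect_error(
    call_responses(compute_dff(recording_from_matrix(m, epochs = late))),
    class = "drgmodal_data_error"
  )
})

test_that("raising the activation threshold never increases activated counts", {
  sim <- simulate_recording(calcium_sim_config(
    n_neurons = 60, noise_sd = 5, seed = 21,
    class_counts = c(both = 20, only_a = 20, only_b = 10, none = 10)))
  dff <- compute_dff(sim$recording)
  thresholds <- c(5, 10, 20, 30, 50, 80)
  counts <- vapply(thresholds, function(th) {
    calls <- call_responses(dff, threshold_pct = th)
    c(sum(calls$activated[calls$stimulus == "pinch"]),
      sum(calls$activated[calls$stimulus == "brush"]),
      summarize_overlap(calls, "pinch", "brush")$n_union)
  }, numeric(3))
  for (row in 1:3) expect_true(all(diff(counts[row, ]) <= 0))
})

test_that("overlap summaries reproduce printed Venn arithmetic", {
  ov <- summarize_overlap(overlap_fixture(198, 293, 39), "pinch", "brush")
  expect_equal(ov$n_union, 530)
  expect_equal(c(ov$pct_both, ov$pct_only_a, ov$pct_only_b), c(37.4, 55.3, 7.4))

  ov2 <- summarize_overlap(overlap_fixture(88, 50, 94, "CQ", "FM"), "CQ", "FM")
  expect_equal(ov2$n_union, 232)
  expect_equal(c(ov2$pct_both, ov2$pct_only_a, ov2$pct_only_b),
               c(37.9, 21.6, 40.5))

  ov3 <- summarize_overlap(overlap_fixture(0, 5, 0), "pinch", "brush")
  expect_equal(c(ov3$pct_both, ov3$pct_only_a, ov3$pct_only_b), c(0, 100, 0))
})

test_that("overlap percentages are conserved before and after rounding", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(0:400, 3)
    if (sum(n) == 0) n <- c(1, 0, 0)
    ov <- summarize_overlap(overlap_fixture(n[1], n[2], n[3]), "pinch", "brush")
    expect_equal(sum(attr(ov, "pct_exact")), 100, tolerance = 1e-9)
    rounded <- ov$pct_both + ov$pct_only_a + ov$pct_only_b
    expect_gte(rounded, 99.8)
    expect_lte(rounded, 100.2)
    expect_equal(ov$n_union, ov$n_both + ov$n_only_a + ov$n_only_b)
  }
})

test_that("an empty union is flagged rather than divided by zero", {
  calls <- tibble::tibble(
    neuron = c("n1", "n1"), stimulus = c("a", "b"), activated = FALSE)
  ov <- summarize_overlap(calls, "a", "b")
  expect_false(ov$defined)
  expect_true(is.na(ov$pct_both))
  expect_equal(ov$n_union, 0)
})

test_that("activated fractions use the detectable-neuron denominator", {
  calls <- overlap_fixture(0, 50, 0)
  expect_equal(activated_fraction(calls, "pinch", 200), 25)
  expect_equal(activated_fraction(calls, "brush", 100), 0)
  expect_error(activated_fraction(calls, "pinch", 0), class = "drgmodal_config_error")
  expect_error(activated_fraction(calls, "pinch", 10), class = "drgmodal_data_error")
})

test_that("population mean and SEM match a brute-force oracle", {
  set.seed(9)
  m <- matrix(exp(rnorm(5 * 150, log(100), 0.2)), nrow = 5)
  dff <- compute_dff(recording_from_matrix(m))

  pop <- population_mean_dff(dff)
  wide <- tidyr::pivot_wider(dff, names_from = "neuron", values_from = "dff")
  vals <- as.matrix(wide[-1])
  expect_equal(pop$mean_dff, unname(rowMeans(vals)), tolerance = 1e-12)
  expect_equal(pop$sem_dff, unname(apply(vals, 1, sd) / sqrt(5)), tolerance = 1e-12)

  one <- population_mean_dff(dff, "n002")
  expect_equal(one$mean_dff, dff$dff[dff$neuron == "n002"])
  expect_true(all(one$sem_dff == 0))
  expect_false(any(one$sem_defined))

  # two identical neurons -> SEM identically zero
  m2 <- rbind(m[1, ], m[1, ])
  pop2 <- population_mean_dff(compute_dff(recording_from_matrix(m2)))
  expect_true(all(pop2$sem_dff < 1e-12))

  expect_error(population_mean_dff(dff, character(0)), class = "drgmodal_data_error")
})

test_that("the amplitude comparison matches the pooled-variance closed form", {
  cmp <- compare_amplitudes(c(1, 2, 3), c(4, 5, 6))
  # closed form: pooled sd 1, se = sqrt(2/3)
  t_oracle <- (2 - 5) / sqrt(1 * (1 / 3 + 1 / 3))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 4)
  expect_equal(cmp$t, t_oracle, tolerance = 1e-12)
  expect_equal(cmp$p_value, p_oracle, tolerance = 1e-12)

  same <- compare_amplitudes(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_identical(same$stars, "ns")

  swapped <- compare_amplitudes(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swapped$t, -cmp$t)
  expect_equal(swapped$p_value, cmp$p_value)

  expect_error(compare_amplitudes(1, c(1, 2)), class = "drgmodal_data_error")

  td <- tidy(cmp)
  expect_equal(td$estimate, -3)
  expect_named(glance(cmp), c("n_a", "n_b", "var_equal", "statistic", "p.value"))
})

test_that("a planted multisensory amplitude gap is detected at n = 50 per group", {
  sim <- simulate_recording(calcium_sim_config(
    n_neurons = 100, noise_sd = 2, seed = 14,
    class_counts = c(both = 50, only_a = 50, only_b = 0, none = 0)))
  calls <- call_responses(compute_dff(sim$recording))
  pinch <- calls[calls$stimulus == "pinch", ]
  peaks <- setNames(pinch$peak_dff, pinch$neuron)
  both_ids <- sim$truth$neuron[sim$truth$class == "both"]
  only_ids <- sim$truth$neuron[sim$truth$class == "only_a"]
  cmp <- compare_amplitudes(peaks[both_ids], peaks[only_ids])
  expect_lt(cmp$p_value, 0.05)
  expect_gt(cmp$mean_a, cmp$mean_b)
})

test_that("planted responder classes are recovered exactly at low noise", {
  sim <- simulate_recording(calcium_sim_config(
    n_neurons = 530, noise_sd = 2, seed = 5)) # noise 2% of baseline 100
  calls <- call_responses(compute_dff(sim$recording))
  ov <- summarize_overlap(calls, "pinch", "brush")
  expect_equal(c(ov$n_both, ov$n_only_a, ov$n_only_b), c(198, 293, 39))
})
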