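make_qc_matrix <- function() {
  # 560 background genes + one mito gene; counts chosen to probe both QC
  # boundaries exactly
  genes <- c(sprintf("g%03d", 1:560), "mt-x")
  cells <- c("pass", "genes501", "genes500", "mito20", "mito16")
  m <- matrix(0L, nrow = length(genes), ncol = length(cells),
              dimnames = list(genes, cells))
  m[1:540, "pass"] <- 1L          # 540 genes, no mito
  m[1:501, "genes501"] <- 1L      # 501 genes  -> retained (strict >500)
  m[1:500, "genes500"] <- 1L      # 500 genes  -> dropped
  m[1:520, "mito20"] <- 1L        # mito 130/650 = 20% -> dropped
  m["mt-x", "mito20"] <- 130L
  m[1:520, "mito16"] <- 1L        # mito 100/620 ~ 16% -> retained
  m["mt-x", "mito16"] <- 100L
  umi_from_dense(m)
}

test_that("QC keeps cells strictly above 500 genes and strictly below 20% mito", {
  qc <- qc_filter(make_qc_matrix())
  rep <- qc$report
  expect_true(rep$retained[rep$cell == "pass"])
  expect_true(rep$retained[rep$cell == "genes501"])
  expect_false(rep$retained[rep$cell == "genes500"])
  expect_false(rep$retained[rep$cell == "mito20"])
  expect_true(rep$retained[rep$cell == "mito16"])
  expect_equal(rep$mito_rate[rep$cell == "mito20"], 0.2, tolerance = 1e-12)
  expect_equal(unname(attr(rep, "totals")), c(5, 3))

  # mito rows removed from the retained matrix
  expect_false("mt-x" %in% qc$counts$genes$gene)
  expect_equal(ncol(qc$counts$counts), 3)
})

test_that("missing mito annotation warns and treats mito rates as zero", {
  m <- matrix(1L, nrow = 600, ncol = 3,
              dimnames = list(sprintf("g%03d", 1:600), c("a", "b", "c")))
  x <- umi_from_dense(m, mito = rep(FALSE, 600))
  expect_warning(qc <- qc_filter(x), "mito")
  expect_true(all(qc$report$mito_rate == 0))
  expect_true(all(qc$report$retained))
})

test_that("gene positivity reproduces hand-computed thresholds", {
  r1 <- gene_positivity(c(10, 8, 6, 0.2, 0))
  expect_equal(r1$max_level, 8)
  expect_equal(r1$threshold, 0.4)
  expect_equal(r1$n_positive, 3L)
  expect_equal(r1$fraction, 0.6)

  # fewer than three nonzero values: top-3 includes zeros
  r2 <- gene_positivity(c(5, 0, 0, 0))
  expect_equal(r2$max_level, 5 / 3)
  expect_equal(r2$threshold, 1 / 12)
  expect_equal(r2$fraction, 0.25)

  # all-zero gene: threshold 0, strict > keeps fraction at 0
  r3 <- gene_positivity(c(0, 0, 0, 0))
  expect_equal(r3$max_level, 0)
  expect_equal(r3$fraction, 0)

  expect_error(gene_positivity(c(1, 2)), class = "drgmodal_data_error")
})

test_that("positivity is invariant to rescaling one gene and monotone in the threshold", {
  set.seed(12)
  for (i in 1:10) {
    v <- rexp(30) * sample(c(0, 1), 30, replace = TRUE, prob = c(0.3, 0.7))
    for (c_scale in c(0.01, 3, 1000)) {
      expect_equal(gene_positivity(v)$fraction,
                   gene_positivity(c_scale * v)$fraction)
    }
    fracs <- vapply(c(0.01, 0.05, 0.1, 0.3, 0.8),
                    function(f) gene_positivity(v, f)$fraction, numeric(1))
    expect_true(all(diff(fracs) <= 0))
  }

  # matrix-level: multiplying one gene's row leaves its calls unchanged
  set.seed(13)
  m <- matrix(rpois(5 * 20, 3), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:20)))
  x1 <- umi_from_dense(m)
  m2 <- m
  m2[2, ] <- m2[2, ] * 7L
  x2 <- umi_from_dense(m2)
  expect_identical(positivity_calls(x1, "g2", scale = "counts"),
                   positivity_calls(x2, "g2", scale = "counts"))
})

test_that("neuron classes follow the marker-combination rule", {
  genes <- c("Mrgpra3", "Nmb", "Tac1", "Calca")
  m <- matrix(0, nrow = 4, ncol = 5,
              dimnames = list(genes, paste0("c", 1:5)))
  m["Nmb", 1] <- 100                     # itch
  m["Nmb", 2] <- 100; m["Tac1", 2] <- 100 # itch_pain
  m["Calca", 3] <- 100                   # pain
  m["Mrgpra3", 4] <- 100; m["Nmb", 4] <- 100 # still itch
  # c5 negative for all -> unclassified
  cls <- classify_neurons(umi_from_dense(m))
  expect_equal(cls$class, c("itch", "itch_pain", "pain", "itch", "unclassified"))

  cs <- class_summary(cls)
  expect_equal(attr(cs, "n_classified"), 4L)
  expect_true(is.na(cs$pct[cs$class == "unclassified"]))

  expect_error(classify_neurons(umi_from_dense(m[1:3, ])),
               class = "drgmodal_config_error")
})

test_that("classes partition the marker-positive cells and ignore unclassified additions", {
  sim <- simulate_umi_counts(transcriptome_sim_config(
    n_cells_per_sample = 80, seed = 17))
  qc <- qc_filter(sim$counts)
  cls <- classify_neurons(qc$counts)
  calls <- positivity_calls(qc$counts, c("Mrgpra3", "Nmb", "Tac1", "Calca"))
  n_pos <- sum(rowSums(calls) > 0)
  cs <- class_summary(cls)
  expect_equal(sum(cs$n[cs$class != "unclassified"]), n_pos)
  expect_equal(sum(cs$n), nrow(cls))
})

test_that("permuting cells permutes positivity calls identically", {
  set.seed(19)
  m <- matrix(rpois(4 * 30, 4), nrow = 4,
              dimnames = list(c("Mrgpra3", "Nmb", "Tac1", "Calca"),
                              sprintf("c%02d", 1:30)))
  x <- umi_from_dense(m)
  perm <- sample(colnames(m))
  xp <- umi_from_dense(m[, perm])
  c1 <- positivity_calls(x, rownames(m), scale = "counts")
  c2 <- positivity_calls(xp, rownames(m), scale = "counts")
  expect_identical(c1[perm, ], c2)
})

test_that("venn counts are disjoint, exhaustive and match brute-force enumeration", {
  # two disjoint markers: only singleton combinations populated
  m <- matrix(0, nrow = 2, ncol = 6,
              dimnames = list(c("Nmb", "Tac1"), paste0("c", 1:6)))
  m["Nmb", 1:3] <- 50
  m["Tac1", 4:6] <- 50
  v <- marker_venn(umi_from_dense(m), c("Nmb", "Tac1"))
  expect_equal(v$n[v$combination == "Nmb"], 3L)
  expect_equal(v$n[v$combination == "Tac1"], 3L)
  expect_equal(v$n[v$combination == "Nmb+Tac1"], 0L)

  # one cell positive for all four markers
  m4 <- matrix(0, nrow = 4, ncol = 4,
               dimnames = list(c("Mrgpra3", "Nmb", "Tac1", "Calca"),
                               paste0("c", 1:4)))
  m4[, 1] <- 100
  m4["Nmb", 2] <- 100
  v4 <- marker_venn(umi_from_dense(m4))
  expect_equal(v4$n[v4$combination == "Nmb+Mrgpra3+Tac1+Calca"], 1L)
  expect_equal(nrow(v4), 15)

  # random 20-cell fixture vs exhaustive per-cell enumeration
  set.seed(23)
  mr <- matrix(rpois(4 * 20, 2) * rbinom(80, 1, 0.5), nrow = 4,
               dimnames = list(c("Mrgpra3", "Nmb", "Tac1", "Calca"),
                               sprintf("c%02d", 1:20)))
  x <- umi_from_dense(mr)
  markers <- rownames(mr)
  v <- marker_venn(x, markers, scale = "counts")
  calls <- positivity_calls(x, markers, scale = "counts")
  for (i in seq_len(nrow(v))) {
    want <- unlist(v[i, markers])
    oracle <- sum(apply(calls, 1, function(row) all(row == want)))
    expect_equal(v$n[i], oracle)
  }
  expect_equal(sum(v$n), sum(rowSums(calls) > 0))
})
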