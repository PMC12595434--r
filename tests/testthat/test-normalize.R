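test_that("scaling factors follow the within-condition mean rule", {
  m <- data.frame(run_id = c("a", "b", "c"), condition = "x",
                  replicate = 1:3, temperature = c(40, 50, 60),
                  is_reference = FALSE,
                  precursor_count = c(100000L, 120000L, 80000L))
  sf <- compute_scaling_factors(m)
  expect_equal(sf$factor, c(1.0, 1.2, 0.8))
  expect_equal(compute_scaling_factors(m, invert = TRUE)$factor,
               1 / c(1.0, 1.2, 0.8))
})

test_that("single-run conditions get factor 1 and references stay at 1", {
  m <- make_manifest(conditions = "only", n_replicates = 1)
  m$precursor_count <- c(rep(77777L, 10), 12345L)
  sf <- compute_scaling_factors(m)
  expect_equal(sf$factor, rep(1, 11))
})

test_that("scaling-factor mean is 1 per condition on random input", {
  set.seed(21)
  for (trial in 1:10) {
    m <- make_manifest(n_replicates = sample(2:4, 1))
    m$precursor_count <- as.integer(round(runif(nrow(m), 2e4, 8e4)))
    sf <- compute_scaling_factors(m)
    for (cond in unique(m$condition)) {
      denat <- !m$is_reference & m$condition == cond
      expect_equal(mean(sf$factor[sf$run_id %in% m$run_id[denat]]), 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("zero precursor counts are an error", {
  m <- make_manifest(conditions = "x", n_replicates = 1)
  m$precursor_count[2] <- 0L
  expect_error(compute_scaling_factors(m), "zero precursor")
})

test_that("apply_scaling multiplies elementwise and keeps missingness", {
  m <- make_manifest(conditions = "x", n_replicates = 1)
  m$precursor_count <- as.integer(c(seq(40000, 85000, by = 5000), 50000))
  set.seed(3)
  ab <- matrix(runif(4 * nrow(m), 1, 100), nrow = 4,
               dimnames = list(sprintf("P%d", 1:4), m$run_id))
  ab[2, 5] <- NA
  tab <- make_table(ab, m)
  sf <- compute_scaling_factors(m)
  out <- apply_scaling(tab, sf)
  expect_equal(table_stage(out), "scaled")
  for (j in seq_len(nrow(m))) {
    f <- sf$factor[sf$run_id == m$run_id[j]]
    expect_equal(out[[m$run_id[j]]], unname(ab[, j] * f))
  }
  expect_true(is.na(out[[m$run_id[5]]][2]))
  ## factor 1 everywhere is the identity
  m1 <- m; m1$precursor_count <- 60000L
  out1 <- apply_scaling(tab, compute_scaling_factors(m1))
  expect_equal(as.data.frame(out1), as.data.frame(tab),
               ignore_attr = TRUE)
})

test_that("scaling with uncovered runs is an error", {
  m <- make_manifest(conditions = "x", n_replicates = 1)
  ab <- matrix(1, 2, nrow(m), dimnames = list(c("A", "B"), m$run_id))
  tab <- make_table(ab, m)
  sf <- compute_scaling_factors(m)
  expect_error(apply_scaling(tab, sf[-1, ]), "no scaling factor")
})

test_that("median normalization divides by the per-condition median", {
  m <- make_manifest(conditions = "x", n_replicates = 1,
                     ladder = c(40, 50, 60))
  ab <- matrix(c(2, 4, 8, 10), nrow = 1,
               dimnames = list("P1", m$run_id))
  tab <- make_table(ab, m)
  out <- median_normalize_by_protein(as_protein_table(
    as.data.frame(tab), "scaled"), m)
  ## denaturation values [2,4,8], median 4; reference (10) also divided
  expect_equal(as.numeric(out[1, m$run_id]), c(0.5, 1, 2, 2.5))
  expect_equal(table_stage(out), "median_normalized")
})

test_that("per-protein per-condition median is 1 after normalization", {
  set.seed(13)
  m <- make_manifest()
  ab <- matrix(exp(rnorm(25 * nrow(m), 3, 1)), nrow = 25,
               dimnames = list(sprintf("P%02d", 1:25), m$run_id))
  ab[runif(length(ab)) < 0.05] <- NA
  tab <- as_protein_table(as.data.frame(make_table(ab, m)), "scaled")
  out <- median_normalize_by_protein(tab, m)
  for (cond in unique(m$condition)) {
    denat <- m$run_id[m$condition == cond & !m$is_reference]
    med <- apply(as.matrix(out[, denat]), 1, median, na.rm = TRUE)
    expect_equal(unname(med), rep(1, 25), tolerance = 1e-12)
  }
  ## missingness pattern unchanged
  expect_equal(is.na(as.matrix(out[, m$run_id])),
               is.na(ab), ignore_attr = TRUE)
})

test_that("all-equal values normalize to all 1", {
  m <- make_manifest(conditions = "x", n_replicates = 2)
  ab <- matrix(7, nrow = 2, ncol = nrow(m),
               dimnames = list(c("A", "B"), m$run_id))
  tab <- as_protein_table(as.data.frame(make_table(ab, m)), "scaled")
  out <- median_normalize_by_protein(tab, m)
  expect_true(all(as.matrix(out[, m$run_id]) == 1))
})

test_that("reference normalization divides by the reference median", {
  ladder <- c(40, 50, 60)
  rows <- data.frame(
    run_id = c("T1", "T2", "T3", "R1", "R2", "R3"),
    condition = "x", replicate = c(1, 1, 1, 1, 2, 3),
    temperature = c(ladder, NA, NA, NA),
    is_reference = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    precursor_count = 50000L)
  ab <- matrix(c(6, 3, 1.5, 2, 2, 4,   # P1: ref median 2
                 10, 5, 2.5, NA, NA, NA), # P2: no ref values
               nrow = 2, byrow = TRUE,
               dimnames = list(c("P1", "P2"), rows$run_id))
  tab <- as_protein_table(as.data.frame(make_table(ab, rows)),
                          "median_normalized")
  out <- reference_normalize(tab, rows)
  expect_equal(as.numeric(out[1, c("T1", "T2", "T3")]), c(3, 1.5, 0.75))
  ## fallback divisor: median over per-protein ref medians = median({2}) = 2
  expect_equal(as.numeric(out[2, c("T1", "T2", "T3")]), c(5, 2.5, 1.25))
  expect_equal(attr(out, "audit")$x$n_fallback_proteins, 1L)
})

test_that("fallback divisor is the median of per-protein ref medians", {
  rows <- data.frame(
    run_id = c("T1", "R1"), condition = "x", replicate = 1,
    temperature = c(45, NA), is_reference = c(FALSE, TRUE),
    precursor_count = 50000L)
  ab <- matrix(c(10, 2,
                 10, 8,
                 10, NA), nrow = 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), rows$run_id))
  tab <- as_protein_table(as.data.frame(make_table(ab, rows)),
                          "median_normalized")
  out <- reference_normalize(tab, rows)
  ## per-protein ref medians {2, 8}; median = 5 is C's divisor
  expect_equal(out$T1, c(5, 1.25, 2))
})

test_that("reference-run values have per-protein median 1 afterwards", {
  set.seed(31)
  m <- make_manifest()
  ab <- matrix(exp(rnorm(20 * nrow(m))), nrow = 20,
               dimnames = list(sprintf("P%02d", 1:20), m$run_id))
  tab <- as_protein_table(as.data.frame(make_table(ab, m)),
                          "median_normalized")
  out <- reference_normalize(tab, m)
  for (cond in unique(m$condition)) {
    refs <- m$run_id[m$condition == cond & m$is_reference]
    med <- apply(as.matrix(out[, refs]), 1, median)
    expect_equal(unname(med), rep(1, 20), tolerance = 1e-12)
  }
})

test_that("a condition without references is an error", {
  m <- make_manifest(conditions = "x", n_replicates = 1)
  m2 <- m[!m$is_reference, ]
  ab <- matrix(1, 1, nrow(m2), dimnames = list("P1", m2$run_id))
  tab <- as_protein_table(as.data.frame(make_table(ab, m2)),
                          "median_normalized")
  expect_error(reference_normalize(tab, m2), "no reference run")
})

test_that("missing-pattern filter implements the rescue clause", {
  m <- make_manifest(conditions = "x", n_replicates = 1)
  runs <- run_ids_for(m, "x", 1)
  ab <- matrix(0.8, nrow = 4, ncol = nrow(m),
               dimnames = list(c("high4", "low4", "miss3", "full"),
                               m$run_id))
  ab["high4", runs[7:10]] <- NA   # 4 missing, all in the top half -> kept
  ab["low4", runs[c(3, 8, 9, 10)]] <- NA  # 4 missing incl. a low temp -> drop
  ab["miss3", runs[c(1, 5, 9)]] <- NA     # 3 missing anywhere -> kept
  tab <- as_protein_table(as.data.frame(make_table(ab, m)),
                          "reference_normalized")
  out <- filter_missing_pattern(tab, m)
  expect_equal(table_stage(out), "filtered")
  dropped <- attr(out, "dropped_curves")
  expect_equal(dropped$protein_id, "low4")
  expect_true(all(is.na(as.matrix(out[out$protein_id == "low4", runs]))))
  expect_equal(sum(is.na(out[out$protein_id == "high4", runs])), 4L)
  expect_equal(sum(is.na(out[out$protein_id == "miss3", runs])), 3L)
})

test_that("missing filter agrees with a brute-force row scan", {
  set.seed(99)
  m <- make_manifest()
  for (trial in 1:4) {
    n <- 40
    ab <- matrix(runif(n * nrow(m), 0.1, 1), nrow = n,
                 dimnames = list(sprintf("P%02d", 1:n), m$run_id))
    ab[runif(length(ab)) < 0.25] <- NA
    tab <- as_protein_table(as.data.frame(make_table(ab, m)),
                            "reference_normalized")
    out <- filter_missing_pattern(tab, m)
    dropped <- attr(out, "dropped_curves")
    for (cond in unique(m$condition)) {
      for (r in unique(m$replicate)) {
        runs <- run_ids_for(m, cond, r)
        low5 <- runs[1:5]
        for (i in seq_len(n)) {
          n_miss <- sum(is.na(ab[i, runs]))
          low_ok <- !anyNA(ab[i, low5])
          should_drop <- n_miss > 3 && !low_ok
          was_dropped <- any(dropped$protein_id == rownames(ab)[i] &
                               dropped$condition == cond &
                               dropped$replicate == r)
          expect_equal(was_dropped, should_drop)
        }
      }
    }
  }
})

test_that("pipeline stages refuse out-of-order input", {
  m <- make_manifest(conditions = "x", n_replicates = 1)
  ab <- matrix(1, 1, nrow(m), dimnames = list("P1", m$run_id))
  raw <- make_table(ab, m)
  expect_error(median_normalize_by_protein(raw, m), "stage")
  expect_error(reference_normalize(raw, m), "stage")
  expect_error(filter_missing_pattern(raw, m), "stage")
  scaled <- apply_scaling(raw, compute_scaling_factors(m))
  expect_error(apply_scaling(scaled, compute_scaling_factors(m)), "stage")
})

test_that("full normalization recovers the analytic curve when noiseless", {
  cfg <- sim_config(n_proteins = 15, n_spiked = 3, noise_sd = 0,
                    missing_rate = 0, n_contaminants = 0,
                    low_peptide_rate = 0, seed = 17)
  sim <- simulate_melt_dataset(cfg)
  sim$manifest$precursor_count <- 50000L  # equal sequencing depth
  tab <- as_protein_table(sim$report)
  norm <- normalize_melt_table(tab, sim$manifest)
  for (cond in cfg$conditions) {
    tm_true <- sim$truth[[paste0("tm_", cond)]]
    for (r in seq_len(cfg$n_replicates)) {
      runs <- run_ids_for(sim$manifest, cond, r)
      got <- as.matrix(norm[, runs])
      want <- t(vapply(seq_len(nrow(norm)), function(i)
        melt_curve_model(cfg$ladder, tm_true[i], sim$truth$slope[i],
                         sim$truth$plateau[i]),
        numeric(length(cfg$ladder))))
      expect_lt(max(abs(got - want)), 1e-9)
    }
  }
})
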