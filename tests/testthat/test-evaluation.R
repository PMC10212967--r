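test_that("compare_to_truth is exact set arithmetic", {
  v <- key_pool(4)
  expect_equal(compare_to_truth(v[c(1, 3)], v[c(1, 2)]),
               c(tp = 1L, fp = 1L, fn = 1L))
  expect_equal(compare_to_truth(v, v), c(tp = 4L, fp = 0L, fn = 0L))
  expect_equal(compare_to_truth(character(0), v),
               c(tp = 0L, fp = 0L, fn = 4L))
  # CallSet inputs and the accounting identities
  acc <- mock_callset("a", v[1:3])
  tr <- mock_callset("t", v[2:4])
  cmp <- compare_to_truth(acc, tr)
  expect_equal(cmp[["tp"]] + cmp[["fn"]], 3L)
  expect_equal(cmp[["tp"]] + cmp[["fp"]], 3L)
})

test_that("compute_metrics matches the independent oracle", {
  got <- compute_metrics(8, 2, 2)
  expect_equal(got$precision, 0.8)
  expect_equal(got$sensitivity, 0.8)
  expect_equal(got$f1, 0.8)

  expect_equal(unlist(compute_metrics(0, 5, 5)[c("precision", "sensitivity", "f1")]),
               c(precision = 0, sensitivity = 0, f1 = 0))
  expect_equal(compute_metrics(10, 0, 0)$f1, 1)
  expect_equal(compute_metrics(0, 0, 0)$f1, 0)   # zero-denominator convention

  set.seed(5)
  for (i in 1:100) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    got <- compute_metrics(tp, fp, fn)
    exp <- oracle_metrics(tp, fp, fn)
    expect_equal(c(precision = got$precision, sensitivity = got$sensitivity,
                   f1 = got$f1), exp)
    # F1 bounds that do hold
    expect_lte(got$f1, 2 * min(got$precision, got$sensitivity) + 1e-12)
    expect_lte(got$f1, max(got$precision, got$sensitivity) + 1e-12)
  }
  expect_error(compute_metrics(-1, 0, 0), class = "cvc_config_error")
})

test_that("threshold_sweep equals the combine/compare/compute composition", {
  set.seed(31)
  pool <- key_pool(120)
  truth_keys <- sample(pool, 60)
  callsets <- lapply(1:3, function(i) {
    mock_callset(paste0("c", i),
                 unique(c(sample(truth_keys, 50), sample(pool, 15))))
  })
  truth <- mock_callset("truth", truth_keys)
  sw <- threshold_sweep(callsets, truth)
  expect_equal(nrow(sw), 12L)  # 3 + 3*2 + ... = sum m*choose(3,m)
  for (i in seq_len(nrow(sw))) {
    row <- sw[i]
    sub <- callsets[match(strsplit(row$subset, "+", fixed = TRUE)[[1]],
                          vapply(callsets, `[[`, "", "caller_id"))]
    ct <- combine_at_threshold(sub, row$k)
    cmp <- compare_to_truth(ct$accepted, truth_keys)
    met <- compute_metrics(cmp[["tp"]], cmp[["fp"]], cmp[["fn"]])
    expect_equal(row$tp, met$tp)
    expect_equal(row$f1, met$f1)
    expect_equal(row$tp + row$fn, length(truth_keys))
  }

  # single perfect caller
  one <- threshold_sweep(list(mock_callset("solo", truth_keys)), truth)
  expect_equal(nrow(one), 1L)
  expect_equal(one$f1, 1)

  # duplicate callsets: f1 identical across k within the full subset
  dup <- lapply(1:3, function(i) mock_callset(paste0("d", i), callset_keys(callsets[[1]])))
  sw_dup <- threshold_sweep(dup, truth)
  full <- sw_dup[m == 3]
  expect_equal(length(unique(full$f1)), 1L)
})

test_that("sweep is monotone in k: sensitivity and FPs never increase", {
  set.seed(77)
  for (i in 1:10) {
    pool <- key_pool(100)
    truth_keys <- sample(pool, 40)
    callsets <- random_collection(4L, 60L, pool = pool)
    sw <- threshold_sweep(callsets, mock_callset("t", truth_keys))
    by_sub <- split(sw, sw$subset)
    for (tbl in by_sub) {
      tbl <- tbl[order(tbl$k)]
      expect_true(all(diff(tbl$sensitivity) <= 1e-12))
      expect_true(all(diff(tbl$fp) <= 0L))
    }
  }
})

test_that("sweep_summary reports medians, maxima and conservative argmax", {
  sw <- data.table::as.data.table(list(
    subset = c("a", "a", "a", "b"), m = c(3L, 3L, 3L, 1L), k = c(1L, 2L, 3L, 1L),
    variant_class = "SNV", tp = 1L, fp = 1L, fn = 1L,
    precision = 0.5, sensitivity = 0.5, f1 = c(0.4, 0.9, 0.9, 0.7)))
  smry <- sweep_summary(sw)
  expect_equal(smry$by_threshold[m == 3 & k == 2]$median_f1, 0.9)
  # tie at f1 = 0.9 between k = 2 and k = 3: largest k wins
  expect_equal(smry$best_k[subset == "a"]$k_best, 3L)
  expect_equal(smry$best_k[subset == "b"]$f1_best, 0.7)
})

test_that("noise_table counts accepted noise per sample and threshold", {
  v <- key_pool(12)
  # 2 samples x 3 callers, disjoint noise in sample s1, one shared key in s2
  samples <- list(
    s1 = list(a = mock_callset("a", v[1]), b = mock_callset("b", v[2]),
              c = mock_callset("c", v[3])),
    s2 = list(a = mock_callset("a", v[4:5]), b = mock_callset("b", v[4]),
              c = mock_callset("c", v[4])))
  nt <- noise_table(samples)
  counts <- nt$counts
  expect_equal(counts[counts$sample == "s1" & counts$k == 1]$n_noise, 3L)
  expect_equal(counts[counts$sample == "s1" & counts$k == 2]$n_noise, 0L)
  expect_equal(counts[counts$sample == "s2"]$n_noise, c(2L, 1L, 1L))
  # non-increasing in k for every sample
  for (s in unique(counts$sample)) {
    expect_true(all(diff(counts[counts$sample == s][order(k)]$n_noise) <= 0))
  }
  # drop-caller mode: auto picks the caller with most noise ("a" here)
  nt2 <- noise_table(samples, drop_caller = "auto")
  expect_equal(nt2$dropped_caller, "a")
  expect_equal(nrow(nt2$counts_dropped), 2L * 2L)
  expect_true(all(nt2$additional[rel == 0]$additional >= 0L))
  # inconsistent rosters across samples
  bad <- samples
  bad$s2 <- bad$s2[c("a", "b")]
  expect_error(noise_table(bad), class = "cvc_config_error")
})
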