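# Truth comparison and benchmarking: precision TP/(TP+FP), sensitivity
# TP/(TP+FN), and their harmonic mean F1, for every caller subset at every
# minimum intersection threshold; plus the germline noise table for
# amplicon panels.

#' Compare accepted keys against a truth set
#'
#' Pure set arithmetic on normalized keys: `tp = |accepted n truth|`,
#' `fp = |accepted \\ truth|`, `fn = |truth \\ accepted|`. Both sides must
#' have been normalized with the same settings.
#'
#' @param accepted character vector of accepted keys (or a `CallSet`).
#' @param truth character vector of truth keys (or a `CallSet`).
#' @return named integer vector with elements `tp`, `fp`, `fn`.
#' @export
compare_to_truth <- function(accepted, truth) {
  if (inherits(accepted, "CallSet")) accepted <- callset_keys(accepted)
  if (inherits(truth, "CallSet")) truth <- callset_keys(truth)
  accepted <- unique(accepted)
  truth <- unique(truth)
  tp <- sum(accepted %in% truth)
  c(tp = tp, fp = length(accepted) - tp, fn = length(truth) - tp)
}

#' Precision, sensitivity and F1 from confusion counts
#'
#' `precision = tp/(tp+fp)`, `sensitivity = tp/(tp+fn)`, `f1` their
#' harmonic mean. Zero-denominator convention: a ratio whose denominator is
#' zero is 0, and `f1 = 0` when either component is 0 (the undefined cases
#' never arise on non-empty truth sets with non-empty acceptance; the
#' convention just makes degenerate rows well-defined).
#'
#' @param tp,fp,fn non-negative integer counts (vectorized).
#' @return a `data.frame` with columns `tp`, `fp`, `fn`, `precision`,
#'   `sensitivity`, `f1`.
#' @export
#' @examples
#' compute_metrics(8, 2, 2)   # precision = sensitivity = f1 = 0.8
compute_metrics <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0) || anyNA(c(tp, fp, fn))) {
    stop_config("tp, fp, fn must be non-negative")
  }
  n <- max(length(tp), length(fp), length(fn))
  tp <- rep_len(tp, n); fp <- rep_len(fp, n); fn <- rep_len(fn, n)
  precision <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  sensitivity <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(precision == 0 | sensitivity == 0, 0,
               2 * precision * sensitivity / (precision + sensitivity))
  data.frame(tp = tp, fp = fp, fn = fn, precision = precision,
             sensitivity = sensitivity, f1 = f1)
}

#' Evaluate a consensus (or single callset) against truth
#'
#' @param accepted accepted keys, `CallSet`, or `ConsensusTable`.
#' @param truth truth keys or `CallSet`.
#' @return one-row metrics `data.frame` as from [compute_metrics()].
#' @export
evaluate_consensus <- function(accepted, truth) {
  if (inherits(accepted, "ConsensusTable")) accepted <- accepted$accepted
  cmp <- compare_to_truth(accepted, truth)
  compute_metrics(cmp[["tp"]], cmp[["fp"]], cmp[["fn"]])
}

keys_by_class <- function(cs, class) {
  v <- cs$variants
  v$key[v$variant_class == class]
}

#' Sweep every caller subset at every threshold
#'
#' For every non-empty subset of the roster and every threshold under the
#' chosen rule (see [enumerate_combinations()]), combines the subset,
#' compares to truth, and computes metrics — separately for SNVs and
#' indels, which are treated as distinct problems throughout. Each row
#' equals an independent recomputation via the
#' combine/compare/compute chain.
#'
#' @param callsets list of [callset()]s.
#' @param truth a truth `CallSet` (its `variant_class` column drives the
#'   per-class split) or character vector of keys (single class `"ALL"`).
#' @param rule threshold rule, `"full"` (default) or `"methods"`.
#' @param classes variant classes to sweep; default: the classes present
#'   in the truth set.
#' @param allow_large combinatorial guard override.
#' @return a `data.table` with one row per (subset, k, class): columns
#'   `subset` (caller ids joined by `+`), `m`, `k`, `variant_class`, `tp`,
#'   `fp`, `fn`, `precision`, `sensitivity`, `f1`.
#' @export
threshold_sweep <- function(callsets, truth, rule = c("full", "methods"),
                            classes = NULL, allow_large = FALSE) {
  rule <- match.arg(rule)
  callsets <- callset_list(callsets)
  by_class <- inherits(truth, "CallSet")
  if (by_class) {
    classes <- classes %||% sort(unique(truth$variants$variant_class))
    if (length(classes) == 0L) stop_config("truth set is empty")
  } else {
    if (length(truth) == 0L) stop_config("truth set is empty")
    classes <- "ALL"
  }

  rows <- list()
  for (cl in classes) {
    truth_keys <- if (by_class) keys_by_class(truth, cl) else unique(truth)
    if (length(truth_keys) == 0L) next
    # roster for this class: callers contributing at least one such variant
    key_sets <- lapply(callsets, function(cs) {
      if (by_class) keys_by_class(cs, cl) else callset_keys(cs)
    })
    key_sets <- key_sets[lengths(key_sets) > 0L]
    if (length(key_sets) == 0L) next
    roster <- names(key_sets)
    combos <- enumerate_combinations(roster, rule = rule,
                                     allow_large = allow_large)
    # group thresholds per subset so support counts are computed once
    subset_ids <- vapply(combos, function(x) paste(x$callers, collapse = "+"),
                         character(1))
    for (sid in unique(subset_ids)) {
      idx <- which(subset_ids == sid)
      sub_callers <- combos[[idx[1L]]]$callers
      tab <- table(unlist(key_sets[sub_callers], use.names = FALSE))
      support <- as.integer(tab)
      is_true <- names(tab) %in% truth_keys
      n_truth <- length(unique(truth_keys))
      for (i in idx) {
        k <- combos[[i]]$k
        acc <- support >= k
        tp <- sum(acc & is_true)
        fp <- sum(acc & !is_true)
        fn <- n_truth - tp
        rows[[length(rows) + 1L]] <- data.table::data.table(
          subset = sid, m = length(sub_callers), k = k, variant_class = cl,
          tp = tp, fp = fp, fn = fn)
      }
    }
  }
  if (length(rows) == 0L) stop_config("no callset contributes variants of the requested classes")
  out <- data.table::rbindlist(rows)
  out <- cbind(out[, .(subset, m, k, variant_class)],
               compute_metrics(out$tp, out$fp, out$fn))
  data.table::setDT(out)
  data.table::setorder(out, variant_class, m, subset, k)
  out[]
}

#' Summarize a threshold sweep
#'
#' Per-(class, subset size, threshold) median and maximum F1, plus each
#' subset's F1-maximizing threshold (ties broken toward the largest k, the
#' most conservative acceptance). The relative threshold `n - k` is
#' reported alongside so "accept n-1 of n" patterns can be read directly.
#'
#' @param sweep a sweep table from [threshold_sweep()].
#' @return list with `by_threshold` (median/max F1 per class, m, k) and
#'   `best_k` (one row per class and subset: `k_best`, `f1_best`).
#' @export
sweep_summary <- function(sweep) {
  sweep <- data.table::as.data.table(sweep)
  by_threshold <- sweep[, .(median_f1 = stats::median(f1), max_f1 = max(f1),
                            n_subsets = .N),
                        by = .(variant_class, m, k)]
  by_threshold[, rel := m - k]
  data.table::setorder(by_threshold, variant_class, m, k)
  best_k <- sweep[order(-f1, -k), .SD[1L], by = .(variant_class, subset, m)][
    , .(variant_class, subset, m, k_best = k, f1_best = f1)]
  data.table::setorder(best_k, variant_class, m, subset)
  list(by_threshold = by_threshold[], best_k = best_k[])
}

#' Germline noise counts per sample and threshold
#'
#' For each germline sample, combines the per-caller noise callsets (the
#' `noise` side of [germline_noise_partition()]) and counts accepted noise
#' keys at every minimum intersection threshold `k = 1..n`. Optionally
#' recomputes with one caller removed and reports the additional counts at
#' matched relative thresholds (`n` vs `n-1` callers at the same `n - k`),
#' the "drop the noisiest caller" comparison.
#'
#' @param samples named list: sample id -> named list of per-caller noise
#'   [callset()]s. Caller rosters must be identical across samples.
#' @param drop_caller `NULL` (no drop mode), a caller id, or `"auto"` to
#'   drop the caller with the highest total noise count across samples (a
#'   heuristic; the choice is reported in the result).
#' @return list with `counts` (a `data.table` sample x k: columns `sample`,
#'   `k`, `rel` = n-k label, `n_noise`), and when dropping:
#'   `counts_dropped`, `additional` (dropped-roster counts minus full-roster
#'   counts at equal relative threshold) and `dropped_caller`.
#' @export
noise_table <- function(samples, drop_caller = NULL) {
  if (length(samples) == 0L) stop_config("no samples supplied")
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    stop_config("samples must be a named list")
  }
  rosters <- lapply(samples, function(s) sort(names(s)))
  if (length(unique(rosters)) != 1L) {
    stop_config("caller rosters differ across samples")
  }
  roster <- names(samples[[1L]])
  n <- length(roster)

  count_one <- function(callsets) {
    supp <- support_table(callset_list(callsets))$n_support
    vapply(seq_len(n2 <- length(callsets)), function(k) sum(supp >= k), integer(1))
  }
  counts <- data.table::rbindlist(lapply(names(samples), function(sid) {
    cnt <- count_one(samples[[sid]])
    data.table::data.table(sample = sid, k = seq_len(n), rel = n - seq_len(n),
                           n_noise = cnt)
  }))
  out <- list(counts = counts)

  if (!is.null(drop_caller)) {
    if (identical(drop_caller, "auto")) {
      totals <- vapply(roster, function(id) {
        sum(vapply(samples, function(s) nrow(s[[id]]$variants), integer(1)))
      }, numeric(1))
      drop_caller <- roster[which.max(totals)]
    }
    if (!drop_caller %in% roster) {
      stop_config(sprintf("drop_caller '%s' not in roster", drop_caller))
    }
    reduced <- lapply(samples, function(s) s[setdiff(roster, drop_caller)])
    counts2 <- data.table::rbindlist(lapply(names(reduced), function(sid) {
      cnt <- count_one(reduced[[sid]])
      m <- n - 1L
      data.table::data.table(sample = sid, k = seq_len(m), rel = m - seq_len(m),
                             n_noise = cnt)
    }))
    merged <- merge(counts2, counts, by = c("sample", "rel"),
                    suffixes = c("_dropped", "_full"))
    merged[, additional := n_noise_dropped - n_noise_full]
    out$counts_dropped <- counts2
    out$additional <- merged[, .(sample, rel, k_dropped, k_full,
                                 additional)]
    out$dropped_caller <- drop_caller
  }
  out
}
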