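# k-of-n minimum-intersection consensus.
#
# A variant is accepted by an ensemble of n callers at minimum intersection
# threshold k when at least k of the callsets contain its normalized key.
# k = 1 is the union, k = n the full intersection; the recommended default
# is k = n-1 for SNVs (keep positives missed by at most one caller) and
# k = n for indel pairs.

#' Resolve a threshold specification against a roster size
#'
#' Accepts an integer or the symbolic forms `"n"`, `"n-1"`, `"n-2"`, ...
#' and `"majority"` (strict majority, `floor(n/2) + 1`). Symbolic forms
#' resolve once the roster size is known; results are clamped to at least
#' 1 (so `"n-1"` with a single caller means `k = 1`).
#'
#' @param spec integer or symbolic string.
#' @param n roster size.
#' @return integer threshold in `1..n`.
#' @export
#' @examples
#' resolve_threshold("n-1", 6)     # 5
#' resolve_threshold("majority", 6) # 4
resolve_threshold <- function(spec, n) {
  if (!is_count1(n) || n < 1L) stop_config("roster size n must be >= 1")
  symbolic <- FALSE
  k <- if (is.numeric(spec)) {
    spec
  } else if (is_string1(spec)) {
    if (grepl("^[0-9]+$", spec)) {
      as.integer(spec)
    } else if (spec == "majority") {
      symbolic <- TRUE
      n %/% 2L + 1L
    } else if (grepl("^n(-[0-9]+)?$", spec)) {
      symbolic <- TRUE
      n - abs(as.integer(sub("^n", "", sub("^n$", "n-0", spec))))
    } else {
      stop_config(sprintf("cannot parse threshold '%s'", spec))
    }
  } else {
    stop_config("threshold must be an integer or a symbolic string")
  }
  if (symbolic) k <- max(1L, k)  # n-1 with one caller degenerates to k=1
  k <- as.integer(k)
  if (k < 1L || k > n) {
    stop_config(sprintf("threshold k=%d out of range for n=%d callers", k, n))
  }
  k
}

callset_list <- function(callsets) {
  if (inherits(callsets, "CallSet")) callsets <- list(callsets)
  if (length(callsets) == 0L) stop_config("need at least one callset")
  if (!all(vapply(callsets, inherits, logical(1), "CallSet"))) {
    stop_config("all inputs must be CallSet objects")
  }
  ids <- vapply(callsets, `[[`, character(1), "caller_id")
  if (anyDuplicated(ids)) {
    stop_config(sprintf("duplicate caller ids: %s",
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  names(callsets) <- ids
  callsets
}

support_table <- function(callsets) {
  roster <- names(callsets)
  per <- lapply(roster, function(id) {
    v <- callsets[[id]]$variants
    data.table::as.data.table(list(key = v$key, chrom = v$chrom, pos = v$pos,
                                   ref = v$ref, alt = v$alt,
                                   variant_class = v$variant_class,
                                   caller = rep(id, nrow(v)), vaf = v$vaf))
  })
  all <- data.table::rbindlist(per)
  if (nrow(all) == 0L) {
    return(data.table::as.data.table(list(
      key = character(0), chrom = character(0), pos = integer(0),
      ref = character(0), alt = character(0), variant_class = character(0),
      n_support = integer(0), callers = character(0), vafs = list())))
  }
  all[, caller := factor(caller, levels = roster)]
  data.table::setorder(all, key, caller)
  supp <- all[, .(
    chrom = chrom[1L], pos = pos[1L], ref = ref[1L], alt = alt[1L],
    variant_class = variant_class[1L],
    n_support = .N,
    callers = paste(as.character(caller), collapse = ","),
    vafs = list(vaf)
  ), by = "key"]
  data.table::setorder(supp, chrom, pos, ref, alt)
  supp
}

#' Combine callsets at a minimum intersection threshold
#'
#' Counts, for every normalized variant key, how many callsets contain it,
#' and accepts the keys supported by at least `k` callers. Deterministic
#' regardless of callset order (support and output ordering depend only on
#' the roster and the keys).
#'
#' @param callsets list of [callset()]s with distinct `caller_id`s.
#' @param k minimum intersection threshold: an integer in `1..n` or a
#'   symbolic form understood by [resolve_threshold()].
#' @return an object of class `ConsensusTable`: list with `roster`,
#'   `support` (a `data.table` with one row per key: `n_support`,
#'   supporting `callers`, per-caller `vafs`), `k`, `accepted` (character
#'   vector of accepted keys) and `contigs` (first-seen contig order).
#' @export
#' @examples
#' a <- callset("a", data.frame(chrom = "c", pos = c(1, 2), ref = "A", alt = "G"))
#' b <- callset("b", data.frame(chrom = "c", pos = c(1, 3), ref = "A", alt = "G"))
#' combine_at_threshold(list(a, b), k = 2)$accepted
combine_at_threshold <- function(callsets, k) {
  callsets <- callset_list(callsets)
  n <- length(callsets)
  k <- resolve_threshold(k, n)
  supp <- support_table(callsets)
  contigs <- unique(unlist(lapply(callsets, function(cs) {
    c(attr(cs, "contigs") %||% character(0), unique(cs$variants$chrom))
  }), use.names = FALSE))
  structure(
    list(roster = names(callsets), support = supp, k = k,
         accepted = supp$key[supp$n_support >= k], contigs = contigs),
    class = "ConsensusTable")
}

#' @export
print.ConsensusTable <- function(x, ...) {
  cat(sprintf("ConsensusTable: %d callers (%s), k=%d\n",
              length(x$roster), paste(x$roster, collapse = ", "), x$k))
  cat(sprintf("  %d distinct keys, %d accepted at k=%d\n",
              nrow(x$support), length(x$accepted), x$k))
  invisible(x)
}

#' Histogram of caller support counts
#'
#' Tallies, over the union of keys, how many keys are called by exactly
#' 1, 2, ..., n callers. The tallies sum to the size of the union.
#'
#' @param callsets list of [callset()]s.
#' @param class optional variant class restriction (`"SNV"`, `"INDEL"`).
#' @return named integer vector over support counts `1..n` (zeros kept).
#' @export
support_histogram <- function(callsets, class = NULL) {
  callsets <- callset_list(callsets)
  if (!is.null(class)) {
    callsets <- lapply(callsets, function(cs) {
      callset_replace(cs, cs$variants[cs$variants$variant_class %in% class])
    })
  }
  n <- length(callsets)
  supp <- support_table(callsets)
  counts <- tabulate(supp$n_support, nbins = n)
  stats::setNames(as.integer(counts), as.character(seq_len(n)))
}

#' Enumerate caller subsets and thresholds
#'
#' Produces every non-empty subset of the roster, paired with every
#' threshold under the chosen rule, in deterministic order (subsets by
#' size, then lexicographic in roster order).
#'
#' The `"full"` rule sweeps k = 1..m for a subset of size m. The
#' `"methods"` rule sweeps k = 2..m (singletons at k = 1), the narrower
#' range the text of the source protocol states; the full rule matches the
#' reported sweeps, which extend down to k = 1, and is the default.
#'
#' @param roster character vector of caller ids.
#' @param rule `"full"` or `"methods"`.
#' @param allow_large allow rosters larger than 12 callers (combinatorial
#'   guard; 12 callers already mean 4095 subsets).
#' @return list of elements `list(callers, k)`.
#' @export
#' @examples
#' length(enumerate_combinations(letters[1:3]))  # 12 (subset, k) pairs
enumerate_combinations <- function(roster, rule = c("full", "methods"),
                                   allow_large = FALSE) {
  rule <- match.arg(rule)
  if (length(roster) == 0L) stop_config("roster must be non-empty")
  if (anyDuplicated(roster)) stop_config("duplicate caller ids in roster")
  if (length(roster) > 12L && !allow_large) {
    stop_config("roster has more than 12 callers; pass allow_large=TRUE to proceed")
  }
  per_size <- lapply(seq_along(roster), function(m) {
    subsets <- utils::combn(roster, m, simplify = FALSE)
    ks <- if (rule == "full" || m == 1L) seq_len(m) else 2:m
    unlist(lapply(subsets, function(sub) {
      lapply(ks, function(k) list(callers = sub, k = as.integer(k)))
    }), recursive = FALSE)
  })
  unlist(per_size, recursive = FALSE)
}
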