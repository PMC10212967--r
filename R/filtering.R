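# Record-retention rules applied before and around consensus:
#  * a low-stringency pre-filter per caller (FILTER is PASS or ".",
#    ALT depth > 3, VAF > 0.02 — strict, low on purpose: it removes random
#    stochastic noise while keeping each caller's systematic false
#    positives for the consensus vote to handle),
#  * a candidate filter for exome tumor/normal screening,
#  * germline VAF-window partitioning for amplicon panels (true germline
#    allele frequencies can only be ~0.5 or ~1.0, so calls outside
#    [0.4,0.6] u [0.9,1.0] are noise),
#  * callset subtraction (germline/shared-noise removal from somatic calls).

GERMLINE_HET_WINDOW <- c(0.4, 0.6)
GERMLINE_HOM_WINDOW <- c(0.9, 1.0)

#' Construct a retention filter policy
#'
#' Defaults are the low-stringency retention rule: keep a record iff its
#' FILTER value is `"PASS"` or `"."`, its ALT-supporting read count is
#' strictly greater than 3, and its VAF is strictly greater than 0.02.
#' Records whose support fields could not be extracted ("unknown") are
#' retained by default — the filter is deliberately permissive — but can be
#' dropped via `unknown_support`.
#'
#' @param allowed_filter FILTER strings that pass.
#' @param min_alt_depth exclusive ALT-depth threshold (keep if
#'   `alt_depth > min_alt_depth`).
#' @param min_vaf exclusive VAF threshold (keep if `vaf > min_vaf`), in
#'   `[0, 1)`.
#' @param unknown_support `"retain"` or `"drop"`: what to do with records
#'   whose `alt_depth`/`vaf` is unknown.
#' @return an object of class `FilterPolicy`.
#' @export
filter_policy <- function(allowed_filter = c("PASS", "."),
                          min_alt_depth = 3L,
                          min_vaf = 0.02,
                          unknown_support = c("retain", "drop")) {
  unknown_support <- match.arg(unknown_support)
  if (!is_count1(min_alt_depth)) stop_config("min_alt_depth must be a non-negative integer")
  if (!is.numeric(min_vaf) || length(min_vaf) != 1L || min_vaf < 0 || min_vaf >= 1) {
    stop_config("min_vaf must be in [0, 1)")
  }
  structure(list(allowed_filter = allowed_filter,
                 min_alt_depth = as.integer(min_alt_depth),
                 min_vaf = min_vaf,
                 unknown_support = unknown_support),
            class = "FilterPolicy")
}

#' @export
print.FilterPolicy <- function(x, ...) {
  cat(sprintf("FilterPolicy: FILTER in {%s}, alt_depth > %d, vaf > %g, unknown -> %s\n",
              paste(x$allowed_filter, collapse = ", "), x$min_alt_depth,
              x$min_vaf, x$unknown_support))
  invisible(x)
}

#' Low-stringency per-caller retention filter
#'
#' Retains exactly the variants whose FILTER value is allowed AND whose
#' ALT depth and VAF clear the policy's strict thresholds; unknown support
#' values are handled per the policy. Contractive and idempotent. Applied
#' per caller, before consensus.
#'
#' @param cs a [callset()].
#' @param policy a [filter_policy()]; defaults to the standard thresholds.
#' @return the filtered `CallSet`; retention counts are logged.
#' @export
low_stringency_filter <- function(cs, policy = filter_policy()) {
  stopifnot(inherits(cs, "CallSet"), inherits(policy, "FilterPolicy"))
  dt <- cs$variants
  filter_ok <- dt$filter_status %in% policy$allowed_filter
  unknown <- is.na(dt$alt_depth) | is.na(dt$vaf)
  support_ok <- !is.na(dt$alt_depth) & !is.na(dt$vaf) &
    dt$alt_depth > policy$min_alt_depth & dt$vaf > policy$min_vaf
  support_ok[unknown] <- policy$unknown_support == "retain"
  keep <- filter_ok & support_ok
  cvc_log(sprintf("filter caller=%s in=%d kept=%d dropped=%d unknown_support=%d",
                  cs$caller_id, nrow(dt), sum(keep), sum(!keep), sum(unknown)))
  callset_replace(cs, dt[keep])
}

#' Exome candidate filter for tumor/normal screening
#'
#' Flags a tumor variant as a somatic candidate iff total depth > 20 reads,
#' ALT-supporting reads > 5, VAF in the matched germline normal < 0.25, the
#' tumor VAF > 0.20, and the site is called by at least two callers. All
#' comparisons strict, as printed. Vectorized.
#'
#' @param total_depth,alt_depth tumor read counts at the site.
#' @param normal_vaf VAF in the matched normal sample.
#' @param tumor_vaf VAF in the tumor sample.
#' @param support_count number of callers calling this key.
#' @return logical vector; `NA` (indeterminate, distinct from `FALSE`) where
#'   a required field is unknown.
#' @export
#' @examples
#' wes_candidate_filter(25, 6, 0.10, 0.25, 2)   # TRUE
#' wes_candidate_filter(20, 6, 0.10, 0.25, 2)   # FALSE: depth not > 20
wes_candidate_filter <- function(total_depth, alt_depth, normal_vaf,
                                 tumor_vaf, support_count) {
  n <- max(lengths(list(total_depth, alt_depth, normal_vaf, tumor_vaf,
                        support_count)))
  total_depth <- rep_len(total_depth, n)
  alt_depth <- rep_len(alt_depth, n)
  normal_vaf <- rep_len(normal_vaf, n)
  tumor_vaf <- rep_len(tumor_vaf, n)
  support_count <- rep_len(support_count, n)
  total_depth > 20 & alt_depth > 5 & normal_vaf < 0.25 &
    tumor_vaf > 0.20 & support_count >= 2
}

#' Partition a germline callset into in-window calls and noise
#'
#' True germline allele frequencies can only be heterozygous (~0.5) or
#' homozygous (~1.0); a call whose VAF falls outside the inclusive windows
#' `[0.4, 0.6]` and `[0.9, 1.0]` is treated as noise. The partition is
#' exhaustive and disjoint. Calls with unknown VAF are routed to the noise
#' side (conservative for a selectivity analysis) and counted in the
#' `unknown_vaf` attribute of the noise callset.
#'
#' @param cs a [callset()] of germline-sample calls with VAFs.
#' @return list with `CallSet` elements `germline_consistent` and `noise`.
#' @export
germline_noise_partition <- function(cs) {
  stopifnot(inherits(cs, "CallSet"))
  v <- cs$variants$vaf
  in_window <- !is.na(v) &
    ((v >= GERMLINE_HET_WINDOW[1L] & v <= GERMLINE_HET_WINDOW[2L]) |
       (v >= GERMLINE_HOM_WINDOW[1L] & v <= GERMLINE_HOM_WINDOW[2L]))
  n_unknown <- sum(is.na(v))
  if (n_unknown > 0L) {
    cvc_log(sprintf("germline_partition caller=%s unknown_vaf=%d routed=noise",
                    cs$caller_id, n_unknown))
  }
  noise <- callset_replace(cs, cs$variants[!in_window])
  attr(noise, "unknown_vaf") <- n_unknown
  list(germline_consistent = callset_replace(cs, cs$variants[in_window]),
       noise = noise)
}

#' Subtract callsets by key
#'
#' Removes from `minuend` every variant whose key appears in any of the
#' subtrahend callsets (e.g. subtracting germline calls and shared noise
#' from somatic calls); metadata of surviving variants is unchanged.
#'
#' @param minuend a [callset()].
#' @param ... subtrahend `CallSet`s (or character vectors of keys).
#' @return the reduced `CallSet`.
#' @export
subtract_callsets <- function(minuend, ...) {
  stopifnot(inherits(minuend, "CallSet"))
  subs <- list(...)
  drop_keys <- unique(unlist(lapply(subs, function(s) {
    if (inherits(s, "CallSet")) callset_keys(s)
    else if (is.character(s)) s
    else stop_config("subtrahends must be CallSets or key vectors")
  })))
  callset_replace(minuend, minuend$variants[!minuend$variants$key %in% drop_keys])
}
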