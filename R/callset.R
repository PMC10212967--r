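# CallSet: one caller's normalized, keyed variants.

VARIANT_COLS <- c("key", "chrom", "pos", "ref", "alt", "variant_class",
                  "filter_status", "alt_depth", "total_depth", "vaf")

#' Construct a CallSet
#'
#' A `CallSet` holds one caller's normalized variants, keyed by the
#' cross-caller matching key, together with read/retain/skip accounting.
#' Keys are unique within a callset: duplicate keys are collapsed keeping
#' the record with the highest ALT depth (ties: first seen, unknown depth
#' loses to any known depth).
#'
#' @param caller_id identifier of the originating caller.
#' @param variants a `data.frame`/`data.table` with columns `chrom`, `pos`,
#'   `ref`, `alt` and optionally `filter_status`, `alt_depth`,
#'   `total_depth`, `vaf`. Assumed already normalized if a `key` column is
#'   present; otherwise normalized via [normalize_variants()].
#' @param path source file path, if any.
#' @param n_read,n_skipped record accounting from the reader;
#'   `n_read = n_retained + n_skipped` always holds.
#' @param skip_reasons named integer vector tallying why records were
#'   skipped.
#' @param reference optional reference for normalization.
#' @return an object of class `CallSet`.
#' @export
callset <- function(caller_id, variants, path = NA_character_,
                    n_read = NULL, n_skipped = 0L,
                    skip_reasons = integer(0), reference = NULL) {
  if (!is_string1(caller_id)) stop_config("caller_id must be a single string")
  dt <- data.table::as.data.table(variants)
  if (nrow(dt) > 0L && !"key" %in% names(dt)) {
    dt <- normalize_variants(dt, reference = reference)
  }
  for (col in VARIANT_COLS) {
    if (!col %in% names(dt)) {
      dt[, (col) := switch(col,
        filter_status = "PASS",
        alt_depth = NA_integer_,
        total_depth = NA_integer_,
        vaf = NA_real_,
        variant_class = if (nrow(dt)) classify_variant(dt$ref, dt$alt) else character(0),
        key = character(0),
        chrom = character(0), ref = character(0), alt = character(0),
        pos = integer(0))]
    }
  }
  dt <- dt[, VARIANT_COLS, with = FALSE]
  dt <- collapse_duplicate_keys(dt)
  data.table::setorder(dt, chrom, pos, ref, alt)
  structure(
    list(
      caller_id = caller_id,
      variants = dt,
      path = path,
      n_read = as.integer(n_read %||% nrow(dt)),
      n_retained = as.integer(if (is.null(n_read)) nrow(dt) else n_read - n_skipped),
      n_skipped = as.integer(n_skipped),
      skip_reasons = skip_reasons
    ),
    class = "CallSet"
  )
}

collapse_duplicate_keys <- function(dt) {
  if (nrow(dt) <= 1L || !anyDuplicated(dt$key)) return(dt)
  dt[, .ord__ := .I]
  dt[, .ad__ := data.table::fifelse(is.na(alt_depth), -1L, as.integer(alt_depth))]
  data.table::setorder(dt, key, -.ad__, .ord__)
  dt <- unique(dt, by = "key")
  dt[, c(".ord__", ".ad__") := NULL]
  dt
}

#' @export
print.CallSet <- function(x, ...) {
  cat(sprintf("CallSet '%s': %d variants (%s)\n", x$caller_id,
              nrow(x$variants),
              paste(sprintf("%d %s", table(x$variants$variant_class),
                            names(table(x$variants$variant_class))),
                    collapse = ", ")))
  cat(sprintf("  records read=%d retained=%d skipped=%d\n",
              x$n_read, x$n_retained, x$n_skipped))
  if (!is.na(x$path)) cat(sprintf("  source: %s\n", x$path))
  invisible(x)
}

#' Keys of a CallSet
#'
#' @param x a `CallSet`.
#' @param class optional variant class (`"SNV"`, `"INDEL"`) to restrict to.
#' @return character vector of variant keys.
#' @export
callset_keys <- function(x, class = NULL) {
  stopifnot(inherits(x, "CallSet"))
  if (is.null(class)) return(x$variants$key)
  x$variants$key[x$variants$variant_class %in% class]
}

# Replace the variant table of a callset; reader-level record accounting
# (n_read/n_retained/n_skipped) is provenance and is left untouched.
callset_replace <- function(x, dt) {
  x$variants <- dt
  x
}
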