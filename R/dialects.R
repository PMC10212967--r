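# Caller dialects: how to pull (alt_depth, total_depth, vaf) out of each
# caller's FORMAT fields. Somatic callers disagree wildly here: Mutect2
# writes fractional AF plus an AD pair, VarScan writes a percent string in
# FREQ and a single ALT count in AD, Strelka SNVs carry tiered per-base
# counts (AU/CU/GU/TU) and Strelka indels TAR/TIR. A dialect is an ordered
# list of extraction strategies, tried until a field is resolved; fields no
# strategy resolves stay unknown (NA) — never guessed.

STRATEGY_TYPES <- c("af", "ad", "percent", "alt_dp", "dp", "dp4",
                    "strelka_snv", "strelka_indel")

#' Construct a caller dialect
#'
#' @param caller_id caller identifier.
#' @param strategies list of strategies, each a list with element `type`
#'   (one of `"af"`, `"ad"`, `"percent"`, `"alt_dp"`, `"dp"`, `"dp4"`,
#'   `"strelka_snv"`, `"strelka_indel"`) plus the FORMAT field names it
#'   reads (`field` for single-field types; `alt_field`/`dp_field` for
#'   `alt_dp`).
#' @param tumor_sample explicit tumor sample name, or `NULL` to use the
#'   default rule (single sample; else a sample literally named `"TUMOR"`;
#'   else an explicit name is required).
#' @return an object of class `CallerDialect`.
#' @export
#' @examples
#' caller_dialect("varscan", list(
#'   list(type = "percent", field = "FREQ"),
#'   list(type = "alt_dp", alt_field = "AD", dp_field = "DP")))
caller_dialect <- function(caller_id, strategies, tumor_sample = NULL) {
  if (!is_string1(caller_id)) stop_config("caller_id must be a single string")
  if (length(strategies) == 0L) {
    stop_config("a dialect needs at least one extraction strategy")
  }
  for (s in strategies) {
    if (is.null(s$type) || !s$type %in% STRATEGY_TYPES) {
      stop_config(sprintf("unknown extraction strategy type '%s'",
                          s$type %||% "<missing>"))
    }
  }
  structure(list(caller_id = caller_id, strategies = strategies,
                 tumor_sample = tumor_sample),
            class = "CallerDialect")
}

#' @export
print.CallerDialect <- function(x, ...) {
  cat(sprintf("CallerDialect '%s': %s\n", x$caller_id,
              paste(vapply(x$strategies, strategy_label, character(1)),
                    collapse = " > ")))
  invisible(x)
}

strategy_label <- function(s) {
  fields <- unlist(s[setdiff(names(s), "type")], use.names = FALSE)
  if (length(fields)) paste0(s$type, ":", paste(fields, collapse = ",")) else s$type
}

parse_strategy_spec <- function(spec) {
  # "type:FIELD" or "alt_dp:ALTFIELD,DPFIELD" or bare "strelka_snv"
  parts <- strsplit(spec, ":", fixed = TRUE)[[1L]]
  type <- parts[1L]
  args <- if (length(parts) > 1L) strsplit(parts[2L], ",", fixed = TRUE)[[1L]] else character(0)
  switch(type,
    alt_dp = {
      if (length(args) != 2L) stop_config("alt_dp strategy needs 'ALTFIELD,DPFIELD'")
      list(type = "alt_dp", alt_field = args[1L], dp_field = args[2L])
    },
    strelka_snv = list(type = "strelka_snv"),
    strelka_indel = list(type = "strelka_indel"),
    {
      if (length(args) != 1L) {
        stop_config(sprintf("strategy '%s' needs exactly one FORMAT field", type))
      }
      list(type = type, field = args[1L])
    }
  )
}

#' Read a dialect configuration file
#'
#' The file is a plain-text, human-editable set of sections:
#' ```
#' [varscan]
#' strategy = percent:FREQ
#' strategy = alt_dp:AD,DP
#' tumor_sample = TUMOR
#' ```
#' Strategies are tried in the order written. Lines starting with `#` are
#' comments.
#'
#' @param path path to the configuration file.
#' @return named list of [caller_dialect()] objects.
#' @export
read_dialect_config <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("dialect config '%s' not found", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  dialects <- list()
  current <- NULL
  strategies <- list()
  tumor <- NULL
  flush <- function() {
    if (!is.null(current)) {
      dialects[[current]] <<- caller_dialect(current, strategies, tumor)
    }
  }
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      flush()
      current <- sub("^\\[(.+)\\]$", "\\1", ln)
      strategies <- list()
      tumor <- NULL
    } else if (grepl("^strategy\\s*=", ln)) {
      strategies[[length(strategies) + 1L]] <-
        parse_strategy_spec(trimws(sub("^strategy\\s*=", "", ln)))
    } else if (grepl("^tumor_sample\\s*=", ln)) {
      tumor <- trimws(sub("^tumor_sample\\s*=", "", ln))
    } else {
      stop_config(sprintf("cannot parse dialect config line: '%s'", ln))
    }
  }
  flush()
  if (length(dialects) == 0L) stop_config("dialect config defines no callers")
  dialects
}

#' Built-in caller dialect presets
#'
#' Presets for the supported somatic callers, loaded from the package's
#' `caller_dialects.conf` (data, not code — copy it, edit it, and pass your
#' version to [read_dialect_config()] to add callers or override fields).
#' A `"generic"` preset tries the common conventions in order and suits
#' most well-behaved VCFs, including this package's own consensus output.
#'
#' @return named list of [caller_dialect()] objects.
#' @export
#' @examples
#' names(dialect_presets())
dialect_presets <- function() {
  path <- system.file("extdata", "caller_dialects.conf", package = "consensusvc")
  if (!nzchar(path)) stop_config("packaged dialect presets not found")
  read_dialect_config(path)
}

resolve_dialect <- function(dialect, caller_id = NULL) {
  if (inherits(dialect, "CallerDialect")) return(dialect)
  if (is_string1(dialect)) {
    presets <- dialect_presets()
    if (!dialect %in% names(presets)) {
      stop_config(sprintf("unknown dialect preset '%s' (have: %s)",
                          dialect, paste(names(presets), collapse = ", ")))
    }
    d <- presets[[dialect]]
    if (!is.null(caller_id)) d$caller_id <- caller_id
    return(d)
  }
  stop_config("dialect must be a CallerDialect or a preset name")
}

split_num <- function(x) suppressWarnings(as.numeric(strsplit(x, ",", fixed = TRUE)[[1L]]))

apply_strategy <- function(s, tags, alt_index, ref, alt) {
  out <- list(alt_depth = NA_integer_, total_depth = NA_integer_, vaf = NA_real_)
  val <- function(field) if (field %in% names(tags)) tags[[field]] else NA_character_
  switch(s$type,
    af = {
      v <- val(s$field)
      if (!is.na(v)) {
        nums <- split_num(v)
        f <- if (length(nums) >= alt_index) nums[alt_index] else nums[1L]
        if (length(f) == 1L && !is.na(f) && f >= 0 && f <= 1) out$vaf <- f
      }
    },
    ad = {
      v <- val(s$field)
      if (!is.na(v)) {
        counts <- split_num(v)
        if (length(counts) >= alt_index + 1L && !anyNA(counts)) {
          a <- counts[alt_index + 1L]
          r <- counts[1L]
          out$alt_depth <- as.integer(a)
          out$total_depth <- as.integer(r + a)
          out$vaf <- if (r + a > 0) a / (r + a) else 0
        }
      }
    },
    percent = {
      v <- val(s$field)
      if (!is.na(v) && grepl("%$", v)) {
        f <- suppressWarnings(as.numeric(sub("%$", "", v))) / 100
        if (!is.na(f) && f >= 0 && f <= 1) out$vaf <- f
      }
    },
    alt_dp = {
      a <- split_num(val(s$alt_field))[1L]
      d <- split_num(val(s$dp_field))[1L]
      if (!is.na(a)) out$alt_depth <- as.integer(a)
      if (!is.na(d)) out$total_depth <- as.integer(d)
      if (!is.na(a) && !is.na(d)) out$vaf <- if (d > 0) a / d else 0
    },
    dp = {
      d <- split_num(val(s$field))[1L]
      if (!is.na(d)) out$total_depth <- as.integer(d)
    },
    dp4 = {
      v <- split_num(val(s$field))
      if (length(v) == 4L && !anyNA(v)) {
        a <- v[3L] + v[4L]
        tot <- sum(v)
        out$alt_depth <- as.integer(a)
        out$total_depth <- as.integer(tot)
        out$vaf <- if (tot > 0) a / tot else 0
      }
    },
    strelka_snv = {
      # tiered per-base counts: AU/CU/GU/TU = "tier1,tier2"
      if (nchar(alt) == 1L && nchar(ref) == 1L) {
        a <- split_num(val(paste0(alt, "U")))[1L]
        r <- split_num(val(paste0(ref, "U")))[1L]
        if (!is.na(a) && !is.na(r)) {
          out$alt_depth <- as.integer(a)
          out$total_depth <- as.integer(a + r)
          out$vaf <- if (a + r > 0) a / (a + r) else 0
        }
      }
    },
    strelka_indel = {
      a <- split_num(val("TIR"))[1L]
      r <- split_num(val("TAR"))[1L]
      if (!is.na(a) && !is.na(r)) {
        out$alt_depth <- as.integer(a)
        out$total_depth <- as.integer(a + r)
        out$vaf <- if (a + r > 0) a / (a + r) else 0
      }
    }
  )
  out
}

#' Extract support fields from one VCF record
#'
#' Runs a dialect's extraction strategies in order, filling `alt_depth`,
#' `total_depth` and `vaf` from the first strategy that yields each field.
#' Fields no strategy resolves are returned as `NA` ("unknown") — the
#' downstream filter decides what to do with unknowns; nothing is guessed.
#'
#' @param format FORMAT column of the record (colon-separated field names).
#' @param sample_value the chosen sample's value string (colon-separated).
#' @param dialect a [caller_dialect()] (or preset name).
#' @param alt_index 1-based index of the ALT allele within the record's ALT
#'   list (for `Number=A`/`Number=R` fields).
#' @param ref,alt the record's REF and this ALT allele (needed by the
#'   Strelka tier-count strategies).
#' @return list with elements `alt_depth`, `total_depth`, `vaf` (NA when
#'   unknown).
#' @export
#' @examples
#' d <- caller_dialect("x", list(list(type = "ad", field = "AD")))
#' extract_support("GT:AD", "0/1:18,2", d)
extract_support <- function(format, sample_value, dialect, alt_index = 1L,
                            ref = "N", alt = "N") {
  dialect <- resolve_dialect(dialect)
  keys <- strsplit(format, ":", fixed = TRUE)[[1L]]
  vals <- strsplit(sample_value, ":", fixed = TRUE)[[1L]]
  n <- min(length(keys), length(vals))
  tags <- as.list(vals[seq_len(n)])
  names(tags) <- keys[seq_len(n)]
  tags[vapply(tags, function(v) v == "." || v == "", logical(1))] <- NULL

  out <- list(alt_depth = NA_integer_, total_depth = NA_integer_, vaf = NA_real_)
  for (s in dialect$strategies) {
    got <- apply_strategy(s, tags, alt_index, ref, alt)
    if (is.na(out$alt_depth) && !is.na(got$alt_depth)) out$alt_depth <- got$alt_depth
    if (is.na(out$total_depth) && !is.na(got$total_depth)) out$total_depth <- got$total_depth
    if (is.na(out$vaf) && !is.na(got$vaf)) out$vaf <- got$vaf
    if (!anyNA(out)) break
  }
  out
}
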