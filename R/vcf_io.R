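# VCF reading/writing. The reader is a light line-oriented parser (VCF v4.x
# site + single-tumor-sample subset) built on data.table; it exists because
# the consensus workflow reads many small per-caller files and the heavier
# Bioconductor readers pay a fixed per-file cost that dominates at this
# scale. The test suite cross-checks it against VariantAnnotation.

VCF_FIXED_COLS <- c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")

read_vcf_lines <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("VCF '%s' not found", path))
  con <- gzfile(path, open = "rt")  # transparently handles plain and (b)gzip
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

parse_vcf_header <- function(lines, path) {
  meta_n <- match(FALSE, startsWith(lines, "##")) - 1L
  if (is.na(meta_n)) meta_n <- length(lines)
  header_idx <- meta_n + 1L
  if (header_idx > length(lines) || !startsWith(lines[header_idx], "#CHROM")) {
    stop_format(sprintf("'%s': missing #CHROM header line", path))
  }
  meta <- lines[seq_len(meta_n)]
  if (meta_n == 0L || !grepl("^##fileformat=VCF", meta[1L])) {
    stop_format(sprintf("'%s': missing ##fileformat=VCFv4.x line", path))
  }
  cols <- strsplit(sub("^#", "", lines[header_idx]), "\t", fixed = TRUE)[[1L]]
  if (length(cols) < 8L || !identical(cols[1:8], VCF_FIXED_COLS)) {
    stop_format(sprintf("'%s': malformed #CHROM header line", path))
  }
  contig_lines <- meta[startsWith(meta, "##contig=")]
  contigs <- sub(".*<ID=([^,>]+).*", "\\1", contig_lines)
  samples <- if (length(cols) > 9L) cols[10:length(cols)] else character(0)
  list(meta = meta, columns = cols, samples = samples, contigs = contigs,
       body_start = header_idx + 1L)
}

resolve_tumor_sample <- function(samples, dialect, tumor_sample, path) {
  explicit <- tumor_sample %||% dialect$tumor_sample
  if (!is.null(explicit)) {
    if (!explicit %in% samples) {
      stop_config(sprintf("declared tumor sample '%s' not in '%s' (samples: %s)",
                          explicit, path, paste(samples, collapse = ", ")))
    }
    return(explicit)
  }
  if (length(samples) == 1L) return(samples)
  if ("TUMOR" %in% samples) return("TUMOR")
  if (length(samples) == 0L) return(NA_character_)
  stop_config(sprintf(
    "'%s' has samples [%s]; none is 'TUMOR' — specify tumor_sample explicitly",
    path, paste(samples, collapse = ", ")))
}

is_symbolic_alt <- function(alt) {
  # symbolic (<DEL>), breakend (]chr1:5]A), spanning-deletion and missing ALTs
  alt == "*" | alt == "." | grepl("[][<>]", alt)
}

#' Read one caller's VCF into a CallSet
#'
#' Parses a VCF v4.x file (plain or gzipped), selects the tumor sample,
#' extracts support fields via the caller's dialect, decomposes
#' multi-allelic records, normalizes every variant (trimming, MNV
#' decomposition, optional left-alignment), and collapses duplicate keys
#' keeping the record with the highest ALT depth. Symbolic ALTs (`<DEL>`,
#' breakends, spanning `*`) are skipped with a reason tally; malformed
#' alleles raise an invalid-variant error carrying the line number.
#'
#' @param path VCF file path.
#' @param dialect a [caller_dialect()], or a preset name from
#'   [dialect_presets()] (default `"generic"`).
#' @param caller_id caller identifier; defaults to the file's base name
#'   without extension.
#' @param reference optional reference (named character vector or
#'   `DNAStringSet`) enabling indel left-alignment.
#' @param tumor_sample explicit tumor sample name, overriding the dialect
#'   and the default rule (single sample, else literal `"TUMOR"`).
#' @param contig_alias optional named character vector renaming contigs on
#'   ingest (e.g. `c("1" = "chr1")` to reconcile `chr`-less callers with a
#'   `chr`-prefixed roster). Contig matching is otherwise exact.
#' @return a [callset()] with record accounting
#'   (`n_read = n_retained + n_skipped`).
#' @export
read_caller_vcf <- function(path, dialect = "generic", caller_id = NULL,
                            reference = NULL, tumor_sample = NULL,
                            contig_alias = NULL) {
  caller_id <- caller_id %||% sub("\\.vcf(\\.gz|\\.bgz)?$", "", basename(path))
  dialect <- resolve_dialect(dialect, caller_id = caller_id)
  lines <- read_vcf_lines(path)
  hdr <- parse_vcf_header(lines, path)
  body <- lines[seq.int(hdr$body_start, length.out = max(0L, length(lines) - hdr$body_start + 1L))]
  body <- body[nzchar(body)]

  empty <- data.table::data.table(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), filter_status = character(0),
    alt_depth = integer(0), total_depth = integer(0), vaf = numeric(0))
  if (length(body) == 0L) {
    empty[, `:=`(variant_class = character(0), key = character(0))]
    return(callset(caller_id, empty, path = path, n_read = 0L, n_skipped = 0L))
  }

  fields <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  if (length(fields) < 8L) {
    stop_format(sprintf("'%s': data line with fewer than 8 columns", path))
  }
  ncols <- length(hdr$columns)
  sample_name <- resolve_tumor_sample(hdr$samples, dialect, tumor_sample, path)
  sample_col <- if (!is.na(sample_name)) 9L + match(sample_name, hdr$samples) else NA_integer_

  dt <- data.table::data.table(
    line = hdr$body_start - 1L + seq_along(body),
    chrom = fields[[1L]],
    pos = suppressWarnings(as.integer(fields[[2L]])),
    ref = toupper(fields[[4L]]),
    alt_raw = toupper(fields[[5L]]),
    filter_status = fields[[7L]],
    format = if (ncols >= 9L && length(fields) >= 9L) fields[[9L]] else NA_character_,
    sample = if (!is.na(sample_col) && length(fields) >= sample_col) fields[[sample_col]] else NA_character_
  )
  if (anyNA(dt$pos)) {
    stop_format(sprintf("'%s': non-numeric POS at line %d", path,
                        dt$line[which(is.na(dt$pos))[1L]]))
  }
  if (!is.null(contig_alias)) {
    if (is.null(names(contig_alias))) {
      stop_config("contig_alias must be a named character vector")
    }
    hit <- dt$chrom %in% names(contig_alias)
    dt[hit, chrom := unname(contig_alias[chrom])]
  }

  n_read <- nrow(dt)
  skip_reasons <- integer(0)
  skip <- function(reason, n) {
    if (n > 0L) {
      cur <- if (reason %in% names(skip_reasons)) skip_reasons[[reason]] else 0L
      skip_reasons[reason] <<- cur + n
    }
  }

  # decompose multi-allelic records: one row per ALT with its allele index
  alts <- strsplit(dt$alt_raw, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  rec <- dt[rep(seq_len(nrow(dt)), n_alt)]
  rec[, alt := unlist(alts)]
  rec[, alt_index := unlist(lapply(n_alt, seq_len))]

  sym <- is_symbolic_alt(rec$alt)
  if (any(sym)) {
    # a record is skipped only if *all* its ALTs are symbolic
    dropped_recs <- setdiff(rec$line[sym], rec$line[!sym])
    skip("symbolic_alt", length(dropped_recs))
    if (length(dropped_recs)) {
      cvc_log(sprintf("vcf=%s skipped=%d reason=symbolic_alt", basename(path),
                      length(dropped_recs)))
    }
    rec <- rec[!sym]
  }

  bad <- !grepl(ALLELE_RE, rec$ref) | !grepl(ALLELE_RE, rec$alt) | rec$ref == rec$alt
  if (any(bad)) {
    i <- which(bad)[1L]
    stop_invalid_variant(
      sprintf("'%s' line %d: malformed alleles '%s'/'%s'", path,
              rec$line[i], rec$ref[i], rec$alt[i]),
      line = rec$line[i])
  }

  if (nrow(rec) > 0L && !all(is.na(rec$format)) && !all(is.na(rec$sample))) {
    supp <- mapply(function(fmt, sv, ai, r, a) {
      extract_support(fmt, sv, dialect, alt_index = ai, ref = r, alt = a)
    }, rec$format, rec$sample, rec$alt_index, rec$ref, rec$alt,
    SIMPLIFY = FALSE, USE.NAMES = FALSE)
    rec[, alt_depth := vapply(supp, function(x) as.integer(x$alt_depth), integer(1))]
    rec[, total_depth := vapply(supp, function(x) as.integer(x$total_depth), integer(1))]
    rec[, vaf := vapply(supp, function(x) as.numeric(x$vaf), numeric(1))]
  } else {
    rec[, `:=`(alt_depth = NA_integer_, total_depth = NA_integer_, vaf = NA_real_)]
  }

  rec <- rec[, .(chrom, pos, ref, alt, filter_status, alt_depth, total_depth, vaf)]
  norm <- normalize_variants(rec, reference = reference)
  cs <- callset(caller_id, norm, path = path, n_read = n_read,
                n_skipped = sum(skip_reasons), skip_reasons = skip_reasons)
  attr(cs, "contigs") <- hdr$contigs
  cs
}

format_vcf_number <- function(x) {
  ifelse(is.na(x), ".", sub("\\.?0+$", "", formatC(x, digits = 6, format = "f")))
}

#' Write a consensus VCF
#'
#' Writes the accepted variants of a [combine_at_threshold()] result as a
#' valid VCF v4.2 file: one record per accepted key, sorted by declared
#' contig order, position, REF, ALT; `FILTER=PASS`; INFO fields `SUPP`
#' (supporting caller count), `CALLERS` (supporting caller ids) and `VAFS`
#' (per-caller VAFs aligned with `CALLERS`, `.` when unknown). The header
#' records the threshold and caller roster, so the file round-trips through
#' [read_consensus_vcf()].
#'
#' @param ct a `ConsensusTable` from [combine_at_threshold()].
#' @param path output path. Written atomically (temp file + rename).
#' @param contigs contig names in output order; defaults to the order
#'   recorded in the consensus table. Records on undeclared contigs are a
#'   header error.
#' @return the path, invisibly.
#' @export
write_consensus_vcf <- function(ct, path, contigs = NULL) {
  stopifnot(inherits(ct, "ConsensusTable"))
  contigs <- contigs %||% ct$contigs
  acc <- ct$support[ct$support$key %in% ct$accepted]
  if (nrow(acc) > 0L) {
    missing_contig <- setdiff(unique(acc$chrom), contigs)
    if (length(missing_contig)) {
      stop_format(sprintf(
        "records on contig(s) %s but no declared contig list covering them",
        paste(missing_contig, collapse = ", ")))
    }
    acc <- acc[order(match(chrom, contigs), pos, ref, alt)]
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=consensusvc-%s",
            as.character(utils::packageVersion("consensusvc"))),
    sprintf("##consensus_threshold=%d", ct$k),
    sprintf("##consensus_callers=%s", paste(ct$roster, collapse = ",")),
    sprintf("##contig=<ID=%s>", contigs),
    "##INFO=<ID=SUPP,Number=1,Type=Integer,Description=\"Number of callers supporting the variant\">",
    "##INFO=<ID=CALLERS,Number=.,Type=String,Description=\"Supporting caller ids\">",
    "##INFO=<ID=VAFS,Number=.,Type=String,Description=\"Per-caller VAFs, aligned with CALLERS\">",
    "##FILTER=<ID=PASS,Description=\"Supported by at least the consensus threshold of callers\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t")
  )
  body <- if (nrow(acc) == 0L) character(0) else {
    info <- sprintf("SUPP=%d;CALLERS=%s;VAFS=%s", acc$n_support, acc$callers,
                    vapply(acc$vafs, function(v)
                      paste(format_vcf_number(v), collapse = ","), character(1)))
    paste(acc$chrom, acc$pos, ".", acc$ref, acc$alt, ".", "PASS", info,
          sep = "\t")
  }
  write_atomically(path, function(tmp) writeLines(c(header, body), tmp))
}

#' Read back a consensus VCF
#'
#' Parses a file written by [write_consensus_vcf()] and recovers the keys,
#' support counts, supporting caller ids and per-caller VAFs, plus the
#' threshold and roster recorded in the header.
#'
#' @param path path to a consensus VCF.
#' @return list with elements `variants` (a `data.table` with `key`,
#'   `n_support`, `callers`, `vafs`), `k`, and `roster`.
#' @export
read_consensus_vcf <- function(path) {
  lines <- read_vcf_lines(path)
  hdr <- parse_vcf_header(lines, path)
  k_line <- grep("^##consensus_threshold=", hdr$meta, value = TRUE)
  roster_line <- grep("^##consensus_callers=", hdr$meta, value = TRUE)
  k <- if (length(k_line)) as.integer(sub("^##consensus_threshold=", "", k_line[1L])) else NA_integer_
  roster <- if (length(roster_line)) {
    strsplit(sub("^##consensus_callers=", "", roster_line[1L]), ",", fixed = TRUE)[[1L]]
  } else character(0)
  body <- lines[seq.int(hdr$body_start, length.out = max(0L, length(lines) - hdr$body_start + 1L))]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(list(variants = data.table::as.data.table(list(
      key = character(0), chrom = character(0), pos = integer(0),
      ref = character(0), alt = character(0), n_support = integer(0),
      callers = character(0), vafs = list())),
      k = k, roster = roster))
  }
  fields <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  info <- fields[[8L]]
  grab <- function(tag) {
    m <- regmatches(info, regexpr(paste0("(^|;)", tag, "=[^;]*"), info))
    out <- rep(NA_character_, length(info))
    hit <- regexpr(paste0("(^|;)", tag, "=[^;]*"), info) > 0
    out[hit] <- sub(paste0("^;?", tag, "="), "", m)
    out
  }
  vafs_str <- grab("VAFS")
  dt <- data.table::data.table(
    chrom = fields[[1L]],
    pos = as.integer(fields[[2L]]),
    ref = toupper(fields[[4L]]),
    alt = toupper(fields[[5L]]),
    n_support = as.integer(sub("^;?SUPP=", "",
      regmatches(info, regexpr("(^|;)SUPP=[0-9]+", info)))),
    callers = grab("CALLERS"),
    vafs = lapply(strsplit(vafs_str, ",", fixed = TRUE),
                  function(v) suppressWarnings(as.numeric(v)))
  )
  dt[, key := make_key(chrom, pos, ref, alt)]
  data.table::setcolorder(dt, c("key", "chrom", "pos", "ref", "alt"))
  list(variants = dt, k = k, roster = roster)
}
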