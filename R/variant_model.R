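# Canonical variant representation, normalization, and cross-caller matching.
#
# All coordinates are 1-based and inclusive, as in VCF, and are never
# converted internally. Alleles are upper-cased on ingest and compared
# case-insensitively. The matching key of a variant is its normalized
# (chrom, pos, ref, alt) tuple: alleles trimmed of shared prefix/suffix and,
# when a reference sequence is available, indels shifted to their leftmost
# equivalent position in standard VCF anchored style.

ALLELE_RE <- "^[ACGTN]+$"

#' Classify alleles as SNV, INDEL or MNV
#'
#' A variant is an SNV when both alleles are single bases, an INDEL when
#' allele lengths differ, and an MNV when both alleles have the same length
#' greater than one. MNVs never survive normalization: they are decomposed
#' into per-base SNVs (see [normalize_variants()]).
#'
#' @param ref,alt character vectors of REF and ALT alleles.
#' @return character vector with values `"SNV"`, `"INDEL"` or `"MNV"`.
#' @export
#' @examples
#' classify_variant(c("A", "AT", "AG"), c("G", "A", "TC"))
classify_variant <- function(ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  ifelse(nr == 1L & na == 1L, "SNV", ifelse(nr == na, "MNV", "INDEL"))
}

validate_alleles <- function(ref, alt, line = NA_integer_) {
  bad <- !nzchar(ref) | !nzchar(alt) | !grepl(ALLELE_RE, ref) | !grepl(ALLELE_RE, alt)
  if (any(bad)) {
    stop_invalid_variant(
      sprintf("malformed allele(s) '%s'/'%s'%s",
              ref[bad][1L], alt[bad][1L],
              if (is.na(line)) "" else sprintf(" at line %d", line)),
      line = line
    )
  }
  same <- ref == alt
  if (any(same)) {
    stop_invalid_variant(
      sprintf("REF equals ALT ('%s')%s", ref[same][1L],
              if (is.na(line)) "" else sprintf(" at line %d", line)),
      line = line
    )
  }
  invisible(TRUE)
}

trim_one <- function(pos, ref, alt) {
  # shared suffix first, then shared prefix (advancing pos); both alleles
  # must keep at least one base
  nr <- nchar(ref)
  na <- nchar(alt)
  while (nr > 1L && na > 1L &&
         substr(ref, nr, nr) == substr(alt, na, na)) {
    nr <- nr - 1L
    na <- na - 1L
  }
  ref <- substr(ref, 1L, nr)
  alt <- substr(alt, 1L, na)
  while (nr > 1L && na > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nr)
    alt <- substr(alt, 2L, na)
    nr <- nr - 1L
    na <- na - 1L
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Trim shared allele prefix and suffix
#'
#' Removes the shared suffix, then the shared prefix (advancing `pos` by one
#' per removed leading base), while both alleles keep at least one base.
#' This yields the unique minimal representation used for cross-caller
#' matching. Idempotent. Vectorized over records.
#'
#' @param pos integer vector of 1-based positions.
#' @param ref,alt character vectors of alleles (uppercase `ACGTN`).
#' @return a `data.frame` with columns `pos`, `ref`, `alt`.
#' @export
#' @examples
#' trim_alleles(100, "ATG", "AG")   # -> 100, "AT", "A"
#' trim_alleles(10, "GCC", "GTC")   # -> 11, "C", "T"
trim_alleles <- function(pos, ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  validate_alleles(ref, alt)
  out <- mapply(trim_one, as.integer(pos), ref, alt,
                SIMPLIFY = FALSE, USE.NAMES = FALSE)
  data.frame(
    pos = vapply(out, `[[`, integer(1), "pos"),
    ref = vapply(out, `[[`, character(1), "ref"),
    alt = vapply(out, `[[`, character(1), "alt"),
    stringsAsFactors = FALSE
  )
}

get_contig_seq <- function(reference, chrom) {
  if (is.null(reference)) return(NULL)
  if (inherits(reference, "DNAStringSet")) {
    nm <- names(reference)
    if (!chrom %in% nm) stop_data(sprintf("contig '%s' absent from reference", chrom))
    return(toupper(as.character(reference[[match(chrom, nm)]])))
  }
  if (is.character(reference)) {
    if (!chrom %in% names(reference)) {
      stop_data(sprintf("contig '%s' absent from reference", chrom))
    }
    return(toupper(reference[[chrom]]))
  }
  stop_config("reference must be a named character vector or a DNAStringSet")
}

#' Read a reference FASTA into a named character vector
#'
#' Thin wrapper over `Biostrings::readDNAStringSet()`; contig names are
#' truncated at the first whitespace, matching common FASTA usage.
#'
#' @param path path to a FASTA file (plain or gzipped).
#' @return named character vector, one element per contig.
#' @export
read_reference_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop_config("reading FASTA requires the Biostrings package")
  }
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

left_align_one <- function(pos, ref, alt, contig_seq) {
  if (nchar(ref) == nchar(alt)) return(list(pos = pos, ref = ref, alt = alt))
  if (pos + nchar(ref) - 1L > nchar(contig_seq) ||
      substr(contig_seq, pos, pos + nchar(ref) - 1L) != ref) {
    stop_reference_mismatch(
      sprintf("REF allele '%s' at pos %d disagrees with reference sequence", ref, pos)
    )
  }
  repeat {
    nr <- nchar(ref)
    na <- nchar(alt)
    if (nr > 0L && na > 0L && substr(ref, nr, nr) == substr(alt, na, na)) {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
    } else if (nr == 0L || na == 0L) {
      if (pos <= 1L) {
        # contig start: no upstream base to anchor on; the leftmost valid
        # VCF form here is right-anchored on the base after the REF allele
        if (pos + nr > nchar(contig_seq)) {
          stop_context(
            "insufficient reference context to left-align at contig start")
        }
        b <- substr(contig_seq, pos + nr, pos + nr)
        ref <- paste0(ref, b)
        alt <- paste0(alt, b)
        break
      }
      pos <- pos - 1L
      b <- substr(contig_seq, pos, pos)
      ref <- paste0(b, ref)
      alt <- paste0(b, alt)
    } else {
      break
    }
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Left-align an indel against a reference sequence
#'
#' Shifts a trimmed indel to the leftmost position at which applying the
#' edit yields the same haplotype, anchored on one preceding reference base
#' in standard VCF style. SNVs and MNVs are returned unchanged. Idempotent.
#'
#' @param pos 1-based position of the first REF base.
#' @param ref,alt trimmed alleles (uppercase).
#' @param reference named character vector (or `DNAStringSet`) of contig
#'   sequences, as from [read_reference_fasta()].
#' @param chrom contig name to align against.
#' @return list with elements `pos`, `ref`, `alt`.
#' @export
#' @examples
#' ref <- c(chr1 = "CCCCCCCCCCCCCCCCCCCTAAAAC")
#' left_align(23, "AA", "A", ref, "chr1")   # -> 20, "TA", "T"
left_align <- function(pos, ref, alt, reference, chrom) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  validate_alleles(ref, alt)
  contig_seq <- get_contig_seq(reference, chrom)
  left_align_one(as.integer(pos), ref, alt, contig_seq)
}

decompose_mnv <- function(pos, ref, alt) {
  bases_r <- strsplit(ref, "", fixed = TRUE)[[1L]]
  bases_a <- strsplit(alt, "", fixed = TRUE)[[1L]]
  i <- which(bases_r != bases_a)
  data.frame(pos = pos + i - 1L, ref = bases_r[i], alt = bases_a[i],
             stringsAsFactors = FALSE)
}

#' Normalize a table of raw variant records
#'
#' Applies the full normalization pipeline used for cross-caller matching:
#' alleles are upper-cased and validated, trimmed of shared prefix/suffix,
#' MNVs decomposed into their mismatching per-base SNVs, and indels
#' left-aligned when `reference` is supplied. Input rows may expand (MNV
#' decomposition); all other columns are carried through unchanged.
#' Idempotent: normalizing twice equals normalizing once.
#'
#' @param dt a `data.frame`/`data.table` with at least columns `chrom`
#'   (character), `pos` (integer), `ref`, `alt` (character). Symbolic
#'   alleles must already have been removed (see [read_caller_vcf()]).
#' @param reference optional named character vector / `DNAStringSet` of
#'   contig sequences for indel left-alignment. Without it, trimming-only
#'   normalization is performed (matching is then exact-representation for
#'   indels in repeat context).
#' @return a `data.table` of normalized records with recomputed
#'   `variant_class` and `key` columns.
#' @export
normalize_variants <- function(dt, reference = NULL) {
  dt <- data.table::as.data.table(dt)
  if (nrow(dt) == 0L) {
    dt[, `:=`(variant_class = character(0), key = character(0))]
    return(dt)
  }
  dt[, `:=`(ref = toupper(ref), alt = toupper(alt), pos = as.integer(pos))]
  validate_alleles(dt$ref, dt$alt)

  trimmed <- trim_alleles(dt$pos, dt$ref, dt$alt)
  dt[, `:=`(pos = trimmed$pos, ref = trimmed$ref, alt = trimmed$alt)]
  dt[, variant_class := classify_variant(ref, alt)]

  if (any(dt$variant_class == "MNV")) {
    idx <- which(dt$variant_class == "MNV")
    expanded <- lapply(idx, function(i) {
      snvs <- decompose_mnv(dt$pos[i], dt$ref[i], dt$alt[i])
      row <- dt[rep(i, nrow(snvs))]
      row[, `:=`(pos = snvs$pos, ref = snvs$ref, alt = snvs$alt,
                 variant_class = "SNV")]
      row
    })
    dt <- data.table::rbindlist(c(list(dt[-idx]), expanded), use.names = TRUE)
  }

  if (!is.null(reference) && any(dt$variant_class == "INDEL")) {
    idx <- which(dt$variant_class == "INDEL")
    for (i in idx) {
      la <- left_align_one(dt$pos[i], dt$ref[i], dt$alt[i],
                           get_contig_seq(reference, dt$chrom[i]))
      data.table::set(dt, i, "pos", la$pos)
      data.table::set(dt, i, "ref", la$ref)
      data.table::set(dt, i, "alt", la$alt)
    }
  }

  dt[, key := make_key(chrom, pos, ref, alt)]
  data.table::setorder(dt, chrom, pos, ref, alt)
  dt[]
}

#' Build the cross-caller matching key of normalized variants
#'
#' The key is the normalized `(chrom, pos, ref, alt)` tuple rendered as
#' `"chrom:pos:ref:alt"`; two call representations of the same allele change
#' map to equal keys after [normalize_variants()]. Inputs that are not
#' trimmed (a removable shared prefix or suffix while both alleles keep one
#' base) raise a contract error.
#'
#' @param chrom,pos,ref,alt vectors describing normalized variants.
#' @return character vector of keys.
#' @export
#' @examples
#' make_key("chr1", 100, "AT", "A")
make_key <- function(chrom, pos, ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  untrimmed <- (nr > 1L & na > 1L) &
    (substr(ref, nr, nr) == substr(alt, na, na) |
       substr(ref, 1L, 1L) == substr(alt, 1L, 1L))
  if (any(untrimmed)) {
    stop_config(sprintf(
      "make_key() requires normalized alleles; '%s'/'%s' has a removable shared prefix/suffix",
      ref[untrimmed][1L], alt[untrimmed][1L]))
  }
  paste(chrom, as.integer(pos), ref, alt, sep = ":")
}

#' Split matching keys back into their components
#'
#' Inverse of [make_key()].
#'
#' @param key character vector of `"chrom:pos:ref:alt"` keys.
#' @return a `data.table` with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
parse_key <- function(key) {
  parts <- data.table::tstrsplit(key, ":", fixed = TRUE)
  if (length(parts) != 4L) stop_data("malformed variant key")
  data.table::data.table(
    chrom = parts[[1L]],
    pos = as.integer(parts[[2L]]),
    ref = parts[[3L]],
    alt = parts[[4L]]
  )
}
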