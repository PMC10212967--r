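# Shared fixtures and independent oracles. Everything is built in code at
# test time; no binary files.

options(consensusvc.quiet = TRUE)

# --- tiny VCF construction -------------------------------------------------

vcf_text <- function(records, format_defs = character(0), samples = "TUMOR",
                     contig = "chr1", fileformat = "VCFv4.2") {
  header <- c(
    sprintf("##fileformat=%s", fileformat),
    sprintf("##contig=<ID=%s,length=1000000>", contig),
    format_defs,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t"))
  c(header, records)
}

write_tmp_vcf <- function(lines) {
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  path
}

std_format_defs <- c(
  '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
  '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="AD">',
  '##FORMAT=<ID=AF,Number=A,Type=Float,Description="AF">',
  '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="DP">',
  '##FORMAT=<ID=FREQ,Number=1,Type=String,Description="FREQ">')

# --- callsets from bare keys ------------------------------------------------

mock_callset <- function(id, keys, vaf = NA_real_, alt_depth = NA_integer_) {
  if (length(keys) == 0L) {
    dt <- data.table::as.data.table(list(
      chrom = character(0), pos = integer(0), ref = character(0),
      alt = character(0), key = character(0)))
  } else {
    dt <- parse_key(keys)
    dt[, key := keys]
    dt[, vaf := rep_len(vaf, .N)]
    dt[, alt_depth := rep_len(as.integer(alt_depth), .N)]
  }
  callset(id, dt)
}

key_pool <- function(n) sprintf("chr1:%d:A:G", seq_len(n))

make_filter_cs <- function(filter, ad, vaf) {
  n <- length(filter)
  dt <- parse_key(key_pool(n))
  dt[, key := key_pool(n)]
  dt[, `:=`(filter_status = filter, alt_depth = as.integer(ad),
            total_depth = as.integer(ad * 2L), vaf = vaf)]
  callset("f", dt)
}

# random collection of callsets over a shared key pool
random_collection <- function(n_callers_max = 5L, n_keys_max = 200L,
                              pool = key_pool(250L)) {
  n <- sample.int(n_callers_max, 1L)
  lapply(seq_len(n), function(i) {
    sz <- sample.int(n_keys_max + 1L, 1L) - 1L  # allows empty callsets
    mock_callset(paste0("c", i), sample(pool, min(sz, length(pool))))
  })
}

# --- independent consensus oracle ------------------------------------------

# per-key counting, one key at a time, straight off the callset key vectors
oracle_accepted <- function(callsets, k) {
  keys <- unique(unlist(lapply(callsets, callset_keys)))
  supp <- vapply(keys, function(ky) {
    sum(vapply(callsets, function(cs) ky %in% callset_keys(cs), logical(1)))
  }, integer(1))
  sort(keys[supp >= k])
}

# --- independent metric oracle ----------------------------------------------

oracle_metrics <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  s <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p > 0 && s > 0) 2 / (1 / p + 1 / s) else 0
  c(precision = p, sensitivity = s, f1 = f)
}

# --- normalization equivalence oracle ---------------------------------------

# All VCF-style representations (pos, ref, alt) over `window` whose applied
# edit reproduces the same haplotype: enumerate every (pos, ref-length)
# pair, derive the alt that would restore the haplotype, keep the
# consistent ones. Brute force, independent of the package's trimming and
# left-alignment code.
enumerate_equivalent_reps <- function(window, pos, ref, alt) {
  w <- nchar(window)
  hap <- paste0(substr(window, 1L, pos - 1L), alt,
                substr(window, pos + nchar(ref), w))
  h <- nchar(hap)
  reps <- list()
  for (p in seq_len(w)) {
    for (lr in 0:(w - p + 1L)) {
      la <- h - (w - lr)
      if (la < 0L) next
      if (p + la - 1L > h) next
      r <- substr(window, p, p + lr - 1L)
      a <- substr(hap, p, p + la - 1L)
      if (!nzchar(r) || !nzchar(a) || r == a) next
      if (substr(window, 1L, p - 1L) != substr(hap, 1L, p - 1L)) next
      if (substr(window, p + lr, w) != substr(hap, p + la, h)) next
      reps[[length(reps) + 1L]] <- list(pos = p, ref = r, alt = a)
    }
  }
  reps
}

# windows with homopolymer runs / short repeats, where representation
# ambiguity actually arises
random_repeat_window <- function(len = 24L) {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  while (sum(nchar(out)) < len) {
    unit <- paste(sample(bases, sample(1:2, 1L), replace = TRUE), collapse = "")
    out <- c(out, strrep(unit, sample(1:4, 1L)))
  }
  substr(paste(out, collapse = ""), 1L, len)
}

# random indel expressed against the window, deliberately un-normalized
random_indel_rep <- function(window) {
  w <- nchar(window)
  repeat {
    p <- sample.int(w - 6L, 1L) + 1L
    lr <- sample(1:3, 1L)
    if (stats::runif(1) < 0.5) {          # deletion of lr bases, anchored
      ref <- substr(window, p, p + lr)
      alt <- substr(window, p, p)
      if (nchar(ref) <= nchar(alt)) next
    } else {                              # insertion of lr random bases
      ref <- substr(window, p, p)
      alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), lr, replace = TRUE),
                               collapse = ""))
    }
    if (ref != alt) return(list(pos = p, ref = ref, alt = alt))
  }
}

# --- small simulated datasets -----------------------------------------------

small_sim_config <- function(seed, ...) {
  defaults <- list(seed = seed, n_callers = 4L, n_true = 60L,
                   snv_fraction = 0.8, miss_prob = 0.1, private_fp = 10L,
                   shared_fp = 5L, shared_fp_callers = 2L,
                   contig_length = 1e6)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

read_back_dataset <- function(ds, dir = tempfile()) {
  files <- write_fixture_vcfs(ds, dir)
  callsets <- lapply(names(files$caller_vcfs), function(cid) {
    read_caller_vcf(files$caller_vcfs[[cid]], dialect = files$dialects[[cid]],
                    caller_id = cid)
  })
  names(callsets) <- names(files$caller_vcfs)
  truth <- read_caller_vcf(files$truth_vcf, dialect = "generic",
                           caller_id = "truth")
  list(callsets = callsets, truth = truth, files = files)
}
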