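# Synthetic multi-caller datasets with known truth.
#
# The generator instantiates the noise taxonomy the consensus strategy is
# built around: a shared truth set that every caller sees minus independent
# per-variant misses (false negatives), caller-private systematic false
# positives ("deterministic noise"), and false positives shared by a small
# group of callers (correlated/"stochastic" noise). In germline mode it
# instead emits per-sample germline calls with VAFs inside the
# heterozygous/homozygous windows plus off-window noise calls, emulating an
# amplicon panel run on normal samples. Exact bookkeeping (which keys are
# true, which callers carry each key) is returned so every downstream stage
# can be checked against the generator, not against itself.

FIXTURE_STYLES <- c("ad", "af", "percent", "alt_dp", "strelka")

#' Simulation configuration
#'
#' Defaults describe the standard somatic regime used throughout the test
#' suite: 6 callers over 1000 true SNVs, a 5% independent miss probability
#' per (caller, variant), 100 private false positives per caller, and 10
#' correlated false positives each shared by 2 callers — enough signal for
#' union, majority and full intersection to separate visibly. Somatic VAFs
#' are drawn from Beta(8, 12) (mean 0.4); per-caller observed depths and
#' ALT counts come from a beta-binomial around the variant's VAF. Every
#' emitted record has FILTER PASS, ALT depth >= 4 and VAF > 0.02, so the
#' low-stringency filter is the identity on fixture data and bookkeeping is
#' exact through the whole pipeline.
#'
#' @param seed integer seed; every output is bit-reproducible given it.
#' @param n_callers number of callers.
#' @param n_true number of true variants.
#' @param snv_fraction fraction of true variants that are SNVs (the rest
#'   are short indels).
#' @param miss_prob independent per-(caller, variant) miss probability.
#' @param private_fp private false positives per caller.
#' @param shared_fp number of correlated false positives.
#' @param shared_fp_callers how many callers carry each shared false
#'   positive (must be <= `n_callers`).
#' @param contig,contig_length contig name and length for generated
#'   positions.
#' @param mean_depth,min_depth,max_depth sequencing depth model (Poisson
#'   between floor and cap).
#' @param vaf_concentration beta-binomial concentration of per-caller
#'   observed VAF around the variant's true VAF.
#' @param germline emit germline-mode data (VAFs in
#'   `[0.4,0.6] u [0.9,1.0]` for true keys, outside for noise keys).
#' @param het_fraction fraction of germline variants that are heterozygous.
#' @param germline_depth mean amplicon depth in germline mode.
#' @return an object of class `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1L,
                              n_callers = 6L,
                              n_true = 1000L,
                              snv_fraction = 1,
                              miss_prob = 0.05,
                              private_fp = 100L,
                              shared_fp = 10L,
                              shared_fp_callers = 2L,
                              contig = "chr1",
                              contig_length = 1e7,
                              mean_depth = 80,
                              min_depth = 30L,
                              max_depth = 150L,
                              vaf_concentration = 60,
                              germline = FALSE,
                              het_fraction = 0.8,
                              germline_depth = 2000) {
  cfg <- list(seed = as.integer(seed), n_callers = as.integer(n_callers),
              n_true = as.integer(n_true), snv_fraction = snv_fraction,
              miss_prob = miss_prob, private_fp = as.integer(private_fp),
              shared_fp = as.integer(shared_fp),
              shared_fp_callers = as.integer(shared_fp_callers),
              contig = contig, contig_length = contig_length,
              mean_depth = mean_depth, min_depth = as.integer(min_depth),
              max_depth = as.integer(max_depth),
              vaf_concentration = vaf_concentration,
              germline = isTRUE(germline), het_fraction = het_fraction,
              germline_depth = germline_depth)
  for (p in c("snv_fraction", "miss_prob", "het_fraction")) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop_config(sprintf("%s must be in [0, 1]", p))
    }
  }
  if (cfg$n_callers < 1L) stop_config("need at least one caller")
  if (any(c(cfg$n_true, cfg$private_fp, cfg$shared_fp) < 0L)) {
    stop_config("counts must be non-negative")
  }
  if (cfg$shared_fp > 0L &&
      (cfg$shared_fp_callers < 1L || cfg$shared_fp_callers > cfg$n_callers)) {
    stop_config("shared_fp_callers must be between 1 and n_callers")
  }
  structure(cfg, class = "SimulationConfig")
}

random_alleles <- function(n, snv_fraction) {
  bases <- c("A", "C", "G", "T")
  is_snv <- stats::runif(n) < snv_fraction
  ref <- alt <- character(n)
  for (i in seq_len(n)) {
    anchor <- sample(bases, 1L)
    if (is_snv[i]) {
      ref[i] <- anchor
      alt[i] <- sample(setdiff(bases, anchor), 1L)
    } else if (stats::runif(1) < 0.5) {  # insertion
      ins <- paste(sample(bases, sample(1:3, 1L), replace = TRUE), collapse = "")
      ref[i] <- anchor
      alt[i] <- paste0(anchor, ins)
    } else {                             # deletion
      del <- paste(sample(bases, sample(1:3, 1L), replace = TRUE), collapse = "")
      ref[i] <- paste0(anchor, del)
      alt[i] <- anchor
    }
  }
  data.table::data.table(ref = ref, alt = alt)
}

draw_support <- function(true_vaf, cfg) {
  n <- length(true_vaf)
  depth <- pmin(cfg$max_depth,
                cfg$min_depth + stats::rpois(n, max(0, cfg$mean_depth - cfg$min_depth)))
  conc <- cfg$vaf_concentration
  p <- stats::rbeta(n, true_vaf * conc, (1 - true_vaf) * conc)
  alt <- stats::rbinom(n, depth, p)
  alt <- pmax(alt, 4L)   # every fixture record clears the retention filter
  alt <- pmin(alt, depth)
  list(depth = as.integer(depth), alt = as.integer(alt), vaf = alt / depth)
}

draw_germline_support <- function(target_vaf, cfg) {
  n <- length(target_vaf)
  depth <- as.integer(cfg$germline_depth + stats::rpois(n, cfg$germline_depth / 10))
  alt <- as.integer(round(target_vaf * depth))
  alt <- pmax(1L, pmin(alt, depth))
  list(depth = depth, alt = alt, vaf = alt / depth)
}

#' Simulate a multi-caller dataset with known truth
#'
#' See [simulation_config()] for the generative model. Returns the truth
#' callset, one callset per caller, and a manifest recording every key's
#' role (`true`, `private_fp`, `shared_fp`; in germline mode `germline`,
#' `noise_private`, `noise_shared`) and exactly which callers carry it —
#' the oracle against which reading, filtering, consensus and evaluation
#' are all checked.
#'
#' @param config a [simulation_config()].
#' @return list of class `SimulatedDataset`: `config`, `truth` (a
#'   [callset()]), `callsets` (named list), `manifest` (a `data.table`) and
#'   `dialect_styles` (named character; FORMAT style each caller's fixture
#'   VCF will use, cycling through ad, af, percent, alt_dp, strelka).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  set.seed(cfg$seed)
  callers <- sprintf("caller%d", seq_len(cfg$n_callers))
  styles <- stats::setNames(rep_len(FIXTURE_STYLES, cfg$n_callers), callers)
  if (cfg$germline) styles[] <- rep_len(setdiff(FIXTURE_STYLES, "strelka"),
                                        cfg$n_callers)

  n_fp_total <- cfg$n_callers * cfg$private_fp + cfg$shared_fp
  n_total <- cfg$n_true + n_fp_total
  pos <- sort(sample.int(cfg$contig_length - 10L, n_total)) + 1L
  alleles <- random_alleles(n_total, if (cfg$germline) cfg$snv_fraction else cfg$snv_fraction)

  univ <- data.table::data.table(
    chrom = cfg$contig, pos = pos, ref = alleles$ref, alt = alleles$alt)
  univ[, variant_class := classify_variant(ref, alt)]
  univ[, key := make_key(chrom, pos, ref, alt)]

  idx_true <- seq_len(cfg$n_true)
  role <- rep("", n_total)
  role[idx_true] <- if (cfg$germline) "germline" else "true"
  owner <- vector("list", n_total)          # callers carrying each FP
  i <- cfg$n_true
  for (cid in callers) {
    take <- seq_len(cfg$private_fp) + i
    role[take] <- if (cfg$germline) "noise_private" else "private_fp"
    owner[take] <- list(cid)
    i <- i + cfg$private_fp
  }
  if (cfg$shared_fp > 0L) {
    take <- seq_len(cfg$shared_fp) + i
    role[take] <- if (cfg$germline) "noise_shared" else "shared_fp"
    owner[take] <- lapply(take, function(.) sample(callers, cfg$shared_fp_callers))
  }
  univ[, role := role]

  # true underlying VAF per variant
  if (cfg$germline) {
    is_het <- stats::runif(cfg$n_true) < cfg$het_fraction
    true_vaf <- numeric(n_total)
    true_vaf[idx_true] <- ifelse(is_het, stats::runif(cfg$n_true, 0.44, 0.56),
                                 stats::runif(cfg$n_true, 0.92, 0.98))
    off <- which(role %in% c("noise_private", "noise_shared"))
    low <- stats::runif(length(off)) < 0.8
    true_vaf[off] <- ifelse(low, stats::runif(length(off), 0.03, 0.35),
                            stats::runif(length(off), 0.64, 0.86))
  } else {
    true_vaf <- numeric(n_total)
    true_vaf[idx_true] <- stats::rbeta(cfg$n_true, 8, 12)
    fp <- which(role %in% c("private_fp", "shared_fp"))
    true_vaf[fp] <- stats::rbeta(length(fp), 2, 8)
  }
  univ[, true_vaf := true_vaf]

  # per-caller membership
  membership <- lapply(callers, function(cid) {
    called_true <- idx_true[stats::runif(cfg$n_true) >= cfg$miss_prob]
    fp_idx <- which(vapply(owner, function(o) !is.null(o) && cid %in% o, logical(1)))
    sort(c(called_true, fp_idx))
  })
  names(membership) <- callers

  callsets <- lapply(callers, function(cid) {
    idx <- membership[[cid]]
    v <- univ[idx]
    supp <- if (cfg$germline) draw_germline_support(v$true_vaf, cfg)
            else draw_support(v$true_vaf, cfg)
    dt <- v[, .(chrom, pos, ref, alt, variant_class, key)]
    dt[, `:=`(filter_status = "PASS", alt_depth = supp$alt,
              total_depth = supp$depth, vaf = supp$vaf)]
    callset(cid, dt)
  })
  names(callsets) <- callers

  truth_dt <- univ[idx_true, .(chrom, pos, ref, alt, variant_class, key)]
  truth_supp <- if (cfg$germline) draw_germline_support(univ$true_vaf[idx_true], cfg)
                else draw_support(univ$true_vaf[idx_true], cfg)
  truth_dt[, `:=`(filter_status = "PASS", alt_depth = truth_supp$alt,
                  total_depth = truth_supp$depth, vaf = truth_supp$vaf)]

  caller_of <- stats::setNames(lapply(callers, function(cid) membership[[cid]]), callers)
  key_callers <- vapply(seq_len(n_total), function(i) {
    paste(callers[vapply(callers, function(cid) i %in% caller_of[[cid]], logical(1))],
          collapse = ",")
  }, character(1))
  manifest <- univ[, .(key, chrom, pos, ref, alt, variant_class, role, true_vaf)]
  manifest[, callers := key_callers]
  manifest[, n_support := data.table::fifelse(callers == "", 0L,
    lengths(strsplit(callers, ",", fixed = TRUE)))]

  structure(list(config = cfg, truth = callset("truth", truth_dt),
                 callsets = callsets, manifest = manifest,
                 dialect_styles = styles),
            class = "SimulatedDataset")
}

#' Expected confusion counts from the generator manifest
#'
#' Computes, purely from the bookkeeping manifest (never from the package's
#' consensus path), the tp/fp/fn that combining all callers at threshold
#' `k` must yield against the truth set.
#'
#' @param dataset a `SimulatedDataset`.
#' @param k minimum intersection threshold.
#' @return named integer vector `tp`, `fp`, `fn`.
#' @export
manifest_confusion <- function(dataset, k) {
  m <- dataset$manifest
  truth_roles <- c("true", "germline")
  accepted <- m$n_support >= k
  is_true <- m$role %in% truth_roles
  c(tp = sum(accepted & is_true), fp = sum(accepted & !is_true),
    fn = sum(!accepted & is_true))
}

fixture_header <- function(cfg, style) {
  fmt <- switch(style,
    ad = c('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'),
    af = c('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=AF,Number=A,Type=Float,Description="Allele fraction">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'),
    percent = c('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                '##FORMAT=<ID=AD,Number=1,Type=Integer,Description="ALT read count">',
                '##FORMAT=<ID=FREQ,Number=1,Type=String,Description="Variant frequency percent">',
                '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'),
    alt_dp = c('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=AO,Number=A,Type=Integer,Description="ALT observation count">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'),
    strelka = c('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
                '##FORMAT=<ID=AU,Number=2,Type=Integer,Description="A counts tier1,tier2">',
                '##FORMAT=<ID=CU,Number=2,Type=Integer,Description="C counts tier1,tier2">',
                '##FORMAT=<ID=GU,Number=2,Type=Integer,Description="G counts tier1,tier2">',
                '##FORMAT=<ID=TU,Number=2,Type=Integer,Description="T counts tier1,tier2">',
                '##FORMAT=<ID=TAR,Number=2,Type=Integer,Description="Ref indel counts tier1,tier2">',
                '##FORMAT=<ID=TIR,Number=2,Type=Integer,Description="Indel counts tier1,tier2">'))
  c("##fileformat=VCFv4.2",
    "##source=consensusvc-simulate",
    sprintf("##contig=<ID=%s,length=%d>", cfg$contig, as.integer(cfg$contig_length)),
    fmt,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "TUMOR"), collapse = "\t"))
}

fixture_sample_field <- function(v, style) {
  gt <- "0/1"
  refd <- v$total_depth - v$alt_depth
  switch(style,
    ad = sprintf("%s:%d,%d:%d", gt, refd, v$alt_depth, v$total_depth),
    af = sprintf("%s:%.6f:%d,%d:%d", gt, v$vaf, refd, v$alt_depth, v$total_depth),
    percent = sprintf("%s:%d:%.4f%%:%d", gt, v$alt_depth, v$vaf * 100, v$total_depth),
    alt_dp = sprintf("%s:%d:%d", gt, v$alt_depth, v$total_depth),
    strelka = {
      snv <- v$variant_class == "SNV"
      out <- character(nrow(v))
      if (any(snv)) {
        s <- v[snv]
        rd <- refd[snv]
        cnt <- function(b) {
          c1 <- ifelse(s$ref == b, rd, ifelse(s$alt == b, s$alt_depth, 0L))
          sprintf("%d,%d", c1, c1)
        }
        out[snv] <- sprintf("%s:%d:%s:%s:%s:%s:.:.", gt, s$total_depth,
                            cnt("A"), cnt("C"), cnt("G"), cnt("T"))
      }
      if (any(!snv)) {
        s <- v[!snv]
        out[!snv] <- sprintf("%s:%d:.:.:.:.:%d,%d:%d,%d", gt, s$total_depth,
                             s$total_depth - s$alt_depth, s$total_depth - s$alt_depth,
                             s$alt_depth, s$alt_depth)
      }
      out
    })
}

fixture_format_string <- function(style, variant_class) {
  switch(style,
    ad = "GT:AD:DP",
    af = "GT:AF:AD:DP",
    percent = "GT:AD:FREQ:DP",
    alt_dp = "GT:AO:DP",
    strelka = ifelse(variant_class == "SNV", "GT:DP:AU:CU:GU:TU:TAR:TIR",
                     "GT:DP:AU:CU:GU:TU:TAR:TIR"))
}

#' The dialect matching a fixture FORMAT style
#'
#' @param style one of `"ad"`, `"af"`, `"percent"`, `"alt_dp"`, `"strelka"`.
#' @param caller_id caller id to stamp on the dialect.
#' @return a [caller_dialect()].
#' @export
fixture_dialect <- function(style, caller_id = style) {
  strategies <- switch(style,
    ad = list(list(type = "ad", field = "AD"), list(type = "dp", field = "DP")),
    af = list(list(type = "af", field = "AF"), list(type = "ad", field = "AD"),
              list(type = "dp", field = "DP")),
    percent = list(list(type = "percent", field = "FREQ"),
                   list(type = "alt_dp", alt_field = "AD", dp_field = "DP")),
    alt_dp = list(list(type = "alt_dp", alt_field = "AO", dp_field = "DP")),
    strelka = list(list(type = "strelka_snv"), list(type = "strelka_indel"),
                   list(type = "dp", field = "DP")),
    stop_config(sprintf("unknown fixture style '%s'", style)))
  caller_dialect(caller_id, strategies)
}

write_one_fixture_vcf <- function(cs, style, cfg, path) {
  v <- cs$variants
  header <- fixture_header(cfg, style)
  body <- if (nrow(v) == 0L) character(0) else {
    paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".",
          fixture_format_string(style, v$variant_class),
          fixture_sample_field(v, style), sep = "\t")
  }
  write_atomically(path, function(tmp) writeLines(c(header, body), tmp))
}

#' Write a simulated dataset as per-caller VCF fixtures
#'
#' Writes one VCF per caller (each in its assigned FORMAT dialect, so every
#' support-extraction strategy gets exercised), a truth VCF, and the
#' bookkeeping manifest as TSV. All files are plain text and read back with
#' zero skipped records.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return list with `caller_vcfs` (named paths), `truth_vcf`,
#'   `manifest`, and `dialects` (named list of [caller_dialect()]s to read
#'   the files back with).
#' @export
write_fixture_vcfs <- function(dataset, dir) {
  stopifnot(inherits(dataset, "SimulatedDataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- dataset$config
  paths <- character(0)
  dialects <- list()
  for (cid in names(dataset$callsets)) {
    style <- dataset$dialect_styles[[cid]]
    p <- file.path(dir, paste0(cid, ".vcf"))
    write_one_fixture_vcf(dataset$callsets[[cid]], style, cfg, p)
    paths[cid] <- p
    dialects[[cid]] <- fixture_dialect(style, cid)
  }
  truth_path <- file.path(dir, "truth.vcf")
  write_one_fixture_vcf(dataset$truth, "ad", cfg, truth_path)
  manifest_path <- file.path(dir, "manifest.tsv")
  write_atomically(manifest_path, function(tmp) {
    data.table::fwrite(dataset$manifest, tmp, sep = "\t")
  })
  list(caller_vcfs = paths, truth_vcf = truth_path,
       manifest = manifest_path, dialects = dialects)
}
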