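test_that("extract_support resolves each dialect strategy", {
  # direct AF tag
  d_af <- caller_dialect("x", list(list(type = "af", field = "AF")))
  expect_equal(extract_support("GT:AF", "0/1:0.12", d_af)$vaf, 0.12)

  # AD pair: vaf = alt/(ref+alt)
  d_ad <- caller_dialect("x", list(list(type = "ad", field = "AD")))
  got <- extract_support("GT:AD:DP", "0/1:18,2:20", d_ad)
  expect_equal(got$alt_depth, 2L)
  expect_equal(got$total_depth, 20L)
  expect_equal(got$vaf, 0.1)
  # zero denominator convention
  expect_equal(extract_support("AD", "0,0", d_ad)$vaf, 0)

  # percent string
  d_pc <- caller_dialect("x", list(list(type = "percent", field = "FREQ")))
  expect_equal(extract_support("FREQ", "10%", d_pc)$vaf, 0.1)

  # alt count + DP
  d_adp <- caller_dialect("x", list(
    list(type = "alt_dp", alt_field = "AD", dp_field = "DP")))
  got <- extract_support("AD:DP", "5:50", d_adp)
  expect_equal(got$vaf, 0.1)

  # DP4 strand counts
  d_dp4 <- caller_dialect("x", list(list(type = "dp4", field = "DP4")))
  got <- extract_support("DP4", "10,8,3,4", d_dp4)
  expect_equal(got$alt_depth, 7L)
  expect_equal(got$total_depth, 25L)

  # strelka tier-1 counts
  d_st <- caller_dialect("x", list(list(type = "strelka_snv")))
  got <- extract_support("AU:CU:GU:TU", "2,3:28,30:0,0:0,0", d_st,
                         ref = "C", alt = "A")
  expect_equal(got$alt_depth, 2L)
  expect_equal(got$total_depth, 30L)

  # ordered fallback: first applicable strategy wins; absence -> unknown
  d_multi <- caller_dialect("x", list(
    list(type = "af", field = "AF"),
    list(type = "ad", field = "AD")))
  expect_equal(extract_support("GT:AD", "0/1:18,2", d_multi)$vaf, 0.1)
  unknown <- extract_support("GT", "0/1", d_multi)
  expect_true(is.na(unknown$vaf) && is.na(unknown$alt_depth))
})

test_that("read_caller_vcf parses, skips symbolic ALTs, and accounts records", {
  recs <- c(
    "chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT:AD:DP\t0/1:20,10:30",
    "chr1\t200\t.\tT\t<DEL>\t50\tPASS\t.\tGT:AD:DP\t0/1:20,10:30",
    "chr1\t300\t.\tC\tT,G\t50\tPASS\t.\tGT:AD:DP\t0/1:20,6,4:30")
  path <- write_tmp_vcf(vcf_text(recs, std_format_defs))
  cs <- read_caller_vcf(path, dialect = "generic", caller_id = "c1")
  expect_s3_class(cs, "CallSet")
  expect_equal(cs$n_read, 3L)
  expect_equal(cs$n_skipped, 1L)
  expect_equal(cs$n_read, cs$n_retained + cs$n_skipped)
  # multi-allelic decomposed with per-allele AD
  expect_setequal(cs$variants$key,
                  c("chr1:100:A:G", "chr1:300:C:T", "chr1:300:C:G"))
  expect_equal(cs$variants[cs$variants$key == "chr1:300:C:G"]$alt_depth, 4L)

  # empty VCF: all counts zero
  empty <- read_caller_vcf(write_tmp_vcf(vcf_text(character(0), std_format_defs)))
  expect_equal(nrow(empty$variants), 0L)
  expect_equal(empty$n_read, 0L)
})

test_that("duplicate keys collapse to the record with highest alt depth", {
  recs <- c(
    "chr1\t100\t.\tATG\tAG\t50\tPASS\t.\tGT:AD:DP\t0/1:20,5:25",
    "chr1\t100\t.\tATGC\tAGC\t50\tPASS\t.\tGT:AD:DP\t0/1:20,9:29")
  path <- write_tmp_vcf(vcf_text(recs, std_format_defs))
  cs <- read_caller_vcf(path, caller_id = "c1")
  expect_equal(nrow(cs$variants), 1L)
  expect_equal(cs$variants$key, "chr1:100:AT:A")
  expect_equal(cs$variants$alt_depth, 9L)
})

test_that("reader errors carry the right classes", {
  garbled <- tempfile(fileext = ".vcf")
  writeLines(c("not a vcf", "chr1\t1\t.\tA\tG\t.\tPASS\t."), garbled)
  expect_error(read_caller_vcf(garbled), class = "cvc_format_error")

  bad <- write_tmp_vcf(vcf_text("chr1\t5\t.\tAX\tG\t.\tPASS\t.\tGT\t0/1",
                                std_format_defs))
  expect_error(read_caller_vcf(bad), class = "cvc_invalid_variant")

  two_samples <- write_tmp_vcf(vcf_text(
    "chr1\t5\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/1",
    std_format_defs, samples = c("S1", "S2")))
  expect_error(read_caller_vcf(two_samples), class = "cvc_config_error")
  expect_silent(cs <- read_caller_vcf(two_samples, tumor_sample = "S2"))
  expect_error(read_caller_vcf(two_samples, tumor_sample = "S3"),
               class = "cvc_config_error")
})

test_that("contig matching is exact unless an alias map is supplied", {
  recs <- "1\t100\t.\tA\tG\t50\tPASS\t.\tGT:AD:DP\t0/1:20,10:30"
  path <- write_tmp_vcf(vcf_text(recs, std_format_defs, contig = "1"))
  plain <- read_caller_vcf(path, caller_id = "x")
  expect_equal(plain$variants$key, "1:100:A:G")
  aliased <- read_caller_vcf(path, caller_id = "x",
                             contig_alias = c("1" = "chr1"))
  expect_equal(aliased$variants$key, "chr1:100:A:G")
  expect_error(read_caller_vcf(path, contig_alias = c("chr1")),
               class = "cvc_config_error")
})

test_that("dialect config files round-trip through the parser", {
  conf <- tempfile(fileext = ".conf")
  writeLines(c("# comment", "[mycaller]", "strategy = percent:FREQ",
               "strategy = alt_dp:AO,DP", "tumor_sample = T1"), conf)
  d <- read_dialect_config(conf)
  expect_named(d, "mycaller")
  expect_equal(d$mycaller$tumor_sample, "T1")
  expect_equal(d$mycaller$strategies[[1]]$type, "percent")
  expect_equal(d$mycaller$strategies[[2]]$alt_field, "AO")

  presets <- dialect_presets()
  expect_true(all(c("muse", "mutect", "mutect2", "pindel", "somaticsniper",
                    "vardict", "varscan", "strelka", "generic") %in%
                    names(presets)))
  expect_error(read_dialect_config(tempfile()), class = "cvc_config_error")
})

test_that("consensus VCF write -> read round-trips keys and support", {
  set.seed(9)
  for (rep in 1:5) {
    callsets <- random_collection(4L, 60L)
    k <- sample(length(callsets), 1L)
    ct <- combine_at_threshold(callsets, k)
    path <- tempfile(fileext = ".vcf")
    write_consensus_vcf(ct, path)
    rt <- read_consensus_vcf(path)
    expect_setequal(rt$variants$key, ct$accepted)
    expect_equal(rt$k, ct$k)
    expect_equal(rt$roster, ct$roster)
    acc <- ct$support[ct$support$key %in% ct$accepted]
    merged <- merge(rt$variants[, .(key, n_support)],
                    acc[, .(key, n_support)], by = "key")
    expect_equal(merged$n_support.x, merged$n_support.y)
    # and the file re-reads as a plain callset with zero skips
    back <- read_caller_vcf(path, caller_id = "consensus")
    expect_setequal(back$variants$key, ct$accepted)
    expect_equal(back$n_skipped, 0L)
  }
  # empty acceptance -> header-only VCF that still parses
  empty_ct <- combine_at_threshold(list(mock_callset("a", character(0))), 1)
  p <- tempfile(fileext = ".vcf")
  write_consensus_vcf(empty_ct, p)
  expect_equal(nrow(read_consensus_vcf(p)$variants), 0L)
})

test_that("reader agrees with VariantAnnotation on a mixed fixture", {
  skip_if_not_installed("VariantAnnotation")
  ds <- simulate_dataset(small_sim_config(23, n_callers = 1L, snv_fraction = 0.6,
                                          shared_fp = 0L, shared_fp_callers = 1L))
  files <- write_fixture_vcfs(ds, tempfile())
  path <- files$caller_vcfs[[1]]
  mine <- read_caller_vcf(path, dialect = files$dialects[[1]])
  va <- suppressWarnings(VariantAnnotation::readVcf(path, genome = "x"))
  rr <- SummarizedExperiment::rowRanges(va)
  va_keys <- paste(as.character(GenomicRanges::seqnames(rr)),
                   GenomicRanges::start(rr),
                   as.character(rr$REF),
                   vapply(rr$ALT, function(a) as.character(a)[1], character(1)),
                   sep = ":")
  expect_setequal(mine$variants$key, va_keys)
})
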