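test_that("trim_alleles reduces to the minimal form and is idempotent", {
  out <- trim_alleles(c(100L, 5L, 10L), c("ATG", "C", "GCC"),
                      c("AG", "T", "GTC"))
  expect_equal(out$pos, c(100L, 5L, 11L))
  expect_equal(out$ref, c("AT", "C", "C"))
  expect_equal(out$alt, c("A", "T", "T"))

  again <- trim_alleles(out$pos, out$ref, out$alt)
  expect_equal(again, out)

  # brute force over trim orders: suffix-then-prefix equals any interleaving
  # for a set of padded representations of the same edit
  cases <- list(
    list(pos = 7L, ref = "CCATGG", alt = "CCAGG"),
    list(pos = 3L, ref = "TTTA", alt = "TA"),
    list(pos = 1L, ref = "GATTACA", alt = "GATCACA"))
  for (cs in cases) {
    t1 <- trim_alleles(cs$pos, cs$ref, cs$alt)
    expect_true(nchar(t1$ref) >= 1 && nchar(t1$alt) >= 1)
    # re-trim of any partially trimmed intermediate converges to same form
    expect_equal(trim_alleles(t1$pos, t1$ref, t1$alt), t1)
  }
})

test_that("trim_alleles rejects invalid alleles", {
  expect_error(trim_alleles(1, "", "A"), class = "cvc_invalid_variant")
  expect_error(trim_alleles(1, "A", "A"), class = "cvc_invalid_variant")
  expect_error(trim_alleles(1, "AX", "A"), class = "cvc_invalid_variant")
})

test_that("left_align shifts indels through repeat runs", {
  # positions 20..25 spell TAAAAC
  ref <- c(chr1 = paste0(strrep("C", 19), "TAAAAC"))
  out <- left_align(23, "AA", "A", ref, "chr1")
  expect_equal(out, list(pos = 20L, ref = "TA", alt = "T"))

  # every single-A deletion in the run maps to the same leftmost form
  dels <- lapply(21:23, function(p) left_align(p, "AA", "A", ref, "chr1"))
  expect_true(all(vapply(dels, identical, logical(1), out)))

  # SNVs unchanged; already-leftmost unchanged (idempotence)
  expect_equal(left_align(21, "A", "G", ref, "chr1"),
               list(pos = 21L, ref = "A", alt = "G"))
  expect_equal(left_align(20, "TA", "T", ref, "chr1"), out)
})

test_that("left_align errors on reference mismatch; contig start is right-anchored", {
  ref <- c(chr1 = "AAAAATTTTT")
  expect_error(left_align(6, "AA", "A", ref, "chr1"),
               class = "cvc_reference_mismatch")
  expect_error(left_align(3, "AA", "A", ref, "chr2"),
               class = "cvc_data_error")
  # a deletion shifted to the contig start has no upstream anchor: the
  # leftmost valid VCF form anchors on the following base instead
  expect_equal(left_align(3, "AA", "A", ref, "chr1"),
               list(pos = 1L, ref = "AA", alt = "A"))
})

test_that("normalize_variants decomposes multi-base and MNV records", {
  # MNV decomposition: mismatching positions only
  dt <- data.frame(chrom = "chr1", pos = 7L, ref = "AT", alt = "GC")
  out <- normalize_variants(dt)
  expect_equal(nrow(out), 2L)
  expect_equal(out$pos, c(7L, 8L))
  expect_equal(out$ref, c("A", "T"))
  expect_equal(out$alt, c("G", "C"))
  expect_true(all(out$variant_class == "SNV"))

  # positionwise mismatch scan with identical middle base
  out2 <- normalize_variants(
    data.frame(chrom = "chr1", pos = 10L, ref = "ACG", alt = "GCT"))
  expect_equal(out2$pos, c(10L, 12L))
  expect_equal(out2$alt, c("G", "T"))

  # classification partition: SNV or INDEL only after normalization
  set.seed(11)
  rand <- data.frame(
    chrom = "chr1", pos = sample(1000, 50),
    ref = replicate(50, paste(sample(c("A", "C", "G", "T"),
                                     sample(1:4, 1), TRUE), collapse = "")),
    alt = replicate(50, paste(sample(c("A", "C", "G", "T"),
                                     sample(1:4, 1), TRUE), collapse = "")))
  rand <- rand[rand$ref != rand$alt, ]
  norm <- normalize_variants(rand)
  expect_true(all(norm$variant_class %in% c("SNV", "INDEL")))
  expect_equal(normalize_variants(norm), norm)  # idempotence
})

test_that("make_key matches equivalent representations and rejects raw ones", {
  # left-anchored and right-anchored forms of the same T deletion: trimming
  # alone cannot unify them (the shared suffix is the ALT's only base), but
  # normalization against the reference maps both to one key
  reference <- c(chr1 = paste0(strrep("C", 99), "ATGGGG"))
  k1 <- normalize_variants(data.frame(chrom = "chr1", pos = 100L,
                                      ref = "ATG", alt = "AG"),
                           reference = reference)$key
  k2 <- normalize_variants(data.frame(chrom = "chr1", pos = 101L,
                                      ref = "TG", alt = "G"),
                           reference = reference)$key
  expect_identical(k1, k2)
  # suffix-then-prefix trimming unifies padded forms without a reference
  t1 <- trim_alleles(100L, "ATG", "AG")
  t2 <- trim_alleles(100L, "ATGC", "AGC")
  expect_identical(make_key("chr1", t1$pos, t1$ref, t1$alt),
                   make_key("chr1", t2$pos, t2$ref, t2$alt))
  expect_false(make_key("chr1", 7, "A", "G") == make_key("chr1", 7, "A", "T"))
  expect_error(make_key("chr1", 100, "ATG", "AG"), class = "cvc_config_error")
  expect_equal(parse_key("chr1:100:AT:A"),
               data.table::as.data.table(list(chrom = "chr1", pos = 100L,
                                              ref = "AT", alt = "A")))
})

test_that("normalization maps brute-forced equivalent indel reps to one key", {
  set.seed(71)
  for (i in 1:40) {
    window <- random_repeat_window(24L)
    rep0 <- random_indel_rep(window)
    reps <- enumerate_equivalent_reps(window, rep0$pos, rep0$ref, rep0$alt)
    expect_gt(length(reps), 0L)
    reference <- c(chrW = window)
    keys <- vapply(reps, function(r) {
      normalize_variants(data.frame(chrom = "chrW", pos = r$pos,
                                    ref = r$ref, alt = r$alt),
                         reference = reference)$key
    }, character(1))
    expect_length(unique(keys), 1L)
  }
})
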