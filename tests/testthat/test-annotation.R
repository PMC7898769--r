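test_that("rmsk parsing maps fields, filters, and validates", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t1000\t1337\t+\tIAPLTR2_Mm\tLTR/ERVK\t7",
               "chr1\t2000\t2500\t-\tL1Md_A\tLINE/L1\t8"), tmp)
  f <- parse_rm_annotation(tmp)
  expect_equal(nrow(f), 2L)
  expect_equal(f$element_id[1], 7L)
  expect_equal(f$start[1], 1000L)
  expect_equal(f$end[1], 1337L)

  f_iap <- parse_rm_annotation(tmp, iap_only = TRUE)
  expect_equal(f_iap$rep_name, "IAPLTR2_Mm")

  # UCSC header dialect
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("genoName", "genoStart", "genoEnd", "strand", "repName",
                     "repClass", "repFamily", "id", sep = "\t"),
               "chr2\t10\t90\t+\tIAPEz-int\tLTR\tERVK\t3"), tmp2)
  f2 <- parse_rm_annotation(tmp2)
  expect_equal(f2$chrom, "chr2")
  expect_equal(f2$rep_class_family, "LTR/ERVK")

  # malformed rows
  tmp3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chr1\t500\t100\t+\tIAPLTR2_Mm\tLTR/ERVK\t1", tmp3)
  expect_error(parse_rm_annotation(tmp3), "line 1")
  tmp4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chr1\t100\t500\t*\tIAPLTR2_Mm\tLTR/ERVK\t1", tmp4)
  expect_error(parse_rm_annotation(tmp4), "strand")
})

test_that("empty annotation gives an empty catalogue with zero summary", {
  cat0 <- group_into_elements(feat(character(0), integer(0), integer(0),
                                   character(0), character(0), integer(0)))
  expect_equal(nrow(cat0$elements), 0L)
  s <- summarize_catalogue(cat0)
  expect_equal(s$n_elements, 0L)
  expect_equal(s$fragmented_fraction, 0)
})

test_that("grouping unites ids and splits on chrom/strand with a warning", {
  f <- rbind(feat("chr1", c(100, 600, 1200), c(500, 1100, 1600),
                  "+", c("IAPLTR1_Mm", "IAPEz-int", "IAPLTR1_Mm"), 7),
             feat("chr1", 5000, 5400, "+", "IAPLTR2_Mm", 8))
  cat0 <- group_into_elements(f)
  expect_equal(nrow(cat0$elements), 2L)
  expect_equal(cat0$elements$n_features, c(3L, 1L))

  f2 <- rbind(feat("chr1", 100, 400, "+", "IAPLTR2_Mm", 7),
              feat("chr2", 100, 400, "+", "IAPLTR2_Mm", 7))
  expect_warning(cat2 <- group_into_elements(f2), "chromosomes")
  expect_equal(nrow(cat2$elements), 2L)

  # interleaved ids (nested insertion) stay grouped
  f3 <- rbind(feat("chr1", c(100, 3000), c(500, 3400), "+",
                   c("IAPLTR1_Mm", "IAPLTR1_Mm"), 7),
              feat("chr1", 600, 2900, "+", "IAPEz-int", 9))
  cat3 <- group_into_elements(f3)
  expect_equal(nrow(cat3$elements), 2L)
  expect_equal(sort(cat3$elements$n_features), c(1L, 2L))

  # same id, huge gap: guard rail splits
  f4 <- feat("chr1", c(100, 90000), c(500, 90500), "+",
             c("IAPLTR2_Mm", "IAPLTR2_Mm"), 7)
  expect_equal(nrow(group_into_elements(f4)$elements), 2L)
})

test_that("structure classification covers all classes, strand-aware", {
  mk <- function(names, strand = "+") {
    n <- length(names)
    feat("chr1", seq(0, by = 1000, length.out = n),
         seq(900, by = 1000, length.out = n), strand, names, 1)
  }
  expect_equal(classify_structure(mk(c("IAPLTR1_Mm", "IAPEz-int",
                                       "IAPLTR1_Mm"))), "FULL")
  expect_equal(classify_structure(mk("IAPLTR2_Mm")), "SOLO_LTR")
  expect_equal(classify_structure(mk("IAPEz-int")), "FRAG_INTERNAL_ONLY")
  expect_equal(classify_structure(mk(c("IAPLTR1_Mm", "IAPEz-int"))), "FRAG_NO3")
  expect_equal(classify_structure(mk(c("IAPEz-int", "IAPLTR1_Mm"))), "FRAG_NO5")
  expect_equal(classify_structure(mk(c("IAPEz-int", "IAPLTR1_Mm",
                                       "IAPEz-int"))), "FRAG_OTHER")
  # minus strand flips 5'/3'
  expect_equal(classify_structure(mk(c("IAPLTR1_Mm", "IAPEz-int"), "-")),
               "FRAG_NO5")
  # IAPLTR4_I is internal by registry, RLTR10B2 is an LTR
  expect_equal(classify_structure(mk(c("RLTR10B2", "IAPLTR4_I", "RLTR10B2"))),
               "FULL")
  expect_error(classify_structure(mk(character(0))), "no features")
})

test_that("500 kb boundary splits are patched exactly at multiples", {
  f <- rbind(feat("chr1", 499000, 500000, "+", "IAPLTR1_Mm", 1),
             feat("chr1", 500000, 501500, "+", "IAPEz-int", 2),
             feat("chr1", 501500, 502500, "+", "IAPLTR1_Mm", 2))
  cat0 <- group_into_elements(f)
  expect_equal(nrow(cat0$elements), 2L)
  patched <- patch_boundary_splits(cat0)
  expect_equal(nrow(patched$elements), 1L)
  expect_equal(patched$elements$structure, "FULL")

  # facing boundaries not at a multiple: untouched
  f2 <- rbind(feat("chr1", 498000, 499123, "+", "IAPLTR1_Mm", 1),
              feat("chr1", 499123, 499500, "+", "IAPEz-int", 2))
  expect_equal(nrow(patch_boundary_splits(group_into_elements(f2))$elements),
               2L)

  # different strand never unified
  f3 <- rbind(feat("chr1", 499000, 500000, "+", "IAPLTR1_Mm", 1),
              feat("chr1", 500000, 500800, "-", "IAPLTR1_Mm", 2))
  expect_equal(nrow(patch_boundary_splits(group_into_elements(f3))$elements),
               2L)

  empty <- group_into_elements(feat(character(0), integer(0), integer(0),
                                    character(0), character(0), integer(0)))
  expect_equal(nrow(patch_boundary_splits(empty)$elements), 0L)
})

test_that("mending merges facing fragments within the gap limit", {
  # FRAG_NO3 + FRAG_NO5, gap 500 <= 2000: one FULL element
  f <- rbind(feat("chr1", c(1000, 2000), c(1900, 3000), "+",
                  c("IAPLTR1_Mm", "IAPEz-int"), 1),
             feat("chr1", c(3500, 5200), c(5100, 6000), "+",
                  c("IAPEz-int", "IAPLTR1_Mm"), 2))
  m <- mend_fragmented(group_into_elements(f))
  expect_equal(nrow(m$elements), 1L)
  expect_equal(m$elements$structure, "FULL")
  expect_equal(m$elements$start, 1000L)
  expect_equal(m$elements$end, 6000L)

  # same pair, gap 2500: unchanged
  f2 <- rbind(feat("chr1", c(1000, 2000), c(1900, 3000), "+",
                   c("IAPLTR1_Mm", "IAPEz-int"), 1),
              feat("chr1", c(5500, 7200), c(7100, 8000), "+",
                   c("IAPEz-int", "IAPLTR1_Mm"), 2))
  m2 <- mend_fragmented(group_into_elements(f2))
  expect_equal(nrow(m2$elements), 2L)

  # FRAG_NO5 with a solo LTR ending 100 bp upstream: merged to FULL
  f3 <- rbind(feat("chr1", 1000, 1400, "+", "IAPLTR2_Mm", 1),
              feat("chr1", c(1500, 3000), c(2900, 3400), "+",
                   c("IAPEz-int", "IAPLTR2_Mm"), 2))
  m3 <- mend_fragmented(group_into_elements(f3))
  expect_equal(nrow(m3$elements), 1L)
  expect_equal(m3$elements$structure, "FULL")

  # merging with a FULL partner forms a higher-order FULL element
  f4 <- rbind(feat("chr1", c(1000, 1500, 3000), c(1400, 2900, 3400), "+",
                   c("IAPLTR1_Mm", "IAPEz-int", "IAPLTR1_Mm"), 1),
              feat("chr1", c(3600, 5200), c(5100, 5600), "+",
                   c("IAPEz-int", "IAPLTR1_Mm"), 2))
  m4 <- mend_fragmented(group_into_elements(f4))
  expect_equal(nrow(m4$elements), 1L)
  expect_equal(m4$elements$structure, "FULL")
  expect_equal(m4$elements$n_features, 5L)

  # internal-only fragment mends on both edges with two solo LTRs
  f5 <- rbind(feat("chr1", 1000, 1400, "+", "IAPLTR2_Mm", 1),
              feat("chr1", 1500, 2900, "+", "IAPEz-int", 2),
              feat("chr1", 3000, 3400, "+", "IAPLTR2_Mm", 3))
  m5 <- mend_fragmented(group_into_elements(f5))
  expect_equal(nrow(m5$elements), 1L)
  expect_equal(m5$elements$structure, "FULL")

  # strand mismatch blocks merging
  f6 <- rbind(feat("chr1", c(1000, 2000), c(1900, 3000), "+",
                   c("IAPLTR1_Mm", "IAPEz-int"), 1),
              feat("chr1", c(3500, 5200), c(5100, 6000), "-",
                   c("IAPEz-int", "IAPLTR1_Mm"), 2))
  expect_equal(nrow(mend_fragmented(group_into_elements(f6))$elements), 2L)
})

test_that("minus-strand fragments mend with strand-aware edges", {
  # on -, the 5' LTR sits at the genomic right; a FRAG_NO5 (- strand) must
  # find its partner to the genomic right
  f <- rbind(feat("chr1", c(1000, 2000), c(1900, 3000), "-",
                  c("IAPLTR1_Mm", "IAPEz-int"), 1),   # LTR at left = 3' LTR
             feat("chr1", 3200, 3600, "-", "IAPLTR1_Mm", 2))
  cat0 <- group_into_elements(f)
  expect_equal(sort(cat0$elements$structure), c("FRAG_NO5", "SOLO_LTR"))
  m <- mend_fragmented(cat0)
  expect_equal(m$elements$structure, "FULL")
})

test_that("catalogue summary counts match structures and io round-trips", {
  f <- rbind(feat("chr1", c(1000, 1500, 3000), c(1400, 2900, 3400), "+",
                  c("IAPLTR1_Mm", "IAPEz-int", "IAPLTR1_Mm"), 1),
             feat("chr1", 10000, 10400, "-", "IAPLTR2_Mm", 2),
             feat("chr1", 20000, 21500, "+", "IAPEz-int", 3))
  cat0 <- group_into_elements(f)
  s <- summarize_catalogue(cat0)
  expect_equal(s$n_elements, 3L)
  expect_equal(s$n_full, 1L)
  expect_equal(s$n_solo_ltr, 1L)
  expect_equal(s$n_fragmented, 1L)
  expect_equal(s$fragmented_fraction, 1 / 3)

  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_catalogue(cat0, tmp)
  back <- read_catalogue(tmp)
  expect_equal(nrow(back), 3L)
  expect_equal(sort(back$structure), sort(cat0$elements$structure))
  # subelement order is element-relative 5' to 3'
  expect_equal(back$subelements[back$element_id == 1],
               "IAPLTR1_Mm,IAPEz-int,IAPLTR1_Mm")

  bed <- withr::local_tempfile(fileext = ".bed")
  write_catalogue_bed(cat0, bed)
  b <- read.table(bed, sep = "\t")
  expect_equal(ncol(b), 6L)
  expect_equal(nrow(b), 3L)
})

test_that("registry io round-trips and roles fall back to naming", {
  reg <- default_iap_registry()
  expect_length(reg$iap_types, 25L)
  expect_length(reg$ltr_types, 15L)
  expect_length(reg$internal_types, 10L)
  expect_true("IAPLTR4_I" %in% reg$internal_types)
  expect_true("RLTR10B2" %in% reg$ltr_types)

  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_iap_registry(reg, tmp)
  reg2 <- read_iap_registry(tmp)
  expect_setequal(reg2$internal_types, reg$internal_types)

  expect_equal(subelement_role(c("FOO_LTR", "FOO-int"), reg),
               c("ltr", "internal"))
})
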