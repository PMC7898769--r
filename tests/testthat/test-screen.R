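# helpers to build hand-crafted coverage for one sample
cov_df <- function(pos, n_meth, n_unmeth, chrom = "chr1") {
  data.frame(chrom = chrom, pos = as.integer(pos),
             n_meth = as.integer(n_meth), n_unmeth = as.integer(n_unmeth),
             stringsAsFactors = FALSE)
}

test_that("edge windows take the nearest inside CpGs, strand-aware", {
  p <- screen_params()
  el <- data.frame(chrom = "chr1", start = 0L, end = 1000L, strand = "+")
  w <- build_edge_windows(el, seq(10L, 200L, by = 10L), p)
  expect_equal(w$five_prime, seq(10L, 80L, by = 10L))
  expect_equal(w$three_prime, seq(130L, 200L, by = 10L))

  # minus strand swaps the element-relative edges
  el_m <- transform(el, strand = "-")
  wm <- build_edge_windows(el_m, seq(10L, 200L, by = 10L), p)
  expect_equal(wm$five_prime, w$three_prime)
  expect_equal(wm$three_prime, w$five_prime)

  # fewer CpGs than requested: all returned
  w5 <- build_edge_windows(el, c(10L, 20L, 30L, 40L, 50L), p)
  expect_equal(w5$five_prime, c(10L, 20L, 30L, 40L, 50L))

  # CpGs outside the element are never used
  w_out <- build_edge_windows(el, c(-50L, 10L, 1500L), p)
  expect_equal(w_out$five_prime, 10L)

  # distance cap for the non-IAP screen
  p200 <- screen_params(edge_max_dist = 200)
  wc <- build_edge_windows(el, c(50L, 300L), p200)
  expect_equal(wc$five_prime, 50L)

  # zero internal CpGs: empty window, not an error
  expect_equal(build_edge_windows(el, integer(0), p)$five_prime, integer(0))
})

test_that("sample edge methylation pools counts and flags informativeness", {
  p <- screen_params()
  w <- seq(10L, 80L, by = 10L)
  # 8 CpGs each 5/0: fully methylated and informative
  s <- sample_edge_methylation(w, cov_df(w, 5, 0), p)
  expect_equal(s$mean_meth, 1)
  expect_equal(s$total_calls, 40L)
  expect_true(s$informative)

  # 19 calls over 8 CpGs: below the 20-call floor
  s19 <- sample_edge_methylation(w, cov_df(w, c(2, 2, 2, 2, 2, 2, 2, 2),
                                           c(1, 0, 0, 0, 0, 1, 0, 1)), p)
  expect_equal(s19$total_calls, 19L)
  expect_false(s19$informative)

  # 30 calls but only 3 covered CpGs: below the 4-CpG floor
  s3 <- sample_edge_methylation(w, cov_df(w[1:3], 10, 0), p)
  expect_equal(s3$covered_cpgs, 3L)
  expect_false(s3$informative)

  # empty window: undefined mean, uninformative
  s0 <- sample_edge_methylation(integer(0), cov_df(w, 5, 0), p)
  expect_true(is.na(s0$mean_meth))
  expect_false(s0$informative)

  # pooled mean weights CpGs by coverage
  sp <- sample_edge_methylation(w[1:4], cov_df(w[1:4], c(30, 0, 0, 0),
                                               c(0, 10, 10, 10)), p)
  expect_equal(sp$mean_meth, 0.5)
  pp <- screen_params(mean_method = "per_cpg")
  sp2 <- sample_edge_methylation(w[1:4], cov_df(w[1:4], c(30, 0, 0, 0),
                                                c(0, 10, 10, 10)), pp)
  expect_equal(sp2$mean_meth, 0.25)
})

test_that("edge ranges, sample filter and candidate rule follow the design", {
  p <- screen_params()
  mk <- function(B, T_, inf_B = TRUE, inf_T = TRUE) {
    data.frame(group = rep(c("B", "T"), c(length(B), length(T_))),
               mean_meth = c(B, T_),
               informative = c(rep_len(inf_B, length(B)),
                               rep_len(inf_T, length(T_))))
  }
  # range is max - min with no trimming of extremes
  r <- edge_range(mk(c(.20, .35, .50, .70, .90), rep(.5, 5)), p)
  expect_equal(unname(r$range["B"]), 0.70)

  # 4 informative samples in one group: filter fails
  r4 <- edge_range(mk(c(.2, .3, .4, .5), rep(.5, 5)), p)
  expect_false(r4$passed_sample_filter)
  expect_false(r4$candidate)
  expect_true(is.na(r4$statistic))

  # statistic is the min over groups; candidate at >= 0.10
  r2 <- edge_range(mk(c(.2, .25, .3, .35, .45), c(.50, .52, .54, .56, .62)), p)
  expect_equal(unname(r2$statistic), 0.12)
  expect_true(r2$candidate)
  r3 <- edge_range(mk(c(.2, .25, .3, .35, .45), c(.50, .52, .54, .56, .59)), p)
  expect_equal(unname(r3$statistic), 0.09)
  expect_false(r3$candidate)

  # uninformative samples never change a range
  base <- mk(c(.2, .3, .4, .5, .6), rep(.5, 5))
  extra <- rbind(base, data.frame(group = "B", mean_meth = 0,
                                  informative = FALSE))
  expect_equal(edge_range(base, p)$range, edge_range(extra, p)$range)

  # an entirely uninformative group fails the filter
  rno <- edge_range(mk(c(.2, .3, .4, .5, .6), rep(.5, 5), inf_T = FALSE), p)
  expect_false(rno$passed_sample_filter)
})

test_that("screen equals the brute-force oracle on hand-built data", {
  # 5 elements x 6 samples (3 per group), permissive thresholds so all
  # combinations of informative/uninformative and ranges are exercised
  p <- screen_params(min_calls = 10, min_covered_cpgs = 2,
                     min_informative_samples = 2, n_edge_cpgs = 4)
  set.seed(42)
  elements <- data.frame(
    element_id = 1:5, chrom = "chr1",
    start = seq(0L, by = 4000L, length.out = 5),
    end = seq(0L, by = 4000L, length.out = 5) + 2000L,
    strand = c("+", "-", "+", "-", "+"),
    structure = "FULL", stringsAsFactors = FALSE)
  cpgs <- sort(unlist(lapply(elements$start, function(s)
    s + sort(sample(0:1999, 12)))))
  samples <- data.frame(sample_id = sprintf("s%d", 1:6),
                        group = rep(c("B", "T"), each = 3),
                        stringsAsFactors = FALSE)
  coverage <- lapply(setNames(nm = samples$sample_id), function(s) {
    keep <- runif(length(cpgs)) > 0.2   # random missingness
    tot <- rpois(sum(keep), 8)
    meth <- rbinom(sum(keep), tot, runif(1, .1, .9))
    cov_df(cpgs[keep], meth, tot - meth)
  })
  scr <- screen_catalogue(elements, coverage, samples, p)
  want <- oracle_screen(elements, coverage, samples, p)
  for (i in seq_len(nrow(scr$edges))) {
    e <- scr$edges[i, ]
    o <- want[[paste(e$element_id, e$edge)]]
    expect_equal(e$passed_sample_filter, o$passed)
    expect_equal(c(e$n_informative_B, e$n_informative_T),
                 unname(unlist(o$n_informative)))
    expect_equal(c(e$range_B, e$range_T), unname(unlist(o$range)))
    expect_equal(e$statistic, unname(o$statistic))
    expect_equal(e$candidate, o$candidate)
  }
  # per-sample audit means equal brute-force recomputation
  aud <- scr$sample_edges
  for (j in sample(nrow(aud), 20)) {
    r <- aud[j, ]
    el <- elements[elements$element_id == r$element_id, ]
    w <- oracle_screen(el, coverage[r$sample_id],
                       samples[samples$sample_id == r$sample_id, , drop = FALSE],
                       screen_params(min_calls = 1, min_covered_cpgs = 1,
                                     min_informative_samples = 1,
                                     n_edge_cpgs = 4))
    # recompute the pooled mean directly
    cc <- coverage[[r$sample_id]]
    inside <- cpgs[cpgs >= el$start & cpgs < el$end]
    d <- if ((r$edge == "five_prime") == (el$strand == "+")) {
      inside - el$start
    } else (el$end - 1) - inside
    wpos <- inside[order(d)][1:4]
    cc <- cc[cc$pos %in% wpos, ]
    if (sum(cc$n_meth + cc$n_unmeth) > 0) {
      expect_equal(r$mean_meth,
                   sum(cc$n_meth) / sum(cc$n_meth + cc$n_unmeth))
    } else {
      expect_true(is.na(r$mean_meth))
    }
  }
})

test_that("screen is invariant to sample and row ordering", {
  sim <- simulate_genome(sim_params(n_elements = 15, seed = 21,
                                    vm_fraction = 0.2))
  cov <- simulate_coverage(sim)
  cat0 <- group_into_elements(parse_rm_annotation(sim$truth$features))
  s1 <- screen_catalogue(cat0, cov$coverage, cov$samples,
                         cpg_positions = cov$cpg_positions)
  perm <- rev(seq_len(nrow(cov$samples)))
  shuffled_cov <- lapply(cov$coverage[perm], function(cc) {
    cc[sample(nrow(cc)), , drop = FALSE]
  })
  s2 <- screen_catalogue(cat0, shuffled_cov, cov$samples[perm, ],
                         cpg_positions = cov$cpg_positions)
  expect_equal(s1$edges, s2$edges)
})

test_that("filter monotonicity: stricter thresholds never add survivors", {
  sim <- simulate_genome(sim_params(n_elements = 12, seed = 33,
                                    coverage_mean = 4))  # sparse coverage
  cov <- simulate_coverage(sim)
  cat0 <- group_into_elements(parse_rm_annotation(sim$truth$features))
  loose <- screen_catalogue(cat0, cov$coverage, cov$samples,
                            screen_params(min_calls = 10, min_covered_cpgs = 2),
                            cpg_positions = cov$cpg_positions)
  strict <- screen_catalogue(cat0, cov$coverage, cov$samples,
                             screen_params(min_calls = 25, min_covered_cpgs = 6),
                             cpg_positions = cov$cpg_positions)
  expect_lte(sum(strict$sample_edges$informative),
             sum(loose$sample_edges$informative))
  expect_lte(sum(strict$edges$passed_sample_filter),
             sum(loose$edges$passed_sample_filter))
  stricter_n <- screen_catalogue(cat0, cov$coverage, cov$samples,
                                 screen_params(min_informative_samples = 8),
                                 cpg_positions = cov$cpg_positions)
  base_n <- screen_catalogue(cat0, cov$coverage, cov$samples,
                             screen_params(min_informative_samples = 5),
                             cpg_positions = cov$cpg_positions)
  expect_lte(sum(stricter_n$edges$passed_sample_filter),
             sum(base_n$edges$passed_sample_filter))
})

test_that("degenerate screens behave: no samples, saturated methylation", {
  el <- data.frame(element_id = 1L, chrom = "chr1", start = 0L, end = 1000L,
                   strand = "+", structure = "FULL")
  expect_error(screen_catalogue(el, list(), data.frame()), "no samples")

  # fully methylated everywhere: ranges 0, zero candidates
  pos <- seq(10L, 900L, by = 50L)
  samples <- data.frame(sample_id = sprintf("s%d", 1:10),
                        group = rep(c("B", "T"), each = 5))
  coverage <- lapply(setNames(nm = samples$sample_id),
                     function(s) cov_df(pos, 10, 0))
  scr <- screen_catalogue(el, coverage, samples)
  expect_true(all(scr$edges$passed_sample_filter))
  expect_equal(sum(scr$edges$candidate), 0L)
  expect_equal(max(abs(scr$edges$statistic)), 0)
})

test_that("non-IAP element preparation joins same-class neighbours", {
  f <- rbind(feat("chr1", c(100, 1080), c(1000, 2000), "+",
                  "L1Md_A", 1:2, family = "LINE/L1"),
             feat("chr1", c(5000, 6150), c(6000, 7000), "+",
                  "L1Md_A", 3:4, family = "LINE/L1"),
             feat("chr2", c(100, 1050), c(1000, 1900), c("+", "-"),
                  "B1_Mm", 5:6, family = "SINE/Alu"))
  el <- prepare_non_iap_elements(f)
  # 80 bp gap joined; 150 bp gap not; opposite strands never joined
  expect_equal(nrow(el), 5L)
  joined <- el[el$n_features == 2L, ]
  expect_equal(joined$start, 100L)
  expect_equal(joined$end, 2000L)
  expect_equal(prepare_non_iap_elements(f[0, ]) |> nrow(), 0L)
})
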