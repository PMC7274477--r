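peaks_at <- function(starts, width = 1000, chrom = "cA") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts + 1,
                                                       width = width))
  names(gr) <- paste0("p", seq_along(gr))
  gr
}

test_that("stitching respects the strict gap rule and sums signal", {
  single <- peaks_at(1000)
  st <- stitch_peaks(single, 5)
  expect_length(st, 1)
  expect_equal(st$total_signal, 5)

  # gaps of 12499 stitch, gaps of 12500 do not
  p <- peaks_at(c(0, 1000 + 12499, 1000 + 12499 + 1000 + 12500))
  st2 <- stitch_peaks(p, c(1, 2, 4))
  expect_length(st2, 2)
  expect_equal(sort(st2$total_signal), c(3, 4))
  expect_equal(st2$n_constituents[order(st2$total_signal)], c(2L, 1L))
})

test_that("stitching matches a brute-force connected-components oracle", {
  set.seed(91)
  for (rep in 1:20) {
    n <- 200
    gr <- GenomicRanges::sort(GenomicRanges::GRanges(
      sample(c("cA", "cB"), n, TRUE),
      IRanges::IRanges(sample.int(3e6, n), width = sample(200:1500, n, TRUE))))
    names(gr) <- paste0("p", seq_len(n))
    sig <- runif(n, 0, 10)
    st <- stitch_peaks(gr, sig, 12500)
    # oracle: quadratic transitive closure of the gap-<12500 relation
    comp <- seq_len(n)
    ch <- as.character(GenomicRanges::seqnames(gr))
    s <- GenomicRanges::start(gr); e <- GenomicRanges::end(gr)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      gap <- max(s[j], s[i]) - min(e[j], e[i]) - 1
      if (ch[i] == ch[j] && gap < 12500) {
        old <- comp[j]; comp[comp == old] <- comp[i]
      }
    }
    want_sig <- sort(as.numeric(tapply(sig, comp, sum)))
    expect_equal(sort(st$total_signal), want_sig, tolerance = 1e-9)
    expect_equal(length(st), length(unique(comp)))
  }
})

test_that("stitching is idempotent", {
  set.seed(92)
  gr <- peaks_at(cumsum(sample(c(3000, 20000), 50, TRUE)))
  sig <- runif(50)
  st1 <- stitch_peaks(gr, sig)
  st2 <- stitch_peaks(st1, st1$total_signal)
  expect_equal(GenomicRanges::ranges(st1), GenomicRanges::ranges(st2))
  expect_equal(st1$total_signal, st2$total_signal)
})

test_that("slope cutoff isolates signal outliers and is scale invariant", {
  gr <- peaks_at(seq(0, by = 5e4, length.out = 100))
  sig <- c(rep(1, 99), 100)
  se <- se_cutoff(stitch_peaks(gr, sig, 100))
  expect_equal(sum(se$is_super), 1)
  expect_true(se$is_super[se$total_signal == 100])
  expect_equal(se$rank[se$is_super], 1)

  se2 <- se_cutoff(stitch_peaks(gr, sig * 7, 100))
  expect_identical(se$is_super, se2$is_super)

  expect_warning(out <- se_cutoff(stitch_peaks(gr, rep(3, 100), 100)),
                 "no super")
  expect_false(any(out$is_super))
  expect_error(se_cutoff(stitch_peaks(gr[1:2], c(1, 2), 100)), ">= 3")
})

test_that("adding signal to a super constituent never demotes it", {
  set.seed(93)
  gr <- peaks_at(seq(0, by = 5e4, length.out = 200))
  sig <- rexp(200, 1)^2 * 10
  se <- se_cutoff(stitch_peaks(gr, sig, 100))
  top <- which(se$is_super)
  for (i in top[1:min(3, length(top))]) {
    sig2 <- sig
    sig2[i] <- sig2[i] + 50
    se2 <- se_cutoff(stitch_peaks(gr, sig2, 100))
    expect_true(se2$is_super[i])
  }
})

test_that("planted SE clusters are recovered and enriched for no/TRBS co-occupancy", {
  sim <- small_sim()
  tr <- sim$truth$regions
  ss <- sim$chip_samples[sim$chip_samples$target == "H3K27Ac", ]
  cnt <- sim$chip_counts$H3K27Ac
  norm <- sweep(cnt, 2, median_ratio_size_factors(cnt), "/")
  sig <- rowMeans(norm[, ss$condition[match(colnames(cnt),
                                            ss$sample_id)] == "hyper"])
  ses <- se_cutoff(stitch_peaks(sim$regions, unname(sig)))
  supers <- ses[ses$is_super]
  cl <- tr[!is.na(tr$se_cluster), ]
  spans <- do.call(rbind, lapply(split(cl, cl$se_cluster), function(d)
    data.frame(chrom = d$chrom[1], start = min(d$start), end = max(d$end))))
  span_gr <- GenomicRanges::GRanges(spans$chrom,
                                    IRanges::IRanges(spans$start + 1,
                                                     spans$end))
  expect_gte(mean(IRanges::overlapsAny(span_gr, supers)), 0.8)
  # mean super span close to the configured cluster span
  expect_lt(mean(GenomicRanges::width(supers)), 2 * sim$config$se_span)

  w_gr <- sim$regions[tr$region_id[tr$class %in% c("type1A", "type1B")]]
  no_gr <- sim$regions[tr$region_id[tr$class %in% c("indirect_SE",
                                                    "indirect_loop")]]
  enr <- se_cooccupancy_enrichment(ses, no_gr, w_gr, sim$regions,
                                   n_random = 200, seed = 1001)
  expect_lt(enr$p_value, 0.01)
  expect_gt(enr$odds_ratio, 1)

  # null self-consistency: test set drawn from the pool itself
  set.seed(1002)
  null_test <- sim$regions[sample(length(sim$regions), 80)]
  enr0 <- se_cooccupancy_enrichment(ses, null_test, w_gr, sim$regions,
                                    n_random = 200, seed = 1003)
  expect_gt(enr0$p_value, 0.01)

  # empty SE set degenerates gracefully
  empty <- supers[0]
  enr_e <- se_cooccupancy_enrichment(empty, no_gr, w_gr, sim$regions,
                                     n_random = 100, seed = 1)
  expect_equal(enr_e$fraction, 0)
  expect_equal(enr_e$p_value, 1)
})
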