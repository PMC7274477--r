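tiny_cfg <- function(seed = 9, ...) {
  sim_config(seed = seed, n_regions = 120, n_genes = 80, n_chrom = 2,
             chrom_len = 6e6, hic_max_dist = 4e5,
             loop_dist_range = c(5e4, 1.5e5), ...)
}

test_that("generation is deterministic under the seed", {
  a <- simulate_dataset(tiny_cfg())
  b <- simulate_dataset(tiny_cfg())
  expect_identical(a$truth, b$truth)
  expect_identical(a$chip_counts, b$chip_counts)
  expect_identical(a$rna_counts, b$rna_counts)
  expect_identical(a$hic$contacts, b$hic$contacts)
  c_ <- simulate_dataset(tiny_cfg(seed = 10))
  expect_false(identical(a$chip_counts, c_$chip_counts))
})

test_that("planted class fractions and layout invariants hold", {
  sim <- small_sim()
  tr <- sim$truth$regions
  expect_equal(nrow(tr), 600)
  # hyperacetylated fraction forced by the class fractions
  expect_equal(mean(tr$class %in% hyperac_classes), 0.26, tolerance = 0.01)
  # regions never overlap (clusters are spaced inside their span)
  expect_true(all(GenomicRanges::countOverlaps(sim$regions,
                                               sim$regions) == 1))
  # every indirect_SE region shares its cluster with a TR-bound region
  ise <- tr[tr$class == "indirect_SE", ]
  for (cl in unique(ise$se_cluster)) {
    members <- tr$class[!is.na(tr$se_cluster) & tr$se_cluster == cl]
    expect_true(any(members %in% c("type1A", "type1B")))
  }
  # every indirect_loop region has exactly one loop to a TR-bound partner
  il <- tr$region_id[tr$class == "indirect_loop"]
  expect_setequal(sim$truth$loops$region_b, il)
  expect_equal(anyDuplicated(sim$truth$loops$region_b), 0L)
  partner_class <- tr$class[match(sim$truth$loops$region_a, tr$region_id)]
  expect_true(all(partner_class %in% c("type1A", "type1B")))
  # loop pairs share a TAD
  lp <- sim$truth$loops
  for (i in seq_len(nrow(lp))) {
    anchors <- GenomicRanges::GRanges(lp$chrom[i],
                                      IRanges::IRanges(c(lp$mid_a[i],
                                                         lp$mid_b[i]),
                                                       width = 1))
    hits <- GenomicRanges::findOverlaps(anchors, sim$tads, select = "first")
    expect_equal(hits[1], hits[2])
  }
})

test_that("marginal count means match the configured model", {
  sim <- small_sim()
  cfg <- sim$config
  tr <- sim$truth$regions
  ss <- sim$chip_samples[sim$chip_samples$target == "H3K27Ac", ]
  cnt <- sim$chip_counts$H3K27Ac
  nulls <- tr$region_id[tr$class == "null"]
  for (cond in c("hypo", "hyper")) {
    ids <- ss$sample_id[ss$condition == cond]
    for (s in ids) {
      x <- cnt[nulls, s]
      mu <- cfg$baseline_mean * ss$lib_factor[ss$sample_id == s]
      se <- sqrt((mu + cfg$dispersion * mu^2) / length(x))
      expect_lt(abs(mean(x) - mu), 3 * se)
    }
  }
  # planted acetylation fold at responsive regions
  resp <- tr$region_id[tr$class %in% hyperac_classes]
  lib <- stats::setNames(ss$lib_factor, ss$sample_id)
  norm <- sweep(cnt[, ss$sample_id], 2, lib[ss$sample_id], "/")
  f <- mean(norm[resp, ss$condition == "hyper"]) /
    mean(norm[resp, ss$condition == "hypo"])
  expect_equal(f, cfg$ac_fold, tolerance = 0.1)
})

test_that("switching the acetylation response off yields a calibrated null", {
  sim <- simulate_dataset(sim_config(seed = 17, n_regions = 400,
                                     n_genes = 80, n_chrom = 2,
                                     chrom_len = 1.2e7, hic_max_dist = 4e5,
                                     loop_dist_range = c(5e4, 1.5e5),
                                     ac_fold = 1))
  grp <- sim$chip_samples$condition[sim$chip_samples$target == "H3K27Ac"]
  res <- differential_regions(sim$chip_counts$H3K27Ac, grp,
                              c("hypo", "hyper"))
  expect_gt(mean(res$result$p_value < 0.05), 0.02)
  expect_lt(mean(res$result$p_value < 0.05), 0.09)
  expect_lte(length(res$significant), 2)
})

test_that("synthetic Hi-C loops beat the mirrored background; no-signal case is flat", {
  sim <- small_sim()
  lp <- sim$truth$loops
  obs <- bg <- numeric(nrow(lp))
  for (i in seq_len(nrow(lp))) {
    a <- list(chrom = lp$chrom[i], mid = lp$mid_a[i])
    b <- list(chrom = lp$chrom[i], mid = lp$mid_b[i])
    obs[i] <- quantify_contact(sim$hic, a, b)
    bg[i] <- opposite_background(sim$hic, a, b)$count
  }
  expect_lt(wilcoxon_signed_rank(obs, bg)$p_value, 0.001)
  expect_gt(mean(obs), mean(bg))

  # loop_boost = 1: planted pairs statistically indistinguishable
  sim0 <- simulate_dataset(tiny_cfg(seed = 23, loop_boost = 1))
  lp0 <- sim0$truth$loops
  obs0 <- bg0 <- numeric(nrow(lp0))
  for (i in seq_len(nrow(lp0))) {
    a <- list(chrom = lp0$chrom[i], mid = lp0$mid_a[i])
    b <- list(chrom = lp0$chrom[i], mid = lp0$mid_b[i])
    obs0[i] <- quantify_contact(sim0$hic, a, b)
    bg0[i] <- opposite_background(sim0$hic, a, b)$count
  }
  expect_gt(wilcoxon_signed_rank(obs0, bg0)$p_value, 0.05)
})

test_that("Hi-C background decays monotonically from the diagonal", {
  sim <- small_sim()
  dt <- sim$hic$contacts
  d <- dt$bin2 - dt$bin1
  nb <- ceiling(sim$config$chrom_len / sim$config$hic_resolution)
  mean_at <- function(k) sum(dt$count[d == k]) / (2 * (nb - k))
  m <- vapply(c(0, 5, 20, 60), mean_at, numeric(1))
  expect_true(all(diff(m) < 0))
})

test_that("recovery scoring behaves on perfect, permuted and empty labels", {
  sim <- small_sim()
  truth <- truth_classes(sim)
  perfect <- evaluate_recovery(truth, truth)
  expect_true(all(perfect$per_class$precision == 1))
  expect_true(all(perfect$per_class$recall == 1))

  set.seed(7)
  permuted <- stats::setNames(sample(truth), names(truth))
  r <- evaluate_recovery(permuted, truth)
  freq <- table(truth) / length(truth)
  for (i in seq_len(nrow(r$per_class))) {
    cl <- r$per_class$class[i]
    expect_lt(abs(r$per_class$recall[i] - freq[[cl]]), 0.12)
  }

  none <- stats::setNames(rep("none", length(truth)), names(truth))
  r0 <- evaluate_recovery(none, truth)
  expect_true(all(r0$per_class$recall == 0))
  expect_true(all(is.nan(r0$per_class$precision)))

  bad <- stats::setNames(rep("exotic", length(truth)), names(truth))
  expect_error(evaluate_recovery(bad, truth), "unknown label")
})

test_that("infeasible placement fails with an informative error", {
  expect_error(
    simulate_dataset(sim_config(seed = 1, n_regions = 2000, n_chrom = 1,
                                chrom_len = 1e6)),
    "placement infeasible")
})
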