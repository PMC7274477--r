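# dense toy matrix helpers -------------------------------------------------
dense_to_hic <- function(mat, chrom = "cA", resolution = 5000) {
  idx <- which(upper.tri(mat, diag = TRUE) & mat != 0, arr.ind = TRUE)
  hic_matrix(data.frame(chrom = rep(chrom, nrow(idx)), bin1 = idx[, 1] - 1,
                        bin2 = idx[, 2] - 1, count = mat[idx]),
             resolution = resolution,
             chrom_sizes = stats::setNames(nrow(mat) * resolution, chrom))
}

anchor <- function(mid, chrom = "cA") list(chrom = chrom, mid = mid)

test_that("contact quantification matches dense summation and is symmetric", {
  n <- 120
  m0 <- matrix(0, n, n)
  expect_equal(quantify_contact(dense_to_hic(m0), anchor(1e5), anchor(3e5)),
               0)

  m1 <- m0
  m1[21, 61] <- 7   # bins 20 and 60 (0-based)
  h1 <- dense_to_hic(m1)
  expect_equal(quantify_contact(h1, anchor(20 * 5000 + 2500),
                                anchor(60 * 5000 + 2500)), 7)

  set.seed(111)
  m <- matrix(0, n, n)
  nz <- cbind(sample(n, 400, TRUE), sample(n, 400, TRUE))
  for (k in 1:400) {
    i <- min(nz[k, ]); j <- max(nz[k, ])
    m[i, j] <- m[i, j] + rpois(1, 4)
  }
  h <- dense_to_hic(m)
  sym <- m + t(m); diag(sym) <- diag(m)
  for (k in 1:50) {
    ma <- sample(5e5, 1); mb <- sample(5e5, 1)
    got <- quantify_contact(h, anchor(ma), anchor(mb))
    bins <- function(mid) {
      b <- floor((mid - 5000) / 5000):floor((mid + 4999) / 5000)
      b[b >= 0 & b < n] + 1
    }
    want <- sum(sym[bins(ma), bins(mb), drop = FALSE])
    expect_equal(got, want)
    expect_equal(quantify_contact(h, anchor(mb), anchor(ma)), got)
  }
  expect_error(quantify_contact(h, anchor(1e5), anchor(1e5, "cB")),
               "cis only")
})

test_that("opposite background equals observed on translation-invariant matrices", {
  n <- 200
  m <- matrix(0, n, n)
  for (i in 1:n) for (j in i:n) m[i, j] <- 100 - min(abs(j - i), 90)
  h <- dense_to_hic(m)
  for (pair in list(c(3e5, 5e5), c(4.2e5, 7.7e5), c(2.5e5, 4.5e5))) {
    obs <- quantify_contact(h, anchor(pair[1]), anchor(pair[2]))
    bg <- opposite_background(h, anchor(pair[1]), anchor(pair[2]))
    expect_false(bg$excluded)
    expect_identical(bg$count, obs)
  }
})

test_that("opposite background mirrors across the other anchor near edges", {
  n <- 100
  m <- matrix(5, n, n)
  h <- dense_to_hic(m)
  # a near chromosome start: mirror of b across a is off-chromosome
  r <- opposite_background(h, anchor(10000), anchor(2e5))
  expect_equal(r$side, "b")
  # both mirrors off-chromosome on a tiny chromosome
  tiny <- dense_to_hic(matrix(1, 4, 4))
  r2 <- opposite_background(tiny, anchor(5000), anchor(15000))
  expect_true(r2$excluded)
})

test_that("planted loops stand out over a flat background", {
  n <- 150
  m <- matrix(2, n, n)
  m[40:41, 80:81] <- 40
  h <- dense_to_hic(m)
  obs <- quantify_contact(h, anchor(40 * 5000 + 5000),
                          anchor(80 * 5000 + 5000))
  bg <- opposite_background(h, anchor(40 * 5000 + 5000),
                            anchor(80 * 5000 + 5000))$count
  expect_gt(obs, bg)
})

test_that("interaction detection recovers planted loops and stays quiet on nulls", {
  sim <- small_sim()
  # full region universe: the detector itself, not the upstream caller
  pairs <- detect_interactions(sim$hic, sim$regions,
                               min_distance = 2e4, max_distance = 6e5)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  lp <- sim$truth$loops
  expect_gte(mean(key(lp$region_a, lp$region_b) %in%
                  key(pairs$id_a, pairs$id_b)), 0.8)

  # max_distance below the smallest planted distance: nothing detectable
  short <- detect_interactions(sim$hic, sim$regions,
                               min_distance = 2e4, max_distance = 4e4)
  expect_false(any(key(lp$region_a, lp$region_b) %in%
                   key(short$id_a, short$id_b)))

  # background-only matrix: false positives bounded by the Poisson budget
  sim0 <- simulate_dataset(sim_config(seed = 77, n_regions = 120,
                                      n_genes = 60, n_chrom = 2,
                                      chrom_len = 6e6, hic_max_dist = 4e5,
                                      loop_dist_range = c(5e4, 1.5e5),
                                      loop_boost = 1))
  p0 <- detect_interactions(sim0$hic, sim0$regions,
                            min_distance = 2e4, max_distance = 4e5)
  expect_lte(nrow(p0), 2)
})

test_that("TAD confinement: degenerate layouts and planted enrichment", {
  sim <- small_sim()
  tr <- sim$truth$regions
  w_gr <- sim$regions[tr$region_id[tr$class %in% c("type1A", "type1B")]]
  no_gr <- sim$regions[tr$region_id[tr$class %in% c("indirect_SE",
                                                    "indirect_loop")]]
  one_tad <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(GenomeInfoDb::seqinfo(sim$regions)),
    IRanges::IRanges(1, sim$config$chrom_len))
  r1 <- tad_confinement(no_gr, w_gr, one_tad, sim$regions,
                        n_random = 100, seed = 5)
  expect_equal(r1$fraction, 1)

  r0 <- tad_confinement(no_gr, w_gr, GenomicRanges::GRanges(), sim$regions,
                        n_random = 100, seed = 5)
  expect_equal(r0$p_value, 1)

  r <- tad_confinement(no_gr, w_gr, sim$tads, sim$regions,
                       n_random = 200, seed = 5)
  expect_lt(r$p_value, 0.01)
  expect_gt(r$fraction, 0.9)
})

test_that("nearest-distance profile: self, missing chromosome, planted proximity", {
  sim <- small_sim()
  tr <- sim$truth$regions
  a <- sim$regions[1:20]
  self <- nearest_distance_profile(a, a, sim$regions, seed = 3)
  expect_true(all(self$dist_to_b == 0))

  onlyA <- sim$regions[as.character(GenomicRanges::seqnames(sim$regions)) ==
                       "chrS1"]
  onlyB <- sim$regions[as.character(GenomicRanges::seqnames(sim$regions)) ==
                       "chrS2"]
  r <- nearest_distance_profile(onlyA[1:10], onlyB, sim$regions, seed = 3)
  expect_length(r$dist_to_b, 0)
  expect_equal(r$n_dropped, 10)

  w_gr <- sim$regions[tr$region_id[tr$class %in% c("type1A", "type1B")]]
  no_gr <- sim$regions[tr$region_id[tr$class %in% c("indirect_SE",
                                                    "indirect_loop")]]
  prof <- nearest_distance_profile(no_gr, w_gr, sim$regions, seed = 3)
  expect_lt(prof$median_b, prof$median_random)
  expect_lt(wilcoxon_signed_rank(prof$dist_to_b,
                                 prof$dist_to_random)$p_value, 0.05)
})
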