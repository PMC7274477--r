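#' Sparse cis Hi-C contact matrix
#'
#' Container for a binned, cis-only, symmetric contact map stored as an
#' upper-triangular triplet table (`chrom`, `bin1`, `bin2`, `count`) with
#' 0-based bin indices (`bin i` spans `[i * resolution, (i+1) * resolution)`).
#'
#' @param contacts `data.frame`/`data.table` with columns `chrom`, `bin1`,
#'   `bin2`, `count`; pairs with `bin1 > bin2` are flipped, duplicates
#'   summed.
#' @param resolution Bin size in bp.
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @return Object of class `hic_matrix`.
#' @export
hic_matrix <- function(contacts, resolution, chrom_sizes) {
  dt <- data.table::as.data.table(contacts)
  need <- c("chrom", "bin1", "bin2", "count")
  if (!all(need %in% names(dt))) stop("contacts needs chrom, bin1, bin2, count")
  if (is.null(names(chrom_sizes))) stop("chrom_sizes must be named")
  b1 <- pmin(dt$bin1, dt$bin2); b2 <- pmax(dt$bin1, dt$bin2)
  dt$bin1 <- as.integer(b1); dt$bin2 <- as.integer(b2)
  dt <- dt[, list(count = sum(count)), by = c("chrom", "bin1", "bin2")]
  data.table::setkeyv(dt, c("chrom", "bin1", "bin2"))
  structure(list(contacts = dt, resolution = resolution,
                 chrom_sizes = chrom_sizes),
            class = "hic_matrix")
}

#' @export
print.hic_matrix <- function(x, ...) {
  cat("hic_matrix:", nrow(x$contacts), "nonzero cis cells at",
      x$resolution, "bp over", length(x$chrom_sizes), "chromosomes\n")
  invisible(x)
}

n_bins_of <- function(hic, chrom) {
  as.integer(ceiling(hic$chrom_sizes[[chrom]] / hic$resolution))
}

anchor_info <- function(x) {
  if (inherits(x, "GRanges")) {
    if (length(x) != 1) stop("anchor must be a single interval")
    list(chrom = as.character(GenomicRanges::seqnames(x)),
         mid = floor((GenomicRanges::start(x) - 1 + GenomicRanges::end(x)) / 2))
  } else if (is.list(x) && all(c("chrom", "mid") %in% names(x))) {
    x
  } else stop("anchor must be a GRanges of length 1 or list(chrom, mid)")
}

window_bins <- function(hic, chrom, mid, window) {
  half <- window / 2
  lo <- floor((mid - half) / hic$resolution)
  hi <- floor((mid + half - 1) / hic$resolution)
  bins <- lo:hi
  bins[bins >= 0 & bins < n_bins_of(hic, chrom)]
}

#' Quantify the Hi-C contact between two anchors
#'
#' Sums matrix entries over all bin pairs (i, j) with bin i covering the
#' `window`-wide window around anchor a's midpoint and bin j likewise for
#' anchor b. Symmetric in the anchors; cis only.
#'
#' @param hic A [hic_matrix()].
#' @param anchor_a,anchor_b Single-interval `GRanges` or `list(chrom, mid)`.
#' @param window Window width in bp (default 10000).
#' @return Numeric tag count.
#' @export
quantify_contact <- function(hic, anchor_a, anchor_b, window = 10000) {
  a <- anchor_info(anchor_a); b <- anchor_info(anchor_b)
  if (a$chrom != b$chrom) stop("cis only")
  ba <- window_bins(hic, a$chrom, a$mid, window)
  bb <- window_bins(hic, b$chrom, b$mid, window)
  if (length(ba) == 0 || length(bb) == 0) return(0)
  cells <- expand.grid(i = ba, j = bb)
  q <- data.table::data.table(chrom = a$chrom,
                              bin1 = as.integer(pmin(cells$i, cells$j)),
                              bin2 = as.integer(pmax(cells$i, cells$j)))
  hit <- hic$contacts[q, on = c("chrom", "bin1", "bin2")]
  sum(hit$count, na.rm = TRUE)
}

#' Opposite-direction background contact
#'
#' Background control for an observed contact between cis anchors a and b
#' (b downstream): the contact between a and the mirror image of b across a
#' (mirror midpoint = mid_a - distance). If that window falls off the
#' chromosome start, the mirror of a across b is used instead; if both
#' mirrors are off-chromosome the pair is excluded.
#'
#' @inheritParams quantify_contact
#' @return List with `count`, `side` ("a", "b" or NA), `excluded` flag.
#' @export
opposite_background <- function(hic, anchor_a, anchor_b, window = 10000) {
  a <- anchor_info(anchor_a); b <- anchor_info(anchor_b)
  if (a$chrom != b$chrom) stop("cis only")
  if (b$mid < a$mid) { tmp <- a; a <- b; b <- tmp }
  d <- b$mid - a$mid
  half <- window / 2
  mirror_b <- a$mid - d
  if (mirror_b - half >= 0) {
    return(list(count = quantify_contact(hic, a,
                                         list(chrom = a$chrom, mid = mirror_b),
                                         window),
                side = "a", excluded = FALSE))
  }
  mirror_a <- b$mid + d
  if (mirror_a + half <= hic$chrom_sizes[[a$chrom]]) {
    return(list(count = quantify_contact(hic, b,
                                         list(chrom = b$chrom, mid = mirror_a),
                                         window),
                side = "b", excluded = FALSE))
  }
  list(count = NA_real_, side = NA_character_, excluded = TRUE)
}

# Distance-decay curve: mean count per cell (zeros included) in log-spaced
# bins of bin-distance, with linear interpolation between bin centers.
decay_curve <- function(hic, max_bin_dist) {
  dt <- hic$contacts[, list(total = sum(count)), by = list(d = bin2 - bin1)]
  nb <- vapply(names(hic$chrom_sizes), function(ch) n_bins_of(hic, ch),
               integer(1))
  dist <- 0:max_bin_dist
  npairs <- vapply(dist, function(d) sum(pmax(nb - d, 0)), numeric(1))
  tot <- numeric(length(dist))
  m <- match(dt$d, dist)
  ok <- !is.na(m)
  tot[m[ok]] <- dt$total[ok]
  mean_d <- ifelse(npairs > 0, tot / npairs, 0)
  # log-spaced aggregation (distance 0 kept as its own bin)
  br <- unique(c(0, round(exp(seq(log(1), log(max_bin_dist + 1),
                                  length.out = 30)))))
  bin <- findInterval(dist, br)
  bx <- tapply(dist, bin, mean)
  by <- tapply(mean_d * npairs, bin, sum) / tapply(npairs, bin, sum)
  keep <- !is.na(bx) & !is.na(by)
  function(d) {
    y <- stats::approx(bx[keep], by[keep], xout = d, rule = 2)$y
    pmax(y, 0)
  }
}

#' Detect interactions between regions from a Hi-C matrix
#'
#' Candidate pairs are all same-chromosome region pairs with midpoint
#' distance in `[min_distance, max_distance]`. A pair is kept when its
#' windowed contact exceeds `fold` times the expected count from the
#' distance-decay curve (mean count per cell in log-spaced distance bins,
#' linearly interpolated, times the number of cells in the window block)
#' and the Poisson upper-tail p-value against that expectation is below
#' `significance`.
#'
#' @param hic A [hic_matrix()].
#' @param regions `GRanges` region universe (named or with `region_id`).
#' @param min_distance,max_distance Midpoint distance range in bp.
#' @param window Quantification window in bp.
#' @param fold Minimal observed/expected ratio.
#' @param significance Poisson upper-tail p threshold.
#' @return `data.frame` of detected pairs: ids, chrom, distance, observed,
#'   expected, p_value.
#' @export
detect_interactions <- function(hic, regions, min_distance = 2e4,
                                max_distance = 1e6, window = 10000,
                                fold = 2, significance = 1e-5) {
  ids <- names(regions)
  if (is.null(ids)) ids <- as.character(seq_along(regions))
  chrom <- as.character(GenomicRanges::seqnames(regions))
  mid <- floor((GenomicRanges::start(regions) - 1 +
                GenomicRanges::end(regions)) / 2)
  res <- hic$resolution
  curve <- decay_curve(hic, ceiling(max_distance / res) + 2)
  out <- list()
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    if (length(sel) < 2) next
    ord <- sel[order(mid[sel])]
    m <- mid[ord]
    for (ii in seq_along(ord)) {
      jj <- which(m - m[ii] >= min_distance & m - m[ii] <= max_distance)
      jj <- jj[jj > ii]
      for (j in jj) {
        a <- list(chrom = ch, mid = m[ii]); b <- list(chrom = ch, mid = m[j])
        obs <- quantify_contact(hic, a, b, window)
        ba <- window_bins(hic, ch, m[ii], window)
        bb <- window_bins(hic, ch, m[j], window)
        cells <- expand.grid(i = ba, j = bb)
        dmean <- curve(abs(cells$j - cells$i))
        expct <- sum(dmean)
        if (expct <= 0) next
        p <- stats::ppois(obs - 1, expct, lower.tail = FALSE)
        if (obs > fold * expct && p < significance) {
          out[[length(out) + 1]] <- data.frame(
            id_a = ids[ord[ii]], id_b = ids[ord[j]], chrom = ch,
            distance = m[j] - m[ii], observed = obs, expected = expct,
            p_value = p, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(id_a = character(), id_b = character(),
                      chrom = character(), distance = numeric(),
                      observed = numeric(), expected = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

midpoints_gr <- function(gr) {
  floor((GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2)
}

# Draw n regions from pool excluding anything overlapping `exclude`.
sample_random_regions <- function(pool, n, exclude = NULL, seed = NULL) {
  if (!is.null(exclude) && length(exclude))
    pool <- pool[!IRanges::overlapsAny(pool, exclude)]
  if (n > length(pool)) stop("n_random exceeds available pool size")
  if (!is.null(seed)) set.seed(seed)
  pool[sample(length(pool), n)]
}

fisher_enrichment <- function(test_pos, rand_pos) {
  tab <- matrix(c(sum(test_pos), sum(!test_pos),
                  sum(rand_pos), sum(!rand_pos)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("test", "random"),
                                c("positive", "negative")))
  ft <- fisher_exact_2x2(tab)
  list(table = tab, odds_ratio = ft$odds_ratio, p_value = ft$p_value,
       fraction = mean(test_pos))
}

#' TAD confinement of TR-independent hyperacetylated regions
#'
#' Assigns each region to the TAD containing its midpoint, scores it
#' positive when that TAD also contains at least one TR-bound
#' hyperacetylated region, and tests the fraction against a random draw of
#' acetylated regions with Fisher's exact test.
#'
#' @param regions_no `GRanges` of hyperacetylated regions without a TRBS.
#' @param regions_w `GRanges` of hyperacetylated regions with a TRBS.
#' @param tads Non-overlapping `GRanges` of TADs.
#' @param random_pool `GRanges` pool of acetylated regions.
#' @param n_random Number of random regions (default 600).
#' @param seed Seed for the random draw.
#' @return List: `fraction`, `table`, `odds_ratio`, `p_value`, `seed`,
#'   `n_unassigned`.
#' @export
tad_confinement <- function(regions_no, regions_w, tads, random_pool,
                            n_random = 600, seed = NULL) {
  tad_of <- function(gr) {
    if (length(gr) == 0) return(integer(0))
    mids <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                   IRanges::IRanges(midpoints_gr(gr) + 1,
                                                    width = 1))
    hit <- GenomicRanges::findOverlaps(mids, tads, select = "first")
    as.integer(hit)
  }
  w_tads <- unique(stats::na.omit(tad_of(regions_w)))
  pos_of <- function(gr) {
    t <- tad_of(gr)
    !is.na(t) & t %in% w_tads
  }
  test_pos <- pos_of(regions_no)
  rand <- sample_random_regions(random_pool, n_random, exclude = regions_no,
                                seed = seed)
  rand_pos <- pos_of(rand)
  if (length(tads) == 0 || length(test_pos) == 0) {
    return(list(fraction = if (length(test_pos)) 0 else NA_real_,
                table = NULL, odds_ratio = NA_real_, p_value = 1,
                seed = seed, n_unassigned = length(regions_no)))
  }
  out <- fisher_enrichment(test_pos, rand_pos)
  out$seed <- seed
  out$n_unassigned <- sum(is.na(tad_of(regions_no)))
  out
}

#' Nearest-neighbor distance profile between region sets
#'
#' For every region in `regions_a`, the midpoint distance to the nearest
#' region of `regions_b` on the same chromosome (dropped when none), and
#' the same against an equal-size random draw from `random_pool`.
#'
#' @param regions_a,regions_b `GRanges`.
#' @param random_pool `GRanges` pool for the control draw.
#' @param seed Seed for the random draw.
#' @return List: `dist_to_b`, `dist_to_random`, `median_b`,
#'   `median_random`, `n_dropped`, `seed`.
#' @export
nearest_distance_profile <- function(regions_a, regions_b, random_pool,
                                     seed = NULL) {
  # the control draw must not contain the query regions themselves,
  # otherwise self-hits at distance 0 deflate the control median
  nearest_d <- function(a, b) {
    ca <- as.character(GenomicRanges::seqnames(a))
    cb <- as.character(GenomicRanges::seqnames(b))
    ma <- midpoints_gr(a); mb <- midpoints_gr(b)
    vapply(seq_along(a), function(i) {
      cand <- mb[cb == ca[i]]
      if (length(cand) == 0) return(NA_real_)
      min(abs(cand - ma[i]))
    }, numeric(1))
  }
  pool <- random_pool[!IRanges::overlapsAny(random_pool, regions_a)]
  rand <- sample_random_regions(pool, min(length(regions_b), length(pool)),
                                seed = seed)
  d_b <- nearest_d(regions_a, regions_b)
  d_r <- nearest_d(regions_a, rand)
  list(dist_to_b = d_b[!is.na(d_b)], dist_to_random = d_r[!is.na(d_r)],
       median_b = stats::median(d_b, na.rm = TRUE),
       median_random = stats::median(d_r, na.rm = TRUE),
       n_dropped = sum(is.na(d_b)), seed = seed)
}
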