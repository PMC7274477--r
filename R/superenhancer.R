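#' Stitch acetylation peaks into candidate super-enhancer entities
#'
#' Transitive closure of the "gap < stitch_distance" relation per
#' chromosome (strict: peaks exactly `stitch_distance` apart are not
#' joined, following the ROSE/HOMER convention); each stitched interval
#' spans the first start to the last end and carries the summed signal.
#'
#' @param peaks `GRanges`, sorted or not.
#' @param signal Nonnegative numeric vector, one value per peak (e.g.
#'   normalized H3K27Ac tags).
#' @param stitch_distance Maximum gap in bp (default 12500).
#' @return `GRanges` with `total_signal`, `n_constituents` and
#'   `constituents` (a `CharacterList` of peak ids).
#' @export
stitch_peaks <- function(peaks, signal, stitch_distance = 12500) {
  if (length(signal) != length(peaks)) stop("one signal per peak required")
  if (any(signal < 0)) stop("signals must be nonnegative")
  ids <- names(peaks)
  if (is.null(ids)) ids <- as.character(seq_along(peaks))
  # reduce() merges ranges whose gap is strictly below min.gapwidth, which
  # is exactly the strict "< stitch_distance" rule
  st <- GenomicRanges::reduce(peaks, min.gapwidth = stitch_distance,
                              with.revmap = TRUE)
  rev <- st$revmap
  st$total_signal <- vapply(rev, function(ii) sum(signal[ii]), numeric(1))
  st$n_constituents <- lengths(rev)
  st$constituents <- rev
  st$constituent_ids <- lapply(rev, function(ii) ids[ii])
  st$revmap <- NULL
  names(st) <- paste0("SE", seq_along(st))
  st
}

#' Super-enhancer cutoff by the rank-signal slope rule
#'
#' Stitched entities are ranked ascending by total signal; with
#' `x_i = i/n` and `y_i = signal_i / max(signal)`, the cutoff index is
#' `argmin_i (y_i - x_i)` — the point where the tangent to the rank curve
#' has slope 1 — and everything beyond it is a super-enhancer. The discrete
#' slope at each rank is the central difference of y against x.
#'
#' @param stitched `GRanges` from [stitch_peaks()] (needs `total_signal`),
#'   at least 3 entities.
#' @return The input with added metadata: `rank` (1 = strongest signal),
#'   `slope_at_rank`, `is_super`.
#' @export
se_cutoff <- function(stitched) {
  n <- length(stitched)
  if (n < 3) stop("need >= 3 stitched regions")
  s <- stitched$total_signal
  if (length(unique(s)) == 1) {
    warning("all signals equal: no super-enhancers called")
    stitched$rank <- rank(-s, ties.method = "first")
    stitched$slope_at_rank <- 0
    stitched$is_super <- FALSE
    return(stitched)
  }
  ord <- order(s)
  x <- seq_len(n) / n
  y <- s[ord] / max(s)
  istar <- which.min(y - x)
  slope <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - 1); hi <- min(n, i + 1)
    slope[i] <- (y[hi] - y[lo]) / (x[hi] - x[lo])
  }
  is_super_sorted <- seq_len(n) > istar
  out_rank <- out_slope <- numeric(n)
  out_super <- logical(n)
  out_rank[ord] <- n + 1 - seq_len(n)        # rank 1 = highest signal
  out_slope[ord] <- slope
  out_super[ord] <- is_super_sorted
  stitched$rank <- out_rank
  stitched$slope_at_rank <- out_slope
  stitched$is_super <- out_super
  stitched
}

#' Super-enhancer co-occupancy enrichment of TR-independent regions
#'
#' Scores each no/TRBS hyperacetylated region positive when it falls in a
#' super-enhancer that also contains a w/TRBS hyperacetylated region, and
#' compares against `n_random` acetylated regions drawn without replacement
#' from `random_pool` (test regions excluded) with Fisher's exact test.
#'
#' @param ses `GRanges` of called super-enhancers (only entities with
#'   `is_super == TRUE` are used if the column is present).
#' @param regions_no,regions_w `GRanges`: hyperacetylated regions without /
#'   with a TRBS.
#' @param random_pool `GRanges` pool of acetylated regions.
#' @param n_random Number of random regions (default 600).
#' @param seed Seed for the draw.
#' @return List: `fraction`, `table`, `odds_ratio`, `p_value`, `seed`.
#' @export
se_cooccupancy_enrichment <- function(ses, regions_no, regions_w,
                                      random_pool, n_random = 600,
                                      seed = NULL) {
  if (!is.null(ses$is_super)) ses <- ses[ses$is_super]
  if (length(ses) == 0 || length(regions_no) == 0) {
    return(list(fraction = 0, table = NULL, odds_ratio = NA_real_,
                p_value = 1, seed = seed))
  }
  se_with_w <- ses[IRanges::overlapsAny(ses, regions_w, minoverlap = 1)]
  pos_of <- function(gr) IRanges::overlapsAny(gr, se_with_w, minoverlap = 1)
  rand <- sample_random_regions(random_pool, n_random, exclude = regions_no,
                                seed = seed)
  out <- fisher_enrichment(pos_of(regions_no), pos_of(rand))
  out$seed <- seed
  out
}
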