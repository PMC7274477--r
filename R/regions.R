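#' Build a binned tag-count track
#'
#' @param chrom,start,count Equal-length vectors: chromosome, 0-based bin
#'   start, tag count.
#' @param bin_size Bin width in bp.
#' @return `data.frame` with a `bin_size` attribute.
#' @export
bin_track <- function(chrom, start, count, bin_size) {
  df <- data.frame(chrom = as.character(chrom), start = start, count = count,
                   stringsAsFactors = FALSE)
  attr(df, "bin_size") <- bin_size
  df
}

track_bin_size <- function(track) {
  bs <- attr(track, "bin_size")
  if (!is.null(bs)) return(bs)
  d <- unlist(tapply(track$start, track$chrom,
                     function(s) diff(sort(s))), use.names = FALSE)
  if (length(d) == 0) stop("cannot infer bin size from a single-bin track")
  min(d)
}

#' Call enriched regions or factor peaks from a binned track
#'
#' Window significance is a Poisson upper-tail test of the window tag sum
#' against the genome-wide expectation (mean bin count times window size in
#' bins). Region mode slides `region_size`-wide windows at bin-size steps
#' and merges significant windows separated by less than `min_dist` bp.
#' Factor mode tests `peak_width`-wide windows and greedily keeps
#' non-overlapping fixed-width peaks centered on the maximum bin of each
#' significant window, highest window sum first.
#'
#' @param track Track from [bin_track()] (or any data.frame with `chrom`,
#'   `start`, `count`).
#' @param mode `"region"` or `"factor"`.
#' @param region_size Window size for region mode, bp (default 1000).
#' @param min_dist Merge distance for region mode, bp (default 2500;
#'   strict: gaps of exactly `min_dist` are not merged).
#' @param peak_width Window/peak width for factor mode, bp (default 200).
#' @param p_thresh Poisson p-value threshold (default 1e-4).
#' @return Sorted disjoint `GRanges` with a `score` column
#'   (max -log10 p over merged windows).
#' @export
call_regions <- function(track, mode = c("region", "factor"),
                         region_size = 1000, min_dist = 2500,
                         peak_width = 200, p_thresh = 1e-4) {
  mode <- match.arg(mode)
  empty <- GenomicRanges::GRanges(score = numeric(0))
  if (nrow(track) == 0 || sum(track$count) == 0) return(empty)
  bs <- track_bin_size(track)
  win <- if (mode == "region") region_size else peak_width
  if (win %% bs != 0) stop("bin size must divide the window size")
  w <- win / bs
  lambda_bin <- sum(track$count) / nrow(track)
  lambda_win <- w * lambda_bin

  pieces <- list()
  for (ch in unique(track$chrom)) {
    sub <- track[track$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    n <- nrow(sub)
    if (n < w) next
    cs <- cumsum(c(0, sub$count))
    sums <- cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]
    starts <- sub$start[1:(n - w + 1)]
    p <- stats::ppois(sums - 1, lambda_win, lower.tail = FALSE)
    sig <- which(p < p_thresh)
    if (length(sig) == 0) next
    if (mode == "region") {
      ws <- starts[sig]; we <- ws + win
      sc <- -log10(pmax(p[sig], 1e-300))
      ord <- order(ws)
      ws <- ws[ord]; we <- we[ord]; sc <- sc[ord]
      m_start <- ws[1]; m_end <- we[1]; m_sc <- sc[1]
      rows <- list()
      for (k in seq_along(ws)[-1]) {
        if (ws[k] - m_end < min_dist) {
          m_end <- max(m_end, we[k]); m_sc <- max(m_sc, sc[k])
        } else {
          rows[[length(rows) + 1]] <- c(m_start, m_end, m_sc)
          m_start <- ws[k]; m_end <- we[k]; m_sc <- sc[k]
        }
      }
      rows[[length(rows) + 1]] <- c(m_start, m_end, m_sc)
      mat <- do.call(rbind, rows)
      pieces[[ch]] <- data.frame(chrom = ch, start = mat[, 1],
                                 end = mat[, 2], score = mat[, 3])
    } else {
      ord <- sig[order(-sums[sig])]
      kept <- list()
      for (k in ord) {
        # center of the maximal bin inside the window
        bins <- k:(k + w - 1)
        bmax <- bins[which.max(sub$count[bins])]
        center <- sub$start[bmax] + bs / 2
        ps <- center - peak_width / 2; pe <- center + peak_width / 2
        clash <- FALSE
        for (kk in kept)
          if (ps < kk[2] && kk[1] < pe) { clash <- TRUE; break }
        if (!clash)
          kept[[length(kept) + 1]] <- c(ps, pe, -log10(max(p[k], 1e-300)))
      }
      if (length(kept)) {
        mat <- do.call(rbind, kept)
        mat <- mat[order(mat[, 1]), , drop = FALSE]
        pieces[[ch]] <- data.frame(chrom = ch, start = mat[, 1],
                                   end = mat[, 2], score = mat[, 3])
      }
    }
  }
  if (length(pieces) == 0) return(empty)
  df <- do.call(rbind, pieces)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1, df$end))
  gr$score <- df$score
  gr
}

#' Replicate-concordant peaks
#'
#' Peaks from replicate 1 overlapping (>= 1 bp) at least one replicate-2
#' peak; replicate-1 coordinates are retained.
#'
#' @param peaks_rep1,peaks_rep2 `GRanges`.
#' @return Subset of `peaks_rep1`.
#' @export
concordant_set <- function(peaks_rep1, peaks_rep2) {
  peaks_rep1[IRanges::overlapsAny(peaks_rep1, peaks_rep2, minoverlap = 1)]
}

#' Differential tag-count test over a fixed region universe
#'
#' Wraps [nb_differential_test()] and [bh_adjust()]; the significant set is
#' one-directional (increase only): `q_value < q_thresh` and
#' `log2fc > lfc_thresh`.
#'
#' @param counts Region x sample count matrix.
#' @param group Condition label per column.
#' @param contrast `c(reference, treatment)`.
#' @param q_thresh,lfc_thresh Significance thresholds (defaults 0.01 and 1;
#'   the acute-kinetics variant uses 0.05 and 0).
#' @param size_factors Optional size factors.
#' @return List: `result` (full table), `significant` (ids of increased
#'   regions), `thresholds`.
#' @export
differential_regions <- function(counts, group, contrast,
                                 q_thresh = 0.01, lfc_thresh = 1,
                                 size_factors = NULL) {
  res <- nb_differential_test(counts, group, contrast,
                              size_factors = size_factors)
  sig <- res$unit_id[res$q_value < q_thresh & res$log2fc > lfc_thresh &
                     !is.na(res$q_value)]
  list(result = res, significant = sig,
       thresholds = c(q = q_thresh, lfc = lfc_thresh))
}

#' High-confidence hyperacetylated regions
#'
#' Intersection of the per-mark hyperacetylated sets. When both inputs are
#' differential result tables over the same region universe the
#' intersection is by region id, and the returned table carries both marks'
#' statistics plus `is_high_confidence` (both marks pass `q < q_thresh` and
#' `log2fc > lfc_thresh`). When both inputs are `GRanges` of significant
#' regions, K27 regions overlapping (>= 1 bp) any significant K9 region are
#' returned with K27 coordinates.
#'
#' @param k27,k9 Differential tables from [differential_regions()]`$result`
#'   (same `unit_id` universe) or `GRanges`.
#' @param q_thresh,lfc_thresh Per-mark thresholds (defaults 0.01, 1).
#' @return `data.frame` (id mode) or `GRanges` (overlap mode).
#' @export
high_confidence_intersect <- function(k27, k9, q_thresh = 0.01,
                                      lfc_thresh = 1) {
  if (inherits(k27, "GRanges") && inherits(k9, "GRanges")) {
    return(k27[IRanges::overlapsAny(k27, k9, minoverlap = 1)])
  }
  if (!identical(k27$unit_id, k9$unit_id))
    stop("id mode requires the same region universe in the same order")
  pass <- function(r) r$q_value < q_thresh & r$log2fc > lfc_thresh &
    !is.na(r$q_value)
  data.frame(
    unit_id = k27$unit_id,
    k27_log2fc = k27$log2fc, k27_q = k27$q_value,
    k9_log2fc = k9$log2fc, k9_q = k9$q_value,
    is_high_confidence = pass(k27) & pass(k9),
    stringsAsFactors = FALSE)
}
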