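#' Annotate regions with factor-peak overlaps
#'
#' Flags each region for >= 1 bp overlap with the TR, HDAC3 and DNase
#' hypersensitive site peak sets and derives the TR status ("w/TRBS" vs
#' "no/TRBS"). Explanation tags for no/TRBS regions are initialized empty
#' and filled in by the super-enhancer and chromatin-3D stages.
#'
#' @param regions `GRanges` (named or with `region_id` metadata).
#' @param peak_sets Named list of `GRanges` with elements `TR`, `HDAC3`,
#'   `DHS` (missing elements are treated as empty).
#' @return `data.frame`: `region_id`, `has_trbs`, `has_hdac3`, `has_dhs`,
#'   `tr_status`, `explanation` (empty string placeholder).
#' @export
annotate_overlaps <- function(regions, peak_sets) {
  ids <- names(regions)
  if (is.null(ids)) ids <- as.character(seq_along(regions))
  ov <- function(nm) {
    p <- peak_sets[[nm]]
    if (is.null(p) || length(p) == 0) return(rep(FALSE, length(regions)))
    IRanges::overlapsAny(regions, p, minoverlap = 1)
  }
  has_trbs <- ov("TR")
  data.frame(region_id = ids,
             has_trbs = has_trbs,
             has_hdac3 = ov("HDAC3"),
             has_dhs = ov("DHS"),
             tr_status = ifelse(has_trbs, "w/TRBS", "no/TRBS"),
             explanation = character(length(regions)),
             stringsAsFactors = FALSE)
}

#' Classify TR binding sites into HDAC3-occupancy tertiles
#'
#' Sites are sorted by descending HDAC3 density (hypothyroid condition),
#' ties broken by (chrom, start). The top third becomes type 1A (poised),
#' the bottom third type 1B (T3-established), the rest "mid". With n sites,
#' type 1A gets `floor(n/3)` (+1 when `n %% 3 == 2`) and type 1B
#' `floor(n/3)`, so tertile sizes differ by at most one.
#'
#' @param trbs `GRanges` of TRBSs (named) or `data.frame` with `region_id`,
#'   `chrom`, `start`.
#' @param density Nonnegative numeric vector: HDAC3 density per site.
#' @return `data.frame`: `region_id`, `density`, `tertile_class`
#'   (`type1A` / `mid` / `type1B`), in input order.
#' @export
classify_tertiles <- function(trbs, density) {
  if (inherits(trbs, "GRanges")) {
    ids <- names(trbs)
    if (is.null(ids)) ids <- as.character(seq_along(trbs))
    chrom <- as.character(GenomicRanges::seqnames(trbs))
    start <- GenomicRanges::start(trbs) - 1
  } else {
    ids <- trbs$region_id; chrom <- trbs$chrom; start <- trbs$start
  }
  n <- length(ids)
  if (length(density) != n) stop("one density per site required")
  if (any(density < 0, na.rm = TRUE)) stop("densities must be nonnegative")
  cls <- rep("mid", n)
  if (n < 3) {
    warning("fewer than 3 sites: all classified as mid")
  } else {
    ord <- order(-density, chrom, start)
    n1a <- n %/% 3 + as.integer(n %% 3 == 2)
    n1b <- n %/% 3
    cls[ord[seq_len(n1a)]] <- "type1A"
    cls[ord[(n - n1b + 1):n]] <- "type1B"
  }
  data.frame(region_id = ids, density = density, tertile_class = cls,
             stringsAsFactors = FALSE)
}

#' Quantify ChIP occupancy at sites from binned tracks
#'
#' Sums tags within a fixed window around each site center and scales to
#' library size per 1e7 tags. Windows truncated at chromosome ends are
#' flagged in the `"truncated"` attribute.
#'
#' @param sites `GRanges`.
#' @param tracks Named list; each element is a list with `track` (from
#'   [bin_track()]) and `lib_size` (total mapped tags).
#' @param window Half-window in bp around the site center (default 500,
#'   i.e. a 1 kb window).
#' @return Matrix sites x tracks of normalized tag counts.
#' @export
quantify_occupancy <- function(sites, tracks, window = 500) {
  ids <- names(sites)
  if (is.null(ids)) ids <- as.character(seq_along(sites))
  centers <- floor((GenomicRanges::start(sites) - 1 +
                    GenomicRanges::end(sites)) / 2)
  chrom <- as.character(GenomicRanges::seqnames(sites))
  sl <- GenomeInfoDb::seqlengths(sites)
  truncated <- rep(FALSE, length(sites))
  out <- matrix(0, length(sites), length(tracks),
                dimnames = list(ids, names(tracks)))
  for (t in seq_along(tracks)) {
    trk <- tracks[[t]]$track
    lib <- tracks[[t]]$lib_size
    if (is.null(lib) || lib <= 0) stop("positive lib_size required per track")
    bs <- track_bin_size(trk)
    for (i in seq_along(sites)) {
      lo <- centers[i] - window; hi <- centers[i] + window
      if (lo < 0) { lo <- 0; truncated[i] <- TRUE }
      len <- sl[chrom[i]]
      if (!is.na(len) && hi > len) { hi <- len; truncated[i] <- TRUE }
      sub <- trk[trk$chrom == chrom[i], , drop = FALSE]
      inwin <- sub$start + bs > lo & sub$start < hi
      out[i, t] <- sum(sub$count[inwin]) * 1e7 / lib
    }
  }
  attr(out, "truncated") <- which(truncated)
  out
}
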