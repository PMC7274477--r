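#' Median-of-ratios size factors
#'
#' DESeq-style normalization: each sample's factor is the median across
#' regions of the ratio between its count and the row geometric mean.
#' Rows containing any zero are excluded from the reference set. Factors
#' are returned unscaled (no renormalization to unit product).
#'
#' @param counts Integer matrix, regions x samples. Column names are sample
#'   ids, row names are region/gene ids.
#' @return Named numeric vector of positive size factors, one per column.
#' @examples
#' m <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
#' median_ratio_size_factors(m)
#' @export
median_ratio_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) stop("no reference rows")
  x <- counts[ref, , drop = FALSE]
  loggeo <- rowMeans(log(x))
  factors <- apply(x, 2, function(col) exp(stats::median(log(col) - loggeo)))
  names(factors) <- colnames(counts)
  factors
}

# Raw per-row method-of-moments dispersion: (pooled within-group variance -
# mean) / mean^2 on size-factor-normalized counts. Noisy at low replication;
# callers should smooth before plugging into a Wald variance.
mom_dispersion_raw <- function(norm_counts, group) {
  group <- as.factor(droplevels(as.factor(group)))
  lv <- levels(group)
  n_by <- table(group)
  ss <- 0
  df <- 0
  msum <- 0
  for (g in lv) {
    sub <- norm_counts[, group == g, drop = FALSE]
    if (ncol(sub) >= 2) {
      mu <- rowMeans(sub)
      ss <- ss + rowSums((sub - mu)^2)
      df <- df + ncol(sub) - 1
    }
    msum <- msum + rowMeans(sub)
  }
  if (df == 0) stop("need >= 2 samples in at least one group")
  vw <- ss / df
  mbar <- msum / length(lv)
  list(raw = (vw - mbar) / mbar^2, mean = mbar)
}

# Mean-dispersion trend: mean of raw MoM estimates within quantile bins of
# log mean, linearly interpolated. Deliberately an average, not a robust
# fit: the raw estimates are right-skewed and a median-type smoother is
# biased low, which makes the Wald test anticonservative.
dispersion_trend <- function(mean_, raw, n_bins = 20, floor = 1e-8) {
  ok <- is.finite(raw) & is.finite(mean_) & mean_ > 0
  if (sum(ok) < 2) return(rep(floor, length(mean_)))
  x <- log(mean_[ok]); y <- raw[ok]
  br <- unique(stats::quantile(x, seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 3) {
    fit <- rep(mean(y), length(mean_))
  } else {
    bin <- cut(x, br, include.lowest = TRUE)
    bx <- tapply(x, bin, mean)
    by <- tapply(y, bin, mean)
    keep <- !is.na(bx)
    xq <- log(pmax(mean_, min(mean_[ok])))
    fit <- stats::approx(bx[keep], by[keep], xout = xq, rule = 2)$y
  }
  pmax(fit, floor)
}

#' Negative-binomial two-group differential test
#'
#' Simplified DESeq2-style Wald test for a two-group contrast on count data.
#' Counts are modelled as NB(mean = s_j * q_ig, dispersion alpha_i). Raw
#' per-region dispersions come from the method of moments on normalized
#' counts (pooled within groups); the Wald variance uses a mean-dispersion
#' trend (binned means of the raw estimates) floored at `dispersion_floor`.
#' The log2 fold change is computed on group means of normalized counts with
#' a pseudocount, and the two-sided p-value from the normal approximation.
#' No dispersion or LFC shrinkage, no independent filtering, no outlier
#' replacement.
#'
#' @param counts Integer matrix, units x samples.
#' @param group Factor/character vector, one condition label per column.
#' @param contrast Length-2 character vector `c(reference, treatment)`;
#'   log2fc is treatment over reference.
#' @param size_factors Optional per-sample size factors; computed by
#'   [median_ratio_size_factors()] from the contrast samples when `NULL`.
#' @param pseudocount Added to each group's normalized mean before log2.
#' @param dispersion_floor Lower bound for the fitted dispersion.
#' @return `data.frame` in input row order with columns `unit_id`,
#'   `base_mean`, `log2fc`, `p_value`, `q_value` (BH within this contrast),
#'   `dispersion` (fitted), `dispersion_raw`, and `degenerate` (TRUE when a
#'   group had zero total counts so log2fc rests on the pseudocount alone).
#' @export
nb_differential_test <- function(counts, group, contrast,
                                 size_factors = NULL,
                                 pseudocount = 0.5,
                                 dispersion_floor = 1e-8) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  group <- as.character(group)
  if (length(group) != ncol(counts)) stop("one group label per column required")
  if (length(contrast) != 2) stop("contrast must be c(reference, treatment)")
  use <- group %in% contrast
  if (sum(group == contrast[1]) < 2 || sum(group == contrast[2]) < 2)
    stop("need >= 2 samples per contrast side")
  cnt <- counts[, use, drop = FALSE]
  grp <- group[use]
  if (is.null(size_factors)) {
    size_factors <- median_ratio_size_factors(cnt)
  } else {
    size_factors <- size_factors[use]
  }
  norm <- sweep(cnt, 2, size_factors, "/")

  ref <- norm[, grp == contrast[1], drop = FALSE]
  trt <- norm[, grp == contrast[2], drop = FALSE]
  n_ref <- ncol(ref); n_trt <- ncol(trt)
  m_ref <- rowMeans(ref); m_trt <- rowMeans(trt)

  mom <- mom_dispersion_raw(norm, grp)
  disp <- dispersion_trend(mom$mean, mom$raw, floor = dispersion_floor)

  lfc <- log2((m_trt + pseudocount) / (m_ref + pseudocount))
  var_ref <- (m_ref + disp * m_ref^2) / n_ref
  var_trt <- (m_trt + disp * m_trt^2) / n_trt
  se <- sqrt(var_ref / (m_ref + pseudocount)^2 +
             var_trt / (m_trt + pseudocount)^2) / log(2)
  z <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  p[se == 0 & lfc == 0] <- 1

  degenerate <- rowSums(cnt[, grp == contrast[1], drop = FALSE]) == 0 |
    rowSums(cnt[, grp == contrast[2], drop = FALSE]) == 0

  ids <- rownames(counts)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(counts)))
  data.frame(
    unit_id = ids,
    base_mean = (m_ref * n_ref + m_trt * n_trt) / (n_ref + n_trt),
    log2fc = lfc,
    p_value = p,
    q_value = bh_adjust(p),
    dispersion = disp,
    dispersion_raw = mom$raw,
    degenerate = degenerate,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH q-values. `NA`/`NaN` entries propagate and are excluded from
#' the number of tests m. Input order is preserved.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  q <- rep(NA_real_, length(p_values))
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) stop("p-values must be in [0, 1]")
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  q
}

#' Fisher's exact test for a 2x2 table
#'
#' Conditional hypergeometric test: the two-sided p-value is the sum of the
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (within a 1 + 1e-7 relative
#' tolerance, as is conventional). The reported odds ratio is the sample
#' odds ratio ad/bc; degenerate ratios (0/0 -> NaN, x/0 -> Inf) are flagged.
#'
#' @param table 2x2 matrix of nonnegative integers.
#' @return List with `odds_ratio`, `p_value`, and `degenerate_or` flag.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) stop("table must be 2x2")
  if (any(tab < 0)) stop("table entries must be nonnegative")
  if (any(tab != round(tab))) stop("table entries must be integers")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + c_            # first-column margin
  n <- b + d             # second-column margin
  k <- a + b             # first-row margin
  if (m + n == 0 || k == 0 || k == m + n) {
    p <- 1
  } else {
    lo <- max(0L, k - n)
    hi <- min(k, m)
    support <- lo:hi
    dens <- stats::dhyper(support, m, n, k)
    p_obs <- stats::dhyper(a, m, n, k)
    p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
    p <- min(1, max(p, 0))
  }
  or <- if (b * c_ == 0 && a * d == 0) NaN else (a * d) / (b * c_)
  list(odds_ratio = or, p_value = p,
       degenerate_or = !is.finite(or))
}

# Exact distribution of the positive-rank sum W+ over all 2^n sign
# assignments, via the shift algorithm on doubled (integer) midranks.
# Returns P(W+ <= w) and P(W+ >= w) for an observed doubled statistic w2.
signed_rank_exact_p <- function(ranks2, w2) {
  total <- sum(ranks2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (r in ranks2) {
    g <- f
    idx <- (r + 1):(total + 1)
    g[idx] <- g[idx] + f[idx - r]
    f <- g
  }
  f <- f / sum(f)
  w2 <- round(w2)
  p_le <- sum(f[seq_len(w2 + 1)])
  p_ge <- sum(f[(w2 + 1):(total + 1)])
  c(p_le = p_le, p_ge = p_ge)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; ties receive midranks. For fewer than 25
#' nonzero differences the p-value is exact (full enumeration of sign
#' assignments via the shift algorithm, valid with midranks); otherwise a
#' tie-corrected normal approximation is used. Two-sided.
#'
#' @param paired_a,paired_b Equal-length numeric vectors.
#' @param exact_below Sample-size threshold under which the exact
#'   distribution is enumerated (default 25).
#' @return List with `statistic` (positive-rank sum W+), `n_used`,
#'   `p_value`, `method`, and `all_zero` flag.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b, exact_below = 25) {
  if (length(paired_a) != length(paired_b)) stop("paired vectors must have equal length")
  d <- paired_a - paired_b
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, n_used = 0, p_value = 1,
                method = "degenerate", all_zero = TRUE))
  }
  r <- rank(abs(d))            # midranks for ties
  w_pos <- sum(r[d > 0])
  if (n < exact_below) {
    ranks2 <- round(2 * r)     # doubled midranks are integers
    pe <- signed_rank_exact_p(ranks2, 2 * w_pos)
    p <- min(1, 2 * min(pe["p_le"], pe["p_ge"]))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_pos - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(statistic = w_pos, n_used = n, p_value = unname(p),
       method = method, all_zero = FALSE)
}

#' Row-wise z-score normalization
#'
#' Centers and scales each row to mean 0 and population standard deviation 1
#' (divisor n, not n-1). Constant rows become all zeros and are flagged in
#' the `"constant_rows"` attribute.
#'
#' @param mat Numeric matrix, rows x samples; each row needs >= 2 finite
#'   values.
#' @return Matrix of the same shape.
#' @export
zscore_normalize <- function(mat) {
  mat <- as.matrix(mat)
  n <- ncol(mat)
  if (n < 2) stop("need >= 2 columns")
  mu <- rowMeans(mat)
  sd_pop <- sqrt(rowMeans((mat - mu)^2))
  const <- sd_pop == 0
  out <- (mat - mu) / ifelse(const, 1, sd_pop)
  out[const, ] <- 0
  attr(out, "constant_rows") <- which(const)
  out
}
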