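#' Reads per kilobase of exon per million mapped reads
#'
#' `rpkm = count / (exonic_length/1e3) / (lib_size/1e6)`.
#'
#' @param gene_counts Gene x sample count matrix.
#' @param exonic_lengths Positive lengths in bp, one per gene.
#' @param library_sizes Positive totals, one per sample.
#' @return Numeric matrix of the same shape.
#' @export
compute_rpkm <- function(gene_counts, exonic_lengths, library_sizes) {
  m <- as.matrix(gene_counts)
  if (any(exonic_lengths <= 0)) stop("exonic lengths must be positive")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (length(exonic_lengths) != nrow(m)) stop("one length per gene required")
  if (length(library_sizes) != ncol(m)) stop("one library size per sample required")
  sweep(m / (exonic_lengths / 1e3), 2, library_sizes / 1e6, "/")
}

#' Differentially expressed gene sets
#'
#' Wraps the NB test; induced genes satisfy `q < q_thresh` and
#' `log2fc > lfc_thresh`, repressed genes `q < q_thresh` and
#' `log2fc < -lfc_thresh`. The hormone contrast uses `lfc_thresh = 1`; the
#' corepressor-mutant (NCOR1dID) contrast uses `lfc_thresh = 0`.
#'
#' @param rna_counts Gene x sample count matrix.
#' @param group Group label per column.
#' @param contrast `c(reference, treatment)`.
#' @param q_thresh,lfc_thresh Thresholds (defaults 0.01 and 1).
#' @return List: `result`, `induced`, `repressed`, `thresholds`.
#' @export
de_genes <- function(rna_counts, group, contrast, q_thresh = 0.01,
                     lfc_thresh = 1) {
  res <- nb_differential_test(rna_counts, group, contrast)
  ok <- !is.na(res$q_value)
  list(result = res,
       induced = res$unit_id[ok & res$q_value < q_thresh &
                             res$log2fc > lfc_thresh],
       repressed = res$unit_id[ok & res$q_value < q_thresh &
                               res$log2fc < -lfc_thresh],
       thresholds = c(q = q_thresh, lfc = lfc_thresh))
}

#' Link hyperacetylated regions to genes near their TSS
#'
#' A gene is linked to a region when the distance from its TSS to the
#' nearest base of the region is at most `max_distance` (inclusive;
#' distance 0 when the region spans the TSS).
#'
#' @param regions `GRanges`, named or with `region_id`; an optional
#'   `class` metadata column is carried into the links.
#' @param genes `data.frame` with `gene_id`, `chrom`, `tss`.
#' @param max_distance Bp (default 100000).
#' @return `data.frame` of links: `gene_id`, `region_id`, `distance`,
#'   `region_class` (NA when regions carry no class).
#' @export
link_regions_to_genes <- function(regions, genes, max_distance = 1e5) {
  ids <- names(regions)
  if (is.null(ids)) ids <- as.character(seq_along(regions))
  cls <- if (!is.null(regions$class)) as.character(regions$class)
         else rep(NA_character_, length(regions))
  rchrom <- as.character(GenomicRanges::seqnames(regions))
  rstart <- GenomicRanges::start(regions) - 1   # 0-based
  rend <- GenomicRanges::end(regions)           # half-open end
  out <- list()
  for (i in seq_len(nrow(genes))) {
    sel <- which(rchrom == genes$chrom[i])
    if (length(sel) == 0) next
    tss <- genes$tss[i]
    d <- pmax(rstart[sel] - tss, tss - (rend[sel] - 1), 0)
    hit <- sel[d <= max_distance]
    if (length(hit))
      out[[length(out) + 1]] <- data.frame(
        gene_id = genes$gene_id[i], region_id = ids[hit],
        distance = d[d <= max_distance], region_class = cls[hit],
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(gene_id = character(), region_id = character(),
                      distance = numeric(), region_class = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fold enrichment of an outcome in a gene set versus random gene sets
#'
#' Compares the outcome fraction in `gene_set` with the mean fraction over
#' `n_sets` random draws of `n_per_set` genes from `all_genes`, and tests
#' the random fractions against the observed fraction with a two-sided
#' one-sample Student's t-test.
#'
#' @param gene_set Character vector of gene ids.
#' @param outcome Named logical vector over all genes (e.g. induced in the
#'   NCOR1dID mutant).
#' @param all_genes Character vector of all annotated gene ids.
#' @param n_per_set Genes per random set (default 1000).
#' @param n_sets Number of random sets (default 10).
#' @param seed Seed for the draws.
#' @return List: `observed_fraction`, `random_fractions`,
#'   `fold_enrichment` (NA-flagged when the random mean is 0), `t_p`,
#'   `degenerate`, `seed`.
#' @export
random_gene_enrichment <- function(gene_set, outcome, all_genes,
                                   n_per_set = 1000, n_sets = 10,
                                   seed = NULL) {
  if (n_per_set > length(all_genes)) stop("n_per_set exceeds gene universe")
  if (is.null(names(outcome))) stop("outcome must be named by gene id")
  if (!is.null(seed)) set.seed(seed)
  if (length(gene_set) == 0) {
    return(list(observed_fraction = NA_real_, random_fractions = numeric(0),
                fold_enrichment = NA_real_, t_p = NA_real_,
                degenerate = TRUE, seed = seed))
  }
  obs <- mean(outcome[gene_set], na.rm = TRUE)
  rand <- vapply(seq_len(n_sets), function(i) {
    g <- sample(all_genes, n_per_set)
    mean(outcome[g], na.rm = TRUE)
  }, numeric(1))
  mu_rand <- mean(rand)
  degenerate <- mu_rand == 0
  fold <- if (degenerate) NA_real_ else obs / mu_rand
  t_p <- if (stats::sd(rand) == 0) {
    if (obs == mu_rand) 1 else 0
  } else {
    stats::t.test(rand, mu = obs)$p.value
  }
  list(observed_fraction = obs, random_fractions = rand,
       fold_enrichment = fold, t_p = t_p, degenerate = degenerate,
       seed = seed)
}
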