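#' Pipeline run configuration
#'
#' All thresholds default to the study's printed values: per-mark
#' significance FDR < 0.01 with log2FC > 1, acute kinetics FDR < 0.05 with
#' log2FC > 0, super-enhancer stitch distance 12.5 kb, Hi-C window 10 kb,
#' gene linkage within 100 kb of the TSS, 600 random acetylated regions for
#' Fisher controls and 10 sets of 1000 random genes for expression
#' enrichment.
#'
#' @param seed Integer master seed; fanned out to per-stage streams.
#' @param sim A [sim_config()]; defaults to `sim_config(seed = seed)`.
#' @param fdr,lfc Hyperacetylation thresholds per mark.
#' @param acute_fdr,acute_lfc Acute-kinetics thresholds.
#' @param se_stitch Super-enhancer stitch distance, bp.
#' @param hic_window Hi-C quantification window, bp.
#' @param hic_min_dist,hic_max_dist Candidate pair distance range, bp.
#' @param hic_fold,hic_significance Interaction detection thresholds.
#' @param link_distance Gene linkage distance, bp.
#' @param n_random_regions Random acetylated regions per Fisher control.
#' @param n_random_genes,n_random_gene_sets Random-gene null dimensions.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed, sim = NULL, fdr = 0.01, lfc = 1,
                       acute_fdr = 0.05, acute_lfc = 0, se_stitch = 12500,
                       hic_window = 10000, hic_min_dist = 2e4,
                       hic_max_dist = 1e6, hic_fold = 2,
                       hic_significance = 1e-5, link_distance = 1e5,
                       n_random_regions = 600, n_random_genes = 1000,
                       n_random_gene_sets = 10) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(sim)) sim <- sim_config(seed = seed)
  stopifnot(fdr > 0, lfc >= 0, acute_fdr > 0, se_stitch > 0,
            hic_window > 0, link_distance > 0, n_random_regions > 0,
            n_random_genes > 0, n_random_gene_sets > 0)
  structure(list(seed = as.integer(seed), sim = sim, fdr = fdr, lfc = lfc,
                 acute_fdr = acute_fdr, acute_lfc = acute_lfc,
                 se_stitch = se_stitch, hic_window = hic_window,
                 hic_min_dist = hic_min_dist, hic_max_dist = hic_max_dist,
                 hic_fold = hic_fold, hic_significance = hic_significance,
                 link_distance = link_distance,
                 n_random_regions = n_random_regions,
                 n_random_genes = n_random_genes,
                 n_random_gene_sets = n_random_gene_sets),
            class = "run_config")
}

chip_group <- function(sim, target) {
  ss <- sim$chip_samples[sim$chip_samples$target == target, ]
  mat <- sim$chip_counts[[target]]
  ss$condition[match(colnames(mat), ss$sample_id)]
}

#' Run the full enhancer-classification pipeline on a synthetic dataset
#'
#' Executes simulate -> per-mark differential tests -> dual-mark
#' high-confidence intersection -> TRBS annotation and HDAC3-tertile
#' classification -> super-enhancer calling and co-occupancy enrichment ->
#' Hi-C interaction detection, opposite-direction background comparison,
#' TAD confinement and distance profiling -> gene linkage with
#' differential expression and random-gene enrichment -> recovery scoring
#' against the planted truth. Deterministic: identical config and seed
#' yield an identical report.
#'
#' @param config A [run_config()].
#' @return A nested list report (JSON-serializable via [write_report()]).
#' @export
run_all <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  seed <- config$seed
  sim <- simulate_dataset(config$sim)
  regions <- sim$regions
  truth_r <- sim$truth$regions

  ## --- differential acetylation per mark -------------------------------
  k27 <- differential_regions(sim$chip_counts$H3K27Ac,
                              chip_group(sim, "H3K27Ac"),
                              c("hypo", "hyper"), config$fdr, config$lfc)
  k9 <- differential_regions(sim$chip_counts$H3K9Ac,
                             chip_group(sim, "H3K9Ac"),
                             c("hypo", "hyper"), config$fdr, config$lfc)
  hc <- high_confidence_intersect(k27$result, k9$result,
                                  config$fdr, config$lfc)
  hyper_ids <- hc$unit_id[hc$is_high_confidence]
  hyper_gr <- regions[hyper_ids]

  ## --- TRBS annotation and HDAC3 tertiles ------------------------------
  ann <- annotate_overlaps(hyper_gr, sim$peaks)
  trbs_ids <- ann$region_id[ann$has_trbs]
  no_ids <- ann$region_id[!ann$has_trbs]
  w_gr <- regions[trbs_ids]
  no_gr <- regions[no_ids]

  hdac3 <- sim$chip_counts$HDAC3
  grp_h <- chip_group(sim, "HDAC3")
  sf_h <- median_ratio_size_factors(hdac3)
  norm_h <- sweep(hdac3, 2, sf_h, "/")
  hdac3_hypo <- rowMeans(norm_h[, grp_h == "hypo", drop = FALSE])
  tert <- classify_tertiles(
    data.frame(region_id = trbs_ids,
               chrom = as.character(GenomicRanges::seqnames(w_gr)),
               start = GenomicRanges::start(w_gr) - 1,
               stringsAsFactors = FALSE),
    density = unname(hdac3_hypo[trbs_ids]))

  ## --- super-enhancers --------------------------------------------------
  grp_k27 <- chip_group(sim, "H3K27Ac")
  k27m <- sim$chip_counts$H3K27Ac[, grp_k27 %in% c("hypo", "hyper"),
                                  drop = FALSE]
  sf_k <- median_ratio_size_factors(k27m)
  norm_k <- sweep(k27m, 2, sf_k, "/")
  k27_hyper_signal <- rowMeans(
    norm_k[, grp_k27[grp_k27 %in% c("hypo", "hyper")] == "hyper",
           drop = FALSE])
  stitched <- stitch_peaks(regions, unname(k27_hyper_signal),
                           config$se_stitch)
  ses <- se_cutoff(stitched)
  supers <- ses[ses$is_super]
  se_enrich <- se_cooccupancy_enrichment(
    ses, no_gr, w_gr, random_pool = regions,
    n_random = config$n_random_regions, seed = seed + 201L)

  ## --- chromatin 3D -----------------------------------------------------
  pairs <- detect_interactions(sim$hic, hyper_gr,
                               min_distance = config$hic_min_dist,
                               max_distance = config$hic_max_dist,
                               window = config$hic_window,
                               fold = config$hic_fold,
                               significance = config$hic_significance)
  is_cross <- (pairs$id_a %in% no_ids & pairs$id_b %in% trbs_ids) |
    (pairs$id_b %in% no_ids & pairs$id_a %in% trbs_ids)
  cross <- pairs[is_cross, , drop = FALSE]
  if (nrow(cross) > 0) {
    bg <- vapply(seq_len(nrow(cross)), function(i) {
      ob <- opposite_background(sim$hic, regions[cross$id_a[i]],
                                regions[cross$id_b[i]], config$hic_window)
      if (ob$excluded) NA_real_ else ob$count
    }, numeric(1))
    keep <- !is.na(bg)
    loop_test <- wilcoxon_signed_rank(cross$observed[keep], bg[keep])
    cross$background <- bg
  } else {
    loop_test <- list(statistic = NA_real_, n_used = 0, p_value = NA_real_,
                      method = "none", all_zero = NA)
  }
  tad_res <- tad_confinement(no_gr, w_gr, sim$tads, regions,
                             n_random = config$n_random_regions,
                             seed = seed + 202L)
  ndist <- nearest_distance_profile(no_gr, w_gr, regions,
                                    seed = seed + 203L)

  ## --- explanations for no/TRBS regions --------------------------------
  se_with_w <- supers[IRanges::overlapsAny(supers, w_gr, minoverlap = 1)]
  in_se <- no_ids[IRanges::overlapsAny(no_gr, se_with_w, minoverlap = 1)]
  in_loop <- unique(c(cross$id_a, cross$id_b))
  in_loop <- intersect(in_loop, no_ids)
  tadded <- character(0)
  if (length(no_ids)) {
    mids <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(no_gr),
      IRanges::IRanges(midpoints_gr(no_gr) + 1, width = 1))
    w_mids <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(w_gr),
      IRanges::IRanges(midpoints_gr(w_gr) + 1, width = 1))
    t_no <- GenomicRanges::findOverlaps(mids, sim$tads, select = "first")
    t_w <- unique(GenomicRanges::findOverlaps(w_mids, sim$tads,
                                              select = "first"))
    tadded <- no_ids[!is.na(t_no) & t_no %in% t_w]
  }
  explanation <- vapply(no_ids, function(id) {
    tags <- c(if (id %in% in_se) "in_SE_with_TRBS",
              if (id %in% in_loop) "loop_to_TRBS",
              if (id %in% tadded) "TAD_with_TRBS")
    if (length(tags) == 0) "unexplained" else paste(tags, collapse = ",")
  }, character(1))
  ann$explanation[match(no_ids, ann$region_id)] <- explanation

  ## --- region class labels ----------------------------------------------
  region_class <- stats::setNames(rep("none", length(regions)),
                                  names(regions))
  region_class[tert$region_id] <- tert$tertile_class
  region_class[no_ids] <-
    ifelse(no_ids %in% in_se, "indirect_SE",
    ifelse(no_ids %in% in_loop, "indirect_loop", "indirect_unexplained"))

  ## --- gene linkage ------------------------------------------------------
  grp_rna <- paste(sim$rna_samples$genotype, sim$rna_samples$condition,
                   sep = "_")
  de_t3 <- de_genes(sim$rna_counts, grp_rna, c("WT_hypo", "WT_hyper"),
                    config$fdr, 1)
  de_ncor <- de_genes(sim$rna_counts, grp_rna, c("WT_hypo", "NCOR1dID_hypo"),
                      config$fdr, 0)
  rpkm <- compute_rpkm(sim$rna_counts, sim$genes$exonic_length,
                       colSums(sim$rna_counts))
  link_gr <- hyper_gr
  link_gr$class <- region_class[hyper_ids]
  links <- link_regions_to_genes(link_gr, sim$genes, config$link_distance)
  linked_genes <- unique(links$gene_id)
  # exclusive bins: genes associated with type1A but not type1B TRBSs, and
  # vice versa, so the corepressor-dependence contrast is not diluted by
  # genes near both classes
  g1a_any <- links$gene_id[links$region_class == "type1A"]
  g1b_any <- links$gene_id[links$region_class == "type1B"]
  genes_1a <- intersect(de_t3$induced, setdiff(g1a_any, g1b_any))
  genes_1b <- intersect(de_t3$induced, setdiff(g1b_any, g1a_any))
  outcome <- stats::setNames(sim$genes$gene_id %in% de_ncor$induced,
                             sim$genes$gene_id)
  enr_1a <- random_gene_enrichment(genes_1a, outcome, sim$genes$gene_id,
                                   config$n_random_genes,
                                   config$n_random_gene_sets,
                                   seed = seed + 204L)
  enr_1b <- random_gene_enrichment(genes_1b, outcome, sim$genes$gene_id,
                                   config$n_random_genes,
                                   config$n_random_gene_sets,
                                   seed = seed + 205L)
  ind_linked <- sum(de_t3$induced %in% linked_genes)
  rep_linked <- sum(de_t3$repressed %in% linked_genes)
  link_fisher <- fisher_exact_2x2(matrix(
    c(ind_linked, length(de_t3$induced) - ind_linked,
      rep_linked, length(de_t3$repressed) - rep_linked), 2, byrow = TRUE))

  ## --- acute kinetics ----------------------------------------------------
  acute_2h <- differential_regions(sim$chip_counts$H3K27Ac, grp_k27,
                                   c("hypo", "t3_2h"),
                                   config$acute_fdr, config$acute_lfc)
  acute_6h <- differential_regions(sim$chip_counts$H3K27Ac, grp_k27,
                                   c("hypo", "t3_6h"),
                                   config$acute_fdr, config$acute_lfc)
  frac_acute <- function(a) {
    if (length(trbs_ids) == 0) return(NA_real_)
    mean(trbs_ids %in% a$significant)
  }
  cond_means <- vapply(c("hypo", "t3_2h", "t3_6h", "hyper"), function(cc) {
    rowMeans(sweep(sim$chip_counts$H3K27Ac[, grp_k27 == cc, drop = FALSE],
                   2, median_ratio_size_factors(
                        sim$chip_counts$H3K27Ac)[grp_k27 == cc], "/"))
  }, numeric(nrow(sim$chip_counts$H3K27Ac)))
  z_w <- zscore_normalize(cond_means[trbs_ids, , drop = FALSE])
  acute_profile <- colMeans(z_w)

  ## --- recovery ----------------------------------------------------------
  truth_class <- stats::setNames(truth_r$class, truth_r$region_id)
  hyper_truth <- truth_class %in% c("type1A", "type1B", "indirect_SE",
                                    "indirect_loop")
  hyper_pred <- names(truth_class) %in% hyper_ids
  hc_recall <- sum(hyper_pred & hyper_truth) / sum(hyper_truth)
  hc_precision <- sum(hyper_pred & hyper_truth) / max(sum(hyper_pred), 1)
  recovery <- evaluate_recovery(region_class, truth_class,
                                extra_labels = c("mid",
                                                 "indirect_unexplained"))
  # planted SE clusters recovered by a called super-enhancer
  cl <- truth_r[!is.na(truth_r$se_cluster), ]
  cluster_rec <- NA_real_
  if (nrow(cl) > 0) {
    spans <- do.call(rbind, lapply(split(cl, cl$se_cluster), function(d)
      data.frame(chrom = d$chrom[1], start = min(d$start),
                 end = max(d$end))))
    span_gr <- GenomicRanges::GRanges(spans$chrom,
                                      IRanges::IRanges(spans$start + 1,
                                                       spans$end))
    cluster_rec <- mean(IRanges::overlapsAny(span_gr, supers))
  }
  # planted loops recovered among detected pairs
  tl <- sim$truth$loops
  loop_rec <- NA_real_
  if (nrow(tl) > 0) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    loop_rec <- mean(key(tl$region_a, tl$region_b) %in%
                     key(pairs$id_a, pairs$id_b))
  }

  list(
    config = unclass(config)[setdiff(names(unclass(config)), "sim")],
    sim_config = unclass(config$sim),
    counts = list(
      n_regions = length(regions),
      n_hyperacetylated = length(hyper_ids),
      n_with_trbs = length(trbs_ids),
      n_without_trbs = length(no_ids),
      n_superenhancers = length(supers),
      n_detected_pairs = nrow(pairs),
      n_cross_pairs = nrow(cross),
      n_genes = nrow(sim$genes),
      n_induced = length(de_t3$induced),
      n_repressed = length(de_t3$repressed),
      n_induced_linked = ind_linked,
      n_links = nrow(links)
    ),
    hyperacetylated = data.frame(
      region_id = hyper_ids,
      chrom = as.character(GenomicRanges::seqnames(hyper_gr)),
      start = GenomicRanges::start(hyper_gr) - 1,
      end = GenomicRanges::end(hyper_gr),
      tr_status = ann$tr_status,
      class = unname(region_class[hyper_ids]),
      explanation = ann$explanation,
      stringsAsFactors = FALSE),
    tertiles = list(
      n = nrow(tert),
      n_type1A = sum(tert$tertile_class == "type1A"),
      n_mid = sum(tert$tertile_class == "mid"),
      n_type1B = sum(tert$tertile_class == "type1B")),
    hdac3_contrast = {
      d1a <- sort(tert$density[tert$tertile_class == "type1A"],
                  decreasing = TRUE)
      d1b <- sort(tert$density[tert$tertile_class == "type1B"],
                  decreasing = TRUE)
      m <- min(length(d1a), length(d1b))
      wt <- if (m >= 6) wilcoxon_signed_rank(d1a[seq_len(m)],
                                             d1b[seq_len(m)])
      else list(p_value = NA_real_)
      list(mean_type1A = mean(d1a), mean_type1B = mean(d1b),
           signed_rank_p = wt$p_value)
    },
    superenhancer = list(
      n_super = length(supers),
      mean_span = if (length(supers)) mean(GenomicRanges::width(supers))
                  else NA_real_,
      enrichment = se_enrich[c("fraction", "odds_ratio", "p_value",
                               "seed")]),
    hic = list(
      loop_signed_rank_p = loop_test$p_value,
      loop_n = loop_test$n_used,
      tad = tad_res[c("fraction", "odds_ratio", "p_value", "seed")],
      median_dist_to_trbs = ndist$median_b,
      median_dist_to_random = ndist$median_random),
    genes = list(
      fold_type1A = enr_1a$fold_enrichment, t_p_type1A = enr_1a$t_p,
      fold_type1B = enr_1b$fold_enrichment, t_p_type1B = enr_1b$t_p,
      induced_vs_repressed_link_or = link_fisher$odds_ratio,
      induced_vs_repressed_link_p = link_fisher$p_value,
      median_rpkm_induced = stats::median(
        rpkm[rownames(rpkm) %in% de_t3$induced, , drop = FALSE])),
    acute = list(
      frac_sig_2h = frac_acute(acute_2h),
      frac_sig_6h = frac_acute(acute_6h),
      zscore_profile = as.list(acute_profile)),
    recovery = list(
      hc_recall = hc_recall,
      hc_precision = hc_precision,
      per_class = recovery$per_class,
      macro = as.list(recovery$macro),
      se_cluster_recovery = cluster_rec,
      loop_recovery = loop_rec),
    seed = seed
  )
}

#' Write a run report as JSON
#'
#' @param report List from [run_all()].
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
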