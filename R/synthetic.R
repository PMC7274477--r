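#' Configuration for the synthetic T3-response dataset
#'
#' Defines the study conditions emulated by [simulate_dataset()]: a small
#' multi-chromosome genome carrying planted enhancer classes, NB-distributed
#' ChIP tag counts per target and condition with two biological replicates,
#' clustered constituents forming super-enhancers, a distance-decaying Hi-C
#' background with planted loops, TADs confining co-regulated regions, and
#' NB gene-expression counts coupled to the planted enhancer classes.
#'
#' Planted classes (fractions of `n_regions`):
#' * `type1A` — poised TR binding site: HDAC3/NCOR1 high in hypothyroid and
#'   dropping `hdac3_fold_drop`-fold with T3; TR/CBP constitutively high;
#'   acetylation up `ac_fold` with T3.
#' * `type1B` — T3-established TRBS: HDAC3 low throughout; TR, CBP, MED1 and
#'   DNase recruited `tr_recruit_fold`-fold with T3; acetylation up `ac_fold`.
#' * `indirect_SE` — hyperacetylated without TR, sitting in a planted
#'   super-enhancer cluster that also contains a TR-bound region.
#' * `indirect_loop` — hyperacetylated without TR, connected by a planted
#'   Hi-C loop to a TR-bound region in the same TAD.
#' * `constitutive` — high acetylation in both conditions, no T3 response.
#' * `null` — background acetylation, no effect anywhere.
#'
#' @param seed Integer seed (mandatory); the placement, count, Hi-C and RNA
#'   layers use streams `seed + 1 .. seed + 4`.
#' @param n_chrom,chrom_len Number and length (bp) of chromosomes.
#' @param n_regions Total planted acetylated regions (the region universe).
#' @param class_fractions Named fractions for the six classes; must sum to
#'   at most 1 (remainder goes to `null`).
#' @param baseline_mean Baseline NB mean tag count per region and sample.
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2).
#' @param ac_fold Acetylation fold change hyper/hypo at planted responsive
#'   regions (>= 1; 1 switches the T3 response off).
#' @param hdac3_fold_drop Fold drop of HDAC3/NCOR1 at type1A sites with T3.
#' @param tr_recruit_fold Fold recruitment of TR/CBP/MED1/DNase at type1B.
#' @param libsize_jitter Library-size factors drawn log-uniformly in
#'   `[1 - jitter, 1 + jitter]`.
#' @param se_cluster_size Length-2 integer range of constituents per planted
#'   super-enhancer cluster.
#' @param se_span Genomic span (bp) of one planted SE cluster.
#' @param hic_resolution Hi-C bin size (bp).
#' @param hic_window Quantification window (bp) used when boosting loop
#'   anchor bins.
#' @param loop_boost Multiplier on the Hi-C background at planted loop
#'   anchor bin pairs.
#' @param hic_background Background contact rate at distance 0 (`c0`).
#' @param hic_decay_bp Distance scale Delta of the `1/(1 + d/Delta)` decay.
#' @param hic_max_dist Maximal distance (bp) at which background contacts
#'   are generated.
#' @param loop_dist_range Range (bp) of planted loop anchor distances.
#' @param n_genes Number of genes.
#' @param frac_induced,frac_repressed Fractions of genes planted as
#'   T3-induced (coupled to a hyperacetylated driver region) or repressed.
#' @param rna_fold Expression fold change of induced/repressed genes.
#' @param ncor_derepression_fold Derepression of NCOR1-dID-responsive genes
#'   (those with a type1A driver) in the mutant hypothyroid samples.
#' @param region_width Width (bp) of each planted region.
#' @param min_gap Minimal gap (bp) between planted units outside clusters.
#' @param gap_range Range (bp) the gap between consecutive planted units is
#'   drawn from; the default keeps isolated regions farther apart than the
#'   usual 12.5 kb super-enhancer stitch distance so only planted clusters
#'   stitch.
#' @param active_tad_fraction Fraction of TADs designated "active": all
#'   T3-responsive and TR-bound units are placed inside them, background
#'   (null/constitutive) units in the remaining TADs. This concentrates
#'   regulatory activity in a subset of domains, giving TAD-confinement
#'   tests a real contrast.
#' @param tad_len_range Range (bp) of TAD lengths tiling each chromosome.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed,
                       n_chrom = 3,
                       chrom_len = 2e7,
                       n_regions = 2000,
                       class_fractions = c(type1A = 0.10, type1B = 0.10,
                                           indirect_SE = 0.03,
                                           indirect_loop = 0.03,
                                           constitutive = 0.24, null = 0.50),
                       baseline_mean = 100,
                       dispersion = 0.05,
                       ac_fold = 4,
                       hdac3_fold_drop = 3,
                       tr_recruit_fold = 5,
                       libsize_jitter = 0.3,
                       se_cluster_size = c(5L, 10L),
                       se_span = 12000,
                       hic_resolution = 5000,
                       hic_window = 10000,
                       loop_boost = 6,
                       hic_background = 10,
                       hic_decay_bp = 5e4,
                       hic_max_dist = 1.5e6,
                       loop_dist_range = c(1e5, 3e5),
                       n_genes = 1500,
                       frac_induced = 0.20,
                       frac_repressed = 0.10,
                       rna_fold = 4,
                       ncor_derepression_fold = 3,
                       region_width = 1000,
                       min_gap = 5000,
                       gap_range = c(13000, 24000),
                       active_tad_fraction = 0.4,
                       tad_len_range = c(5e5, 2e6)) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  cf <- class_fractions
  need <- c("type1A", "type1B", "indirect_SE", "indirect_loop",
            "constitutive", "null")
  if (!all(need %in% names(cf))) stop("class_fractions must name all six classes")
  if (sum(cf) > 1 + 1e-9) stop("class_fractions must sum to <= 1")
  if (ac_fold < 1 || hdac3_fold_drop < 1 || tr_recruit_fold < 1)
    stop("fold parameters must be >= 1")
  cfg <- list(seed = as.integer(seed), n_chrom = n_chrom,
              chrom_len = chrom_len, n_regions = n_regions,
              class_fractions = cf[need], baseline_mean = baseline_mean,
              dispersion = dispersion, ac_fold = ac_fold,
              hdac3_fold_drop = hdac3_fold_drop,
              tr_recruit_fold = tr_recruit_fold,
              libsize_jitter = libsize_jitter,
              se_cluster_size = as.integer(se_cluster_size),
              se_span = se_span, hic_resolution = hic_resolution,
              hic_window = hic_window, loop_boost = loop_boost,
              hic_background = hic_background, hic_decay_bp = hic_decay_bp,
              hic_max_dist = hic_max_dist, loop_dist_range = loop_dist_range,
              n_genes = n_genes, frac_induced = frac_induced,
              frac_repressed = frac_repressed, rna_fold = rna_fold,
              ncor_derepression_fold = ncor_derepression_fold,
              region_width = region_width, min_gap = min_gap,
              gap_range = gap_range,
              active_tad_fraction = active_tad_fraction,
              tad_len_range = tad_len_range)
  class(cfg) <- "sim_config"
  cfg
}

sim_chrom_names <- function(cfg) paste0("chrS", seq_len(cfg$n_chrom))

sim_seqlengths <- function(cfg) {
  stats::setNames(rep(cfg$chrom_len, cfg$n_chrom), sim_chrom_names(cfg))
}

# Tile each chromosome with non-overlapping TAD blocks of random length.
place_tads <- function(cfg) {
  chroms <- sim_chrom_names(cfg)
  out <- list()
  for (ch in chroms) {
    pos <- 0
    starts <- ends <- numeric(0)
    while (pos < cfg$chrom_len) {
      len <- round(stats::runif(1, cfg$tad_len_range[1], cfg$tad_len_range[2]))
      end <- min(pos + len, cfg$chrom_len)
      starts <- c(starts, pos); ends <- c(ends, end)
      pos <- end
    }
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends)
  }
  df <- do.call(rbind, out)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1, df$end),
                               seqlengths = sim_seqlengths(cfg))
  names(gr) <- paste0("TAD", seq_along(gr))
  gr
}

# Integer class counts from fractions; remainder is null.
class_counts <- function(cfg) {
  cf <- cfg$class_fractions
  n <- cfg$n_regions
  cnt <- floor(cf * n)
  cnt["null"] <- n - sum(cnt[names(cnt) != "null"])
  cnt
}

# Build the list of placement units: SE clusters (compound), loop pairs
# (compound: TR-bound partner + indirect_loop region), and singletons.
build_units <- function(cfg) {
  cnt <- class_counts(cfg)
  budget <- as.list(cnt)
  take <- function(cls, k = 1) {
    k <- min(k, budget[[cls]])
    budget[[cls]] <<- budget[[cls]] - k
    rep(cls, k)
  }
  units <- list()
  # SE clusters: 2 indirect_SE + up to 2 TR-bound + constitutive filler.
  i_cl <- 0
  while (budget$indirect_SE > 0) {
    i_cl <- i_cl + 1
    k <- sample(seq(cfg$se_cluster_size[1], cfg$se_cluster_size[2]), 1)
    members <- c(take("indirect_SE", 2),
                 take(if (i_cl %% 2 == 1) "type1A" else "type1B", 1),
                 take(if (i_cl %% 2 == 1) "type1B" else "type1A", 1))
    filler <- k - length(members)
    if (filler > 0) {
      fill <- take("constitutive", filler)
      if (length(fill) < filler) fill <- c(fill, take("null", filler - length(fill)))
      members <- c(members, fill)
    }
    units[[length(units) + 1]] <- list(kind = "cluster",
                                       classes = sample(members),
                                       cluster_id = paste0("SE_CL", i_cl))
  }
  # Loop pairs: TR-bound anchor + indirect_loop region.
  i_lp <- 0
  while (budget$indirect_loop > 0) {
    i_lp <- i_lp + 1
    partner <- if (budget$type1A >= budget$type1B) "type1A" else "type1B"
    pc <- take(partner, 1)
    if (length(pc) == 0) pc <- take(if (partner == "type1A") "type1B" else "type1A", 1)
    if (length(pc) == 0) stop("not enough TR-bound regions for planted loops")
    units[[length(units) + 1]] <- list(kind = "loop_pair",
                                       classes = c(pc, take("indirect_loop", 1)),
                                       loop_id = paste0("LOOP", i_lp))
  }
  # Singletons for whatever budget remains.
  singles <- unlist(lapply(names(budget), function(cl) rep(cl, budget[[cl]])))
  singles <- sample(singles)
  for (cl in singles)
    units[[length(units) + 1]] <- list(kind = "single", classes = cl)
  units <- sample(units)
  # Responsive/TR-bound units live in active TADs, background elsewhere.
  for (i in seq_along(units))
    units[[i]]$active <- units[[i]]$kind != "single" ||
      units[[i]]$classes %in% c("type1A", "type1B", "indirect_SE",
                                "indirect_loop")
  units
}

# First-fit placement of units into TADs, with randomized gaps drawn from
# gap_range (>= min_gap). Units flagged active go to active TADs only,
# background units to the remaining TADs.
place_units <- function(cfg, units, tads) {
  w <- cfg$region_width
  tad_df <- data.frame(chrom = as.character(GenomicRanges::seqnames(tads)),
                       start = GenomicRanges::start(tads) - 1,
                       end = GenomicRanges::end(tads),
                       stringsAsFactors = FALSE)
  tad_df <- tad_df[sample(nrow(tad_df)), ]
  n_tads <- nrow(tad_df)
  n_active <- max(1, round(cfg$active_tad_fraction * n_tads))
  tad_df$active <- seq_len(n_tads) <= n_active   # order already random
  if (all(tad_df$active)) tad_df$active[n_tads] <- FALSE
  cursor <- tad_df$start + cfg$min_gap
  rows <- list()
  ptr <- 1
  for (u in units) {
    d_loop <- 0
    if (u$kind == "cluster") {
      need <- cfg$se_span
    } else if (u$kind == "loop_pair") {
      d_loop <- round(stats::runif(1, cfg$loop_dist_range[1],
                                   cfg$loop_dist_range[2]))
      need <- d_loop + 2 * w
    } else {
      need <- w
    }
    placed <- FALSE
    for (step in seq_len(n_tads)) {
      i <- ((ptr + step - 2) %% n_tads) + 1
      if (tad_df$active[i] != u$active) next
      gap <- round(stats::runif(1, cfg$gap_range[1], cfg$gap_range[2]))
      at <- cursor[i] + gap
      if (at + need + cfg$min_gap <= tad_df$end[i]) {
        if (u$kind == "cluster") {
          k <- length(u$classes)
          offs <- if (k == 1) 0 else round((0:(k - 1)) * (cfg$se_span - w) / (k - 1))
          for (j in seq_len(k))
            rows[[length(rows) + 1]] <- data.frame(
              chrom = tad_df$chrom[i], start = at + offs[j],
              end = at + offs[j] + w, class = u$classes[j],
              se_cluster = u$cluster_id, loop_id = NA_character_,
              loop_role = NA_character_, stringsAsFactors = FALSE)
        } else if (u$kind == "loop_pair") {
          rows[[length(rows) + 1]] <- data.frame(
            chrom = tad_df$chrom[i], start = at, end = at + w,
            class = u$classes[1], se_cluster = NA_character_,
            loop_id = u$loop_id, loop_role = "anchor",
            stringsAsFactors = FALSE)
          rows[[length(rows) + 1]] <- data.frame(
            chrom = tad_df$chrom[i], start = at + d_loop,
            end = at + d_loop + w, class = u$classes[2],
            se_cluster = NA_character_, loop_id = u$loop_id,
            loop_role = "indirect", stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1]] <- data.frame(
            chrom = tad_df$chrom[i], start = at, end = at + w,
            class = u$classes, se_cluster = NA_character_,
            loop_id = NA_character_, loop_role = NA_character_,
            stringsAsFactors = FALSE)
        }
        cursor[i] <- at + need
        ptr <- i + 1
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("class placement infeasible for genome size; need at least ",
           need + 2 * cfg$min_gap, " bp of free TAD space")
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$start, df$end), ]
  df$region_id <- sprintf("R%04d", seq_len(nrow(df)))
  rownames(df) <- NULL
  df
}

# Mean multiplier (relative to baseline_mean) per class x target x condition.
class_multiplier <- function(cfg, class, target, condition) {
  F <- cfg$ac_fold; Dr <- cfg$hdac3_fold_drop; Tr <- cfg$tr_recruit_fold
  hyperac <- class %in% c("type1A", "type1B", "indirect_SE", "indirect_loop")
  m <- rep(1, length(class))
  if (target %in% c("H3K27Ac", "H3K9Ac")) {
    base <- ifelse(class == "constitutive", 3, 1)
    resp <- switch(condition, hypo = 1, hyper = F,
                   t3_2h = sqrt(F), t3_6h = F^0.9, 1)
    m <- base * ifelse(hyperac, resp, 1)
  } else if (target == "H3K4me1") {
    m <- ifelse(class == "type1A", 3,
         ifelse(class == "type1B", if (condition == "hyper") 2 else 0.5,
         ifelse(class == "constitutive", 1.5, 1)))
  } else if (target == "HDAC3") {
    m <- ifelse(class == "type1A", if (condition == "hyper") 5 / Dr else 5, 0.3)
  } else if (target == "NCOR1") {
    m <- ifelse(class == "type1A", if (condition == "hyper") 4 / Dr else 4, 0.3)
  } else if (target == "TR") {
    m <- ifelse(class == "type1A", 5,
         ifelse(class == "type1B", if (condition == "hyper") 0.5 * Tr else 0.5,
                0.2))
  } else if (target == "CBP") {
    m <- ifelse(class == "type1A", 3,
         ifelse(class == "type1B", if (condition == "hyper") 0.4 * Tr else 0.4,
                0.5))
  } else if (target == "MED1") {
    m <- ifelse(class == "type1A", if (condition == "hyper") 1.5 else 1,
         ifelse(class == "type1B", if (condition == "hyper") 0.4 * Tr else 0.4,
                0.5))
  } else if (target == "DNase") {
    m <- ifelse(class == "type1A", 3,
         ifelse(class == "type1B", if (condition == "hyper") 0.5 * Tr else 0.5,
         ifelse(class == "constitutive", 1.5, 1)))
  }
  m
}

sim_targets <- function() {
  c("H3K27Ac", "H3K9Ac", "H3K4me1", "HDAC3", "NCOR1", "CBP", "MED1",
    "TR", "DNase")
}

draw_lib_factor <- function(n, jitter) {
  exp(stats::runif(n, log(1 - jitter), log(1 + jitter)))
}

simulate_chip_counts <- function(cfg, region_df) {
  targets <- sim_targets()
  counts <- list()
  sheets <- list()
  for (tg in targets) {
    conds <- c("hypo", "hyper")
    if (tg == "H3K27Ac") conds <- c(conds, "t3_2h", "t3_6h")
    samples <- expand.grid(replicate = 1:2, condition = conds,
                           stringsAsFactors = FALSE)
    samples$target <- tg
    samples$genotype <- "WT"
    samples$sample_id <- paste(tg, samples$condition, samples$replicate,
                               sep = "_")
    samples$lib_factor <- draw_lib_factor(nrow(samples), cfg$libsize_jitter)
    mat <- matrix(0L, nrow(region_df), nrow(samples),
                  dimnames = list(region_df$region_id, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      mult <- class_multiplier(cfg, region_df$class, tg, samples$condition[j])
      mu <- cfg$baseline_mean * mult * samples$lib_factor[j]
      mat[, j] <- stats::rnbinom(nrow(region_df), mu = mu,
                                 size = 1 / cfg$dispersion)
    }
    counts[[tg]] <- mat
    sheets[[tg]] <- samples
  }
  sheet <- do.call(rbind, sheets)
  rownames(sheet) <- NULL
  list(counts = counts,
       sample_sheet = sheet[, c("sample_id", "target", "condition",
                                "genotype", "replicate", "lib_factor")])
}

# Narrow factor peaks planted inside regions of the appropriate classes.
plant_peaks <- function(cfg, region_df) {
  mk <- function(sel, label) {
    sub <- region_df[sel, , drop = FALSE]
    if (nrow(sub) == 0)
      return(GenomicRanges::GRanges(seqlengths = sim_seqlengths(cfg)))
    mid <- floor((sub$start + sub$end) / 2)
    gr <- GenomicRanges::GRanges(sub$chrom,
                                 IRanges::IRanges(mid - 149, mid + 150),
                                 seqlengths = sim_seqlengths(cfg))
    names(gr) <- paste0(label, "_", sub$region_id)
    gr
  }
  list(TR = mk(region_df$class %in% c("type1A", "type1B"), "TR"),
       HDAC3 = mk(region_df$class == "type1A", "HDAC3"),
       DHS = mk(region_df$class %in% c("type1A", "type1B", "constitutive"),
                "DHS"))
}

#' Generate the synthetic Hi-C contact map
#'
#' Cis-only background: the count of a bin pair at distance d bp is Poisson
#' with mean `c0 / (1 + d / Delta)`, generated out to `hic_max_dist`.
#' Planted loops multiply the background mean by `loop_boost` over the bin
#' blocks covering a `hic_window`-wide window around each anchor midpoint.
#' The matrix is symmetric and stored as an upper triangle.
#'
#' @param config A [sim_config()].
#' @param region_df Region table from placement (internal layout).
#' @param loops `data.frame` with columns `chrom`, `mid_a`, `mid_b`.
#' @return A `hic_matrix` object (see [hic_matrix()]).
#' @export
generate_hic <- function(config, region_df, loops) {
  cfg <- config
  res <- cfg$hic_resolution
  chroms <- sim_chrom_names(cfg)
  n_bins <- ceiling(cfg$chrom_len / res)
  max_off <- min(n_bins - 1, floor(cfg$hic_max_dist / res))
  pieces <- list()
  for (ch in chroms) {
    for (d in 0:max_off) {
      n <- n_bins - d
      mu <- cfg$hic_background / (1 + d * res / cfg$hic_decay_bp)
      x <- stats::rpois(n, mu)
      nz <- which(x > 0)
      if (length(nz))
        pieces[[length(pieces) + 1]] <- data.table::data.table(
          chrom = ch, bin1 = nz - 1L, bin2 = nz - 1L + d, count = x[nz])
    }
  }
  # Planted loops: add extra Poisson counts so the anchor-block mean is
  # boost * background.
  if (!is.null(loops) && nrow(loops) > 0 && cfg$loop_boost > 1) {
    half <- cfg$hic_window / 2
    for (i in seq_len(nrow(loops))) {
      ba <- floor((loops$mid_a[i] - half) / res):floor((loops$mid_a[i] + half - 1) / res)
      bb <- floor((loops$mid_b[i] - half) / res):floor((loops$mid_b[i] + half - 1) / res)
      ba <- ba[ba >= 0 & ba < n_bins]; bb <- bb[bb >= 0 & bb < n_bins]
      cells <- expand.grid(i = ba, j = bb)
      b1 <- pmin(cells$i, cells$j); b2 <- pmax(cells$i, cells$j)
      d <- b2 - b1
      mu <- cfg$hic_background / (1 + d * res / cfg$hic_decay_bp)
      extra <- stats::rpois(length(b1), mu * (cfg$loop_boost - 1))
      nz <- which(extra > 0)
      if (length(nz))
        pieces[[length(pieces) + 1]] <- data.table::data.table(
          chrom = loops$chrom[i], bin1 = as.integer(b1[nz]),
          bin2 = as.integer(b2[nz]), count = extra[nz])
    }
  }
  contacts <- data.table::rbindlist(pieces)
  contacts <- contacts[, list(count = sum(count)),
                       by = c("chrom", "bin1", "bin2")]
  data.table::setorderv(contacts, c("chrom", "bin1", "bin2"))
  hic_matrix(contacts, resolution = res, chrom_sizes = sim_seqlengths(cfg))
}

simulate_genes <- function(cfg, region_df) {
  n <- cfg$n_genes
  n_ind <- round(cfg$frac_induced * n)
  n_rep <- round(cfg$frac_repressed * n)
  hyper_classes <- c("type1A", "type1B", "indirect_SE", "indirect_loop")
  drivers_1a <- region_df$region_id[region_df$class == "type1A"]
  drivers_1b <- region_df$region_id[region_df$class == "type1B"]
  drivers_ind <- region_df$region_id[region_df$class %in%
                                     c("indirect_SE", "indirect_loop")]
  n_a <- round(0.4 * n_ind); n_b <- round(0.4 * n_ind)
  n_i <- n_ind - n_a - n_b
  driver <- c(sample(drivers_1a, n_a, replace = n_a > length(drivers_1a)),
              sample(drivers_1b, n_b, replace = n_b > length(drivers_1b)),
              sample(drivers_ind, n_i, replace = n_i > length(drivers_ind)))
  rmap <- region_df[match(driver, region_df$region_id), ]
  side <- sample(c(-1, 1), n_ind, replace = TRUE)
  off <- round(stats::runif(n_ind, 1e4, 8e4))
  tss_ind <- pmin(pmax(floor((rmap$start + rmap$end) / 2) + side * off, 1000),
                  cfg$chrom_len - 1000)
  chrom_ind <- rmap$chrom
  n_other <- n - n_ind
  chrom_oth <- sample(sim_chrom_names(cfg), n_other, replace = TRUE)
  tss_oth <- round(stats::runif(n_other, 1000, cfg$chrom_len - 1000))
  genes <- data.frame(
    gene_id = sprintf("G%04d", seq_len(n)),
    chrom = c(chrom_ind, chrom_oth),
    tss = c(tss_ind, tss_oth),
    strand = sample(c("+", "-"), n, replace = TRUE),
    exonic_length = round(exp(stats::runif(n, log(500), log(20000)))),
    stringsAsFactors = FALSE)
  cls <- c(rep("induced", n_ind), rep("repressed", n_rep),
           rep("null", n_other - n_rep))
  truth <- data.frame(
    gene_id = genes$gene_id,
    class = cls,
    is_induced = cls == "induced",
    driver_region = c(driver, rep(NA_character_, n_other)),
    driver_class = c(rmap$class, rep(NA_character_, n_other)),
    stringsAsFactors = FALSE)
  truth$is_ncor_dependent <- !is.na(truth$driver_class) &
    truth$driver_class == "type1A"

  samples <- data.frame(
    sample_id = c("RNA_WT_hypo_1", "RNA_WT_hypo_2", "RNA_WT_hyper_1",
                  "RNA_WT_hyper_2", "RNA_dID_hypo_1", "RNA_dID_hypo_2"),
    condition = c("hypo", "hypo", "hyper", "hyper", "hypo", "hypo"),
    genotype = c("WT", "WT", "WT", "WT", "NCOR1dID", "NCOR1dID"),
    replicate = c(1, 2, 1, 2, 1, 2),
    stringsAsFactors = FALSE)
  samples$group <- paste(samples$genotype, samples$condition, sep = "_")
  samples$lib_factor <- draw_lib_factor(nrow(samples), cfg$libsize_jitter)

  mu0 <- exp(stats::runif(n, log(50), log(500)))
  counts <- matrix(0L, n, nrow(samples),
                   dimnames = list(genes$gene_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    mult <- rep(1, n)
    if (samples$group[j] == "WT_hyper") {
      mult[truth$class == "induced"] <- cfg$rna_fold
      mult[truth$class == "repressed"] <- 1 / cfg$rna_fold
    } else if (samples$group[j] == "NCOR1dID_hypo") {
      mult[truth$is_ncor_dependent] <- cfg$ncor_derepression_fold
    }
    counts[, j] <- stats::rnbinom(n, mu = mu0 * mult * samples$lib_factor[j],
                                  size = 1 / cfg$dispersion)
  }
  list(genes = genes, truth = truth, counts = counts, samples = samples)
}

#' Generate the full truth-labelled synthetic dataset
#'
#' Runs four independently seeded layers (placement, ChIP counts, Hi-C,
#' RNA) and returns every input the downstream pipeline consumes together
#' with the planted truth. Deterministic: the same config yields identical
#' output.
#'
#' @param config A [sim_config()].
#' @return Object of class `t3_sim`: a list with elements `config`,
#'   `regions` (`GRanges` with `region_id`), `chip_counts` (list of
#'   region x sample matrices per target), `chip_samples` (sample sheet),
#'   `peaks` (list of `GRanges`: TR, HDAC3, DHS), `hic` (`hic_matrix`),
#'   `tads` (`GRanges`), `genes`, `rna_counts`, `rna_samples`, and `truth`
#'   (list: `regions`, `genes`, `loops`).
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 1, n_regions = 50,
#'                                    n_genes = 40, chrom_len = 4e6,
#'                                    hic_max_dist = 5e5))
#' table(sim$truth$regions$class)
#' @export
simulate_dataset <- function(config) {
  cfg <- config
  if (!inherits(cfg, "sim_config")) stop("config must be a sim_config")

  set.seed(cfg$seed + 1L)            # placement layer
  tads <- place_tads(cfg)
  units <- build_units(cfg)
  region_df <- place_units(cfg, units, tads)
  peaks <- plant_peaks(cfg, region_df)

  regions <- GenomicRanges::GRanges(
    region_df$chrom,
    IRanges::IRanges(region_df$start + 1, region_df$end),
    seqlengths = sim_seqlengths(cfg))
  names(regions) <- region_df$region_id
  regions$region_id <- region_df$region_id

  loops <- region_df[!is.na(region_df$loop_id) &
                     region_df$loop_role == "indirect",
                     c("loop_id", "chrom", "region_id")]
  anchors <- region_df[!is.na(region_df$loop_id) &
                       region_df$loop_role == "anchor", ]
  loops$region_a <- anchors$region_id[match(loops$loop_id, anchors$loop_id)]
  names(loops)[names(loops) == "region_id"] <- "region_b"
  mid <- function(id) {
    i <- match(id, region_df$region_id)
    floor((region_df$start[i] + region_df$end[i]) / 2)
  }
  loops$mid_a <- mid(loops$region_a)
  loops$mid_b <- mid(loops$region_b)
  rownames(loops) <- NULL

  set.seed(cfg$seed + 2L)            # ChIP count layer
  chip <- simulate_chip_counts(cfg, region_df)

  set.seed(cfg$seed + 3L)            # Hi-C layer
  hic <- generate_hic(cfg, region_df, loops)

  set.seed(cfg$seed + 4L)            # RNA layer
  rna <- simulate_genes(cfg, region_df)

  structure(list(
    config = cfg,
    regions = regions,
    chip_counts = chip$counts,
    chip_samples = chip$sample_sheet,
    peaks = peaks,
    hic = hic,
    tads = tads,
    genes = rna$genes,
    rna_counts = rna$counts,
    rna_samples = rna$samples,
    truth = list(
      regions = region_df[, c("region_id", "chrom", "start", "end", "class",
                              "se_cluster", "loop_id", "loop_role")],
      genes = rna$truth,
      loops = loops[, c("loop_id", "chrom", "region_a", "region_b",
                        "mid_a", "mid_b")])
  ), class = "t3_sim")
}

#' @export
print.t3_sim <- function(x, ...) {
  cat("t3_sim synthetic dataset (seed", x$config$seed, ")\n")
  cat(" ", length(x$regions), "regions on", x$config$n_chrom, "chromosomes;",
      nrow(x$genes), "genes\n")
  cat("  planted classes:",
      paste(names(table(x$truth$regions$class)),
            table(x$truth$regions$class), collapse = ", "), "\n")
  invisible(x)
}

#' Score label recovery against planted truth
#'
#' @param predicted Named character vector: unit id -> predicted class
#'   label. Labels must come from the truth's class universe plus `"none"`
#'   and any `extra_labels`; anything else is an error.
#' @param truth Named character vector: unit id -> planted class.
#' @param extra_labels Additional admissible prediction labels (e.g.
#'   `"mid"` for the middle HDAC3 tertile, which has no planted analogue).
#' @return List with `per_class` data.frame (class, tp, fp, fn, precision,
#'   recall; precision is `NaN`-flagged when nothing was predicted for a
#'   class) and `macro` (mean precision/recall over classes with defined
#'   values).
#' @export
evaluate_recovery <- function(predicted, truth, extra_labels = character(0)) {
  if (is.null(names(predicted)) || is.null(names(truth)))
    stop("predicted and truth must be named by unit id")
  common <- intersect(names(predicted), names(truth))
  if (length(common) == 0) stop("label universes do not overlap")
  allowed <- c(union(unique(truth), "none"), extra_labels)
  bad <- setdiff(unique(predicted), allowed)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  p <- predicted[common]; t <- truth[common]
  classes <- sort(unique(t))
  per <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(p == cl & t == cl)
    fp <- sum(p == cl & t != cl)
    fn <- sum(p != cl & t == cl)
    data.frame(class = cl, tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp == 0) NaN else tp / (tp + fp),
               recall = if (tp + fn == 0) NaN else tp / (tp + fn),
               stringsAsFactors = FALSE)
  }))
  macro <- c(precision = mean(per$precision, na.rm = TRUE),
             recall = mean(per$recall, na.rm = TRUE))
  list(per_class = per, macro = macro)
}
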