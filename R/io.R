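#' Write genomic intervals to BED
#'
#' @param gr `GRanges`; names become the BED name field. An optional
#'   `score` column is written, otherwise 0.
#' @param path Output file.
#' @export
write_bed <- function(gr, path) {
  out <- gr
  if (is.null(out$score)) out$score <- 0
  if (is.null(names(out))) names(out) <- as.character(seq_along(out))
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Read a BED file as GRanges
#' @param path BED file.
#' @return `GRanges` named by the BED name field when present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(gr$name)) names(gr) <- gr$name
  gr
}

#' Write a count table as TSV (first column `unit_id`)
#' @param counts Matrix with row and column names.
#' @param path Output file.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(unit_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table written by [write_counts_tsv()]
#' @param path TSV file.
#' @return Integer matrix with `unit_id` rownames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a differential result table as TSV
#'
#' Columns `unit_id`, `baseMean`, `log2FC`, `pvalue`, `qvalue`.
#' @param result Table from [nb_differential_test()].
#' @param path Output file.
#' @export
write_diff_tsv <- function(result, path) {
  df <- data.frame(unit_id = result$unit_id, baseMean = result$base_mean,
                   log2FC = result$log2fc, pvalue = result$p_value,
                   qvalue = result$q_value, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a Hi-C matrix as triplet TSV plus chromosome sizes
#' @param hic A [hic_matrix()].
#' @param path Triplet TSV (`chrom`, `bin1`, `bin2`, `count`).
#' @param sizes_path Chromosome sizes TSV (`chrom`, `length`).
#' @export
write_hic_tsv <- function(hic, path, sizes_path) {
  utils::write.table(hic$contacts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(chrom = names(hic$chrom_sizes),
                                length = unname(hic$chrom_sizes)),
                     sizes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a Hi-C matrix from triplet TSV plus chromosome sizes
#' @param path,sizes_path Files written by [write_hic_tsv()].
#' @param resolution Bin size in bp.
#' @return A [hic_matrix()].
#' @export
read_hic_tsv <- function(path, sizes_path, resolution) {
  trip <- utils::read.delim(path, stringsAsFactors = FALSE)
  sizes <- utils::read.delim(sizes_path, stringsAsFactors = FALSE)
  hic_matrix(trip, resolution = resolution,
             chrom_sizes = stats::setNames(sizes$length, sizes$chrom))
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Regions/peaks/TADs as BED, counts and sample sheets as TSV, Hi-C as
#' triplet TSV, genes and truth as TSV, config as YAML.
#'
#' @param sim A `t3_sim` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_bed(sim$regions, p("regions.bed"))
  for (nm in names(sim$peaks))
    if (length(sim$peaks[[nm]]))
      write_bed(sim$peaks[[nm]], p(paste0("peaks_", nm, ".bed")))
  write_bed(sim$tads, p("tads.bed"))
  for (tg in names(sim$chip_counts))
    write_counts_tsv(sim$chip_counts[[tg]], p(paste0("counts_", tg, ".tsv")))
  utils::write.table(sim$chip_samples, p("chip_samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_hic_tsv(sim$hic, p("hic_contacts.tsv"), p("chrom_sizes.tsv"))
  utils::write.table(sim$genes, p("genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_counts_tsv(sim$rna_counts, p("rna_counts.tsv"))
  utils::write.table(sim$rna_samples, p("rna_samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$regions, p("truth_regions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$genes, p("truth_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$loops, p("truth_loops.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, p("config.yaml"))
  invisible(dir)
}
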