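# Shared fixtures, built once per session and memoized.

.fixtures <- new.env(parent = emptyenv())

# Reduced-scale synthetic dataset for module-level tests.
small_sim <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- simulate_dataset(sim_config(
      seed = 42, n_regions = 600, n_genes = 300, n_chrom = 2,
      chrom_len = 1.2e7, hic_max_dist = 6e5,
      loop_dist_range = c(8e4, 2e5)))
  }
  .fixtures$small
}

# Default-scale dataset (the study conditions) for acceptance checks.
default_sim <- function() {
  if (is.null(.fixtures$default)) {
    .fixtures$default <- simulate_dataset(sim_config(seed = 42))
  }
  .fixtures$default
}

# Two identical default-scale pipeline runs (determinism + recovery).
acceptance_reports <- function() {
  if (is.null(.fixtures$reports)) {
    .fixtures$reports <- list(run_all(run_config(seed = 7)),
                              run_all(run_config(seed = 7)))
  }
  .fixtures$reports
}

# Random non-overlap-free interval set on a toy genome.
random_gr <- function(n, chroms = c("cA", "cB"), max_pos = 1e6,
                     width_range = c(200, 2000)) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(max_pos, n, replace = TRUE)
  width <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, width = width))
  names(gr) <- paste0("iv", seq_len(n))
  GenomicRanges::sort(gr)
}

# Truth lookup helpers.
truth_classes <- function(sim) {
  stats::setNames(sim$truth$regions$class, sim$truth$regions$region_id)
}

hyperac_classes <- c("type1A", "type1B", "indirect_SE", "indirect_loop")
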