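# Shared builders for small in-code fixtures.

# Segregation table from a logical matrix, one chromosome by default.
make_seg <- function(mat, chrom = rep("chr1", nrow(mat)),
                     phase = "unphased", window_size = 50e3) {
  mode(mat) <- "logical"
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("S%03d", seq_len(ncol(mat)))
  offsets <- stats::ave(seq_along(chrom), chrom, FUN = seq_along) - 1
  windows <- data.table::data.table(
    chrom = chrom, start = offsets * window_size,
    stop = (offsets + 1) * window_size)
  gamhap:::new_segregation(windows, mat, phase)
}

# gam_matrix wrapper around a plain numeric matrix.
make_matrix <- function(mat, kind = "npmi", phase = "unphased",
                        resolution = 50e3, n_samples = 10L,
                        marginals = NULL) {
  n <- nrow(mat)
  windows <- data.table::data.table(
    chrom = "chr1", start = (seq_len(n) - 1) * resolution,
    stop = seq_len(n) * resolution)
  gamhap:::new_gam_matrix(mat, windows, kind, phase, resolution, n_samples,
                          marginals)
}

# Random boolean segregation matrix under a fixed seed.
random_seg_mat <- function(n_windows, n_samples, p = 0.3, seed = 1) {
  gamhap:::with_seed(seed,
    matrix(stats::runif(n_windows * n_samples) < p, n_windows, n_samples))
}

# Shared mid-size simulated dataset for downstream module tests (built once
# per test run; ~200 samples keeps it fast).
sim_cache <- new.env(parent = emptyenv())
shared_sim <- function() {
  if (is.null(sim_cache$sim)) {
    model <- gam_genome_model(c(chr1 = 10e6), seed = 101)
    sim_cache$model <- model
    sim_cache$sim <- gam_simulate(model, n_samples = 200, n_slices = 3,
                                  seed = 102)
    sim_cache$phased <- suppressWarnings(
      build_segregation_tables(sim_cache$sim$coverage))
  }
  list(model = sim_cache$model, sim = sim_cache$sim,
       phased = sim_cache$phased)
}
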