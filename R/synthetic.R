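# ---------------------------------------------------------------------------
# Diploid nuclear-slicing simulator.
#
# Each simulated cell carries two haplotype copies ("cast", "s129") of every
# chromosome. A genomic window is represented by one locus sphere per
# haplotype: a centre coordinate along the slicing axis (only the coordinate
# perpendicular to the cryosection matters for capture) and a radius that
# acts as a compaction proxy. Centres are block-correlated Gaussians:
#   z = g[compartment] + t[TAD] + jitter
# so windows of the same TAD co-locate within a cell, and same-compartment
# blocks share a long-range component. A nuclear profile captures a window
# when its locus sphere intersects a slab of thickness h placed uniformly
# across the nucleus diameter; for a locus of radius r inside a nucleus of
# radius R the capture probability is (2r + h) / (2R + h).
# ---------------------------------------------------------------------------

#' Build a diploid genome model for the nuclear-slicing simulator
#'
#' Defines the window grid, planted TAD boundaries, compartment labels,
#' per-window locus radii (compaction proxy) and SNP counts for the two
#' haplotypes. By default the two haplotypes are identical; differences are
#' planted explicitly via `extra_boundaries`, `flip_blocks`,
#' `radius_multiplier` or `contact_plan`.
#'
#' Geometry defaults mimic a ~10 um mESC nucleus sliced at ~230 nm: with
#' `nucleus_radius = 5000` nm and `locus_radius = 300` nm a single slice
#' captures (2*300 + 230)/(2*5000 + 230) = 8.1% of windows, inside the
#' 5-15% per-profile range typical of GAM data.
#'
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param window_size window size in bp.
#' @param nucleus_radius,slab_thickness,locus_radius geometry in nm.
#' @param tad_size,compartment_size mean planted TAD / compartment run
#'   lengths in bp; compartment labels are assigned per `compartment_block`
#'   bp block (default 100 kb).
#' @param compartment_block compartment label block size in bp (must be a
#'   multiple of `window_size`).
#' @param sigma_comp,sigma_tad,sigma_jitter standard deviations (nm) of the
#'   compartment, TAD and per-window components of locus centres.
#' @param extra_boundaries optional `list(cast = , s129 = )` of per-chromosome
#'   integer vectors: additional TAD start indices (1-based window index
#'   within the chromosome) planted on one haplotype only.
#' @param flip_tads optional `list(cast = , s129 = )` of per-chromosome
#'   integer vectors of TAD indices whose A/B compartment label is flipped
#'   on that haplotype (compartment runs are composed of whole TADs, as in
#'   real genomes; per-100-kb-block labels are derived truth).
#' @param radius_multiplier optional `list(cast = , s129 = )`: scalar or
#'   per-window multiplier of `locus_radius` (compaction plan; a larger
#'   radius means a more decondensed locus).
#' @param contact_plan optional `data.frame(chrom, tad_a, tad_b, hap)`: on
#'   haplotype `hap` the 3D centre of TAD `tad_b` is tied to TAD `tad_a`
#'   (indices within the chromosome), planting a long-range contact.
#' @param snp_density mean SNPs per bp (default 1/124, the F123 genome
#'   density).
#' @param seed integer seed for the planted layout.
#' @return an object of class `gam_genome_model`.
#' @export
gam_genome_model <- function(chrom_sizes,
                             window_size = 50000,
                             nucleus_radius = 5000,
                             slab_thickness = 230,
                             locus_radius = 300,
                             tad_size = 8e5,
                             compartment_block = 1e5,
                             compartment_size = 2e6,
                             sigma_comp = 2200,
                             sigma_tad = 1000,
                             sigma_jitter = 330,
                             extra_boundaries = NULL,
                             flip_tads = NULL,
                             radius_multiplier = NULL,
                             contact_plan = NULL,
                             snp_density = 1 / 124,
                             seed = 1L) {
  if (any(chrom_sizes <= 0) || window_size <= 0)
    stop_config("chromosome lengths and window size must be positive")
  if (slab_thickness <= 0 || slab_thickness >= 2 * nucleus_radius)
    stop_config("slab thickness must satisfy 0 < h < 2R")
  if (compartment_block %% window_size != 0)
    stop_config("compartment_block must be a multiple of window_size")
  windows <- gam_windows(chrom_sizes, window_size)
  n <- nrow(windows)
  wpb <- compartment_block / window_size

  model <- with_seed(seed, {
    snps <- rpois(n, (windows$stop - windows$start) * snp_density)
    haps <- list()
    # common layout drawn once, then per-haplotype modifications applied
    common <- lapply(names(chrom_sizes), function(ch) {
      nw <- sum(windows$chrom == ch)
      # TAD start indices: gaps uniform in [0.6, 1.4] * tad_size
      gaps <- pmax(2L, round(runif(ceiling(nw * window_size / tad_size * 2),
                                   0.6, 1.4) * tad_size / window_size))
      starts <- cumsum(c(1L, gaps))
      starts <- starts[starts <= nw]
      # compartment runs made of whole TADs (compartment boundaries
      # coincide with a subset of TAD boundaries, as in real genomes)
      nt <- length(starts)
      mean_run <- max(1, round(compartment_size / tad_size))
      tad_lab <- character(0)
      cur <- sample(c("A", "B"), 1L)
      while (length(tad_lab) < nt) {
        run <- max(1L, round(runif(1, 0.5, 1.5) * mean_run))
        tad_lab <- c(tad_lab, rep(cur, run))
        cur <- if (cur == "A") "B" else "A"
      }
      list(tad_starts = starts, tad_labels = tad_lab[seq_len(nt)], nw = nw)
    })
    names(common) <- names(chrom_sizes)
    for (hap in c("cast", "s129")) {
      hp <- list()
      for (ch in names(chrom_sizes)) {
        cc <- common[[ch]]
        tad_lab <- cc$tad_labels
        fl <- flip_tads[[hap]][[ch]] %||% integer(0)
        tad_lab[fl] <- ifelse(tad_lab[fl] == "A", "B", "A")
        extra <- extra_boundaries[[hap]][[ch]] %||% integer(0)
        if (any(extra < 1 | extra > cc$nw))
          stop_config("extra boundary outside chromosome %s", ch)
        starts <- sort(unique(c(cc$tad_starts, extra)))
        # labels follow the common TADs; extra boundaries split a TAD
        # without changing its compartment
        parent <- findInterval(starts, cc$tad_starts)
        lab_per_tad <- tad_lab[parent]
        tad_id <- findInterval(seq_len(cc$nw), starts)
        comp <- lab_per_tad[tad_id]
        # derived 100-kb block labels (first window of each block)
        nb <- ceiling(cc$nw / wpb)
        block_labels <- comp[(seq_len(nb) - 1L) * wpb + 1L]
        hp[[ch]] <- list(tad_starts = starts, tad_id = tad_id,
                         comp = comp, tad_comp = lab_per_tad,
                         block_labels = block_labels)
      }
      mult <- radius_multiplier[[hap]] %||% 1
      if (length(mult) != 1L && length(mult) != n)
        stop_config("radius_multiplier must be scalar or one value per window")
      radius <- rep_len(locus_radius * mult, n)
      if (any(radius <= 0)) stop_config("locus radii must be positive")
      haps[[hap]] <- list(per_chrom = hp, radius = radius)
    }
    list(snps = snps, haps = haps)
  })

  if (!is.null(contact_plan)) {
    contact_plan <- as.data.table(contact_plan)
    need <- c("chrom", "tad_a", "tad_b", "hap")
    if (!all(need %in% names(contact_plan)))
      stop_config("contact_plan needs columns %s", paste(need, collapse = ", "))
  }

  structure(list(
    windows = windows, chrom_sizes = chrom_sizes, window_size = window_size,
    nucleus_radius = nucleus_radius, slab_thickness = slab_thickness,
    locus_radius = locus_radius,
    sigma = c(comp = sigma_comp, tad = sigma_tad, jitter = sigma_jitter),
    snps = model$snps, haps = model$haps, contact_plan = contact_plan,
    seed = seed
  ), class = "gam_genome_model")
}

#' @export
print.gam_genome_model <- function(x, ...) {
  cat(sprintf(
    "gam_genome_model: %d windows (%g kb) on %d chromosome(s)\n",
    nrow(x$windows), x$window_size / 1e3, length(x$chrom_sizes)))
  for (hap in c("cast", "s129")) {
    nt <- sum(vapply(x$haps[[hap]]$per_chrom,
                     function(p) length(p$tad_starts), 1L))
    cat(sprintf("  %s: %d planted TADs\n", hap, nt))
  }
  invisible(x)
}

# Per-nucleus locus centres for one haplotype; uses the current RNG stream.
draw_positions <- function(model, hap) {
  R <- model$nucleus_radius
  z <- numeric(nrow(model$windows))
  radius <- model$haps[[hap]]$radius
  offset <- 0L
  for (ch in names(model$chrom_sizes)) {
    hp <- model$haps[[hap]]$per_chrom[[ch]]
    nw <- length(hp$tad_id)
    g <- rnorm(2, sd = model$sigma[["comp"]])
    names(g) <- c("A", "B")
    tc <- rnorm(length(hp$tad_starts), sd = model$sigma[["tad"]])
    ctr <- g[hp$tad_comp] + tc # one 3D centre per TAD
    if (!is.null(model$contact_plan)) {
      cp <- as.data.frame(model$contact_plan)
      cp <- cp[cp$chrom == ch & cp$hap == hap, , drop = FALSE]
      # a planted contact co-locates the two TADs entirely
      if (nrow(cp)) ctr[cp$tad_b] <- ctr[cp$tad_a]
    }
    eps <- rnorm(nw, sd = model$sigma[["jitter"]])
    zc <- ctr[hp$tad_id] + eps
    idx <- offset + seq_len(nw)
    lim <- pmax(0, R - radius[idx])
    z[idx] <- pmin(pmax(zc, -lim), lim)
    offset <- offset + nw
  }
  z
}

#' Simulate the nuclear slicing of one cell
#'
#' Draws fresh locus positions for both haplotypes (each simulated sample is
#' a different cell), places `n_slices` slabs uniformly across the nucleus
#' diameter, and records which windows are captured on each haplotype. The
#' captured fraction (slab overlap relative to the slab/locus extent) is
#' retained as a sequencing-depth multiplier.
#'
#' @param model a [gam_genome_model()].
#' @param n_slices nuclear profiles multiplexed into the sample (1-3).
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return list with logical capture flags and capture fractions per
#'   haplotype, slab positions, and the drawn locus coordinates.
#' @export
slice_nucleus <- function(model, n_slices = 1L, seed = NULL) {
  stopifnot(inherits(model, "gam_genome_model"))
  if (!n_slices %in% 1:3)
    stop_config("slices per sample must be 1, 2 or 3")
  run <- function() {
    R <- model$nucleus_radius
    h <- model$slab_thickness
    slabs <- runif(n_slices, -R - h / 2, R + h / 2)
    out <- list(slabs = slabs)
    for (hap in c("cast", "s129")) {
      z <- draw_positions(model, hap)
      r <- model$haps[[hap]]$radius
      frac <- rep(0, length(z))
      for (u in slabs) {
        ov <- pmax(0, pmin(z + r, u + h / 2) - pmax(z - r, u - h / 2))
        frac <- frac + ov / pmin(2 * r, h)
      }
      frac <- pmin(1, frac)
      out[[paste0("cap_", hap)]] <- frac > 0
      out[[paste0("frac_", hap)]] <- frac
      out[[paste0("z_", hap)]] <- z
    }
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Coverage for one sample given capture fractions; current RNG stream.
sample_coverage_row <- function(model, sl, depth, read_length, background,
                                error_rate) {
  n <- nrow(model$windows)
  wlen <- model$windows$stop - model$windows$start
  p_snp <- 1 - exp(-model$snps * read_length / wlen)
  cov_c <- rpois(n, depth * sl$frac_cast)
  cov_s <- rpois(n, depth * sl$frac_s129)
  phased_c <- rbinom(n, cov_c, p_snp)
  phased_s <- rbinom(n, cov_s, p_snp)
  miss_c <- rbinom(n, phased_c, error_rate) # cast-origin assigned to s129
  miss_s <- rbinom(n, phased_s, error_rate)
  bg <- if (background > 0) rpois(n, background) else integer(n)
  list(total = cov_c + cov_s + bg,
       cast = phased_c - miss_c + miss_s,
       s129 = phased_s - miss_s + miss_c)
}

#' Simulate a GAM dataset with ground truth
#'
#' Runs [slice_nucleus()] for `n_samples` cells and converts captures into a
#' per-sample per-window coverage table. Captured windows receive Poisson
#' nucleotide coverage proportional to `depth` times the captured fraction
#' of the locus; reads overlapping a SNP (probability
#' `1 - exp(-snps * read_length / window_size)`) are phased to the captured
#' haplotype, with `error_rate` of phased reads assigned to the wrong
#' haplotype. Uncaptured windows receive Poisson(`background`) noise.
#'
#' @inheritParams slice_nucleus
#' @param n_samples number of GAM samples (>= 1).
#' @param depth expected nucleotide coverage of a fully captured window.
#' @param read_length read length in bp for the SNP-overlap model.
#' @param background expected noise coverage of uncaptured windows.
#' @param error_rate fraction of phased reads assigned to the wrong
#'   haplotype.
#' @param seed integer seed; the whole dataset is deterministic given the
#'   seed.
#' @return object of class `gam_sim`: `coverage` (long `data.table` with
#'   columns chrom, start, stop, sample, total_cov, cast_cov, s129_cov),
#'   `truth` (capture flags per haplotype, windows x samples), and the
#'   `model`.
#' @export
gam_simulate <- function(model, n_samples, n_slices = 3L, depth = 4e4,
                         read_length = 75, background = 0, error_rate = 0,
                         seed = 1L) {
  stopifnot(inherits(model, "gam_genome_model"))
  if (!is_count(n_samples) || n_samples < 1)
    stop_config("n_samples must be a positive integer")
  if (depth <= 0) stop_config("depth must be positive")
  n <- nrow(model$windows)
  cap_cast <- matrix(FALSE, n, n_samples)
  cap_s129 <- matrix(FALSE, n, n_samples)
  tot <- matrix(0L, n, n_samples)
  cas <- matrix(0L, n, n_samples)
  s12 <- matrix(0L, n, n_samples)
  with_seed(seed, {
    for (k in seq_len(n_samples)) {
      sl <- slice_nucleus(model, n_slices)
      cap_cast[, k] <- sl$cap_cast
      cap_s129[, k] <- sl$cap_s129
      cv <- sample_coverage_row(model, sl, depth, read_length, background,
                                error_rate)
      tot[, k] <- cv$total
      cas[, k] <- cv$cast
      s12[, k] <- cv$s129
    }
  })
  samples <- sprintf("S%04d", seq_len(n_samples))
  coverage <- data.table(
    chrom = rep(model$windows$chrom, n_samples),
    start = rep(model$windows$start, n_samples),
    stop = rep(model$windows$stop, n_samples),
    sample = rep(samples, each = n),
    total_cov = as.vector(tot),
    cast_cov = as.vector(cas),
    s129_cov = as.vector(s12))
  colnames(cap_cast) <- colnames(cap_s129) <- samples
  structure(list(
    coverage = coverage,
    truth = list(cap_cast = cap_cast, cap_s129 = cap_s129),
    model = model,
    params = list(n_samples = n_samples, n_slices = n_slices, depth = depth,
                  read_length = read_length, background = background,
                  error_rate = error_rate, seed = seed)
  ), class = "gam_sim")
}

#' Write a simulated dataset to disk
#'
#' Emits `coverage.tsv` (coverage table), `truth_cast.tsv` /
#' `truth_s129.tsv` (0/1 capture flags, windows x samples), `windows.bed`
#' (BED3 grid) and `metadata.txt` (flat key = value, including the seed).
#'
#' @param sim a `gam_sim` object.
#' @param dir output directory (created if missing).
#' @export
write_gam_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "gam_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_coverage_table(sim$coverage, file.path(dir, "coverage.tsv"))
  for (hap in c("cast", "s129")) {
    out <- cbind(as.data.table(sim$model$windows),
                 as.data.table(sim$truth[[paste0("cap_", hap)]] * 1L))
    fwrite(out, file.path(dir, sprintf("truth_%s.tsv", hap)), sep = "\t")
  }
  fwrite(as.data.table(sim$model$windows), file.path(dir, "windows.bed"),
         sep = "\t", col.names = FALSE)
  meta <- c(sprintf("seed = %d", sim$params$seed),
            sprintf("n_samples = %d", sim$params$n_samples),
            sprintf("n_slices = %d", sim$params$n_slices),
            sprintf("depth = %g", sim$params$depth),
            sprintf("background = %g", sim$params$background),
            sprintf("error_rate = %g", sim$params$error_rate),
            sprintf("window_size = %g", sim$model$window_size))
  writeLines(meta, file.path(dir, "metadata.txt"))
  invisible(dir)
}
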