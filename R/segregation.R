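# ---------------------------------------------------------------------------
# Window calling and haplotype phasing.
#
# Positive windows per GAM sample are defined by a sample-specific nucleotide
# coverage threshold: the lowest coverage that maximizes the fraction of
# positive windows with at least one adjacent positive window on the same
# chromosome (true positives cluster; sequencing noise is scattered). The
# same threshold is then applied to the CAST- and S129-SNP read coverage to
# phase windows to haplotypes.
# ---------------------------------------------------------------------------

new_segregation <- function(windows, mat, phase,
                            thresholds = NULL, samples = colnames(mat)) {
  structure(list(windows = as.data.table(windows), mat = mat, phase = phase,
                 thresholds = thresholds, samples = samples),
            class = "gam_segregation")
}

#' @export
print.gam_segregation <- function(x, ...) {
  cat(sprintf("gam_segregation [%s]: %d windows x %d samples, %.1f%% positive\n",
              x$phase, nrow(x$mat), ncol(x$mat), 100 * mean(x$mat)))
  invisible(x)
}

neighbor_fraction <- function(positive, chrom) {
  np <- sum(positive)
  if (np == 0L) return(0)
  sum(positive & has_positive_neighbor(positive, chrom)) / np
}

#' Optimal coverage threshold for one GAM sample
#'
#' For each candidate threshold `t`, windows with coverage `>= t` are called
#' positive and the neighbour fraction (positive windows with at least one
#' adjacent positive window on the same chromosome, over all positive
#' windows) is computed. The returned threshold is the lowest candidate
#' achieving the maximal neighbour fraction.
#'
#' @param coverage per-window total nucleotide coverage, ordered along the
#'   window grid.
#' @param chrom chromosome of each window (same order).
#' @param candidates candidate thresholds; defaults to the distinct nonzero
#'   coverage values, subsampled to at most `max_candidates` quantile-spaced
#'   values.
#' @param max_candidates cap on the default candidate set size.
#' @return list with `threshold`, `neighbor_fraction` and the evaluated
#'   `candidates`.
#' @export
optimal_threshold <- function(coverage, chrom, candidates = NULL,
                              max_candidates = 256L) {
  if (length(coverage) != length(chrom))
    stop_config("coverage and chrom must have equal length")
  if (all(coverage <= 0))
    stop_config("unsuitable sample: no window with positive coverage")
  if (is.null(candidates)) {
    vals <- sort(unique(coverage[coverage > 0]))
    candidates <- if (length(vals) > max_candidates) {
      sort(unique(quantile(vals, probs = seq(0, 1, length.out = max_candidates),
                           type = 1, names = FALSE)))
    } else vals
  }
  candidates <- sort(unique(candidates))
  if (!length(candidates)) stop_config("empty candidate threshold set")
  fr <- vapply(candidates,
               function(t) neighbor_fraction(coverage >= t, chrom), 0)
  best <- which(fr == max(fr))[1L] # lowest t among the maximizers
  list(threshold = candidates[best], neighbor_fraction = fr[best],
       candidates = candidates, fractions = fr)
}

#' Call positive windows at a given threshold
#'
#' @inheritParams optimal_threshold
#' @param threshold coverage threshold (>= 1); windows with coverage greater
#'   than or equal to the threshold are positive.
#' @return logical vector.
#' @export
call_positive_windows <- function(coverage, threshold) {
  if (threshold < 1) stop_config("threshold must be >= 1")
  coverage >= threshold
}

#' Phase the positive windows of one sample
#'
#' A positive window is phased to CAST when its CAST-SNP read coverage is
#' greater than or equal to the sample threshold, to S129 when the S129-SNP
#' coverage passes the same threshold, to `"both"` (dual phasing) when both
#' do, and left `"unassigned"` otherwise. Non-positive windows are
#' `"negative"`.
#'
#' @param total_cov,cast_cov,s129_cov per-window coverages for the sample.
#' @param threshold the sample's optimal threshold.
#' @param positive logical vector of positive windows (computed with the
#'   same threshold); defaults to `total_cov >= threshold`.
#' @return character vector in
#'   `{"CAST", "S129", "both", "unassigned", "negative"}`.
#' @export
phase_sample_windows <- function(total_cov, cast_cov, s129_cov, threshold,
                                 positive = NULL) {
  if (any(cast_cov + s129_cov > total_cov))
    stop_config("phased coverage exceeds total coverage (data integrity)")
  if (is.null(positive)) positive <- call_positive_windows(total_cov, threshold)
  is_c <- cast_cov >= threshold
  is_s <- s129_cov >= threshold
  out <- rep("negative", length(total_cov))
  out[positive] <- "unassigned"
  out[positive & is_c & !is_s] <- "CAST"
  out[positive & !is_c & is_s] <- "S129"
  out[positive & is_c & is_s] <- "both"
  out
}

#' Build unphased, CAST and S129 segregation tables from a coverage table
#'
#' Computes the optimal threshold for every sample, calls positive windows,
#' phases them, and assembles one boolean windows x samples table per phase.
#' Samples whose threshold cannot be computed (all-zero coverage) are
#' dropped with a warning.
#'
#' @param ct coverage table (see [read_coverage_table()]).
#' @param dual how to treat dual-phased windows: `"both"` (default; the
#'   window enters both haplotype tables) or `"exclude"` (neither).
#' @param candidates,max_candidates passed to [optimal_threshold()].
#' @return object of class `gam_phased`: `unphased`, `cast`, `s129`
#'   segregation tables, per-sample `thresholds`, and a `summary` with the
#'   phasing efficiency (fraction of positive windows phased, incl. dual)
#'   and the dual-phasing rate.
#' @export
build_segregation_tables <- function(ct, dual = c("both", "exclude"),
                                     candidates = NULL,
                                     max_candidates = 256L) {
  dual <- match.arg(dual)
  ct <- validate_coverage_table(ct)
  samples <- unique(ct$sample)
  if (length(samples) < 2L)
    stop_config("at least 2 samples are required")
  windows <- unique(ct[, .(chrom, start, stop)])
  setkey(ct, sample)
  n <- nrow(windows)
  mats <- list(unphased = NULL, cast = NULL, s129 = NULL)
  for (p in names(mats)) mats[[p]] <- matrix(FALSE, n, length(samples),
                                             dimnames = list(NULL, samples))
  th <- data.table(sample = samples, threshold = NA_real_,
                   neighbor_fraction = NA_real_)
  dropped <- character(0)
  n_pos <- n_phased <- n_dual <- 0
  for (k in seq_along(samples)) {
    sdt <- ct[.(samples[[k]])]
    if (nrow(sdt) != n || !same_grid(sdt[, .(chrom, start, stop)], windows))
      stop_config("sample %s is not on the shared window grid", samples[[k]])
    ot <- tryCatch(optimal_threshold(sdt$total_cov, sdt$chrom,
                                     candidates = candidates,
                                     max_candidates = max_candidates),
                   error = function(e) NULL)
    if (is.null(ot)) {
      dropped <- c(dropped, samples[[k]])
      next
    }
    th[k, `:=`(threshold = ot$threshold,
               neighbor_fraction = ot$neighbor_fraction)]
    phase <- phase_sample_windows(sdt$total_cov, sdt$cast_cov, sdt$s129_cov,
                                  ot$threshold)
    pos <- phase != "negative"
    mats$unphased[, k] <- pos
    mats$cast[, k] <- phase == "CAST" | (dual == "both" & phase == "both")
    mats$s129[, k] <- phase == "S129" | (dual == "both" & phase == "both")
    n_pos <- n_pos + sum(pos)
    n_phased <- n_phased + sum(phase %in% c("CAST", "S129", "both"))
    n_dual <- n_dual + sum(phase == "both")
  }
  if (length(dropped)) {
    warning(sprintf("dropped %d sample(s) with unsuitable coverage: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
    keep <- !samples %in% dropped
    for (p in names(mats)) mats[[p]] <- mats[[p]][, keep, drop = FALSE]
    th <- th[keep]
    samples <- samples[keep]
  }
  tables <- lapply(names(mats), function(p)
    new_segregation(windows, mats[[p]], p, thresholds = th))
  names(tables) <- names(mats)
  structure(list(
    unphased = tables$unphased, cast = tables$cast, s129 = tables$s129,
    thresholds = th,
    summary = list(
      n_samples = length(samples),
      positive_windows = n_pos,
      phasing_efficiency = if (n_pos > 0) n_phased / n_pos else NA_real_,
      dual_rate = if (n_pos > 0) n_dual / n_pos else NA_real_,
      dropped = dropped)
  ), class = "gam_phased")
}

#' @export
print.gam_phased <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "gam_phased: %d samples, %d positive window calls\n",
    "  phasing efficiency: %.1f%% (dual %.2f%%)\n"),
    s$n_samples, s$positive_windows, 100 * s$phasing_efficiency,
    100 * s$dual_rate))
  invisible(x)
}

#' Rebin a segregation table to a coarser resolution
#'
#' A coarse window is positive when any of its constituent fine windows is
#' positive (union rule), matching how GAM presence calls aggregate.
#'
#' @param seg a `gam_segregation` object.
#' @param factor integer number of fine windows per coarse window.
#' @return a `gam_segregation` object on the coarser grid.
#' @export
rebin_segregation <- function(seg, factor) {
  stopifnot(inherits(seg, "gam_segregation"), is_count(factor), factor >= 1)
  if (factor == 1L) return(seg)
  w <- seg$windows
  grp <- paste(w$chrom, (w$start %/% (factor * (w$stop[1] - w$start[1]))))
  grp <- factor(grp, levels = unique(grp))
  idx <- split(seq_len(nrow(w)), grp)
  windows <- rbindlist(lapply(idx, function(ii)
    data.table(chrom = w$chrom[ii[1]], start = min(w$start[ii]),
               stop = max(w$stop[ii]))))
  mat <- do.call(rbind, lapply(idx, function(ii)
    colSums(seg$mat[ii, , drop = FALSE]) > 0))
  rownames(mat) <- NULL
  new_segregation(windows, mat, seg$phase, thresholds = seg$thresholds)
}
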