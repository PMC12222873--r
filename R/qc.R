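# ---------------------------------------------------------------------------
# Sample- and window-level quality control.
# ---------------------------------------------------------------------------

#' Quality metrics for one GAM sample
#'
#' @param positive logical vector of positive windows along the grid.
#' @param chrom chromosome of each window.
#' @param reads number of uniquely mapped reads for the sample.
#' @param orphan_max,min_reads pass thresholds: a sample passes when its
#'   orphan percentage is `< orphan_max` and its read count is strictly
#'   `> min_reads` (and it is not flagged as cross-contaminated, which is
#'   assessed separately by [contamination_filter()]).
#' @return list with `orphan_pct` (percentage of positive windows with no
#'   adjacent positive window), `coverage_pct` (percent of windows positive),
#'   `reads`, `pass` and `fail_reason`.
#' @export
sample_metrics <- function(positive, chrom, reads,
                           orphan_max = 60, min_reads = 50000) {
  np <- sum(positive)
  if (np == 0L) {
    return(list(orphan_pct = NA_real_, coverage_pct = 0, reads = reads,
                pass = FALSE, fail_reason = "no positive windows"))
  }
  orphan <- positive & !has_positive_neighbor(positive, chrom)
  orphan_pct <- 100 * sum(orphan) / np
  coverage_pct <- 100 * np / length(positive)
  reasons <- character(0)
  if (orphan_pct >= orphan_max) reasons <- c(reasons, "orphan windows")
  if (reads <= min_reads) reasons <- c(reasons, "low read count")
  list(orphan_pct = orphan_pct, coverage_pct = coverage_pct, reads = reads,
       pass = length(reasons) == 0L,
       fail_reason = if (length(reasons)) paste(reasons, collapse = "; ")
       else NA_character_)
}

#' Cross-contamination screen via pairwise Jaccard similarity
#'
#' Computes the Jaccard index between the positive-window sets of every pair
#' of samples within each plate group; any sample participating in a pair
#' with J greater than `jaccard_max` is flagged as potentially
#' cross-contaminated.
#'
#' @param mat logical windows x samples matrix.
#' @param plate optional plate group per sample; default one group.
#' @param jaccard_max exclusion threshold (default 0.4).
#' @return list with `jaccard` (pair table), `max_jaccard` per sample and
#'   the logical `flagged` vector.
#' @export
contamination_filter <- function(mat, plate = NULL, jaccard_max = 0.4) {
  m <- ncol(mat)
  plate <- plate %||% rep("plate1", m)
  if (length(plate) != m) stop_config("plate must have one entry per sample")
  max_j <- rep(0, m)
  pairs <- list()
  for (g in unique(plate)) {
    idx <- which(plate == g)
    if (length(idx) < 2L) next
    x <- mat[, idx, drop = FALSE] * 1L
    inter <- crossprod(x)
    sizes <- colSums(x)
    uni <- outer(sizes, sizes, "+") - inter
    jac <- ifelse(uni > 0, inter / uni, 0)
    diag(jac) <- 0
    max_j[idx] <- pmax(max_j[idx], apply(jac, 1, max))
    ut <- which(upper.tri(jac), arr.ind = TRUE)
    pairs[[g]] <- data.table(sample_a = colnames(mat)[idx[ut[, 1]]],
                             sample_b = colnames(mat)[idx[ut[, 2]]],
                             plate = g, jaccard = jac[ut])
  }
  list(jaccard = if (length(pairs)) rbindlist(pairs) else
    data.table(sample_a = character(), sample_b = character(),
               plate = character(), jaccard = numeric()),
    max_jaccard = max_j, flagged = max_j > jaccard_max)
}

#' Full QC report for a segregation table
#'
#' @param seg unphased `gam_segregation` table.
#' @param reads named (or ordered) vector of uniquely mapped read counts.
#' @param plate optional plate group per sample.
#' @inheritParams sample_metrics
#' @inheritParams contamination_filter
#' @return `data.table` with one row per sample: reads, orphan percentage,
#'   genome coverage percentage, maximal within-plate Jaccard, pass flag and
#'   failure reason.
#' @export
qc_samples <- function(seg, reads, plate = NULL, orphan_max = 60,
                       min_reads = 50000, jaccard_max = 0.4) {
  stopifnot(inherits(seg, "gam_segregation"))
  m <- ncol(seg$mat)
  if (length(reads) != m) stop_config("reads must have one entry per sample")
  cont <- contamination_filter(seg$mat, plate, jaccard_max)
  rows <- lapply(seq_len(m), function(k)
    sample_metrics(seg$mat[, k], seg$windows$chrom, reads[[k]],
                   orphan_max, min_reads))
  reason <- vapply(rows, `[[`, "", "fail_reason")
  reason[cont$flagged] <- ifelse(
    is.na(reason[cont$flagged]), "cross-contamination",
    paste(reason[cont$flagged], "cross-contamination", sep = "; "))
  data.table(
    sample = colnames(seg$mat),
    reads = as.numeric(reads),
    orphan_pct = vapply(rows, `[[`, 0, "orphan_pct"),
    coverage_pct = vapply(rows, `[[`, 0, "coverage_pct"),
    max_jaccard = cont$max_jaccard,
    pass = vapply(rows, `[[`, TRUE, "pass") & !cont$flagged,
    fail_reason = reason)
}

# --- Yeo-Johnson power transform (counts are >= 0, so only the positive
# branch is exercised; the negative branch is kept for completeness) -------

yeo_johnson <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- x >= 0
  if (abs(lambda) > 1e-8) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else out[pos] <- log(x[pos] + 1)
  if (any(!pos)) {
    l2 <- 2 - lambda
    if (abs(l2) > 1e-8) {
      out[!pos] <- -((-x[!pos] + 1)^l2 - 1) / l2
    } else out[!pos] <- -log(-x[!pos] + 1)
  }
  out
}

# Gaussian-likelihood MLE of the Yeo-Johnson lambda.
yj_lambda_mle <- function(x, interval = c(-2, 3)) {
  ll <- function(lambda) {
    y <- yeo_johnson(x, lambda)
    v <- var(y)
    if (!is.finite(v) || v <= 0) return(-Inf)
    n <- length(x)
    -n / 2 * log(v) + (lambda - 1) * sum(sign(x) * log(abs(x) + 1))
  }
  optimize(ll, interval, maximum = TRUE)$maximum
}

# Kendall tau-b between two vectors that are both sorted ascending. With
# both vectors sorted no pair is discordant, so tau-b reduces to a function
# of the tie structure, computable in O(n) from run lengths. Used so the
# quantile-aligned comparison scales to large strata.
kendall_tau_sorted <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop_config("length mismatch")
  n0 <- n * (n - 1) / 2
  tx <- rle(x)$lengths
  ty <- rle(y)$lengths
  txy <- rle(paste(x, y))$lengths
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  nb <- sum(txy * (txy - 1) / 2)
  conc <- n0 - n1 - n2 + nb
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0) return(NA_real_)
  conc / den
}

#' Compare a co-segregation count distribution with a Poisson reference
#'
#' Core of [resolution_check()]: fits the Yeo-Johnson lambda to the counts
#' by maximum likelihood, draws a Poisson reference of matching mean and
#' size, applies the same transform to both, and computes Kendall's tau
#' between the quantile-aligned (sorted) vectors.
#'
#' @param counts raw co-segregation counts of the window pairs in one
#'   stratum.
#' @param seed seed for the Poisson reference draw.
#' @return list with `lambda`, `tau`, `detectability` (fraction of nonzero
#'   counts) and `reason` (`NA` unless degenerate).
#' @export
coseg_poisson_tau <- function(counts, seed = 1L) {
  det <- mean(counts >= 1)
  if (all(counts == counts[[1L]])) {
    return(list(lambda = NA_real_, tau = NA_real_, detectability = det,
                reason = "degenerate counts"))
  }
  lambda <- yj_lambda_mle(counts)
  emp <- sort(yeo_johnson(counts, lambda))
  ref <- with_seed(seed, rpois(length(counts), mean(counts)))
  ref <- sort(yeo_johnson(ref, lambda))
  list(lambda = lambda, tau = kendall_tau_sorted(emp, ref),
       detectability = det, reason = NA_character_)
}

#' Assess dataset resolution against a Poisson reference
#'
#' Collects the raw co-segregation counts of all intrachromosomal window
#' pairs in a genomic-distance stratum, applies a Yeo-Johnson power
#' transform (lambda fitted by maximum likelihood), and compares the
#' transformed distribution with a Poisson reference of matching mean (same
#' size, same transform) using Kendall's rank correlation between
#' quantile-aligned (sorted) vectors. A stratum passes when tau >= 0.95.
#' The fraction of pairs co-detected at least once is reported as
#' detectability.
#'
#' @param seg a `gam_segregation` table.
#' @param resolution window size in bp of the table's grid.
#' @param strata list of `c(min, max)` genomic distance ranges in bp.
#' @param tau_min pass threshold for Kendall's tau.
#' @param min_pairs minimum number of window pairs required per stratum.
#' @param seed seed for the Poisson reference draw.
#' @return `data.table` with one row per stratum: distance range, number of
#'   pairs, fitted lambda, tau, detectability and pass flag.
#' @export
resolution_check <- function(seg, resolution,
                             strata = list(c(0, 10e6)),
                             tau_min = 0.95, min_pairs = 100L, seed = 1L) {
  stopifnot(inherits(seg, "gam_segregation"))
  counts_by_stratum <- lapply(strata, function(s) {
    dmin <- max(1L, ceiling(s[[1]] / resolution))
    dmax <- floor(s[[2]] / resolution)
    unlist(lapply(split(seq_len(nrow(seg$mat)), seg$windows$chrom),
                  function(idx) {
      if (length(idx) < 2L) return(numeric(0))
      x <- seg$mat[idx, , drop = FALSE] * 1L
      co <- tcrossprod(x)
      d <- abs(row(co) - col(co))
      co[d >= dmin & d <= dmax & upper.tri(co)]
    }), use.names = FALSE)
  })
  out <- rbindlist(lapply(seq_along(strata), function(k) {
    cnt <- counts_by_stratum[[k]]
    base <- data.table(dist_min = strata[[k]][1], dist_max = strata[[k]][2],
                       n_pairs = length(cnt))
    if (length(cnt) < min_pairs) {
      warning(sprintf("stratum %d: only %d pairs, skipped", k, length(cnt)))
      return(cbind(base, data.table(lambda = NA_real_, tau = NA_real_,
                                    detectability = NA_real_, pass = FALSE,
                                    reason = "too few pairs")))
    }
    cmp <- coseg_poisson_tau(cnt, seed = seed)
    cbind(base, data.table(lambda = cmp$lambda, tau = cmp$tau,
                           detectability = cmp$detectability,
                           pass = !is.na(cmp$tau) && cmp$tau >= tau_min,
                           reason = cmp$reason))
  }))
  out[]
}

#' Mask undersampled and low-mappability windows
#'
#' Smooths the window detection frequency (WDF) track with a centred moving
#' mean over 11 windows per chromosome (edge-truncated), computes the
#' normalized delta ND = (raw - smoothed) / smoothed, and excludes windows
#' with ND greater than `nd_max` together with the two adjacent windows on
#' each side. Windows with mean mappability below `mappability_min` are
#' excluded irrespective of WDF.
#'
#' @param wdf numeric WDF per window along the grid.
#' @param chrom chromosome per window.
#' @param mappability optional mean mappability per window.
#' @param nd_max ND exclusion threshold (default 5).
#' @param mappability_min mappability exclusion threshold (default 0.2).
#' @param smooth_k moving-mean width in windows (default 11).
#' @param flank windows removed on each side of an ND-excluded window
#'   (default 2).
#' @return `data.table` with `usable` flag, `nd` value and primary exclusion
#'   `reason` in `{undersampled-ND, low-mappability, neighbor-of-ND}`.
#' @export
undersampling_mask <- function(wdf, chrom, mappability = NULL, nd_max = 5,
                               mappability_min = 0.2, smooth_k = 11L,
                               flank = 2L) {
  n <- length(wdf)
  if (!is.null(mappability) && length(mappability) != n)
    stop_config("mappability must match the window grid")
  smoothed <- unlist(lapply(split(seq_len(n), factor(chrom, unique(chrom))),
                            function(idx) {
    moving_mean(wdf[idx], smooth_k)
  }), use.names = FALSE)
  nd <- ifelse(smoothed > 0, (wdf - smoothed) / smoothed, NA_real_)
  nd_hit <- (is.na(nd) | nd > nd_max)
  reason <- rep(NA_character_, n)
  reason[nd_hit] <- "undersampled-ND"
  # flanks, chromosome-bounded
  neigh <- rep(FALSE, n)
  hit_idx <- which(nd_hit)
  for (i in hit_idx) {
    rng <- setdiff(max(1, i - flank):min(n, i + flank), i)
    rng <- rng[chrom[rng] == chrom[i]]
    neigh[rng] <- TRUE
  }
  if (!is.null(mappability)) {
    low <- mappability < mappability_min & is.na(reason)
    reason[low] <- "low-mappability"
  }
  reason[neigh & is.na(reason)] <- "neighbor-of-ND"
  data.table(usable = is.na(reason), nd = nd, reason = reason)
}

moving_mean <- function(x, k) {
  half <- (k - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
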