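# ---------------------------------------------------------------------------
# Co-segregation and NPMI contact matrices, distance decay, per-distance
# z-scores, allele-specific and strong contact calls.
# ---------------------------------------------------------------------------

new_gam_matrix <- function(mat, windows, kind, phase, resolution, n_samples,
                           marginals = NULL) {
  structure(list(mat = mat, windows = as.data.table(windows), kind = kind,
                 phase = phase, resolution = resolution,
                 n_samples = n_samples, marginals = marginals),
            class = "gam_matrix")
}

#' @export
print.gam_matrix <- function(x, ...) {
  cat(sprintf("gam_matrix [%s, %s]: %d x %d at %g kb (%d samples)\n",
              x$kind, x$phase, nrow(x$mat), ncol(x$mat),
              x$resolution / 1e3, x$n_samples))
  invisible(x)
}

#' Raw co-segregation matrix for one chromosome
#'
#' Entry (i, j) counts the samples in which windows i and j are both
#' positive; the marginals count the samples in which each window is
#' positive.
#'
#' @param seg a `gam_segregation` table.
#' @param chromosome chromosome to extract.
#' @param max_distance optional genomic distance cap in bp; entries beyond
#'   it are set to `NA`.
#' @return a `gam_matrix` of kind `"coseg-count"`.
#' @export
cosegregation_matrix <- function(seg, chromosome, max_distance = NULL) {
  stopifnot(inherits(seg, "gam_segregation"))
  idx <- which(seg$windows$chrom == chromosome)
  if (!length(idx)) stop_config("chromosome %s not on the grid", chromosome)
  x <- seg$mat[idx, , drop = FALSE] * 1L
  co <- tcrossprod(x)
  windows <- seg$windows[idx]
  resolution <- max(windows$stop - windows$start)
  if (!is.null(max_distance)) {
    d <- abs(row(co) - col(co)) * resolution
    co[d > max_distance] <- NA_integer_
  }
  new_gam_matrix(co, windows, "coseg-count", seg$phase, resolution,
                 ncol(seg$mat), marginals = rowSums(x))
}

#' NPMI normalization of a co-segregation matrix
#'
#' With `p_i = marginal_i / M` and `p_ij = coseg_ij / M`, the normalized
#' pointwise mutual information is
#' `NPMI = ln(p_ij / (p_i * p_j)) / (-ln p_ij)`, the mutual dependence of
#' the two windows' detection relative to their individual detection rates,
#' bounded in `[-1, 1]`. Pairs never co-detected get -1; pairs always
#' co-detected together (`p_ij = p_i = p_j`) get 1. Windows with zero
#' marginal and the diagonal are `NA`.
#'
#' @param coseg a `gam_matrix` of kind `"coseg-count"`.
#' @return a `gam_matrix` of kind `"npmi"`.
#' @export
npmi_matrix <- function(coseg) {
  stopifnot(inherits(coseg, "gam_matrix"), coseg$kind == "coseg-count")
  M <- coseg$n_samples
  if (M <= 0) stop_config("sample count must be positive")
  p <- coseg$marginals / M
  pij <- coseg$mat / M
  if (any(pij > pmin(outer(p, p, pmin), 1) + 1e-12, na.rm = TRUE))
    stop_config("co-segregation exceeds marginals (data integrity)")
  pi_mat <- outer(p, p)
  npmi <- matrix(NA_real_, nrow(pij), ncol(pij))
  ok <- !is.na(pij) & p > 0 & matrix(p > 0, nrow(pij), ncol(pij),
                                     byrow = TRUE)
  pos <- ok & pij > 0 & pij < 1
  npmi[pos] <- log(pij[pos] / pi_mat[pos]) / (-log(pij[pos]))
  npmi[ok & pij == 0] <- -1
  # p_ij = p_i = p_j (incl. p_ij = 1): perfect co-segregation
  perfect <- ok & pij > 0 &
    abs(pij - outer(p, rep(1, length(p)))) < 1e-12 &
    abs(pij - outer(rep(1, length(p)), p)) < 1e-12
  npmi[perfect] <- 1
  diag(npmi) <- NA_real_
  new_gam_matrix(npmi, coseg$windows, "npmi", coseg$phase, coseg$resolution,
                 M, marginals = coseg$marginals)
}

#' Per-distance z-score matrix
#'
#' Standardizes every diagonal (genomic distance stratum) of the matrix to
#' mean 0 and population standard deviation 1 over its finite entries.
#' Strata with zero variance get z = 0. With `per_distance = FALSE` a single
#' global standardization over all off-diagonal finite entries is applied.
#'
#' @param m a `gam_matrix` (typically NPMI).
#' @param per_distance standardize per diagonal (default) or globally.
#' @return a `gam_matrix` of kind `"z-score"`.
#' @export
zscore_by_distance <- function(m, per_distance = TRUE) {
  stopifnot(inherits(m, "gam_matrix"))
  z <- matrix(NA_real_, nrow(m$mat), ncol(m$mat))
  if (per_distance) {
    n <- nrow(m$mat)
    for (d in seq_len(n - 1L)) {
      ii <- seq_len(n - d)
      v <- m$mat[cbind(ii, ii + d)]
      fin <- is.finite(v)
      if (!any(fin)) next
      mu <- mean(v[fin])
      sdv <- sqrt(mean((v[fin] - mu)^2)) # population sd
      zv <- if (sdv > 0) (v - mu) / sdv else ifelse(fin, 0, NA_real_)
      zv[!fin] <- NA_real_
      z[cbind(ii, ii + d)] <- zv
      z[cbind(ii + d, ii)] <- zv
    }
  } else {
    v <- m$mat[upper.tri(m$mat)]
    fin <- is.finite(v)
    mu <- mean(v[fin])
    sdv <- sqrt(mean((v[fin] - mu)^2))
    z <- if (sdv > 0) (m$mat - mu) / sdv else
      ifelse(is.finite(m$mat), 0, NA_real_)
    diag(z) <- NA_real_
  }
  new_gam_matrix(z, m$windows, "z-score", m$phase, m$resolution,
                 m$n_samples, m$marginals)
}

#' Distance decay curve and momentum (derivative) track
#'
#' Computes the mean contact intensity per genomic distance (per diagonal),
#' places it on the log10-distance axis, smooths it with a Normal-kernel
#' regression (`ksmooth`, bandwidth 0.3 in log10 bp units) evaluated at
#' breakpoints spaced 0.1 apart, and reports the successive differences of
#' the smoothed curve as slopes.
#'
#' @param m a `gam_matrix` (typically NPMI).
#' @param bandwidth kernel bandwidth on the log10 axis.
#' @param spacing breakpoint spacing on the log10 axis.
#' @return list with `raw` (per-distance means), `grid`, `smoothed`,
#'   `slopes`.
#' @export
decay_curve <- function(m, bandwidth = 0.3, spacing = 0.1) {
  stopifnot(inherits(m, "gam_matrix"))
  n <- nrow(m$mat)
  means <- vapply(seq_len(n - 1L), function(d) {
    v <- m$mat[cbind(seq_len(n - d), seq_len(n - d) + d)]
    if (all(!is.finite(v))) NA_real_ else mean(v[is.finite(v)])
  }, 0)
  keep <- is.finite(means)
  if (sum(keep) < 2L) stop_config("fewer than 2 populated distance bins")
  dist_bp <- seq_len(n - 1L) * m$resolution
  x <- log10(dist_bp[keep])
  y <- means[keep]
  grid <- seq(ceiling(min(x) / spacing) * spacing,
              floor(max(x) / spacing) * spacing, by = spacing)
  sm <- ksmooth(x, y, kernel = "normal", bandwidth = bandwidth,
                x.points = grid)
  list(raw = data.table(distance = dist_bp, mean_intensity = means),
       grid = sm$x, smoothed = sm$y, slopes = diff(sm$y))
}

#' Call allele-specific contacts from two haplotype maps
#'
#' Computes the delta z-score (CAST - S129) per window pair; pairs with
#' delta >= `delta_cutoff` and NPMI above `npmi_cutoff` are CAST-specific,
#' pairs with delta <= `-delta_cutoff` S129-specific. The NPMI intensity
#' filter is applied to the map of the gaining haplotype by default, or to
#' either map with `npmi_filter = "either"`. Only pairs within
#' `max_distance` and outside the mask are eligible.
#'
#' @param z_cast,z_s129 z-score `gam_matrix` objects on a shared grid.
#' @param npmi_cast,npmi_s129 matching NPMI matrices.
#' @param mask optional logical vector, `TRUE` for usable windows.
#' @param delta_cutoff,npmi_cutoff,max_distance call thresholds.
#' @param npmi_filter `"gaining"` or `"either"`.
#' @return `data.table` of calls: window indices, genomic distance, delta
#'   z-score, NPMI per phase and class.
#' @export
allele_specific_contacts <- function(z_cast, z_s129, npmi_cast, npmi_s129,
                                     mask = NULL, delta_cutoff = 1,
                                     npmi_cutoff = 0.3, max_distance = 50e6,
                                     npmi_filter = c("gaining", "either")) {
  npmi_filter <- match.arg(npmi_filter)
  for (m in list(z_s129, npmi_cast, npmi_s129))
    assert_same_grid(z_cast$windows, m$windows)
  n <- nrow(z_cast$mat)
  delta <- z_cast$mat - z_s129$mat
  idx <- which(upper.tri(delta), arr.ind = TRUE)
  d_bp <- (idx[, 2] - idx[, 1]) * z_cast$resolution
  keep <- d_bp <= max_distance
  if (!is.null(mask)) {
    if (length(mask) != n) stop_config("mask must match the window grid")
    keep <- keep & mask[idx[, 1]] & mask[idx[, 2]]
  }
  idx <- idx[keep, , drop = FALSE]
  d_bp <- d_bp[keep]
  dv <- delta[idx]
  nc <- npmi_cast$mat[idx]
  ns <- npmi_s129$mat[idx]
  pass_c <- if (npmi_filter == "gaining") nc > npmi_cutoff else
    (nc > npmi_cutoff | ns > npmi_cutoff)
  pass_s <- if (npmi_filter == "gaining") ns > npmi_cutoff else
    (nc > npmi_cutoff | ns > npmi_cutoff)
  cls <- rep(NA_character_, length(dv))
  cls[!is.na(dv) & dv >= delta_cutoff & pass_c] <- "CAST-specific"
  cls[!is.na(dv) & dv <= -delta_cutoff & pass_s] <- "S129-specific"
  sel <- !is.na(cls)
  data.table(i = idx[sel, 1], j = idx[sel, 2], distance = d_bp[sel],
             delta_z = dv[sel], npmi_cast = nc[sel], npmi_s129 = ns[sel],
             class = cls[sel])
}

#' Select strong contacts in one haplotype map
#'
#' A pair is a strong contact when its z-score exceeds `z_cutoff` and its
#' NPMI exceeds `npmi_cutoff`; the selection is made per haplotype without
#' reference to the other allele, so a pair may be strong in both.
#'
#' @param z,npmi z-score and NPMI `gam_matrix` objects on a shared grid.
#' @param z_cutoff,npmi_cutoff thresholds (defaults 2.0 and 0.3).
#' @param max_distance optional distance cap in bp.
#' @param mask optional logical usable-window vector.
#' @return `data.table` of selected pairs.
#' @export
strong_contacts <- function(z, npmi, z_cutoff = 2, npmi_cutoff = 0.3,
                            max_distance = NULL, mask = NULL) {
  assert_same_grid(z$windows, npmi$windows)
  idx <- which(upper.tri(z$mat), arr.ind = TRUE)
  d_bp <- (idx[, 2] - idx[, 1]) * z$resolution
  keep <- rep(TRUE, nrow(idx))
  if (!is.null(max_distance)) keep <- d_bp <= max_distance
  if (!is.null(mask)) keep <- keep & mask[idx[, 1]] & mask[idx[, 2]]
  zv <- z$mat[idx]
  nv <- npmi$mat[idx]
  sel <- keep & !is.na(zv) & !is.na(nv) & zv > z_cutoff & nv > npmi_cutoff
  data.table(i = idx[sel, 1], j = idx[sel, 2], distance = d_bp[sel],
             z = zv[sel], npmi = nv[sel], phase = z$phase)
}

#' Write a contact matrix as triplet TSV
#'
#' One row per finite upper-triangle entry: both windows as BED3 plus the
#' value (BEDPE-like layout).
#'
#' @param m a `gam_matrix`.
#' @param path output file.
#' @export
write_matrix_triplets <- function(m, path) {
  idx <- which(upper.tri(m$mat) & is.finite(m$mat), arr.ind = TRUE)
  w <- m$windows
  out <- data.table(chrom1 = w$chrom[idx[, 1]], start1 = w$start[idx[, 1]],
                    stop1 = w$stop[idx[, 1]], chrom2 = w$chrom[idx[, 2]],
                    start2 = w$start[idx[, 2]], stop2 = w$stop[idx[, 2]],
                    value = m$mat[idx])
  fwrite(out, path, sep = "\t")
  invisible(path)
}
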