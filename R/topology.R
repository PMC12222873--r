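# ---------------------------------------------------------------------------
# Insulation-square TAD calling and A/B compartment eigenvector analysis.
# ---------------------------------------------------------------------------

#' Insulation score track (insulation square method)
#'
#' For window `i` and a square of `s = square_size / resolution` bins, the
#' insulation score is the mean matrix value over all pairs `(a, b)` with
#' `a` in `[i - s, i - 1]` and `b` in `[i + 1, i + s]`, clipped to valid
#' indices at chromosome ends. The normalized track is the log2 ratio of
#' each value to the chromosome mean. A window gets `NA` when more than
#' `na_tolerance` of its square entries are missing.
#'
#' @param m a `gam_matrix` (typically NPMI) for one chromosome.
#' @param square_size square size in bp (multiple of the matrix resolution,
#'   at least 2 bins).
#' @param na_tolerance maximal fraction of missing entries per square.
#' @return `data.table` with `chrom`, `start`, `stop`, `value`
#'   (raw insulation) and `normalized` (log2 ratio to chromosome mean).
#' @export
insulation_score <- function(m, square_size, na_tolerance = 0.5) {
  stopifnot(inherits(m, "gam_matrix"))
  s <- square_size / m$resolution
  if (s != round(s)) stop_config("square size must be a multiple of resolution")
  s <- as.integer(s)
  if (s < 2L) stop_config("insulation square must span at least 2 bins")
  n <- nrow(m$mat)
  value <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- max(1L, i - s):(i - 1L)
    b <- (i + 1L):min(n, i + s)
    if (i == 1L || i == n) next
    sq <- m$mat[a, b, drop = FALSE]
    if (mean(is.na(sq)) > na_tolerance) next
    value[i] <- mean(sq, na.rm = TRUE)
  }
  chrom_mean <- mean(value[is.finite(value) & value > 0])
  normalized <- ifelse(is.finite(value) & value > 0 & chrom_mean > 0,
                       log2(value / chrom_mean), NA_real_)
  data.table(chrom = m$windows$chrom, start = m$windows$start,
             stop = m$windows$stop, value = value, normalized = normalized)
}

#' Call TAD borders from an insulation track
#'
#' Borders are strict local minima of the insulation score (value lower
#' than both finite neighbours; for plateaus of equal minimal values the
#' leftmost window is taken), widened by one bin on each side. Minima with
#' missing values on both sides are dropped.
#'
#' @param ins insulation track as returned by [insulation_score()].
#' @return `data.table` of borders: `chrom`, `first`/`last` window index
#'   (center +/- 1, clipped), `center`, `depth` (insulation at the
#'   minimum).
#' @export
call_tad_borders <- function(ins) {
  v <- ins$value
  n <- length(v)
  if (all(!is.finite(v))) {
    warning("insulation track is all missing; no borders called")
    return(data.table(chrom = character(), first = integer(),
                      last = integer(), center = integer(),
                      depth = numeric()))
  }
  centers <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (!is.finite(v[i]) || ins$chrom[i] != ins$chrom[i - 1L] ||
        ins$chrom[i] != ins$chrom[i + 1L]) { i <- i + 1L; next }
    # plateau run of equal values starting at i
    j <- i
    while (j < n && is.finite(v[j + 1L]) && v[j + 1L] == v[i] &&
           ins$chrom[j + 1L] == ins$chrom[i]) j <- j + 1L
    left <- v[i - 1L]
    right <- if (j < n && ins$chrom[min(j + 1L, n)] == ins$chrom[i])
      v[j + 1L] else NA_real_
    if (!is.finite(left) && !is.finite(right)) { i <- j + 1L; next }
    lower_left <- is.finite(left) && v[i] < left
    lower_right <- is.finite(right) && v[i] < right
    strict <- (is.finite(left) && is.finite(right) && lower_left &&
                 lower_right) ||
      (!is.finite(left) && lower_right) || (!is.finite(right) && lower_left)
    if (strict) centers <- c(centers, i) # leftmost window of the plateau
    i <- j + 1L
  }
  if (!length(centers))
    return(data.table(chrom = character(), first = integer(),
                      last = integer(), center = integer(),
                      depth = numeric()))
  data.table(chrom = as.character(ins$chrom[centers]),
             first = pmax(1L, centers - 1L),
             last = pmin(n, centers + 1L),
             center = centers, depth = v[centers])
}

#' Partition borders by haplotype membership
#'
#' Clusters the borders of several sets (e.g. CAST, S129, unphased) by
#' interval overlap (intervals within `slack` extra windows of each other
#' are merged) and counts each membership combination, UpSet-style.
#'
#' @param border_sets named list of border tables from
#'   [call_tad_borders()].
#' @param slack extra windows allowed between matched intervals (default 0:
#'   the 3-window intervals must intersect).
#' @return list with `partition` (counts per membership combination) and
#'   `clusters` (one row per merged border with membership flags).
#' @export
compare_border_sets <- function(border_sets, slack = 0L) {
  stopifnot(is.list(border_sets), !is.null(names(border_sets)))
  all_b <- rbindlist(lapply(names(border_sets), function(nm) {
    b <- border_sets[[nm]]
    if (!nrow(b)) return(NULL)
    data.table(set = nm, chrom = b$chrom, first = b$first - slack,
               last = b$last + slack, center = b$center)
  }))
  if (is.null(all_b) || !nrow(all_b))
    return(list(partition = data.table(members = character(), n = integer()),
                clusters = data.table()))
  setorder(all_b, chrom, first)
  cl <- integer(nrow(all_b))
  cid <- 0L
  last_end <- -Inf
  last_chrom <- ""
  for (k in seq_len(nrow(all_b))) {
    if (all_b$chrom[k] != last_chrom || all_b$first[k] > last_end) {
      cid <- cid + 1L
      last_end <- all_b$last[k]
      last_chrom <- all_b$chrom[k]
    } else last_end <- max(last_end, all_b$last[k])
    cl[k] <- cid
  }
  all_b[, cluster := cl]
  clusters <- all_b[, .(members = paste(sort(unique(set)), collapse = "+"),
                        chrom = chrom[1], center = round(mean(center))),
                    by = cluster]
  partition <- clusters[, .(n = .N), by = members]
  list(partition = partition[], clusters = clusters[])
}

#' A/B compartment calling by eigenvector analysis
#'
#' From a co-segregation (observed) matrix: divides observed by the
#' expected per-distance mean (O/E), computes the Pearson correlation
#' matrix of the O/E columns, takes its leading eigenvectors, selects the
#' component (first by default, best-GC-correlated among the first three
#' with `select_pc = "by-gc"`) and orients it so that positive values
#' correlate positively with GC content. Positive windows are compartment
#' A, negative B; values are rescaled per chromosome to (0, 1] for A and
#' [-1, 0) for B.
#'
#' @param coseg a `gam_matrix` of kind `"coseg-count"` (typically 100 kb).
#' @param gc numeric GC-content track on the same grid.
#' @param select_pc `"first"` (default) or `"by-gc"` (scan components 1-3).
#' @param min_windows minimum usable windows.
#' @return `data.table` with `chrom`, `start`, `stop`, `value` (normalized
#'   eigenvector) and `label` (`"A"`/`"B"`/`NA`), plus attribute `pc` for
#'   the selected component.
#' @export
call_compartments <- function(coseg, gc, select_pc = c("first", "by-gc"),
                              min_windows = 10L) {
  select_pc <- match.arg(select_pc)
  stopifnot(inherits(coseg, "gam_matrix"))
  O <- coseg$mat
  n <- nrow(O)
  if (length(gc) != n) stop_config("GC track must match the window grid")
  usable <- coseg$marginals > 0 & !is.na(gc)
  if (sum(usable) < min_windows)
    stop_config("fewer than %d usable windows", min_windows)
  Ou <- O[usable, usable, drop = FALSE]
  nu <- nrow(Ou)
  # expected = per-distance mean; O/E
  E <- matrix(NA_real_, nu, nu)
  for (d in 0:(nu - 1L)) {
    ii <- seq_len(nu - d)
    v <- Ou[cbind(ii, ii + d)]
    mv <- mean(v, na.rm = TRUE)
    E[cbind(ii, ii + d)] <- mv
    E[cbind(ii + d, ii)] <- mv
  }
  OE <- ifelse(is.na(E) | E == 0, NA_real_, Ou / E)
  if (all(is.na(OE)) || sd(OE[is.finite(OE)]) == 0)
    stop_config("degenerate matrix: no contrast for eigendecomposition")
  C <- suppressWarnings(cor(OE, use = "pairwise.complete.obs"))
  C[!is.finite(C)] <- 0
  eig <- eigen(C, symmetric = TRUE)
  if (eig$values[1] <= .Machine$double.eps)
    stop_config("degenerate eigendecomposition")
  k_max <- min(3L, ncol(eig$vectors))
  cors <- vapply(seq_len(k_max), function(k)
    suppressWarnings(cor(eig$vectors[, k], gc[usable])), 0)
  cors[is.na(cors)] <- 0
  k_sel <- if (select_pc == "by-gc") which.max(abs(cors)) else 1L
  if (select_pc == "first" && cors[1] == 0 && all(cors == 0))
    stop_config("cannot orient eigenvector: GC correlation undefined")
  ev <- eig$vectors[, k_sel] * sign(cors[k_sel] + (cors[k_sel] == 0))
  value <- rep(NA_real_, n)
  value[usable] <- ev
  # per-chromosome rescale: A to (0, 1], B to [-1, 0)
  for (ch in unique(coseg$windows$chrom)) {
    sel <- coseg$windows$chrom == ch
    vpos <- value[sel]
    if (any(vpos > 0, na.rm = TRUE))
      vpos[vpos > 0] <- vpos[vpos > 0] / max(vpos[vpos > 0], na.rm = TRUE)
    if (any(vpos < 0, na.rm = TRUE))
      vpos[vpos < 0] <- vpos[vpos < 0] / abs(min(vpos[vpos < 0], na.rm = TRUE))
    value[sel] <- vpos
  }
  label <- ifelse(is.na(value) | value == 0, NA_character_,
                  ifelse(value > 0, "A", "B"))
  out <- data.table(chrom = coseg$windows$chrom,
                    start = coseg$windows$start,
                    stop = coseg$windows$stop,
                    value = value, label = label)
  setattr(out, "pc", k_sel)
  out[]
}

#' Haplotype concordance of compartment annotations
#'
#' @param cast,s129 compartment tracks from [call_compartments()] on the
#'   same grid.
#' @return list of fractions `AA`, `BB`, `AB`, `BA` (CAST label first) over
#'   jointly-called windows, plus `discordant = AB + BA` and the number of
#'   joint windows.
#' @export
compartment_concordance <- function(cast, s129) {
  if (nrow(cast) != nrow(s129)) stop_config("tracks are on different grids")
  joint <- !is.na(cast$label) & !is.na(s129$label)
  if (!any(joint)) stop_config("no jointly-called windows")
  key <- paste0(cast$label[joint], s129$label[joint])
  f <- function(k) mean(key == k)
  list(AA = f("AA"), BB = f("BB"), AB = f("AB"), BA = f("BA"),
       discordant = f("AB") + f("BA"), n = sum(joint))
}
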