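# ---------------------------------------------------------------------------
# Haplotype-resolved feature statistics: WDF/compaction tracks, ASE calling,
# peak phasing, promoter states, permutation tests, regulatory contacts,
# methylation, cryo-FISH, feature co-occurrence.
# ---------------------------------------------------------------------------

# Overlap count of half-open query intervals against half-open subjects.
count_overlaps <- function(query, subject) {
  if (is.null(subject) || nrow(subject) == 0L) return(integer(nrow(query)))
  q <- data.table(chrom = query$chrom, s = query$start, e = query$stop - 1L,
                  qid = seq_len(nrow(query)))
  s <- data.table(chrom = subject$chrom, s = subject$start,
                  e = subject$stop - 1L)
  setkey(s, chrom, s, e)
  hits <- foverlaps(q, s, by.x = c("chrom", "s", "e"), type = "any",
                    nomatch = NULL)
  out <- integer(nrow(query))
  if (nrow(hits)) {
    tab <- hits[, .N, by = qid]
    out[tab$qid] <- tab$N
  }
  out
}

overlaps_any <- function(query, subject) count_overlaps(query, subject) > 0L

#' Window detection frequency (WDF) tracks
#'
#' WDF is the fraction of samples in which a window is positive; through the
#' slicing process, loci with larger physical volume (more decondensed
#' chromatin) are captured more frequently, so WDF is a compaction proxy.
#' The differential track is CAST - S129: positive values indicate
#' decompaction in CAST, negative in S129.
#'
#' @param cast,s129 `gam_segregation` tables on the same grid.
#' @return `data.table` with per-window `wdf_cast`, `wdf_s129` and
#'   `differential`.
#' @export
wdf_tracks <- function(cast, s129) {
  stopifnot(inherits(cast, "gam_segregation"),
            inherits(s129, "gam_segregation"))
  assert_same_grid(cast$windows, s129$windows)
  if (ncol(cast$mat) == 0L || ncol(s129$mat) == 0L)
    stop_config("segregation tables have zero samples")
  wc <- rowMeans(cast$mat)
  ws <- rowMeans(s129$mat)
  data.table(chrom = cast$windows$chrom, start = cast$windows$start,
             stop = cast$windows$stop, wdf_cast = wc, wdf_s129 = ws,
             differential = wc - ws)
}

#' Allele-specific expression calling
#'
#' Genes with fewer than `min_total` allelic reads are excluded; the rest
#' are tested with a two-sided exact binomial test against 0.5 and
#' corrected by Benjamini-Hochberg. A gene is ASE when the adjusted p-value
#' is at most `padj_max`, the absolute log2 fold change (CAST over S129) is
#' at least `lfc_min` and TPM is at least `tpm_min`; ASE genes with one
#' allele at zero reads are monoallelic. A zero denominator yields a signed
#' infinite fold change (the monoallelic path) and always satisfies the
#' fold-change criterion.
#'
#' @param counts `data.frame` with `gene_id`, `cast`, `s129` and `tpm`.
#' @param min_total minimum total allelic reads to test (default 20).
#' @param padj_max,lfc_min,tpm_min ASE thresholds (defaults 0.05, 1, 1).
#' @return `data.table` with ratio, log2FC, p-value, BH-adjusted p and
#'   class in `{CAST-ASE, S129-ASE, monoallelic-CAST, monoallelic-S129,
#'   biallelic, no-SNP, excluded}`.
#' @export
ase_call <- function(counts, min_total = 20L, padj_max = 0.05, lfc_min = 1,
                     tpm_min = 1) {
  counts <- as.data.table(counts)
  if (any(counts$cast < 0 | counts$s129 < 0))
    stop_config("allelic counts must be non-negative")
  total <- counts$cast + counts$s129
  ratio <- ifelse(total > 0, counts$cast / total, NA_real_)
  lfc <- suppressWarnings(log2(counts$cast / counts$s129))
  lfc[counts$cast == 0 & counts$s129 == 0] <- NA_real_
  tested <- total >= min_total
  p <- rep(NA_real_, nrow(counts))
  p[tested] <- vapply(which(tested), function(k)
    binom.test(counts$cast[[k]], total[[k]], 0.5)$p.value, 0)
  padj <- rep(NA_real_, nrow(counts))
  padj[tested] <- p.adjust(p[tested], method = "BH")
  is_ase <- tested & !is.na(padj) & padj <= padj_max &
    abs(lfc) >= lfc_min & counts$tpm >= tpm_min
  cls <- rep("biallelic", nrow(counts))
  cls[total == 0] <- "no-SNP"
  cls[total > 0 & !tested] <- "excluded"
  cls[is_ase & lfc > 0] <- "CAST-ASE"
  cls[is_ase & lfc < 0] <- "S129-ASE"
  cls[is_ase & counts$s129 == 0] <- "monoallelic-CAST"
  cls[is_ase & counts$cast == 0] <- "monoallelic-S129"
  data.table(gene_id = counts$gene_id, cast = counts$cast,
             s129 = counts$s129, total = total, tpm = counts$tpm,
             ase_ratio = ratio, log2fc = lfc, p_value = p, padj = padj,
             class = cls)
}

#' Phase ChIP-seq peaks by allelic read counts
#'
#' Peaks with fewer than `min_reads` SNP-containing reads are unphased;
#' peaks with an absolute log2 fold change (CAST over S129) above
#' `lfc_cutoff` are allele-specific (a zero denominator counts as an
#' infinite fold change); the rest are common.
#'
#' @param counts `data.frame` with `peak_id`, `cast`, `s129`.
#' @param min_reads,lfc_cutoff rule parameters (defaults 10 and 2).
#' @return `data.table` with `log2fc` and class in
#'   `{CAST, S129, common, unphased}`.
#' @export
phase_peaks <- function(counts, min_reads = 10L, lfc_cutoff = 2) {
  counts <- as.data.table(counts)
  total <- counts$cast + counts$s129
  lfc <- suppressWarnings(log2(counts$cast / counts$s129))
  lfc[counts$cast == 0 & counts$s129 == 0] <- NA_real_
  cls <- rep("common", nrow(counts))
  cls[!is.na(lfc) & lfc > lfc_cutoff] <- "CAST"
  cls[!is.na(lfc) & lfc < -lfc_cutoff] <- "S129"
  cls[total < min_reads] <- "unphased"
  data.table(peak_id = counts$peak_id, cast = counts$cast,
             s129 = counts$s129, total = total, log2fc = lfc, class = cls)
}

# Permutation p-value for one peak: null relabels each of the m reads to
# CAST with probability 0.5 and measures |D|. The null |D| is a function of
# a Binomial(m, 1/2) draw, so the exhaustive p-value is computed exactly
# from the binomial distribution; the sampled path keeps the standard
# (1 + #null >= obs) / (1 + n) estimator.
d_score_perm_p <- function(cast, s129, n_perm, method, exhaustive_max = 15L) {
  m <- cast + s129
  if (m == 0L) return(NA_real_)
  d_obs <- abs((cast - s129) / m)
  if (method == "auto") method <- if (m <= exhaustive_max) "exhaustive"
  else "sample"
  if (method == "exhaustive") {
    b <- 0:m
    null_d <- abs(2 * b / m - 1)
    sum(dbinom(b, m, 0.5)[null_d >= d_obs - 1e-12])
  } else {
    b <- rbinom(n_perm, m, 0.5)
    null_d <- abs(2 * b / m - 1)
    (1 + sum(null_d >= d_obs - 1e-12)) / (1 + n_perm)
  }
}

#' Allele-specific ATAC peaks by D score and permutation test
#'
#' The D score of a peak is `(CAST - S129) / (CAST + S129)` per replicate.
#' The permutation null reassigns each read's allele label with probability
#' 0.5 and uses |D| as statistic; for peaks with at most `exhaustive_max`
#' reads the p-value is computed by exhaustive enumeration, otherwise by
#' `n_perm` Monte-Carlo draws (pooled counts across replicates are used for
#' the test). BH correction is applied across peaks. A peak is
#' allele-specific when every replicate passes the D-magnitude criterion
#' (`|D| >= d_cutoff`; the literal inside-range reading
#' `-d_cutoff <= D <= d_cutoff` is available via `rule = "literal"`), the
#' pooled read count is at least `min_reads`, and the FDR-adjusted p-value
#' is below `p_max`. The sign of the pooled D gives the haplotype.
#'
#' @param counts `data.frame` with `peak_id`, `rep`, `cast`, `s129`.
#' @param n_perm Monte-Carlo permutations (>= 1000).
#' @param seed RNG seed for the sampled path.
#' @param d_cutoff,min_reads,p_max rule parameters (defaults 0.3, 10, 0.01).
#' @param rule `"magnitude"` (default) or `"literal"`.
#' @param method `"auto"` (default), `"exhaustive"` or `"sample"`.
#' @param exhaustive_max largest read count enumerated exhaustively.
#' @return `data.table`, one row per peak: per-replicate D scores, pooled
#'   D, p-value, FDR and class in `{CAST, S129, common, unphased}`.
#' @export
atac_allelic_peaks <- function(counts, n_perm = 10000L, seed = 1L,
                               d_cutoff = 0.3, min_reads = 10L,
                               p_max = 0.01,
                               rule = c("magnitude", "literal"),
                               method = c("auto", "exhaustive", "sample"),
                               exhaustive_max = 15L) {
  rule <- match.arg(rule)
  method <- match.arg(method)
  if (n_perm < 1000L && method != "exhaustive")
    stop_config("n_perm must be at least 1000")
  counts <- copy(as.data.table(counts))
  counts[, `:=`(d = ifelse(cast + s129 > 0,
                           (cast - s129) / (cast + s129), NA_real_))]
  pooled <- counts[, .(cast = sum(cast), s129 = sum(s129),
                       d_scores = list(d), n_rep = .N), by = peak_id]
  pooled[, `:=`(total = cast + s129,
                d_pooled = ifelse(cast + s129 > 0,
                                  (cast - s129) / (cast + s129), NA_real_))]
  pooled[, p_value := with_seed(seed, vapply(seq_len(.N), function(k)
    d_score_perm_p(cast[[k]], s129[[k]], n_perm, method, exhaustive_max),
    0))]
  pooled[, fdr := p.adjust(p_value, method = "BH")]
  d_pass <- vapply(seq_len(nrow(pooled)), function(k) {
    ds <- pooled$d_scores[[k]]
    if (anyNA(ds)) return(FALSE)
    if (rule == "magnitude") all(abs(ds) >= d_cutoff)
    else all(ds >= -d_cutoff & ds <= d_cutoff)
  }, TRUE)
  cls <- rep("common", nrow(pooled))
  sig <- d_pass & pooled$total >= min_reads & !is.na(pooled$fdr) &
    pooled$fdr < p_max
  cls[sig & pooled$d_pooled > 0] <- "CAST"
  cls[sig & pooled$d_pooled < 0] <- "S129"
  cls[pooled$total == 0] <- "unphased"
  pooled[, class := cls]
  pooled[]
}

#' Classify promoter states from Pol2-S5p, Pol2-S7p and H3K27me3
#'
#' A gene is positive for a mark when (i) the 2-kb window centred on its
#' TSS overlaps a region enriched for the mark and (ii) its TSS-window read
#' count reaches a threshold defined as the 5th percentile of the read
#' counts of the genes passing criterion (i) alone (one-pass bootstrap of
#' the threshold). States: Active = S5p+ S7p+ K27me3-; PRCa (Polycomb-
#' Active) = S5p+ S7p+ K27me3+; PRC = K27me3+ S7p-; Inactive = all others.
#'
#' @param genes `data.frame` with `gene_id`, per-mark TSS-window read
#'   counts `reads_s5p`, `reads_s7p`, `reads_k27me3`, per-mark overlap
#'   flags `overlap_s5p`, `overlap_s7p`, `overlap_k27me3`, and optionally
#'   a logical `excluded` column (overlapping genes) with reasons kept by
#'   the caller.
#' @param percentile threshold percentile among provisional positives
#'   (default 0.05).
#' @return `data.table` with per-mark positivity flags and `state` in
#'   `{Active, PRCa, PRC, Inactive, excluded-overlapping}`.
#' @export
promoter_state_classify <- function(genes, percentile = 0.05) {
  genes <- as.data.table(genes)
  excluded <- if ("excluded" %in% names(genes)) genes$excluded else
    rep(FALSE, nrow(genes))
  marks <- c("s5p", "s7p", "k27me3")
  flags <- list()
  for (mk in marks) {
    ov <- genes[[paste0("overlap_", mk)]] & !excluded
    reads <- genes[[paste0("reads_", mk)]]
    if (!any(ov)) {
      warning(sprintf("no provisional positives for %s; all negative", mk))
      flags[[mk]] <- rep(FALSE, nrow(genes))
      next
    }
    # empirical percentile without interpolation (type 1): the threshold is
    # an observed read count among the provisional positives
    thr <- quantile(reads[ov], percentile, names = FALSE, type = 1)
    flags[[mk]] <- ov & reads >= thr
  }
  state <- rep("Inactive", nrow(genes))
  state[flags$k27me3 & !flags$s7p] <- "PRC"
  state[flags$s5p & flags$s7p & !flags$k27me3] <- "Active"
  state[flags$s5p & flags$s7p & flags$k27me3] <- "PRCa"
  state[excluded] <- "excluded-overlapping"
  data.table(gene_id = genes$gene_id, s5p = flags$s5p, s7p = flags$s7p,
             k27me3 = flags$k27me3, state = state)
}

#' Select one isoform per gene
#'
#' Cascade: highest Pol2-S5p TSS-window reads, then highest Pol2-S7p, then
#' longest isoform, then a seeded random choice among exact ties.
#'
#' @param isoforms `data.frame` with `gene_id`, `isoform_id`, `s5p`, `s7p`,
#'   `length`.
#' @param seed seed for the final random tie-break.
#' @return `data.table` with one row per gene and the criterion that
#'   resolved it (`s5p`, `s7p`, `length`, `random` or `single`).
#' @export
select_isoform <- function(isoforms, seed = 1L) {
  isoforms <- as.data.table(isoforms)
  with_seed(seed, {
    rbindlist(lapply(split(isoforms, by = "gene_id"), function(g) {
      if (nrow(g) == 1L) return(cbind(g, criterion = "single"))
      for (crit in c("s5p", "s7p", "length")) {
        top <- g[[crit]] == max(g[[crit]])
        if (sum(top) == 1L)
          return(cbind(g[which(top)], criterion = crit))
        g <- g[top]
      }
      cbind(g[sample.int(nrow(g), 1L)], criterion = "random")
    }))
  })
}

# Rotate features on one circular chromosome by `offset` bp; wrapping
# intervals are split in two.
rotate_features <- function(feat, L, offset) {
  s <- (feat$start + offset) %% L
  e <- s + (feat$stop - feat$start)
  wrap <- e > L
  out <- data.table(chrom = feat$chrom, start = s, stop = pmin(e, L))
  if (any(wrap)) {
    out <- rbind(out, data.table(chrom = feat$chrom[wrap], start = 0,
                                 stop = e[wrap] - L))
  }
  out
}

#' Circular permutation test for genomic interval association
#'
#' Each permutation rotates all feature positions by a single uniform
#' offset per chromosome (rigid rotation wrapping at chromosome ends,
#' preserving intra-chromosomal spacing) and recomputes the statistic:
#' the number of features overlapping the target regions (default) or the
#' mean distance from each feature midpoint to the nearest target midpoint
#' (circular distance; use `alternative = "less"` to test for proximity).
#' On a single chromosome with at most `exhaustive_max` distinct offsets
#' (multiples of `offset_unit`) the rotation space is enumerated
#' exhaustively and the p-value is exact; otherwise `n_perm` random
#' rotations are drawn and `p = (1 + #null as-extreme) / (1 + n_perm)`.
#'
#' @param features,targets interval tables with `chrom`, `start`, `stop`.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param n_perm number of random rotations.
#' @param seed RNG seed.
#' @param statistic `"overlap_count"` or `"mean_nn_dist"`.
#' @param alternative `"greater"` (enrichment) or `"less"` (depletion /
#'   proximity).
#' @param method `"auto"`, `"exhaustive"` or `"sample"`.
#' @param offset_unit granularity of rotation offsets in bp.
#' @param exhaustive_max largest enumerable rotation space.
#' @return list with `p_value`, `observed`, `null_mean`, `null_sd`,
#'   `method` and the number of rotations.
#' @export
circular_permutation_test <- function(features, targets, chrom_sizes,
                                      n_perm = 10000L, seed = 1L,
                                      statistic = c("overlap_count",
                                                    "mean_nn_dist"),
                                      alternative = c("greater", "less"),
                                      method = c("auto", "exhaustive",
                                                 "sample"),
                                      offset_unit = 1,
                                      exhaustive_max = 32768L) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  features <- as.data.table(features)
  targets <- as.data.table(targets)
  if (nrow(features) == 0L) stop_config("empty feature set")
  chroms <- unique(features$chrom)
  if (!all(chroms %in% names(chrom_sizes)))
    stop_config("features on chromosomes absent from chrom_sizes")
  stat_fun <- if (statistic == "overlap_count") {
    function(f) sum(overlaps_any(f, targets))
  } else {
    tmid <- (targets$start + targets$stop) / 2
    function(f) {
      mean(vapply(seq_len(nrow(f)), function(k) {
        L <- chrom_sizes[[f$chrom[k]]]
        tm <- tmid[targets$chrom == f$chrom[k]]
        if (!length(tm)) return(L / 2)
        fm <- (f$start[k] + f$stop[k]) / 2
        dd <- abs(tm - fm)
        min(pmin(dd, L - dd))
      }, 0))
    }
  }
  observed <- stat_fun(features)
  rotate_all <- function(offsets) {
    rbindlist(lapply(chroms, function(ch)
      rotate_features(features[features$chrom == ch],
                      chrom_sizes[[ch]], offsets[[ch]])))
  }
  n_off <- floor(chrom_sizes[chroms] / offset_unit)
  if (method == "auto") {
    method <- if (length(chroms) == 1L && n_off[[1]] <= exhaustive_max)
      "exhaustive" else "sample"
  }
  if (method == "exhaustive") {
    if (length(chroms) != 1L)
      stop_config("exhaustive rotation requires a single chromosome")
    offs <- offset_unit * (seq_len(n_off[[1]]) - 1L)
    null <- vapply(offs, function(o)
      stat_fun(rotate_all(setNames(o, chroms))), 0)
    n_used <- length(offs)
    extreme <- if (alternative == "greater") sum(null >= observed)
    else sum(null <= observed)
    p <- extreme / n_used
  } else {
    null <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
      offs <- setNames(vapply(chroms, function(ch)
        offset_unit * (sample.int(n_off[[ch]], 1L) - 1), 0), chroms)
      stat_fun(rotate_all(offs))
    }, 0))
    n_used <- n_perm
    extreme <- if (alternative == "greater") sum(null >= observed)
    else sum(null <= observed)
    p <- (1 + extreme) / (1 + n_perm)
  }
  list(p_value = p, observed = observed, null_mean = mean(null),
       null_sd = sd(null), method = method, n = n_used)
}

#' Annotate strong contacts as enhancer-promoter pairs or CTCF loops
#'
#' EP mode keeps contacts within `max_distance` where one anchor window
#' contains the TSS of an ASE gene together with Pol2-S5p and ATAC peaks,
#' and the other anchor contains Pol2-S5p, ATAC and H3K27ac peaks (a
#' putative enhancer). CTCF-loop mode keeps contacts within `max_distance`
#' with CTCF and RAD21 peaks at both anchors and convergent CTCF motifs
#' (a "+" motif at the left anchor and a "-" motif at the right). Kept
#' contacts are labelled by haplotype configuration: whether the contact's
#' haplotype is the most- or least-expressed allele of the anchored ASE
#' gene (EP mode; `NA` for CTCF loops without an ASE anchor).
#'
#' @param contacts `data.table` from [strong_contacts()] (columns `i`, `j`,
#'   `phase`).
#' @param windows the matrix window grid the indices refer to.
#' @param genes `data.frame` with `gene_id`, `chrom`, `tss` and
#'   `ase_class` (`"CAST-ASE"`/`"S129-ASE"`/other).
#' @param peaks named list of interval tables; EP mode needs `s5p`, `atac`,
#'   `h3k27ac`; CTCF mode needs `ctcf` (with a `strand` column) and
#'   `rad21`.
#' @param mode `"EP"` or `"CTCF-loop"`.
#' @param max_distance anchor distance cap in bp (default 2 Mb).
#' @return the kept contacts with annotation columns.
#' @export
annotate_regulatory_contacts <- function(contacts, windows, genes, peaks,
                                         mode = c("EP", "CTCF-loop"),
                                         max_distance = 2e6) {
  mode <- match.arg(mode)
  windows <- as.data.table(windows)
  genes <- as.data.table(genes)
  need <- if (mode == "EP") c("s5p", "atac", "h3k27ac") else
    c("ctcf", "rad21")
  miss <- setdiff(need, names(peaks))
  if (length(miss))
    stop_config("missing peak set(s) for %s mode: %s", mode,
                paste(miss, collapse = ", "))
  if (nrow(contacts) == 0L)
    return(cbind(contacts, data.table(kept = logical(0))))
  dist_bp <- abs(windows$start[contacts$j] - windows$start[contacts$i])
  keep <- dist_bp <= max_distance
  if (mode == "EP") {
    tss_dt <- data.table(chrom = genes$chrom, start = genes$tss,
                         stop = genes$tss + 1L)
    ase <- genes$ase_class %in% c("CAST-ASE", "S129-ASE",
                                  "monoallelic-CAST", "monoallelic-S129")
    has_ase_tss <- overlaps_any(windows, tss_dt[ase])
    has_s5p <- overlaps_any(windows, peaks$s5p)
    has_atac <- overlaps_any(windows, peaks$atac)
    has_k27ac <- overlaps_any(windows, peaks$h3k27ac)
    prom_ok <- has_ase_tss & has_s5p & has_atac
    enh_ok <- has_s5p & has_atac & has_k27ac
    left_prom <- prom_ok[contacts$i] & enh_ok[contacts$j]
    right_prom <- prom_ok[contacts$j] & enh_ok[contacts$i]
    keep <- keep & (left_prom | right_prom)
    # haplotype configuration relative to the ASE gene at the promoter anchor
    gene_dir <- function(widx) {
      vapply(widx, function(w) {
        hit <- genes[ase & genes$chrom == windows$chrom[w] &
                       genes$tss >= windows$start[w] &
                       genes$tss < windows$stop[w]]
        if (!nrow(hit)) return(NA_character_)
        if (grepl("CAST", hit$ase_class[1])) "cast" else "s129"
      }, "")
    }
    prom_anchor <- ifelse(left_prom, contacts$i, contacts$j)
    expressed <- rep(NA_character_, nrow(contacts))
    expressed[keep] <- gene_dir(prom_anchor[keep])
    config <- ifelse(is.na(expressed), NA_character_,
                     ifelse(expressed == contacts$phase,
                            "most-expressed", "least-expressed"))
    out <- cbind(as.data.table(contacts),
                 data.table(distance_bp = dist_bp, kept = keep,
                            promoter_anchor = prom_anchor,
                            expressed_allele = expressed,
                            configuration = config))
  } else {
    ctcf <- as.data.table(peaks$ctcf)
    if (!"strand" %in% names(ctcf))
      stop_config("CTCF peaks need a strand column for motif orientation")
    has_rad21 <- overlaps_any(windows, peaks$rad21)
    has_plus <- overlaps_any(windows, ctcf[ctcf$strand == "+"])
    has_minus <- overlaps_any(windows, ctcf[ctcf$strand == "-"])
    has_ctcf <- overlaps_any(windows, ctcf)
    anchors_ok <- has_ctcf & has_rad21
    convergent <- has_plus[contacts$i] & has_minus[contacts$j]
    keep <- keep & anchors_ok[contacts$i] & anchors_ok[contacts$j] &
      convergent
    out <- cbind(as.data.table(contacts),
                 data.table(distance_bp = dist_bp, kept = keep,
                            convergent = convergent))
  }
  out[kept == TRUE]
}

#' Differentially methylated promoters between alleles
#'
#' Per allele, a CpG is methylated when its methylation percentage exceeds
#' 50. For each promoter (TSS +/- 1000 bp) of a gene longer than 2000 bp,
#' the ratio of methylated to unmethylated covered CpGs is computed per
#' allele; the differential is the S129 ratio minus the CAST ratio.
#' Promoters whose absolute differential exceeds the 95th percentile of
#' all absolute differentials are called (two-tailed default; `tail =
#' "upper"` applies the literal one-tailed rule on the signed
#' differential). Promoters with no covered CpGs on either allele, or an
#' undefined ratio difference, are excluded with a reason.
#'
#' @param cpg_cast,cpg_s129 per-CpG tables with `chrom`, `pos`,
#'   `meth_pct`.
#' @param genes `data.frame` with `gene_id`, `chrom`, `tss`, `length`.
#' @param pct_cutoff methylation-call cutoff on the percentage (default
#'   50, strict).
#' @param min_gene_length promoter analysis restricted to genes longer
#'   than this (default 2000).
#' @param promoter_flank TSS flank in bp (default 1000).
#' @param tail `"two"` or `"upper"`.
#' @return `data.table` with per-allele ratios, differential, `called`
#'   flag, `direction` and exclusion `reason`.
#' @export
differential_methylation <- function(cpg_cast, cpg_s129, genes,
                                     pct_cutoff = 50,
                                     min_gene_length = 2000,
                                     promoter_flank = 1000,
                                     tail = c("two", "upper")) {
  tail <- match.arg(tail)
  genes <- as.data.table(genes)
  genes <- genes[genes$length > min_gene_length]
  ratio_for <- function(cpg) {
    cpg <- as.data.table(cpg)
    vapply(seq_len(nrow(genes)), function(k) {
      sel <- cpg$chrom == genes$chrom[k] &
        cpg$pos >= genes$tss[k] - promoter_flank &
        cpg$pos < genes$tss[k] + promoter_flank
      if (!any(sel)) return(NA_real_)
      m <- sum(cpg$meth_pct[sel] > pct_cutoff)
      u <- sum(sel) - m
      if (u == 0L) Inf else m / u
    }, 0)
  }
  rc <- ratio_for(cpg_cast)
  rs <- ratio_for(cpg_s129)
  diffv <- rs - rc
  reason <- rep(NA_character_, nrow(genes))
  reason[is.na(rc) | is.na(rs)] <- "no covered CpGs"
  reason[is.na(reason) & !is.finite(diffv)] <- "undefined ratio difference"
  ok <- is.na(reason)
  called <- rep(FALSE, nrow(genes))
  if (any(ok)) {
    if (tail == "two") {
      thr <- quantile(abs(diffv[ok]), 0.95, names = FALSE)
      called[ok] <- abs(diffv[ok]) > thr
    } else {
      thr <- quantile(diffv[ok], 0.95, names = FALSE)
      called[ok] <- diffv[ok] > thr
    }
  }
  data.table(gene_id = genes$gene_id, ratio_cast = rc, ratio_s129 = rs,
             differential = diffv, called = called,
             direction = ifelse(called & diffv > 0, "S129-methylated",
                                ifelse(called, "CAST-methylated",
                                       NA_character_)),
             reason = reason)
}

#' Fraction of cryosections containing both alleles
#'
#' @param section_counts integer vector of allele counts per nuclear
#'   section (1 or 2).
#' @return fraction of sections containing both alleles among sections
#'   containing at least one.
#' @export
cryofish_allele_fraction <- function(section_counts) {
  if (!length(section_counts)) stop_config("empty section table")
  if (!all(section_counts %in% c(1L, 2L)))
    stop_config("section allele counts must be 1 or 2")
  sum(section_counts == 2L) / length(section_counts)
}

#' Genome-wide feature co-occurrence
#'
#' Bins the genome (default 200 kb), counts the peaks of every feature set
#' per bin, and returns the Pearson correlation matrix of the count
#' vectors. Sets with zero peaks or constant counts give `NA` with a
#' warning.
#'
#' @param peak_sets named list of interval tables (`chrom`, `start`,
#'   `stop`).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param bin_size bin size in bp (default 200 kb).
#' @return correlation matrix with one row/column per feature set.
#' @export
feature_cooccurrence <- function(peak_sets, chrom_sizes, bin_size = 2e5) {
  if (length(peak_sets) < 2L) stop_config("need at least 2 peak sets")
  bins <- gam_windows(chrom_sizes, bin_size)
  cnt <- vapply(peak_sets, function(p) count_overlaps(bins, p),
                integer(nrow(bins)))
  empty <- colSums(cnt) == 0
  if (any(empty))
    warning(sprintf("peak set(s) with zero peaks: %s",
                    paste(names(peak_sets)[empty], collapse = ", ")))
  suppressWarnings(cor(cnt))
}
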