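test_that("WDF tracks are exact ratios with signed differential", {
  mat_c <- matrix(FALSE, 2, 200); mat_c[1, 1:50] <- TRUE
  mat_s <- matrix(FALSE, 2, 200); mat_s[1, 1:30] <- TRUE
  tr <- wdf_tracks(make_seg(mat_c, phase = "cast"),
                   make_seg(mat_s, phase = "s129"))
  expect_equal(tr$wdf_cast, c(0.25, 0))
  expect_equal(tr$differential, c(0.1, 0))
  # equal tables: differential 0 everywhere
  tr0 <- wdf_tracks(make_seg(mat_c, phase = "cast"),
                    make_seg(mat_c, phase = "s129"))
  expect_true(all(tr0$differential == 0))
})

test_that("differential WDF follows planted compaction asymmetry", {
  mult <- rep(1, 100); mult[21:40] <- 2
  m <- gam_genome_model(c(chr1 = 5e6), seed = 61,
                        radius_multiplier = list(cast = mult))
  sim <- gam_simulate(m, n_samples = 300, n_slices = 3, seed = 62)
  ph <- suppressWarnings(build_segregation_tables(sim$coverage))
  tr <- wdf_tracks(ph$cast, ph$s129)
  expect_gt(mean(tr$differential[21:40]), 0)
  expect_gt(mean(tr$differential[21:40]),
            mean(tr$differential[-(21:40)]) + 0.02)
})

test_that("ASE calling applies the coverage, test and fold-change rules", {
  counts <- data.frame(
    gene_id = c("mono", "bal", "low", "nosnp", "lowtpm"),
    cast = c(20, 10, 12, 0, 40),
    s129 = c(0, 10, 7, 0, 5),
    tpm = c(5, 5, 5, 5, 0.5))
  res <- ase_call(counts)
  expect_equal(res[gene_id == "mono", class], "monoallelic-CAST")
  expect_equal(res[gene_id == "mono", p_value], 2 * 0.5^20)
  expect_equal(res[gene_id == "mono", log2fc], Inf)
  expect_equal(res[gene_id == "bal", class], "biallelic")
  expect_equal(res[gene_id == "bal", log2fc], 0)
  expect_equal(res[gene_id == "low", class], "excluded")
  expect_equal(res[gene_id == "nosnp", class], "no-SNP")
  expect_equal(res[gene_id == "lowtpm", class], "biallelic") # TPM < 1
  expect_equal(res$ase_ratio[1], 1)
  expect_error(ase_call(data.frame(gene_id = "g", cast = -1, s129 = 2,
                                   tpm = 1)), "non-negative")
})

test_that("ASE calling is calibrated and powered", {
  # type-I: balanced alleles, 500 genes -> at most 5% called ASE
  n <- 500
  tot <- gamhap:::with_seed(71, 20 + rpois(n, 30))
  ca <- gamhap:::with_seed(72, rbinom(n, tot, 0.5))
  null_res <- ase_call(data.frame(gene_id = seq_len(n), cast = ca,
                                  s129 = tot - ca, tpm = 5))
  expect_lte(mean(grepl("ASE|monoallelic", null_res$class)), 0.05)
  # power: true allelic ratio 0.8, totals >= 50 -> >= 80% called ASE
  tot2 <- gamhap:::with_seed(73, 50 + rpois(n, 30))
  ca2 <- gamhap:::with_seed(74, rbinom(n, tot2, 0.8))
  alt_res <- ase_call(data.frame(gene_id = seq_len(n), cast = ca2,
                                 s129 = tot2 - ca2, tpm = 5))
  expect_gte(mean(grepl("CAST", alt_res$class)), 0.8)
})

test_that("ChIP peak phasing follows the log2FC > 2 rule", {
  counts <- data.frame(peak_id = 1:5,
                       cast = c(40, 8, 20, 0, 60),
                       s129 = c(5, 1, 18, 30, 0))
  res <- phase_peaks(counts)
  expect_equal(res$class, c("CAST", "unphased", "common", "S129", "CAST"))
  expect_equal(res$log2fc[1], 3)
  expect_equal(res$log2fc[3], log2(20 / 18))
  expect_equal(res$log2fc[5], Inf)
})

test_that("D scores and permutation p-values match enumeration", {
  counts <- data.frame(peak_id = c("p", "p", "q", "q"),
                       rep = c(1, 2, 1, 2),
                       cast = c(30, 24, 5, 6),
                       s129 = c(10, 8, 5, 6))
  res <- atac_allelic_peaks(counts, n_perm = 1000)
  expect_equal(res[peak_id == "p", d_scores][[1]], c(0.5, 0.5))
  expect_equal(res[peak_id == "q", d_scores][[1]], c(0, 0))
  # exhaustive p-value equals a literal loop over all 2^10 relabelings
  obs_d <- abs((10 - 0) / 10)
  null_ge <- 0
  for (b in 0:(2^10 - 1)) {
    lab <- as.integer(intToBits(b))[1:10]
    d <- abs((sum(lab) - (10 - sum(lab))) / 10)
    if (d >= obs_d) null_ge <- null_ge + 1
  }
  one <- atac_allelic_peaks(
    data.frame(peak_id = "x", rep = 1, cast = 10, s129 = 0),
    n_perm = 1000, method = "exhaustive")
  expect_equal(one$p_value, null_ge / 2^10)
  # zero reads: unphased
  z <- atac_allelic_peaks(data.frame(peak_id = "z", rep = 1, cast = 0,
                                     s129 = 0), n_perm = 1000)
  expect_equal(z$class, "unphased")
})

test_that("ATAC allele-specific rule needs D, reads and FDR together", {
  counts <- data.frame(
    peak_id = rep(c("big", "weak", "few"), each = 2),
    rep = rep(1:2, 3),
    cast = c(45, 40, 22, 21, 4, 3),
    s129 = c(5, 8, 18, 19, 0, 0))
  res <- atac_allelic_peaks(counts, n_perm = 2000, seed = 5)
  expect_equal(res[peak_id == "big", class], "CAST")
  expect_equal(res[peak_id == "weak", class], "common") # |D| < 0.3
  expect_equal(res[peak_id == "few", class], "common")  # < 10 reads
  # literal inside-range rule inverts the D-magnitude criterion
  lit <- atac_allelic_peaks(counts, n_perm = 2000, seed = 5,
                            rule = "literal")
  expect_equal(lit[peak_id == "big", class], "common")
})

test_that("global CAST/S129 relabeling mirrors every statistic", {
  counts <- data.frame(gene_id = 1:50,
                       cast = gamhap:::with_seed(81, rpois(50, 30)),
                       s129 = gamhap:::with_seed(82, rpois(50, 15)),
                       tpm = 5)
  a <- ase_call(counts)
  b <- ase_call(transform(counts, cast = s129, s129 = cast))
  expect_equal(b$log2fc, -a$log2fc)
  expect_equal(b$p_value, a$p_value)
  map <- c("CAST-ASE" = "S129-ASE", "S129-ASE" = "CAST-ASE",
           "monoallelic-CAST" = "monoallelic-S129",
           "monoallelic-S129" = "monoallelic-CAST",
           "biallelic" = "biallelic", "excluded" = "excluded",
           "no-SNP" = "no-SNP")
  expect_equal(b$class, unname(map[a$class]))
  pk <- data.frame(peak_id = 1:4, rep = 1, cast = c(40, 5, 12, 0),
                   s129 = c(4, 45, 11, 20))
  d1 <- atac_allelic_peaks(pk, n_perm = 1000, seed = 3)
  d2 <- atac_allelic_peaks(transform(pk, cast = s129, s129 = cast),
                           n_perm = 1000, seed = 3)
  expect_equal(d2$d_pooled, -d1$d_pooled)
})

test_that("promoter states follow the occupancy flag combinations", {
  genes <- data.frame(
    gene_id = sprintf("g%02d", 1:6),
    reads_s5p = c(100, 100, 5, 100, 0, 100),
    reads_s7p = c(80, 80, 5, 0, 0, 80),
    reads_k27me3 = c(0, 50, 60, 60, 0, 0),
    overlap_s5p = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    overlap_s7p = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    overlap_k27me3 = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE),
    excluded = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  st <- promoter_state_classify(genes)
  # g3: with so few provisional positives the 5th-percentile threshold is
  # the minimum observed count, so its low reads still pass -> PRCa.
  # g4 is S5p+ S7p- K27me3+: the PRC state does not require S5p-.
  expect_equal(st$state,
               c("Active", "PRCa", "PRCa", "PRC", "Inactive",
                 "excluded-overlapping"))
  # the 5th-percentile read threshold can veto an overlap
  many <- data.frame(
    gene_id = seq_len(101),
    reads_s5p = c(rep(100, 100), 1), # gene 101 overlaps but is below p5
    reads_s7p = 0, reads_k27me3 = 0,
    overlap_s5p = TRUE, overlap_s7p = FALSE, overlap_k27me3 = FALSE)
  st2 <- suppressWarnings(promoter_state_classify(many)) # s7p/k27 all-neg
  expect_false(st2$s5p[101])
  expect_true(all(st2$s5p[1:100]))
  w <- tryCatch(promoter_state_classify(transform(many,
                                                  overlap_s5p = FALSE)),
                warning = function(w) conditionMessage(w))
  expect_match(w, "no provisional positives")
})

test_that("isoform selection cascades through the criteria", {
  iso <- data.frame(
    gene_id = c("a", "a", "b", "b", "c", "c", "d"),
    isoform_id = c("a1", "a2", "b1", "b2", "c1", "c2", "d1"),
    s5p = c(100, 50, 10, 10, 1, 1, 5),
    s7p = c(0, 0, 30, 10, 2, 2, 5),
    length = c(1e3, 2e3, 1e3, 2e3, 5e3, 1e3, 1e3))
  sel <- select_isoform(iso, seed = 4)
  pick <- setNames(sel$isoform_id, sel$gene_id)
  expect_equal(pick[["a"]], "a1") # criterion i
  expect_equal(pick[["b"]], "b1") # criterion ii
  expect_equal(pick[["c"]], "c1") # criterion iii
  expect_equal(pick[["d"]], "d1") # single isoform
  expect_equal(sel$criterion[sel$gene_id == "d"], "single")
  # exact ties resolve deterministically under a fixed seed
  tie <- data.frame(gene_id = "t", isoform_id = c("t1", "t2"),
                    s5p = 1, s7p = 1, length = 100)
  expect_equal(select_isoform(tie, seed = 9)$isoform_id,
               select_isoform(tie, seed = 9)$isoform_id)
})

test_that("circular permutation p-values match exhaustive rotation", {
  sizes <- c(chr1 = 10)
  feat <- data.frame(chrom = "chr1", start = 2, stop = 3)
  targ <- data.frame(chrom = "chr1", start = 2, stop = 3)
  res <- circular_permutation_test(feat, targ, sizes, offset_unit = 1)
  expect_equal(res$method, "exhaustive")
  # literal enumeration of the 10 rotations
  null <- vapply(0:9, function(o) {
    s <- (2 + o) %% 10
    as.numeric(s < 3 && s + 1 > 2) # unit interval overlap after rotation
  }, 0)
  expect_equal(res$p_value, mean(null >= res$observed))
  expect_equal(res$p_value, 0.1)
  # whole-genome target: every rotation overlaps -> p = 1
  whole <- data.frame(chrom = "chr1", start = 0, stop = 10)
  expect_equal(circular_permutation_test(feat, whole, sizes)$p_value, 1)
  # sampled mode is reproducible under a fixed seed
  sizes2 <- c(chr1 = 1e6)
  feat2 <- data.frame(chrom = "chr1", start = c(100, 5000), stop =
                        c(200, 5100))
  targ2 <- data.frame(chrom = "chr1", start = 0, stop = 1000)
  r1 <- circular_permutation_test(feat2, targ2, sizes2, n_perm = 500,
                                  seed = 7, method = "sample")
  r2 <- circular_permutation_test(feat2, targ2, sizes2, n_perm = 500,
                                  seed = 7, method = "sample")
  expect_identical(r1$p_value, r2$p_value)
  expect_error(circular_permutation_test(feat2[0, ], targ2, sizes2),
               "empty")
})

test_that("regulatory contact annotation enforces marks and distance", {
  windows <- data.table::data.table(chrom = "chr1",
                                    start = (0:99) * 5e4,
                                    stop = (1:100) * 5e4)
  genes <- data.frame(gene_id = "g1", chrom = "chr1", tss = 10 * 5e4 + 100,
                      ase_class = "CAST-ASE")
  bed <- function(w) data.frame(chrom = "chr1", start = w * 5e4 + 10,
                                stop = w * 5e4 + 500)
  peaks <- list(s5p = bed(c(10, 30)), atac = bed(c(10, 30)),
                h3k27ac = bed(30))
  contacts <- data.table::data.table(i = 11L, j = 31L, phase = "cast")
  kept <- annotate_regulatory_contacts(contacts, windows, genes, peaks,
                                       mode = "EP")
  expect_equal(nrow(kept), 1)
  expect_equal(kept$configuration, "most-expressed")
  # the same contact on the s129 map is the least-expressed configuration
  kept_s <- annotate_regulatory_contacts(
    data.table::data.table(i = 11L, j = 31L, phase = "s129"),
    windows, genes, peaks, mode = "EP")
  expect_equal(kept_s$configuration, "least-expressed")
  # anchors 2.5 Mb apart are rejected on distance
  far <- data.table::data.table(i = 11L, j = 61L, phase = "cast")
  peaks_far <- list(s5p = bed(c(10, 60)), atac = bed(c(10, 60)),
                    h3k27ac = bed(60))
  expect_equal(nrow(annotate_regulatory_contacts(far, windows, genes,
                                                 peaks_far, mode = "EP")), 0)
  # enhancer anchor must carry H3K27ac
  no_ac <- list(s5p = bed(c(10, 30)), atac = bed(c(10, 30)),
                h3k27ac = bed(80))
  expect_equal(nrow(annotate_regulatory_contacts(contacts, windows, genes,
                                                 no_ac, mode = "EP")), 0)
  expect_error(annotate_regulatory_contacts(contacts, windows, genes,
                                            list(s5p = bed(10)),
                                            mode = "EP"), "missing peak")
})

test_that("CTCF loops require cohesin and convergent motifs", {
  windows <- data.table::data.table(chrom = "chr1",
                                    start = (0:99) * 5e4,
                                    stop = (1:100) * 5e4)
  bed_s <- function(w, strand) data.frame(chrom = "chr1",
                                          start = w * 5e4 + 10,
                                          stop = w * 5e4 + 40,
                                          strand = strand)
  genes <- data.frame(gene_id = character(), chrom = character(),
                      tss = numeric(), ase_class = character())
  # peaks at window offsets w land in 1-based window w + 1
  contacts <- data.table::data.table(i = 6L, j = 26L, phase = "cast")
  conv <- list(ctcf = rbind(bed_s(5, "+"), bed_s(25, "-")),
               rad21 = rbind(bed_s(5, "."), bed_s(25, ".")))
  expect_equal(nrow(annotate_regulatory_contacts(contacts, windows, genes,
                                                 conv, "CTCF-loop")), 1)
  tandem <- list(ctcf = rbind(bed_s(5, "+"), bed_s(25, "+")),
                 rad21 = conv$rad21)
  expect_equal(nrow(annotate_regulatory_contacts(contacts, windows, genes,
                                                 tandem, "CTCF-loop")), 0)
  no_rad <- list(ctcf = conv$ctcf, rad21 = bed_s(5, "."))
  expect_equal(nrow(annotate_regulatory_contacts(contacts, windows, genes,
                                                 no_rad, "CTCF-loop")), 0)
})

test_that("differential methylation calls the extreme 5% tail", {
  genes <- data.frame(gene_id = sprintf("g%03d", 1:100), chrom = "chr1",
                      tss = (1:100) * 1e4, length = 5000)
  # two CpGs per promoter, one methylated (80%) one not (20%): ratio 1
  base_cpg <- data.frame(
    chrom = "chr1",
    pos = rep((1:100) * 1e4, each = 2) + rep(c(-100, 100), 100),
    meth_pct = rep(c(80, 20), 100))
  cast <- base_cpg
  # one extreme promoter on S129: two extra methylated CpGs at gene 1
  # give meth/unmeth 3/1 -> ratio 3 vs 1 on CAST, differential +2
  s129 <- rbind(base_cpg, data.frame(chrom = "chr1", pos = c(9950, 10050),
                                     meth_pct = c(90, 95)))
  dm <- differential_methylation(cast, s129, genes)
  expect_true(dm[gene_id == "g001", called])
  expect_equal(sum(dm$called, na.rm = TRUE), 1)
  expect_equal(dm[gene_id == "g002", differential], 0)
  expect_false(dm[gene_id == "g002", called])
  # genes of length <= 2000 bp are excluded from the analysis
  short <- data.frame(gene_id = "s", chrom = "chr1", tss = 1e4,
                      length = 1500)
  expect_equal(nrow(differential_methylation(cast, s129, short)), 0)
  # promoters without covered CpGs carry a reason
  lonely <- data.frame(gene_id = "far", chrom = "chr1", tss = 5e6,
                       length = 5000)
  dm2 <- differential_methylation(cast, s129, rbind(genes, lonely))
  expect_equal(dm2[gene_id == "far", reason], "no covered CpGs")
})

test_that("cryo-FISH both-allele fraction is a plain ratio", {
  expect_equal(cryofish_allele_fraction(c(rep(2, 6), rep(1, 40))), 6 / 46)
  expect_equal(cryofish_allele_fraction(rep(2, 10)), 1)
  expect_equal(cryofish_allele_fraction(rep(1, 10)), 0)
  expect_error(cryofish_allele_fraction(integer(0)), "empty")
  expect_error(cryofish_allele_fraction(c(1, 3)), "1 or 2")
})

test_that("feature co-occurrence correlates binned peak counts", {
  sizes <- c(chr1 = 4e5) # two 200-kb bins
  in_bin <- function(b, n) data.frame(
    chrom = rep("chr1", n), start = (b - 1) * 2e5 + seq_len(n) * 10,
    stop = (b - 1) * 2e5 + seq_len(n) * 10 + 5)
  cc <- feature_cooccurrence(list(x = in_bin(1, 3), y = in_bin(1, 3)),
                             sizes)
  expect_equal(cc["x", "y"], 1)
  # disjoint bins on a two-bin toy: counts (1,0) vs (0,1) -> r = -1
  cc2 <- feature_cooccurrence(list(x = in_bin(1, 1), y = in_bin(2, 1)),
                              sizes)
  expect_equal(cc2["x", "y"], -1)
  expect_warning(cc3 <- feature_cooccurrence(
    list(x = in_bin(1, 1), empty = in_bin(1, 0)), sizes), "zero peaks")
  expect_true(is.na(cc3["x", "empty"]))
  expect_error(feature_cooccurrence(list(x = in_bin(1, 1)), sizes),
               "at least 2")
})
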