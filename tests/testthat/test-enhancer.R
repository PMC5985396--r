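# Enhancer-signature statistics.

# a track whose windows are easy to count: k reads fully inside each TSS
# window of the given genes
window_track <- function(mark, gts, k_per_gene, total_mapped, rl = 50) {
  rows <- mapply(function(tss, k, chrom) {
    if (k == 0) return(NULL)
    data.frame(chrom = chrom, start = seq(tss - 100, by = 2, length.out = k))
  }, gts$tss, k_per_gene, gts$chrom, SIMPLIFY = FALSE)
  rd <- do.call(rbind, rows)
  rd$end <- rd$start + rl
  read_track(mark, rd, total_mapped = total_mapped)
}

linc_set <- function(tss, ids = sprintf("L%02d", seq_along(tss))) {
  transcript_set(
    data.frame(transcript_id = ids, gene_id = ids, biotype = "lincRNA"),
    data.frame(transcript_id = ids, chrom = "chr1", start = tss,
               end = tss + 300, strand = "+"))
}

test_that("acetylation_ratio computes the stated pseudocounted log2 ratio", {
  lincs <- linc_set(c(5000, 50000))
  # gene 1: ac rpm 8, me3 rpm 2 -> log2(9/3); gene 2: equal marks -> 0
  ac <- window_track("H3K27ac", gene_tss(lincs), c(8, 4), total_mapped = 1e6)
  me <- window_track("H3K27me3", gene_tss(lincs), c(2, 4), total_mapped = 1e6)
  res <- acetylation_ratio(lincs, ara = "L01", nona = "L02", ac, me)
  r <- setNames(res$ratios$log2_ratio, res$ratios$gene_id)
  expect_equal(r[["L01"]], log2(9 / 3))
  expect_equal(r[["L02"]], 0)
})

test_that("one-sided KS statistic equals the brute-force ECDF sup", {
  set.seed(15)
  for (rep in 1:5) {
    x <- rnorm(40, mean = 0.5)
    y <- rnorm(60)
    got <- suppressWarnings(ks.test(x, y, alternative = "less"))
    expect_equal(unname(got$statistic), bf_ks(x, y)$Dminus)
  }
  # planted enrichment at ARA promoters is detected
  st <- generate_study(small_config(seed = 61, frac_ara = 0.4,
                                    mark_enrichment_fold = 4))
  lincs <- subset_transcripts(st$annotation, biotype = "lincRNA")
  ara <- st$truth$gene_id[st$truth$is_ara]
  nona <- st$truth$gene_id[!st$truth$is_ara]
  res <- acetylation_ratio(lincs, ara, nona, st$tracks$H3K27ac,
                           st$tracks$H3K27me3)
  expect_lt(res$p, 0.05)
  expect_gt(mean(res$ratios$log2_ratio[res$ratios$group == "ARA"]),
            mean(res$ratios$log2_ratio[res$ratios$group == "NonA"]))
})

test_that("Spearman rho equals the rank-and-Pearson oracle", {
  set.seed(16)
  for (rep in 1:5) {
    x <- rnorm(30)
    y <- 0.5 * x + rnorm(30)
    got <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = FALSE))
    expect_equal(unname(got$estimate), bf_spearman(x, y))
  }
})

test_that("stringency ladder: perfect coupling, monotone n, small-n notice", {
  tss <- seq(5000, by = 10000, length.out = 20)
  lincs <- linc_set(tss)
  gts <- gene_tss(lincs)
  pairs <- data.frame(lincrna_id = gts$gene_id,
                      pc_id = paste0("P", seq_along(tss)),
                      tss_distance = 1000, orientation = "downstream")
  set.seed(17)
  lfc <- setNames(rnorm(20), gts$gene_id)
  nbr <- setNames(unname(lfc), pairs$pc_id) # exact copy -> rho 1
  # mark levels ramp across genes so thresholds actually filter
  k <- seq(2, 40, by = 2)
  me1 <- window_track("H3K4me1", gts, k, total_mapped = 1e6)
  ac <- window_track("H3K27ac", gts, k, total_mapped = 1e6)
  lad <- stringency_correlation(pairs, lfc, nbr, lincs, me1, ac,
                                thresholds = c(5, 15, 25, 41))
  expect_equal(nrow(lad), 4)
  expect_true(all(diff(lad$n) <= 0))
  expect_equal(lad$rho[1:3], rep(1, 3))
  expect_true(is.na(lad$rho[4]))
  expect_match(lad$note[4], "fewer than")
})

test_that("rho is non-decreasing when coupling tracks enhancer strength", {
  # planted world: coupling noise shrinks with enhancer strength, and mark
  # abundance grows with it, so stricter thresholds keep better-coupled
  # pairs; averaged over seeds the ladder rises (thresholds are quantile-
  # spread because the toy genome's background RPM dwarfs the paper's 0.5-2)
  deltas <- vapply(1:6, function(seed) {
    st <- generate_study(small_config(seed = 200 + seed, n_lincrna = 300,
                                      n_pc = 300, frac_ara = 0.6,
                                      chrom_length = 2.2e7,
                                      neighbor_coupling = 0.6,
                                      coupling_noise_sd = 1.5,
                                      repress_frac = 0,
                                      reads_per_track = 4e5))
    lincs <- subset_transcripts(st$annotation, biotype = "lincRNA")
    pcs <- subset_transcripts(st$annotation, biotype = "protein_coding")
    pairs <- closest_tss(lincs, pcs)
    ara <- st$truth$gene_id[st$truth$is_ara]
    pa <- pairs[pairs$lincrna_id %in% ara, ]
    lfc <- setNames(st$truth$lfc_rna, st$truth$gene_id)
    nbr <- setNames(st$truth$neighbor_lfc_rna, st$truth$neighbor_pc)
    w <- tss_window(gene_tss(lincs)[match(pa$lincrna_id,
                                          gene_tss(lincs)$gene_id), ])
    rpm <- count_in_window(st$tracks$H3K4me1, w)
    th <- unname(quantile(rpm, c(0.1, 0.4, 0.7)))
    lad <- stringency_correlation(pa, lfc, nbr, lincs, st$tracks$H3K4me1,
                                  st$tracks$H3K27ac, thresholds = th)
    lad$rho[3] - lad$rho[1]
  }, numeric(1))
  expect_gt(mean(deltas, na.rm = TRUE), 0)
})

test_that("peak_tss_distance uses midpoints and log2(d+1)", {
  lincs <- linc_set(c(1000, 2000), ids = c("A", "B"))
  pk <- data.frame(chrom = "chr1", start = c(950, 950), end = c(1050, 1050))
  res <- peak_tss_distance(list(m = pk), lincs, ara = "A", nona = "B")
  expect_equal(res$mean_ara, 0)          # overlap -> log2(0 + 1)
  expect_equal(res$mean_nona, log2(1001)) # midpoint 1000 vs TSS 2000
  # exhaustive-scan oracle on a random instance
  set.seed(18)
  tssv <- sort(sample(1000:100000, 30))
  lincs2 <- linc_set(tssv)
  pk2 <- data.frame(chrom = "chr1", start = sample(1000:100000, 50))
  pk2$end <- pk2$start + 200
  res2 <- peak_tss_distance(list(m = pk2), lincs2,
                            ara = gene_tss(lincs2)$gene_id, nona = "L01")
  mid <- (pk2$start + pk2$end) / 2
  want <- mean(log2(vapply(mid, function(m) min(abs(tssv - m)),
                           numeric(1)) + 1))
  expect_equal(res2$mean_ara, want)
})

test_that("neighbor_response_compare filters on PolII and splits by response", {
  tssv <- seq(5000, by = 10000, length.out = 40)
  lincs <- linc_set(tssv)
  gts <- gene_tss(lincs)
  pairs <- data.frame(lincrna_id = gts$gene_id,
                      pc_id = paste0("P", seq_along(tssv)),
                      tss_distance = 1000, orientation = "downstream")
  ara <- gts$gene_id[1:20]
  nona <- gts$gene_id[21:40]
  set.seed(19)
  nbr <- setNames(c(rnorm(10, 2, .3), rnorm(10, -2, .3),
                    rnorm(10, 2, .3), rnorm(10, -2, .3)), pairs$pc_id)
  de_up <- names(nbr)[nbr > 0]
  de_down <- names(nbr)[nbr < 0]
  # PolII present everywhere except the first ARA lincRNA
  pol <- window_track("PolII", gts, c(0, rep(3, 39)), total_mapped = 1e6)
  res <- neighbor_response_compare(pairs, ara, nona, nbr, de_up, de_down,
                                   lincs, pol)
  expect_equal(res$n_ara[res$subset == "activated"] +
               res$n_ara[res$subset == "inhibited"], 19) # L01 excluded
  expect_true(all(res$n_nona == 10))
  # identical distributions -> no signal
  expect_true(all(res$p > 0.05))
  # a planted +0.5 shift for ARA activated neighbors is detected
  nbr2 <- nbr
  nbr2[pairs$pc_id[pairs$lincrna_id %in% ara]] <-
    nbr2[pairs$pc_id[pairs$lincrna_id %in% ara]] +
    ifelse(nbr2[pairs$pc_id[pairs$lincrna_id %in% ara]] > 0, 0.5, 0)
  res2 <- neighbor_response_compare(pairs, ara, nona, nbr2,
                                    names(nbr2)[nbr2 > 0],
                                    names(nbr2)[nbr2 < 0], lincs, pol)
  expect_lt(res2$p[res2$subset == "activated"], 0.05)
})
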