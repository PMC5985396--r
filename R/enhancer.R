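# Enhancer-signature statistics: the H3K27ac/H3K27me3 promoter ratio, the
# enhancer-mark stringency correlation ladder, peak-to-TSS distance
# comparisons, and neighbor-expression response comparisons.

#' Promoter acetylation ratio and group comparison
#'
#' Per lincRNA, `log2((rpm_H3K27ac + 1) / (rpm_H3K27me3 + 1))` over the
#' +/-`flank` bp TSS window (pseudocount 1 RPM), followed by a one-sided
#' two-sample Kolmogorov-Smirnov test of whether the ARA ratios are
#' stochastically larger than the NonA ratios.
#'
#' @param lincs `transcript_set` of the lincRNAs.
#' @param ara,nona gene-id groups.
#' @param k27ac,k27me3 [read_track()]s of the two marks.
#' @param flank window half-width (default 500).
#' @param pseudocount RPM pseudocount (default 1).
#' @return list with `ratios` (data.frame `gene_id`, `group`, `log2_ratio`),
#'   `ks_stat`, `p`.
#' @export
acetylation_ratio <- function(lincs, ara, nona, k27ac, k27me3, flank = 500,
                              pseudocount = 1) {
  g <- gene_tss(lincs)
  g <- g[g$gene_id %in% c(ara, nona), ]
  w <- tss_window(g, flank = flank)
  ac <- count_in_window(k27ac, w)
  me <- count_in_window(k27me3, w)
  ratios <- data.frame(
    gene_id = g$gene_id,
    group = ifelse(g$gene_id %in% ara, "ARA", "NonA"),
    log2_ratio = log2((ac + pseudocount) / (me + pseudocount)),
    stringsAsFactors = FALSE)
  a <- ratios$log2_ratio[ratios$group == "ARA"]
  b <- ratios$log2_ratio[ratios$group == "NonA"]
  # alternative = "less": the ARA ECDF lies below, i.e. ARA values are
  # stochastically larger
  ks <- suppressWarnings(ks.test(a, b, alternative = "less"))
  list(ratios = ratios, ks_stat = unname(ks$statistic), p = ks$p.value)
}

#' Enhancer-mark stringency correlation ladder
#'
#' For each RPM threshold, retains the lincRNA/neighbor pairs whose lincRNA
#' TSS carries BOTH enhancer marks (H3K4me1 and H3K27ac) above the
#' threshold, then correlates lincRNA and neighbor androgen log2 fold
#' changes (Spearman by default).
#'
#' @param pairs neighbor table ([closest_tss()]) restricted to one group.
#' @param linc_lfc,nbr_lfc named log2 fold-change vectors (by gene id) for
#'   lincRNAs / their neighbors.
#' @param lincs `transcript_set` of the lincRNAs.
#' @param k4me1,k27ac enhancer-mark [read_track()]s.
#' @param thresholds RPM cutoffs (default `c(0.5, 1, 1.5, 2)`).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param flank TSS window half-width (default 500).
#' @param min_n below this many retained pairs the correlation is reported
#'   as NA with a note (default 5).
#' @return data.frame (one rung per threshold): `threshold`, `rho`, `p`,
#'   `n`, `note`.
#' @export
stringency_correlation <- function(pairs, linc_lfc, nbr_lfc, lincs, k4me1,
                                   k27ac, thresholds = c(0.5, 1, 1.5, 2),
                                   method = "spearman", flank = 500,
                                   min_n = 5) {
  g <- gene_tss(lincs)
  g <- g[match(pairs$lincrna_id, g$gene_id), ]
  w <- tss_window(g, flank = flank)
  me1 <- count_in_window(k4me1, w)
  ac <- count_in_window(k27ac, w)
  x <- unname(linc_lfc[pairs$lincrna_id])
  y <- unname(nbr_lfc[pairs$pc_id])
  ok0 <- !is.na(x) & !is.na(y)
  out <- lapply(thresholds, function(t) {
    keep <- ok0 & me1 > t & ac > t
    n <- sum(keep)
    if (n < min_n) {
      return(data.frame(threshold = t, rho = NA_real_, p = NA_real_, n = n,
                        note = sprintf("fewer than %d pairs retained", min_n)))
    }
    ct <- suppressWarnings(cor.test(x[keep], y[keep], method = method,
                                    exact = FALSE))
    data.frame(threshold = t, rho = unname(ct$estimate), p = ct$p.value,
               n = n, note = "")
  })
  do.call(rbind, out)
}

#' Peak-to-nearest-TSS distance distributions
#'
#' Per mark and per lincRNA group, the distance from each peak midpoint to
#' the nearest group TSS on the peak's chromosome, on the `log2(d + 1)`
#' scale (overlap maps to 0); groups are compared by a two-sample t-test.
#' Peaks on chromosomes where a group has no TSS are skipped for that group.
#'
#' @param peaks_by_mark named list of peak tables (`chrom`, `start`, `end`).
#' @param lincs `transcript_set` of the lincRNAs.
#' @param ara,nona gene-id groups.
#' @return data.frame per mark: `mark`, `mean_ara`, `mean_nona`, `n_ara`,
#'   `n_nona`, `p`.
#' @export
peak_tss_distance <- function(peaks_by_mark, lincs, ara, nona) {
  g <- gene_tss(lincs)
  dist_to_group <- function(pk, ids) {
    tss <- g[g$gene_id %in% ids, ]
    unlist(lapply(unique(pk$chrom), function(ch) {
      tt <- sort(tss$tss[tss$chrom == ch])
      if (length(tt) == 0) return(numeric(0))
      mid <- (pk$start[pk$chrom == ch] + pk$end[pk$chrom == ch]) / 2
      k <- findInterval(mid, tt)
      lo <- ifelse(k >= 1, mid - tt[pmax(k, 1)], Inf)
      hi <- ifelse(k < length(tt), tt[pmin(k + 1, length(tt))] - mid, Inf)
      pmin(lo, hi)
    }), use.names = FALSE)
  }
  out <- lapply(names(peaks_by_mark), function(m) {
    pk <- as.data.frame(peaks_by_mark[[m]])
    if (nrow(pk) == 0) {
      return(data.frame(mark = m, mean_ara = NA_real_, mean_nona = NA_real_,
                        n_ara = 0L, n_nona = 0L, p = NA_real_))
    }
    da <- log2(dist_to_group(pk, ara) + 1)
    db <- log2(dist_to_group(pk, nona) + 1)
    p <- if (length(da) >= 2 && length(db) >= 2 && (sd(da) > 0 || sd(db) > 0))
      t.test(da, db)$p.value else NA_real_
    data.frame(mark = m, mean_ara = mean(da), mean_nona = mean(db),
               n_ara = length(da), n_nona = length(db), p = p)
  })
  do.call(rbind, out)
}

#' Neighbor androgen-response comparison for PolII-marked lincRNAs
#'
#' Restricts each group to lincRNAs with a Pol II signal at the TSS (a
#' significant PolII peak overlapping the +/-500 bp window when a peak set
#' is supplied, otherwise PolII RPM > 0), then compares the neighbor
#' log2(androgen/vehicle) between ARA and NonA pairs with a two-sample
#' t-test -- separately for androgen-activated and androgen-inhibited
#' neighbors.
#'
#' @param pairs neighbor table covering both groups.
#' @param ara,nona lincRNA gene-id groups.
#' @param nbr_lfc named neighbor log2 fold changes (by pc gene id).
#' @param de_up,de_down androgen-responsive pc gene-id sets.
#' @param lincs `transcript_set` of the lincRNAs.
#' @param polii PolII [read_track()].
#' @param polii_peaks optional PolII `peak_set`; when given, the TSS filter
#'   uses peak overlap instead of raw RPM.
#' @param flank TSS window half-width (default 500).
#' @return data.frame with one row per subset (`"activated"`,
#'   `"inhibited"`): group means, sizes, `p` (NA with a note when a subset
#'   is empty on either side).
#' @export
neighbor_response_compare <- function(pairs, ara, nona, nbr_lfc, de_up,
                                      de_down, lincs, polii,
                                      polii_peaks = NULL, flank = 500) {
  g <- gene_tss(lincs)
  g <- g[match(pairs$lincrna_id, g$gene_id), ]
  w <- tss_window(g, flank = flank)
  if (!is.null(polii_peaks) && nrow(polii_peaks) > 0) {
    pgr <- GenomicRanges::GRanges(polii_peaks$chrom,
             IRanges::IRanges(polii_peaks$start + 1L, polii_peaks$end))
    has_pol <- GenomicRanges::countOverlaps(windows_gr(w), pgr,
                                            minoverlap = 1L) > 0
  } else {
    has_pol <- count_in_window(polii, w) > 0
  }
  pr <- pairs[has_pol, ]
  one <- function(subset_ids, label) {
    sub <- pr[pr$pc_id %in% subset_ids, ]
    a <- unname(nbr_lfc[sub$pc_id[sub$lincrna_id %in% ara]])
    b <- unname(nbr_lfc[sub$pc_id[sub$lincrna_id %in% nona]])
    if (length(a) < 2 || length(b) < 2) {
      return(data.frame(subset = label, mean_ara = mean(a),
                        mean_nona = mean(b), n_ara = length(a),
                        n_nona = length(b), p = NA_real_,
                        note = "subset too small: no test"))
    }
    data.frame(subset = label, mean_ara = mean(a), mean_nona = mean(b),
               n_ara = length(a), n_nona = length(b),
               p = t.test(a, b)$p.value, note = "")
  }
  rbind(one(de_up, "activated"), one(de_down, "inhibited"))
}
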