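# Topologically-associating-domain profiling: TSS-based assignment, per-TAD
# peak counts with one-sided group tests, the normalized boundary-distance
# metric, and TAD-level expression comparisons.

#' Validate a TAD table
#' @noRd
check_tads <- function(tads) {
  assert_that(all(c("tad_id", "chrom", "start", "end") %in% names(tads)),
              "tads need columns tad_id, chrom, start, end")
  assert_that(all(tads$end > tads$start), "TAD with non-positive length")
  for (ch in unique(tads$chrom)) {
    b <- tads[tads$chrom == ch, ]
    b <- b[order(b$start), ]
    assert_that(all(b$start[-1] >= b$end[-nrow(b)]) || nrow(b) == 1,
                "overlapping TADs on %s", ch)
  }
  invisible(tads)
}

#' Assign genes to TADs by their TSS
#'
#' A gene is assigned to the TAD containing its gene-level TSS; TSSs falling
#' in boundary gaps stay unassigned (`NA`).
#'
#' @param ts a `transcript_set`.
#' @param tads TAD table (`tad_id`, `chrom`, `start`, `end`, non-overlapping
#'   within each chromosome).
#' @return data.frame with `gene_id`, `chrom`, `tss`, `tad_id` (NA when
#'   unassigned).
#' @export
assign_to_tads <- function(ts, tads) {
  check_tads(tads)
  g <- gene_tss(ts)
  g$tad_id <- NA_character_
  for (ch in unique(g$chrom)) {
    b <- tads[tads$chrom == ch, ]
    if (nrow(b) == 0) next
    b <- b[order(b$start), ]
    gi <- which(g$chrom == ch)
    k <- findInterval(g$tss[gi], b$start)
    ok <- k >= 1 & g$tss[gi] < b$end[pmax(k, 1)]
    g$tad_id[gi[ok]] <- b$tad_id[k[ok]]
  }
  g[c("gene_id", "chrom", "tss", "tad_id")]
}

#' Group membership profile of TADs
#'
#' Flags each TAD for whether it contains at least one ARA and/or at least
#' one NonA lincRNA locus; a TAD holding both belongs to both groups.
#'
#' @param assignment output of [assign_to_tads()] for the lincRNAs.
#' @param ara,nona lincRNA gene-id sets.
#' @param tads TAD table.
#' @return data.frame `tad_id`, `chrom`, `start`, `end`, `contains_ara`,
#'   `contains_nona`.
#' @export
tad_group_profile <- function(assignment, ara, nona, tads) {
  check_tads(tads)
  at <- assignment$tad_id[assignment$gene_id %in% ara]
  nt <- assignment$tad_id[assignment$gene_id %in% nona]
  data.frame(tads[c("tad_id", "chrom", "start", "end")],
             contains_ara = tads$tad_id %in% at[!is.na(at)],
             contains_nona = tads$tad_id %in% nt[!is.na(nt)],
             stringsAsFactors = FALSE)
}

#' Per-TAD peak counts and one-sided group tests
#'
#' Counts FDR-filtered peaks overlapping each TAD (a peak straddling a
#' boundary counts in every TAD it overlaps) and, per mark, compares
#' ARA-containing vs NonA-containing TADs by a one-sided two-sample t-test
#' (alternative: ARA greater).
#'
#' @param profile output of [tad_group_profile()].
#' @param peaks_by_mark named list of `peak_set`s (or data.frames with
#'   `chrom`, `start`, `end`).
#' @param length_normalize divide counts by TAD length in Mb (default FALSE,
#'   raw counts).
#' @return list with `counts` (matrix TAD x mark) and `tests` (data.frame
#'   `mark`, `p`, `mean_ara`, `mean_nona`, `note`).
#' @export
tad_peak_counts <- function(profile, peaks_by_mark, length_normalize = FALSE) {
  tgr <- GenomicRanges::GRanges(profile$chrom,
                                IRanges::IRanges(profile$start + 1L,
                                                 profile$end))
  counts <- vapply(peaks_by_mark, function(pk) {
    pk <- as.data.frame(pk)
    if (nrow(pk) == 0) return(numeric(nrow(profile)))
    pgr <- GenomicRanges::GRanges(pk$chrom,
                                  IRanges::IRanges(pk$start + 1L, pk$end))
    as.numeric(GenomicRanges::countOverlaps(tgr, pgr, minoverlap = 1L))
  }, numeric(nrow(profile)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = nrow(profile))
  colnames(counts) <- names(peaks_by_mark)
  rownames(counts) <- profile$tad_id
  if (length_normalize) {
    counts <- counts / ((profile$end - profile$start) / 1e6)
  }
  tests <- do.call(rbind, lapply(names(peaks_by_mark), function(m) {
    a <- counts[profile$contains_ara, m]
    b <- counts[profile$contains_nona, m]
    if (length(a) < 2 || length(b) < 2) {
      return(data.frame(mark = m, p = NA_real_, mean_ara = mean(a),
                        mean_nona = mean(b),
                        note = "skipped: < 2 TADs in a group"))
    }
    tt <- tryCatch(t.test(a, b, alternative = "greater"),
                   error = function(e) NULL)
    data.frame(mark = m, p = if (is.null(tt)) NA_real_ else tt$p.value,
               mean_ara = mean(a), mean_nona = mean(b),
               note = if (is.null(tt)) "skipped: degenerate data" else "")
  }))
  list(counts = counts, tests = tests)
}

#' Normalized distance of a TSS to its TAD boundary
#'
#' `100 * min(tss - start, end - tss) / (length / 2)`: 0% at a boundary,
#' 100% at the exact middle of the TAD.
#'
#' @param tss TSS coordinate(s), inside the TAD.
#' @param tad one TAD row (list/data.frame with `start`, `end`) recycled
#'   against `tss`, or a data.frame with one row per TSS.
#' @return numeric percent in `[0, 100]`.
#' @export
boundary_distance <- function(tss, tad) {
  start <- rep_len(tad$start, length(tss))
  end <- rep_len(tad$end, length(tss))
  assert_that(all(tss >= start & tss < end), "TSS outside its TAD")
  100 * pmin(tss - start, end - tss) / ((end - start) / 2)
}

#' TAD-level expression comparison
#'
#' Pools `log2(FPKM + 0.01)` of protein-coding genes inside ARA-containing
#' vs NonA-containing TADs (a gene whose TAD is in both groups contributes
#' to both pools) and applies a one-sided t-test (ARA greater). Expression
#' is the androgen-condition FPKM.
#'
#' @param profile output of [tad_group_profile()].
#' @param pc_assignment [assign_to_tads()] output for protein-coding genes.
#' @param fpkm table with `gene_id` and `fpkm_androgen`.
#' @return list `mean_ara`, `mean_nona`, `n_ara`, `n_nona`, `p`.
#' @export
tad_expression_compare <- function(profile, pc_assignment, fpkm) {
  x <- merge(pc_assignment, fpkm, by = "gene_id")
  x <- x[!is.na(x$tad_id), ]
  grp <- function(flag_col) {
    ids <- profile$tad_id[profile[[flag_col]]]
    log2(x$fpkm_androgen[x$tad_id %in% ids] + 0.01)
  }
  a <- grp("contains_ara")
  b <- grp("contains_nona")
  assert_that(length(a) >= 2 && length(b) >= 2,
              "need >= 2 protein-coding genes per TAD group")
  tt <- t.test(a, b, alternative = "greater")
  list(mean_ara = mean(a), mean_nona = mean(b),
       n_ara = length(a), n_nona = length(b), p = tt$p.value)
}
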