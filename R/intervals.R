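# TSS windows, window/gene counting, neighbor pairing and catalog filters.

#' TSS flanking window
#'
#' Returns the `[tss - flank, tss + flank)` window around the strand-aware
#' TSS of each transcript (or of each row of a [gene_tss()] table), clipped
#' at chromosome bounds.
#'
#' @param x a `transcript_set` or a data.frame with `chrom` and `tss`.
#' @param flank half-width in bp (default 500, i.e. a 1 kb promoter window).
#' @param chrom_length optional named vector of chromosome lengths used to
#'   clip the right edge.
#' @return data.frame with `chrom`, `start`, `end` and the id column of the
#'   input (`transcript_id` or `gene_id`).
#' @export
tss_window <- function(x, flank = 500, chrom_length = NULL) {
  assert_that(flank >= 0, "flank must be >= 0")
  tab <- if (inherits(x, "transcript_set")) x$transcripts else as.data.frame(x)
  idcol <- intersect(c("transcript_id", "gene_id"), names(tab))[1]
  start <- pmax(0, tab$tss - flank)
  end <- tab$tss + flank
  if (!is.null(chrom_length)) {
    lim <- chrom_length[tab$chrom]
    end <- pmin(end, lim)
    start <- pmin(start, end) # degenerate guard when tss beyond chrom end
  }
  out <- data.frame(chrom = tab$chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (!is.na(idcol)) out[[idcol]] <- tab[[idcol]]
  out
}

#' Normalized read count in windows
#'
#' Counts reads of a track overlapping each window by at least 1 bp and
#' normalizes to reads-per-million mapped reads (RPM):
#' `count * 1e6 / total_mapped`.
#'
#' @param track a [read_track()].
#' @param windows data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @return numeric vector of RPM values, one per window.
#' @export
count_in_window <- function(track, windows) {
  assert_that(inherits(track, "read_track"), "track must be a read_track")
  windows <- as.data.frame(windows)
  if (nrow(windows) == 0) return(numeric(0))
  # suppress the seqlevel-union warning when a window's chromosome carries
  # no reads at all (a legitimate zero)
  n <- suppressWarnings(
    GenomicRanges::countOverlaps(windows_gr(windows), reads_gr(track),
                                 minoverlap = 1L))
  as.numeric(n) * 1e6 / track$total_mapped
}

#' Exon-union gene counting
#'
#' HTSeq-style union-mode counting: a read is assigned to a gene when it
#' overlaps the exon union of that gene and of no other gene; reads touching
#' exons of two or more distinct genes are ambiguous and counted for none.
#'
#' @param reads data.frame of read intervals (`chrom`, `start`, `end`).
#' @param ts a `transcript_set` whose exons define the gene models.
#' @return named integer vector of counts, one entry per gene in `ts`.
#' @export
count_per_gene <- function(reads, ts) {
  assert_that(nrow(ts$transcripts) > 0, "empty transcript set")
  genes <- unique(ts$transcripts$gene_id)
  out <- setNames(integer(length(genes)), genes)
  if (nrow(reads) == 0) return(out)
  ex <- merge(ts$exons, ts$transcripts[c("transcript_id", "gene_id")],
              by = "transcript_id", sort = FALSE)
  rgr <- GenomicRanges::GRanges(reads$chrom,
                                IRanges::IRanges(reads$start + 1L, reads$end))
  egr <- GenomicRanges::GRanges(ex$chrom,
                                IRanges::IRanges(ex$start + 1L, ex$end))
  ov <- GenomicRanges::findOverlaps(rgr, egr, minoverlap = 1L)
  if (length(ov) == 0) return(out)
  hit_gene <- ex$gene_id[S4Vectors::subjectHits(ov)]
  by_read <- split(hit_gene, S4Vectors::queryHits(ov))
  uniq <- vapply(by_read, function(g) {
    u <- unique(g)
    if (length(u) == 1L) u else NA_character_
  }, character(1))
  uniq <- uniq[!is.na(uniq)]
  tb <- table(uniq)
  out[names(tb)] <- as.integer(tb)
  out
}

#' Closest expressed protein-coding TSS for each lincRNA
#'
#' For each lincRNA gene, finds the expressed protein-coding gene (FPKM
#' strictly above `fpkm_min` in at least one condition) whose gene-level TSS
#' minimizes the absolute TSS distance on the same chromosome. Equidistant
#' candidates are broken toward the downstream gene (larger coordinate), then
#' lexicographically by gene id. lincRNAs with no same-chromosome expressed
#' candidate yield no pair.
#'
#' @param lincs,pcs `transcript_set`s of lincRNAs / protein-coding genes. The
#'   protein-coding transcript table must carry FPKM columns (any column
#'   starting with `fpkm`).
#' @param fpkm_min expression cutoff (default 1, strict `>`).
#' @return data.frame with `lincrna_id`, `pc_id`, `tss_distance`,
#'   `orientation` (`"upstream"`/`"downstream"` of the lincRNA TSS in genome
#'   coordinates).
#' @export
closest_tss <- function(lincs, pcs, fpkm_min = 1) {
  assert_that(nrow(lincs$transcripts) > 0 && nrow(pcs$transcripts) > 0,
              "transcript sets must be non-empty")
  ltss <- gene_tss(lincs)
  ptss <- gene_tss(pcs)
  fcols <- grep("^fpkm", names(pcs$transcripts), value = TRUE)
  if (length(fcols) > 0) {
    fp <- pcs$transcripts[c("gene_id", fcols)]
    expr_gene <- unique(fp$gene_id[
      apply(as.matrix(fp[fcols]), 1, function(v) any(v > fpkm_min, na.rm = TRUE))])
    ptss <- ptss[ptss$gene_id %in% expr_gene, , drop = FALSE]
  }
  if (nrow(ptss) == 0) {
    return(data.frame(lincrna_id = character(0), pc_id = character(0),
                      tss_distance = numeric(0), orientation = character(0)))
  }
  res <- vector("list", length(unique(ltss$chrom)))
  ri <- 0L
  for (ch in unique(ltss$chrom)) {
    cand <- ptss[ptss$chrom == ch, , drop = FALSE]
    li <- ltss[ltss$chrom == ch, , drop = FALSE]
    if (nrow(cand) == 0 || nrow(li) == 0) next
    # dedupe candidates sharing a TSS position, keeping the lexicographically
    # smallest gene id (matches the stated tie-break)
    cand <- cand[order(cand$tss, cand$gene_id), , drop = FALSE]
    cand <- cand[!duplicated(cand$tss), , drop = FALSE]
    k <- findInterval(li$tss, cand$tss)
    d_left <- ifelse(k >= 1, li$tss - cand$tss[pmax(k, 1)], Inf)
    d_right <- ifelse(k < nrow(cand), cand$tss[pmin(k + 1, nrow(cand))] - li$tss,
                      Inf)
    use_right <- d_right <= d_left | d_left == 0 # ties go downstream; a
    # candidate exactly at the lincRNA TSS counts as downstream
    best <- ifelse(use_right & d_right <= d_left, pmin(k + 1, nrow(cand)),
                   pmax(k, 1))
    ri <- ri + 1L
    res[[ri]] <- data.frame(
      lincrna_id = li$gene_id, pc_id = cand$gene_id[best],
      tss_distance = pmin(d_left, d_right),
      orientation = ifelse(use_right, "downstream", "upstream"),
      stringsAsFactors = FALSE)
  }
  out <- if (ri > 0) do.call(rbind, res[seq_len(ri)]) else
    data.frame(lincrna_id = character(0), pc_id = character(0),
               tss_distance = numeric(0), orientation = character(0))
  out <- out[order(out$lincrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Catalog assembled transcripts as known or novel lincRNAs
#'
#' Mirrors a reference-guided lincRNA discovery step: transcripts already
#' annotated as lincRNAs in the reference are kept as "known" when expressed
#' (FPKM >= `fpkm_min`); assembled transcripts with no exonic overlap with
#' any reference transcript on either strand are "novel" intergenic
#' candidates, retained when expressed, at least `min_len` nt long, and
#' classified noncoding by [coding_filter()]. Everything else is excluded
#' with a reason.
#'
#' @param assembled,reference `transcript_set`s on the same assembly. The
#'   assembled transcript table must carry FPKM columns.
#' @param orf_aa optional named vector (by transcript id) of longest-ORF
#'   lengths in amino acids for the coding filter; transcripts missing from
#'   it are treated as noncoding.
#' @param fpkm_min expression floor (default 1, `>=` rule).
#' @param min_len minimum transcript length in nt (default 200, `>=` rule).
#' @param min_orf_aa coding-filter threshold passed to [coding_filter()].
#' @return data.frame with `transcript_id`, `gene_id`, `status`
#'   (`"known_lincrna"`, `"novel_lincrna"`, `"excluded"`) and `reason`.
#' @export
classify_novel_lincrnas <- function(assembled, reference, orf_aa = NULL,
                                    fpkm_min = 1, min_len = 200,
                                    min_orf_aa = 100) {
  tr <- assembled$transcripts
  fcols <- grep("^fpkm", names(tr), value = TRUE)
  assert_that(length(fcols) > 0, "assembled transcripts carry no FPKM columns")
  fpkm_ok <- apply(as.matrix(tr[fcols]), 1,
                   function(v) any(v >= fpkm_min, na.rm = TRUE))
  ref_linc <- reference$transcripts$transcript_id[
    reference$transcripts$biotype == "lincRNA"]

  # exonic overlap with any reference transcript, either strand
  agr <- GenomicRanges::GRanges(assembled$exons$chrom,
           IRanges::IRanges(assembled$exons$start + 1L, assembled$exons$end))
  rgr <- GenomicRanges::GRanges(reference$exons$chrom,
           IRanges::IRanges(reference$exons$start + 1L, reference$exons$end))
  ov <- GenomicRanges::findOverlaps(agr, rgr, minoverlap = 1L)
  overlapping_tr <- unique(assembled$exons$transcript_id[S4Vectors::queryHits(ov)])

  coding <- rep(FALSE, nrow(tr))
  if (!is.null(orf_aa)) {
    hit <- match(tr$transcript_id, names(orf_aa))
    known_orf <- !is.na(hit)
    coding[known_orf] <- coding_filter(orf_aa[hit[known_orf]],
                                       min_orf = min_orf_aa) == "coding"
  }

  status <- character(nrow(tr))
  reason <- rep("", nrow(tr))
  is_known <- tr$transcript_id %in% ref_linc
  is_intergenic <- !(tr$transcript_id %in% overlapping_tr)
  for (i in seq_len(nrow(tr))) {
    if (is_known[i]) {
      if (fpkm_ok[i]) { status[i] <- "known_lincrna" }
      else { status[i] <- "excluded"; reason[i] <- "low_fpkm" }
    } else if (!is_intergenic[i]) {
      status[i] <- "excluded"; reason[i] <- "reference_overlap"
    } else if (!fpkm_ok[i]) {
      status[i] <- "excluded"; reason[i] <- "low_fpkm"
    } else if (tr$length[i] < min_len) {
      status[i] <- "excluded"; reason[i] <- "short"
    } else if (coding[i]) {
      status[i] <- "excluded"; reason[i] <- "coding_potential"
    } else {
      status[i] <- "novel_lincrna"
    }
  }
  data.frame(transcript_id = tr$transcript_id, gene_id = tr$gene_id,
             status = status, reason = reason, stringsAsFactors = FALSE)
}

#' Longest-ORF coding filter
#'
#' A self-contained replacement for SVM-based coding-potential scoring: a
#' transcript is called coding iff its longest open reading frame (ATG to
#' stop, any of the six frames) spans at least `min_orf` codons (stop
#' excluded).
#'
#' @param x either a character vector of nucleotide sequences (IUPAC
#'   alphabet; anything else is an error) or a numeric vector of precomputed
#'   longest-ORF lengths in amino acids.
#' @param min_orf minimum ORF length in codons (default 100, `>=` rule).
#' @return character vector, `"coding"` or `"noncoding"`.
#' @export
coding_filter <- function(x, min_orf = 100) {
  if (is.numeric(x)) {
    return(ifelse(x >= min_orf, "coding", "noncoding"))
  }
  vapply(x, function(s) {
    if (longest_orf_aa(s) >= min_orf) "coding" else "noncoding"
  }, character(1), USE.NAMES = FALSE)
}

#' Longest ORF length in amino acids over six frames
#' @param seq a nucleotide sequence (character scalar, IUPAC alphabet).
#' @return integer: codons from ATG up to (excluding) the first in-frame
#'   stop; ORFs running off the transcript end without a stop also count.
#' @export
longest_orf_aa <- function(seq) {
  s <- Biostrings::DNAString(toupper(seq)) # errors on non-IUPAC symbols
  best <- 0L
  for (strand_seq in list(s, Biostrings::reverseComplement(s))) {
    ch <- strsplit(as.character(strand_seq), "")[[1]]
    n <- length(ch)
    for (off in 0:2) {
      starts <- seq.int(1 + off, n - 2, by = 3)
      if (length(starts) == 0) next
      codons <- paste0(ch[starts], ch[starts + 1], ch[starts + 2])
      is_start <- codons == "ATG"
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      open <- NA_integer_
      for (k in seq_along(codons)) {
        if (is.na(open) && is_start[k]) open <- k
        if (!is.na(open) && is_stop[k]) {
          best <- max(best, k - open)
          open <- NA_integer_
        }
      }
      if (!is.na(open)) best <- max(best, length(codons) - open + 1L)
    }
  }
  best
}
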