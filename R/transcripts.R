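# Transcript models and genomic containers.
#
# All internal coordinates are 0-based half-open ([start, end)), i.e. BED
# arithmetic. GTF I/O converts from/to the 1-based closed convention.

#' Build a transcript set
#'
#' A `transcript_set` bundles a transcript-level table with its exon table.
#' Exons of a transcript must share one chromosome and strand and be
#' non-overlapping; they are stored sorted by start. Transcript span, length
#' (sum of exon widths) and the strand-aware TSS are derived from the exons.
#'
#' The TSS is stored as a half-open boundary coordinate: the start of the
#' first exon on the plus strand, and the (exclusive) end of the last exon on
#' the minus strand. `[tss - flank, tss + flank)` is therefore centered on
#' the annotated transcription start for either strand.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `biotype` (one of `"lincRNA"`, `"protein_coding"`); optional FPKM
#'   columns (e.g. `fpkm_androgen`, `fpkm_vehicle`) are carried along.
#' @param exons data.frame with columns `transcript_id`, `chrom`, `start`,
#'   `end`, `strand` (0-based half-open coordinates, strand `+` or `-`).
#' @return An object of class `transcript_set` with elements `transcripts`
#'   (augmented with `chrom`, `strand`, `start`, `end`, `tss`, `length`,
#'   `n_exons`) and `exons`.
#' @export
transcript_set <- function(transcripts, exons) {
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  need_t <- c("transcript_id", "gene_id", "biotype")
  need_e <- c("transcript_id", "chrom", "start", "end", "strand")
  assert_that(all(need_t %in% names(transcripts)),
              "transcripts must have columns: %s", paste(need_t, collapse = ", "))
  assert_that(all(need_e %in% names(exons)),
              "exons must have columns: %s", paste(need_e, collapse = ", "))
  assert_that(!anyDuplicated(transcripts$transcript_id),
              "duplicate transcript_id in transcript table")
  assert_that(all(exons$start >= 0 & exons$start < exons$end),
              "exon invariant violated: need 0 <= start < end")
  assert_that(all(exons$strand %in% c("+", "-")),
              "unknown strand in exon table (must be '+' or '-')")
  assert_that(all(exons$transcript_id %in% transcripts$transcript_id),
              "exon table references unknown transcript_id")

  o <- order(exons$transcript_id, exons$start)
  exons <- exons[o, , drop = FALSE]
  dt <- data.table::as.data.table(exons)
  info <- dt[, list(chrom = chrom[1], strand = strand[1],
                    mixed = (data.table::uniqueN(chrom) > 1L ||
                             data.table::uniqueN(strand) > 1L),
                    overlapping = any(start[-1] < end[-.N]),
                    start = min(start), end = max(end),
                    length = sum(end - start), n_exons = .N),
            by = "transcript_id"]
  assert_that(!any(info$mixed),
              "transcript %s has exons on mixed chromosomes/strands",
              info$transcript_id[info$mixed][1])
  assert_that(!any(info$overlapping),
              "transcript %s has overlapping exons",
              info$transcript_id[info$overlapping][1])
  info[, c("mixed", "overlapping")] <- NULL
  info$tss <- ifelse(info$strand == "+", info$start, info$end)
  info <- as.data.frame(info)
  assert_that(all(transcripts$transcript_id %in% info$transcript_id),
              "transcript %s has no exons",
              setdiff(transcripts$transcript_id, info$transcript_id)[1])
  keep <- setdiff(names(transcripts),
                  c("chrom", "strand", "start", "end", "tss", "length", "n_exons"))
  merged <- merge(transcripts[keep], info, by = "transcript_id", sort = FALSE)
  merged <- merged[match(transcripts$transcript_id, merged$transcript_id), ]
  rownames(merged) <- NULL
  structure(list(transcripts = merged, exons = exons), class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  tb <- table(x$transcripts$biotype)
  cat(sprintf("transcript_set: %d transcripts (%s), %d exons\n",
              nrow(x$transcripts),
              paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
              nrow(x$exons)))
  invisible(x)
}

#' Subset a transcript set by transcript id or biotype
#' @param ts a `transcript_set`
#' @param transcript_id,biotype optional filters
#' @return a `transcript_set`
#' @export
subset_transcripts <- function(ts, transcript_id = NULL, biotype = NULL) {
  keep <- ts$transcripts$transcript_id
  if (!is.null(biotype)) {
    keep <- intersect(keep,
      ts$transcripts$transcript_id[ts$transcripts$biotype %in% biotype])
  }
  if (!is.null(transcript_id)) keep <- intersect(keep, transcript_id)
  transcript_set(ts$transcripts[ts$transcripts$transcript_id %in% keep, ],
                 ts$exons[ts$exons$transcript_id %in% keep, ])
}

# 5'-most TSS per gene (the representative promoter when several isoforms
# exist). Returns data.frame(gene_id, chrom, strand, tss).
#' Gene-level TSS table
#' @param ts a `transcript_set`
#' @return data.frame with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `tss` (5'-most transcript TSS).
#' @export
gene_tss <- function(ts) {
  dt <- data.table::as.data.table(ts$transcripts)
  out <- dt[, list(chrom = chrom[1], strand = strand[1],
                   tss = if (strand[1] == "+") min(tss) else max(tss)),
            by = "gene_id"]
  as.data.frame(out)
}

#' Epigenetic read track
#'
#' One aligned epigenetic dataset: a mark name, aligned-read intervals and the
#' total number of mapped reads used as normalization denominator.
#'
#' @param mark track name, e.g. `"H3K27ac"`.
#' @param reads data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param total_mapped total mapped reads; defaults to `nrow(reads)`.
#' @return object of class `read_track`.
#' @export
read_track <- function(mark, reads, total_mapped = nrow(reads)) {
  reads <- as.data.frame(reads, stringsAsFactors = FALSE)
  assert_that(all(c("chrom", "start", "end") %in% names(reads)),
              "reads must have columns chrom, start, end")
  assert_that(nrow(reads) > 0, "read_track '%s' has no reads", mark)
  assert_that(total_mapped >= nrow(reads),
              "total_mapped (%s) < number of reads (%d) for '%s'",
              format(total_mapped), nrow(reads), mark)
  assert_that(all(reads$start >= 0 & reads$start < reads$end),
              "read interval invariant violated in track '%s'", mark)
  structure(list(mark = mark, reads = reads,
                 total_mapped = as.numeric(total_mapped)),
            class = "read_track")
}

#' @export
print.read_track <- function(x, ...) {
  cat(sprintf("read_track '%s': %d reads (total_mapped = %s)\n",
              x$mark, nrow(x$reads), format(x$total_mapped, big.mark = ",")))
  invisible(x)
}

#' @noRd
reads_gr <- function(track) {
  GenomicRanges::GRanges(track$reads$chrom,
                         IRanges::IRanges(track$reads$start + 1L,
                                          track$reads$end))
}

#' @noRd
windows_gr <- function(w) {
  GenomicRanges::GRanges(w$chrom, IRanges::IRanges(w$start + 1L, w$end))
}
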