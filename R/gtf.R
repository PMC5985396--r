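# GTF input/output (GENCODE dialect, 1-based closed coordinates on disk).

#' Read a GTF annotation into a transcript set
#'
#' Exon records are parsed (via rtracklayer) and assembled into a
#' [transcript_set()]. GTF 1-based closed coordinates are converted to the
#' internal 0-based half-open convention. The biotype is taken from the
#' `gene_biotype`, `gene_type` or `transcript_biotype` attribute, in that
#' order of preference.
#'
#' @param path path to a GTF file.
#' @return a `transcript_set`.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  assert_that(length(gr) > 0, "no exon records in %s", path)
  md <- S4Vectors::mcols(gr)
  biotype <- NULL
  for (cand in c("gene_biotype", "gene_type", "transcript_biotype")) {
    if (cand %in% names(md)) { biotype <- as.character(md[[cand]]); break }
  }
  if (is.null(biotype)) biotype <- rep(NA_character_, length(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    stopf("unknown strand '%s' for transcript %s",
          strand[!strand %in% c("+", "-")][1],
          as.character(md$transcript_id)[!strand %in% c("+", "-")][1])
  }
  exons <- data.frame(
    transcript_id = as.character(md$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand,
    stringsAsFactors = FALSE)
  idx <- !duplicated(exons$transcript_id)
  transcripts <- data.frame(
    transcript_id = exons$transcript_id[idx],
    gene_id = as.character(md$gene_id)[idx],
    biotype = biotype[idx],
    stringsAsFactors = FALSE)
  transcript_set(transcripts, exons)
}

#' Write a transcript set as GTF
#'
#' Emits one `transcript` and one `exon` record per feature with `gene_id`,
#' `transcript_id` and `gene_biotype` attributes; internal 0-based half-open
#' coordinates are converted back to 1-based closed. `read_gtf(write_gtf(x))`
#' is the identity on the transcript/exon structure.
#'
#' @param ts a `transcript_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ts, path) {
  tr <- ts$transcripts
  ex <- ts$exons
  ex <- merge(ex, tr[c("transcript_id", "gene_id", "biotype")],
              by = "transcript_id", sort = FALSE)
  attr_str <- function(gid, tid, bt) {
    sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
            gid, tid, bt)
  }
  lines_tr <- sprintf("%s\tarasig\ttranscript\t%.0f\t%.0f\t.\t%s\t.\t%s",
                      tr$chrom, tr$start + 1, tr$end, tr$strand,
                      attr_str(tr$gene_id, tr$transcript_id, tr$biotype))
  lines_ex <- sprintf("%s\tarasig\texon\t%.0f\t%.0f\t.\t%s\t.\t%s",
                      ex$chrom, ex$start + 1, ex$end, ex$strand,
                      attr_str(ex$gene_id, ex$transcript_id, ex$biotype))
  # interleave so each transcript line precedes its exons
  ord_tr <- order(tr$chrom, tr$start)
  out <- character(0)
  ex_by_tr <- split(lines_ex, ex$transcript_id)
  out <- unlist(lapply(ord_tr, function(i) {
    c(lines_tr[i], ex_by_tr[[tr$transcript_id[i]]])
  }), use.names = FALSE)
  writeLines(out, path)
  invisible(path)
}

#' Read/write BED6 interval files
#'
#' Plain BED6 (0-based half-open) used for read tracks, peaks and TADs.
#'
#' @param path file path.
#' @return `read_bed` returns a data.frame with `chrom`, `start`, `end`,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = FALSE)
  names(df)[seq_len(min(6, ncol(df)))] <-
    c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(6, ncol(df)))]
  df
}

#' @param df data.frame with at least `chrom`, `start`, `end`; `name`,
#'   `score`, `strand` default to `"."`, `0`, `"."`.
#' @rdname read_bed
#' @export
write_bed <- function(df, path) {
  out <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = df$name %||% ".", score = df$score %||% 0,
                    strand = df$strand %||% ".")
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
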