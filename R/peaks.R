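# Local-background Poisson peak calling.
#
# Candidate peaks are local maxima of read-start density over fixed-width
# tiles; each candidate is scored against the Poisson expectation of a
# 10 kb window centered on it (excluding the candidate tile itself, floored
# at the chromosome-wide rate), and significance is controlled at FDR <
# 0.001 by Benjamini-Hochberg across candidates.

#' Call peaks against a local Poisson background
#'
#' @param track a [read_track()].
#' @param peak_width candidate tile width in bp (default 200).
#' @param bg_window local background window in bp, centered on the candidate
#'   tile (default 10000; must exceed `peak_width`).
#' @param fdr BH-adjusted significance threshold (default 0.001).
#' @param chrom_length optional named vector of chromosome lengths (defaults
#'   to the maximum read end per chromosome).
#' @return data.frame (class `peak_set`) with `chrom`, `start`, `end`,
#'   `read_count`, `local_lambda`, `p`, `padj`, sorted by position;
#'   overlapping/adjacent significant tiles are merged keeping the best p.
#'   The mark name is kept in the `"mark"` attribute.
#' @export
call_peaks <- function(track, peak_width = 200, bg_window = 10000,
                       fdr = 0.001, chrom_length = NULL) {
  assert_that(bg_window > peak_width,
              "bg_window (%d) must exceed peak_width (%d)",
              bg_window, peak_width)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), read_count = integer(0),
                      local_lambda = numeric(0), p = numeric(0),
                      padj = numeric(0))
  reads <- track$reads
  if (nrow(reads) == 0) return(structure(empty, class = c("peak_set", "data.frame"),
                                         mark = track$mark))
  cand <- list()
  for (chrom in unique(reads$chrom)) {
    starts <- sort(reads$start[reads$chrom == chrom])
    clen <- if (!is.null(chrom_length)) unname(chrom_length[chrom]) else max(
      reads$end[reads$chrom == chrom])
    ntile <- max(1L, as.integer(ceiling(clen / peak_width)))
    tile <- pmin(starts %/% peak_width, ntile - 1L) + 1L
    cnt <- tabulate(tile, nbins = ntile)
    lag <- c(0L, cnt[-ntile])
    lead <- c(cnt[-1], 0L)
    is_cand <- cnt > 0L & cnt >= lag & cnt >= lead
    idx <- which(is_cand)
    if (length(idx) == 0) next
    tile_start <- (idx - 1L) * peak_width
    center <- tile_start + peak_width / 2
    lo <- center - bg_window / 2
    hi <- center + bg_window / 2
    nbg <- findInterval(hi - 1e-9, starts) - findInterval(lo - 1e-9, starts)
    nbg <- nbg - cnt[idx]
    global_rate <- length(starts) / clen * peak_width
    lambda <- pmax(nbg * peak_width / (bg_window - peak_width), global_rate)
    p <- ppois(cnt[idx] - 1L, lambda, lower.tail = FALSE)
    cand[[chrom]] <- data.frame(chrom = chrom, start = tile_start,
                                end = pmin(tile_start + peak_width, clen),
                                read_count = cnt[idx], local_lambda = lambda,
                                p = p, stringsAsFactors = FALSE)
  }
  if (length(cand) == 0) return(structure(empty,
                                          class = c("peak_set", "data.frame"),
                                          mark = track$mark))
  cand <- do.call(rbind, cand)
  cand$padj <- bh_adjust(cand$p)
  keep <- cand[cand$padj < fdr, , drop = FALSE]
  keep <- keep[order(keep$chrom, keep$start), , drop = FALSE]
  rownames(keep) <- NULL
  # merge touching/overlapping retained tiles, keeping the best (smallest) p
  if (nrow(keep) > 1) {
    grp <- cumsum(c(TRUE, !(keep$chrom[-1] == keep$chrom[-nrow(keep)] &
                            keep$start[-1] <= keep$end[-nrow(keep)])))
    keep <- do.call(rbind, lapply(split(keep, grp), function(b) {
      best <- which.min(b$p)
      data.frame(chrom = b$chrom[1], start = min(b$start), end = max(b$end),
                 read_count = max(b$read_count),
                 local_lambda = b$local_lambda[best],
                 p = b$p[best], padj = b$padj[best],
                 stringsAsFactors = FALSE)
    }))
    rownames(keep) <- NULL
  }
  structure(keep, class = c("peak_set", "data.frame"), mark = track$mark)
}

#' Write a peak set as BED6
#'
#' Score is `-10 * log10(padj)` (capped at 10000), name is the mark.
#' @param peaks a `peak_set`.
#' @param path output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  score <- pmin(10000, round(-10 * log10(pmax(peaks$padj, 1e-300))))
  write_bed(data.frame(chrom = peaks$chrom, start = peaks$start,
                       end = peaks$end,
                       name = attr(peaks, "mark") %||% "peak",
                       score = score, strand = "."), path)
}
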