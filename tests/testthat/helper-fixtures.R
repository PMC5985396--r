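# Shared fixtures and independent brute-force oracles. Oracles deliberately
# avoid the code paths they check.

# --- tiny hand-built annotation -------------------------------------------

toy_transcripts <- function() {
  transcripts <- data.frame(
    transcript_id = c("tL1", "tL2", "tP1", "tP2"),
    gene_id = c("L1", "L2", "P1", "P2"),
    biotype = c("lincRNA", "lincRNA", "protein_coding", "protein_coding"),
    fpkm_androgen = c(2, 0.4, 5, 8),
    fpkm_vehicle = c(1, 0.2, 4, 3),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    transcript_id = c("tL1", "tL1", "tL2", "tP1", "tP1", "tP2"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(5000, 6000, 20000, 1000, 2500, 100),
    end   = c(5400, 6500, 20900, 1800, 3200, 900),
    strand = c("+", "+", "-", "+", "+", "-"),
    stringsAsFactors = FALSE)
  transcript_set(transcripts, exons)
}

# small synthetic study for integration-style unit tests
small_config <- function(seed = 1, ...) {
  args <- list(seed = seed, n_chrom = 2, chrom_length = 2e7, n_lincrna = 150,
               n_pc = 150, reads_per_track = 1e5, n_tads = 60)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(study_config, args)
}

# random uniform read track over one chromosome (pure background)
uniform_track <- function(seed, n_reads = 2e4, chrom_len = 5e6, rl = 75,
                          mark = "mark") {
  set.seed(seed)
  s <- floor(runif(n_reads, 0, chrom_len - rl))
  read_track(mark, data.frame(chrom = "chr1", start = s, end = s + rl))
}

# --- oracles ---------------------------------------------------------------

# BH step-up by the direct formula adj_(i) = min_{j >= i} p_(j) * m / j
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i)
    min(1, min(ps[i:m] * m / (i:m))), numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# exhaustive closest-TSS scan with the stated tie-breaks
bf_closest <- function(ltss, ptss) {
  res <- lapply(seq_len(nrow(ltss)), function(i) {
    cand <- ptss[ptss$chrom == ltss$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    d <- abs(cand$tss - ltss$tss[i])
    dn <- as.integer(cand$tss >= ltss$tss[i])
    o <- order(d, -dn, cand$gene_id)
    data.frame(lincrna_id = ltss$gene_id[i], pc_id = cand$gene_id[o[1]],
               tss_distance = d[o[1]],
               orientation = if (dn[o[1]] == 1) "downstream" else "upstream",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$lincrna_id), , drop = FALSE]
}

# brute-force union-mode gene counting
bf_count_per_gene <- function(reads, ts) {
  ex <- merge(ts$exons, ts$transcripts[c("transcript_id", "gene_id")],
              by = "transcript_id")
  genes <- unique(ts$transcripts$gene_id)
  out <- setNames(integer(length(genes)), genes)
  for (r in seq_len(nrow(reads))) {
    hits <- unique(ex$gene_id[ex$chrom == reads$chrom[r] &
                              ex$start < reads$end[r] &
                              ex$end > reads$start[r]])
    if (length(hits) == 1L) out[hits] <- out[hits] + 1L
  }
  out
}

# Poisson upper tail by direct summation
bf_pois_tail <- function(k, lambda, kmax = 1000) {
  sum(exp(-lambda + (k:kmax) * log(lambda) - lfactorial(k:kmax)))
}

# Spearman rho as rank-then-Pearson
bf_spearman <- function(x, y) cor(rank(x), rank(y))

# two-sample KS statistics (two-sided D, and the one-sided variant D^- =
# sup(ecdf_y - ecdf_x), which is large when x is stochastically larger)
bf_ks <- function(x, y) {
  g <- sort(unique(c(x, y)))
  fx <- vapply(g, function(t) mean(x <= t), numeric(1))
  fy <- vapply(g, function(t) mean(y <= t), numeric(1))
  list(D = max(abs(fx - fy)), Dminus = max(fy - fx))
}

# six-frame longest ORF via a regex-free re-implementation (translate every
# frame with Biostrings and scan the aa string)
bf_orf_aa <- function(seq) {
  s <- Biostrings::DNAString(seq)
  best <- 0L
  for (str in list(s, Biostrings::reverseComplement(s))) {
    for (off in 0:2) {
      sub <- Biostrings::subseq(str, off + 1,
                                off + 3 * ((length(str) - off) %/% 3))
      if (length(sub) < 3) next
      aa <- as.character(Biostrings::translate(sub, no.init.codon = TRUE))
      # ORF = run from M to just before * (or sequence end)
      chunks <- strsplit(aa, "\\*")[[1]]
      for (ck in chunks) {
        m <- regexpr("M", ck, fixed = TRUE)
        if (m > 0) best <- max(best, nchar(ck) - m + 1L)
      }
    }
  }
  best
}

# random nucleotide sequence
rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# enrichment_table stub for threshold-rule tests
stub_table <- function(gene_id, log2fc, padj, zero_num = FALSE,
                       zero_den = FALSE) {
  out <- data.frame(gene_id = gene_id, base_mean = 1, log2fc = log2fc,
                    se = 1, p = padj, padj = padj,
                    mean_num = 1, mean_den = 1,
                    zero_num = rep_len(zero_num, length(gene_id)),
                    zero_den = rep_len(zero_den, length(gene_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_table", "data.frame")
  out
}
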