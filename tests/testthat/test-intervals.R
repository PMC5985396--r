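# TSS windows, counting, neighbor pairing, catalog filters.

test_that("tss_window is strand-aware and clips at chromosome bounds", {
  tr <- data.frame(transcript_id = c("p", "m", "edge"),
                   gene_id = c("p", "m", "edge"),
                   biotype = "lincRNA")
  ex <- data.frame(transcript_id = c("p", "m", "edge"), chrom = "chr1",
                   start = c(5000, 8000, 200), end = c(5600, 9000, 400),
                   strand = c("+", "-", "+"))
  ts <- transcript_set(tr, ex)
  w <- tss_window(ts, flank = 500)
  expect_equal(w$start[w$transcript_id == "p"], 4500)
  expect_equal(w$end[w$transcript_id == "p"], 5500)
  # minus strand: window centered on the exon end boundary (9000)
  expect_equal(w$start[w$transcript_id == "m"], 8500)
  expect_equal(w$end[w$transcript_id == "m"], 9500)
  expect_equal(w$start[w$transcript_id == "edge"], 0) # clipped left
  expect_equal(w$end[w$transcript_id == "edge"], 700)
  w0 <- tss_window(ts, flank = 0)
  expect_true(all(w0$end == w0$start))
  expect_error(tss_window(ts, flank = -1), ">= 0")
})

test_that("count_in_window normalizes to reads per million", {
  reads <- data.frame(chrom = "chr1", start = seq(0, 4900, by = 100))
  reads$end <- reads$start + 75
  tr <- read_track("m", reads, total_mapped = 1e6)
  w <- data.frame(chrom = "chr1", start = 0, end = 5000)
  expect_equal(count_in_window(tr, w), 50)
  # empty region, and a 1-bp overlap counts
  expect_equal(count_in_window(tr, data.frame(chrom = "chr2", start = 0,
                                              end = 5000)), 0)
  # 1-bp overlap counts: only read [0,75) touches [74,76)
  expect_equal(count_in_window(tr, data.frame(chrom = "chr1", start = 74,
                                              end = 76)), 1)
  tr2 <- read_track("m", reads, total_mapped = 2e6)
  expect_equal(count_in_window(tr2, w), 25)
})

test_that("count_per_gene implements union-mode ambiguity rules", {
  tr <- data.frame(transcript_id = c("tA", "tB"), gene_id = c("A", "B"),
                   biotype = "protein_coding")
  ex <- data.frame(transcript_id = c("tA", "tA", "tB"), chrom = "chr1",
                   start = c(100, 300, 360), end = c(200, 400, 500),
                   strand = "+")
  ts <- transcript_set(tr, ex)
  reads <- data.frame(chrom = "chr1",
                      start = c(150, 180, 420, 1000),
                      end = c(390, 195, 450, 1050))
  # read1 touches exons of both genes -> ambiguous, counted for neither;
  # read2 inside A only; read3 inside B only; read4 intergenic
  n <- count_per_gene(reads, ts)
  expect_equal(n[["A"]], 1L)
  expect_equal(n[["B"]], 1L)
  expect_equal(unname(count_per_gene(reads[0, ], ts)), c(0L, 0L))
  # a read spanning two exons of the same gene counts once
  n2 <- count_per_gene(data.frame(chrom = "chr1", start = 150, end = 350), ts)
  expect_equal(n2[["A"]], 1L)
})

test_that("count_per_gene equals the brute-force overlap scan", {
  st <- generate_study(small_config(seed = 8, n_lincrna = 30, n_pc = 30,
                                    chrom_length = 3e6))
  set.seed(9)
  n <- 800
  reads <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                      start = floor(runif(n, 0, 3e6 - 80)))
  reads$end <- reads$start + sample(c(75, 150, 5000), n, TRUE)
  expect_equal(count_per_gene(reads, st$annotation),
               bf_count_per_gene(reads, st$annotation))
})

test_that("closest_tss matches the exhaustive scan with stated tie-breaks", {
  # hand case: nearest of {300, 1500} to TSS 1000 is 1500 (distance 500)
  mk <- function(ids, tss, biotype, strand = "+", chrom = "chr1", fpkm = 10) {
    tr <- data.frame(transcript_id = ids, gene_id = ids, biotype = biotype,
                     fpkm_androgen = fpkm, fpkm_vehicle = fpkm)
    ex <- data.frame(transcript_id = ids, chrom = chrom, start = tss,
                     end = tss + 100, strand = strand)
    transcript_set(tr, ex)
  }
  lincs <- mk("L", 1000, "lincRNA")
  pcs <- mk(c("P1", "P2"), c(300, 1500), "protein_coding")
  pr <- closest_tss(lincs, pcs)
  expect_equal(pr$pc_id, "P2")
  expect_equal(pr$tss_distance, 500)
  expect_equal(pr$orientation, "downstream")
  # equidistant: downstream wins
  pcs2 <- mk(c("P1", "P2"), c(500, 1500), "protein_coding")
  expect_equal(closest_tss(lincs, pcs2)$pc_id, "P2")
  # expression filter is strict > fpkm_min
  pcs3 <- mk(c("P1", "P2"), c(980, 1500), "protein_coding", fpkm = c(1, 5))
  expect_equal(closest_tss(lincs, pcs3)$pc_id, "P2")
  # no same-chromosome candidate -> no pair
  pcs4 <- mk("P9", 900, "protein_coding", chrom = "chr9")
  expect_equal(nrow(closest_tss(lincs, pcs4)), 0)

  # randomized equivalence with the O(n*m) oracle, including ties
  set.seed(14)
  for (rep in 1:5) {
    nl <- 40; np <- 60
    lincs_r <- mk(sprintf("L%02d", 1:nl),
                  sample(seq(0, 20000, by = 50), nl), "lincRNA",
                  chrom = sample(c("chr1", "chr2"), nl, TRUE))
    pcs_r <- mk(sprintf("P%02d", 1:np),
                sample(seq(0, 20000, by = 50), np, replace = TRUE),
                "protein_coding", chrom = sample(c("chr1", "chr2"), np, TRUE))
    got <- closest_tss(lincs_r, pcs_r)
    want <- bf_closest(gene_tss(lincs_r), gene_tss(pcs_r))
    rownames(want) <- NULL
    expect_equal(got[c("lincrna_id", "pc_id", "tss_distance")],
                 want[c("lincrna_id", "pc_id", "tss_distance")])
  }
})

test_that("classify_novel_lincrnas applies the catalog filter rules", {
  mk_tr <- function(id, start, len, biotype, fpkm, chrom = "chr1") {
    list(tr = data.frame(transcript_id = id, gene_id = id, biotype = biotype,
                         fpkm_androgen = fpkm, fpkm_vehicle = fpkm / 2),
         ex = data.frame(transcript_id = id, chrom = chrom, start = start,
                         end = start + len, strand = "+"))
  }
  parts <- list(
    mk_tr("known1", 1000, 800, "lincRNA", 3),
    mk_tr("short1", 9000, 150, "lincRNA", 5),      # novel but < 200 nt
    mk_tr("weak1", 20000, 800, "lincRNA", 0.5),    # novel but FPKM < 1
    mk_tr("ovl1", 50100, 500, "lincRNA", 4),       # overlaps reference exon
    mk_tr("coding1", 70000, 900, "lincRNA", 4),    # fails ORF filter
    mk_tr("good1", 90000, 800, "lincRNA", 4))
  assembled <- transcript_set(do.call(rbind, lapply(parts, `[[`, "tr")),
                              do.call(rbind, lapply(parts, `[[`, "ex")))
  ref <- transcript_set(
    data.frame(transcript_id = c("known1", "refpc"), gene_id = c("known1", "refpc"),
               biotype = c("lincRNA", "protein_coding")),
    data.frame(transcript_id = c("known1", "refpc"), chrom = "chr1",
               start = c(1000, 50000), end = c(1800, 50400), strand = "+"))
  cat <- classify_novel_lincrnas(assembled, ref,
                                 orf_aa = c(coding1 = 150, good1 = 30))
  st <- setNames(cat$status, cat$transcript_id)
  expect_equal(st[["known1"]], "known_lincrna")
  expect_equal(st[["short1"]], "excluded")
  expect_equal(st[["weak1"]], "excluded")
  expect_equal(st[["ovl1"]], "excluded")
  expect_equal(st[["coding1"]], "excluded")
  expect_equal(st[["good1"]], "novel_lincrna")
  expect_equal(cat$reason[cat$transcript_id == "ovl1"], "reference_overlap")
})

test_that("coding_filter agrees with a six-frame translation oracle", {
  expect_equal(coding_filter(strrep("TAA", 200)), "noncoding")
  # 400 open codons after ATG
  coding_seq <- paste0("ATG", strrep("GCT", 399), "TAA")
  expect_equal(coding_filter(coding_seq), "coding")
  expect_equal(longest_orf_aa(coding_seq), 400)
  # >= rule at exactly 100 codons
  expect_equal(coding_filter(100), "coding")
  expect_equal(coding_filter(99.9), "noncoding")
  expect_error(longest_orf_aa("ACGTXX"), regexp = ".")
  for (seed in 1:6) {
    s <- rand_seq(600, seed)
    expect_equal(longest_orf_aa(s), bf_orf_aa(s))
  }
})

test_that("planted ARA lincRNAs sit nearer protein-coding genes (KS)", {
  st <- generate_study(small_config(seed = 31, n_lincrna = 250, n_pc = 250,
                                    chrom_length = 2.5e7))
  lincs <- subset_transcripts(st$annotation, biotype = "lincRNA")
  pcs <- subset_transcripts(st$annotation, biotype = "protein_coding")
  pairs <- closest_tss(lincs, pcs)
  ara <- st$truth$gene_id[st$truth$is_ara]
  da <- pairs$tss_distance[pairs$lincrna_id %in% ara]
  db <- pairs$tss_distance[!pairs$lincrna_id %in% ara]
  ks <- suppressWarnings(ks.test(da, db, alternative = "greater"))
  expect_lt(ks$p.value, 0.05)
  expect_lt(median(da), median(db))
})
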