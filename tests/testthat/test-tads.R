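# TAD assignment, peak counting, boundary distance, expression comparison.

toy_tads <- function() {
  data.frame(tad_id = c("t1", "t2", "t3"), chrom = c("chr1", "chr1", "chr2"),
             start = c(0, 1e6, 0), end = c(1e6, 2e6, 5e5))
}

test_that("boundary_distance matches the closed form on a grid", {
  tad <- list(start = 0, end = 1000)
  expect_equal(boundary_distance(0, tad), 0)
  expect_equal(boundary_distance(500, tad), 100)
  expect_equal(boundary_distance(250, tad), 50)
  # exhaustive grid against an independent two-edge computation
  tss <- 0:999
  want <- vapply(tss, function(t) {
    d <- min(t - 0, 1000 - t)
    100 * d / 500
  }, numeric(1))
  expect_equal(boundary_distance(tss, tad), want)
  expect_error(boundary_distance(1000, tad), "outside")
  expect_error(boundary_distance(-1, tad), "outside")
})

test_that("assign_to_tads places TSSs and leaves gap genes unassigned", {
  tads <- data.frame(tad_id = c("a", "b"), chrom = "chr1",
                     start = c(0, 2000), end = c(1000, 3000)) # gap 1000..2000
  tr <- data.frame(transcript_id = c("in1", "gap", "in2", "off"),
                   gene_id = c("in1", "gap", "in2", "off"),
                   biotype = "lincRNA")
  ex <- data.frame(transcript_id = tr$transcript_id,
                   chrom = c("chr1", "chr1", "chr1", "chr9"),
                   start = c(500, 1500, 2500, 10), end = c(600, 1600, 2600, 60),
                   strand = "+")
  a <- assign_to_tads(transcript_set(tr, ex), tads)
  m <- setNames(a$tad_id, a$gene_id)
  expect_equal(m[["in1"]], "a")
  expect_true(is.na(m[["gap"]]))
  expect_equal(m[["in2"]], "b")
  expect_true(is.na(m[["off"]]))
  bad <- data.frame(tad_id = c("a", "b"), chrom = "chr1",
                    start = c(0, 500), end = c(1000, 1500))
  expect_error(assign_to_tads(transcript_set(tr, ex), bad), "overlapping")
})

test_that("a TAD holding both group members appears in both profiles", {
  tads <- toy_tads()
  assignment <- data.frame(gene_id = c("A1", "N1", "N2"), chrom = "chr1",
                           tss = c(100, 200, 1.5e6),
                           tad_id = c("t1", "t1", "t2"))
  prof <- tad_group_profile(assignment, ara = "A1", nona = c("N1", "N2"),
                            tads)
  expect_true(prof$contains_ara[prof$tad_id == "t1"])
  expect_true(prof$contains_nona[prof$tad_id == "t1"])
  expect_false(prof$contains_ara[prof$tad_id == "t2"])
})

test_that("tad_peak_counts equals brute-force intersection", {
  tads <- toy_tads()
  prof <- tad_group_profile(
    data.frame(gene_id = c("A1", "N1"), chrom = "chr1", tss = c(1, 1.5e6),
               tad_id = c("t1", "t2")),
    ara = "A1", nona = "N1", tads)
  set.seed(4)
  pk <- data.frame(chrom = sample(c("chr1", "chr2"), 400, TRUE),
                   start = floor(runif(400, 0, 2e6)))
  pk$end <- pk$start + sample(c(200, 1000, 3e5), 400, TRUE)
  res <- tad_peak_counts(prof, list(m1 = pk))
  want <- vapply(seq_len(nrow(tads)), function(i)
    sum(pk$chrom == tads$chrom[i] & pk$start < tads$end[i] &
        pk$end > tads$start[i]), numeric(1))
  expect_equal(unname(res$counts[, "m1"]), want)
  # a peak straddling the t1/t2 boundary counts in both
  straddle <- data.frame(chrom = "chr1", start = 999900, end = 1000100)
  res2 <- tad_peak_counts(prof, list(m = straddle))
  expect_equal(unname(res2$counts[c("t1", "t2"), "m"]), c(1, 1))
  expect_equal(unname(res2$counts["t3", "m"]), 0)
})

test_that("tad_peak_counts group test flags planted enrichment", {
  set.seed(6)
  n <- 40
  tads <- data.frame(tad_id = sprintf("t%02d", 1:n), chrom = "chr1",
                     start = (0:(n - 1)) * 1e5, end = (1:n) * 1e5)
  is_ara_tad <- rep(c(TRUE, FALSE), n / 2)
  assignment <- data.frame(gene_id = sprintf("g%02d", 1:n), chrom = "chr1",
                           tss = tads$start + 100, tad_id = tads$tad_id)
  prof <- tad_group_profile(assignment,
                            ara = assignment$gene_id[is_ara_tad],
                            nona = assignment$gene_id[!is_ara_tad], tads)
  mk_peaks <- function(lambda_by_tad) {
    counts <- rpois(n, lambda_by_tad)
    data.frame(chrom = "chr1",
               start = unlist(mapply(function(i, k)
                 runif(k, tads$start[i], tads$end[i] - 300), 1:n, counts,
                 SIMPLIFY = FALSE)))
  }
  enriched <- mk_peaks(ifelse(is_ara_tad, 9, 3))
  enriched$end <- enriched$start + 200
  flat <- mk_peaks(rep(4, n))
  flat$end <- flat$start + 200
  res <- tad_peak_counts(prof, list(hot = enriched, cold = flat))
  p <- setNames(res$tests$p, res$tests$mark)
  expect_lt(p[["hot"]], 0.05)
  expect_gt(p[["cold"]], 0.05)
  # a group with < 2 TADs is skipped with a notice
  prof1 <- prof
  prof1$contains_ara <- c(TRUE, rep(FALSE, n - 1))
  res1 <- tad_peak_counts(prof1, list(hot = enriched))
  expect_true(is.na(res1$tests$p))
  expect_match(res1$tests$note, "skipped")
})

test_that("tad_expression_compare pools by group and detects shifts", {
  tads <- data.frame(tad_id = c("a", "n"), chrom = "chr1",
                     start = c(0, 1e6), end = c(1e6, 2e6))
  prof <- tad_group_profile(
    data.frame(gene_id = c("L1", "L2"), chrom = "chr1", tss = c(10, 1e6 + 10),
               tad_id = c("a", "n")),
    ara = "L1", nona = "L2", tads)
  set.seed(8)
  ng <- 60
  pc_assign <- data.frame(gene_id = sprintf("p%03d", 1:(2 * ng)),
                          chrom = "chr1",
                          tss = c(runif(ng, 0, 1e6), runif(ng, 1e6, 2e6)),
                          tad_id = rep(c("a", "n"), each = ng))
  base <- rlnorm(2 * ng, log(5), 0.8)
  # identical distributions: p should hover near 0.5
  fpkm0 <- data.frame(gene_id = pc_assign$gene_id, fpkm_androgen = base)
  r0 <- tad_expression_compare(prof, pc_assign, fpkm0)
  expect_gt(r0$p, 0.05)
  # +1 log2 shift in the ARA-containing TAD
  fpkm1 <- fpkm0
  fpkm1$fpkm_androgen[1:ng] <- fpkm1$fpkm_androgen[1:ng] * 2
  r1 <- tad_expression_compare(prof, pc_assign, fpkm1)
  expect_lt(r1$p, 0.05)
  expect_gt(r1$mean_ara, r1$mean_nona)
  # a gene in a TAD belonging to both groups contributes to both pools
  prof2 <- prof
  prof2$contains_nona <- c(TRUE, TRUE)
  r2 <- tad_expression_compare(prof2, pc_assign, fpkm0)
  expect_equal(r2$n_nona, 2 * ng)
  expect_error(tad_expression_compare(prof, pc_assign[1:ng, ], fpkm0),
               ">= 2")
})
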