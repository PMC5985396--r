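# Negative-binomial enrichment / differential-expression testing.
#
# A self-contained stand-in for the DESeq2 calls of the original analysis:
# median-of-ratios normalization, a method-of-moments dispersion estimate
# shrunk toward the study-wide mean (stabilizing 2-vs-2 designs much like
# dispersion shrinkage does), a delta-method Wald test on log2 fold change,
# and Benjamini-Hochberg FDR control. The Wald statistic is referred to a t
# distribution whose degrees of freedom add the shrinkage prior's effective
# weight (8) to the residual df, which calibrates the 2-vs-2 design.
# Thresholds mirror the published rules:
# FDR < 10% with positive log2(antiAR/IgG) for AR association, q < 0.05 with
# |fold change| >= 2 for androgen response.

#' Count matrix with a two-level condition design
#'
#' @param counts integer matrix, genes x samples, with row and column names.
#' @param condition character/factor of length `ncol(counts)` with exactly
#'   two levels, each represented by at least two samples.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, condition) {
  counts <- as.matrix(counts)
  assert_that(!is.null(rownames(counts)) && !anyDuplicated(rownames(counts)),
              "counts must have unique rownames (gene ids)")
  assert_that(all(counts >= 0) && all(counts == round(counts)),
              "counts must be non-negative integers")
  condition <- as.factor(condition)
  assert_that(length(condition) == ncol(counts),
              "condition length (%d) != number of samples (%d)",
              length(condition), ncol(counts))
  assert_that(nlevels(condition) == 2L,
              "condition must have exactly two levels, got %d",
              nlevels(condition))
  assert_that(all(table(condition) >= 2L),
              "each condition level needs >= 2 samples")
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0(as.character(condition), "_",
                               ave(seq_along(condition), condition, FUN = seq_along))
  }
  structure(list(counts = counts, condition = condition),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", levels(x$condition),
                            table(x$condition)), collapse = ", ")))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (restricted to
#' genes with a positive geometric mean across samples) of the ratio of the
#' gene's count to its geometric mean.
#'
#' @param cm a [count_matrix()] or a plain genes-x-samples count matrix.
#' @return numeric vector of positive per-sample factors.
#' @export
size_factors <- function(cm) {
  k <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  lg <- rowMeans(log(k))
  use <- is.finite(lg)
  assert_that(any(use),
              "no gene has nonzero counts in every sample (conditions: %s)",
              if (inherits(cm, "count_matrix"))
                paste(levels(cm$condition), collapse = " vs ") else "unlabeled")
  f <- apply(k[use, , drop = FALSE], 2, function(col) {
    median(exp(log(col) - lg[use]))
  })
  assert_that(all(f > 0), "non-positive size factor")
  f
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in `[0, 1]` (no NAs).
#' @return adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(p) {
  assert_that(!anyNA(p), "NA/NaN p-values are not allowed")
  assert_that(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / seq(m, 1) * p[o]))[ro]
  adj
}

#' Negative-binomial Wald enrichment test
#'
#' Per gene: counts are normalized by [size_factors()]; the log2 fold change
#' is `log2((mean_num + pc) / (mean_den + pc))` with pseudocount `pc = 0.5`
#' normalized counts; the NB dispersion is estimated by method of moments and
#' shrunk toward the (5% trimmed) study-wide mean with weight
#' `df / (df + 8)` (`df` = samples minus conditions), floored at 1e-8; the
#' Wald statistic uses the delta-method standard error of the log2 fold
#' change, referred to a t distribution with `df + 8` degrees of freedom
#' (residual df plus the prior weight of the dispersion shrinkage).
#'
#' @param cm a [count_matrix()].
#' @param numerator the condition level placed in the ratio numerator.
#' @return data.frame (class `enrichment_table`) with `gene_id`,
#'   `base_mean`, `log2fc`, `se`, `p`, `padj`, plus per-group mean columns
#'   and zero-count flags used by [build_nona()].
#' @export
nb_test <- function(cm, numerator) {
  assert_that(inherits(cm, "count_matrix"), "cm must be a count_matrix")
  assert_that(numerator %in% levels(cm$condition),
              "condition level '%s' absent (levels: %s)", numerator,
              paste(levels(cm$condition), collapse = ", "))
  denominator <- setdiff(levels(cm$condition), numerator)
  sf <- size_factors(cm)
  k <- sweep(cm$counts, 2, sf, "/")
  i1 <- cm$condition == numerator
  i0 <- cm$condition == denominator
  n1 <- sum(i1); n0 <- sum(i0)
  m1 <- rowMeans(k[, i1, drop = FALSE])
  m0 <- rowMeans(k[, i0, drop = FALSE])
  pc <- 0.5
  log2fc <- log2((m1 + pc) / (m0 + pc))

  mu_g <- rowMeans(k)
  ss <- rowSums((k[, i1, drop = FALSE] - m1)^2) +
        rowSums((k[, i0, drop = FALSE] - m0)^2)
  df <- n1 + n0 - 2L
  s2 <- ss / df
  a_hat <- pmax((s2 - mu_g) / mu_g^2, 0)
  a_hat[!is.finite(a_hat)] <- 0
  w <- df / (df + 8)
  disp <- pmax(w * a_hat + (1 - w) * mean(a_hat, trim = 0.05), 1e-8)

  v1 <- (m1 + disp * m1^2) / n1
  v0 <- (m0 + disp * m0^2) / n0
  se <- sqrt(v1 / (m1 + pc)^2 + v0 / (m0 + pc)^2) / log(2)
  se <- pmax(se, 1e-12)
  z <- log2fc / se
  p <- 2 * pt(-abs(z), df = df + 8)
  # exact-null guard: a gene constant across all samples carries no evidence
  const <- apply(cm$counts, 1, function(r) length(unique(r)) == 1L)
  p[const] <- 1
  out <- data.frame(gene_id = rownames(cm$counts),
                    base_mean = mu_g, log2fc = log2fc, se = se,
                    p = p, padj = bh_adjust(p),
                    mean_num = m1, mean_den = m0,
                    zero_num = rowSums(cm$counts[, i1, drop = FALSE]) == 0,
                    zero_den = rowSums(cm$counts[, i0, drop = FALSE]) == 0,
                    stringsAsFactors = FALSE)
  attr(out, "numerator") <- numerator
  attr(out, "denominator") <- denominator
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Call AR-associated genes from a RIP enrichment table
#'
#' ARA rule: `log2fc > 0` and `padj < fdr` (FDR below 10% by default).
#'
#' @param table an `enrichment_table` from RIP counts with numerator
#'   `antiAR`.
#' @param fdr FDR threshold (default 0.10).
#' @return character vector of gene ids.
#' @export
call_ara <- function(table, fdr = 0.10) {
  table$gene_id[table$log2fc > 0 & table$padj < fdr]
}

#' Build the matched NonA control set
#'
#' Excludes genes whose read counts are zero across either condition group,
#' excludes `exclude` (typically the ARA set), sorts the remainder by
#' `|log2fc|` ascending (ties broken lexicographically by gene id) and
#' returns the first `n` -- the genes with antiAR/IgG ratio nearest zero.
#'
#' @param table an `enrichment_table` from the RIP counts.
#' @param n size of the control set (typically `length(ara)`).
#' @param exclude gene ids removed from the candidate pool.
#' @return character vector of `n` gene ids, in rank order (smallest
#'   `|log2fc|` first).
#' @export
build_nona <- function(table, n, exclude = character(0)) {
  pool <- table[!(table$zero_num | table$zero_den), , drop = FALSE]
  pool <- pool[!(pool$gene_id %in% exclude), , drop = FALSE]
  assert_that(n <= nrow(pool),
              "requested n = %d exceeds eligible pool size %d", n, nrow(pool))
  o <- order(abs(pool$log2fc), pool$gene_id)
  pool$gene_id[o][seq_len(n)]
}

#' Call androgen-responsive genes
#'
#' Differential rule: `padj < q` and `|log2fc| >= log2(fc)`.
#'
#' @param table an `enrichment_table` from RNA-seq counts with numerator
#'   `androgen`.
#' @param q adjusted-p threshold (default 0.05).
#' @param fc fold-change threshold on the natural scale (default 2).
#' @return list with character vectors `up` and `down`.
#' @export
call_differential <- function(table, q = 0.05, fc = 2) {
  sig <- table$padj < q
  list(up = table$gene_id[sig & table$log2fc >= log2(fc)],
       down = table$gene_id[sig & table$log2fc <= -log2(fc)])
}

#' Pearson correlation between the two replicates of a condition
#'
#' @param cm a [count_matrix()].
#' @param condition condition level with exactly two samples.
#' @return Pearson r of per-gene counts between the replicates.
#' @export
replicate_correlation <- function(cm, condition) {
  idx <- which(cm$condition == condition)
  assert_that(length(idx) == 2L,
              "condition '%s' has %d samples; need exactly 2",
              condition, length(idx))
  x <- cm$counts[, idx[1]]
  y <- cm$counts[, idx[2]]
  assert_that(sd(x) > 0 && sd(y) > 0,
              "zero-variance replicate in condition '%s'", condition)
  cor(x, y)
}
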