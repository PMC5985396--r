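# TSS-window epigenetic feature encoding and random-forest discrimination of
# ARA- vs NonA-lincRNA loci, with a label-shuffle empirical null on the Gini
# importances.

#' Encode TSS-window features for labeled lincRNA/neighbor pairs
#'
#' For each labeled lincRNA with a neighbor pair, builds a vector of
#' normalized (RPM) read counts of every track in the +/-`flank` bp window
#' around the lincRNA TSS and around the neighbor protein-coding TSS.
#' Columns are named `<mark>@linc` (all tracks, input order) followed by
#' `<mark>@pc`. lincRNAs without a neighbor pair are omitted (with a
#' warning and a count in the `dropped` field).
#'
#' @param pairs neighbor table from [closest_tss()].
#' @param lincs,pcs `transcript_set`s supplying gene-level TSS coordinates.
#' @param tracks list of [read_track()]s (non-empty reads each).
#' @param labels named character vector, `"ARA"`/`"NonA"` by lincRNA gene
#'   id; only labeled lincRNAs become rows.
#' @param flank TSS window half-width in bp (default 500).
#' @return object of class `feature_matrix`: list with `x` (numeric matrix,
#'   rownames = lincRNA ids), `labels` (factor ARA/NonA), `dropped` (number
#'   of labeled lincRNAs without a pair).
#' @export
encode_features <- function(pairs, lincs, pcs, tracks, labels, flank = 500) {
  assert_that(length(tracks) > 0, "need at least one track")
  assert_that(all(labels %in% c("ARA", "NonA")),
              "labels must be 'ARA' or 'NonA'")
  ids <- names(labels)
  paired <- ids[ids %in% pairs$lincrna_id]
  dropped <- length(ids) - length(paired)
  if (dropped > 0) {
    warning(sprintf("%d labeled lincRNA(s) without a neighbor pair omitted",
                    dropped))
  }
  assert_that(length(paired) > 0, "no labeled lincRNA has a neighbor pair")
  pr <- pairs[match(paired, pairs$lincrna_id), ]
  ltss <- gene_tss(lincs)
  ptss <- gene_tss(pcs)
  lw <- tss_window(ltss[match(pr$lincrna_id, ltss$gene_id), ], flank = flank)
  pw <- tss_window(ptss[match(pr$pc_id, ptss$gene_id), ], flank = flank)
  marks <- vapply(tracks, function(t) t$mark, character(1))
  xl <- vapply(tracks, function(t) count_in_window(t, lw),
               numeric(nrow(lw)))
  xp <- vapply(tracks, function(t) count_in_window(t, pw),
               numeric(nrow(pw)))
  if (length(paired) == 1L) { xl <- rbind(xl); xp <- rbind(xp) }
  x <- cbind(xl, xp)
  colnames(x) <- c(paste0(marks, "@linc"), paste0(marks, "@pc"))
  rownames(x) <- paired
  structure(list(x = x,
                 labels = factor(labels[paired], levels = c("NonA", "ARA")),
                 dropped = dropped),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d rows (%s) x %d features, %d dropped\n",
              nrow(x$x),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", "),
              ncol(x$x), x$dropped))
  invisible(x)
}

#' @noRd
rf_call <- function(x, y01, grid, mtry, seed, xtest = NULL) {
  .rf_forest(x, as.integer(y01), as.integer(grid), as.integer(mtry),
             as.numeric(seed), xtest)
}

#' Train the ARA/NonA random-forest discriminator
#'
#' For each candidate ensemble size in `tree_grid`, the forest is grown with
#' warm starts (trees are shared across grid points), Gini splitting and
#' out-of-bag scoring. The mean accuracy of each grid size is measured by
#' stratified k-fold cross-validation; the size maximizing CV accuracy
#' (smallest on ties) is selected, and importances come from a refit on all
#' rows at the chosen size.
#'
#' @param fm a [encode_features()] matrix.
#' @param tree_grid increasing ensemble sizes (default
#'   `c(100, 500, 1000, 10000)`).
#' @param folds number of CV folds (default 5).
#' @param seed integer seed; the whole procedure is deterministic given it.
#' @param mtry features tried per split; default `floor(sqrt(ncol))`.
#' @return object of class `model_report`: `tree_grid`, `cv_accuracy` (one
#'   mean per grid size), `chosen_trees`, `oob_score`, `importances` (named,
#'   summing to 1), `folds`, `seed`.
#' @export
train_classifier <- function(fm, tree_grid = c(100, 500, 1000, 10000),
                             folds = 5, seed = 1, mtry = NULL) {
  x <- fm$x
  y <- fm$labels
  assert_that(nlevels(droplevels(y)) == 2L,
              "both classes must be present in the training labels")
  assert_that(all(table(y) >= folds),
              "need >= %d rows per class for %d-fold CV", folds, folds)
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(x))))
  y01 <- as.integer(y == "ARA")

  old <- local_seed(substream_seed(seed, "cv_folds"))
  on.exit(restore_seed(old), add = TRUE)
  fold <- stratified_folds(as.character(y), folds)

  acc <- matrix(NA_real_, folds, length(tree_grid))
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- rf_call(x[tr, , drop = FALSE], y01[tr], tree_grid, mtry,
                   substream_seed(seed, paste0("fold", f)),
                   x[!tr, , drop = FALSE])
    pred <- fit$votes_test > 0.5
    acc[f, ] <- colMeans(pred == matrix(y01[!tr] == 1L, sum(!tr),
                                        length(tree_grid)))
  }
  cv_accuracy <- colMeans(acc)
  chosen <- tree_grid[which.max(cv_accuracy)]
  final <- rf_call(x, y01, sort(unique(c(tree_grid[tree_grid <= chosen], chosen))),
                   mtry, substream_seed(seed, "final"))
  gi <- length(final$oob)
  importances <- setNames(final$importance[, gi], colnames(x))
  structure(list(tree_grid = tree_grid, cv_accuracy = cv_accuracy,
                 chosen_trees = chosen, oob_score = final$oob[gi],
                 importances = importances, folds = folds, seed = seed,
                 mtry = mtry),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat("random-forest model report\n")
  cat(sprintf("  grid: %s trees; chosen: %d (CV accuracy %.3f, OOB %.3f)\n",
              paste(x$tree_grid, collapse = "/"), x$chosen_trees,
              max(x$cv_accuracy), x$oob_score))
  top <- head(sort(x$importances, decreasing = TRUE), 3)
  cat(sprintf("  top features: %s\n",
              paste(sprintf("%s (%.3f)", names(top), top), collapse = ", ")))
  invisible(x)
}

#' Label-shuffle null distribution of Gini importances
#'
#' Shuffles the ARA/NonA labels `n_shuffles` times; for each shuffle a fresh
#' forest of `trees` trees is trained and all feature importances recorded.
#'
#' @param fm a [encode_features()] matrix.
#' @param n_shuffles number of label permutations (1000 in the full
#'   procedure; below 100 triggers a cutoff-instability warning).
#' @param trees ensemble size per shuffle (typically the chosen size from
#'   [train_classifier()]).
#' @param seed integer seed.
#' @param mtry features tried per split; default `floor(sqrt(ncol))`.
#' @return numeric matrix, `n_shuffles` x n_features (each row sums to 1).
#' @export
importance_null <- function(fm, n_shuffles = 1000, trees = 500, seed = 1,
                            mtry = NULL) {
  if (n_shuffles < 100) {
    warning("fewer than 100 shuffles: the 95% null cutoff will be unstable")
  }
  x <- fm$x
  y01 <- as.integer(fm$labels == "ARA")
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(x))))
  out <- matrix(NA_real_, n_shuffles, ncol(x),
                dimnames = list(NULL, colnames(x)))
  old <- local_seed(substream_seed(seed, "shuffle_perm"))
  on.exit(restore_seed(old), add = TRUE)
  for (b in seq_len(n_shuffles)) {
    yb <- y01[sample(length(y01))]
    fit <- rf_call(x, yb, trees, mtry, substream_seed(seed, paste0("shuf", b)))
    out[b, ] <- fit$importance[, 1]
  }
  out
}

#' Flag features whose importance exceeds the shuffled-label null
#'
#' The per-feature cutoff is the `ci`-th percentile of that feature's null
#' sample; a feature is significant iff its observed Gini importance is
#' strictly greater. The enrichment direction is the sign of (mean feature
#' value in ARA rows - mean in NonA rows): `"up"` means more abundant at the
#' ARA TSS.
#'
#' @param report a [train_classifier()] report.
#' @param null matrix from [importance_null()] covering every feature.
#' @param ci percentile for the cutoff (default 95).
#' @param fm the [encode_features()] matrix (for directions).
#' @return data.frame (class `importance_report`) with `feature`, `gini`,
#'   `null_cutoff`, `significant`, `direction`, `rank`, sorted by descending
#'   importance.
#' @export
significant_features <- function(report, null, ci = 95, fm) {
  gi <- report$importances
  assert_that(all(names(gi) %in% colnames(null)),
              "null matrix does not cover every feature")
  cutoff <- apply(null[, names(gi), drop = FALSE], 2, quantile,
                  probs = ci / 100, names = FALSE, type = 7)
  ara <- fm$labels == "ARA"
  dmean <- colMeans(fm$x[ara, , drop = FALSE]) -
           colMeans(fm$x[!ara, , drop = FALSE])
  out <- data.frame(feature = names(gi), gini = unname(gi),
                    null_cutoff = unname(cutoff),
                    significant = unname(gi > cutoff),
                    direction = ifelse(dmean[names(gi)] >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$gini, out$feature), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("importance_report", "data.frame")
  out
}

# save/restore the global RNG state so exported functions are deterministic
# under their own seed without clobbering the caller's stream
#' @noRd
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

#' @noRd
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
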