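# Orchestration: run every stage in order on a synthetic (or loaded) study
# and assemble one structured report. Also owns the response-subset
# bookkeeping used for the two discrimination runs (activated-neighbor and
# inhibited-neighbor).

#' Partition ARA/NonA lincRNAs by their neighbor's androgen response
#'
#' `ara_up` are the ARA lincRNAs that are themselves androgen-activated;
#' they are sub-divided by whether their closest protein-coding neighbor is
#' androgen-activated (`ara_up_nbr_up`) or androgen-inhibited
#' (`ara_up_nbr_down`); lincRNAs with a non-responsive neighbor fall in
#' neither subset. Matched NonA subsets satisfy the same conditions and are
#' taken in the [build_nona()] ranking order (lowest |log2(antiAR/IgG)|
#' first), truncated to the ARA subset size when the pool permits.
#'
#' @param ara ARA gene ids.
#' @param nona NonA gene ids in [build_nona()] rank order.
#' @param de list with `up` and `down` gene-id sets (lincRNAs and pc genes).
#' @param pairs neighbor table from [closest_tss()].
#' @return list of class `response_subsets` with `ara_up`, `ara_up_nbr_up`,
#'   `ara_up_nbr_down`, `nona_up`, `nona_up_nbr_up`, `nona_up_nbr_down`.
#' @export
subset_by_response <- function(ara, nona, de, pairs) {
  nbr <- setNames(pairs$pc_id, pairs$lincrna_id)
  split_group <- function(ids) {
    up <- ids[ids %in% de$up]
    nb <- nbr[up]
    list(up = up,
         nbr_up = up[!is.na(nb) & nb %in% de$up],
         nbr_down = up[!is.na(nb) & nb %in% de$down])
  }
  a <- split_group(ara)
  n <- split_group(nona) # preserves nona rank order
  structure(list(ara_up = a$up,
                 ara_up_nbr_up = a$nbr_up,
                 ara_up_nbr_down = a$nbr_down,
                 nona_up = n$up,
                 nona_up_nbr_up = head(n$nbr_up, length(a$nbr_up)),
                 nona_up_nbr_down = head(n$nbr_down, length(a$nbr_down))),
            class = "response_subsets")
}

#' Run the full analysis on a study
#'
#' Executes, in order: lincRNA cataloguing, RNA-seq differential calling,
#' RIP-seq ARA calling, NonA control construction, closest-TSS neighbor
#' pairing, per-track peak calling, TSS feature encoding, the two
#' random-forest discrimination runs (activated-neighbor and
#' inhibited-neighbor) with their shuffled-label importance nulls, TAD
#' profiling and the enhancer-signature statistics. Deterministic under
#' `seed` (which defaults to the study config's seed).
#'
#' @param study a [generate_study()] result, a [study_config()] (the study
#'   is generated first), or a directory written by [write_study()].
#' @param out_dir optional directory; when given, tables of every stage are
#'   written there as TSV/BED/JSON.
#' @param seed root seed for classifier training and nulls.
#' @param tree_grid,folds,n_shuffles random-forest settings (paper-scale
#'   defaults; scale `n_shuffles` down for quick runs).
#' @param rip_fdr,de_q,de_fc calling thresholds.
#' @param peak_fdr peak-calling FDR threshold.
#' @param min_rows_per_class a discrimination run is skipped (with a notice
#'   in the report) when either class has fewer labeled rows than this.
#' @return a list of class `arasig_report`.
#' @export
run_study <- function(study, out_dir = NULL, seed = NULL,
                      tree_grid = c(100, 500, 1000, 10000), folds = 5,
                      n_shuffles = 1000, rip_fdr = 0.10, de_q = 0.05,
                      de_fc = 2, peak_fdr = 0.001, min_rows_per_class = 10) {
  if (inherits(study, "study_config")) study <- generate_study(study)
  if (is.character(study)) study <- read_study(study)
  seed <- seed %||% study$config$seed %||% 1L
  notices <- character(0)
  note <- function(msg) notices <<- c(notices, msg)

  lincs <- subset_transcripts(study$annotation, biotype = "lincRNA")
  pcs <- subset_transcripts(study$annotation, biotype = "protein_coding")

  ## catalog
  ref_ids <- c(pcs$transcripts$transcript_id,
               if (!is.null(study$truth))
                 paste0(study$truth$gene_id[study$truth$in_reference], ".t1"))
  reference <- subset_transcripts(study$annotation, transcript_id = ref_ids)
  orf <- if (!is.null(study$truth))
    setNames(study$truth$max_orf_aa, paste0(study$truth$gene_id, ".t1"))
  catalog <- classify_novel_lincrnas(lincs, reference, orf_aa = orf)

  ## differential expression (androgen vs vehicle)
  de_table <- nb_test(study$rnaseq_counts, numerator = "androgen")
  de <- call_differential(de_table, q = de_q, fc = de_fc)

  ## RIP enrichment (antiAR vs IgG) and group construction
  rip_table <- nb_test(study$rip_counts, numerator = "antiAR")
  ara <- call_ara(rip_table, fdr = rip_fdr)
  nona <- build_nona(rip_table, n = min(length(ara),
                                        sum(!(rip_table$zero_num |
                                              rip_table$zero_den |
                                              rip_table$gene_id %in% ara))),
                     exclude = ara)
  if (length(nona) < length(ara)) note("NonA pool smaller than ARA set")

  ## neighbors
  pairs <- closest_tss(lincs, pcs, fpkm_min = 1)

  ## peaks
  peaks <- lapply(study$tracks, call_peaks, fdr = peak_fdr,
                  chrom_length = study$chrom_length)

  ## feature encoding + the two discrimination runs
  lfc_all <- setNames(de_table$log2fc, de_table$gene_id)
  subsets <- subset_by_response(ara, nona, de, pairs)
  run_one <- function(ara_ids, nona_ids, label) {
    labels <- c(setNames(rep("ARA", length(ara_ids)), ara_ids),
                setNames(rep("NonA", length(nona_ids)), nona_ids))
    labels <- labels[names(labels) %in% pairs$lincrna_id]
    if (sum(labels == "ARA") < min_rows_per_class ||
        sum(labels == "NonA") < min_rows_per_class) {
      note(sprintf("discrimination run '%s' skipped: %d ARA / %d NonA rows",
                   label, sum(labels == "ARA"), sum(labels == "NonA")))
      return(NULL)
    }
    fm <- encode_features(pairs, lincs, pcs, study$tracks, labels)
    model <- train_classifier(fm, tree_grid = tree_grid, folds = folds,
                              seed = substream_seed(seed, paste0("train_", label)))
    null <- withCallingHandlers(
      importance_null(fm, n_shuffles = n_shuffles,
                      trees = model$chosen_trees,
                      seed = substream_seed(seed, paste0("null_", label))),
      warning = function(w) {
        note(sprintf("run '%s': %s", label, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    list(label = label, feature_matrix = fm, model = model,
         importance = significant_features(model, null, fm = fm))
  }
  run_act <- run_one(subsets$ara_up_nbr_up, subsets$nona_up_nbr_up,
                     "activated_neighbor")
  run_inh <- run_one(subsets$ara_up_nbr_down, subsets$nona_up_nbr_down,
                     "inhibited_neighbor")

  ## TADs
  linc_assign <- assign_to_tads(lincs, study$tads)
  pc_assign <- assign_to_tads(pcs, study$tads)
  profile <- tad_group_profile(linc_assign, ara, nona, study$tads)
  tad_peaks <- tad_peak_counts(profile, peaks)
  tad_expr <- tryCatch(
    tad_expression_compare(profile, pc_assign, study$fpkm),
    error = function(e) { note(paste("TAD expression:", conditionMessage(e)))
                          NULL })
  bd <- boundary_dist_by_group(linc_assign, study$tads, ara, nona)

  ## enhancer statistics
  track <- function(m) study$tracks[[m]]
  enh <- list()
  if (!is.null(track("H3K27ac")) && !is.null(track("H3K27me3"))) {
    enh$acetylation <- acetylation_ratio(lincs, ara, nona,
                                         track("H3K27ac"), track("H3K27me3"))
  } else note("acetylation ratio skipped: H3K27ac/H3K27me3 track missing")
  if (!is.null(track("H3K4me1")) && !is.null(track("H3K27ac"))) {
    enh$ladder <- list(
      ARA = stringency_correlation(pairs[pairs$lincrna_id %in% ara, ],
                                   lfc_all, lfc_all, lincs,
                                   track("H3K4me1"), track("H3K27ac")),
      NonA = stringency_correlation(pairs[pairs$lincrna_id %in% nona, ],
                                    lfc_all, lfc_all, lincs,
                                    track("H3K4me1"), track("H3K27ac")))
  } else note("stringency ladder skipped: enhancer track missing")
  enh$peak_tss <- peak_tss_distance(peaks, lincs, ara, nona)
  if (!is.null(track("PolII"))) {
    # at toy scale the PolII peak set covers only the strongest promoters,
    # so the raw-RPM fallback is used as the TSS filter
    enh$neighbor_response <- neighbor_response_compare(
      pairs, ara, nona, lfc_all, de$up, de$down, lincs, track("PolII"))
  } else note("neighbor response skipped: PolII track missing")

  report <- structure(list(
    catalog = catalog,
    catalog_summary = table(catalog$status),
    de_table = de_table, de = de,
    de_summary = c(up = length(de$up), down = length(de$down)),
    rip_table = rip_table, ara = ara, nona = nona,
    set_sizes = c(ara = length(ara), nona = length(nona)),
    pairs = pairs, peaks = peaks,
    subsets = subsets,
    runs = Filter(Negate(is.null), list(activated_neighbor = run_act,
                                        inhibited_neighbor = run_inh)),
    tad = list(profile = profile, peak_tests = tad_peaks$tests,
               peak_counts = tad_peaks$counts, expression = tad_expr,
               boundary = bd),
    enhancer = enh,
    notices = notices,
    provenance = list(seed = seed, config = study$config,
                      n_shuffles = n_shuffles, tree_grid = tree_grid,
                      package_version = as.character(utils::packageVersion("arasig")),
                      timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
    class = "arasig_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Boundary-distance metric per lincRNA group, with a one-sided t-test for
# ARA TSSs sitting closer to TAD boundaries (smaller percent).
#' @noRd
boundary_dist_by_group <- function(assignment, tads, ara, nona) {
  x <- assignment[!is.na(assignment$tad_id), ]
  ti <- match(x$tad_id, tads$tad_id)
  x$bdist <- boundary_distance(x$tss, tads[ti, ])
  a <- x$bdist[x$gene_id %in% ara]
  b <- x$bdist[x$gene_id %in% nona]
  p <- if (length(a) >= 2 && length(b) >= 2)
    t.test(a, b, alternative = "less")$p.value else NA_real_
  list(per_gene = x[c("gene_id", "tad_id", "bdist")],
       mean_ara = mean(a), mean_nona = mean(b),
       n_ara = length(a), n_nona = length(b), p = p)
}

#' @export
print.arasig_report <- function(x, ...) {
  cat("arasig analysis report\n")
  cat(sprintf("  catalog: %s\n",
              paste(sprintf("%s=%d", names(x$catalog_summary),
                            x$catalog_summary), collapse = ", ")))
  cat(sprintf("  DE: %d up, %d down | ARA: %d, NonA: %d\n",
              x$de_summary["up"], x$de_summary["down"],
              x$set_sizes["ara"], x$set_sizes["nona"]))
  for (r in x$runs) {
    sig <- r$importance$feature[r$importance$significant]
    cat(sprintf("  run '%s': CV accuracy %.3f (%d trees); significant: %s\n",
                r$label, max(r$model$cv_accuracy), r$model$chosen_trees,
                if (length(sig)) paste(sig, collapse = ", ") else "none"))
  }
  if (!is.null(x$tad$expression)) {
    cat(sprintf("  TAD expression p = %.3g; boundary proximity p = %.3g\n",
                x$tad$expression$p, x$tad$boundary$p))
  }
  if (!is.null(x$enhancer$acetylation)) {
    cat(sprintf("  H3K27ac/H3K27me3 ratio KS p = %.3g\n",
                x$enhancer$acetylation$p))
  }
  if (length(x$notices)) {
    cat("  notices:\n")
    for (n in x$notices) cat("   -", n, "\n")
  }
  invisible(x)
}

#' Write the tables of a report to a directory
#' @param report an `arasig_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) data.table::fwrite(as.data.frame(df),
                                             file.path(dir, name), sep = "\t")
  w(report$catalog, "catalog.tsv")
  w(report$de_table, "de_table.tsv")
  w(report$rip_table, "rip_table.tsv")
  w(data.frame(gene_id = report$ara), "ara.tsv")
  w(data.frame(gene_id = report$nona), "nona.tsv")
  w(report$pairs, "neighbors.tsv")
  for (m in names(report$peaks)) {
    if (nrow(report$peaks[[m]]) > 0)
      write_peaks_bed(report$peaks[[m]], file.path(dir, paste0("peaks_", m, ".bed")))
  }
  for (r in report$runs) {
    w(r$importance, paste0("importance_", r$label, ".tsv"))
  }
  w(report$tad$peak_tests, "tad_peak_tests.tsv")
  w(report$tad$boundary$per_gene, "tad_boundary.tsv")
  if (!is.null(report$enhancer$acetylation))
    w(report$enhancer$acetylation$ratios, "acetylation_ratios.tsv")
  if (!is.null(report$enhancer$ladder)) {
    w(cbind(group = "ARA", report$enhancer$ladder$ARA), "ladder_ara.tsv")
    w(cbind(group = "NonA", report$enhancer$ladder$NonA), "ladder_nona.tsv")
  }
  w(report$enhancer$peak_tss, "peak_tss_distance.tsv")
  if (!is.null(report$enhancer$neighbor_response))
    w(report$enhancer$neighbor_response, "neighbor_response.tsv")
  summary <- list(
    set_sizes = as.list(report$set_sizes),
    de_summary = as.list(report$de_summary),
    catalog_summary = as.list(report$catalog_summary),
    runs = lapply(report$runs, function(r) list(
      label = r$label, chosen_trees = r$model$chosen_trees,
      cv_accuracy = max(r$model$cv_accuracy), oob = r$model$oob_score)),
    notices = report$notices,
    provenance = report$provenance[c("seed", "n_shuffles", "tree_grid",
                                     "package_version", "timestamp")])
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
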