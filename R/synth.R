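# Synthetic study generator.
#
# Emulates the statistical structure the downstream analyses assume real
# LNCaP data to have: negative-binomial RIP-seq counts with a planted
# AR-associated lincRNA subset, RNA-seq counts with planted androgen fold
# changes that are copied in cis to designated protein-coding neighbors,
# fixed-length epigenetic read tracks with Poisson pileups at chosen TSSs,
# lincRNA loci kept intergenic by construction and placed nearer
# protein-coding genes when planted, and TAD partitions whose boundaries are
# attracted to planted lincRNA TSSs. Every planted quantity is recorded in a
# truth table so each pipeline stage has a parameter-recovery oracle.

MARK_NAMES <- c("H3K27ac", "H3K27me3", "H3K4me1", "PolII",
                "H3K4me2", "H4K5ac", "DNaseI", "H2A.Z")

#' Configuration of a synthetic study
#'
#' Defaults describe the package's reference study: 1000 lincRNAs on a
#' 4 x 45 Mb toy genome, 20% of them planted as AR-associated with a mean
#' RIP log2(antiAR/IgG) of 2, four epigenetic tracks (H3K27ac, H3K27me3,
#' H3K4me1, PolII) with fold-5 pileups at planted TSSs, and cis coupling of
#' androgen fold changes to the designated neighbor for 70% of planted
#' lincRNAs.
#'
#' @param seed integer; the study is byte-identical under a fixed seed.
#' @param n_chrom,chrom_length chromosome count and length (bp).
#' @param n_lincrna,n_pc number of lincRNA / protein-coding genes.
#' @param n_marks number of epigenetic tracks (1..8, named from a fixed
#'   catalog starting H3K27ac, H3K27me3, H3K4me1, PolII).
#' @param frac_ara fraction of lincRNAs planted as AR-associated.
#' @param rip_log2fc_mean planted mean RIP log2(antiAR/IgG) (log2 units).
#' @param rnaseq_log2fc_sd sd of planted androgen log2 fold changes.
#' @param nb_dispersion NB dispersion of all count matrices (> 0).
#' @param mark_enrichment_fold TSS pileup fold at planted loci (>= 1; 1
#'   plants nothing).
#' @param reads_per_track background reads per epigenetic track.
#' @param n_tads target TAD count per chromosome.
#' @param neighbor_coupling probability that a planted lincRNA's androgen
#'   fold change is copied (with noise) to its designated neighbor.
#' @param coupling_noise_sd sd of the copy noise at enhancer strength 0.5
#'   (noise shrinks linearly to `0.5 * coupling_noise_sd` at strength 1).
#' @param repress_frac probability that a copied fold change is
#'   sign-flipped (androgen-repressive cis regulation).
#' @param cis_boost extra log2 activation added to coupled, non-flipped
#'   neighbor fold changes (the enhanced androgen response of
#'   protein-coding genes next to AR-associated lincRNAs).
#' @param read_length track read length in bp (fixed-length intervals).
#' @param min_gene_gap minimum distance between a lincRNA locus and any
#'   protein-coding locus (bp).
#' @param min_tad_length minimum TAD length (bp).
#' @return validated list of class `study_config`.
#' @export
study_config <- function(seed = 1, n_chrom = 4, chrom_length = 4.5e7,
                         n_lincrna = 1000, n_pc = 1000, n_marks = 4,
                         frac_ara = 0.2, rip_log2fc_mean = 2,
                         rnaseq_log2fc_sd = 0.5, nb_dispersion = 0.05,
                         mark_enrichment_fold = 5, reads_per_track = 6e5,
                         n_tads = 150, neighbor_coupling = 0.7,
                         coupling_noise_sd = 0.5, repress_frac = 0.25,
                         cis_boost = 0.5, read_length = 75,
                         min_gene_gap = 5000, min_tad_length = 1.5e5) {
  cfg <- list(seed = as.integer(seed), n_chrom = n_chrom,
              chrom_length = chrom_length, n_lincrna = n_lincrna,
              n_pc = n_pc, n_marks = n_marks, frac_ara = frac_ara,
              rip_log2fc_mean = rip_log2fc_mean,
              rnaseq_log2fc_sd = rnaseq_log2fc_sd,
              nb_dispersion = nb_dispersion,
              mark_enrichment_fold = mark_enrichment_fold,
              reads_per_track = reads_per_track, n_tads = n_tads,
              neighbor_coupling = neighbor_coupling,
              coupling_noise_sd = coupling_noise_sd,
              repress_frac = repress_frac, cis_boost = cis_boost,
              read_length = read_length,
              min_gene_gap = min_gene_gap, min_tad_length = min_tad_length)
  for (f in c("n_chrom", "n_lincrna", "n_pc", "n_marks", "reads_per_track",
              "n_tads")) {
    assert_that(cfg[[f]] >= 1, "config parameter '%s' must be >= 1", f)
  }
  assert_that(n_marks <= length(MARK_NAMES),
              "config parameter 'n_marks' must be <= %d", length(MARK_NAMES))
  assert_that(frac_ara >= 0 && frac_ara <= 1,
              "config parameter 'frac_ara' must lie in [0, 1]")
  assert_that(nb_dispersion > 0, "config parameter 'nb_dispersion' must be > 0")
  assert_that(mark_enrichment_fold >= 1,
              "config parameter 'mark_enrichment_fold' must be >= 1")
  assert_that(neighbor_coupling >= 0 && neighbor_coupling <= 1,
              "config parameter 'neighbor_coupling' must lie in [0, 1]")
  assert_that(chrom_length >= 1e6,
              "config parameter 'chrom_length' must be >= 1e6 (need >= 10x the mean gene footprint)")
  assert_that(min_tad_length * 2 < chrom_length,
              "config parameter 'min_tad_length' too large for chrom_length")
  structure(cfg, class = "study_config")
}

#' Generate a complete synthetic study
#'
#' @param config a [study_config()].
#' @return object of class `synthetic_study`: `annotation`
#'   (a [transcript_set()] with FPKM columns), `tracks` (list of
#'   [read_track()]), `rip_counts` and `rnaseq_counts`
#'   ([count_matrix()]s, 2+2 samples each), `fpkm` (per-gene table),
#'   `tads`, `truth` (per-lincRNA planted flags), `chrom_length`,
#'   `config`.
#' @export
generate_study <- function(config) {
  assert_that(inherits(config, "study_config"),
              "config must come from study_config()")
  old <- local_seed(config$seed)
  on.exit(restore_seed(old), add = TRUE)
  cfg <- config
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  chrom_length <- setNames(rep(cfg$chrom_length, cfg$n_chrom), chroms)
  rl <- cfg$read_length

  ## ---- gene structures -------------------------------------------------
  make_structure <- function(n_ex, exon_range, intron_range) {
    ex_len <- round(runif(n_ex, exon_range[1], exon_range[2]))
    in_len <- if (n_ex > 1) round(runif(n_ex - 1, intron_range[1],
                                        intron_range[2])) else numeric(0)
    offs <- cumsum(c(0, head(rep(ex_len, length.out = n_ex), -1) +
                          in_len))
    list(rel_start = offs, rel_end = offs + ex_len,
         span = offs[n_ex] + ex_len[n_ex])
  }
  pc_struct <- lapply(seq_len(cfg$n_pc), function(i)
    make_structure(sample(4:8, 1), c(120, 400), c(200, 800)))
  linc_struct <- lapply(seq_len(cfg$n_lincrna), function(i)
    make_structure(1L + rbinom(1, 1, 0.4), c(200, 900), c(500, 1200)))

  ## ---- planted AR association -----------------------------------------
  n_ara <- round(cfg$frac_ara * cfg$n_lincrna)
  planted <- sort(sample(cfg$n_lincrna, n_ara))
  is_ara <- seq_len(cfg$n_lincrna) %in% planted
  strength <- numeric(cfg$n_lincrna)
  strength[is_ara] <- runif(n_ara, 0.5, 1)

  ## ---- layout ----------------------------------------------------------
  # one protein-coding gene per unit; lincRNAs dealt round-robin to units
  # and placed to the right of the unit's pc gene at a TSS-to-TSS distance
  # that is short for planted lincRNAs and long otherwise.
  unit_of <- ((seq_len(cfg$n_lincrna) - 1L) %% cfg$n_pc) + 1L
  slot_in_unit <- ave(seq_len(cfg$n_lincrna), unit_of, FUN = seq_along)
  d_tss <- ifelse(is_ara, runif(cfg$n_lincrna, 17500, 32000),
                          runif(cfg$n_lincrna, 45000, 110000)) +
           (slot_in_unit - 1L) * 115000
  pc_strand <- sample(c("+", "-"), cfg$n_pc, replace = TRUE)
  linc_strand <- sample(c("+", "-"), cfg$n_lincrna, replace = TRUE)
  inter_gap <- round(runif(cfg$n_pc, 8000, 20000))

  pc_x0 <- numeric(cfg$n_pc); pc_chr <- character(cfg$n_pc)
  linc_tss_pos <- numeric(cfg$n_lincrna); linc_chr <- character(cfg$n_lincrna)
  cursor <- 1000; ci <- 1L
  for (u in seq_len(cfg$n_pc)) {
    span <- pc_struct[[u]]$span
    lincs_here <- which(unit_of == u)
    ext <- span
    if (length(lincs_here) > 0) {
      # reserve a dead zone of one extra TSS distance to the right of each
      # lincRNA so its designated pc gene stays the closest one
      tss_off <- if (pc_strand[u] == "+") 0 else span
      ext <- max(ext, tss_off + 2 * max(d_tss[lincs_here]) + 1000)
    }
    if (cursor + ext + inter_gap[u] > cfg$chrom_length) {
      ci <- ci + 1L
      assert_that(ci <= cfg$n_chrom,
                  "layout overflow: increase chrom_length or n_chrom")
      cursor <- 1000
    }
    pc_x0[u] <- cursor; pc_chr[u] <- chroms[ci]
    pc_tss_u <- if (pc_strand[u] == "+") cursor else cursor + span
    if (length(lincs_here) > 0) {
      linc_tss_pos[lincs_here] <- pc_tss_u + d_tss[lincs_here]
      linc_chr[lincs_here] <- chroms[ci]
    }
    cursor <- cursor + ext + inter_gap[u]
  }
  pc_x0 <- round(pc_x0)
  linc_tss_pos <- round(linc_tss_pos)
  pc_tss_pos <- ifelse(pc_strand == "+", pc_x0,
                       pc_x0 + vapply(pc_struct, `[[`, numeric(1), "span"))

  ## ---- exon tables -----------------------------------------------------
  pc_gene <- sprintf("PC%04d", seq_len(cfg$n_pc))
  linc_gene <- sprintf("LINC%04d", seq_len(cfg$n_lincrna))
  build_exons <- function(ids, structs, x0s, strands, chrs, anchor) {
    # anchor: "left" places the structure at x0; for minus-strand lincRNAs
    # anchored at their TSS coordinate the body extends to the left.
    nex <- vapply(structs, function(s) length(s$rel_start), integer(1))
    span <- vapply(structs, `[[`, numeric(1), "span")
    x0 <- if (anchor == "left") x0s else ifelse(strands == "+", x0s, x0s - span)
    data.frame(
      transcript_id = rep(paste0(ids, ".t1"), nex),
      chrom = rep(chrs, nex),
      start = rep(x0, nex) + unlist(lapply(structs, `[[`, "rel_start")),
      end = rep(x0, nex) + unlist(lapply(structs, `[[`, "rel_end")),
      strand = rep(strands, nex), stringsAsFactors = FALSE)
  }
  exons <- rbind(
    build_exons(pc_gene, pc_struct, pc_x0, pc_strand, pc_chr, "left"),
    build_exons(linc_gene, linc_struct, linc_tss_pos, linc_strand, linc_chr,
                "tss"))

  ## ---- androgen response (RNA-seq truth) ------------------------------
  # androgen-response rates echo the published study, where both the ARA and
  # the matched NonA sets were rich in androgen-activated lincRNAs
  p_up <- ifelse(is_ara, 0.6, 0.35)
  n_gene <- cfg$n_lincrna + cfg$n_pc
  u01 <- runif(n_gene)
  lfc_rna <- numeric(n_gene) # lincs first, then pcs
  p_up_all <- c(p_up, rep(0.25, cfg$n_pc))
  p_down_all <- c(rep(0.15, cfg$n_lincrna), rep(0.20, cfg$n_pc))
  up_all <- u01 < p_up_all
  down_all <- !up_all & (u01 < p_up_all + p_down_all)
  lfc_rna[up_all] <- rnorm(sum(up_all), 2, cfg$rnaseq_log2fc_sd)
  lfc_rna[down_all] <- -rnorm(sum(down_all), 2, cfg$rnaseq_log2fc_sd)

  # cis coupling: a planted lincRNA copies its fold change (possibly
  # sign-flipped, with strength-dependent noise) to its designated neighbor.
  # Stronger enhancers couple more often: p = 1 - 4(1-c)(1-s), clamped at 0,
  # has mean c over s ~ U(0.5, 1) (exactly, for c >= 0.5), spans [2c-1, 1],
  # and is 1 for every strength when c = 1.
  p_couple <- ifelse(is_ara,
                     pmax(0, 1 - 4 * (1 - cfg$neighbor_coupling) *
                               (1 - strength)), 0)
  coupled <- is_ara & (runif(cfg$n_lincrna) < p_couple)
  flipped <- coupled & (runif(cfg$n_lincrna) < cfg$repress_frac)
  copy_noise <- rnorm(cfg$n_lincrna, 0,
                      cfg$coupling_noise_sd * (1.5 - pmax(strength, 0.5)))
  for (i in which(coupled)) {
    nb <- cfg$n_lincrna + unit_of[i]
    lfc_rna[nb] <- if (flipped[i]) -lfc_rna[i] + copy_noise[i] else
      lfc_rna[i] + cfg$cis_boost + copy_noise[i]
  }

  ## ---- count matrices --------------------------------------------------
  size <- 1 / cfg$nb_dispersion
  q <- rlnorm(cfg$n_lincrna, log(100), 1)
  low <- sample(cfg$n_lincrna, max(1, round(0.03 * cfg$n_lincrna)))
  q[low] <- runif(length(low), 0.05, 0.3)
  lfc_rip <- ifelse(is_ara, cfg$rip_log2fc_mean + rnorm(cfg$n_lincrna, 0, 0.25), 0)
  mu_ar <- q * 2^lfc_rip
  rip <- cbind(rnbinom(cfg$n_lincrna, mu = mu_ar, size = size),
               rnbinom(cfg$n_lincrna, mu = mu_ar, size = size),
               rnbinom(cfg$n_lincrna, mu = q, size = size),
               rnbinom(cfg$n_lincrna, mu = q, size = size))
  dimnames(rip) <- list(linc_gene, c("antiAR_1", "antiAR_2", "IgG_1", "IgG_2"))
  rip_counts <- count_matrix(rip, c("antiAR", "antiAR", "IgG", "IgG"))

  e <- c(rlnorm(cfg$n_lincrna, log(50), 1), rlnorm(cfg$n_pc, log(150), 1))
  # chromatin neighborhoods of planted lincRNAs are transcriptionally more
  # active: designated neighbors get a 2^0.75-fold baseline expression boost
  # (the TAD-level expression elevation the analysis is meant to recover)
  e[cfg$n_lincrna + unique(unit_of[is_ara])] <-
    e[cfg$n_lincrna + unique(unit_of[is_ara])] * 2^0.75
  mu_and <- e * 2^lfc_rna
  rna <- cbind(rnbinom(n_gene, mu = mu_and, size = size),
               rnbinom(n_gene, mu = mu_and, size = size),
               rnbinom(n_gene, mu = e, size = size),
               rnbinom(n_gene, mu = e, size = size))
  dimnames(rna) <- list(c(linc_gene, pc_gene),
                        c("androgen_1", "androgen_2", "vehicle_1", "vehicle_2"))
  rnaseq_counts <- count_matrix(rna, c("androgen", "androgen",
                                       "vehicle", "vehicle"))

  ## ---- FPKM ------------------------------------------------------------
  fpkm <- data.frame(gene_id = c(linc_gene, pc_gene),
                     fpkm_vehicle = e / 30,
                     fpkm_androgen = e / 30 * 2^lfc_rna,
                     stringsAsFactors = FALSE)

  ## ---- annotation ------------------------------------------------------
  transcripts <- data.frame(
    transcript_id = paste0(c(pc_gene, linc_gene), ".t1"),
    gene_id = c(pc_gene, linc_gene),
    biotype = c(rep("protein_coding", cfg$n_pc), rep("lincRNA", cfg$n_lincrna)),
    stringsAsFactors = FALSE)
  transcripts <- merge(transcripts, fpkm, by = "gene_id", sort = FALSE)
  annotation <- transcript_set(transcripts, exons)

  ## ---- TADs ------------------------------------------------------------
  tads <- make_tads(cfg, chroms, linc_chr, linc_tss_pos, is_ara)

  ## ---- epigenetic tracks ----------------------------------------------
  marks <- MARK_NAMES[seq_len(cfg$n_marks)]
  total_len <- sum(chrom_length)
  cum0 <- c(0, cumsum(chrom_length))
  lambda_win <- cfg$reads_per_track * (1000 + rl) / total_len
  tracks <- lapply(marks, function(m) {
    pos <- runif(cfg$reads_per_track, 0, total_len - rl)
    ci <- findInterval(pos, cum0, rightmost.closed = TRUE)
    bg <- data.frame(chrom = chroms[ci], start = round(pos - cum0[ci]),
                     stringsAsFactors = FALSE)
    enr <- NULL
    if (m != "H3K27me3" && cfg$mark_enrichment_fold > 1 && n_ara > 0) {
      fold_i <- 1 + (cfg$mark_enrichment_fold - 1) * strength[planted]
      extra <- rpois(n_ara, (fold_i - 1) * lambda_win)
      if (sum(extra) > 0) {
        # pileup concentrated within +/-150 bp of the TSS (point-source
        # binding), still fully inside the +/-500 bp feature window
        tss_i <- rep(linc_tss_pos[planted], extra)
        chr_i <- rep(linc_chr[planted], extra)
        enr <- data.frame(
          chrom = chr_i,
          start = round(runif(length(tss_i), tss_i - 150, tss_i + 150 - rl)),
          stringsAsFactors = FALSE)
      }
    }
    rd <- rbind(bg, enr)
    rd$start <- pmax(0, rd$start)
    rd$end <- rd$start + rl
    read_track(m, rd)
  })
  names(tracks) <- marks

  ## ---- truth -----------------------------------------------------------
  enriched <- paste(setdiff(marks, "H3K27me3"), collapse = ",")
  truth <- data.frame(
    gene_id = linc_gene, is_ara = is_ara, enhancer_strength = strength,
    lfc_rip = ifelse(is_ara, lfc_rip, 0),
    lfc_rna = lfc_rna[seq_len(cfg$n_lincrna)],
    is_androgen_up = up_all[seq_len(cfg$n_lincrna)],
    is_androgen_down = down_all[seq_len(cfg$n_lincrna)],
    neighbor_pc = pc_gene[unit_of],
    neighbor_lfc_rna = lfc_rna[cfg$n_lincrna + unit_of],
    coupled = coupled, flipped = flipped,
    enriched_marks = ifelse(is_ara & cfg$mark_enrichment_fold > 1,
                            enriched, ""),
    in_reference = runif(cfg$n_lincrna) < 0.45,
    max_orf_aa = sample(10:70, cfg$n_lincrna, replace = TRUE),
    stringsAsFactors = FALSE)

  structure(list(annotation = annotation, tracks = tracks,
                 rip_counts = rip_counts, rnaseq_counts = rnaseq_counts,
                 fpkm = fpkm, tads = tads, truth = truth,
                 chrom_length = chrom_length, config = cfg),
            class = "synthetic_study")
}

# TAD partition of each chromosome: boundaries attracted to planted lincRNA
# TSSs (half of the target count, jittered), the rest uniform; minimum TAD
# length enforced greedily; TADs tile the chromosome with no gaps.
#' @noRd
make_tads <- function(cfg, chroms, linc_chr, linc_tss_pos, is_ara) {
  out <- list()
  for (ch in chroms) {
    L <- cfg$chrom_length
    ara_tss <- linc_tss_pos[is_ara & linc_chr == ch]
    n_attract <- min(floor(cfg$n_tads / 2), length(ara_tss))
    # boundaries land a short distance downstream of the attracted TSS, so
    # the lincRNA sits near a boundary while its upstream designated
    # neighbor stays inside the same TAD
    b1 <- if (n_attract > 0) {
      ara_tss[sample.int(length(ara_tss), n_attract)] +
        runif(n_attract, 5000, 20000)
    } else numeric(0)
    b2 <- runif(max(0, cfg$n_tads - 1 - n_attract), 0, L)
    b <- sort(c(b1, b2))
    b <- b[b > cfg$min_tad_length & b < L - cfg$min_tad_length]
    keep <- numeric(0); last <- 0
    for (x in b) {
      if (x - last >= cfg$min_tad_length) { keep <- c(keep, x); last <- x }
    }
    edges <- round(c(0, keep, L))
    out[[ch]] <- data.frame(
      tad_id = sprintf("tad_%s_%03d", ch, seq_len(length(edges) - 1)),
      chrom = ch, start = edges[-length(edges)], end = edges[-1],
      stringsAsFactors = FALSE)
  }
  tads <- do.call(rbind, out)
  rownames(tads) <- NULL
  tads
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("synthetic_study: %d lincRNAs (%d planted ARA), %d pc",
                     " genes, %d tracks, %d TADs, seed %d\n"),
              x$config$n_lincrna, sum(x$truth$is_ara), x$config$n_pc,
              length(x$tracks), nrow(x$tads), x$config$seed))
  invisible(x)
}

#' Write a synthetic study to plain-text files
#'
#' Emits `annotation.gtf`, one `track_<mark>.bed` per track plus a
#' `track_totals.tsv` manifest, `rip_counts.tsv` / `rnaseq_counts.tsv` (gene
#' rows, sample columns) with `conditions.tsv`, `fpkm.tsv`, `tads.bed`,
#' `truth.tsv` and `chroms.tsv`. All files round-trip through
#' [read_study()] / the genome-interval readers.
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  assert_that(dir.exists(dir), "cannot create directory %s", dir)
  write_gtf(study$annotation, file.path(dir, "annotation.gtf"))
  totals <- data.frame(mark = names(study$tracks),
                       total_mapped = vapply(study$tracks, `[[`, numeric(1),
                                             "total_mapped"))
  data.table::fwrite(totals, file.path(dir, "track_totals.tsv"), sep = "\t")
  for (m in names(study$tracks)) {
    write_bed(cbind(study$tracks[[m]]$reads, name = m),
              file.path(dir, paste0("track_", m, ".bed")))
  }
  wcounts <- function(cm, stem) {
    df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                     check.names = FALSE)
    data.table::fwrite(df, file.path(dir, paste0(stem, "_counts.tsv")),
                       sep = "\t")
    data.frame(sample = colnames(cm$counts),
               condition = as.character(cm$condition))
  }
  cond <- rbind(wcounts(study$rip_counts, "rip"),
                wcounts(study$rnaseq_counts, "rnaseq"))
  data.table::fwrite(cond, file.path(dir, "conditions.tsv"), sep = "\t")
  data.table::fwrite(study$fpkm, file.path(dir, "fpkm.tsv"), sep = "\t")
  write_bed(data.frame(chrom = study$tads$chrom, start = study$tads$start,
                       end = study$tads$end, name = study$tads$tad_id),
            file.path(dir, "tads.bed"))
  data.table::fwrite(study$truth, file.path(dir, "truth.tsv"), sep = "\t")
  data.table::fwrite(data.frame(chrom = names(study$chrom_length),
                                length = unname(study$chrom_length)),
                     file.path(dir, "chroms.tsv"), sep = "\t")
  invisible(dir)
}

#' Read a study back from [write_study()] output
#' @param dir directory written by [write_study()].
#' @return a list with the same analysis-facing components as
#'   [generate_study()] (`config` is not recoverable and `truth` is included
#'   when present).
#' @export
read_study <- function(dir) {
  annotation <- read_gtf(file.path(dir, "annotation.gtf"))
  fpkm <- as.data.frame(data.table::fread(file.path(dir, "fpkm.tsv")))
  # re-attach FPKM columns to the transcript table
  tr <- annotation$transcripts
  tr <- merge(tr, fpkm, by = "gene_id", sort = FALSE)
  annotation <- transcript_set(tr, annotation$exons)
  totals <- data.table::fread(file.path(dir, "track_totals.tsv"))
  tracks <- lapply(seq_len(nrow(totals)), function(i) {
    bed <- read_bed(file.path(dir, paste0("track_", totals$mark[i], ".bed")))
    read_track(totals$mark[i], bed[c("chrom", "start", "end")],
               totals$total_mapped[i])
  })
  names(tracks) <- totals$mark
  cond <- as.data.frame(data.table::fread(file.path(dir, "conditions.tsv")))
  rcounts <- function(stem) {
    df <- as.data.frame(data.table::fread(
      file.path(dir, paste0(stem, "_counts.tsv"))))
    m <- as.matrix(df[-1])
    rownames(m) <- df$gene_id
    count_matrix(m, cond$condition[match(colnames(m), cond$sample)])
  }
  tadbed <- read_bed(file.path(dir, "tads.bed"))
  truth_path <- file.path(dir, "truth.tsv")
  chrl <- as.data.frame(data.table::fread(file.path(dir, "chroms.tsv")))
  list(annotation = annotation, tracks = tracks,
       rip_counts = rcounts("rip"), rnaseq_counts = rcounts("rnaseq"),
       fpkm = fpkm,
       tads = data.frame(tad_id = tadbed$name, chrom = tadbed$chrom,
                         start = tadbed$start, end = tadbed$end,
                         stringsAsFactors = FALSE),
       truth = if (file.exists(truth_path))
         as.data.frame(data.table::fread(truth_path)) else NULL,
       chrom_length = setNames(chrl$length, chrl$chrom))
}
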