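# End-to-end drivers: write a simulated cohort to disk in the package's
# interchange formats, read it back, and run every analysis stage on a
# cohort in one call. These functions are the package's batch interface; a
# single config list plus a seed reproduces a full run.

#' Tissue rank-shift recovery study
#'
#' The package's canonical end-to-end experiment for the tissue-of-origin
#' stage: a four-group, three-replicate cohort in which the only difference
#' between groups is that `"old"` doubles the mixture weight of the last
#' tissue. The design isolates the mixture effect: one chromosome with 150
#' identical-length genes well separated from each other and from the (two)
#' CTCF sites, equal subcompartment weights, equal NDR depth and phasing
#' amplitude everywhere, and a binary marker-panel expression table
#' (constant background) under which the tissues are exactly exchangeable
#' apart from their mixture weights. Returns the planted tissue, the
#' rank-shift result and the list of tissues flagged for the old-vs-young
#' pair.
#'
#' @param seed Top-level seed (drives genome, expression and fragments).
#' @param depth Fragments per sample (default 37500).
#' @param n_tissues Number of tissues (default 5).
#' @param replicates Samples per group (default 3).
#' @return List: `planted` (tissue name), `flagged_old_vs_young` (character
#'   vector of tissues significant for that pair), `shift`
#'   ([rank_shift_test()] result), `ranks` (samples x tissues).
#' @export
rank_shift_study <- function(seed, depth = 37500L, n_tissues = 5L,
                             replicates = 3L) {
  cfg <- genome_config(chromosomes = c(chr1 = 4.5e6), n_genes = 150L,
                       n_ctcf = 2L, gene_length = c(15000, 15000))
  model <- build_genome_model(cfg, seed = seed)
  expr <- simulate_tissue_expression(150L, n_tissues,
                                     seed = derive_seed(seed, 777L),
                                     marker_factor = 50,
                                     background_sdlog = 0)
  gp <- default_group_params(tissues = rownames(expr))
  for (g in names(gp)) {
    gp[[g]]$ndr_depth <- 0.6
    gp[[g]]$phasing_amplitude <- 0.8
    gp[[g]]$repeat_5p_weight <- 1
    gp[[g]]$compartment_weights[] <- 1
  }
  planted <- rownames(expr)[n_tissues]
  cohort <- simulate_cohort(gp, replicates, model, expr, depth = depth,
                            seed = seed)
  ctr <- cohort_tissue_ranks(cohort$samples, model, expr)
  shift <- rank_shift_test(ctr$ranks, ctr$groups)
  oy <- shift$pairwise[shift$pairwise$group1 == "young" &
                         shift$pairwise$group2 == "old", ]
  list(planted = planted,
       flagged_old_vs_young = oy$tissue[oy$significant],
       shift = shift, ranks = ctr$ranks)
}

#' Write a simulated cohort to disk
#'
#' One BED3+ fragment file per sample, annotation BEDs (subcompartment
#' labels, gene anchors as BED6, CTCF sites, repeats as BED6+2 with
#' consensus offset/length), the expression table as TSV (tissues x genes),
#' the ground truth as JSON, and a manifest of all files.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param model The [build_genome_model()] the cohort was simulated from.
#' @param expression The expression matrix used.
#' @param dir Output directory (created if needed).
#' @param compress Write fragment BEDs gzip-compressed?
#' @return Named list of written paths, invisibly.
#' @export
write_cohort <- function(cohort, model, expression, dir, compress = FALSE) {
  stopifnot(inherits(cohort, "cfdna_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) cf_stop("cannot create output directory ", dir)
  paths <- list()
  for (sid in names(cohort$samples)) {
    p <- file.path(dir, paste0(sid, if (compress) ".bed.gz" else ".bed"))
    write_fragments(cohort$samples[[sid]], p)
    paths[[paste0("fragments_", sid)]] <- p
  }
  p <- file.path(dir, "subcompartments.bed")
  utils::write.table(model$bins, p, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths$subcompartments <- p

  g <- model$genes
  anchors <- data.frame(chrom = g$chrom, start = pmin(g$tss, g$tts),
                        end = pmax(g$tss, g$tts), name = g$id, score = 0L,
                        strand = g$strand)
  p <- file.path(dir, "genes.bed")
  utils::write.table(anchors, p, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths$genes <- p

  p <- file.path(dir, "ctcf.bed")
  utils::write.table(data.frame(chrom = model$ctcf_sites$chrom,
                                start = model$ctcf_sites$pos,
                                end = model$ctcf_sites$pos + 1L),
                     p, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths$ctcf <- p

  r <- model$repeats
  p <- file.path(dir, "repeats.bed")
  utils::write.table(data.frame(r$chrom, r$start, r$end, r$family, 0L,
                                r$strand, r$consensus_offset,
                                r$consensus_length),
                     p, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths$repeats <- p

  p <- file.path(dir, "expression.tsv")
  utils::write.table(expression, p, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  paths$expression <- p

  paths$truth <- write_truth(cohort$truth, file.path(dir, "truth.json"))
  manifest <- data.frame(key = names(paths),
                         file = basename(unlist(paths)),
                         md5 = unname(tools::md5sum(unlist(paths))))
  p <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$manifest <- p
  invisible(paths)
}

#' Run every analysis stage on a cohort
#'
#' The standard pipeline: per-sample filtering, optional downsampling to
#' the smallest filtered library, fragment-length histograms,
#' subcompartment bin signals (fold changes old-style comparisons, rank and
#' variance tests, per-subcompartment Gibbs comparisons), TSS/TTS/CTCF
#' metaprofiles with window means, CVs and group tests, repeat consensus
#' profiles per family, and tissue rank-shift inference. Stages can be
#' skipped by name.
#'
#' @param samples Named list of [sample_library()] objects (with `group`
#'   set).
#' @param model The [build_genome_model()] the libraries live on.
#' @param expression Tissue-by-gene expression matrix.
#' @param reference_group Baseline group for fold changes (default the
#'   first group encountered; comparisons are each other group vs this).
#' @param downsample_n Common depth to downsample to; `NULL` (default) uses
#'   the minimum filtered library size, `NA` disables downsampling.
#' @param seed Seed for downsampling and MCMC.
#' @param skip Character vector of stage names to skip, among
#'   `"compartments"`, `"metaprofiles"`, `"repeats"`, `"tissues"`,
#'   `"mixed_model"`.
#' @param gibbs_iter,gibbs_burn_in MCMC settings for the per-subcompartment
#'   comparisons.
#' @return Named list with elements `libraries`, `fraglen`, `compartments`,
#'   `metaprofiles`, `repeats`, `tissues` (skipped stages are `NULL`).
#' @export
analyze_cohort <- function(samples, model, expression,
                           reference_group = NULL, downsample_n = NULL,
                           seed = 1L, skip = character(0),
                           gibbs_iter = 13000L, gibbs_burn_in = 3000L) {
  stopifnot(length(samples) >= 1L)
  groups <- vapply(samples, function(s) s$group, character(1))
  if (anyNA(groups)) cf_stop("every sample needs a group label")
  reference_group <- reference_group %||% groups[[1L]]

  libs <- lapply(samples, filter_fragments)
  if (!isTRUE(is.na(downsample_n))) {
    target <- downsample_n %||% min(vapply(libs, function(l) l$library_size, numeric(1)))
    libs <- lapply(seq_along(libs), function(i) {
      downsample_fragments(libs[[i]], target, seed = derive_seed(seed, i))
    })
    names(libs) <- names(samples)
  }
  out <- list(libraries = libs)

  hists <- lapply(libs, length_histogram)
  out$fraglen <- list(
    by_sample = hists,
    by_group = lapply(split(hists, groups), merge_histograms),
    modal = vapply(hists, modal_length, numeric(1)))

  if (!"compartments" %in% skip) {
    counts <- lapply(libs, bin_counts, chrom_lengths = model$chromosomes,
                     binsize = model$binsize)
    bt <- bin_table(counts, model$bins$label, groups)
    others <- setdiff(unique(groups), reference_group)
    lfc <- lapply(others, function(g) log2_fold_change(bt, g, reference_group))
    names(lfc) <- others
    mm <- NULL
    if (!"mixed_model" %in% skip) {
      mm <- lapply(SUBCOMPARTMENTS, function(lb) {
        mixed_model_compare(bt, lb, n_iter = gibbs_iter,
                            burn_in = gibbs_burn_in, seed = derive_seed(seed, 99L))
      })
      names(mm) <- SUBCOMPARTMENTS
    }
    out$compartments <- list(
      bin_table = bt, log2fc = lfc,
      rank_tests = subcompartment_rank_tests(bt, reference_group),
      variance = variance_across_groups(bt),
      mixed_model = mm)
  }

  if (!"metaprofiles" %in% skip) {
    anchor_sets <- list(
      tss = data.frame(chrom = model$genes$chrom, pos = model$genes$tss,
                       strand = model$genes$strand),
      tts = data.frame(chrom = model$genes$chrom, pos = model$genes$tts,
                       strand = model$genes$strand),
      ctcf = data.frame(chrom = model$ctcf_sites$chrom,
                        pos = model$ctcf_sites$pos))
    out$metaprofiles <- lapply(anchor_sets, function(an) {
      profs <- lapply(libs, coverage_at_anchors, anchors = an)
      list(profiles = profs,
           window_means = vapply(profs, window_mean, numeric(1)),
           cv_by_group = vapply(split(profs, groups), replicate_cv, numeric(1)),
           tests = group_profile_tests(profs, groups))
    })
  }

  if (!"repeats" %in% skip) {
    fams <- unique(model$repeats$family)
    out$repeats <- lapply(stats::setNames(fams, fams), function(fam) {
      el <- model$repeats[model$repeats$family == fam, ]
      if (fam == "AluY") el <- dimeric_alu_filter(el)
      lapply(libs, function(l) {
        u <- unique_profile(l, el)
        combine_normalize(u, numeric(length(u)), l$library_size)
      })
    })
  }

  if (!"tissues" %in% skip) {
    if (is.null(expression)) cf_stop("tissue stage needs an expression table")
    ctr <- cohort_tissue_ranks(libs, model, expression)
    out$tissues <- c(ctr, list(shift = rank_shift_test(ctr$ranks, ctr$groups)))
  }
  out
}
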