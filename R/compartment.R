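# 100-kb bin signals annotated with Hi-C subcompartments, and their group
# comparisons: median-of-ratios normalization, log2 fold changes,
# Kruskal-Wallis/Dunn across subcompartments, Brown-Forsythe variance tests
# across groups, and the Gibbs random-intercept credible-interval comparison.

#' Count fragment midpoints in fixed-width bins
#'
#' Each fragment is assigned to the bin containing its midpoint
#' (`floor((start + end) / 2)`, half-open bins). Terminal partial bins are
#' dropped, not rescaled, so all bins are directly comparable.
#'
#' @param lib A [sample_library()] (normally already filtered).
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param binsize Bin width in bp (default 100 kb).
#' @return Data frame `chrom`, `start`, `end`, `count`.
#' @export
bin_counts <- function(lib, chrom_lengths, binsize = 1e5) {
  stopifnot(inherits(lib, "sample_library"))
  if (!is.numeric(binsize) || length(binsize) != 1L || binsize <= 0)
    cf_stop("`binsize` must be positive")
  f <- lib$fragments
  mid <- (f$start + f$end) %/% 2
  out <- vector("list", length(chrom_lengths))
  for (i in seq_along(chrom_lengths)) {
    cn <- names(chrom_lengths)[i]
    nb <- floor(chrom_lengths[[i]] / binsize)
    if (nb < 1) next
    m <- mid[f$chrom == cn]
    idx <- m %/% binsize
    counts <- tabulate(idx[idx < nb] + 1L, nb)
    out[[i]] <- data.frame(chrom = cn, start = (seq_len(nb) - 1) * binsize,
                           end = seq_len(nb) * binsize, count = counts,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Assemble a multi-sample bin table
#'
#' Combines per-sample [bin_counts()] tables that share one bin frame into a
#' counts matrix with subcompartment labels and per-sample size factors.
#' Size factors use median-of-ratios normalization over bins with non-zero
#' counts in every sample; if no such bin exists, library-size factors are
#' used with a warning.
#'
#' @param counts Named list of [bin_counts()] data frames (one per sample,
#'   identical bin frames).
#' @param labels Character vector of subcompartment labels, one per bin.
#' @param groups Character vector of group labels, one per sample.
#' @return A `bin_table`: `bins` (chrom/start/end/label), `counts`
#'   (bins x samples), `samples` (id/group), `size_factors`.
#' @export
bin_table <- function(counts, labels, groups) {
  if (!is.list(counts) || length(counts) < 1L) cf_stop("need at least one sample")
  if (is.null(names(counts))) names(counts) <- paste0("sample", seq_along(counts))
  frame <- counts[[1L]][c("chrom", "start", "end")]
  for (ct in counts) {
    if (!identical(ct[c("chrom", "start", "end")], frame))
      cf_stop("mismatched bin frames across samples")
  }
  if (length(labels) != nrow(frame)) cf_stop("one label per bin required")
  if (length(groups) != length(counts)) cf_stop("one group label per sample required")
  m <- vapply(counts, function(ct) as.numeric(ct$count), numeric(nrow(frame)))
  if (!is.matrix(m)) m <- matrix(m, nrow = nrow(frame))
  colnames(m) <- names(counts)
  frame$label <- labels
  structure(list(bins = frame, counts = m,
                 samples = data.frame(id = names(counts), group = groups,
                                      stringsAsFactors = FALSE),
                 size_factors = median_of_ratios(m)),
            class = "bin_table")
}

#' Median-of-ratios size factors
#'
#' Per-sample size factors as the median ratio of a sample's bin counts to
#' the per-bin geometric mean, computed over bins where every sample has a
#' non-zero count. Falls back to (relative) library-size factors with a
#' warning if every bin contains a zero.
#'
#' @param m Counts matrix, bins x samples.
#' @return Numeric vector of size factors, one per sample, geometric mean 1.
#' @export
median_of_ratios <- function(m) {
  ok <- rowSums(m == 0) == 0
  if (!any(ok)) {
    warning("every bin contains a zero; using library-size factors", call. = FALSE)
    sf <- colSums(m)
    sf <- sf / exp(mean(log(sf)))
    return(stats::setNames(sf, colnames(m)))
  }
  lg <- log(m[ok, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- exp(apply(lg - ref, 2L, stats::median))
  stats::setNames(sf, colnames(m))
}

#' Normalized counts and per-group mean signals
#'
#' `normalized_counts` divides each sample's counts by its size factor;
#' `group_mean_signal` averages the normalized counts arithmetically across
#' the replicates of each group (the "average cfDNA signal" per bin).
#'
#' @param bt A [bin_table()].
#' @return A bins x samples matrix (`normalized_counts`) or bins x groups
#'   matrix (`group_mean_signal`).
#' @export
normalized_counts <- function(bt) {
  stopifnot(inherits(bt, "bin_table"))
  sweep(bt$counts, 2L, bt$size_factors, "/")
}

#' @rdname normalized_counts
#' @export
group_mean_signal <- function(bt) {
  stopifnot(inherits(bt, "bin_table"))
  nc <- normalized_counts(bt)
  g <- unique(bt$samples$group)
  out <- vapply(g, function(gg) {
    rowMeans(nc[, bt$samples$group == gg, drop = FALSE])
  }, numeric(nrow(nc)))
  if (!is.matrix(out)) out <- matrix(out, ncol = length(g), dimnames = list(NULL, g))
  out
}

#' Per-bin log2 fold change between two groups
#'
#' `log2((meanA + pseudocount) / (meanB + pseudocount))` on size-factor
#' normalized group means; the pseudocount keeps every bin finite. Exactly
#' antisymmetric under swapping the groups.
#'
#' @param bt A [bin_table()].
#' @param group_a,group_b Group labels (fold change of A over B).
#' @param pseudocount Added to both normalized means (default 0.5).
#' @return Data frame: bin frame columns, `label`, `mean_a`, `mean_b`,
#'   `log2fc`.
#' @export
log2_fold_change <- function(bt, group_a, group_b, pseudocount = 0.5) {
  stopifnot(inherits(bt, "bin_table"))
  gm <- group_mean_signal(bt)
  if (!all(c(group_a, group_b) %in% colnames(gm)))
    cf_stop("unknown group label")
  out <- bt$bins
  out$mean_a <- gm[, group_a]
  out$mean_b <- gm[, group_b]
  out$log2fc <- log2((out$mean_a + pseudocount) / (out$mean_b + pseudocount))
  out
}

#' Rank tests of bin signal across subcompartments
#'
#' Kruskal-Wallis across the subcompartment labels on one group's per-bin
#' mean signals, with Dunn's post hoc pairwise comparisons (BH-adjusted).
#' Labels with fewer than two bins are excluded with a warning.
#'
#' @param bt A [bin_table()].
#' @param group Group label whose mean signal is tested.
#' @return List: `kruskal` ([kruskal_wallis()] result), `dunn` (pairwise
#'   table), `labels` (labels actually tested).
#' @export
subcompartment_rank_tests <- function(bt, group) {
  stopifnot(inherits(bt, "bin_table"))
  gm <- group_mean_signal(bt)
  if (!group %in% colnames(gm)) cf_stop("unknown group label")
  values <- split(gm[, group], bt$bins$label)
  small <- lengths(values) < 2L
  if (any(small)) {
    warning("excluding label(s) with < 2 bins: ",
            paste(names(values)[small], collapse = ", "), call. = FALSE)
    values <- values[!small]
  }
  if (length(values) < 2L) cf_stop("need at least two labels with >= 2 bins")
  list(kruskal = kruskal_wallis(values), dunn = dunn_posthoc(values),
       labels = names(values))
}

#' Variance comparison of bin signals across groups
#'
#' Brown-Forsythe (median-centred Levene) tests for every pair of groups on
#' the per-bin group mean signals — the statistic behind "signal variance
#' across compartments decreases with age".
#'
#' @param bt A [bin_table()].
#' @return Data frame: `group1`, `group2`, `W`, `p`, `larger_spread` (label
#'   of the group with the larger median absolute deviation).
#' @export
variance_across_groups <- function(bt) {
  stopifnot(inherits(bt, "bin_table"))
  gm <- group_mean_signal(bt)
  g <- colnames(gm)
  if (length(g) < 2L) cf_stop("need at least two groups")
  pairs <- utils::combn(seq_along(g), 2L)
  out <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- gm[, pairs[1L, k]]; b <- gm[, pairs[2L, k]]
    tt <- levene_bf(list(a, b))
    da <- mean(abs(a - stats::median(a)))
    db <- mean(abs(b - stats::median(b)))
    out[[k]] <- data.frame(group1 = g[pairs[1L, k]], group2 = g[pairs[2L, k]],
                           W = tt$statistic, p = tt$p.value,
                           larger_spread = if (da >= db) g[pairs[1L, k]] else g[pairs[2L, k]])
  }
  do.call(rbind, out)
}

#' Bayesian group comparison within one subcompartment
#'
#' Fits the random-intercept model of [gibbs_random_intercept()] to
#' `log2(normalized count + pseudocount)` of every bin x sample observation
#' in one subcompartment: group is the fixed factor, bin the random factor.
#' Reports pairwise posterior median differences with central 95% credible
#' intervals; a comparison is significant when zero is excluded from the
#' interval. A non-convergence warning flag is attached when any split-chain
#' R-hat exceeds 1.1.
#'
#' @param bt A [bin_table()] with at least two groups.
#' @param label Subcompartment to analyse (needs >= 10 bins).
#' @param pseudocount Added before the log2 transform (default 0.5).
#' @param ... MCMC settings passed to [gibbs_random_intercept()]
#'   (`n_iter`, `burn_in`, `thin`, `seed`).
#' @return A `posterior_summary`: data frame `group1`, `group2`, `median`,
#'   `lo`, `hi`, `significant`, with attributes `label`, `rhat`, `converged`.
#' @export
mixed_model_compare <- function(bt, label, pseudocount = 0.5, ...) {
  stopifnot(inherits(bt, "bin_table"))
  sel <- which(bt$bins$label == label)
  if (length(sel) < 10L)
    cf_stop("subcompartment ", label, " has ", length(sel),
            " bins; need at least 10")
  if (length(unique(bt$samples$group)) < 2L) cf_stop("need at least two groups")
  nc <- normalized_counts(bt)[sel, , drop = FALSE]
  y <- as.numeric(log2(nc + pseudocount))
  bin <- rep(seq_along(sel), times = ncol(nc))
  grp <- rep(bt$samples$group, each = length(sel))
  fit <- gibbs_random_intercept(y, bin, grp, ...)
  if (!fit$converged)
    warning("split-chain R-hat > 1.1: chain may not have converged", call. = FALSE)
  out <- posterior_pairwise(fit)
  attr(out, "label") <- label
  attr(out, "rhat") <- fit$rhat
  attr(out, "converged") <- fit$converged
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' Pearson correlation of two binned tracks
#'
#' Product-moment correlation of two signal vectors on the same bin frame
#' (e.g. cfDNA bin signal against an MNase-seq track).
#'
#' @param a,b Numeric vectors of equal length >= 3 with non-zero variance.
#' @return Pearson r.
#' @export
correlate_tracks <- function(a, b) {
  if (length(a) != length(b)) cf_stop("tracks must share a bin frame")
  if (length(a) < 3L) cf_stop("need at least 3 bins")
  if (stats::var(a) == 0 || stats::var(b) == 0) cf_stop("zero-variance track")
  stats::cor(a, b)
}

#' Export per-sample normalized bin signals as bedGraph
#'
#' One bedGraph file per sample: chrom, start, end, normalized count.
#'
#' @param bt A [bin_table()].
#' @param dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
write_bin_signals <- function(bt, dir) {
  stopifnot(inherits(bt, "bin_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nc <- normalized_counts(bt)
  paths <- character(ncol(nc))
  for (j in seq_len(ncol(nc))) {
    paths[j] <- file.path(dir, paste0(bt$samples$id[j], ".bedGraph"))
    utils::write.table(cbind(bt$bins[c("chrom", "start", "end")],
                             signal = nc[, j]),
                       paths[j], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}
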