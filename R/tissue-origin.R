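# Tissue-of-origin inference from nucleosome phasing: window protection
# score tracks downstream of TSS, FFT period spectra, the 193-199 bp
# nucleosome-phasing band, correlation of per-gene band intensities with
# tissue expression, and group rank-shift tests.

#' Window protection score track
#'
#' At each position `p` of `[start, end)`, the WPS with window width `w` is
#' the number of fragments spanning the whole window `[p - w/2, p + w/2)`
#' minus the number of fragments with an endpoint (start, or end - 1)
#' inside the window. Positive scores mark protected (nucleosomal) DNA,
#' negative scores mark preferred cleavage sites; the score oscillates with
#' nucleosome phasing.
#'
#' @param lib A [sample_library()].
#' @param chrom Chromosome name.
#' @param start,end Track interval, 0-based half-open.
#' @param w Even window width in bp (default 120, the long-fragment window).
#' @return Integer vector of length `end - start`; element `i` is the score
#'   at position `start + i - 1`.
#' @export
wps <- function(lib, chrom, start, end, w = 120L) {
  stopifnot(inherits(lib, "sample_library"))
  if (w %% 2L != 0L || w <= 0L) cf_stop("`w` must be a positive even width")
  if (end <= start) cf_stop("empty interval")
  if (w >= end - start) cf_stop("`w` must be smaller than the interval")
  h <- w %/% 2L
  n <- end - start
  f <- lib$fragments
  sel <- f$chrom == chrom & f$end > start - w & f$start < end + w
  fs <- f$start[sel]; fe <- f$end[sel]
  acc <- numeric(n + 1L)
  add_range <- function(acc, lo, hi, sign) {
    # add `sign` over track positions [lo, hi] (absolute coordinates)
    lo <- pmax(lo, start); hi <- pmin(hi, end - 1L)
    ok <- lo <= hi
    if (any(ok)) {
      up <- tabulate(lo[ok] - start + 1L, n + 1L)
      down <- tabulate(hi[ok] - start + 2L, n + 1L)
      acc + sign * (up - down)
    } else acc
  }
  # fragment spans the window at p  <=>  p in [fs + w/2, fe - w/2]
  acc <- add_range(acc, fs + h, fe - h, +1)
  # endpoint q inside [p - w/2, p + w/2)  <=>  p in [q - w/2 + 1, q + w/2];
  # a fragment counts once even when both its endpoints are inside, so the
  # overlap of the two endpoint ranges is added back
  acc <- add_range(acc, fs - h + 1L, fs + h, -1)
  acc <- add_range(acc, fe - 1L - h + 1L, fe - 1L + h, -1)
  acc <- add_range(acc, fe - h, fs + h, +1)
  as.integer(cumsum(acc)[seq_len(n)])
}

#' Detrend a score track
#'
#' Subtracts a running median (odd window; the median track is extended as
#' a constant over the first and last half-window) and then the residual
#' mean, removing slow coverage trends so the periodogram reflects the
#' nucleosome-scale oscillation. A pure cosine in the nucleosome period
#' range passes through with its amplitude essentially intact.
#'
#' @param track Numeric track (e.g. a [wps()] result).
#' @param median_window Approximate running-median span in bp; rounded to
#'   the nearest odd integer (default 1000 -> 1001).
#' @return Detrended numeric track, mean zero.
#' @export
detrend_track <- function(track, median_window = 1000L) {
  k <- 2L * (as.integer(median_window) %/% 2L) + 1L
  k <- min(k, 2L * ((length(track) - 1L) %/% 2L) + 1L)
  x <- as.numeric(track) - as.numeric(stats::runmed(track, k, endrule = "constant"))
  x - mean(x)
}

#' Periodogram by spatial period
#'
#' Squared FFT magnitudes `|X_k|^2 / N^2` mapped from frequency index `k`
#' to spatial period `N/k` bp and aggregated by mean into integer period
#' bins over `[min_period, max_period]`. A rectangular taper is used: the
#' target band (193-199 bp) is broad relative to the bin spacing at
#' N = 10000, so no windowing is needed. The sum of `|X_k|^2 / N^2` over
#' all k equals `sum(track^2) / N` (Parseval), retained as an attribute.
#'
#' @param track Detrended numeric track (length >= 2 * max_period).
#' @param min_period,max_period Period range in bp (defaults 120-280).
#' @return A `period_spectrum` data frame: `period` (bp, only bins that
#'   receive at least one Fourier frequency), `intensity`; attributes `n`
#'   (track length) and `total_power`.
#' @export
period_spectrum <- function(track, min_period = 120L, max_period = 280L) {
  n <- length(track)
  if (n < 2L * max_period) cf_stop("track shorter than twice the maximum period")
  X <- stats::fft(track)
  intens <- Mod(X)^2 / n^2
  k <- seq_len(floor(n / 2))
  period <- n / k
  ok <- period >= min_period & period <= max_period
  bin <- round(period[ok])
  agg <- rowsum(intens[k[ok] + 1L], bin)
  cnt <- rowsum(rep(1, sum(ok)), bin)
  out <- data.frame(period = as.integer(rownames(agg)),
                    intensity = agg[, 1L] / cnt[, 1L])
  out <- out[order(out$period), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n = n, total_power = sum(intens),
            class = c("period_spectrum", "data.frame"))
}

#' Mean intensity in a period band
#'
#' Mean periodogram intensity over period bins in `[lo, hi]` bp; the
#' 193-199 bp band captures the nucleosome phasing signal.
#'
#' @param spectrum A [period_spectrum()].
#' @param lo,hi Band bounds in bp (defaults 193 and 199).
#' @return Scalar mean intensity.
#' @export
band_intensity <- function(spectrum, lo = 193, hi = 199) {
  stopifnot(inherits(spectrum, "period_spectrum"))
  if (!(lo < hi)) cf_stop("need lo < hi")
  sel <- spectrum$period >= lo & spectrum$period <= hi
  if (!any(sel)) cf_stop("band outside the spectrum's period range")
  mean(spectrum$intensity[sel])
}

#' Per-gene phasing band intensities for one sample
#'
#' For each gene: WPS over the 10 kb downstream of the TSS in transcription
#' direction (the track is reversed for minus-strand genes so position 0 is
#' always the TSS), detrended, Fourier-transformed, and summarised by the
#' mean intensity of the `[band_lo, band_hi]` period band. Genes whose
#' downstream window leaves the chromosome are dropped.
#'
#' @param lib A [sample_library()].
#' @param model A [build_genome_model()] result (supplies genes and bounds).
#' @param span Downstream window length in bp (default 10000).
#' @param w WPS window width (default 120).
#' @param band_lo,band_hi Phasing band in bp (defaults 193 and 199).
#' @param median_window Detrending span (default 1000).
#' @return Named numeric vector of band intensities, one per retained gene.
#' @export
gene_band_intensities <- function(lib, model, span = 10000L, w = 120L,
                                  band_lo = 193, band_hi = 199,
                                  median_window = 1000L) {
  g <- model$genes
  out <- rep(NA_real_, nrow(g))
  for (i in seq_len(nrow(g))) {
    clen <- model$chromosomes[[g$chrom[i]]]
    if (g$strand[i] == "+") {
      s <- g$tss[i]; e <- g$tss[i] + span
      if (e > clen) next
      tr <- wps(lib, g$chrom[i], s, e, w)
    } else {
      s <- g$tss[i] - span + 1L; e <- g$tss[i] + 1L
      if (s < 0) next
      tr <- rev(wps(lib, g$chrom[i], s, e, w))
    }
    sp <- period_spectrum(detrend_track(tr, median_window))
    out[i] <- band_intensity(sp, band_lo, band_hi)
  }
  stats::setNames(out, g$id)[!is.na(out)]
}

#' Correlate band intensities with tissue expression
#'
#' Pearson correlation, per tissue, between a sample's per-gene phasing
#' band intensities and `log2(expression + 1)` over the shared genes.
#' Because nucleosome phasing amplitude anti-correlates with expression in
#' the contributing tissue, tissues are ranked by ascending r: rank 1 (most
#' negative correlation) is the strongest inferred contributor. Use
#' `rank_sign = "descending"` to invert the convention. Zero-variance
#' tissues are flagged and excluded from the ranking.
#'
#' @param band Named per-gene band intensity vector
#'   ([gene_band_intensities()]).
#' @param expression Tissue-by-gene expression matrix.
#' @param rank_sign `"ascending"` (default) or `"descending"`.
#' @return Data frame `tissue`, `r`, `rank` (NA for excluded tissues),
#'   `excluded`.
#' @export
tissue_correlations <- function(band, expression,
                                rank_sign = c("ascending", "descending")) {
  rank_sign <- match.arg(rank_sign)
  shared <- intersect(names(band), colnames(expression))
  if (length(shared) < 3L) cf_stop("need at least 3 shared genes")
  b <- band[shared]
  if (stats::var(b) == 0) cf_stop("zero variance in band intensities")
  r <- vapply(rownames(expression), function(t) {
    e <- log2(expression[t, shared] + 1)
    if (stats::var(e) == 0) return(NA_real_)
    stats::cor(b, e)
  }, numeric(1))
  excluded <- is.na(r)
  rk <- rep(NA_real_, length(r))
  rk[!excluded] <- rank(if (rank_sign == "ascending") r[!excluded] else -r[!excluded])
  data.frame(tissue = rownames(expression), r = r, rank = rk,
             excluded = excluded, row.names = NULL)
}

#' Per-sample tissue ranks for a cohort
#'
#' Runs [gene_band_intensities()] and [tissue_correlations()] for every
#' sample and collects the tissue ranks.
#'
#' @param samples List of [sample_library()] objects.
#' @param model A [build_genome_model()] result.
#' @param expression Tissue-by-gene expression matrix.
#' @param ... Passed to [gene_band_intensities()].
#' @return List: `ranks` (samples x tissues matrix), `r` (same shape,
#'   correlations), `groups` (per-sample group labels).
#' @export
cohort_tissue_ranks <- function(samples, model, expression, ...) {
  tissues <- rownames(expression)
  ranks <- r <- matrix(NA_real_, length(samples), length(tissues),
                       dimnames = list(names(samples), tissues))
  for (i in seq_along(samples)) {
    band <- gene_band_intensities(samples[[i]], model, ...)
    tc <- tissue_correlations(band, expression)
    ranks[i, tc$tissue] <- tc$rank
    r[i, tc$tissue] <- tc$r
  }
  list(ranks = ranks, r = r,
       groups = vapply(samples, function(s) s$group, character(1)))
}

#' Rank-shift test across sample groups
#'
#' Per tissue: Kruskal-Wallis across groups on that tissue's per-sample
#' ranks, then Dunn's pairwise comparisons. p-values are BH-adjusted across
#' tissues — Dunn p within each group pair, KW p across the tissue family.
#' A pairwise shift is called significant only when the tissue's omnibus
#' Kruskal-Wallis test rejects at `alpha` AND the pair's BH-adjusted Dunn p
#' is below `alpha`: the omnibus test identifies tissues whose ranking
#' changes, the post hoc test attributes the change to group pairs.
#' The reported shift for a pair is `median(rank in group2) - median(rank
#' in group1)`: positive means the tissue ranks worse (contributes less) in
#' group2, negative means it climbs the ranking (contributes more).
#'
#' @param ranks Samples x tissues rank matrix ([cohort_tissue_ranks()]).
#' @param groups Group label per sample (>= 2 groups, >= 2 samples each).
#' @param alpha Significance level on adjusted p (default 0.05).
#' @return List: `by_tissue` (data frame `tissue`, `kw_p`, `kw_p_adj`),
#'   `pairwise` (data frame `tissue`, `group1`, `group2`, `z`, `p`,
#'   `p_adj`, `rank_shift`, `significant`).
#' @export
rank_shift_test <- function(ranks, groups, alpha = 0.05) {
  if (nrow(ranks) != length(groups)) cf_stop("one group label per sample row")
  if (anyNA(ranks)) cf_stop("tissue missing in at least one sample")
  gl <- unique(groups)
  if (length(gl) < 2L) cf_stop("need at least two groups")
  if (any(table(groups) < 2L)) cf_stop("need at least two samples per group")
  tissues <- colnames(ranks)
  kw_p <- numeric(length(tissues))
  pair_rows <- vector("list", length(tissues))
  for (j in seq_along(tissues)) {
    by_group <- split(ranks[, j], factor(groups, levels = gl))
    kw_p[j] <- kruskal_wallis(by_group)$p.value
    dn <- dunn_posthoc(by_group)
    med <- vapply(by_group, stats::median, numeric(1))
    dn$rank_shift <- med[dn$group2] - med[dn$group1]
    dn$tissue <- tissues[j]
    pair_rows[[j]] <- dn[c("tissue", "group1", "group2", "z", "p", "rank_shift")]
  }
  pairwise <- do.call(rbind, pair_rows)
  # BH across tissues within each group pair (the reported tables are
  # per-pair lists of tissues).
  pairwise$p_adj <- NA_real_
  for (key in unique(paste(pairwise$group1, pairwise$group2))) {
    sel <- paste(pairwise$group1, pairwise$group2) == key
    pairwise$p_adj[sel] <- bh_fdr(pairwise$p[sel])
  }
  kw_gate <- stats::setNames(kw_p < alpha, tissues)
  pairwise$significant <- pairwise$p_adj < alpha & kw_gate[pairwise$tissue]
  list(by_tissue = data.frame(tissue = tissues, kw_p = kw_p,
                              kw_p_adj = bh_fdr(kw_p)),
       pairwise = pairwise)
}

#' Format significant rank shifts as a report table
#'
#' One row per significant tissue x group pair, with the shift magnitude in
#' parentheses after the tissue name (negative = increased contribution).
#'
#' @param shift A [rank_shift_test()] result.
#' @return Data frame `group1`, `group2`, `tissue`, `p_adj`, `label`.
#' @export
format_rank_shifts <- function(shift) {
  sig <- shift$pairwise[shift$pairwise$significant, , drop = FALSE]
  data.frame(group1 = sig$group1, group2 = sig$group2, tissue = sig$tissue,
             p_adj = sig$p_adj,
             label = sprintf("%s (%+g)", sig$tissue, sig$rank_shift),
             row.names = NULL)
}
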