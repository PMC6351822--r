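# Synthetic cfDNA cohort simulator.
#
# The generator does not attempt to model sequencing chemistry; it produces
# aligned fragment intervals whose statistics carry the structure the
# downstream analyses look for: a chromatosome-length fragment mixture,
# compartment-dependent baseline coverage per 100-kb bin, nucleosome-depleted
# dips at TSS/TTS/CTCF, a phased (cosine) nucleosome array downstream of each
# TSS whose amplitude anti-correlates with mixture-weighted expression, and
# attenuated coverage over repeat 5' regions. Coordinates are 0-based
# half-open (BED dialect) throughout.

SUBCOMPARTMENTS <- c("A1", "A2", "B1", "B2", "B3")

#' Fragment length model
#'
#' Truncated-normal model for cfDNA fragment lengths. The defaults
#' (mean 170, sd 10, clipped to \[100, 400\]) put the modal mass in the
#' chromatosome-protected 166-175 bp range seen in plasma cfDNA.
#'
#' @param mean,sd,min,max Length parameters in bp.
#' @return A `fragment_length_model` list.
#' @export
fragment_length_model <- function(mean = 170, sd = 10, min = 100, max = 400) {
  if (!(min <= mean && mean <= max)) cf_stop("need min <= mean <= max")
  if (sd <= 0) cf_stop("sd must be positive")
  structure(list(mean = mean, sd = sd, min = min, max = max),
            class = "fragment_length_model")
}

#' Group-level simulation parameters
#'
#' Bundles the per-group knobs the simulator uses to plant the effects the
#' analyses are meant to recover.
#'
#' @param name Group label (e.g. `"young"`).
#' @param compartment_weights Named non-negative weights for the five
#'   subcompartments A1, A2, B1, B2, B3: relative baseline coverage of a bin
#'   carrying that label.
#' @param ndr_depth Fraction in \[0, 1\] of coverage removed at the centre of
#'   each TSS/TTS/CTCF nucleosome-depleted dip.
#' @param phasing_amplitude Relative amplitude in \[0, 1\] of the periodic
#'   nucleosome-array component downstream of TSS and flanking CTCF sites.
#' @param repeat_5p_weight Non-negative multiplier on coverage over repeat
#'   element 5' consensus regions.
#' @param tissue_mixture Named non-negative tissue weights summing to 1
#'   (tolerance 1e-9).
#' @return A `group_params` list.
#' @export
group_params <- function(name, compartment_weights, ndr_depth,
                         phasing_amplitude, repeat_5p_weight, tissue_mixture) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    cf_stop("`name` must be a non-empty string")
  if (is.null(names(compartment_weights)) ||
      !all(SUBCOMPARTMENTS %in% names(compartment_weights)))
    cf_stop("`compartment_weights` must be named with all of ",
            paste(SUBCOMPARTMENTS, collapse = ", "))
  if (any(compartment_weights < 0)) cf_stop("compartment weights must be >= 0")
  if (!(ndr_depth >= 0 && ndr_depth <= 1)) cf_stop("`ndr_depth` must be in [0, 1]")
  if (!(phasing_amplitude >= 0 && phasing_amplitude <= 1))
    cf_stop("`phasing_amplitude` must be in [0, 1]")
  if (repeat_5p_weight < 0) cf_stop("`repeat_5p_weight` must be >= 0")
  if (is.null(names(tissue_mixture)) || any(tissue_mixture < 0))
    cf_stop("`tissue_mixture` must be named and non-negative")
  if (abs(sum(tissue_mixture) - 1) > 1e-9)
    cf_stop("`tissue_mixture` must sum to 1 (tolerance 1e-9)")
  structure(list(name = name,
                 compartment_weights = compartment_weights[SUBCOMPARTMENTS],
                 ndr_depth = ndr_depth,
                 phasing_amplitude = phasing_amplitude,
                 repeat_5p_weight = repeat_5p_weight,
                 tissue_mixture = tissue_mixture),
            class = "group_params")
}

#' Default four-group study design
#'
#' Parameter sets for the young / healthy-centenarian / old /
#' unhealthy-centenarian design. The defaults are stand-ins chosen to embody
#' the qualitative age effects the analyses target, in the directions the
#' plasma study reports: baseline bin coverage highest in B1, then A, then
#' B2/B3 in the young group, with B2/B3 gaining and A1/B1 losing signal with
#' age; TSS/TTS dips deepening (young < healthy centenarian < old < unhealthy
#' centenarian); phasing amplitude and repeat 5' coverage decaying in the
#' same order; and, in the old group only, a doubled weight for the last
#' tissue of the mixture.
#'
#' @param tissues Tissue names for the mixture (default `tissue1..tissue5`).
#' @param planted_tissue Tissue whose mixture weight is doubled in `"old"`;
#'   defaults to the last one.
#' @return Named list of four [group_params()] objects in age order
#'   young, healthy_cent, old, unhealthy_cent.
#' @export
default_group_params <- function(tissues = paste0("tissue", 1:5),
                                 planted_tissue = tissues[length(tissues)]) {
  nt <- length(tissues)
  if (nt < 2L) cf_stop("need at least two tissues")
  if (!planted_tissue %in% tissues) cf_stop("`planted_tissue` not in `tissues`")
  # Base mixture: the planted tissue gets 2/3 of the others' weight, so it
  # ranks last at baseline but first once its weight doubles (the margin on
  # both sides of the crossing is maximal at this ratio).
  base <- rep(1.5, nt)
  base[tissues == planted_tissue] <- 1
  base <- base / sum(base)
  names(base) <- tissues
  old_mix <- base
  old_mix[planted_tissue] <- 2 * old_mix[planted_tissue]
  old_mix <- old_mix / sum(old_mix)
  w <- function(a1, a2, b1, b2, b3) c(A1 = a1, A2 = a2, B1 = b1, B2 = b2, B3 = b3)
  list(
    young = group_params("young", w(1.25, 1.15, 1.40, 0.85, 0.70),
                         ndr_depth = 0.45, phasing_amplitude = 0.80,
                         repeat_5p_weight = 1.00, tissue_mixture = base),
    healthy_cent = group_params("healthy_cent", w(1.18, 1.12, 1.35, 0.92, 0.78),
                                ndr_depth = 0.55, phasing_amplitude = 0.70,
                                repeat_5p_weight = 0.85, tissue_mixture = base),
    old = group_params("old", w(1.08, 1.08, 1.27, 1.02, 0.88),
                       ndr_depth = 0.65, phasing_amplitude = 0.60,
                       repeat_5p_weight = 0.70, tissue_mixture = old_mix),
    unhealthy_cent = group_params("unhealthy_cent", w(1.02, 1.06, 1.22, 1.08, 0.95),
                                  ndr_depth = 0.75, phasing_amplitude = 0.50,
                                  repeat_5p_weight = 0.60, tissue_mixture = base)
  )
}

#' Genome model configuration
#'
#' @param chromosomes Named numeric vector of chromosome lengths in bp.
#' @param binsize Bin width for subcompartment labels (default 100 kb).
#' @param n_genes,n_ctcf Number of genes / CTCF sites to place.
#' @param gene_length Range of gene body lengths in bp.
#' @param repeat_families List of repeat family configs, each a list with
#'   `family`, `consensus_length`, `n`, `length_range` and optionally
#'   `truncated_fraction` (share of copies 5'-truncated).
#' @param genes,ctcf_sites,repeats,bin_labels Optional explicit annotation
#'   tables overriding random placement; validated against the invariants.
#' @return A `genome_config` list.
#' @export
genome_config <- function(chromosomes = c(chr1 = 2e6, chr2 = 2e6),
                          binsize = 1e5, n_genes = 40L, n_ctcf = 30L,
                          gene_length = c(12000, 20000),
                          repeat_families = list(
                            list(family = "L1HS", consensus_length = 6000,
                                 n = 10L, length_range = c(3000, 6000),
                                 truncated_fraction = 0.3),
                            list(family = "AluY", consensus_length = 310,
                                 n = 10L, length_range = c(250, 310),
                                 truncated_fraction = 0)),
                          genes = NULL, ctcf_sites = NULL, repeats = NULL,
                          bin_labels = NULL) {
  structure(list(chromosomes = chromosomes, binsize = binsize,
                 n_genes = n_genes, n_ctcf = n_ctcf,
                 gene_length = gene_length, repeat_families = repeat_families,
                 genes = genes, ctcf_sites = ctcf_sites, repeats = repeats,
                 bin_labels = bin_labels),
            class = "genome_config")
}

validate_genes <- function(genes, chromosomes) {
  need <- c("id", "chrom", "tss", "tts", "strand")
  if (!all(need %in% names(genes))) cf_stop("genes need columns ", paste(need, collapse = ", "))
  len <- chromosomes[genes$chrom]
  if (any(is.na(len))) cf_stop("gene on unknown chromosome")
  lo <- pmin(genes$tss, genes$tts)
  hi <- pmax(genes$tss, genes$tts)
  if (any(lo < 0) || any(hi > len))
    cf_stop("gene coordinates beyond chromosome end")
  plus <- genes$strand == "+"
  if (any(genes$tss[plus] >= genes$tts[plus]) ||
      any(genes$tss[!plus] <= genes$tts[!plus]))
    cf_stop("need tss < tts on '+' genes and tss > tts on '-' genes")
  genes
}

validate_repeats <- function(repeats, chromosomes) {
  need <- c("family", "chrom", "start", "end", "strand",
            "consensus_offset", "consensus_length")
  if (!all(need %in% names(repeats)))
    cf_stop("repeats need columns ", paste(need, collapse = ", "))
  if (any(repeats$consensus_offset < 0)) cf_stop("consensus_offset must be >= 0")
  if (any(repeats$end - repeats$start >
          repeats$consensus_length - repeats$consensus_offset))
    cf_stop("element longer than remaining consensus")
  len <- chromosomes[repeats$chrom]
  if (any(repeats$start < 0) || any(repeats$end > len))
    cf_stop("repeat beyond chromosome end")
  # Reject overlapping copies on the same strand.
  key <- split(repeats, list(repeats$chrom, repeats$strand), drop = TRUE)
  for (k in key) {
    if (nrow(k) < 2L) next
    o <- order(k$start)
    if (any(k$start[o][-1L] < k$end[o][-nrow(k)]))
      cf_stop("overlapping repeat copies on the same strand")
  }
  repeats
}

#' Build a synthetic genome model
#'
#' Deterministically (given `config` and `seed`) lays out a small genome:
#' equal-width bins carrying one subcompartment label each (all five labels
#' represented in near-equal proportion), stranded genes placed on
#' non-overlapping slots, CTCF sites, and repeat-element copies with
#' consensus coordinates (a configurable fraction 5'-truncated).
#'
#' @param config A [genome_config()].
#' @param seed RNG seed.
#' @return A `genome_model` list: `chromosomes`, `binsize`, `bins`
#'   (chrom/start/end/label), `genes` (id/chrom/tss/tts/strand), `ctcf_sites`
#'   (chrom/pos), `repeats` (BED6 + consensus_offset/consensus_length).
#' @export
build_genome_model <- function(config = genome_config(), seed = 1L) {
  stopifnot(inherits(config, "genome_config"))
  chrom <- config$chromosomes
  if (length(chrom) < 1L) cf_stop("need at least one chromosome")
  if (is.null(names(chrom)) || any(!nzchar(names(chrom))))
    cf_stop("chromosomes must be named")
  if (any(chrom <= 0)) cf_stop("zero-length chromosome")
  binsize <- config$binsize
  if (!is_count(binsize, 1)) cf_stop("invalid binsize")

  nbins <- floor(chrom / binsize)
  if (any(nbins < 1)) cf_stop("every chromosome must hold at least one full bin")
  bins <- data.frame(
    chrom = rep(names(chrom), nbins),
    start = unlist(lapply(nbins, function(n) (seq_len(n) - 1) * binsize), use.names = FALSE),
    stringsAsFactors = FALSE)
  bins$end <- bins$start + binsize

  with_seed(seed, {
    if (is.null(config$bin_labels)) {
      bins$label <- sample(rep_len(SUBCOMPARTMENTS, nrow(bins)))
    } else {
      if (length(config$bin_labels) != nrow(bins) ||
          !all(config$bin_labels %in% SUBCOMPARTMENTS))
        cf_stop("`bin_labels` must supply one valid label per bin")
      bins$label <- config$bin_labels
    }

    if (is.null(config$genes)) {
      genes <- place_genes(chrom, config$n_genes, config$gene_length)
    } else {
      genes <- validate_genes(config$genes, chrom)
    }

    if (is.null(config$ctcf_sites)) {
      pad <- 3000
      per <- drop_distribute(config$n_ctcf, chrom)
      ctcf <- data.frame(
        chrom = rep(names(chrom), per),
        pos = unlist(lapply(seq_along(chrom), function(i) {
          sort(round(runif(per[i], pad, chrom[i] - pad)))
        }), use.names = FALSE))
    } else {
      ctcf <- config$ctcf_sites
      if (any(ctcf$pos < 0) || any(ctcf$pos >= chrom[ctcf$chrom]))
        cf_stop("CTCF site beyond chromosome end")
    }

    if (is.null(config$repeats)) {
      repeats <- place_repeats(chrom, config$repeat_families)
    } else {
      repeats <- validate_repeats(config$repeats, chrom)
    }
  })

  structure(list(chromosomes = chrom, binsize = binsize, bins = bins,
                 genes = genes, ctcf_sites = ctcf, repeats = repeats),
            class = "genome_model")
}

# Distribute n items across chromosomes proportionally to length.
drop_distribute <- function(n, chrom) {
  per <- floor(n * chrom / sum(chrom))
  rem <- n - sum(per)
  if (rem > 0) per[seq_len(rem)] <- per[seq_len(rem)] + 1
  as.integer(per)
}

place_genes <- function(chrom, n_genes, gene_length) {
  if (!is_count(n_genes, 1)) cf_stop("need at least one gene")
  per <- drop_distribute(n_genes, chrom)
  margin <- 4000
  out <- vector("list", length(chrom))
  for (i in seq_along(chrom)) {
    if (per[i] == 0L) next
    slot <- floor((chrom[i] - 2 * margin) / per[i])
    if (slot < gene_length[2] + 2000)
      cf_stop("chromosome too short for requested gene count")
    glen <- round(runif(per[i], gene_length[1], gene_length[2]))
    lo <- margin + (seq_len(per[i]) - 1) * slot +
      round(runif(per[i], 0, pmax(0, slot - glen - 2000)))
    strand <- sample(c("+", "-"), per[i], replace = TRUE)
    out[[i]] <- data.frame(
      chrom = names(chrom)[i],
      tss = ifelse(strand == "+", lo, lo + glen),
      tts = ifelse(strand == "+", lo + glen, lo),
      strand = strand, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, out)
  genes$id <- sprintf("gene%03d", seq_len(nrow(genes)))
  genes[c("id", "chrom", "tss", "tts", "strand")]
}

place_repeats <- function(chrom, families) {
  out <- list()
  occupied <- lapply(chrom, function(...) data.frame(start = numeric(0), end = numeric(0), strand = character(0)))
  for (fam in families) {
    n <- fam$n
    if (n == 0L) next
    placed <- 0L
    tries <- 0L
    while (placed < n && tries < 200L * n) {
      tries <- tries + 1L
      ci <- sample.int(length(chrom), 1L, prob = chrom)
      len <- round(runif(1, fam$length_range[1], fam$length_range[2]))
      trunc_frac <- fam$truncated_fraction %||% 0
      off <- if (runif(1) < trunc_frac && fam$consensus_length > len) {
        sample.int(fam$consensus_length - len, 1L)
      } else 0L
      len <- min(len, fam$consensus_length - off)
      start <- round(runif(1, 1000, chrom[ci] - len - 1000))
      strand <- sample(c("+", "-"), 1L)
      occ <- occupied[[ci]]
      clash <- any(occ$strand == strand & start < occ$end & start + len > occ$start)
      if (clash) next
      occupied[[ci]] <- rbind(occ, data.frame(start = start, end = start + len, strand = strand))
      placed <- placed + 1L
      out[[length(out) + 1L]] <- data.frame(
        family = fam$family, chrom = names(chrom)[ci], start = start,
        end = start + len, strand = strand, consensus_offset = off,
        consensus_length = fam$consensus_length, stringsAsFactors = FALSE)
    }
    if (placed < n) cf_stop("could not place ", n, " non-overlapping copies of ", fam$family)
  }
  rp <- do.call(rbind, out)
  rp[order(rp$chrom, rp$start), , drop = FALSE]
}

#' Simulate a tissue-by-gene expression table
#'
#' Log-normal background expression with, per tissue, a disjoint set of
#' marker genes set to a common elevated level (`marker_factor` times the
#' background scale) — a stand-in for a curated marker-panel expression
#' resource of the kind used for tissue deconvolution. With the default
#' fraction 0.19 and five tissues, nearly every gene is a marker of exactly
#' one tissue, which makes the tissues statistically exchangeable apart
#' from their mixture weights.
#'
#' @param n_genes,n_tissues Table dimensions (both >= 1).
#' @param seed RNG seed.
#' @param marker_fraction Fraction of genes that are markers of each tissue.
#' @param marker_factor Fold elevation of marker genes over the background
#'   scale.
#' @param background_sdlog Log-normal sd of the non-marker background
#'   (default 0.5; 0 gives a binary marker panel with constant background,
#'   under which tissues are exactly exchangeable apart from mixture
#'   weights).
#' @param gene_ids,tissue_ids Optional dimension names.
#' @return Numeric matrix, tissues in rows, genes in columns, all values >= 0,
#'   with a `markers` attribute (list of marker gene ids per tissue).
#' @export
simulate_tissue_expression <- function(n_genes, n_tissues, seed = 1L,
                                       marker_fraction = 0.19,
                                       marker_factor = 20,
                                       background_sdlog = 0.5,
                                       gene_ids = sprintf("gene%03d", seq_len(n_genes)),
                                       tissue_ids = sprintf("tissue%d", seq_len(n_tissues))) {
  if (!is_count(n_genes, 1) || !is_count(n_tissues, 1))
    cf_stop("`n_genes` and `n_tissues` must be positive integers")
  n_mark <- floor(marker_fraction * n_genes)
  if (n_mark * n_tissues > n_genes)
    cf_stop("marker sets must be disjoint: reduce `marker_fraction`")
  base_scale <- 5
  with_seed(seed, {
    expr <- matrix(stats::rlnorm(n_tissues * n_genes, meanlog = log(base_scale),
                                 sdlog = background_sdlog),
                   nrow = n_tissues, dimnames = list(tissue_ids, gene_ids))
    markers <- list()
    if (n_mark > 0) {
      pool <- sample(gene_ids, n_mark * n_tissues)
      for (t in seq_len(n_tissues)) {
        mk <- pool[((t - 1) * n_mark + 1):(t * n_mark)]
        expr[t, mk] <- marker_factor * base_scale
        markers[[tissue_ids[t]]] <- mk
      }
    }
  })
  attr(expr, "markers") <- markers
  expr
}

# Mixture-weighted expression per gene, normalized so the maximum is 1.
mixture_expression <- function(expression, tissue_mixture, gene_ids) {
  if (!all(gene_ids %in% colnames(expression)))
    cf_stop("expression table must cover all gene ids")
  tm <- tissue_mixture[rownames(expression)]
  if (any(is.na(tm)))
    cf_stop("tissue_mixture must name every tissue of the expression table")
  x <- as.numeric(tm %*% expression[, gene_ids, drop = FALSE])
  mx <- max(x)
  if (mx > 0) x <- x / mx
  stats::setNames(x, gene_ids)
}

#' Per-base protection track for one group
#'
#' Builds the expected-coverage (protection) track the fragment sampler
#' draws midpoints from. Per chromosome the track is a product of:
#' a per-bin baseline proportional to `compartment_weights[label]`;
#' Gaussian nucleosome-depleted dips of relative depth `ndr_depth` at each
#' TSS, TTS and CTCF site; a cosine nucleosome-array component of period
#' `spacing` downstream of each TSS with amplitude
#' `phasing_amplitude * (1 - normalized mixture-weighted expression)` (and
#' amplitude `phasing_amplitude` flanking CTCF sites, unstranded); and a
#' `repeat_5p_weight` multiplier over each repeat copy's 5' consensus region.
#'
#' @param model A [build_genome_model()] result.
#' @param params A [group_params()] object.
#' @param expression Tissue-by-gene expression matrix covering all gene ids.
#' @param spacing Planted nucleosome spacing in bp (default 196, inside the
#'   193-199 bp phasing band).
#' @param ndr_sigma,ctcf_sigma Gaussian dip widths (bp) at gene / CTCF anchors.
#' @param phasing_span Length of the phased array downstream of each TSS (bp).
#' @param ctcf_span Half-width of the phased array flanking CTCF sites (bp).
#' @param repeat_5p_len Consensus length (bp) counted as the 5' region.
#' @return Named list of per-chromosome numeric vectors (>= 0 everywhere);
#'   element `i` of a vector is the protection at 0-based position `i - 1`.
#' @export
protection_profile <- function(model, params, expression, spacing = 196,
                               ndr_sigma = 300, ctcf_sigma = 100,
                               phasing_span = 10000, ctcf_span = 2000,
                               repeat_5p_len = 668) {
  stopifnot(inherits(model, "genome_model"), inherits(params, "group_params"))
  if (any(params$compartment_weights < 0)) cf_stop("negative compartment weight")
  xw <- mixture_expression(expression, params$tissue_mixture, model$genes$id)
  amp <- params$phasing_amplitude * (1 - xw)

  out <- list()
  for (ci in seq_along(model$chromosomes)) {
    cn <- names(model$chromosomes)[ci]
    clen <- model$chromosomes[[ci]]
    b <- model$bins[model$bins$chrom == cn, ]
    w <- unname(params$compartment_weights[b$label])
    track <- rep(w, each = model$binsize)
    if (length(track) < clen)  # terminal partial bin: carry mean weight
      track <- c(track, rep(mean(w), clen - length(track)))
    track <- track[seq_len(clen)]

    # NDR dips are applied by in-place subassignment; routing the track
    # through a helper would copy the whole vector at every anchor.
    dip_at <- function(anchor, sigma) {
      w <- round(4 * sigma)
      idx <- max(0, anchor - w):min(clen - 1, anchor + w)
      list(i = idx + 1,
           f = 1 - params$ndr_depth * exp(-0.5 * ((idx - anchor) / sigma)^2))
    }

    g <- model$genes[model$genes$chrom == cn, ]
    for (k in seq_len(nrow(g))) {
      d1 <- dip_at(g$tss[k], ndr_sigma)
      track[d1$i] <- track[d1$i] * d1$f
      d2 <- dip_at(g$tts[k], ndr_sigma)
      track[d2$i] <- track[d2$i] * d2$f
      a <- amp[[g$id[k]]]
      if (a > 0) {
        dir <- if (g$strand[k] == "+") 1 else -1
        d <- 0:(phasing_span - 1)
        pos <- g$tss[k] + dir * d
        ok <- pos >= 0 & pos < clen
        track[pos[ok] + 1] <- track[pos[ok] + 1] *
          (1 + a * cos(2 * pi * d[ok] / spacing))
      }
    }

    ct <- model$ctcf_sites[model$ctcf_sites$chrom == cn, ]
    for (k in seq_len(nrow(ct))) {
      d1 <- dip_at(ct$pos[k], ctcf_sigma)
      track[d1$i] <- track[d1$i] * d1$f
      if (params$phasing_amplitude > 0) {
        d <- -ctcf_span:ctcf_span
        pos <- ct$pos[k] + d
        ok <- pos >= 0 & pos < clen
        track[pos[ok] + 1] <- track[pos[ok] + 1] *
          (1 + params$phasing_amplitude * cos(2 * pi * d[ok] / spacing))
      }
    }

    rp <- model$repeats[model$repeats$chrom == cn, ]
    for (k in seq_len(nrow(rp))) {
      # Genomic footprint of consensus positions < repeat_5p_len.
      n5 <- repeat_5p_len - rp$consensus_offset[k]
      if (n5 <= 0) next
      n5 <- min(n5, rp$end[k] - rp$start[k])
      idx <- if (rp$strand[k] == "+") {
        rp$start[k]:(rp$start[k] + n5 - 1)
      } else {
        (rp$end[k] - n5):(rp$end[k] - 1)
      }
      track[idx + 1] <- track[idx + 1] * params$repeat_5p_weight
    }

    out[[cn]] <- track
  }
  out
}

#' Sample a fragment library from a protection track
#'
#' Fragment midpoints (nucleosome dyads) are sampled proportionally to the
#' track, jittered uniformly by up to `jitter` bp, and extended to lengths
#' drawn from the truncated-normal fragment length model; fragments are
#' shifted to stay within the chromosome. Exactly `depth` fragments are
#' returned, reproducibly for a given seed.
#'
#' @param track Named list of per-chromosome protection vectors
#'   (from [protection_profile()]).
#' @param depth Number of fragments to emit (>= 0).
#' @param flm A [fragment_length_model()].
#' @param seed RNG seed.
#' @param jitter Maximum midpoint jitter in bp (uniform on `-jitter:jitter`).
#' @param sample_id,group Metadata stored on the returned library.
#' @return A [sample_library()].
#' @export
simulate_fragments <- function(track, depth, flm = fragment_length_model(),
                               seed = 1L, jitter = 10L,
                               sample_id = "sample", group = NA_character_) {
  stopifnot(inherits(flm, "fragment_length_model"))
  if (!is_count(depth)) cf_stop("`depth` must be a non-negative integer")
  if (!is.list(track) || is.null(names(track))) cf_stop("`track` must be a named list")
  totals <- vapply(track, sum, numeric(1))
  if (any(totals < 0) || any(vapply(track, function(t) any(t < 0), logical(1))))
    cf_stop("track must be non-negative")
  if (depth == 0L) {
    return(sample_library(empty_fragments(), sample_id = sample_id, group = group))
  }
  if (sum(totals) == 0) cf_stop("all-zero track with positive depth")

  frags <- with_seed(seed, {
    per <- drop(stats::rmultinom(1, depth, totals))
    parts <- vector("list", length(track))
    for (i in seq_along(track)) {
      n <- per[i]
      if (n == 0L) next
      cw <- cumsum(track[[i]])
      clen <- length(track[[i]])
      pos <- findInterval(runif(n, 0, cw[clen]), cw)  # 0-based midpoint
      mid <- pos + sample(seq.int(-jitter, jitter), n, replace = TRUE)
      len <- rtrunc_lengths(n, flm$mean, flm$sd, flm$min, flm$max)
      start <- mid - len %/% 2L
      start <- pmax(0L, pmin(start, clen - len))
      parts[[i]] <- data.frame(
        chrom = names(track)[i], start = start, end = start + len,
        strand = sample(c("+", "-"), n, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, parts)
  })
  frags$name <- sprintf("f%07d", seq_len(nrow(frags)))
  frags$mapq <- 60L
  frags$duplicate <- 0L
  frags$clipped <- 0L
  sample_library(frags[c("chrom", "start", "end", "name", "mapq", "strand",
                         "duplicate", "clipped")],
                 sample_id = sample_id, group = group)
}

#' Simulate a multi-sample cfDNA cohort with ground truth
#'
#' One protection track per group, `replicates` fragment libraries per group
#' with per-sample seeds derived deterministically from the top-level seed,
#' and a truth record (per-sample seeds, depths, tissue mixtures, planted
#' nucleosome spacing and group parameters) for parameter-recovery tests.
#' The default design mirrors a four-group, three-replicate study (12
#' libraries).
#'
#' @param groups Named list of [group_params()] (unique names required).
#' @param replicates Libraries per group (>= 1).
#' @param model A [build_genome_model()] result.
#' @param expression Expression matrix covering the model's gene ids.
#' @param depth Fragments per library.
#' @param flm A [fragment_length_model()].
#' @param seed Top-level RNG seed.
#' @param spacing Planted nucleosome spacing in bp.
#' @param ... Further arguments passed to [protection_profile()].
#' @return A `cfdna_cohort` list: `samples` (list of [sample_library()]) and
#'   `truth` (see [write_truth()]).
#' @export
simulate_cohort <- function(groups, replicates = 3L, model, expression,
                            depth = 40000L, flm = fragment_length_model(),
                            seed = 1L, spacing = 196, ...) {
  if (!is.list(groups) || length(groups) < 1L) cf_stop("need at least one group")
  nm <- vapply(groups, function(g) g$name, character(1))
  if (anyDuplicated(nm)) cf_stop("duplicate group names")
  if (!is_count(replicates, 1)) cf_stop("need at least one replicate")

  samples <- list()
  meta <- list()
  idx <- 0L
  for (g in groups) {
    track <- protection_profile(model, g, expression, spacing = spacing, ...)
    for (r in seq_len(replicates)) {
      idx <- idx + 1L
      sid <- paste0(g$name, "_", r)
      sseed <- derive_seed(seed, idx)
      samples[[sid]] <- simulate_fragments(track, depth, flm, seed = sseed,
                                           sample_id = sid, group = g$name)
      meta[[idx]] <- data.frame(sample_id = sid, group = g$name,
                                seed = sseed, depth = depth,
                                stringsAsFactors = FALSE)
    }
  }
  truth <- list(
    seed = seed, spacing = spacing, replicates = replicates,
    flm = unclass(flm),
    samples = do.call(rbind, meta),
    groups = lapply(groups, function(g) {
      list(name = g$name,
           compartment_weights = as.list(g$compartment_weights),
           ndr_depth = g$ndr_depth,
           phasing_amplitude = g$phasing_amplitude,
           repeat_5p_weight = g$repeat_5p_weight,
           tissue_mixture = as.list(g$tissue_mixture))
    }))
  structure(list(samples = samples, truth = truth), class = "cfdna_cohort")
}

#' Write / read the cohort ground-truth record as JSON
#'
#' The truth record round-trips losslessly: `read_truth(write_truth(x, f))`
#' reproduces the record.
#'
#' @param truth Truth list from [simulate_cohort()].
#' @param path Output JSON path.
#' @return `write_truth` returns `path` invisibly; `read_truth` the record.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$samples <- as.data.frame(x$samples, stringsAsFactors = FALSE)
  x$groups <- lapply(x$groups, function(g) {
    g$compartment_weights <- as.list(g$compartment_weights)
    g$tissue_mixture <- as.list(g$tissue_mixture)
    g
  })
  x
}

#' @export
print.cfdna_cohort <- function(x, ...) {
  cat("cfDNA cohort:", length(x$samples), "samples,",
      length(unique(x$truth$samples$group)), "groups, depth",
      x$truth$samples$depth[1], "fragments/sample\n")
  invisible(x)
}
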