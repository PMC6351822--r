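# Independent oracles and small fixture builders shared across tests.

# Brute-force WPS: double loop over positions x fragments, straight from
# the definition (fragments spanning the whole window minus fragments with
# an endpoint inside it).
wps_brute <- function(frags, start, end, w = 120L) {
  h <- w %/% 2L
  vapply(start:(end - 1L), function(p) {
    win_lo <- p - h
    win_hi <- p + h  # window is [win_lo, win_hi)
    span <- sum(frags$start <= win_lo & frags$end >= win_hi)
    endpoint_in <- function(q) q >= win_lo & q < win_hi
    ends_in <- sum(endpoint_in(frags$start) | endpoint_in(frags$end - 1L))
    span - ends_in
  }, numeric(1))
}

# Brute-force per-base pileup around one anchor set (plus strand only).
pileup_brute <- function(frags, chrom, pos, flank) {
  offs <- -flank:flank
  vapply(offs, function(o) {
    g <- pos + o
    sum(frags$chrom == chrom & frags$start <= g & frags$end > g)
  }, numeric(1))
}

# Tiny deterministic library from explicit intervals.
lib_from_intervals <- function(starts, ends, chrom = "chr1", strand = "+",
                               mapq = 60L, duplicate = 0L, clipped = 0L, ...) {
  n <- length(starts)
  sample_library(data.frame(chrom = rep_len(chrom, n),
                            start = starts, end = ends,
                            strand = rep_len(strand, n),
                            mapq = rep_len(mapq, n),
                            duplicate = rep_len(duplicate, n),
                            clipped = rep_len(clipped, n),
                            stringsAsFactors = FALSE), ...)
}

# Small genome model used by several modules' tests.
small_model <- function(seed = 1L, chrom_len = 2e6, n_genes = 20L,
                        n_ctcf = 8L) {
  build_genome_model(
    genome_config(chromosomes = c(chr1 = chrom_len), n_genes = n_genes,
                  n_ctcf = n_ctcf),
    seed = seed)
}

# Uniform single-chromosome track.
flat_track <- function(len = 1e5, value = 1) {
  list(chr1 = rep(value, len))
}
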