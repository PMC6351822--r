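# Coverage of repeat-element consensus sequences: uniquely mapped fragments
# projected from genomic copies onto the consensus, plus multi-mapped
# fragments deposited with fractional 1/k weights, combined and normalized
# per million library fragments.

#' Project a genomic interval onto a repeat consensus
#'
#' Linear offset map for the overlap of a fragment with one element copy:
#' on the + strand, genomic position `g` maps to
#' `consensus_offset + (g - start)`; on the - strand to
#' `consensus_offset + (end - 1 - g)`. The projection is clipped to the
#' element's consensus span.
#'
#' @param start,end Fragment interval (0-based half-open).
#' @param element One-row data frame (or list) with `chrom`-free fields
#'   `start`, `end`, `strand`, `consensus_offset`, `consensus_length`.
#' @return Half-open consensus interval `c(start, end)`, or `NULL` if the
#'   fragment does not overlap the element.
#' @export
project_to_consensus <- function(start, end, element) {
  es <- element$start; ee <- element$end
  lo <- max(start, es); hi <- min(end, ee)
  if (lo >= hi) return(NULL)
  off <- element$consensus_offset
  if (element$strand == "+") {
    c(off + (lo - es), off + (hi - es))
  } else {
    c(off + (ee - hi), off + (ee - lo))
  }
}

#' Unique-read consensus profile
#'
#' Every fragment overlapping an element copy increments each consensus
#' position of its projection; a position's value is the total increments
#' divided by the number of element copies whose consensus span covers that
#' position (so 5'-truncated copies do not dilute positions they lack).
#'
#' @param lib A [sample_library()] of uniquely mapped fragments.
#' @param elements Data frame of one family's copies (`family`, `chrom`,
#'   `start`, `end`, `strand`, `consensus_offset`, `consensus_length`).
#' @return Numeric vector of per-position averages over the consensus
#'   (length `max(consensus_length)`).
#' @export
unique_profile <- function(lib, elements) {
  stopifnot(inherits(lib, "sample_library"))
  if (nrow(elements) == 0L) cf_stop("need at least one element copy")
  L <- max(elements$consensus_length)
  inc <- numeric(L + 1L)
  copies <- numeric(L + 1L)
  f <- lib$fragments
  for (k in seq_len(nrow(elements))) {
    el <- elements[k, ]
    span_lo <- el$consensus_offset
    span_hi <- el$consensus_offset + (el$end - el$start)
    copies[span_lo + 1L] <- copies[span_lo + 1L] + 1
    copies[span_hi + 1L] <- copies[span_hi + 1L] - 1
    sel <- which(f$chrom == el$chrom & f$end > el$start & f$start < el$end)
    for (i in sel) {
      ci <- project_to_consensus(f$start[i], f$end[i], el)
      inc[ci[1L] + 1L] <- inc[ci[1L] + 1L] + 1
      inc[ci[2L] + 1L] <- inc[ci[2L] + 1L] - 1
    }
  }
  inc <- cumsum(inc)[seq_len(L)]
  copies <- cumsum(copies)[seq_len(L)]
  ifelse(copies > 0, inc / copies, 0)
}

#' Multi-mapped fractional consensus profile
#'
#' Each multi-map record carries a consensus interval and the number `k` of
#' repeat subfamilies it mapped to; it deposits weight `1/k` on every
#' consensus position it covers (the consensus is a single sequence, so the
#' copy-averaging denominator is 1). Total deposited weight is exactly
#' the sum of covered length / k over records.
#'
#' @param records Data frame with `start`, `end` (half-open consensus
#'   interval) and `k` (>= 1, subfamily multiplicity).
#' @param consensus_length Consensus length in bp.
#' @return Numeric vector of per-position weighted counts.
#' @export
multimap_profile <- function(records, consensus_length) {
  if (!is_count(consensus_length, 1)) cf_stop("invalid consensus length")
  acc <- numeric(consensus_length + 1L)
  if (nrow(records) > 0L) {
    if (any(records$k < 1)) cf_stop("records must map to at least one subfamily")
    s <- pmax(records$start, 0)
    e <- pmin(records$end, consensus_length)
    ok <- s < e
    for (i in which(ok)) {
      w <- 1 / records$k[i]
      acc[s[i] + 1L] <- acc[s[i] + 1L] + w
      acc[e[i] + 1L] <- acc[e[i] + 1L] - w
    }
  }
  cumsum(acc)[seq_len(consensus_length)]
}

#' Combine and normalize consensus profiles
#'
#' Final consensus coverage is the sum of the unique-read average and the
#' multi-map weighted profile, normalized per million library fragments.
#'
#' @param unique,multi Per-position vectors of equal length.
#' @param library_size Retained fragment count of the sample (> 0).
#' @return A `consensus_profile` data frame: `position` (0-based), `unique`,
#'   `multi`, `combined`.
#' @export
combine_normalize <- function(unique, multi, library_size) {
  if (length(unique) != length(multi)) cf_stop("profiles must share the consensus length")
  if (!is.numeric(library_size) || library_size <= 0) cf_stop("library_size must be > 0")
  structure(data.frame(position = seq_along(unique) - 1L,
                       unique = unique, multi = multi,
                       combined = (unique + multi) * 1e6 / library_size),
            class = c("consensus_profile", "data.frame"))
}

#' Keep dimeric (full-length) Alu copies
#'
#' Dimeric AluY copies are defined by an element length of 280-320 bp
#' inclusive.
#'
#' @param elements Data frame of AluY copies with `start`, `end`.
#' @param min_len,max_len Inclusive length bounds (defaults 280 and 320).
#' @return The filtered element table.
#' @export
dimeric_alu_filter <- function(elements, min_len = 280, max_len = 320) {
  len <- elements$end - elements$start
  elements[len >= min_len & len <= max_len, , drop = FALSE]
}

#' Mean combined coverage over a consensus region
#'
#' Mean of the combined normalized values over positions `[start, end)` —
#' e.g. the first 668 bp of the L1HS 5'UTR, where its internal promoter
#' lies.
#'
#' @param profile A [combine_normalize()] result or a plain numeric vector.
#' @param start,end Half-open 0-based consensus region, within bounds.
#' @return Scalar mean.
#' @export
region_mean <- function(profile, start, end) {
  v <- if (inherits(profile, "consensus_profile")) profile$combined else profile
  if (!(start >= 0 && start < end && end <= length(v)))
    cf_stop("region out of consensus bounds")
  mean(v[(start + 1L):end])
}

#' Export a consensus profile as TSV
#'
#' @param profile A [combine_normalize()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consensus_profile <- function(profile, path) {
  stopifnot(inherits(profile, "consensus_profile"))
  utils::write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
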