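# Reading, filtering, downsampling and masking of cfDNA fragment libraries.
#
# The on-disk dialect is BED3+ with tab- or space-separated columns
#   chrom  start  end  name  mapq  strand  duplicate(0/1)  [clipped_bases]
# 0-based half-open. BAM input (coordinate-sorted, properly paired) is
# collapsed to one interval per fragment via Rsamtools.

empty_fragments <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             name = character(0), mapq = integer(0), strand = character(0),
             duplicate = integer(0), clipped = integer(0),
             stringsAsFactors = FALSE)
}

#' Fragment library container
#'
#' Holds one sample's fragment records (one row per sequenced cfDNA fragment,
#' as a 0-based half-open genomic interval with mapping quality, duplicate
#' flag and soft-clipped base count) plus sample metadata. `library_size`
#' always equals the number of retained records.
#'
#' @param fragments Data frame with columns `chrom`, `start`, `end`, and
#'   optionally `name`, `mapq`, `strand`, `duplicate`, `clipped` (defaulted
#'   when missing). Records with `end <= start` are invalid.
#' @param sample_id,group Sample metadata.
#' @param n_rejected Count of records rejected during parsing.
#' @return An object of class `sample_library`.
#' @export
sample_library <- function(fragments, sample_id = "sample",
                           group = NA_character_, n_rejected = 0L) {
  if (!is.data.frame(fragments)) cf_stop("`fragments` must be a data frame")
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(fragments)))
    cf_stop("fragments need columns ", paste(need, collapse = ", "))
  n <- nrow(fragments)
  if (is.null(fragments$name)) fragments$name <- sprintf("f%07d", seq_len(n))
  if (is.null(fragments$mapq)) fragments$mapq <- rep(60L, n)
  if (is.null(fragments$strand)) fragments$strand <- rep("+", n)
  if (is.null(fragments$duplicate)) fragments$duplicate <- rep(0L, n)
  if (is.null(fragments$clipped)) fragments$clipped <- rep(0L, n)
  fragments <- fragments[c("chrom", "start", "end", "name", "mapq", "strand",
                           "duplicate", "clipped")]
  if (n > 0) {
    if (any(fragments$end <= fragments$start))
      cf_stop("fragment records must satisfy end > start")
    if (any(fragments$mapq < 0)) cf_stop("mapq must be >= 0")
  }
  structure(list(sample_id = sample_id, group = group,
                 fragments = fragments, library_size = n,
                 n_rejected = as.integer(n_rejected)),
            class = "sample_library")
}

#' @export
print.sample_library <- function(x, ...) {
  cat("sample_library '", x$sample_id, "'", sep = "")
  if (!is.na(x$group)) cat(" [", x$group, "]", sep = "")
  cat(": ", x$library_size, " fragments", sep = "")
  if (x$n_rejected > 0) cat(" (", x$n_rejected, " rejected on input)", sep = "")
  cat("\n")
  invisible(x)
}

#' Read a fragment library from BED or BAM
#'
#' BED input follows the package dialect (see [write_fragments()]); columns
#' beyond chrom/start/end are optional. Malformed lines raise an error naming
#' the line number. Records with `end <= start` are dropped with a warning
#' and counted in `n_rejected`. When the BED file carries no duplicate-flag
#' column, coordinate duplicates (identical chrom/start/end/strand) beyond
#' the first occurrence are flagged as duplicates. Gzip-compressed BED is
#' accepted. BAM input keeps properly paired, non-secondary first mates and
#' collapses each pair to one interval (leftmost start to leftmost start +
#' insert size); soft-clipped bases are summed from the CIGAR.
#'
#' @param path File path.
#' @param format `"bed"` or `"bam"`.
#' @param sample_id,group Metadata for the returned library.
#' @return A [sample_library()].
#' @export
read_fragments <- function(path, format = c("bed", "bam"),
                           sample_id = sub("\\.(bed|bed\\.gz|bam)$", "", basename(path)),
                           group = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) cf_stop("file not found: ", path)
  if (format == "bam") return(read_fragments_bam(path, sample_id, group))

  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(sample_library(empty_fragments(), sample_id, group))

  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    cf_stop("malformed BED line ", lineno[which(nf < 3L)[1L]],
            ": fewer than 3 fields")
  get <- function(i, default = NULL) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  }
  start <- suppressWarnings(as.numeric(get(2L, NA_character_)))
  end <- suppressWarnings(as.numeric(get(3L, NA_character_)))
  bad <- !is.finite(start) | !is.finite(end)
  if (any(bad))
    cf_stop("malformed BED line ", lineno[which(bad)[1L]],
            ": non-numeric coordinates")
  df <- data.frame(chrom = get(1L), start = start, end = end,
                   stringsAsFactors = FALSE)
  df$name <- if (max(nf) >= 4L) get(4L, ".") else sprintf("f%07d", seq_len(nrow(df)))
  df$mapq <- if (max(nf) >= 5L) suppressWarnings(as.integer(get(5L, "60"))) else 60L
  df$strand <- if (max(nf) >= 6L) get(6L, "+") else "+"
  has_flag <- max(nf) >= 7L
  df$duplicate <- if (has_flag) suppressWarnings(as.integer(get(7L, "0"))) else 0L
  df$clipped <- if (max(nf) >= 8L) suppressWarnings(as.integer(get(8L, "0"))) else 0L
  df$mapq[is.na(df$mapq)] <- 60L
  df$duplicate[is.na(df$duplicate)] <- 0L
  df$clipped[is.na(df$clipped)] <- 0L

  invalid <- df$end <= df$start
  n_rej <- sum(invalid)
  if (n_rej > 0) {
    warning(n_rej, " record(s) with end <= start rejected", call. = FALSE)
    df <- df[!invalid, , drop = FALSE]
  }
  if (!has_flag && nrow(df) > 0) {
    # Coordinate-based deduplication when no explicit flag is present.
    df$duplicate <- as.integer(duplicated(df[c("chrom", "start", "end", "strand")]))
  }
  sample_library(df, sample_id, group, n_rejected = n_rej)
}

read_fragments_bam <- function(path, sample_id, group) {
  flags <- Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                                  isSecondaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE)
  par <- Rsamtools::ScanBamParam(
    flag = flags,
    what = c("rname", "pos", "isize", "mapq", "flag", "cigar", "qname"))
  b <- Rsamtools::scanBam(path, param = par)[[1L]]
  # Each proper pair is represented once, by its leftmost mate (isize > 0):
  # fragment spans [pos - 1, pos - 1 + isize) in 0-based half-open terms.
  ok <- !is.na(b$isize) & b$isize > 0
  left <- b$pos[ok] - 1L
  dup <- as.integer(bitwAnd(b$flag[ok], 1024L) > 0L)
  clip <- cigar_clipped(b$cigar[ok])
  df <- data.frame(chrom = as.character(b$rname[ok]), start = left,
                   end = left + b$isize[ok], name = b$qname[ok],
                   mapq = as.integer(b$mapq[ok]),
                   strand = "+", duplicate = dup, clipped = clip,
                   stringsAsFactors = FALSE)
  invalid <- df$end <= df$start
  if (any(invalid)) {
    warning(sum(invalid), " record(s) with end <= start rejected", call. = FALSE)
    df <- df[!invalid, , drop = FALSE]
  }
  sample_library(df, sample_id, group, n_rejected = sum(invalid))
}

cigar_clipped <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg)) return(0L)
    s <- regmatches(cg, gregexpr("[0-9]+S", cg))[[1L]]
    if (length(s) == 0L) return(0L)
    sum(as.integer(sub("S", "", s)))
  }, integer(1), USE.NAMES = FALSE)
}

#' Write a fragment library as BED3+
#'
#' Tab-separated chrom/start/end/name/mapq/strand/duplicate\[/clipped\];
#' paths ending in `.gz` are gzip-compressed. Round-trips losslessly through
#' [read_fragments()].
#'
#' @param lib A [sample_library()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(lib, path) {
  stopifnot(inherits(lib, "sample_library"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(lib$fragments, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

MITO_NAMES <- c("chrM", "MT", "M")
SEX_NAMES <- c("chrX", "X", "chrY", "Y")

#' Apply the standard cfDNA read filters
#'
#' Removes records on the mitochondrial and sex chromosomes, records with
#' mapping quality 0, duplicate records, and soft-clipped records whose
#' aligned span (`end - start`) is below `min_aligned` bp. Unclipped records
#' are not subject to the span threshold.
#'
#' @param lib A [sample_library()].
#' @param min_aligned Minimum aligned span for clipped records (default 75).
#' @return The filtered [sample_library()] with updated `library_size`.
#' @export
filter_fragments <- function(lib, min_aligned = 75) {
  stopifnot(inherits(lib, "sample_library"))
  f <- lib$fragments
  keep <- !(f$chrom %in% c(MITO_NAMES, SEX_NAMES)) &
    f$mapq > 0L &
    f$duplicate == 0L &
    (f$clipped == 0L | (f$end - f$start) >= min_aligned)
  sample_library(f[keep, , drop = FALSE], lib$sample_id, lib$group,
                 n_rejected = lib$n_rejected)
}

#' Downsample a library without replacement
#'
#' Uniform sampling of exactly `n` records, deterministic per seed. Matches
#' the study practice of downsampling all samples to a common depth before
#' bin-signal comparisons.
#'
#' @param lib A [sample_library()].
#' @param n Target record count (`n <= library_size`).
#' @param seed RNG seed.
#' @return The downsampled [sample_library()].
#' @export
downsample_fragments <- function(lib, n, seed = 1L) {
  stopifnot(inherits(lib, "sample_library"))
  if (!is_count(n)) cf_stop("`n` must be a non-negative integer")
  if (n > lib$library_size)
    cf_stop("cannot downsample to ", n, " from ", lib$library_size, " records")
  if (n == lib$library_size) return(lib)
  idx <- with_seed(seed, sort(sample.int(lib$library_size, n)))
  sample_library(lib$fragments[idx, , drop = FALSE], lib$sample_id, lib$group,
                 n_rejected = lib$n_rejected)
}

#' Remove fragments whose midpoint falls in masked intervals
#'
#' Intervals are 0-based half-open; the fragment midpoint is
#' `floor((start + end) / 2)`. A midpoint exactly at an interval end is
#' outside it. Masking with disjoint interval sets composes commutatively.
#'
#' @param lib A [sample_library()].
#' @param intervals Data frame with `chrom`, `start`, `end` (e.g. ±1500 bp
#'   windows around all TSS and TTS).
#' @return The masked [sample_library()].
#' @export
mask_fragments <- function(lib, intervals) {
  stopifnot(inherits(lib, "sample_library"))
  if (nrow(intervals) == 0L || lib$library_size == 0L) return(lib)
  if (any(intervals$end <= intervals$start))
    cf_stop("mask intervals must satisfy end > start")
  f <- lib$fragments
  mid <- (f$start + f$end) %/% 2
  masked <- logical(nrow(f))
  for (cn in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == cn, , drop = FALSE]
    iv <- merge_intervals(iv)
    sel <- f$chrom == cn
    if (!any(sel)) next
    pos <- findInterval(mid[sel], iv$start)
    hit <- pos > 0 & mid[sel] < iv$end[pmax(pos, 1L)]
    masked[sel] <- hit
  }
  sample_library(f[!masked, , drop = FALSE], lib$sample_id, lib$group,
                 n_rejected = lib$n_rejected)
}

# Sort and merge overlapping half-open intervals on one chromosome.
merge_intervals <- function(iv) {
  iv <- iv[order(iv$start), , drop = FALSE]
  if (nrow(iv) < 2L) return(iv)
  start <- iv$start[1L]; end <- iv$end[1L]
  out_s <- out_e <- numeric(0)
  for (i in 2:nrow(iv)) {
    if (iv$start[i] <= end) {
      end <- max(end, iv$end[i])
    } else {
      out_s <- c(out_s, start); out_e <- c(out_e, end)
      start <- iv$start[i]; end <- iv$end[i]
    }
  }
  data.frame(start = c(out_s, start), end = c(out_e, end))
}

#' Anchor mask intervals around gene ends
#'
#' Convenience builder for the ±`halfwidth` bp masking windows around all
#' TSS and TTS of a genome model.
#'
#' @param model A [build_genome_model()] result.
#' @param halfwidth Window half-width in bp (default 1500).
#' @return Data frame of `chrom`, `start`, `end` intervals (clipped at 0).
#' @export
tss_tts_mask <- function(model, halfwidth = 1500) {
  anchors <- c(model$genes$tss, model$genes$tts)
  data.frame(chrom = rep(model$genes$chrom, 2L),
             start = pmax(0, anchors - halfwidth),
             end = anchors + halfwidth)
}
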