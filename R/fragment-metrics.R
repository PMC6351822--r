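# Fragment-length distributions per sample and per group.

#' Fragment-length histogram
#'
#' Tally of `end - start` over all records of a library. The histogram is
#' dense over the observed length range; counts sum to the library size.
#'
#' @param lib A non-empty [sample_library()].
#' @return A `length_histogram`: data frame `length`, `count` plus a `total`
#'   attribute.
#' @export
length_histogram <- function(lib) {
  stopifnot(inherits(lib, "sample_library"))
  if (lib$library_size == 0L) cf_stop("empty library has no length histogram")
  len <- lib$fragments$end - lib$fragments$start
  rng <- range(len)
  counts <- tabulate(len - rng[1L] + 1L, rng[2L] - rng[1L] + 1L)
  structure(data.frame(length = rng[1L]:rng[2L], count = counts),
            total = lib$library_size, class = c("length_histogram", "data.frame"))
}

#' Merge length histograms (count sums)
#'
#' Group-level histograms are count-sums over member libraries, matching the
#' practice of merging replicate alignments before sizing fragments.
#'
#' @param histograms List of [length_histogram()] objects.
#' @return A merged `length_histogram`.
#' @export
merge_histograms <- function(histograms) {
  stopifnot(length(histograms) >= 1L,
            all(vapply(histograms, inherits, logical(1), "length_histogram")))
  rng <- range(unlist(lapply(histograms, function(h) range(h$length))))
  counts <- numeric(rng[2L] - rng[1L] + 1L)
  for (h in histograms)
    counts[h$length - rng[1L] + 1L] <- counts[h$length - rng[1L] + 1L] + h$count
  structure(data.frame(length = rng[1L]:rng[2L], count = counts),
            total = sum(counts), class = c("length_histogram", "data.frame"))
}

#' Modal fragment length
#'
#' The smallest length achieving the maximum count (ties broken toward the
#' smaller length, for deterministic reporting). With simulator defaults the
#' mode falls in the chromatosome range 166-175 bp.
#'
#' @param h A [length_histogram()].
#' @return Modal length in bp.
#' @export
modal_length <- function(h) {
  stopifnot(inherits(h, "length_histogram"))
  if (sum(h$count) == 0) cf_stop("empty histogram")
  h$length[which.max(h$count)]
}

#' Export a length histogram as TSV
#'
#' Columns `length`, `count`, `frequency`.
#'
#' @param h A [length_histogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_length_histogram <- function(h, path) {
  stopifnot(inherits(h, "length_histogram"))
  out <- data.frame(length = h$length, count = h$count,
                    frequency = h$count / sum(h$count))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
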