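# Bin signals, normalization, fold changes and the group comparisons.

test_that("bin counting drops partial bins and assigns midpoints half-open", {
  lib <- lib_from_intervals(c(99900, 99950, 150000), c(100100, 100050, 150170))
  # midpoints: 100000, 100000, 150085
  bc <- bin_counts(lib, c(chr1 = 250000), binsize = 1e5)
  expect_equal(nrow(bc), 2L)   # 250 kb -> 2 full bins, partial dropped
  expect_equal(bc$count, c(0, 3))
  expect_error(bin_counts(lib, c(chr1 = 250000), binsize = 0), "positive")
})

test_that("bin counts equal a naive interval recount", {
  set.seed(12)
  s <- sample(0:999829, 2000)
  lib <- lib_from_intervals(s, s + 170)
  bc <- bin_counts(lib, c(chr1 = 1e6), binsize = 1e5)
  mids <- (lib$fragments$start + lib$fragments$end) %/% 2
  naive <- vapply(seq_len(10), function(i) {
    sum(mids >= (i - 1) * 1e5 & mids < i * 1e5)
  }, numeric(1))
  expect_equal(bc$count, naive)
})

test_that("fragment midpoints on fully binned chromosomes are conserved", {
  set.seed(13)
  s <- sample(0:(1e6 - 200), 500)
  lib <- lib_from_intervals(s, s + 170)
  bc <- bin_counts(lib, c(chr1 = 1e6), binsize = 1e5)
  expect_equal(sum(bc$count), 500)
})

test_that("group means average normalized replicate signals", {
  frame <- data.frame(chrom = "chr1", start = c(0, 1e5), end = c(1e5, 2e5))
  mk <- function(cnt) cbind(frame, count = cnt)
  bt <- bin_table(list(s1 = mk(c(2, 10)), s2 = mk(c(4, 10)), s3 = mk(c(6, 10))),
                  labels = c("A1", "B2"), groups = rep("g", 3))
  # equal per-sample library structure: size factors are ~1, mean is 4
  gm <- group_mean_signal(bt)
  expect_equal(unname(gm[1, "g"]), 4, tolerance = 0.25)
  one <- bin_table(list(s1 = mk(c(5, 7))), labels = c("A1", "B2"), groups = "g")
  expect_equal(unname(group_mean_signal(one)[, "g"]), c(5, 7))
  expect_error(bin_table(list(mk(c(1, 2)), cbind(frame[1, ], count = 1)),
                         labels = c("A1", "B2"), groups = c("a", "b")),
               "mismatched")
})

test_that("median-of-ratios matches a hand computation and falls back", {
  m <- cbind(s1 = c(10, 20, 40), s2 = c(20, 40, 80))
  sf <- median_of_ratios(m)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)
  expect_warning(median_of_ratios(cbind(c(0, 5), c(5, 0))), "library-size")
})

test_that("log2 fold changes are antisymmetric, finite and calibrated", {
  frame <- data.frame(chrom = "chr1", start = seq(0, 9e5, 1e5),
                      end = seq(1e5, 1e6, 1e5))
  set.seed(14)
  base <- rpois(10, 1000)
  counts <- list(a1 = cbind(frame, count = base),
                 a2 = cbind(frame, count = base + rpois(10, 5)),
                 b1 = cbind(frame, count = 2 * base),
                 b2 = cbind(frame, count = 2 * base + rpois(10, 5)))
  bt <- bin_table(counts, labels = rep(c("A1", "B1"), 5),
                  groups = c("A", "A", "B", "B"))
  fc <- log2_fold_change(bt, "A", "B")
  # size factors absorb the global 2x: normalized means agree, lfc ~ 0
  expect_true(all(abs(fc$log2fc) < 0.05))
  rev <- log2_fold_change(bt, "B", "A")
  expect_equal(fc$log2fc, -rev$log2fc)

  # identical groups give exactly zero
  bt2 <- bin_table(counts[c(1, 1)], labels = rep(c("A1", "B1"), 5),
                   groups = c("A", "B"))
  expect_equal(log2_fold_change(bt2, "A", "B")$log2fc, rep(0, 10))

  # a true 2x mean difference in normalized signal appears as lfc ~ 1
  eq <- list(x1 = cbind(frame, count = rep(1000L, 10)),
             x2 = cbind(frame, count = rep(c(2000L, 1000L), 5)))
  bt3 <- bin_table(eq, labels = rep(c("A1", "B1"), 5), groups = c("A", "B"))
  nc <- normalized_counts(bt3)
  manual <- unname(log2((nc[1, 1] + 0.5) / (nc[1, 2] + 0.5)))
  expect_equal(log2_fold_change(bt3, "A", "B")$log2fc[1], manual)

  # zero counts stay finite through the pseudocount
  z <- list(z1 = cbind(frame, count = c(0L, rep(100L, 9))),
            z2 = cbind(frame, count = rep(100L, 10)))
  btz <- bin_table(z, labels = rep(c("A1", "B1"), 5), groups = c("A", "B"))
  expect_true(all(is.finite(log2_fold_change(btz, "A", "B")$log2fc)))
})

test_that("subcompartment rank tests detect a shifted label", {
  set.seed(15)
  nb <- 200
  labels <- rep(c("A1", "B1", "B2"), each = nb)
  frame <- data.frame(chrom = "chr1", start = seq_len(3 * nb) - 1,
                      end = seq_len(3 * nb))
  frame$start <- frame$start * 1e5
  frame$end <- frame$end * 1e5
  counts <- round(rnorm(3 * nb, 100, 5))
  counts[labels == "B1"] <- counts[labels == "B1"] + 10
  bt <- bin_table(list(s1 = cbind(frame, count = counts)), labels = labels,
                  groups = "g")
  res <- subcompartment_rank_tests(bt, "g")
  expect_lt(res$kruskal$p.value, 1e-6)
  b1 <- res$dunn[res$dunn$group1 == "B1" | res$dunn$group2 == "B1", ]
  expect_true(all(b1$p_adj < 0.05))

  # identical label distributions: H ~ 0, nothing significant
  flat <- bin_table(list(s1 = cbind(frame, count = rep(c(7L, 9L), 300L))),
                    labels = labels, groups = "g")
  res2 <- subcompartment_rank_tests(flat, "g")
  expect_false(any(res2$dunn$p_adj < 0.05))

  # three-label toy case equals the hand-ranked H
  toy_frame <- frame[1:9, ]
  toy <- bin_table(list(s1 = cbind(toy_frame, count = c(1:9))),
                   labels = rep(c("A1", "B1", "B2"), each = 3), groups = "g")
  expect_equal(subcompartment_rank_tests(toy, "g")$kruskal$statistic, 7.2)
})

test_that("variance comparisons use median-centred deviations", {
  frame <- data.frame(chrom = "chr1", start = (0:3) * 1e5, end = (1:4) * 1e5)
  counts <- list(a = cbind(frame, count = c(0L, 10L, 0L, 10L)),
                 b = cbind(frame, count = c(4L, 6L, 4L, 6L)))
  bt <- bin_table(counts, labels = rep("A1", 4), groups = c("a", "b"))
  v <- variance_across_groups(bt)
  expect_equal(nrow(v), 1L)
  expect_gt(v$W, 0)
  expect_equal(v$larger_spread, "a")
})

test_that("the Gibbs comparison recovers a planted compartment effect", {
  set.seed(16)
  nb <- 60                       # first 20 bins B2 (planted), rest A1
  labels <- rep(c("B2", "A1"), c(20, 40))
  frame <- data.frame(chrom = "chr1", start = (seq_len(nb) - 1) * 1e5,
                      end = seq_len(nb) * 1e5)
  bin_effect <- exp(rnorm(nb, 0, 0.05))
  mk <- function(mult) {
    lambda <- 1000 * bin_effect * ifelse(labels == "B2", mult, 1)
    cbind(frame, count = rpois(nb, lambda))
  }
  counts <- list(y1 = mk(1), y2 = mk(1), y3 = mk(1),
                 o1 = mk(1.3), o2 = mk(1.3), o3 = mk(1.3))
  bt <- bin_table(counts, labels = labels,
                  groups = rep(c("young", "old"), each = 3))
  ps <- mixed_model_compare(bt, "B2", n_iter = 2000, burn_in = 500, seed = 2)
  expect_s3_class(ps, "posterior_summary")
  expect_true(all(ps$lo <= ps$median & ps$median <= ps$hi))
  d <- ps[ps$group1 == "old" & ps$group2 == "young", ]
  if (nrow(d) == 0) {
    d <- ps[ps$group1 == "young" & ps$group2 == "old", ]
    d[c("median", "lo", "hi")] <- -d[c("median", "hi", "lo")]
  }
  # the estimand is the normalized log2 contrast; median-of-ratios absorbs a
  # little of the planted 1.3x because a third of all bins carry it
  nc <- normalized_counts(bt)
  estimand <- mean(log2(nc[labels == "B2", 4:6] + 0.5)) -
    mean(log2(nc[labels == "B2", 1:3] + 0.5))
  expect_lt(abs(d$median - estimand), 0.02)
  expect_gt(d$median, 0.8 * log2(1.3))
  expect_true(d$significant)
  # the unplanted compartment shows no credible difference
  ps0 <- mixed_model_compare(bt, "A1", n_iter = 2000, burn_in = 500, seed = 2)
  expect_false(any(ps0$significant & abs(ps0$median) > 0.1))
  # a single-bin subcompartment is refused
  bt1 <- bin_table(counts, labels = rep(c("B3", "A1"), c(1, 59)),
                   groups = rep(c("young", "old"), each = 3))
  expect_error(mixed_model_compare(bt1, "B3"), "need at least 10")
})

test_that("track correlation matches cor and validates input", {
  set.seed(17)
  a <- rnorm(50)
  expect_equal(correlate_tracks(a, a), 1)
  expect_equal(correlate_tracks(a, -a + 3), -1)
  b <- rnorm(50)
  expect_equal(correlate_tracks(a, b),
               sum((a - mean(a)) * (b - mean(b))) /
                 sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2)),
               tolerance = 1e-12)
  expect_error(correlate_tracks(a, rep(1, 50)), "zero-variance")
  expect_error(correlate_tracks(1:2, 1:3), "share")
})
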