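# WPS, detrending, periodograms, band intensities, tissue correlations and
# rank-shift inference.

test_that("WPS matches the enumerated single-fragment cases", {
  lib <- lib_from_intervals(100, 267)
  tr <- wps(lib, "chr1", 90, 300, w = 120)
  # p = 183: window [123, 243) inside [100, 267), endpoints outside -> +1
  expect_equal(tr[183 - 90 + 1], 1)
  # p = 100: window [40, 160) is not fully spanned (fragment starts at 100)
  # and the start endpoint lies inside it -> -1
  expect_equal(tr[100 - 90 + 1], -1)
  # p = 95: window [35, 155): does not span, start endpoint inside -> -1
  expect_equal(tr[95 - 90 + 1], -1)
  expect_equal(wps(sample_library(data.frame(chrom = character(0),
                                             start = numeric(0),
                                             end = numeric(0))),
                   "chr1", 0, 200), rep(0L, 200))
  expect_error(wps(lib, "chr1", 0, 100, w = 121), "even")
  expect_error(wps(lib, "chr1", 0, 100, w = 120), "smaller")
})

test_that("WPS equals the brute-force double loop on random instances", {
  set.seed(24)
  for (i in 1:30) {
    n <- sample(1:50, 1)
    s <- sample(0:450, n, replace = TRUE)
    e <- pmin(s + sample(80:300, n, replace = TRUE), 520)
    frags <- data.frame(chrom = "chr1", start = s, end = e)
    frags <- frags[frags$end > frags$start, ]
    lib <- sample_library(frags)
    expect_equal(wps(lib, "chr1", 0, 500), wps_brute(frags, 0, 500),
                 ignore_attr = TRUE)
  }
})

test_that("detrending removes trends but keeps nucleosome-scale cosines", {
  expect_equal(detrend_track(rep(5, 3000)), rep(0, 3000))
  ramp <- seq(0, 10, length.out = 5000)
  expect_lt(max(abs(detrend_track(ramp))), 10 * 1001 / 5000)
  x <- cos(2 * pi * (0:9999) / 196)
  d <- detrend_track(x)
  # amplitude retained within 5%
  expect_gt(max(abs(stats::fft(d)[52])) / 5000, 0.95)
})

test_that("periodograms localise planted cosines and satisfy Parseval", {
  n <- 10000
  x <- cos(2 * pi * (0:(n - 1)) / 196)
  sp <- period_spectrum(x)
  expect_true(sp$period[which.max(sp$intensity)] %in% 193:199)
  expect_equal(attr(sp, "total_power"), sum(x^2) / n, tolerance = 1e-6)

  expect_equal(max(period_spectrum(rep(0, n))$intensity), 0)

  x2 <- cos(2 * pi * (0:(n - 1)) / 196) + cos(2 * pi * (0:(n - 1)) / 100)
  sp2 <- period_spectrum(x2)
  expect_gt(band_intensity(sp2, 193, 199), band_intensity(sp2, 140, 150))
  expect_error(period_spectrum(rep(0, 400)), "shorter")
})

test_that("band intensity is the mean over available period bins", {
  sp <- period_spectrum(rnorm(10000))
  sel <- sp$period >= 193 & sp$period <= 199
  expect_equal(band_intensity(sp), mean(sp$intensity[sel]))
  expect_error(band_intensity(sp, 500, 600), "outside")
  flat <- sp
  flat$intensity <- rep(2, nrow(flat))
  expect_equal(band_intensity(flat), 2)
})

test_that("tissue correlations match the hand Pearson formula and rank by r", {
  band <- c(g1 = 3, g2 = 2, g3 = 1, g4 = 2.5)
  expr <- rbind(
    up = 2^(-c(3, 2, 1, 2.5) * 2 + 10) - 1,  # exactly -2*log2(e+1) + c
    other = c(5, 1, 8, 2))
  colnames(expr) <- names(band)
  tc <- tissue_correlations(band, expr)
  expect_equal(tc$r[tc$tissue == "up"], -1, tolerance = 1e-12)
  manual <- cor(band, log2(expr["other", ] + 1))
  expect_equal(tc$r[tc$tissue == "other"], manual, tolerance = 1e-12)
  expect_equal(tc$rank[order(tc$r)], seq_len(nrow(tc)))

  # descending convention inverts the ranking
  tc2 <- tissue_correlations(band, expr, rank_sign = "descending")
  expect_equal(tc2$rank, rev(tc$rank))

  # zero-variance tissue is excluded, not ranked
  expr0 <- rbind(expr, flat = c(4, 4, 4, 4))
  tc3 <- tissue_correlations(band, expr0)
  expect_true(tc3$excluded[tc3$tissue == "flat"])
  expect_true(is.na(tc3$rank[tc3$tissue == "flat"]))
  expect_error(tissue_correlations(band[1:2], expr[, 1:2]), "3 shared")
})

test_that("shuffled expression yields weak, unstable correlations", {
  set.seed(25)
  band <- rexp(1000)
  names(band) <- sprintf("g%04d", 1:1000)
  rs <- replicate(10, {
    expr <- matrix(sample(rlnorm(1000, log(5), 1)), nrow = 1,
                   dimnames = list("t", names(band)))
    tissue_correlations(c(band[1:999], g0 = 1),
                        cbind(expr[, 1:999, drop = FALSE], g0 = 2))$r
  })
  expect_lt(max(abs(rs)), 0.15)
})

test_that("rank shifts are detected for planted rank changes only", {
  groups <- rep(c("young", "hc", "old", "uc"), each = 3)

  # identical rank vectors across samples: nothing significant
  same <- matrix(rep(1:5, each = 12), nrow = 12,
                 dimnames = list(NULL, paste0("t", 1:5)))
  res <- rank_shift_test(same, groups)
  expect_false(any(res$pairwise$significant))

  # planted: t5 moves from rank 5 to rank 1 in old samples (t1 absorbs it)
  planted <- same
  planted[groups == "old", "t5"] <- 1
  planted[groups == "old", "t1"] <- 2
  planted[groups == "old", "t2"] <- 3
  planted[groups == "old", "t3"] <- 4
  planted[groups == "old", "t4"] <- 5
  res2 <- rank_shift_test(planted, groups)
  oy <- res2$pairwise[res2$pairwise$group1 == "young" &
                        res2$pairwise$group2 == "old", ]
  expect_true(oy$significant[oy$tissue == "t5"])
  expect_equal(oy$rank_shift[oy$tissue == "t5"], -4)

  expect_error(rank_shift_test(same, rep("g", 12)), "two groups")
  na_ranks <- same
  na_ranks[1, 1] <- NA
  expect_error(rank_shift_test(na_ranks, groups), "missing")
})

test_that("toy two-group ranks give a small KW p before adjustment", {
  ranks <- cbind(t1 = c(1, 1, 1, 3, 3, 3), t2 = c(2, 2, 2, 1, 1, 1))
  # direct KW on t1's ranks between the two groups
  kw <- kruskal_wallis(list(c(1, 1, 1), c(3, 3, 3)))
  expect_lt(kw$p.value, 0.05)
})

test_that("band intensity falls with mixture-weighted expression", {
  m <- build_genome_model(genome_config(
    chromosomes = c(chr1 = 2e6), n_genes = 50L, n_ctcf = 2L,
    gene_length = c(15000, 15000)), seed = 26)
  e <- simulate_tissue_expression(50, 3, seed = 9, gene_ids = m$genes$id,
                                  tissue_ids = paste0("t", 1:3))
  tm <- setNames(rep(1 / 3, 3), paste0("t", 1:3))
  gp <- group_params("g", c(A1 = 1, A2 = 1, B1 = 1, B2 = 1, B3 = 1),
                     ndr_depth = 0.5, phasing_amplitude = 0.9,
                     repeat_5p_weight = 1, tissue_mixture = tm)
  lib <- simulate_fragments(protection_profile(m, gp, e), 1e5, seed = 10)
  band <- gene_band_intensities(lib, m)
  x <- as.numeric(tm %*% e[, names(band)])
  expect_lt(cor(band, x, method = "spearman"), -0.5)
})

test_that("the rank-shift study flags its planted tissue", {
  res <- rank_shift_study(seed = 101, depth = 25000L)
  expect_equal(res$flagged_old_vs_young, res$planted)
  # the planted tissue climbs the ranking (negative shift) in old
  oy <- res$shift$pairwise
  oy <- oy[oy$tissue == res$planted & oy$group1 == "young" &
             oy$group2 == "old", ]
  expect_lt(oy$rank_shift, 0)
})
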