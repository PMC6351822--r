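# The cohort simulator: genome layout, expression tables, protection
# tracks, fragment sampling and ground truth.

test_that("genome model echoes its configuration deterministically", {
  cfg <- genome_config(chromosomes = c(chr1 = 2e6, chr2 = 2e6),
                       n_genes = 40L, n_ctcf = 30L)
  m <- build_genome_model(cfg, seed = 3)
  expect_equal(nrow(m$bins), 40L)
  expect_equal(nrow(m$genes), 40L)
  expect_equal(nrow(m$ctcf_sites), 30L)
  expect_equal(nrow(m$repeats), 20L)
  expect_setequal(unique(m$bins$label), c("A1", "A2", "B1", "B2", "B3"))
  m2 <- build_genome_model(cfg, seed = 3)
  expect_identical(m, m2)
  expect_false(identical(m, build_genome_model(cfg, seed = 4)))
})

test_that("genome model validates bounds and overlaps", {
  expect_error(build_genome_model(genome_config(chromosomes = c(chr1 = 0))),
               "zero-length")
  bad_gene <- data.frame(id = "g1", chrom = "chr1", tss = 1.9e6, tts = 2.1e6,
                         strand = "+")
  expect_error(build_genome_model(
    genome_config(chromosomes = c(chr1 = 2e6), genes = bad_gene)),
    "beyond chromosome end")
  flipped <- data.frame(id = "g1", chrom = "chr1", tss = 5e5, tts = 4e5,
                        strand = "+")
  expect_error(build_genome_model(
    genome_config(chromosomes = c(chr1 = 2e6), genes = flipped)),
    "tss < tts")
  overlapping <- data.frame(family = "L1HS", chrom = "chr1",
                            start = c(1000, 3000), end = c(7000, 8000),
                            strand = "+", consensus_offset = 0,
                            consensus_length = 6000)
  expect_error(build_genome_model(
    genome_config(chromosomes = c(chr1 = 2e6), repeats = overlapping)),
    "overlapping repeat")
})

test_that("gene strand invariants hold on generated models", {
  m <- small_model(seed = 5)
  plus <- m$genes$strand == "+"
  expect_true(all(m$genes$tss[plus] < m$genes$tts[plus]))
  expect_true(all(m$genes$tss[!plus] > m$genes$tts[!plus]))
  expect_true(all(m$genes$tss >= 0 & m$genes$tss < 2e6))
})

test_that("expression tables have disjoint elevated marker sets", {
  e <- simulate_tissue_expression(100, 5, seed = 1, marker_fraction = 0.1)
  expect_equal(dim(e), c(5L, 100L))
  expect_true(all(e >= 0))
  mk <- attr(e, "markers")
  expect_equal(lengths(mk), rep(10L, 5), ignore_attr = TRUE)
  expect_equal(anyDuplicated(unlist(mk)), 0L)
  e2 <- simulate_tissue_expression(100, 5, seed = 1, marker_fraction = 0.1)
  expect_identical(e, e2)
  expect_error(simulate_tissue_expression(10, 5, marker_fraction = 0.5),
               "disjoint")
})

test_that("group_params enforces its invariants", {
  w <- c(A1 = 1, A2 = 1, B1 = 1, B2 = 1, B3 = 1)
  tm <- c(liver = 0.5, lung = 0.5)
  expect_s3_class(group_params("g", w, 0.5, 0.5, 1, tm), "group_params")
  expect_error(group_params("g", w, 1.5, 0.5, 1, tm), "ndr_depth")
  expect_error(group_params("g", w - 2, 0.5, 0.5, 1, tm), ">= 0")
  expect_error(group_params("g", w, 0.5, 0.5, 1, c(liver = 0.5, lung = 0.6)),
               "sum to 1")
})

test_that("protection track embodies dips, baseline and phasing", {
  m <- small_model(seed = 6)
  e <- simulate_tissue_expression(nrow(m$genes), 3, seed = 2,
                                  gene_ids = m$genes$id,
                                  tissue_ids = paste0("t", 1:3))
  tm <- setNames(rep(1 / 3, 3), paste0("t", 1:3))
  w1 <- c(A1 = 1, A2 = 1, B1 = 1, B2 = 1, B3 = 1)

  # full-depth NDR zeroes the track at the exact TSS
  gp <- group_params("g", w1, ndr_depth = 1, phasing_amplitude = 0,
                     repeat_5p_weight = 1, tissue_mixture = tm)
  tr <- protection_profile(m, gp, e)
  expect_equal(tr$chr1[m$genes$tss + 1], rep(0, nrow(m$genes)))

  # equal weights + zero amplitude: constant outside NDR/repeat regions
  gp2 <- group_params("g", w1, ndr_depth = 0.5, phasing_amplitude = 0,
                      repeat_5p_weight = 1, tissue_mixture = tm)
  tr2 <- protection_profile(m, gp2, e)
  anchors <- c(m$genes$tss, m$genes$tts, m$ctcf_sites$pos)
  far <- setdiff(seq(0, 2e6 - 1, by = 997),
                 unlist(lapply(anchors, function(a) (a - 1500):(a + 1500))))
  expect_equal(stats::sd(tr2$chr1[far + 1]), 0, tolerance = 1e-12)

  # the maximally expressed gene carries no periodic component downstream
  x <- as.numeric(tm %*% e[, m$genes$id])
  top <- which.max(x)
  gp3 <- group_params("g", w1, ndr_depth = 0, phasing_amplitude = 0.8,
                      repeat_5p_weight = 1, tissue_mixture = tm)
  tr3 <- protection_profile(m, gp3, e)
  g <- m$genes[top, ]
  dyads <- if (g$strand == "+") g$tss + seq(0, 9800, 196) else g$tss - seq(0, 9800, 196)
  # at dyad positions a cosine of nonzero amplitude would raise the track
  expect_equal(tr3$chr1[dyads + 1], rep(1, length(dyads)), tolerance = 1e-9)

  expect_error(protection_profile(m, gp3, e[, 1:10]), "cover all gene ids")
})

test_that("fragment sampler honours depth, truncation and track support", {
  tr <- flat_track(1e5)
  expect_equal(simulate_fragments(tr, 0)$library_size, 0L)
  flm <- fragment_length_model(mean = 167, sd = 0.5, min = 166, max = 175)
  lib <- simulate_fragments(tr, 1e4, flm, seed = 2)
  expect_equal(lib$library_size, 10000L)
  lens <- lib$fragments$end - lib$fragments$start
  expect_true(all(lens >= 166 & lens <= 175))

  half <- list(chr1 = c(rep(0, 5e4), rep(1, 5e4)))
  lib2 <- simulate_fragments(half, 5000, seed = 3, jitter = 0L)
  mids <- (lib2$fragments$start + lib2$fragments$end) %/% 2
  expect_true(all(mids >= 5e4 - 10))

  expect_error(simulate_fragments(list(chr1 = rep(0, 100)), 10), "all-zero")
  expect_error(fragment_length_model(mean = 50, min = 100, max = 400),
               "min <= mean")
})

test_that("fragment sampling is reproducible per seed", {
  tr <- flat_track(5e4)
  a <- simulate_fragments(tr, 2000, seed = 11)
  b <- simulate_fragments(tr, 2000, seed = 11)
  expect_identical(a$fragments, b$fragments)
  expect_false(identical(a$fragments,
                         simulate_fragments(tr, 2000, seed = 12)$fragments))
})

test_that("cohorts have one library per sample and lossless truth JSON", {
  m <- small_model(seed = 7, chrom_len = 1e6, n_genes = 8L, n_ctcf = 4L)
  e <- simulate_tissue_expression(8, 3, seed = 3, gene_ids = m$genes$id,
                                  tissue_ids = paste0("t", 1:3))
  gp <- default_group_params(tissues = paste0("t", 1:3))
  coh <- simulate_cohort(gp, 3L, m, e, depth = 2000L, seed = 5)
  expect_length(coh$samples, 12L)
  expect_equal(vapply(coh$samples, function(s) s$library_size, numeric(1)),
               rep(2000, 12), ignore_attr = TRUE)
  coh2 <- simulate_cohort(gp, 3L, m, e, depth = 2000L, seed = 5)
  expect_identical(coh$samples, coh2$samples)

  p <- withr::local_tempfile(fileext = ".json")
  write_truth(coh$truth, p)
  back <- read_truth(p)
  expect_equal(back$samples, coh$truth$samples)
  expect_equal(back$spacing, coh$truth$spacing)
  expect_equal(back$groups, coh$truth$groups, ignore_attr = TRUE)

  gp_dup <- gp
  gp_dup[[2]]$name <- gp_dup[[1]]$name
  expect_error(simulate_cohort(gp_dup, 3L, m, e, depth = 10L), "duplicate")
})

test_that("deeper NDRs monotonically deplete coverage around the TSS", {
  m <- small_model(seed = 9, chrom_len = 1e6, n_genes = 10L, n_ctcf = 2L)
  e <- simulate_tissue_expression(10, 2, seed = 4, gene_ids = m$genes$id,
                                  tissue_ids = c("t1", "t2"))
  tm <- c(t1 = 0.5, t2 = 0.5)
  w <- c(A1 = 1, A2 = 1, B1 = 1, B2 = 1, B3 = 1)
  anchors <- data.frame(chrom = m$genes$chrom, pos = m$genes$tss,
                        strand = m$genes$strand)
  wm <- vapply(c(0.2, 0.5, 0.8), function(d) {
    gp <- group_params("g", w, ndr_depth = d, phasing_amplitude = 0.3,
                       repeat_5p_weight = 1, tissue_mixture = tm)
    lib <- simulate_fragments(protection_profile(m, gp, e), 5e4,
                              seed = round(1000 * d))
    window_mean(coverage_at_anchors(lib, anchors))
  }, numeric(1))
  expect_true(all(diff(wm) < 0))
})

test_that("planted nucleosome spacing shows up in coverage autocorrelation", {
  m <- small_model(seed = 10, chrom_len = 1e6, n_genes = 10L, n_ctcf = 2L)
  e <- simulate_tissue_expression(10, 2, seed = 5, gene_ids = m$genes$id,
                                  tissue_ids = c("t1", "t2"))
  # zero out expression so every gene phases at full amplitude
  e[, ] <- 0
  gp <- group_params("g", c(A1 = 1, A2 = 1, B1 = 1, B2 = 1, B3 = 1),
                     ndr_depth = 0.3, phasing_amplitude = 0.9,
                     repeat_5p_weight = 1,
                     tissue_mixture = c(t1 = 0.5, t2 = 0.5))
  lib <- simulate_fragments(protection_profile(m, gp, e), 2e5, seed = 6)
  # average per-base coverage autocorrelation downstream of plus-strand TSS
  mids <- (lib$fragments$start + lib$fragments$end) %/% 2
  ac_tot <- 0
  genes <- m$genes[m$genes$strand == "+", ]
  for (i in seq_len(nrow(genes))) {
    cov <- tabulate(mids - genes$tss[i] + 1L, 10000L)
    ac_tot <- ac_tot + acf(cov, lag.max = 250, plot = FALSE)$acf[, 1, 1]
  }
  peak_lag <- 149L + which.max(ac_tot[151:251])  # search lags 150..250
  expect_true(abs(peak_lag - 196L) <= 2L)
})
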