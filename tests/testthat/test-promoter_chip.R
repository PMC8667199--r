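test_that("promoter coverage follows exact interval arithmetic", {
  tr <- toy_track(data.frame(chrom = "chr1", start = c(0L, 150L),
                             end = c(150L, 400L), value = c(2, 4)))
  gm <- data.frame(id = "g1", chrom = "chr1", tss = 200L)
  # window [100, 300): 50bp of value 2 + 150bp of value 4 over 200bp
  expect_equal(unname(promoter_coverage(tr, gm, flank = 100)),
               (50 * 2 + 150 * 4) / 200)

  # window entirely inside one interval -> that value
  gm2 <- data.frame(id = "g1", chrom = "chr1", tss = 250L)
  expect_equal(unname(promoter_coverage(tr, gm2, flank = 40)), 4)

  # empty track / absent chromosome -> 0 with a warning
  empty <- toy_track(data.frame(chrom = character(0), start = integer(0),
                                end = integer(0), value = numeric(0)))
  expect_warning(cov <- promoter_coverage(empty, gm, flank = 100), "absent")
  expect_equal(unname(cov), 0)
})

test_that("depth normalization scales to signal-per-million and is invariant", {
  expect_equal(depth_normalize(3.5, 7e6), 0.5)
  m <- matrix(c(1, 2, 3, 4), 2)
  n1 <- depth_normalize(m, c(1e6, 2e6))
  expect_equal(n1, cbind(c(1, 2), c(1.5, 2)))
  expect_error(depth_normalize(m, c(1e6, 0)), "> 0")

  # scaling a whole track x2 leaves normalized promoter values unchanged
  iv <- data.frame(chrom = "chr1", start = c(0L, 500L), end = c(400L, 900L),
                   value = c(2, 6))
  t1 <- toy_track(iv)
  iv2 <- iv; iv2$value <- iv2$value * 2
  t2 <- toy_track(iv2)
  gm <- data.frame(id = c("a", "b"), chrom = "chr1", tss = c(200L, 700L))
  c1 <- depth_normalize(promoter_coverage(t1, gm, 100), t1$total_signal)
  c2 <- depth_normalize(promoter_coverage(t2, gm, 100), t2$total_signal)
  expect_equal(c1, c2)
})

test_that("fractional ranks average ties and survive monotone transforms", {
  expect_equal(unname(rank_promoters(c(5, 1, 9))), c(2, 1, 3))
  expect_equal(unname(rank_promoters(c(4, 4))), c(1.5, 1.5))
  set.seed(17)
  x <- runif(200)
  maps <- list(function(v) v^3, exp, function(v) 10 * v + 3,
               function(v) atan(v), function(v) v / (1 + v))
  for (f in maps) expect_equal(rank_promoters(f(x)), rank_promoters(x))
  expect_error(rank_promoters(1), ">= 2 promoters")
})

test_that("signed log10 LR matches direct Poisson likelihood evaluation", {
  expect_equal(diff_loglr(10, 10, pseudo = 0), 0)
  # direct evaluation via dpois at x = 20, y = 10
  x <- 20; y <- 10; m <- 15
  direct <- log10((dpois(x, x) * dpois(y, y)) / (dpois(x, m) * dpois(y, m)))
  expect_equal(diff_loglr(20, 10, pseudo = 0), direct, tolerance = 1e-12)
  expect_equal(diff_loglr(20, 10, pseudo = 0), 0.738, tolerance = 1e-3)

  set.seed(53)
  a <- runif(1000, 0, 50); b <- runif(1000, 0, 50)
  s1 <- diff_loglr(a, b); s2 <- diff_loglr(b, a)
  expect_equal(s1, -s2)
  expect_equal(diff_loglr(a, a), rep(0, 1000))
  expect_true(all(sign(s1) == sign(a - b)))
})

test_that("strong-enrichment flag implements the rank box", {
  tab <- data.frame(gene = paste0("g", 1:10),
                    rank_injury = 1:10, rank_sham = c(1, 1, 3:10))
  # gene 2: sham rank 1 (<= 0.2*10), injury rank 2 (< 8) -> not flagged
  f <- flag_strong_enrichment(tab, 0.2, 0.8)
  expect_identical(which(f), integer(0))
  tab$rank_injury[2] <- 9.5; tab$rank_injury[9] <- 2
  f <- flag_strong_enrichment(tab, 0.2, 0.8)
  expect_identical(which(f), 2L)
  expect_error(flag_strong_enrichment(tab, 0, 0.8))
})

test_that("top-k selection is signed, bounded and deterministically tie-broken", {
  tab <- data.frame(gene = c("a", "b", "c"), score = c(3, 1, -2))
  top <- select_top_k(tab, k = 1)
  expect_identical(top$up, "a")
  expect_identical(top$down, "c")
  top0 <- select_top_k(tab, k = 0)
  expect_length(top0$up, 0); expect_length(top0$down, 0)
  w <- capture_warnings(top3 <- select_top_k(tab, k = 3))
  expect_length(w, 2)  # too few genes of each sign
  expect_match(w[1], "only 2 gene")
  expect_match(w[2], "only 1 gene")
  expect_identical(top3$up, c("a", "b"))

  ties <- data.frame(gene = c("z", "m", "a", "q"), score = c(2, 2, 2, -1))
  expect_warning(t1 <- select_top_k(ties, k = 2), "only 1 gene")
  shuffled <- ties[c(3, 1, 4, 2), ]
  expect_warning(t2 <- select_top_k(shuffled, k = 2), "only 1 gene")
  expect_identical(t1$up, c("a", "m"))
  expect_identical(t2$up, t1$up)
})

test_that("per-sample scaling changes no rank and no score end-to-end", {
  sim <- simulate_counts(150, seed = 61)
  chip <- chip_sample_sheet(2, 2)
  tracks <- simulate_pileups(sim$truth, sim$cm$genes, chip, noise = 0, seed = 2)
  tab1 <- score_promoters(tracks, sim$cm$genes, chip)

  scaled <- tracks
  iv <- scaled[["sham_c1"]]$intervals
  iv$value <- iv$value * 7.3
  scaled[["sham_c1"]] <- PileupTrack(iv, sample = "sham_c1")
  tab2 <- score_promoters(scaled, sim$cm$genes, chip)
  expect_equal(tab2$rank_sham_c1, tab1$rank_sham_c1)
  expect_equal(tab2$score, tab1$score, tolerance = 1e-9)
  expect_equal(tab2$rank_injury, tab1$rank_injury)

  # null genes concentrate on the rank diagonal (noise-free)
  null_genes <- sim$truth$true_module == "null"
  med <- median(abs(tab1$rank_injury - tab1$rank_sham)[null_genes])
  expect_lt(med, 0.05 * nrow(tab1))
})

test_that("input subtraction floors at zero and requires the input track", {
  sim <- simulate_counts(60, seed = 67)
  chip <- chip_sample_sheet(2, 2)
  tracks <- simulate_pileups(sim$truth, sim$cm$genes, chip, noise = 0, seed = 3,
                             with_input = TRUE)
  tab <- score_promoters(tracks, sim$cm$genes, chip, subtract_input = TRUE)
  expect_true(all(tab[, paste0("cov_", chip$id)] >= 0))
  expect_error(score_promoters(tracks[chip$id], sim$cm$genes, chip,
                               subtract_input = TRUE), "no input track")
})
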