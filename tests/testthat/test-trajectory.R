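test_that("decision table is exhaustive and each label reachable", {
  statuses <- c("up", "down", "ns")
  cases <- expand.grid(s1 = statuses, s14 = statuses,
                       mag = c("d14_bigger", "d1_bigger", "tie"),
                       stringsAsFactors = FALSE)
  fc <- function(s, big) ifelse(s == "ns", 0, ifelse(s == "up", 1, -1)) * big
  got <- mapply(function(s1, s14, mag) {
    m1 <- switch(mag, d14_bigger = 1, d1_bigger = 2, tie = 1)
    m14 <- switch(mag, d14_bigger = 2, d1_bigger = 1, tie = 1)
    classify_trajectory(s1, s14, fc(s1, m1), fc(s14, m14))
  }, cases$s1, cases$s14, cases$mag)

  expected <- function(s1, s14, mag) {
    key <- paste(s1, s14)
    if (key == "up up") return(if (mag == "d14_bigger") "i" else "ii")
    if (key == "down down") return(if (mag == "d1_bigger") "vii" else "viii")
    switch(key, "ns up" = "iii", "up ns" = "iv", "down ns" = "v",
           "ns down" = "vi", "up down" = , "down up" = "discordant",
           "ns ns" = "unassigned")
  }
  want <- mapply(expected, cases$s1, cases$s14, cases$mag)
  expect_identical(unname(got), unname(want))
  expect_setequal(unique(got),
                  c("i", "ii", "iii", "iv", "v", "vi", "vii", "viii",
                    "discordant", "unassigned"))
})

test_that("paper-style examples classify as named", {
  expect_identical(classify_trajectory("up", "ns", 1.4, 0.1), "iv")
  expect_identical(classify_trajectory("ns", "ns", 0, 0), "unassigned")
  expect_identical(classify_trajectory("up", "up", 0.8, 1.5), "i")
})

test_that("classification is scale-invariant and a partition", {
  set.seed(13)
  for (i in 1:200) {
    s1 <- sample(c("up", "down", "ns"), 1)
    s14 <- sample(c("up", "down", "ns"), 1)
    f1 <- ifelse(s1 == "up", 1, ifelse(s1 == "down", -1, 0)) * runif(1, 0.1, 5)
    f14 <- ifelse(s14 == "up", 1, ifelse(s14 == "down", -1, 0)) * runif(1, 0.1, 5)
    lab <- classify_trajectory(s1, s14, f1, f14)
    expect_length(lab, 1)
    c_pos <- runif(1, 0.01, 100)
    expect_identical(classify_trajectory(s1, s14, c_pos * f1, c_pos * f14), lab)
    # unassigned iff both ns
    expect_identical(lab == "unassigned", s1 == "ns" && s14 == "ns")
  }
})

test_that("RPKM and profile arithmetic follow their formulas", {
  expect_equal(rpkm(100, 2000, 1e7), 5.0)

  cm <- de_count_matrix(6, per_cell = 2, seed = 8)
  d1 <- fit_moderated_de(cm, "day1", use_weights = FALSE)
  d14 <- fit_moderated_de(cm, "day14", use_weights = FALSE)
  d1$log2fc[] <- 2; d14$log2fc[] <- 0.5
  prof <- compute_trajectory_profile(cm, d1, d14)
  expect_equal(prof$value_d1, prof$baseline + 2)
  expect_equal(prof$value_d14, prof$baseline + 0.5)

  # baseline is the mean log2 RPKM over sham day-14 samples
  ref <- cm$samples$condition == "sham" & cm$samples$timepoint == "day14"
  lib <- colSums(cm$counts)
  manual <- rowMeans(sapply(which(ref), function(j)
    log2(rpkm(cm$counts[, j] + 0.5, cm$genes$length, lib[j]))))
  expect_equal(prof$baseline, unname(manual))

  # null gene (NA fold changes) -> flat profile
  d1$log2fc[] <- NA; d14$log2fc[] <- NA
  flat <- compute_trajectory_profile(cm, d1, d14)
  expect_equal(flat$value_d1, flat$baseline)
  expect_equal(flat$value_d14, flat$baseline)

  cm$genes$length <- NULL
  expect_error(compute_trajectory_profile(cm, d1, d14), "length")
})

test_that("sankey flows conserve assigned gene counts", {
  a <- data.frame(gene = sprintf("g%d", 1:10), status_d1 = "up",
                  status_d14 = "ns", module = "iv", stringsAsFactors = FALSE)
  fl <- export_sankey(a)
  expect_equal(nrow(fl), 1L)
  expect_equal(fl$from, "up@day1")
  expect_equal(fl$to, "ns@day14")
  expect_equal(fl$n, 10)

  set.seed(4)
  sim <- simulate_counts(1200, seed = 19)
  d1 <- fit_moderated_de(sim$cm, "day1")
  d14 <- fit_moderated_de(sim$cm, "day14")
  asg <- assign_trajectories(sim$cm, d1, d14)
  fl <- export_sankey(asg)
  expect_equal(sum(fl$n), sum(asg$module != "unassigned"))
})

test_that("trajectory recovery on strong synthetic effects matches truth", {
  sim <- simulate_counts(1500, seed = 23, effect_scale = 3,
                         module_fractions = c(iv = 0.1, v = 0.1),
                         base_mean_range = c(200, 2000))
  d1 <- fit_moderated_de(sim$cm, "day1")
  d14 <- fit_moderated_de(sim$cm, "day14")
  asg <- assign_trajectories(sim$cm, d1, d14)
  for (m in c("iv", "v")) {
    genes <- sim$truth$gene[sim$truth$true_module == m]
    expect_gt(mean(asg$module[asg$gene %in% genes] == m), 0.9)
  }
  # flow table matches truth at these effect sizes
  fl <- export_sankey(asg)
  expect_gt(fl$n[fl$module == "iv"], 0.9 * sum(sim$truth$true_module == "iv"))
})
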