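test_that("log-CPM matches its defining formula and invariances", {
  m <- matrix(c(0, rep(1, 9)), nrow = 5)
  colnames(m) <- c("a", "b")
  # direct formula evaluation at count 0, prior 0.5, libsize 1e6
  lc <- normalize_logcpm(m, prior_count = 0.5, lib_size = c(1e6, 1e6))
  expect_equal(unname(lc[1, 1]), log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)

  # prior = 0: scaling one sample x10 leaves its log-CPM unchanged
  cm <- toy_count_matrix(10, 4)
  l0 <- normalize_logcpm(cm$counts, prior_count = 0)
  scaled <- cm$counts; scaled[, 2] <- scaled[, 2] * 10
  l1 <- normalize_logcpm(scaled, prior_count = 0)
  expect_equal(l1[, 2], l0[, 2])

  # uniform matrix, equal library sizes -> all values equal
  u <- matrix(7, 4, 3)
  lu <- normalize_logcpm(u)
  expect_true(all(abs(lu - lu[1, 1]) < 1e-12))

  z <- matrix(0, 3, 2); colnames(z) <- c("ok", "zero")
  z[, 1] <- 5
  expect_error(normalize_logcpm(z), "all-zero sample")
})

test_that("BH adjustment matches the brute-force step-up on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # independent reference: sort, scale by m/i, cummin from the tail
  bh_ref <- function(p) {
    m <- length(p); o <- order(p)
    adj <- p[o] * m / seq_len(m)
    for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
    out <- numeric(m); out[o] <- pmin(1, adj); out
  }
  set.seed(99)
  for (i in 1:25) {
    p <- runif(sample(2:200, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_ref(p))
  }
  # contract invariants
  p <- runif(100)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("moderated fit is symmetric under condition-label swap", {
  cm <- de_count_matrix(80, per_cell = 3, effect = rep(c(2, -2), 5), seed = 2)
  t1 <- fit_moderated_de(cm, "day1")
  swapped <- cm
  swapped$samples$condition <- ifelse(cm$samples$condition == "sham", "injury", "sham")
  t2 <- fit_moderated_de(swapped, "day1")
  k <- !t1$filtered
  expect_equal(t2$log2fc[k], -t1$log2fc[k], tolerance = 1e-10)
  expect_equal(t2$p[k], t1$p[k], tolerance = 1e-10)
})

test_that("a gene with identical counts everywhere has zero fold change", {
  cm <- de_count_matrix(40, per_cell = 3, seed = 3)
  cm$counts[1:40, ] <- matrix(rep(c(80, 120), 20), 40, ncol(cm$counts))  # rows constant
  tbl <- fit_moderated_de(cm, "day1")
  expect_true(all(abs(tbl$log2fc[!tbl$filtered]) < 1e-10))
})

test_that("DgeTable honors its invariants and filtered genes carry no p", {
  cm <- de_count_matrix(100, per_cell = 3, effect = rep(1.5, 10), seed = 4)
  cm$counts[5, ] <- 0   # guaranteed filtered
  tbl <- fit_moderated_de(cm, "day1")
  expect_true(tbl$filtered[5])
  expect_true(all(is.na(tbl$p[tbl$filtered])))
  expect_true(all(is.na(tbl$adj_p[tbl$filtered])))
  k <- !tbl$filtered
  expect_true(all(tbl$adj_p[k] >= tbl$p[k]))
  o <- order(tbl$p[k])
  expect_true(all(diff(tbl$adj_p[k][o]) >= -1e-15))
})

test_that("with weights and shrinkage off, results equal per-gene OLS t-tests", {
  cm <- de_count_matrix(50, per_cell = 3, effect = rep(c(1, 0), 5), seed = 5)
  tbl <- fit_moderated_de(cm, "day1", moderate = FALSE, use_weights = FALSE,
                          norm_method = "none")
  idx <- cm$samples$timepoint == "day1"
  E <- normalize_logcpm(cm$counts[, idx], prior_count = 0.5)
  cond <- factor(cm$samples$condition[idx], levels = c("sham", "injury"))
  for (g in which(!tbl$filtered)[1:20]) {
    fit <- lm(E[g, ] ~ cond)
    sm <- summary(fit)$coefficients["condinjury", ]
    expect_equal(tbl$log2fc[g], unname(sm["Estimate"]), tolerance = 1e-8)
    expect_equal(tbl$stat[g], unname(sm["t value"]), tolerance = 1e-8)
    expect_equal(tbl$p[g], unname(sm["Pr(>|t|)"]), tolerance = 1e-8)
  }
})

test_that("DEG recall is non-decreasing in effect size", {
  recall <- vapply(c(0.5, 1, 2), function(es) {
    sim <- simulate_counts(1500, seed = 77, effect_scale = es,
                           module_fractions = c(iv = 0.2),
                           base_mean_range = c(50, 500))
    tbl <- fit_moderated_de(sim$cm, "day1")
    st <- call_degs(tbl)
    truth_up <- sim$truth$true_module == "iv"
    mean(st[truth_up] == "up")
  }, numeric(1))
  expect_true(all(diff(recall) >= 0))
  expect_gt(recall[3], 0.8)
})

test_that("call_degs applies strict thresholds and direction", {
  tbl <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc = c(1.2, -0.3, 0, 2),
                    p = c(0.001, 0.002, 0.001, 0.2),
                    adj_p = c(0.04, 0.05, 0.01, 0.6),
                    filtered = FALSE)
  st <- call_degs(tbl, alpha = 0.05)
  expect_identical(st, c("up",  # adj_p 0.04, fc > 0
                         "ns",  # adj_p exactly 0.05: strict '<'
                         "ns",  # fc == 0: no direction
                         "ns"))
  tbl$filtered[1] <- TRUE
  expect_identical(call_degs(tbl)[1], "ns")
  expect_identical(call_degs(tbl, use_adjusted = FALSE)[2], "down")
  expect_error(call_degs(tbl, alpha = 1), "alpha")
})

test_that("zero residual df and too-few samples are hard errors", {
  cm <- de_count_matrix(30, per_cell = 2, seed = 6)
  cm2 <- cm
  keep <- !(cm$samples$timepoint == "day1" & cm$samples$condition == "sham" &
              duplicated(paste(cm$samples$condition, cm$samples$timepoint)))
  cm2 <- CountMatrix(cm$counts[, keep], cm$samples[keep, ], cm$genes)
  expect_error(fit_moderated_de(cm2, "day1"), ">= 2 samples")
})
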