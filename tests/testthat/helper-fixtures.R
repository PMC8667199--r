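# Shared fixtures, all built in code.

toy_count_matrix <- function(n_genes = 3, n_samples = 4, seed = 42) {
  set.seed(seed)
  counts <- matrix(rpois(n_genes * n_samples, 50), n_genes, n_samples)
  samples <- data.frame(
    id = paste0("s", seq_len(n_samples)),
    condition = rep(c("sham", "injury"), length.out = n_samples),
    timepoint = rep(c("day1", "day14"), each = ceiling(n_samples / 2))[seq_len(n_samples)],
    batch = "b1", stringsAsFactors = FALSE)
  genes <- data.frame(id = paste0("g", seq_len(n_genes)), chrom = "chr1",
                      tss = seq(5000, by = 10000, length.out = n_genes),
                      strand = rep(c("+", "-"), length.out = n_genes),
                      length = rep(2000L, n_genes), stringsAsFactors = FALSE)
  CountMatrix(counts, samples, genes)
}

# balanced 2x2 design with >= 2 per cell, for DE fits
de_count_matrix <- function(n_genes = 60, per_cell = 3, effect = NULL, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(condition = c("sham", "injury"),
                      timepoint = c("day1", "day14"),
                      rep = seq_len(per_cell), stringsAsFactors = FALSE)
  samples <- data.frame(
    id = sprintf("%s_%s_%d", grid$condition, grid$timepoint, grid$rep),
    condition = grid$condition, timepoint = grid$timepoint,
    batch = ifelse(grid$timepoint == "day1", "b1", "b2"),
    stringsAsFactors = FALSE)
  mu <- matrix(100, n_genes, nrow(samples))
  if (!is.null(effect)) {
    inj_d1 <- samples$condition == "injury" & samples$timepoint == "day1"
    mu[seq_along(effect), inj_d1] <- 100 * 2^effect
  }
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 10), n_genes)
  genes <- data.frame(id = sprintf("g%03d", seq_len(n_genes)), chrom = "chr1",
                      tss = seq(5000, by = 10000, length.out = n_genes),
                      strand = "+", length = 1000L, stringsAsFactors = FALSE)
  CountMatrix(counts, samples, genes)
}

write_bedgraph_lines <- function(lines, path = tempfile(fileext = ".bedGraph")) {
  writeLines(lines, path)
  path
}

toy_track <- function(df, sample = "t") PileupTrack(df, sample = sample)

chip_sample_sheet <- function(n_sham = 2, n_injury = 2, timepoint = "day1") {
  data.frame(id = c(sprintf("sham_c%d", seq_len(n_sham)),
                    sprintf("injury_c%d", seq_len(n_injury))),
             condition = rep(c("sham", "injury"), c(n_sham, n_injury)),
             timepoint = timepoint, stringsAsFactors = FALSE)
}
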