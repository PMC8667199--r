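MODULE_LABELS <- c("i", "ii", "iii", "iv", "v", "vi", "vii", "viii")

# Per-module (day1, day14) log2 effect multipliers of effect_scale.
# The secondary ratio (1.5) encodes "further increased" / "partial recovery":
# the larger-magnitude day is 1.5x the smaller, consistent with the
# classifier's magnitude-split definitions.
module_effect_template <- function(secondary_ratio = 1.5) {
  r <- secondary_ratio
  rbind(i    = c(1,  r),
        ii   = c(r,  1),
        iii  = c(0,  1),
        iv   = c(1,  0),
        v    = c(-1, 0),
        vi   = c(0, -1),
        vii  = c(-r, -1),
        viii = c(-1, -r))
}

#' Simulate a two-condition, two-timepoint count matrix with known trajectories
#'
#' Draws negative-binomial counts for an injury-vs-sham design at day 1 and
#' day 14, with per-gene trajectory-module effects, a batch effect, and
#' log-normal library-size factors. Ground truth (module labels, effects,
#' promoter-mark shifts) is returned alongside but is never consumed by
#' analysis stages.
#'
#' The default design mirrors a small rodent brain-injury study: 2 sham and
#' 4 injured animals at day 1, 4 and 4 at day 14, one library batch per
#' timepoint (so batch is confounded with time and drops out of the
#' within-timepoint contrasts).
#'
#' @param n_genes number of genes.
#' @param group_sizes named integer vector with names `sham_day1`,
#'   `injury_day1`, `sham_day14`, `injury_day14`; each >= 2.
#' @param module_fractions named numeric over modules `i`..`viii`, summing to
#'   <= 1; the remainder are null genes (no condition effect).
#' @param effect_scale base |log2 fold change| of injury vs sham; the
#'   larger-magnitude day of two-timepoint modules gets `1.5 * effect_scale`.
#' @param batch_sd sd (log2 units) of the per-gene, per-batch offset.
#' @param seed integer seed; required, no implicit RNG state is used.
#' @param base_mean_range range of baseline expected counts, sampled
#'   log-uniformly.
#' @param dispersion_range range of NB dispersions, sampled log-uniformly.
#' @param libsize_sd sd of log-normal library-size factors (log2 scale 0.2
#'   equivalent; natural-log sd).
#' @param chip_shift_by_module optional named vector over modules giving the
#'   injury/sham multiplicative promoter-coverage factor applied at both
#'   timepoints; default derives the shift from the expression effect as
#'   `2^(0.5 * effect)` per timepoint. Null genes always have shift 1.
#' @return list with elements `cm` (a [CountMatrix]) and `truth` (data.frame:
#'   gene, true_module, effect_day1, effect_day14, base_mean, dispersion,
#'   chip_shift_day1, chip_shift_day14).
#' @export
simulate_counts <- function(n_genes,
                            group_sizes = c(sham_day1 = 2, injury_day1 = 4,
                                            sham_day14 = 4, injury_day14 = 4),
                            module_fractions = c(i = 0.004, ii = 0.012, iii = 0.006,
                                                 iv = 0.10, v = 0.09, vi = 0.001,
                                                 vii = 0.001, viii = 0.0005),
                            effect_scale = 2,
                            batch_sd = 0.3,
                            seed,
                            base_mean_range = c(10, 2000),
                            dispersion_range = c(0.02, 0.2),
                            libsize_sd = 0.2,
                            chip_shift_by_module = NULL) {
  if (missing(seed)) stop_located("seed is required")
  need <- c("sham_day1", "injury_day1", "sham_day14", "injury_day14")
  if (!all(need %in% names(group_sizes)))
    stop_located("group_sizes must name: %s", paste(need, collapse = ", "))
  group_sizes <- group_sizes[need]
  if (any(group_sizes < 2)) stop_located("each group needs >= 2 samples")
  module_fractions <- module_fractions[names(module_fractions) %in% MODULE_LABELS]
  if (sum(module_fractions) > 1 + 1e-12)
    stop_located("module fractions sum to %.3f > 1", sum(module_fractions))

  set.seed(seed)
  n_mod <- round(module_fractions * n_genes)
  labels <- c(rep(names(n_mod), n_mod),
              rep("null", n_genes - sum(n_mod)))
  labels <- sample(labels)

  tmpl <- module_effect_template() * effect_scale
  eff <- matrix(0, n_genes, 2, dimnames = list(NULL, c("day1", "day14")))
  idx <- labels != "null"
  eff[idx, ] <- tmpl[labels[idx], , drop = FALSE]

  base_mean <- exp(runif(n_genes, log(base_mean_range[1]), log(base_mean_range[2])))
  dispersion <- exp(runif(n_genes, log(dispersion_range[1]), log(dispersion_range[2])))

  if (is.null(chip_shift_by_module)) {
    chip_d1 <- 2^(0.5 * eff[, "day1"])
    chip_d14 <- 2^(0.5 * eff[, "day14"])
  } else {
    chip_d1 <- chip_d14 <- rep(1, n_genes)
    for (m in names(chip_shift_by_module)) {
      chip_d1[labels == m] <- chip_shift_by_module[[m]]
      chip_d14[labels == m] <- chip_shift_by_module[[m]]
    }
  }

  samples <- do.call(rbind, lapply(need, function(g) {
    cond <- sub("_day.*", "", g)
    tp <- sub(".*_(day\\d+)", "\\1", g)
    data.frame(id = sprintf("%s_%s_r%d", cond, tp, seq_len(group_sizes[[g]])),
               condition = cond, timepoint = tp,
               batch = if (tp == "day1") "b1" else "b2",
               stringsAsFactors = FALSE)
  }))

  batches <- unique(samples$batch)
  batch_off <- matrix(rnorm(n_genes * length(batches), 0, batch_sd),
                      n_genes, length(batches), dimnames = list(NULL, batches))
  sf <- exp(rnorm(nrow(samples), 0, libsize_sd))

  counts <- matrix(0, n_genes, nrow(samples))
  for (j in seq_len(nrow(samples))) {
    s <- samples[j, ]
    lfc <- if (s$condition == "injury") eff[, s$timepoint] else 0
    mu <- base_mean * 2^lfc * 2^batch_off[, s$batch] * sf[j]
    counts[, j] <- rnbinom(n_genes, mu = mu, size = 1 / dispersion)
  }

  genes <- data.frame(id = sprintf("g%05d", seq_len(n_genes)),
                      chrom = paste0("chr", ((seq_len(n_genes) - 1) %% 4) + 1),
                      tss = 5000L + 10000L * ((seq_len(n_genes) - 1) %/% 4),
                      strand = rep(c("+", "-"), length.out = n_genes),
                      length = as.integer(round(runif(n_genes, 500, 5000))),
                      stringsAsFactors = FALSE)

  truth <- data.frame(gene = genes$id, true_module = labels,
                      effect_day1 = eff[, "day1"], effect_day14 = eff[, "day14"],
                      base_mean = base_mean, dispersion = dispersion,
                      chip_shift_day1 = chip_d1, chip_shift_day14 = chip_d14,
                      stringsAsFactors = FALSE)
  dimnames(counts) <- list(genes$id, samples$id)
  list(cm = CountMatrix(counts, samples, genes), truth = truth)
}

#' Simulate promoter-centred ChIP pileup tracks from simulation truth
#'
#' Each ChIP sample receives, per gene promoter (TSS +/- `flank`), a coverage
#' level proportional to an expression-correlated baseline times the gene's
#' condition-dependent promoter-mark shift times the sample's sensitivity
#' factor, with optional Poisson noise per 500-bp bin. Regions between
#' promoters get a low constant background. An optional flat `input` control
#' track per sample can be emitted.
#'
#' @param truth truth data.frame from [simulate_counts()].
#' @param gene_meta gene sheet (id, chrom, tss, strand, length).
#' @param samples data.frame with columns id, condition ("injury"/"sham"),
#'   timepoint ("day1"/"day14"); one ChIP track per row.
#' @param depth expected promoter coverage units for an average gene.
#' @param sensitivity named numeric (> 0) per sample id; emulates the
#'   between-dataset sensitivity differences that rank comparison is meant to
#'   absorb. Default all 1.
#' @param noise 0 for deterministic coverage (exact expected values); > 0 for
#'   Poisson noise, scaled so `noise = 1` is plain Poisson counts and smaller
#'   values shrink the variance.
#' @param seed integer seed; required.
#' @param flank promoter half-width in bp.
#' @param bin bin width (bp) within the promoter window.
#' @param background off-promoter coverage rate (before sensitivity scaling).
#' @param with_input also emit a flat input-control track per sample.
#' @return named list of [PileupTrack] objects, one per sample (plus
#'   `<id>_input` tracks when `with_input`).
#' @export
simulate_pileups <- function(truth, gene_meta, samples,
                             depth = 20, sensitivity = NULL, noise = 1,
                             seed, flank = 1000, bin = 500,
                             background = 0.1, with_input = FALSE) {
  if (missing(seed)) stop_located("seed is required")
  if (is.null(sensitivity))
    sensitivity <- setNames(rep(1, nrow(samples)), samples$id)
  if (any(sensitivity <= 0)) stop_located("sensitivity factors must be > 0")
  stopifnot(all(samples$id %in% names(sensitivity)))
  set.seed(seed)

  gm <- gene_meta[match(truth$gene, gene_meta$id), , drop = FALSE]
  # expression-correlated baseline, mean ~1 across genes
  expr_level <- log2(1 + truth$base_mean)
  expr_level <- expr_level / mean(expr_level)

  win_start <- pmax(0L, gm$tss - flank)
  win_end <- gm$tss + flank
  nb <- max(1L, as.integer(ceiling((2 * flank) / bin)))

  out <- list()
  for (j in seq_len(nrow(samples))) {
    s <- samples[j, ]
    shift_col <- paste0("chip_shift_", s$timepoint)
    shift <- if (s$condition == "injury") truth[[shift_col]] else 1
    lam <- depth * expr_level * shift * sensitivity[[s$id]]

    ivs <- vector("list", length(lam) + 1L)
    for (g in seq_along(lam)) {
      bs <- seq(win_start[g], win_end[g], length.out = nb + 1L)
      bs <- as.integer(round(bs))
      vals <- rep(lam[g], nb)
      if (noise > 0) vals <- rpois(nb, vals / noise) * noise
      ivs[[g]] <- data.frame(chrom = gm$chrom[g],
                             start = bs[-length(bs)], end = bs[-1], value = vals)
    }
    # constant background between promoters, per chrom
    bg <- lapply(split(seq_along(lam), gm$chrom), function(ii) {
      ii <- ii[order(win_start[ii])]
      gaps_start <- c(0L, win_end[ii])
      gaps_end <- c(win_start[ii], max(win_end[ii]) + 5000L)
      keep <- gaps_end > gaps_start
      data.frame(chrom = gm$chrom[ii[1]], start = gaps_start[keep],
                 end = gaps_end[keep],
                 value = background * sensitivity[[s$id]])
    })
    ivs[[length(lam) + 1L]] <- do.call(rbind, bg)
    iv <- do.call(rbind, ivs)
    out[[s$id]] <- PileupTrack(iv, sample = s$id, assay = "chip")
    if (with_input) {
      flat <- data.frame(chrom = unique(gm$chrom), start = 0L,
                         end = vapply(split(win_end, gm$chrom), max, numeric(1))[unique(gm$chrom)] + 5000L,
                         value = background * sensitivity[[s$id]])
      out[[paste0(s$id, "_input")]] <-
        PileupTrack(flat, sample = s$id, assay = "input")
    }
  }
  out
}

#' Write a full simulated dataset to disk
#'
#' Emits the three expression TSVs, one bedGraph per ChIP track, and the
#' ground-truth table (for test harnesses only; analysis stages never read
#' it).
#'
#' @param sim result of [simulate_counts()].
#' @param tracks result of [simulate_pileups()] (optional).
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, tracks = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_count_matrix(sim$cm, dir)
  tp <- file.path(dir, "truth.tsv")
  write.table(sim$truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, truth = tp)
  for (nm in names(tracks)) {
    p <- file.path(dir, paste0(nm, ".bedGraph"))
    write_bedgraph(tracks[[nm]], p)
    paths <- c(paths, setNames(p, nm))
  }
  invisible(paths)
}
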