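#' Mean pileup coverage over promoter windows
#'
#' The promoter window is `[TSS - flank, TSS + flank)` (0-based half-open,
#' clipped at 0), centred on the strand-aware TSS. Mean coverage is
#' `sum(value * overlap_length) / window_length`. Genes on chromosomes absent
#' from the track get coverage 0, reported once as a warning.
#'
#' @param track a [PileupTrack].
#' @param gene_meta gene sheet with id, chrom, tss.
#' @param flank promoter half-width in bp (> 0).
#' @return named numeric vector of mean coverages, one per gene.
#' @export
promoter_coverage <- function(track, gene_meta, flank = 1000) {
  stopifnot(flank > 0)
  ws <- pmax(0L, gene_meta$tss - as.integer(flank))
  we <- gene_meta$tss + as.integer(flank)
  cov <- setNames(numeric(nrow(gene_meta)), gene_meta$id)
  iv <- track$intervals
  miss <- 0L
  for (ch in unique(gene_meta$chrom)) {
    gi <- which(gene_meta$chrom == ch)
    ti <- which(iv$chrom == ch)
    if (!length(ti)) { miss <- miss + length(gi); next }
    # IRanges is 1-based closed; shift half-open [s, e) to [s+1, e]
    q <- IRanges::IRanges(start = ws[gi] + 1L, end = we[gi])
    s <- IRanges::IRanges(start = iv$start[ti] + 1L, end = iv$end[ti])
    hits <- IRanges::findOverlaps(q, s)
    if (length(hits)) {
      ol <- IRanges::width(IRanges::pintersect(
        q[S4Vectors::queryHits(hits)], s[S4Vectors::subjectHits(hits)]))
      sig <- ol * iv$value[ti][S4Vectors::subjectHits(hits)]
      sums <- tapply(sig, S4Vectors::queryHits(hits), sum)
      cov[gi[as.integer(names(sums))]] <- as.numeric(sums)
    }
  }
  cov <- cov / (we - ws)
  if (miss) warning(sprintf("%d gene(s) on chromosome(s) absent from track '%s'; coverage set to 0",
                            miss, track$label$sample))
  cov
}

#' Depth-normalize promoter coverages to signal-per-million
#'
#' `cov * 1e6 / total_signal`, making samples sequenced (or piled up) to
#' different depths comparable. Scaling an entire track by a constant leaves
#' the normalized values unchanged.
#'
#' @param cov numeric vector/matrix of coverages (genes x samples for a
#'   matrix).
#' @param totals per-sample `total_signal` (recycled over matrix columns).
#' @return normalized coverages, same shape.
#' @export
depth_normalize <- function(cov, totals) {
  if (any(totals <= 0)) stop_located("total signal must be > 0 for normalization")
  if (is.matrix(cov)) {
    stopifnot(length(totals) == ncol(cov))
    sweep(cov, 2, totals / 1e6, "/")
  } else {
    cov * 1e6 / totals[1]
  }
}

#' Within-sample fractional ranks of promoter coverage
#'
#' Ascending fractional ranks (ties averaged) per sample, the basis of the
#' injury-vs-sham rank scatter. Ranks are invariant under any strictly
#' monotone transform of a sample's coverages, which is what makes them
#' robust to per-dataset sensitivity differences.
#'
#' @param cov numeric vector or genes x samples matrix of normalized
#'   coverages (>= 2 promoters).
#' @return ranks, same shape.
#' @export
rank_promoters <- function(cov) {
  if (is.matrix(cov)) {
    if (nrow(cov) < 2) stop_located("need >= 2 promoters to rank")
    apply(cov, 2, fractional_rank)
  } else {
    if (length(cov) < 2) stop_located("need >= 2 promoters to rank")
    fractional_rank(cov)
  }
}

#' Signed Poisson log10 likelihood-ratio differential score
#'
#' The bdgdiff-style statistic at one promoter: with `x = c_tbi + pseudo`,
#' `y = c_sham + pseudo` and common mean `m = (x + y) / 2`, the log10
#' likelihood ratio of the two-mean Poisson model over the common-mean model,
#'
#'   `score = sign(x - y) * (x * ln(x/m) + y * ln(y/m)) / ln(10)`
#'
#' Positive scores mean higher signal in injury. The score is exactly 0 when
#' the normalized coverages are equal and exactly antisymmetric under
#' swapping the arguments.
#'
#' @param c_tbi,c_sham normalized promoter coverages (>= 0), vectorized.
#' @param pseudo pseudo-coverage stabilizing near-zero promoters (units of
#'   signal-per-million).
#' @return signed score(s).
#' @export
diff_loglr <- function(c_tbi, c_sham, pseudo = 1) {
  stopifnot(all(c_tbi >= 0), all(c_sham >= 0), pseudo >= 0)
  x <- c_tbi + pseudo
  y <- c_sham + pseudo
  m <- (x + y) / 2
  xlx <- function(a, m) ifelse(a == 0, 0, a * log(a / m))
  llr <- (xlx(x, m) + xlx(y, m)) / log(10)
  sign(x - y) * llr
}

#' Score promoters across conditions from pileup tracks
#'
#' End-to-end promoter quantification: per-sample mean promoter coverage,
#' optional input-control subtraction (floored at 0), depth normalization to
#' signal-per-million, within-sample fractional ranks, condition means
#' (replicates averaged after normalization), the signed log10 likelihood
#' ratio per gene, and the strong-enrichment flag.
#'
#' @param tracks named list of [PileupTrack]s keyed by sample id; input
#'   controls, if used, under `"<id>_input"`.
#' @param gene_meta gene sheet (id, chrom, tss).
#' @param samples data.frame with columns id, condition ("injury"/"sham")
#'   describing the ChIP samples to use.
#' @param flank promoter half-width (bp).
#' @param pseudo pseudo-coverage for [diff_loglr()].
#' @param subtract_input subtract the matched input track's promoter coverage
#'   (raw scale, floored at 0) before normalization.
#' @param sham_max_quantile,tbi_min_quantile strong-enrichment box bounds as
#'   rank fractions.
#' @return `PromoterScoreTable` data.frame: gene, chrom, start, end, one
#'   `cov_<id>` and `rank_<id>` column per sample, cov_injury, cov_sham,
#'   rank_injury, rank_sham, score, strong_flag.
#' @export
score_promoters <- function(tracks, gene_meta, samples, flank = 1000,
                            pseudo = 1, subtract_input = FALSE,
                            sham_max_quantile = 0.2, tbi_min_quantile = 0.8) {
  stopifnot(all(samples$id %in% names(tracks)),
            all(samples$condition %in% c("injury", "sham")))
  n <- nrow(gene_meta)
  covm <- matrix(0, n, nrow(samples),
                 dimnames = list(gene_meta$id, samples$id))
  totals <- numeric(nrow(samples))
  for (j in seq_len(nrow(samples))) {
    id <- samples$id[j]
    cov <- promoter_coverage(tracks[[id]], gene_meta, flank = flank)
    if (subtract_input) {
      inp <- tracks[[paste0(id, "_input")]]
      if (is.null(inp)) stop_located("no input track for sample '%s'", id)
      cov <- pmax(0, cov - promoter_coverage(inp, gene_meta, flank = flank))
    }
    covm[, j] <- cov
    totals[j] <- tracks[[id]]$total_signal
  }
  norm <- depth_normalize(covm, totals)
  ranks <- rank_promoters(norm)
  colnames(ranks) <- colnames(norm)

  inj <- samples$condition == "injury"
  cov_injury <- rowMeans(norm[, inj, drop = FALSE])
  cov_sham <- rowMeans(norm[, !inj, drop = FALSE])
  rank_injury <- fractional_rank(cov_injury)
  rank_sham <- fractional_rank(cov_sham)
  score <- diff_loglr(cov_injury, cov_sham, pseudo = pseudo)

  out <- data.frame(gene = gene_meta$id, chrom = gene_meta$chrom,
                    start = pmax(0L, gene_meta$tss - as.integer(flank)),
                    end = gene_meta$tss + as.integer(flank),
                    stringsAsFactors = FALSE)
  colnames(norm) <- paste0("cov_", samples$id)
  colnames(ranks) <- paste0("rank_", samples$id)
  out <- cbind(out, norm, ranks)
  out$cov_injury <- cov_injury
  out$cov_sham <- cov_sham
  out$rank_injury <- rank_injury
  out$rank_sham <- rank_sham
  out$score <- score
  out$strong_flag <- flag_strong_enrichment(out,
                                            sham_max_quantile = sham_max_quantile,
                                            tbi_min_quantile = tbi_min_quantile)
  class(out) <- c("PromoterScoreTable", "data.frame")
  rownames(out) <- NULL
  out
}

#' Flag promoters with distinctive injury-side enrichment
#'
#' The "dashed box" selection: sham rank at or below `sham_max_quantile` of
#' promoters AND injury rank at or above `tbi_min_quantile` — promoters with
#' low-to-undetectable signal in sham controls but high signal after injury.
#'
#' @param table a `PromoterScoreTable` (needs rank_injury/rank_sham).
#' @param sham_max_quantile,tbi_min_quantile rank-fraction bounds in (0, 1).
#' @return logical vector of flags.
#' @export
flag_strong_enrichment <- function(table, sham_max_quantile = 0.2,
                                   tbi_min_quantile = 0.8) {
  stopifnot(sham_max_quantile > 0, sham_max_quantile < 1,
            tbi_min_quantile > 0, tbi_min_quantile < 1)
  N <- nrow(table)
  table$rank_sham / N <= sham_max_quantile &
    table$rank_injury / N >= tbi_min_quantile
}

#' Select the top-k up- and down-regulated promoters by differential score
#'
#' Up list: the k largest strictly positive scores; down list: the k most
#' negative. Ties are broken lexicographically by gene id, so repeated runs
#' are reproducible. If fewer than k genes carry the sign, all are returned
#' with a warning.
#'
#' @param table a `PromoterScoreTable`.
#' @param k number of genes per direction.
#' @return list with character vectors `up` and `down`.
#' @export
select_top_k <- function(table, k = 100) {
  stopifnot(k >= 0)
  pick <- function(tab, dir) {
    tab <- if (dir > 0) tab[tab$score > 0, ] else tab[tab$score < 0, ]
    if (nrow(tab) < k)
      warning(sprintf("only %d gene(s) with %s score (requested %d)",
                      nrow(tab), if (dir > 0) "positive" else "negative", k))
    o <- order(if (dir > 0) -tab$score else tab$score, tab$gene)
    tab$gene[utils::head(o, k)]
  }
  list(up = pick(table, 1), down = pick(table, -1))
}
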