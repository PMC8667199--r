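#' Log2 counts-per-million with a prior count
#'
#' `log2((count + prior) / (libsize + 2 * prior) * 1e6)`. The doubled prior in
#' the denominator keeps the transform monotone across samples of different
#' depth and bounds values away from -Inf.
#'
#' @param cm a [CountMatrix] or a bare counts matrix.
#' @param prior_count pseudo-count added to each observation.
#' @param lib_size optional library sizes; default column sums.
#' @return matrix of log2 CPM, same shape as counts.
#' @export
normalize_logcpm <- function(cm, prior_count = 0.5, lib_size = NULL) {
  counts <- if (inherits(cm, "CountMatrix")) cm$counts else as.matrix(cm)
  if (is.null(lib_size)) lib_size <- colSums(counts)
  zero <- which(lib_size <= 0)
  if (length(zero))
    stop_located("all-zero sample(s): %s",
                 paste(colnames(counts)[zero] %||% zero, collapse = ", "))
  log2(sweep(counts + prior_count, 2, (lib_size + 2 * prior_count) / 1e6, "/"))
}

#' Low-expression filter: CPM above a cutoff in enough samples
#'
#' @param cm a [CountMatrix].
#' @param cpm_cutoff CPM threshold (strict `>`).
#' @param min_samples minimum number of samples above the cutoff; default the
#'   smallest (condition, timepoint) group size.
#' @return logical vector over genes, TRUE = kept.
#' @export
filter_expressed <- function(cm, cpm_cutoff = 1, min_samples = NULL) {
  if (is.null(min_samples))
    min_samples <- min(table(cm$samples$condition, cm$samples$timepoint))
  cpm <- sweep(cm$counts, 2, colSums(cm$counts) / 1e6, "/")
  rowSums(cpm > cpm_cutoff) >= min_samples
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Order-preserving with the input; monotone non-decreasing in p-rank after
#' the step-up monotonization; `adj_p >= p` elementwise.
#'
#' @param pvalues numeric vector in `[0, 1]` (NA passed through).
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop_located("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  p <- pvalues[ok]
  n <- length(p)
  if (n) {
    o <- order(p, decreasing = TRUE)
    adj <- rep(NA_real_, n)
    adj[o] <- pmin(1, cummin(p[o] * n / (n:1)))
    out[ok] <- adj
  }
  out
}

#' Moderated differential expression at one timepoint (injury vs sham)
#'
#' Precision-weighted moderated linear model in the voom tradition:
#' observation weights from a lowess mean-variance trend on log-CPM,
#' empirical-Bayes shrinkage of residual variances toward a global prior, and
#' a moderated t with augmented degrees of freedom; BH adjustment across all
#' unfiltered genes at the timepoint. Each timepoint is fitted independently;
#' a batch covariate enters only when at least two batches are present within
#' the timepoint (otherwise it is dropped with a warning only if requested
#' explicitly). The stage is fully deterministic given its inputs.
#'
#' @param cm a [CountMatrix].
#' @param timepoint "day1" or "day14".
#' @param include_batch include a batch covariate when >= 2 batches exist
#'   within the timepoint.
#' @param prior_count pseudo-count for log-CPM (recorded in output headers).
#' @param cpm_cutoff,min_samples passed to [filter_expressed()] (computed on
#'   the timepoint's samples only).
#' @param moderate apply empirical-Bayes variance shrinkage; `FALSE` gives the
#'   ordinary per-gene weighted least-squares t-test (used by the oracle
#'   tests).
#' @param use_weights fit the mean-variance trend and use precision weights;
#'   `FALSE` forces all observation weights to 1.
#' @param lowess_span span of the lowess mean-variance trend.
#' @param norm_method between-sample normalization of effective library
#'   sizes: `"TMM"` (default; robust to composition bias from coordinated
#'   induction) or `"none"` (plain library sizes).
#' @return a `DgeTable` data.frame: gene, timepoint, log2fc (injury - sham),
#'   mean_logexpr, stat, p, adj_p, filtered. Filtered genes carry NA
#'   statistics.
#' @export
fit_moderated_de <- function(cm, timepoint = c("day1", "day14"),
                             include_batch = TRUE, prior_count = 0.5,
                             cpm_cutoff = 1, min_samples = NULL,
                             moderate = TRUE, use_weights = TRUE,
                             lowess_span = 0.5,
                             norm_method = c("TMM", "none")) {
  timepoint <- match.arg(timepoint)
  norm_method <- match.arg(norm_method)
  idx <- cm$samples$timepoint == timepoint
  smp <- cm$samples[idx, , drop = FALSE]
  counts <- cm$counts[, idx, drop = FALSE]
  tab <- table(smp$condition)
  if (!all(c("injury", "sham") %in% names(tab)) || any(tab < 2))
    stop_located("need >= 2 samples per condition at %s", timepoint)

  sub <- CountMatrix(counts, smp, cm$genes)
  keep <- filter_expressed(sub, cpm_cutoff = cpm_cutoff, min_samples = min_samples)
  ck <- counts[keep, , drop = FALSE]
  lib <- colSums(counts)
  if (norm_method == "TMM") {
    # trimmed-mean scaling guards the injury-vs-sham contrast against
    # composition bias from large blocks of strongly induced genes
    lib <- lib * edgeR::calcNormFactors(ck, lib.size = lib, method = "TMM")
  }

  cond <- factor(smp$condition, levels = c("sham", "injury"))
  design <- stats::model.matrix(~cond)
  if (include_batch && length(unique(smp$batch)) >= 2) {
    design <- stats::model.matrix(~factor(smp$batch) + cond)
  }
  coef_name <- "condinjury"
  if (nrow(ck) <= 1 && use_weights) {
    warning("too few genes for a mean-variance trend; using unit weights")
    use_weights <- FALSE
  }
  if (ncol(ck) - ncol(design) < 1) stop_located("zero residual degrees of freedom")

  if (use_weights) {
    v <- tryCatch(
      limma::voom(ck, design, lib.size = lib, span = lowess_span),
      error = function(e) {
        warning("mean-variance trend fit failed (", conditionMessage(e),
                "); falling back to unit weights")
        NULL
      })
  } else v <- NULL

  if (!is.null(v)) {
    fit <- limma::lmFit(v, design)
    amean <- rowMeans(v$E)
  } else {
    E <- normalize_logcpm(ck, prior_count = prior_count, lib_size = lib)
    fit <- limma::lmFit(E, design)
    amean <- rowMeans(E)
  }

  if (moderate) {
    fit <- limma::eBayes(fit)
    stat <- fit$t[, coef_name]
    p <- fit$p.value[, coef_name]
  } else {
    ordinary_t <- fit$coefficients[, coef_name] /
      (fit$stdev.unscaled[, coef_name] * fit$sigma)
    stat <- ordinary_t
    p <- 2 * pt(-abs(ordinary_t), df = fit$df.residual)
  }
  lfc <- fit$coefficients[, coef_name]

  out <- data.frame(gene = cm$genes$id, timepoint = timepoint,
                    log2fc = NA_real_, mean_logexpr = NA_real_,
                    stat = NA_real_, p = NA_real_, adj_p = NA_real_,
                    filtered = !keep, stringsAsFactors = FALSE)
  out$log2fc[keep] <- lfc
  out$mean_logexpr[keep] <- amean
  out$stat[keep] <- stat
  out$p[keep] <- p
  out$adj_p[keep] <- bh_adjust(p)
  class(out) <- c("DgeTable", "data.frame")
  attr(out, "params") <- list(timepoint = timepoint, prior_count = prior_count,
                              cpm_cutoff = cpm_cutoff, lowess_span = lowess_span,
                              moderate = moderate, use_weights = use_weights,
                              batch_in_model = ncol(design) > 2)
  out
}

#' Call differential status from a DgeTable
#'
#' `up` iff adjusted p < alpha and log2fc > 0; `down` iff adjusted p < alpha
#' and log2fc < 0 (strict inequalities; a fold change of exactly 0 has no
#' direction and stays `ns`). Filtered genes are `ns`. Setting
#' `use_adjusted = FALSE` thresholds the raw p instead (exposed because some
#' displays use unadjusted p; the default is the corrected one).
#'
#' @param tbl a `DgeTable`.
#' @param alpha significance threshold in (0, 1).
#' @param use_adjusted threshold `adj_p` (default) or raw `p`.
#' @return character vector over genes: "up", "down" or "ns".
#' @export
call_degs <- function(tbl, alpha = 0.05, use_adjusted = TRUE) {
  stopifnot(alpha > 0, alpha < 1)
  pv <- if (use_adjusted) tbl$adj_p else tbl$p
  status <- rep("ns", nrow(tbl))
  sig <- !is.na(pv) & pv < alpha & !tbl$filtered
  status[sig & tbl$log2fc > 0] <- "up"
  status[sig & tbl$log2fc < 0] <- "down"
  status
}
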