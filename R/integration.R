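#' One-way ANOVA of promoter differential scores over trajectory modules
#'
#' Tests whether the signed promoter H3K4me3 differential score differs by
#' expression-trajectory module relative to the genes that were never
#' differentially expressed (the "NS" reference). One linear model does both
#' jobs: its omnibus F is the one-way ANOVA, and its coefficients with NS as
#' the reference level are the module-vs-NS contrasts. Family-wise adjusted
#' p-values for each module-vs-NS comparison use the Tukey-Kramer
#' generalization of Tukey's HSD (studentized range with unequal group
#' sizes, exact tail via `stats::ptukey`).
#'
#' @param scores named numeric vector of signed scores, names = gene ids.
#' @param assignments a `TrajectoryAssignment` table; modules i-viii form
#'   the test groups and `unassigned` genes form NS. `discordant` genes are
#'   excluded.
#' @param min_group groups with fewer genes are dropped with a warning.
#' @return `ModuleAssociationResult` data.frame: group, n_genes, mean_score,
#'   contrast_vs_ns, tukey_p_vs_ns, stars, anova_F, anova_p (omnibus values
#'   repeated on every row; NS row has contrast 0 and NA Tukey p).
#' @export
module_anova <- function(scores, assignments, min_group = 2) {
  grp <- ifelse(assignments$module %in% MODULE_LABELS, assignments$module,
                ifelse(assignments$module == "unassigned", "NS", NA))
  keep <- !is.na(grp) & assignments$gene %in% names(scores)
  grp <- grp[keep]
  y <- scores[assignments$gene[keep]]

  sizes <- table(grp)
  small <- names(sizes)[sizes < min_group]
  if (length(small)) {
    warning(sprintf("dropping group(s) with < %d genes: %s", min_group,
                    paste(small, collapse = ", ")))
    sel <- !(grp %in% small)
    grp <- grp[sel]; y <- y[sel]
  }
  groups <- intersect(c("NS", MODULE_LABELS), unique(grp))
  if (!("NS" %in% groups)) stop_located("no NS reference genes available")
  if (length(groups) < 2) stop_located("need >= 2 groups with >= %d genes", min_group)
  g <- factor(grp, levels = groups)  # NS first -> reference level

  fit <- lm(y ~ g)
  an <- anova(fit)
  F_val <- an$`F value`[1]
  F_p <- an$`Pr(>F)`[1]
  k <- length(groups)
  df_w <- fit$df.residual
  msw <- an$`Mean Sq`[2]
  if (all(abs(y - mean(y)) < 1e-12 * max(1, abs(mean(y))))) {
    # identical constant groups: no between- or within-variance; F := 0
    F_val <- 0; F_p <- 1
  }

  means <- tapply(y, g, mean)
  ns_n <- sum(g == "NS")
  rows <- lapply(groups, function(m) {
    n_m <- sum(g == m)
    if (m == "NS") {
      contrast <- 0; tp <- NA_real_
    } else {
      contrast <- means[[m]] - means[["NS"]]
      se <- sqrt((msw / 2) * (1 / n_m + 1 / ns_n))
      q <- abs(contrast) / se
      tp <- ptukey(q, nmeans = k, df = df_w, lower.tail = FALSE)
    }
    data.frame(group = m, n_genes = n_m, mean_score = means[[m]],
               contrast_vs_ns = contrast, tukey_p_vs_ns = tp,
               stars = significance_stars(tp),
               anova_F = F_val, anova_p = F_p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ModuleAssociationResult", "data.frame")
  rownames(out) <- NULL
  out
}

#' All-pairs Tukey-Kramer honest significant difference
#'
#' Every pairwise group contrast with its studentized-range (Tukey-Kramer,
#' unequal-n) family-wise adjusted p. `module_anova()` reports the vs-NS
#' subset of these comparisons; this helper exposes the full family, e.g.
#' for family-wise error calibration.
#'
#' @param y numeric response.
#' @param g group factor/character (>= 2 groups of >= 2).
#' @return data.frame: group1, group2, diff, q_stat, p_adj.
#' @export
tukey_hsd <- function(y, g) {
  g <- factor(g)
  stopifnot(nlevels(g) >= 2, all(table(g) >= 2))
  fit <- lm(y ~ g)
  msw <- anova(fit)$`Mean Sq`[2]
  df_w <- fit$df.residual
  k <- nlevels(g)
  means <- tapply(y, g, mean)
  ns <- table(g)
  pairs <- utils::combn(levels(g), 2)
  rows <- apply(pairs, 2, function(pr) {
    d <- means[[pr[2]]] - means[[pr[1]]]
    se <- sqrt((msw / 2) * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    q <- abs(d) / se
    data.frame(group1 = pr[1], group2 = pr[2], diff = d, q_stat = q,
               p_adj = ptukey(q, nmeans = k, df = df_w, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) "" else if (pi <= 0.001) "***" else if (pi <= 0.01) "**"
    else if (pi <= 0.05) "*" else ""
  }, character(1))
}

#' Box-plot summary of per-group score distributions
#'
#' Per group: quartiles, whiskers by the 1.5 x IQR rule (most extreme data
#' point within the fences), and the Tukey significance stars — a TSV-ready
#' companion to the association box plot.
#'
#' @param results a `ModuleAssociationResult` from [module_anova()].
#' @param scores named numeric vector of signed scores.
#' @param assignments a `TrajectoryAssignment` table.
#' @return data.frame: group, n, lower_whisker, q1, median, q3,
#'   upper_whisker, stars.
#' @export
summarize_fig_association <- function(results, scores, assignments) {
  grp <- ifelse(assignments$module %in% MODULE_LABELS, assignments$module,
                ifelse(assignments$module == "unassigned", "NS", NA))
  keep <- !is.na(grp) & assignments$gene %in% names(scores)
  grp <- grp[keep]
  y <- scores[assignments$gene[keep]]
  rows <- lapply(results$group, function(m) {
    v <- y[grp == m]
    qs <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- qs[3] - qs[1]
    lw <- min(v[v >= qs[1] - 1.5 * iqr])
    uw <- max(v[v <= qs[3] + 1.5 * iqr])
    data.frame(group = m, n = length(v), lower_whisker = lw, q1 = qs[1],
               median = qs[2], q3 = qs[3], upper_whisker = uw,
               stars = results$stars[results$group == m],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
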