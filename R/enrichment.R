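#' Storey q-values at a fixed lambda
#'
#' `pi0 = #\{p > lambda\} / (m (1 - lambda))` capped at 1 (no smoother), then
#' the BH-style step-up scaled by `pi0`. Deterministic by construction.
#'
#' @param p p-values.
#' @param lambda tuning point for the null-proportion estimate.
#' @return q-values in input order.
#' @export
storey_q <- function(p, lambda = 0.5) {
  m <- length(p)
  if (!m) return(numeric(0))
  pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
  pi0 <- max(pi0, 1 / m)  # guard: all-significant input
  pi0 * bh_adjust(p)
}

#' Hypergeometric over-representation analysis
#'
#' For each library term with in-universe annotation count `K` within
#' `[min_set, max_set]`, the upper-tail probability `P(X >= k)` of the
#' overlap `k` between the query (size `n`) and the term under
#' `Hypergeometric(N, K, n)` with `N` the universe size. BH adjustment and
#' Storey q-values are computed across the tested terms; rows are sorted by
#' p, ties broken by term id.
#'
#' @param query character vector of query gene ids (must be within the
#'   universe).
#' @param universe character vector of background gene ids.
#' @param lib a [GeneSetLibrary].
#' @param min_set,max_set in-universe term size bounds for testing.
#' @return data.frame: term_id, description, k, K, n, N, p, adj_p, q.
#' @export
hypergeom_ora <- function(query, universe, lib, min_set = 10, max_set = 500) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (!length(lib$terms)) stop_located("empty gene-set library")
  off <- setdiff(query, universe)
  if (length(off))
    stop_located("query gene(s) not in universe: %s",
                 paste(utils::head(off, 10), collapse = ", "))
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(lib$terms), function(id) {
    genes <- intersect(lib$terms[[id]]$genes, universe)
    K <- length(genes)
    if (K < min_set || K > max_set) return(NULL)
    k <- length(intersect(genes, query))
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, description = lib$terms[[id]]$description,
               k = k, K = K, n = n, N = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(0), description = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), adj_p = numeric(0),
                      q = numeric(0)))
  out$adj_p <- bh_adjust(out$p)
  out$q <- storey_q(out$p)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-module over-representation against a gene-set library
#'
#' One ORA per trajectory module i-viii, with the universe fixed to all genes
#' that survived the expression filter (i.e. were actually tested for DE) —
#' standard ORA practice, avoiding inflation from never-testable genes. Rows
#' are retained iff `adj_p <= p_cut` and `q <= q_cut` (closed cutoffs). An
#' empty result for a module is a legitimate outcome, not an error.
#'
#' @param assignments a `TrajectoryAssignment` table.
#' @param lib a [GeneSetLibrary].
#' @param universe character vector of tested genes.
#' @param p_cut,q_cut significance cutoffs applied as `<=`.
#' @param min_set,max_set passed to [hypergeom_ora()].
#' @return named list over modules: each a filtered enrichment data.frame
#'   (possibly 0-row), with the unfiltered table in attribute `"all"`.
#' @export
enrich_modules <- function(assignments, lib, universe,
                           p_cut = 0.05, q_cut = 0.05,
                           min_set = 10, max_set = 500) {
  out <- list()
  for (m in MODULE_LABELS) {
    genes <- intersect(assignments$gene[assignments$module == m], universe)
    tab <- hypergeom_ora(genes, universe, lib, min_set = min_set, max_set = max_set)
    kept <- tab[tab$adj_p <= p_cut & tab$q <= q_cut, , drop = FALSE]
    attr(kept, "all") <- tab
    out[[m]] <- kept
  }
  out
}

#' Term-by-module summary of per-module enrichment (dot-plot style)
#' @param enrichments result of [enrich_modules()].
#' @return long data.frame: module, term_id, description, k, p, adj_p, q.
#' @export
summarize_enrichment <- function(enrichments) {
  rows <- lapply(names(enrichments), function(m) {
    e <- enrichments[[m]]
    if (!nrow(e)) return(NULL)
    cbind(module = m, e[, c("term_id", "description", "k", "p", "adj_p", "q")])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(module = character(0), term_id = character(0),
                      description = character(0), k = integer(0),
                      p = numeric(0), adj_p = numeric(0), q = numeric(0))
  out
}
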