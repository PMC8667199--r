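#' @keywords internal
"_PACKAGE"

#' @importFrom stats anova aov lm lowess median pnbinom pnorm pt ptukey phyper
#'   quantile rnbinom rnorm rpois runif setNames var approx
#' @importFrom utils read.delim write.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a TSV with a commented provenance header
#'
#' All pipeline outputs share this dialect: `#`-prefixed header lines carrying
#' the package version and the parameters that produced the table, followed by
#' a plain tab-separated table with a column header row. Readers that skip
#' `#` lines (e.g. `read.delim(comment.char = "#")`) see an ordinary TSV.
#'
#' @param df data.frame to write.
#' @param path output file path.
#' @param params named list of parameters recorded in the header.
#' @param timestamp logical; include a timestamp line (excluded from
#'   determinism comparisons, which only cover non-`#` lines).
#' @return `path`, invisibly.
#' @export
write_output_tsv <- function(df, path, params = list(), timestamp = FALSE) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# trajectome %s", as.character(packageVersion("trajectome"))), con)
  if (length(params)) {
    kv <- vapply(names(params), function(k) {
      sprintf("%s=%s", k, paste(format(params[[k]], trim = TRUE), collapse = ","))
    }, character(1))
    writeLines(paste0("# ", kv), con)
  }
  if (timestamp) {
    writeLines(sprintf("# written=%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fractional (mid) ranks in ascending order, ties averaged
#' @param x numeric vector.
#' @return numeric vector of ranks in `[1, length(x)]`.
#' @export
fractional_rank <- function(x) {
  stopifnot(is.numeric(x))
  rank(x, ties.method = "average", na.last = "keep")
}

stop_located <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
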