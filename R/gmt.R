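#' Gene-set library (GMT)
#'
#' @param terms named list; each element a list with `description` and
#'   `genes` (character vector, de-duplicated, non-empty).
#' @return object of class `GeneSetLibrary`.
#' @export
GeneSetLibrary <- function(terms) {
  if (anyDuplicated(names(terms)))
    stop_located("duplicate term id(s): %s",
                 paste(unique(names(terms)[duplicated(names(terms))]), collapse = ", "))
  for (id in names(terms)) {
    terms[[id]]$genes <- unique(as.character(terms[[id]]$genes))
    if (!length(terms[[id]]$genes)) stop_located("empty gene set for term '%s'", id)
  }
  structure(list(terms = terms), class = "GeneSetLibrary")
}

#' @export
print.GeneSetLibrary <- function(x, ...) {
  sizes <- lengths(lapply(x$terms, `[[`, "genes"))
  cat(sprintf("GeneSetLibrary: %d terms, set sizes %d-%d\n",
              length(x$terms), if (length(sizes)) min(sizes) else 0L,
              if (length(sizes)) max(sizes) else 0L))
  invisible(x)
}

#' @export
length.GeneSetLibrary <- function(x) length(x$terms)

#' Read a GMT gene-set file
#'
#' Tab-delimited lines: term id, description, then one gene per field.
#' Duplicate genes within a set are de-duplicated; duplicate term ids and
#' lines with fewer than 3 fields are hard errors.
#'
#' @param path GMT file.
#' @return a [GeneSetLibrary].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_located("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3))
    stop_located("%s: line %d has %d field(s), expected >= 3 (term, description, genes...)",
                 path, which(nf < 3)[1], nf[which(nf < 3)[1]])
  ids <- vapply(parts, `[`, character(1), 1)
  if (anyDuplicated(ids))
    stop_located("duplicate term id(s) in %s: %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  terms <- lapply(parts, function(p) list(description = p[2], genes = unique(p[-(1:2)])))
  names(terms) <- ids
  GeneSetLibrary(terms)
}

#' Write a GeneSetLibrary as a GMT file
#' @param lib a [GeneSetLibrary].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(lib, path) {
  lines <- vapply(names(lib$terms), function(id) {
    t <- lib$terms[[id]]
    paste(c(id, t$description, t$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
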