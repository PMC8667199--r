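#' Pileup coverage track (bedGraph semantics)
#'
#' An interval-run-length genome coverage track with 0-based half-open
#' coordinates, as produced by MACS2's pileup output. Overlapping intervals
#' on one chromosome are an error: a pileup is a step function, not a
#' feature set.
#'
#' @param intervals data.frame with columns chrom, start, end, value.
#' @param sample sample id carried in the label.
#' @param assay "chip" or "input".
#' @return object of class `PileupTrack` with fields `intervals`,
#'   `total_signal` (sum of value x width) and `label`.
#' @export
PileupTrack <- function(intervals, sample = "sample", assay = c("chip", "input")) {
  assay <- match.arg(assay)
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(intervals)))
  intervals <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  rownames(intervals) <- NULL
  bad <- which(intervals$end <= intervals$start)
  if (length(bad))
    stop_located("zero- or negative-length interval at %s:%d-%d",
                 intervals$chrom[bad[1]], intervals$start[bad[1]], intervals$end[bad[1]])
  if (any(intervals$value < 0))
    stop_located("negative coverage value in pileup")
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)]))
      stop_located("overlapping intervals on %s (pileup must be a step function)", ch)
  }
  total <- sum(intervals$value * (intervals$end - intervals$start))
  structure(list(intervals = intervals, total_signal = total,
                 label = list(sample = sample, assay = assay)),
            class = "PileupTrack")
}

#' @export
print.PileupTrack <- function(x, ...) {
  cat(sprintf("PileupTrack '%s' (%s): %d intervals on %d chrom(s), total signal %.4g\n",
              x$label$sample, x$label$assay, nrow(x$intervals),
              length(unique(x$intervals$chrom)), x$total_signal))
  invisible(x)
}

#' Read a bedGraph pileup file
#'
#' Whitespace-delimited 4-column lines (chrom, start, end, value); an
#' optional leading `track` line and `#` comments are skipped. Coordinates
#' are kept 0-based half-open exactly as on disk. Overlaps within a
#' chromosome, zero-length intervals and negative values are hard errors.
#'
#' @param path bedGraph file.
#' @param sample,assay carried into the track label.
#' @return a [PileupTrack]; an empty file yields an empty track with
#'   `total_signal` 0.
#' @export
read_bedgraph <- function(path, sample = basename(path), assay = "chip") {
  if (!file.exists(path)) stop_located("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    iv <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0), value = numeric(0))
    return(PileupTrack(iv, sample = sample, assay = assay))
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 4))
    stop_located("%s: line %d has %d field(s), expected 4",
                 path, which(nf < 4)[1], nf[which(nf < 4)[1]])
  m <- matrix(unlist(lapply(parts, `[`, 1:4)), ncol = 4, byrow = TRUE)
  iv <- data.frame(chrom = m[, 1],
                   start = as.integer(m[, 2]),
                   end = as.integer(m[, 3]),
                   value = as.numeric(m[, 4]))
  if (anyNA(iv$start) || anyNA(iv$end) || anyNA(iv$value))
    stop_located("%s: non-numeric coordinate or value", path)
  PileupTrack(iv, sample = sample, assay = assay)
}

#' Write a PileupTrack as a bedGraph file
#' @param track a [PileupTrack].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  iv <- track$intervals
  writeLines(sprintf("%s\t%d\t%d\t%s", iv$chrom, iv$start, iv$end,
                     format(iv$value, trim = TRUE, scientific = FALSE)),
             path)
  invisible(path)
}
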