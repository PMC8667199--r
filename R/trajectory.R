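TRAJECTORY_LABELS <- c(MODULE_LABELS, "discordant", "unassigned")

#' Classify genes into the eight expression-trajectory modules
#'
#' Decision table over per-timepoint differential status (day 1, day 14) and
#' the relative magnitude of the model log2 fold changes:
#'
#' | day1 | day14 | magnitude            | module |
#' |------|-------|----------------------|--------|
#' | up   | up    | `|fc14| > |fc1|`     | i (persistently up, still growing) |
#' | up   | up    | `|fc14| <= |fc1|`    | ii (up, partial recovery) |
#' | ns   | up    |                      | iii (delayed up) |
#' | up   | ns    |                      | iv (acute up, full recovery) |
#' | down | ns    |                      | v (acute down, full recovery) |
#' | ns   | down  |                      | vi (delayed down) |
#' | down | down  | `|fc14| < |fc1|`     | vii (down, partial recovery) |
#' | down | down  | `|fc14| >= |fc1|`    | viii (persistently down, deepening) |
#' | up/down | down/up |                 | discordant |
#' | ns   | ns    |                      | unassigned |
#'
#' Ties in magnitude go to the label on the inequality's closed side (ii and
#' viii). The classifier is scale-invariant: multiplying both fold changes by
#' one positive constant never changes the label. Every input maps to exactly
#' one of the ten labels.
#'
#' @param status_d1,status_d14 character vectors in `{"up","down","ns"}`.
#' @param log2fc_d1,log2fc_d14 finite model fold changes (values for `ns`
#'   timepoints are not consulted except in the two-significant cases).
#' @return character vector of module labels.
#' @export
classify_trajectory <- function(status_d1, status_d14, log2fc_d1, log2fc_d14) {
  stopifnot(all(status_d1 %in% c("up", "down", "ns")),
            all(status_d14 %in% c("up", "down", "ns")),
            length(status_d1) == length(status_d14))
  key <- paste(status_d1, status_d14, sep = ",")
  out <- rep("unassigned", length(key))
  out[key == "ns,up"] <- "iii"
  out[key == "up,ns"] <- "iv"
  out[key == "down,ns"] <- "v"
  out[key == "ns,down"] <- "vi"
  out[key %in% c("up,down", "down,up")] <- "discordant"
  uu <- key == "up,up"
  out[uu] <- ifelse(abs(log2fc_d14[uu]) > abs(log2fc_d1[uu]), "i", "ii")
  dd <- key == "down,down"
  out[dd] <- ifelse(abs(log2fc_d14[dd]) < abs(log2fc_d1[dd]), "vii", "viii")
  out
}

#' Reads per kilobase per million mapped reads
#' @param count read count (may include a prior).
#' @param length_bp gene length in bp.
#' @param lib_size library size (total mapped reads).
#' @return RPKM value(s).
#' @export
rpkm <- function(count, length_bp, lib_size) {
  stopifnot(all(length_bp >= 1), all(lib_size > 0))
  count / ((length_bp / 1000) * (lib_size / 1e6))
}

#' Baseline-anchored trajectory profiles
#'
#' The expression baseline is sham at day 14 (sham animals having recovered
#' from the acute effect of the surgery itself): per gene, the mean log2 RPKM
#' over sham/day-14 samples, with a prior count to bound zeros. The profile
#' values at each timepoint are `baseline + log2fc` using the model-estimated
#' (batch-corrected) fold changes, not raw group means; non-significant or
#' filtered timepoints with NA fold change contribute 0.
#'
#' @param cm a [CountMatrix] (gene lengths required).
#' @param dge_d1,dge_d14 `DgeTable`s for day 1 and day 14.
#' @param prior_count pseudo-count used inside the RPKM log.
#' @return data.frame: gene, baseline, value_d1, value_d14 (log2 RPKM scale).
#' @export
compute_trajectory_profile <- function(cm, dge_d1, dge_d14, prior_count = 0.5) {
  if (is.null(cm$genes$length) || anyNA(cm$genes$length))
    stop_located("gene lengths are required for RPKM profiles")
  ref <- cm$samples$condition == "sham" & cm$samples$timepoint == "day14"
  if (!any(ref)) stop_located("no sham day14 samples to anchor the baseline")
  lib <- colSums(cm$counts)
  logr <- sapply(which(ref), function(j)
    log2(rpkm(cm$counts[, j] + prior_count, cm$genes$length, lib[j])))
  baseline <- rowMeans(as.matrix(logr))
  f1 <- dge_d1$log2fc[match(cm$genes$id, dge_d1$gene)]
  f14 <- dge_d14$log2fc[match(cm$genes$id, dge_d14$gene)]
  f1[!is.finite(f1)] <- 0
  f14[!is.finite(f14)] <- 0
  data.frame(gene = cm$genes$id, baseline = baseline,
             value_d1 = baseline + f1, value_d14 = baseline + f14,
             stringsAsFactors = FALSE)
}

#' Assign all genes to trajectory modules from two DgeTables
#'
#' Combines per-timepoint DEG calls, the module decision table and the
#' baseline-anchored profile into one `TrajectoryAssignment` table. Genes
#' significant at either timepoint partition exactly into modules i-viii plus
#' `discordant`; the remainder are `unassigned` (the NS reference set for the
#' epigenome association test).
#'
#' @param cm a [CountMatrix].
#' @param dge_d1,dge_d14 `DgeTable`s from [fit_moderated_de()].
#' @param alpha DEG threshold (strict, on adjusted p).
#' @param use_adjusted threshold adjusted (default) or raw p.
#' @return data.frame: gene, status_d1, status_d14, log2fc_d1, log2fc_d14,
#'   module, baseline, value_d1, value_d14.
#' @export
assign_trajectories <- function(cm, dge_d1, dge_d14, alpha = 0.05,
                                use_adjusted = TRUE) {
  stopifnot(identical(dge_d1$gene, dge_d14$gene))
  s1 <- call_degs(dge_d1, alpha = alpha, use_adjusted = use_adjusted)
  s14 <- call_degs(dge_d14, alpha = alpha, use_adjusted = use_adjusted)
  f1 <- ifelse(is.na(dge_d1$log2fc), 0, dge_d1$log2fc)
  f14 <- ifelse(is.na(dge_d14$log2fc), 0, dge_d14$log2fc)
  module <- classify_trajectory(s1, s14, f1, f14)
  prof <- compute_trajectory_profile(cm, dge_d1, dge_d14)
  prof <- prof[match(dge_d1$gene, prof$gene), ]
  out <- data.frame(gene = dge_d1$gene, status_d1 = s1, status_d14 = s14,
                    log2fc_d1 = dge_d1$log2fc, log2fc_d14 = dge_d14$log2fc,
                    module = module, baseline = prof$baseline,
                    value_d1 = prof$value_d1, value_d14 = prof$value_d14,
                    stringsAsFactors = FALSE)
  class(out) <- c("TrajectoryAssignment", "data.frame")
  out
}

#' Sankey node/flow table of trajectory module membership
#'
#' Nodes are direction strata at each timepoint (`up@day1`, ...); flows carry
#' the gene count per module. Flow totals equal the number of genes assigned
#' to any module (everything except `unassigned`).
#'
#' @param assignments a `TrajectoryAssignment` table.
#' @return data.frame: from, to, module, n.
#' @export
export_sankey <- function(assignments) {
  a <- assignments[assignments$module != "unassigned", , drop = FALSE]
  if (!nrow(a))
    return(data.frame(from = character(0), to = character(0),
                      module = character(0), n = integer(0)))
  key <- paste(a$status_d1, a$status_d14, a$module)
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- strsplit(agg$key, " ", fixed = TRUE)
  data.frame(from = paste0(vapply(parts, `[`, "", 1), "@day1"),
             to = paste0(vapply(parts, `[`, "", 2), "@day14"),
             module = vapply(parts, `[`, "", 3),
             n = agg$Freq, stringsAsFactors = FALSE)
}
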