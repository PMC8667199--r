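DEFAULT_CONFIG <- list(
  counts = NULL, samples = NULL, genes = NULL,   # expression TSVs
  chip_samples = NULL,                            # TSV: id, condition, timepoint, path
  gmt = NULL,
  outdir = "trajectome_out",
  alpha = 0.05, use_adjusted = TRUE,
  prior_count = 0.5, cpm_cutoff = 1, lowess_span = 0.5,
  flank = 1000, pseudo = 1, k_top = 100,
  sham_max_quantile = 0.2, tbi_min_quantile = 0.8,
  subtract_input = FALSE, chip_timepoint = "day1",
  min_set = 10, max_set = 500, p_cut = 0.05, q_cut = 0.05,
  seed = 1,
  stages = list(dge = TRUE, trajectory = TRUE, enrich = TRUE,
                chip = TRUE, integrate = TRUE),
  verbose = TRUE)

#' Read a pipeline configuration file (JSON)
#'
#' Unknown keys are an error; missing keys take package defaults. The config
#' round-trips losslessly through its on-disk JSON form.
#'
#' @param path JSON file.
#' @return validated config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_located("config not found: %s", path)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(utils::modifyList(DEFAULT_CONFIG, as.list(user)))
}

#' Validate a pipeline configuration
#' @param config config list (see `read_config`).
#' @return the config, invisibly-validated; errors before any compute.
#' @export
validate_config <- function(config) {
  unknown <- setdiff(names(config), names(DEFAULT_CONFIG))
  if (length(unknown))
    stop_located("unknown config key(s): %s", paste(unknown, collapse = ", "))
  config <- utils::modifyList(DEFAULT_CONFIG, config)
  st <- config$stages
  with(config, {
    stopifnot(alpha > 0, alpha < 1, flank > 0, k_top >= 0, pseudo >= 0,
              sham_max_quantile > 0, sham_max_quantile < 1,
              tbi_min_quantile > 0, tbi_min_quantile < 1,
              p_cut > 0, q_cut > 0)
  })
  need_expr <- st$dge || st$trajectory || st$enrich || st$integrate
  if (need_expr) {
    for (key in c("counts", "samples", "genes")) {
      if (is.null(config[[key]]))
        stop_located("config key '%s' required for expression stages", key)
      if (!file.exists(config[[key]]))
        stop_located("%s file not found: %s", key, config[[key]])
    }
  }
  if (st$enrich) {
    if (is.null(config$gmt)) stop_located("gmt required when enrichment stage enabled")
    if (!file.exists(config$gmt)) stop_located("gmt file not found: %s", config$gmt)
  }
  if (st$chip || st$integrate) {
    if (is.null(config$chip_samples))
      stop_located("chip_samples sheet required for chip/integration stages")
    if (!file.exists(config$chip_samples))
      stop_located("chip_samples file not found: %s", config$chip_samples)
  }
  config
}

#' Run the full pipeline from a configuration
#'
#' Stages run in dependency order: dge -> trajectory -> enrichment on the
#' expression side; chip -> integration on the epigenome side (integration
#' also needs trajectory). Every output TSV carries a `#` header with package
#' version and the parameters used. The pipeline is deterministic given its
#' inputs: rerunning with the same config reproduces identical non-header
#' content. Ground-truth files from the simulator are never read. On stage
#' failure, partial outputs from this run are removed and the error names
#' the failing stage.
#'
#' @param config validated config list (see [read_config()]).
#' @return named character vector: manifest of written output paths.
#' @export
run_all <- function(config) {
  config <- validate_config(config)
  st <- config$stages
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  note <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))
  emit <- function(df, name, params) {
    p <- file.path(config$outdir, name)
    write_output_tsv(df, p, params = params)
    written <<- c(written, setNames(p, name))
    p
  }
  stage <- "config"
  tryCatch({
    dge1 <- dge14 <- assignments <- ptab <- NULL
    hdr <- config[c("alpha", "prior_count", "cpm_cutoff", "lowess_span")]

    if (st$dge || st$trajectory || st$enrich || st$integrate) {
      stage <- "dge"
      note("[dge] reading count matrix")
      cm <- read_count_matrix(config$counts, config$samples, config$genes)
      dge1 <- fit_moderated_de(cm, "day1", prior_count = config$prior_count,
                               cpm_cutoff = config$cpm_cutoff,
                               lowess_span = config$lowess_span)
      dge14 <- fit_moderated_de(cm, "day14", prior_count = config$prior_count,
                                cpm_cutoff = config$cpm_cutoff,
                                lowess_span = config$lowess_span)
      for (tbl in list(dge1, dge14)) {
        tbl$status <- call_degs(tbl, alpha = config$alpha,
                                use_adjusted = config$use_adjusted)
        emit(tbl, sprintf("dge_%s.tsv", tbl$timepoint[1]), hdr)
      }
    }
    if (st$trajectory || st$enrich || st$integrate) {
      stage <- "trajectory"
      assignments <- assign_trajectories(cm, dge1, dge14, alpha = config$alpha,
                                         use_adjusted = config$use_adjusted)
      emit(assignments, "trajectory_modules.tsv", hdr["alpha"])
      emit(export_sankey(assignments), "sankey.tsv", hdr["alpha"])
    }
    if (st$enrich) {
      stage <- "enrichment"
      lib <- read_gmt(config$gmt)
      universe <- dge1$gene[!dge1$filtered | !dge14$filtered]
      enr <- enrich_modules(assignments, lib, universe,
                            p_cut = config$p_cut, q_cut = config$q_cut,
                            min_set = config$min_set, max_set = config$max_set)
      ep <- config[c("p_cut", "q_cut", "min_set", "max_set")]
      for (m in names(enr))
        emit(enr[[m]], sprintf("enrichment_module_%s.tsv", m), ep)
      emit(summarize_enrichment(enr), "enrichment_summary.tsv", ep)
    }
    if (st$chip || st$integrate) {
      stage <- "chip"
      chip <- read.delim(config$chip_samples, comment.char = "#",
                         stringsAsFactors = FALSE)
      chip <- chip[chip$timepoint == config$chip_timepoint, , drop = FALSE]
      if (!nrow(chip))
        stop_located("no chip samples at timepoint '%s'", config$chip_timepoint)
      note("[chip] reading %d bedGraph track(s)", nrow(chip))
      tracks <- list()
      for (i in seq_len(nrow(chip)))
        tracks[[chip$id[i]]] <- read_bedgraph(chip$path[i], sample = chip$id[i])
      gm <- read.delim(config$genes, comment.char = "#", stringsAsFactors = FALSE)
      ptab <- score_promoters(tracks, gm, chip, flank = config$flank,
                              pseudo = config$pseudo,
                              subtract_input = config$subtract_input,
                              sham_max_quantile = config$sham_max_quantile,
                              tbi_min_quantile = config$tbi_min_quantile)
      cp <- config[c("flank", "pseudo", "sham_max_quantile", "tbi_min_quantile")]
      emit(ptab, "promoter_scores.tsv", cp)
      top <- select_top_k(ptab, k = config$k_top)
      up_p <- file.path(config$outdir, sprintf("top%d_up.txt", config$k_top))
      dn_p <- file.path(config$outdir, sprintf("top%d_down.txt", config$k_top))
      writeLines(top$up, up_p); writeLines(top$down, dn_p)
      written <- c(written, setNames(c(up_p, dn_p), basename(c(up_p, dn_p))))
    }
    if (st$integrate) {
      stage <- "integration"
      scores <- setNames(ptab$score, ptab$gene)
      assoc <- module_anova(scores, assignments)
      emit(assoc, "module_h3k4me3_association.tsv", hdr["alpha"])
      emit(summarize_fig_association(assoc, scores, assignments),
           "association_boxplot.tsv", hdr["alpha"])
    }
    written
  }, error = function(e) {
    unlink(written)
    stop_located("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
}
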