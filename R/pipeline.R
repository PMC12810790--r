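## End-to-end pipeline runner: simulate (or load) -> quantify -> normalize
## -> differential expression -> cluster -> report.

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order, writing every intermediate as a
#' stamped TSV under `outdir` and finishing with a markdown report (and
#' optional PNG figures) summarizing detection counts, abundance
#' distributions, the differential expression contrast, and -- when ground
#' truth is available -- false-positive and recovery summaries. All
#' randomness derives from `seed`; rerunning with the same configuration
#' and seed reproduces every output byte-for-byte. With `resume = TRUE`,
#' stages whose output file already exists are skipped and their output
#' reused.
#'
#' @param config list (or path to a JSON file) with optional entries:
#'   \describe{
#'     \item{sim}{arguments for [simConfig()].}
#'     \item{acquisition}{arguments for [acquisitionConfig()].}
#'     \item{conditions, n_fractions}{passed to [simulateExperiment()].}
#'     \item{observations}{path to an existing observation TSV; replaces the
#'       simulate stage.}
#'     \item{contrast}{character(2), default `c("coculture", "mono_mix")`.}
#'     \item{rollup_mode}{`"sum_log2"` (default) or `"log2_sum"`.}
#'     \item{stages}{character subset of `c("simulate", "quantify",
#'       "normalize", "de", "cluster", "report")`; default all.}
#'     \item{cluster_k}{named list with `alga` and `bacterium` k (defaults
#'       6 and 3).}
#'     \item{figures}{write PNG figures (default TRUE).}
#'   }
#' @param outdir output directory, created if needed.
#' @param seed master seed (default 1).
#' @param resume reuse existing stage outputs (default FALSE).
#' @return invisibly, a list with the stage outputs (`sim`, `matrix`,
#'   `normalized`, `loq`, `de`, `clusters`, `report_path`) and the paths
#'   written.
#' @export
runPipeline <- function(config = list(), outdir, seed = 1L, resume = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  if (!is.null(config$observations) && !file.exists(config$observations)) {
    stop("configuration error: observations path does not exist: ",
         config$observations, call. = FALSE)
  }
  stages_all <- c("simulate", "quantify", "normalize", "de", "cluster", "report")
  stages <- if (is.null(config$stages)) stages_all else {
    match.arg(config$stages, stages_all, several.ok = TRUE)
  }
  if (!is.null(config$observations)) stages <- setdiff(stages, "simulate")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(outdir, f)
  log_msg <- function(fmt, ...) message(sprintf(paste0("[monomix] ", fmt), ...))
  skipped <- character()

  sim <- NULL; obs <- NULL; design <- NULL; map <- NULL; truth <- NULL
  contrast <- config$contrast %||% c("coculture", "mono_mix")
  rollup_mode <- config$rollup_mode %||% "sum_log2"

  ## --- simulate ---------------------------------------------------------
  if ("simulate" %in% stages) {
    if (resume && file.exists(path("peptide_obs.tsv"))) {
      log_msg("simulate: reusing %s", path("peptide_obs.tsv"))
    } else {
      t0 <- Sys.time()
      scfg <- do.call(simConfig, as.list(config$sim %||% list()))
      acq <- do.call(acquisitionConfig, as.list(config$acquisition %||% list()))
      sim <- simulateExperiment(scfg, acq,
                                conditions = config$conditions %||% .SIM_CONDITIONS,
                                n_fractions = config$n_fractions %||% 1L,
                                seed = seed)
      writePeptideObservations(sim$observations, path("peptide_obs.tsv"),
                               seed = seed, config = config)
      .writeTsv(sim$design, path("design.tsv"), seed = seed, config = config)
      .writeTsv(sim$truth, path("truth.tsv"), seed = seed, config = config)
      log_msg("simulate: %d observations, %d samples (%.1fs)",
              nrow(sim$observations), nrow(sim$design),
              as.numeric(difftime(Sys.time(), t0, units = "secs")))
    }
  }
  if (!is.null(sim)) {
    obs <- sim$observations; design <- sim$design
    map <- sim$proteome$map; truth <- sim$truth
  } else if (!is.null(config$observations)) {
    obs <- readPeptideObservations(config$observations)
    if (!is.null(config$design)) design <- .readTsv(config$design)
  } else if (file.exists(path("peptide_obs.tsv"))) {
    obs <- readPeptideObservations(path("peptide_obs.tsv"))
    if (file.exists(path("design.tsv"))) design <- .readTsv(path("design.tsv"))
    if (file.exists(path("truth.tsv"))) {
      truth <- .readTsv(path("truth.tsv"))
      truth$is_regulated <- as.logical(truth$is_regulated)
    }
  }
  if (is.null(map) && !is.null(obs)) {
    proteins <- if (!is.null(truth)) {
      data.frame(protein_id = truth$protein_id, gene_id = truth$gene_id,
                 organism = truth$organism,
                 fasta_order = seq_len(nrow(truth)), stringsAsFactors = FALSE)
    } else NULL
    map <- mapFromObservations(obs, proteins)
  }

  ## --- quantify ---------------------------------------------------------
  pqm <- NULL
  if ("quantify" %in% stages) {
    if (is.null(obs)) stop("quantify: no observations available", call. = FALSE)
    t0 <- Sys.time()
    pqm <- buildProteinMatrix(obs, map, design = design, mode = rollup_mode)
    writeProteinMatrix(pqm, path("protein_matrix.tsv"), seed = seed,
                       config = config)
    jsonlite::write_json(metadata(pqm)$filter_report,
                         path("filter_report.json"), auto_unbox = TRUE)
    log_msg("quantify: %d genes x %d samples retained (%.1fs)",
            nrow(pqm), ncol(pqm),
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  ## --- normalize --------------------------------------------------------
  npqm <- NULL; loq <- NULL
  if ("normalize" %in% stages && !is.null(pqm)) {
    npqm <- quantileNormalizeByOrganism(pqm)
    loq <- computeLoq(npqm, scope = "organism")
    writeProteinMatrix(npqm, path("normalized_matrix.tsv"), seed = seed,
                       config = config)
    log_msg("normalize: per-organism quantile normalization; LOQ %s",
            paste(sprintf("%s=%.2f", names(loq), loq), collapse = ", "))
  }

  ## --- differential expression -----------------------------------------
  de <- NULL
  if ("de" %in% stages && !is.null(npqm)) {
    cond_avail <- unique(as.character(colData(npqm)$condition))
    if (all(contrast %in% cond_avail)) {
      de <- differentialExpression(npqm, contrast = contrast, loq = loq)
      .writeTsv(de, path("de_results.tsv"), seed = seed, config = config)
      log_msg("de: %s vs %s; %d tested, %d significant (%d up, %d down)",
              contrast[1], contrast[2], sum(de$tested), sum(de$significant),
              sum(de$direction == "increased"), sum(de$direction == "decreased"))
    } else {
      skipped <- c(skipped, sprintf("de (conditions %s unavailable)",
                                    paste(setdiff(contrast, cond_avail),
                                          collapse = ",")))
    }
  } else if (!"de" %in% stages) {
    skipped <- c(skipped, "de (disabled)")
  }

  ## --- cluster ----------------------------------------------------------
  clusters <- NULL
  if ("cluster" %in% stages && !is.null(npqm)) {
    kk <- config$cluster_k %||% list(alga = 6L, bacterium = 3L)
    org_all <- as.character(rowData(npqm)$organism)
    cond_all <- as.character(colData(npqm)$condition)
    clusters <- list()
    for (o in unique(org_all)) {
      sub <- npqm[org_all == o, ]
      ## only conditions in which a real share of this organism's proteome
      ## is observed (cross-organism shared peptides can put a stray value
      ## into a foreign monoculture)
      seen <- vapply(unique(cond_all), function(cc) {
        blk <- log2Abundance(sub)[, cond_all == cc, drop = FALSE]
        mean(rowSums(!is.na(blk)) > 0L) >= 0.1
      }, logical(1))
      sub <- sub[, cond_all %in% names(seen)[seen]]
      zo <- computeZScores(sub)
      zo <- zo[stats::complete.cases(zo), , drop = FALSE]
      ko <- min(as.integer(kk[[o]] %||% 3L), max(1L, nrow(zo) - 1L))
      if (nrow(zo) >= 3L && ko >= 1L) {
        clusters[[o]] <- clusterProteins(zo, k = ko, seed = .splitSeed(seed, 999L))
      } else {
        skipped <- c(skipped, sprintf("cluster/%s (too few complete profiles)", o))
      }
    }
    if (length(clusters)) {
      cl_df <- do.call(rbind, lapply(names(clusters), function(o) {
        data.frame(gene_id = names(clusters[[o]]$cluster), organism = o,
                   cluster = as.integer(clusters[[o]]$cluster),
                   stringsAsFactors = FALSE)
      }))
      .writeTsv(cl_df, path("clusters.tsv"), seed = seed, config = config)
      log_msg("cluster: %s",
              paste(sprintf("%s k=%d", names(clusters),
                            vapply(clusters, `[[`, integer(1), "k")),
                    collapse = "; "))
    }
  } else if (!"cluster" %in% stages) {
    skipped <- c(skipped, "cluster (disabled)")
  }

  ## --- report -----------------------------------------------------------
  report_path <- NULL
  if ("report" %in% stages && !is.null(pqm)) {
    report_path <- .writeReport(outdir, pqm, npqm, loq, de, truth, contrast,
                                seed, config, skipped,
                                figures = isTRUE(config$figures %||% TRUE))
    log_msg("report: %s", report_path)
  }

  invisible(list(sim = sim, matrix = pqm, normalized = npqm, loq = loq,
                 de = de, clusters = clusters, report_path = report_path,
                 skipped = skipped, outdir = outdir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.writeReport <- function(outdir, pqm, npqm, loq, de, truth, contrast, seed,
                         config, skipped, figures = TRUE) {
  path <- file.path(outdir, "report.md")
  lines <- c(.outputHeader(seed = seed, config = config),
             "", "# Pipeline report", "")
  X <- log2Abundance(pqm)
  cond <- as.character(colData(pqm)$condition)
  org <- as.character(rowData(pqm)$organism)
  lines <- c(lines, "## Detected proteins per sample", "",
             "| sample | condition | alga | bacterium |",
             "|---|---|---|---|")
  for (j in seq_len(ncol(X))) {
    lines <- c(lines, sprintf("| %s | %s | %d | %d |",
                              colnames(X)[j],
                              if (length(cond)) cond[j] else "?",
                              sum(!is.na(X[org == "alga", j])),
                              sum(!is.na(X[org == "bacterium", j]))))
  }
  if (!is.null(npqm)) {
    lines <- c(lines, "", "## Median normalized abundance per condition", "")
    XN <- log2Abundance(npqm)
    for (o in unique(org)) {
      meds <- tapply(seq_len(ncol(XN)), cond, function(jj) {
        stats::median(XN[org == o, jj], na.rm = TRUE)
      })
      lines <- c(lines, sprintf("- %s: %s", o,
                                paste(sprintf("%s %.2f", names(meds), meds),
                                      collapse = ", ")))
    }
    lines <- c(lines, "",
               sprintf("Limit of quantitation: %s",
                       paste(sprintf("%s %.2f", names(loq), loq),
                             collapse = ", ")))
  }
  if (!is.null(de)) {
    lines <- c(lines, "", sprintf("## Differential expression: %s vs %s",
                                  contrast[1], contrast[2]), "")
    for (o in unique(de$organism)) {
      d <- de[de$organism == o, ]
      lines <- c(lines, sprintf(
        "- %s: %d tested, %d significant (%d increased, %d decreased)",
        o, sum(d$tested), sum(d$significant),
        sum(d$direction == "increased"), sum(d$direction == "decreased")))
    }
    if (!is.null(truth) && any(truth$is_regulated)) {
      reg <- truth$gene_id[truth$is_regulated]
      called <- de$gene_id[de$significant]
      tp <- sum(called %in% reg)
      lines <- c(lines, "",
                 sprintf("Ground truth: %d regulated; recovered %d; false positives %d.",
                         length(reg), tp, length(called) - tp))
    } else if (!is.null(truth)) {
      lines <- c(lines,
                 sprintf("Ground truth: no regulated proteins; all %d significant calls are false positives.",
                         sum(de$significant)))
    }
    if (figures) {
      fp <- file.path(outdir, "volcano.png")
      d <- de[de$tested, ]
      gp <- ggplot2::ggplot(d, ggplot2::aes(x = log2_fc,
                                            y = -log10(p_adj),
                                            colour = direction)) +
        ggplot2::geom_point(size = 0.8) +
        ggplot2::facet_wrap(~organism, scales = "free") +
        ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p") +
        ggplot2::theme_minimal()
      suppressWarnings(ggplot2::ggsave(fp, gp, width = 7, height = 3.5, dpi = 120))
      lines <- c(lines, "", "![volcano](volcano.png)")
    }
  }
  if (figures && !is.null(npqm)) {
    fp <- file.path(outdir, "abundance_hist.png")
    XN <- log2Abundance(npqm)
    df <- data.frame(value = as.numeric(XN),
                     organism = rep(org, ncol(XN)),
                     condition = rep(if (length(cond)) cond else colnames(XN),
                                     each = nrow(XN)))
    df <- df[!is.na(df$value), ]
    gp <- ggplot2::ggplot(df, ggplot2::aes(x = value, fill = condition)) +
      ggplot2::geom_histogram(alpha = 0.5, position = "identity", bins = 40) +
      ggplot2::facet_wrap(~organism, scales = "free") +
      ggplot2::labs(x = "normalized log2 abundance") +
      ggplot2::theme_minimal()
    suppressWarnings(ggplot2::ggsave(fp, gp, width = 7, height = 3.5, dpi = 120))
    lines <- c(lines, "", "![abundance](abundance_hist.png)")
  }
  if (length(skipped)) {
    lines <- c(lines, "", "## Skipped stages", "",
               paste("-", skipped))
  }
  writeLines(lines, path)
  path
}
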