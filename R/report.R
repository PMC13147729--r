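# Pipeline orchestration: run every analysis stage from one configuration,
# write all report tables and plot-ready CSVs, and record a run manifest.

#' Build a pipeline configuration
#'
#' A run takes its data either from fixture files (`input`) or from the
#' synthetic generator (`synthetic`); exactly one must be given.
#'
#' @param input named list of file paths for [load_dataset()]
#'   (`beta_path`, `covariate_path`, `annotation_path`, and optional
#'   `icr_path`, `imprinted_path`, `gene_list_paths`, `truth_path`).
#' @param synthetic a [generator_config()] (or argument list for one).
#' @param outdir output directory.
#' @param alpha FDR threshold in (0, 1).
#' @param k_top per-subgroup top-list size.
#' @param magnitude_threshold strict |delta-M| cutoff for the
#'   high-magnitude flag.
#' @param filter probe-filter switches (see [run_ewas()]).
#' @param formula regression formula.
#' @param sensitivity character vector of sensitivity scenarios to rerun
#'   (see [sensitivity_rerun()]).
#' @param external_list_names names of `gene_lists` entries that count as
#'   external studies for the `co` indicator and overlap counting.
#' @param asd_list_name,pseudogene_list_name names of `gene_lists` entries
#'   holding the disease gene list and the pseudogene exclusion list.
#' @param seed seed for a synthetic run (overrides the generator's).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL, outdir = tempfile("spermage_run_"),
                            alpha = 0.05, k_top = 30, magnitude_threshold = 0.1,
                            filter = list(detection = TRUE, snp = FALSE,
                                          crossreactive = FALSE),
                            formula = ~ age + bmi + patient,
                            sensitivity = character(),
                            external_list_names = NULL,
                            asd_list_name = "asd_genes",
                            pseudogene_list_name = "pseudogenes",
                            seed = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop2("`alpha` must lie in (0, 1)")
  }
  if (is.null(input) == is.null(synthetic)) {
    stop2("exactly one of `input` and `synthetic` must be given")
  }
  if (!is.null(synthetic)) {
    if (!inherits(synthetic, "generator_config")) {
      synthetic <- do.call(generator_config, as.list(synthetic))
    }
    if (!is.null(seed)) synthetic$seed <- as.integer(seed)
  }
  structure(list(input = input, synthetic = synthetic, outdir = outdir,
                 alpha = alpha, k_top = assert_count(k_top, "k_top"),
                 magnitude_threshold = magnitude_threshold, filter = filter,
                 formula = formula, sensitivity = sensitivity,
                 external_list_names = external_list_names,
                 asd_list_name = asd_list_name,
                 pseudogene_list_name = pseudogene_list_name,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()]; a `synthetic:` block holds [generator_config()]
#'   arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$formula)) y$formula <- stats::as.formula(y$formula)
  do.call(pipeline_config, y)
}

log_stage <- function(con, msg) {
  message(format(Sys.time(), "%H:%M:%S "), msg)
  if (!is.null(con)) writeLines(msg, con)  # log file kept timestamp-free so
                                           # identical runs are byte-identical
}

write_report_csv <- function(df, path, signif_digits = 4) {
  full <- sub("\\.csv$", "_full.csv", path)
  utils::write.csv(df, full, row.names = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, signif_digits))
  utils::write.csv(df, path, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (load or simulate), global
#' methylation tests, the per-CpG EWAS, subgroup summary, top-list
#' selection, genomic-context cross-tabs, imprinted-gene and ICR mapping,
#' cross-study overlap counting, score cards, biomarker selection, plot
#' tables, optional sensitivity reruns, and a run manifest. All outputs are
#' CSV (plus `manifest.json` and `run.log`) in `config$outdir`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a `report_bundle` list with every intermediate table.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop2("`config` must be a pipeline_config")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file(file.path(config$outdir, "run.log"), open = "wt")
  on.exit(close(logfile), add = TRUE)
  stage <- "setup"
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      stop2("pipeline stage `", name, "` failed: ", conditionMessage(e))
    })
  }

  dataset <- run_stage("data", {
    if (!is.null(config$synthetic)) {
      log_stage(logfile, sprintf("stage data: simulating %d probes x %d subjects",
                                 config$synthetic$n_probes, config$synthetic$n_subjects))
      simulate_dataset(config$synthetic)
    } else {
      log_stage(logfile, "stage data: loading fixture files")
      do.call(load_dataset, config$input)
    }
  })

  global <- run_stage("global_tests", {
    log_stage(logfile, "stage global_tests")
    global_methylation_tests(dataset$beta, dataset$covariates)
  })

  fits <- run_stage("ewas", {
    log_stage(logfile, "stage ewas")
    run_ewas(dataset, formula = config$formula, alpha = config$alpha,
             filter = config$filter)
  })
  dmcs <- fits[fits$significant, , drop = FALSE]
  log_stage(logfile, sprintf("  %d probes, %d DMCs at FDR < %g",
                             nrow(fits), nrow(dmcs), config$alpha))

  subgroup_summary <- run_stage("subgroups", summarize_dmcs(fits, alpha = config$alpha))
  top <- run_stage("top_lists", {
    log_stage(logfile, "stage top_lists")
    suppressWarnings(select_top(fits, k = config$k_top,
                                magnitude_threshold = config$magnitude_threshold))
  })
  crosstabs <- run_stage("genomic_allocation", {
    log_stage(logfile, "stage genomic_allocation")
    crosstab_genomic(fits, dataset$annotation)
  })

  gene_map <- icr_map <- poo <- NULL
  if (!is.null(dataset$imprinted)) {
    gene_map <- run_stage("imprinted_genes", {
      log_stage(logfile, "stage imprinted_genes")
      map_genes(dmcs, dataset$annotation, dataset$imprinted)
    })
  }
  if (!is.null(dataset$icrs)) {
    icr_map <- run_stage("icr_mapping", {
      log_stage(logfile, "stage icr_mapping")
      map_icrs(dmcs, dataset$annotation, dataset$icrs)
    })
  }
  if (!is.null(gene_map) || !is.null(icr_map)) {
    poo <- run_stage("parent_of_origin", parent_of_origin_summary(
      gene_hits = gene_map$hits, icr_hits = icr_map$hits))
  }

  lists <- dataset$gene_lists %||% list()
  ext_names <- config$external_list_names %||%
    grep("^study", names(lists), value = TRUE)
  external <- lists[intersect(ext_names, names(lists))]
  overlaps <- NULL
  if (length(external) >= 2) {
    overlaps <- run_stage("cross_study", {
      log_stage(logfile, "stage cross_study")
      overlap_counts(external)
    })
  }

  scorecards <- biomarkers <- NULL
  if (!is.null(gene_map) && nrow(gene_map$hits) > 0) {
    scorecards <- run_stage("scorecards", {
      log_stage(logfile, "stage scorecards")
      build_scorecards(dmcs, dataset$annotation, icr_hits = icr_map$hits,
                       top_probes = top$probe_id, external_lists = external,
                       genes = unique(gene_map$hits$gene),
                       magnitude_threshold = config$magnitude_threshold)
    })
    asd <- lists[[config$asd_list_name]]
    if (!is.null(asd)) {
      biomarkers <- run_stage("biomarker_selection", {
        log_stage(logfile, "stage biomarker_selection")
        select_biomarkers(scorecards, asd_genes = asd,
                          pseudogenes = lists[[config$pseudogene_list_name]] %||%
                            character())
      })
    }
  }

  plot_paths <- run_stage("plot_tables", {
    log_stage(logfile, "stage plot_tables")
    export_plot_tables(fits, dataset$annotation,
                       imprinted_genes = dataset$imprinted$gene,
                       outdir = config$outdir, alpha = config$alpha)
  })

  sens <- list()
  for (sc in config$sensitivity) {
    sens[[sc]] <- run_stage(paste0("sensitivity_", sc), {
      log_stage(logfile, paste("stage sensitivity:", sc))
      sensitivity_rerun(dataset, sc, main = fits, formula = config$formula,
                        alpha = config$alpha, filter = config$filter)
    })
  }

  run_stage("write_outputs", {
    log_stage(logfile, "stage write_outputs")
    out <- config$outdir
    write_report_csv(data.frame(fits), file.path(out, "moderated_fits.csv"))
    utils::write.csv(subgroup_summary, file.path(out, "subgroup_summary.csv"),
                     row.names = FALSE)
    top_out <- data.frame(
      subgroup = top$subgroup, probe_id = top$probe_id,
      delta_m = signif(top$slope_m_per_year, 4),
      mean_m = signif(top$mean_m, 4), p_adj = signif(top$p_adj, 4),
      mean_beta = signif(top$mean_beta, 4),
      delta_beta = signif(top$delta_beta, 4),
      gene = dataset$annotation$genes[match(top$probe_id,
                                            dataset$annotation$probe_id)],
      chr = dataset$annotation$chr[match(top$probe_id,
                                         dataset$annotation$probe_id)],
      location = dataset$annotation$pos[match(top$probe_id,
                                              dataset$annotation$probe_id)],
      high_magnitude = top$high_magnitude)
    utils::write.csv(top_out, file.path(out, "top_table.csv"), row.names = FALSE)
    utils::write.csv(global$tests, file.path(out, "global_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(crosstabs$island, file.path(out, "island_crosstab.csv"),
                     row.names = FALSE)
    utils::write.csv(crosstabs$functional,
                     file.path(out, "functional_crosstab.csv"), row.names = FALSE)
    if (!is.null(gene_map)) {
      utils::write.csv(gene_map$summary, file.path(out, "imprinted_summary.csv"),
                       row.names = FALSE)
    }
    if (!is.null(icr_map)) {
      utils::write.csv(icr_map$summary, file.path(out, "icr_summary.csv"),
                       row.names = FALSE)
    }
    if (!is.null(overlaps)) {
      utils::write.csv(overlaps$at_least, file.path(out, "overlap_counts.csv"),
                       row.names = FALSE)
    }
    if (!is.null(scorecards)) {
      utils::write.csv(scorecards, file.path(out, "scorecards.csv"),
                       row.names = FALSE)
    }
    if (!is.null(biomarkers)) {
      utils::write.csv(biomarkers, file.path(out, "biomarkers.csv"),
                       row.names = FALSE)
    }
    cfg_json <- jsonlite::toJSON(
      list(alpha = config$alpha, k_top = config$k_top,
           magnitude_threshold = config$magnitude_threshold,
           filter = config$filter,
           formula = deparse(config$formula),
           seed = config$synthetic$seed %||% config$seed,
           synthetic = !is.null(config$synthetic)),
      auto_unbox = TRUE)
    jsonlite::write_json(
      list(config = jsonlite::fromJSON(cfg_json),
           config_hash = sum(utf8ToInt(as.character(cfg_json))),
           n_probes = nrow(fits), n_dmcs = nrow(dmcs),
           package_version = as.character(utils::packageVersion("spermage")),
           r_version = paste(R.version$major, R.version$minor, sep = ".")),
      file.path(out, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  })

  invisible(structure(
    list(dataset = dataset, global = global, fits = fits,
         subgroup_summary = subgroup_summary, top = top, crosstabs = crosstabs,
         gene_map = gene_map, icr_map = icr_map, parent_of_origin = poo,
         overlaps = overlaps, scorecards = scorecards, biomarkers = biomarkers,
         sensitivity = sens, outdir = config$outdir),
    class = "report_bundle"))
}

#' Export volcano- and Miami-plot tables
#'
#' Writes `volcano.csv` (`probe_id`, `delta_beta`, `neg_log10_p_adj`,
#' `significant`, `highlight_gene`) and `miami.csv` (`chr`, `pos`,
#' `delta_beta`, `direction`, `imprinted_flag`; chromosomes ordered
#' 1..22, X) for downstream plotting.
#'
#' @param fits a `moderated_fit_table` carrying `delta_beta`.
#' @param annotation probe annotation.
#' @param imprinted_genes character vector of imprinted gene symbols used
#'   for highlighting (optional).
#' @param outdir output directory.
#' @param alpha FDR threshold used for the `significant` column.
#' @return invisibly, the two file paths.
#' @export
export_plot_tables <- function(fits, annotation, imprinted_genes = NULL,
                               outdir, alpha = 0.05) {
  if (is.null(fits$delta_beta)) stop2("`fits` must carry a `delta_beta` column")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  idx <- match(fits$probe_id, annotation$probe_id)
  imprinted_genes <- norm_genes(imprinted_genes %||% character())

  probe_imprinted_gene <- rep("", nrow(fits))
  if (length(imprinted_genes) && nrow(fits)) {
    long <- explode_genes(fits$probe_id, annotation$genes[idx])
    long <- long[long$gene %in% imprinted_genes, , drop = FALSE]
    first <- long[!duplicated(long$probe_id), , drop = FALSE]
    probe_imprinted_gene[match(first$probe_id, fits$probe_id)] <- first$gene
  }

  volcano <- data.frame(
    probe_id = fits$probe_id,
    delta_beta = fits$delta_beta,
    neg_log10_p_adj = -log10(pmax(fits$p_adj, .Machine$double.xmin)),
    significant = fits$p_adj < alpha,
    highlight_gene = probe_imprinted_gene,
    stringsAsFactors = FALSE
  )
  volcano_path <- file.path(outdir, "volcano.csv")
  utils::write.csv(volcano, volcano_path, row.names = FALSE)

  chr_levels <- c(as.character(1:22), "X")
  miami <- data.frame(
    chr = as.character(annotation$chr[idx]),
    pos = annotation$pos[idx],
    delta_beta = fits$delta_beta,
    direction = ifelse(fits$delta_beta >= 0, "hyper", "hypo"),
    imprinted_flag = as.integer(nzchar(probe_imprinted_gene)),
    stringsAsFactors = FALSE
  )
  miami <- miami[as.logical(fits$significant), , drop = FALSE]
  miami <- miami[order(match(miami$chr, chr_levels), miami$pos), , drop = FALSE]
  miami_path <- file.path(outdir, "miami.csv")
  utils::write.csv(miami, miami_path, row.names = FALSE)

  invisible(c(volcano = volcano_path, miami = miami_path))
}
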