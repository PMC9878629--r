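# Orchestration: run the full diversity analysis over a set of libraries
# from a single configuration and emit the report bundle.

#' Default run configuration
#'
#' @param libraries list of library entries, each a list with `name`,
#'   `path`, `format` (`"smiles"`/`"sdf"`).
#' @param outdir output directory.
#' @param level scaffold level (default `"GNB"`).
#' @param sse_n top-n grid for the scaled Shannon entropy table.
#' @param seed top-level seed fanned out to every stochastic stage.
#' @param max_molecules optional per-library subsample cap for the distance
#'   stage.
#' @param auc_threshold CDP y-axis threshold.
#' @param embedding_features `"properties"` or `"fingerprints"`.
#' @param gtm list of GTM settings passed to [fit_gtm()].
#' @param plot_format `"pdf"` or `"png"`.
#' @return a `RunConfig` list.
#' @export
run_config <- function(libraries, outdir,
                       level = "GNB",
                       sse_n = c(5, 10, 20, 30, 40, 50, 60, 70),
                       seed = 1L,
                       max_molecules = NULL,
                       auc_threshold = 0.75,
                       embedding_features = c("properties", "fingerprints"),
                       gtm = list(),
                       plot_format = c("pdf", "png")) {
  structure(
    list(libraries = libraries, outdir = outdir, level = level,
         sse_n = sse_n, seed = as.integer(seed),
         max_molecules = max_molecules, auc_threshold = auc_threshold,
         embedding_features = match.arg(embedding_features),
         gtm = gtm, plot_format = match.arg(plot_format)),
    class = "RunConfig")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; `libraries` is a
#' sequence of `name`/`path`/`format` mappings.
#'
#' @param path YAML file path.
#' @return a `RunConfig`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$libraries) || !length(y$libraries))
    stop("config must list at least one library")
  do.call(run_config, c(
    list(libraries = y$libraries, outdir = y$outdir %||% "scafdiv_report"),
    y[setdiff(names(y), c("libraries", "outdir"))]))
}

#' @noRd
save_plot <- function(p, path, format, width = 7, height = 6) {
  if (format == "png") {
    grDevices::png(paste0(path, ".png"), width = width * 100,
                   height = height * 100, res = 100)
  } else {
    grDevices::pdf(paste0(path, ".pdf"), width = width, height = height)
  }
  on.exit(grDevices::dev.off())
  print(p)
}

#' @noRd
stage <- function(tag, code) {
  tryCatch(code, error = function(e) {
    stop(sprintf("[stage: %s] %s", tag, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full diversity report
#'
#' Executes the complete pipeline for every configured library: cleaning,
#' scaffold census, CSR/SSE diversity metrics, MACCS- and property-based
#' inter-/intra-library distances, the consensus diversity plot, and 2D
#' embeddings (PCA and GTM), writing all tables (CSV/TSV), plots, and a
#' run log into `config$outdir`. Stages requiring at least two libraries
#' (distances, CDP) are skipped with a notice for single-library runs.
#' Re-running with the same configuration and seed reproduces every table
#' byte for byte.
#'
#' @param config a [run_config()] or path to a YAML file for
#'   [read_run_config()].
#' @return (invisibly) a list with all in-memory results: `libraries`,
#'   `cleaning_reports`, `scaffold_counts`, `summary`, `sse`, `csr`,
#'   `distances`, `cdp`, `embeddings`, `paths`.
#' @export
run_full_report <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "RunConfig"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fmt <- config$plot_format
  log_lines <- c(sprintf("scafdiv %s run log", utils::packageVersion("scafdiv")),
                 sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("seed: %d", config$seed),
                 sprintf("scaffold level: %s", config$level),
                 sprintf("sse n grid: %s", paste(config$sse_n, collapse = ",")),
                 sprintf("distance subsample cap: %s",
                         config$max_molecules %||% "none (exact)"),
                 sprintf("cdp auc threshold: %s", config$auc_threshold),
                 sprintf("embedding features: %s", config$embedding_features),
                 "cleaning: stereo stripped, largest fragment kept, first duplicate kept",
                 "property standardization: z-scores pooled over all libraries",
                 "all-zero fingerprint pairs: Soergel distance 0",
                 "csr ties: lexicographic scaffold key; p50: linear interpolation")

  # --- stage 1: read + clean -------------------------------------------
  libs <- list()
  reports <- list()
  stage("library_io", {
    for (entry in config$libraries) {
      raw <- read_library(entry$path, entry$format %||% "smiles",
                          entry$name %||% NULL)
      cleaned <- clean_and_deduplicate(raw)
      libs[[cleaned$library$name]] <- cleaned$library
      reports[[cleaned$library$name]] <- cleaned$report
      write_smiles_library(cleaned$library,
                           file.path(outdir, paste0(cleaned$library$name,
                                                    "_cleaned.smi")))
      log_lines <- c(log_lines, sprintf(
        "library %s: input %d, unparseable %d, duplicates %d, kept %d",
        cleaned$library$name, cleaned$report$n_input,
        cleaned$report$n_unparseable, cleaned$report$n_duplicates_removed,
        cleaned$report$n_output))
    }
  })

  # --- stage 2: scaffold census + diversity metrics --------------------
  counts <- list()
  curves <- list()
  stage("scaffolds", {
    for (nm in names(libs)) {
      counts[[nm]] <- scaffold_counts(libs[[nm]], config$level)
      write_scaffold_table(counts[[nm]],
                           file.path(outdir, paste0(nm, "_scaffolds.tsv")))
    }
  })
  stage("scaffold_diversity", {
    summary_df <- do.call(rbind, lapply(counts, diversity_summary))
    utils::write.csv(summary_df, file.path(outdir, "diversity_summary.csv"),
                     row.names = FALSE)
    sse_df <- do.call(rbind, lapply(names(counts), function(nm) {
      prof <- sse_profile(counts[[nm]], config$sse_n)
      cbind(library = nm, prof)
    }))
    utils::write.csv(sse_df, file.path(outdir, "sse_profiles.csv"),
                     row.names = FALSE)
    for (nm in names(counts)) {
      curves[[nm]] <- csr_curve(counts[[nm]])
      utils::write.table(curves[[nm]]$points,
                         file.path(outdir, paste0(nm, "_csr.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      save_plot(plot_scaffold_frequencies(counts[[nm]]),
                file.path(outdir, paste0(nm, "_top_scaffolds")), fmt)
    }
    save_plot(plot_csr(curves), file.path(outdir, "csr_curves"), fmt)
  })
  summary_df <- do.call(rbind, lapply(counts, diversity_summary))

  # --- stage 3: descriptors + distances --------------------------------
  fps <- list()
  props <- list()
  stage("chem_descriptors", {
    for (nm in names(libs)) {
      smi <- stats::setNames(libs[[nm]]$records$smiles, libs[[nm]]$records$id)
      fps[[nm]] <- maccs_fingerprint(smi)
      props[[nm]] <- property_matrix(libs[[nm]])
    }
  })

  distances <- NULL
  cdp <- NULL
  if (length(libs) >= 2) {
    stage("library_distances", {
      dm_s <- distance_matrix(fps, "soergel_maccs",
                              max_molecules = config$max_molecules,
                              seed = config$seed)
      dm_e <- distance_matrix(props, "euclid_props",
                              max_molecules = config$max_molecules,
                              seed = config$seed + 1000L)
      write_distance_matrix(dm_s, file.path(outdir, "distance_soergel.csv"))
      write_distance_matrix(dm_e, file.path(outdir, "distance_euclid.csv"))
      save_plot(plot_thp(dm_s), file.path(outdir, "thp_soergel"), fmt)
      save_plot(plot_thp(dm_e), file.path(outdir, "thp_euclid"), fmt)
      distances <- list(soergel_maccs = dm_s, euclid_props = dm_e)
    })
    stage("global_diversity", {
      cdp_in <- data.frame(
        library = names(libs),
        intra_soergel = diag(distances$soergel_maccs$matrix),
        auc = summary_df$AUC[match(names(libs), summary_df$library)],
        intra_euclid = diag(distances$euclid_props$matrix),
        M = summary_df$M[match(names(libs), summary_df$library)])
      cdp <- assemble_cdp(cdp_in, config$auc_threshold)
      write_cdp(cdp, file.path(outdir, "cdp.csv"))
      save_plot(plot_cdp(cdp), file.path(outdir, "cdp"), fmt)
    })
  } else {
    message("single library: distance matrix and CDP stages skipped (need >= 2)")
    log_lines <- c(log_lines,
                   "notice: distance/CDP stages skipped (single library)")
  }

  # --- stage 4: embeddings ---------------------------------------------
  embeddings <- list()
  stage("chem_embedding", {
    feats <- if (config$embedding_features == "fingerprints") fps else props
    pooled <- do.call(rbind, feats)
    labels <- rep(names(feats), vapply(feats, nrow, integer(1)))
    scale_feats <- config$embedding_features == "properties"
    embeddings$pca <- fit_pca(pooled, labels, scale. = scale_feats)
    gtm_args <- c(list(data = if (scale_feats)
      apply_scale(pooled, pooled_scale_params(list(pooled))) else pooled,
      labels = labels, seed = config$seed), config$gtm)
    embeddings$gtm <- do.call(fit_gtm, gtm_args)
    write_embedding(embeddings$pca, file.path(outdir, "embedding_pca.csv"))
    write_embedding(embeddings$gtm, file.path(outdir, "embedding_gtm.csv"))
    save_plot(plot_embedding(embeddings$pca),
              file.path(outdir, "embedding_pca"), fmt)
    save_plot(plot_embedding(embeddings$gtm),
              file.path(outdir, "embedding_gtm"), fmt)
    log_lines <- c(log_lines, sprintf(
      "gtm: grid %s, rbf %s, width factor %s, regularization %s, max_iter %s",
      config$gtm$grid_size %||% 16, config$gtm$rbf_grid %||% 4,
      config$gtm$rbf_width_factor %||% 0.3,
      config$gtm$regularization %||% 0.1, config$gtm$max_iter %||% 200))
  })

  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(list(libraries = libs, cleaning_reports = reports,
                 scaffold_counts = counts, summary = summary_df,
                 csr = curves, distances = distances, cdp = cdp,
                 embeddings = embeddings, outdir = outdir))
}
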