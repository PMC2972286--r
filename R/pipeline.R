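#' Run the full pathway-survival pipeline from a config
#'
#' Orchestrates simulate (or load) -> align -> clinical model selection ->
#' per-gene scan -> gene-set analysis -> PRI stratification -> cross-study
#' comparison, writing every stage's table as TSV under `out_dir` plus a
#' deterministic `manifest.json` (package version, seed, per-stage row
#' counts, output checksums). A rerun with the same config and seed
#' reproduces all outputs byte-identically. A stage failure halts the run
#' with the stage name; completed-stage outputs are left on disk.
#'
#' Config (YAML file or list) fields:
#' \describe{
#'   \item{simulation}{list of [simulation_spec()] arguments, or}
#'   \item{studies}{named list of directories readable by [read_study()]}
#'   \item{gmt}{path to a GMT file (required with `studies`; optional with
#'     `simulation`, which otherwise writes its own generated database)}
#'   \item{model_specs}{character subset of the [scan_genes()] specs
#'     (default all four)}
#'   \item{q}{gene FDR level (default 0.2)}
#'   \item{gsa}{list of [gsa_config()] arguments (defaults: B = 1000,
#'     R = 1000, sizes 15-250, alpha = 0.2, u = 5)}
#'   \item{clinical_candidates}{candidate variables for AIC/BIC selection
#'     (default er_status, tumor_size, grade, age, as available)}
#'   \item{cohorts}{named list of cohort filters for PRI stratification
#'     (default: `er_positive = list(er_status = "positive")`)}
#'   \item{pri_pathways}{pathway names to stratify (default: gFWER-rejected
#'     pathways per study)}
#' }
#'
#' @param config path to a YAML config or an equivalent list.
#' @param out_dir output directory.
#' @param seed integer seed overriding the config's.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) {
    .assert(file.exists(config), "config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  .assert(is.list(config), "config must be a list or a YAML path")
  .assert(!is.null(config$simulation) || !is.null(config$studies),
          "config needs either 'simulation' or 'studies'")
  if (!is.null(config$studies)) {
    .assert(!is.null(config$gmt), "config with 'studies' needs a 'gmt' path")
    for (d in unlist(config$studies))
      .assert(dir.exists(d), "study directory not found: ", d)
  }
  if (!is.null(config$gmt))
    .assert(file.exists(config$gmt), "gmt file not found: ", config$gmt)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "pathsurv",
                   version = as.character(packageVersion("pathsurv")),
                   seed = seed, stages = list())
  logf <- file.path(out_dir, "run.log")
  cat(sprintf("pathsurv pipeline, seed %d\n", seed), file = logf)
  note <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # -- simulate / load ------------------------------------------------------
  studies <- db <- NULL
  stage("input", {
    if (!is.null(config$simulation)) {
      spec <- do.call(simulation_spec, c(config$simulation, list(seed = seed)))
      sim <- generate_multistudy(spec)
      studies <- sim$studies
      db <- if (!is.null(config$gmt)) read_gmt(config$gmt) else sim$db
      for (nm in names(studies))
        write_study(studies[[nm]], file.path(out_dir, "studies", nm))
      write_gmt(db, file.path(out_dir, "pathways.gmt"))
    } else {
      dirs <- config$studies
      studies <- lapply(dirs, read_study)
      names(studies) <- names(dirs) %||% basename(unlist(dirs))
      db <- read_gmt(config$gmt)
    }
    note("input: %d studies, %d pathways", length(studies),
         length(db$pathways))
  })
  manifest$stages$input <- list(n_studies = length(studies),
                                n_pathways = length(db$pathways))

  q <- config$q %||% 0.2
  model_specs <- config$model_specs %||%
    c("univariate", "er_size", "aic_best", "bic_best")
  gsa_args <- config$gsa %||% list()
  cohorts <- config$cohorts %||% list(er_positive = list(er_status = "positive"))

  scan_tables <- list(); gsa_tables <- list(); clin_models <- list()
  for (nm in names(studies)) {
    st <- studies[[nm]]
    cand <- config$clinical_candidates %||%
      intersect(c("er_status", "tumor_size", "grade", "age"),
                names(st$clinical))
    cand <- cand[vapply(cand, function(v) any(!is.na(st$clinical[[v]])),
                        logical(1))]

    stage("clinical_model", {
      cm <- lapply(c(AIC = "AIC", BIC = "BIC"), function(cr)
        select_clinical_model(st, cand, criterion = cr))
      clin_models[[nm]] <- cm
      tab <- do.call(rbind, lapply(names(cm), function(cr)
        data.frame(criterion = cr,
                   variables = paste(cm[[cr]]$variables, collapse = "+"),
                   criterion_value = cm[[cr]]$criterion_value,
                   n_events = cm[[cr]]$n_events)))
      write.table(tab, file.path(out_dir, paste0(nm, "_clinical_models.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    })

    stage("gene_scan", {
      tabs <- lapply(model_specs, function(sp) {
        cmod <- switch(sp, aic_best = clin_models[[nm]]$AIC,
                       bic_best = clin_models[[nm]]$BIC, NULL)
        scan_genes(st, sp, clinical_model = cmod, q = q)
      })
      tabs <- Filter(Negate(is.null), tabs)
      scan_tables[[nm]] <- tabs
      write.table(do.call(rbind, tabs),
                  file.path(out_dir, paste0(nm, "_gene_scan.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(count_significant(tabs),
                  file.path(out_dir, paste0(nm, "_gene_counts.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    })

    stage("gsa", {
      covs <- intersect(c("er_status", "tumor_size"), names(st$clinical))
      covs <- covs[vapply(covs, function(v) any(!is.na(st$clinical[[v]])),
                          logical(1))]
      cfg <- do.call(gsa_config, c(gsa_args,
                                   list(seed = seed, covariates = covs)))
      res <- restandardized_pathway_test(st, db, cfg)
      gsa_tables[[nm]] <- res
      write.table(res, file.path(out_dir, paste0(nm, "_gsa.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      note("gsa %s: %d pathways tested, %d rejected", nm, nrow(res),
           sum(res$gfwer_reject))
    })

    stage("pri", {
      pw <- config$pri_pathways %||%
        gsa_tables[[nm]]$pathway[gsa_tables[[nm]]$gfwer_reject]
      rows <- list()
      for (p in pw) for (co in names(cohorts)) {
        ps <- tryCatch(cohort_stratified_survival(
          st, db$pathways[[p]], cohorts[[co]], pathway_name = p),
          error = function(e) NULL)
        if (is.null(ps)) next
        rows[[length(rows) + 1]] <- data.frame(
          pathway = p, cohort = co, n = ps$n, n_events = ps$n_events,
          degenerate = ps$degenerate, log_hr_high = ps$coef_high,
          wald_p = ps$wald_p, logrank_p = ps$logrank_p)
      }
      if (length(rows))
        write.table(do.call(rbind, rows),
                    file.path(out_dir, paste0(nm, "_pri.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    })
    manifest$stages[[nm]] <- list(
      genes_scanned = nrow(st$expression),
      pathways_tested = nrow(gsa_tables[[nm]]),
      pathways_rejected = sum(gsa_tables[[nm]]$gfwer_reject))
  }

  stage("comparative", {
    if (length(studies) >= 2) {
      ct <- build_cross_table(gsa_tables, "pathway")
      write.table(ct, file.path(out_dir, "cross_pathways.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      oc <- overlap_counts(lapply(gsa_tables, function(tb)
        tb$pathway[tb$gfwer_reject]))
      write.table(oc$patterns, file.path(out_dir, "pathway_overlap.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$stages$comparative <- list(items = nrow(ct))
    }
  })

  outs <- setdiff(list.files(out_dir, recursive = TRUE),
                  c("run.log", "manifest.json"))
  manifest$checksums <- as.list(tools::md5sum(file.path(out_dir, outs)))
  names(manifest$checksums) <- outs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
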