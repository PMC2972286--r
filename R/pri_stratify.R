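#' Pathway risk index (PRI)
#'
#' For subject j and a pathway with genes i = 1..G, the PRI is the number
#' of pathway genes whose expression in subject j strictly exceeds that
#' gene's sample mean taken over *all* subjects in the study:
#' `PRI(j) = sum_i I(x_ij > mean_i)`. A scalar readout of pathway activity:
#' high PRI means most pathway genes are expressed above their study-wide
#' mean. Integer-valued in `[0, G]`.
#'
#' @param study [expression_study()].
#' @param pathway_genes character vector of member gene identifiers (is
#'   intersected with the study's genes; empty intersection is an error).
#' @return named integer vector, one PRI per subject.
#' @export
compute_pri <- function(study, pathway_genes) {
  .assert(inherits(study, "expression_study"), "study must be an expression_study")
  genes <- intersect(pathway_genes, rownames(study$expression))
  .assert(length(genes) > 0, "pathway has no genes in this study")
  sub <- study$expression[genes, , drop = FALSE]
  xbar <- rowMeans(sub)
  pri <- colSums(sub > xbar)
  storage.mode(pri) <- "integer"
  pri
}

#' Median split of PRI values into low/high strata
#'
#' Subjects at or below the cohort median PRI are labelled `low`, those
#' strictly above it `high` (values equal to the median go to `low`, a
#' deterministic tie rule that keeps integer-valued strata close in size).
#' If every subject has the same PRI the split is degenerate and no test
#' should be run.
#'
#' @param pri_values numeric/integer vector, length >= 2.
#' @return factor with levels `low`, `high`; attributes `median` and
#'   `degenerate`.
#' @export
stratify_median <- function(pri_values) {
  .assert(length(pri_values) >= 2, "need at least 2 subjects to stratify")
  med <- median(pri_values)
  degenerate <- length(unique(pri_values)) == 1
  f <- factor(ifelse(pri_values <= med, "low", "high"),
              levels = c("low", "high"))
  attr(f, "median") <- med
  attr(f, "degenerate") <- degenerate
  f
}

# evaluate a cohort filter against a clinical table -> logical
.cohort_keep <- function(clinical, cohort_filter) {
  if (is.null(cohort_filter)) return(rep(TRUE, nrow(clinical)))
  if (is.function(cohort_filter)) return(cohort_filter(clinical))
  if (is.logical(cohort_filter)) return(cohort_filter)
  .assert(is.list(cohort_filter) && !is.null(names(cohort_filter)),
          "cohort_filter must be NULL, a named list, a logical vector or a function")
  keep <- rep(TRUE, nrow(clinical))
  for (nm in names(cohort_filter))
    keep <- keep & !is.na(clinical[[nm]]) &
      clinical[[nm]] == cohort_filter[[nm]]
  keep
}

#' PRI-stratified survival within a clinical cohort
#'
#' Computes the PRI against the full study's per-gene means, restricts to
#' the requested cohort (e.g. ER-positive patients, or one tumor grade),
#' median-splits the cohort's PRI values into low/high strata, and tests
#' survival separation with a single-covariate Cox Wald test on the
#' high-PRI indicator (log-rank reported alongside). Kaplan-Meier curves
#' are returned per stratum.
#'
#' @param study [expression_study()].
#' @param pathway_genes member gene identifiers.
#' @param cohort_filter NULL (whole study), a named list of clinical
#'   equality conditions such as `list(er_status = "positive")`, a logical
#'   vector, or a function of the clinical table.
#' @param pathway_name label carried into the result.
#' @param min_subjects,min_events cohort-size guards (defaults 10 and 2).
#' @return object of class `pri_strata`: per-subject `pri` and `stratum`,
#'   `wald_p`, `coef_high` (log hazard ratio high vs low), `logrank_p`,
#'   `km` (list of two [km_estimate()] curves), cohort description and
#'   counts. If every cohort PRI is identical the result is flagged
#'   `degenerate` and no test is performed.
#' @export
cohort_stratified_survival <- function(study, pathway_genes,
                                       cohort_filter = NULL,
                                       pathway_name = "pathway",
                                       min_subjects = 10L, min_events = 2L) {
  pri_all <- compute_pri(study, pathway_genes)
  keep <- .cohort_keep(study$clinical, cohort_filter)
  clin <- study$clinical[keep, , drop = FALSE]
  .assert(nrow(clin) >= min_subjects,
          sprintf("cohort too small (%d subjects < %d)", nrow(clin),
                  min_subjects))
  .assert(sum(clin$event) >= min_events,
          sprintf("cohort has too few events (%d < %d)", sum(clin$event),
                  min_events))
  pri <- pri_all[clin$sample_id]
  stratum <- stratify_median(pri)
  desc <- if (is.null(cohort_filter)) "all subjects"
          else if (is.list(cohort_filter))
            paste(names(cohort_filter), unlist(cohort_filter),
                  sep = "=", collapse = ", ")
          else "custom cohort"
  if (isTRUE(attr(stratum, "degenerate"))) {
    return(structure(list(pathway_name = pathway_name, pri = pri,
                          stratum = stratum, cohort = desc,
                          degenerate = TRUE, wald_p = NA_real_,
                          coef_high = NA_real_, logrank_p = NA_real_,
                          km = NULL, n = nrow(clin),
                          n_events = sum(clin$event)),
                     class = "pri_strata"))
  }
  fit <- fit_cox(clin$time, clin$event,
                 cbind(high_pri = as.numeric(stratum == "high")))
  lr <- logrank_test(clin$time, clin$event, stratum)
  km <- km_estimate(clin$time, clin$event, stratum)
  structure(list(pathway_name = pathway_name, pri = pri, stratum = stratum,
                 cohort = desc, degenerate = FALSE,
                 wald_p = unname(fit$wald_p[1]),
                 coef_high = unname(fit$coefficients[1]),
                 logrank_p = lr$p, km = km, n = nrow(clin),
                 n_events = sum(clin$event)),
            class = "pri_strata")
}

#' @export
print.pri_strata <- function(x, ...) {
  cat(sprintf("PRI stratification: %s, cohort: %s (n = %d, events = %d)\n",
              x$pathway_name, x$cohort, x$n, x$n_events))
  if (x$degenerate) {
    cat("  degenerate: all PRI values identical, no test performed\n")
  } else {
    cat(sprintf("  high vs low PRI: log HR = %.3f, Wald p = %.4g, log-rank p = %.4g\n",
                x$coef_high, x$wald_p, x$logrank_p))
  }
  invisible(x)
}
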