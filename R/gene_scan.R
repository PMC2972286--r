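#' Benjamini-Hochberg FDR rejection flags
#'
#' Step-up BH at level `q` via [stats::p.adjust()]: a hypothesis is rejected
#' iff its BH-adjusted p-value is at most `q`, equivalent to rejecting the
#' `i*` smallest p-values where `i* = max{i : p(i) <= i q / m}`.
#'
#' @param p p-values in \[0,1\].
#' @param q FDR level in (0,1).
#' @return logical rejection flags (empty input gives empty output).
#' @export
bh_fdr <- function(p, q = 0.2) {
  .assert(q > 0 && q < 1, "q must be in (0,1)")
  if (length(p) == 0) return(logical(0))
  .assert(all(p >= 0 & p <= 1), "p-values must lie in [0,1]")
  p.adjust(p, method = "BH") <= q
}

# covariate design for a model spec; NULL means the spec is unavailable
.spec_variables <- function(study, spec, clinical_model) {
  switch(spec,
    univariate = character(0),
    er_size = {
      have <- vapply(c("er_status", "tumor_size"), function(v)
        v %in% names(study$clinical) && any(!is.na(study$clinical[[v]])),
        logical(1))
      if (!all(have)) return(NULL)
      c("er_status", "tumor_size")
    },
    aic_best = ,
    bic_best = clinical_model$variables)
}

#' Per-gene survival scan under one model specification
#'
#' Fits, for every gene, a Cox model of survival on the gene's expression
#' (as a continuous covariate) plus the specification's clinical
#' covariates: none (`univariate`), ER status and tumor size (`er_size`),
#' or the variables of an AIC/BIC-selected clinical model (`aic_best`,
#' `bic_best`). The per-gene p-value is the 1-df partial-likelihood-ratio
#' test of the gene term against the same model without it; the Wald p is
#' also reported. Non-converged or collinear fits score p = 1 with a flag
#' so the multiplicity count stays fixed. Significance flags come from
#' [bh_fdr()] at level `q`.
#'
#' @param study [expression_study()].
#' @param spec one of `"univariate"`, `"er_size"`, `"aic_best"`,
#'   `"bic_best"`.
#' @param clinical_model a `clinical_model` (required for
#'   `aic_best`/`bic_best`; selected automatically over ER status, tumor
#'   size, grade and age when omitted).
#' @param q BH-FDR level.
#' @return data.frame (class `gene_score_table`): `gene_id`, `model_spec`,
#'   `coef`, `z`, `p` (likelihood ratio), `wald_p`, `converged`,
#'   `significant`; NULL with a warning if the spec's covariates are
#'   unavailable in this study.
#' @export
scan_genes <- function(study, spec = c("univariate", "er_size", "aic_best",
                                       "bic_best"),
                       clinical_model = NULL, q = 0.2) {
  spec <- match.arg(spec)
  .assert(inherits(study, "expression_study"), "study must be an expression_study")
  .assert(nrow(study$expression) > 0 && ncol(study$expression) > 0,
          "empty study")
  if (spec %in% c("aic_best", "bic_best") && is.null(clinical_model)) {
    cand <- intersect(c("er_status", "tumor_size", "grade", "age"),
                      names(study$clinical))
    cand <- cand[vapply(cand, function(v) any(!is.na(study$clinical[[v]])),
                        logical(1))]
    clinical_model <- select_clinical_model(
      study, cand, criterion = if (spec == "aic_best") "AIC" else "BIC")
  }
  vars <- .spec_variables(study, spec, clinical_model)
  if (is.null(vars)) {
    warning(sprintf("study '%s': covariates for spec '%s' unavailable; skipped",
                    study$study_name, spec))
    return(NULL)
  }
  keep <- .complete_rows(study$clinical, vars)
  clin <- study$clinical[keep, , drop = FALSE]
  .assert(sum(clin$event) >= 1, "no events in complete-case subset")
  expr <- study$expression[, keep, drop = FALSE]
  Z <- clinical_design(clin, vars)
  sc <- .cox_scan_z(clin$time, clin$event, expr, Z)
  lrt <- pmax(0, 2 * (sc$loglik - sc$loglik_ref))
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  wald_p <- pchisq(sc$z^2, df = 1, lower.tail = FALSE)
  bad <- !sc$converged | !is.finite(p)
  p[bad] <- 1; wald_p[bad] <- 1
  out <- data.frame(gene_id = rownames(expr), model_spec = spec,
                    coef = sc$coef, z = sc$z, p = p, wald_p = wald_p,
                    converged = sc$converged,
                    significant = bh_fdr(p, q),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n") <- nrow(clin)
  attr(out, "n_events") <- sum(clin$event)
  class(out) <- c("gene_score_table", "data.frame")
  out
}

# shared fast path: per-gene Cox of survival on gene + fixed covariates Z
.cox_scan_z <- function(time, event, expr, Z) {
  ord <- order(time, decreasing = TRUE) - 1L
  if (ncol(Z) > 0) {
    zfit <- cpp_cox_fit(time, as.integer(event), Z, ord, numeric(ncol(Z)),
                        30L, 1e-10, 15)
    z_init <- as.numeric(zfit$coef)
    loglik_ref <- zfit$loglik
  } else {
    z_init <- numeric(0)
    loglik_ref <- cpp_cox_loglik(time, as.integer(event),
                                 matrix(0, length(time), 1), ord, 0)
  }
  m <- cpp_cox_scan(time, as.integer(event), t(expr), Z, ord, z_init,
                    30L, 1e-10, 15)
  list(coef = m[, 1], se = m[, 2], z = m[, 3], loglik = m[, 4],
       converged = m[, 5] == 1, loglik_ref = loglik_ref)
}

#' Count significant genes across model specifications
#'
#' Summarizes one study's [scan_genes()] tables into a per-specification
#' count of BH-significant genes.
#'
#' @param tables list of `gene_score_table`s from the same study (NULL
#'   entries, e.g. skipped specs, are dropped).
#' @return data.frame with `model_spec`, `n_significant`, `n_genes`.
#' @export
count_significant <- function(tables) {
  tables <- Filter(Negate(is.null), tables)
  out <- do.call(rbind, lapply(tables, function(tb)
    data.frame(model_spec = tb$model_spec[1],
               n_significant = sum(tb$significant),
               n_genes = nrow(tb), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
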