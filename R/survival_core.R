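#' Fit a Cox proportional-hazards model (Breslow ties)
#'
#' Maximizes the Breslow-tie partial likelihood by Newton-Raphson with step
#' halving. Separation (a monotone likelihood) is caught by capping
#' coefficients at `coef_cap` and flagging the fit as non-converged;
#' singular information (collinear covariates) is likewise flagged.
#'
#' @param time nonnegative follow-up times.
#' @param event event indicators, 0 (censored) or 1 (event).
#' @param covariates numeric matrix or data.frame, one column per covariate.
#'   Rows with missing values are dropped (complete-case analysis).
#' @param max_iter maximum Newton iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @param coef_cap absolute bound on coefficients; hitting it flags
#'   separation.
#' @return An object of class `cox_fit`: coefficients, standard errors,
#'   two-sided Wald p-values (chi-square on 1 df), maximized and null partial
#'   log-likelihoods, event count and convergence flag.
#' @examples
#' fit <- fit_cox(c(2, 4, 3, 5, 1, 6), c(1, 1, 0, 1, 1, 0),
#'                cbind(x = c(0.5, -1, 0.2, 1.4, -0.3, 0.8)))
#' fit$coefficients
#' @export
fit_cox <- function(time, event, covariates, max_iter = 30L, tol = 1e-10,
                    coef_cap = 15) {
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  .assert(length(time) == length(event) && nrow(X) == length(time),
          "time, event and covariates must have matching lengths")
  keep <- complete.cases(time, event, X)
  time <- time[keep]; event <- event[keep]; X <- X[keep, , drop = FALSE]
  .assert(all(time >= 0), "negative follow-up time")
  .assert(all(event %in% c(0, 1)), "event must be 0/1")
  .assert(sum(event) >= 1, "no events: cannot fit a Cox model")
  csd <- apply(X, 2, sd)
  if (any(csd < 1e-12))
    stop("constant covariate column(s): ",
         paste(colnames(X)[csd < 1e-12], collapse = ", "), call. = FALSE)
  ord <- order(time, decreasing = TRUE) - 1L
  r <- cpp_cox_fit(time, as.integer(event), X, ord,
                   numeric(ncol(X)), max_iter, tol, coef_cap)
  coefs <- as.numeric(r$coef); se <- as.numeric(r$se)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_along(coefs))
  names(coefs) <- names(se) <- nm
  wald_p <- pchisq((coefs / se)^2, df = 1, lower.tail = FALSE)
  structure(list(coefficients = coefs, se = se, wald_p = wald_p,
                 loglik = r$loglik, loglik_null = r$loglik_null,
                 n = length(time), n_events = as.integer(sum(event)),
                 converged = isTRUE(r$converged), iter = r$iter),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Breslow ties)\n")
  cat(sprintf("  n = %d, events = %d, loglik = %.4f, converged = %s\n",
              x$n, x$n_events, x$loglik, x$converged))
  tab <- data.frame(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
                    se = x$se, wald_p = x$wald_p, check.names = FALSE)
  print(tab, digits = 4)
  invisible(x)
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimates per group via [survival::survfit()]. Censored
#' observations do not drop the curve.
#'
#' @param time,event follow-up times and 0/1 event indicators.
#' @param group optional group labels; one curve per level (default: one
#'   curve for the whole sample).
#' @return A list of `km_curve` data frames (columns `time`, `n_risk`,
#'   `n_event`, `surv`), one per group, named by group label.
#' @export
km_estimate <- function(time, event, group = NULL) {
  .assert(length(time) == length(event), "time/event length mismatch")
  if (is.null(group)) group <- rep("all", length(time))
  .assert(length(group) == length(time), "group length mismatch")
  .assert(all(table(group) > 0), "empty group")
  out <- lapply(split(seq_along(time), group), function(idx) {
    sf <- survival::survfit(survival::Surv(time[idx], event[idx]) ~ 1)
    structure(data.frame(time = sf$time, n_risk = sf$n.risk,
                         n_event = sf$n.event, surv = sf$surv),
              class = c("km_curve", "data.frame"))
  })
  out
}

#' Log-rank test between survival curves
#'
#' K-sample log-rank chi-square test on K-1 degrees of freedom via
#' [survival::survdiff()].
#'
#' @inheritParams km_estimate
#' @param group group labels with at least two levels.
#' @return list with `statistic`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  g <- factor(group)
  .assert(nlevels(g) >= 2, "log-rank test needs at least two groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

# Build a numeric design matrix (no intercept column) from clinical records
# for variables given as column names or "a:b" interactions. er_status is
# coded as an ER-negative indicator so positive coefficients mean worse
# prognosis for ER-negative disease.
clinical_design <- function(clinical, variables) {
  if (length(variables) == 0)
    return(matrix(numeric(0), nrow = nrow(clinical), ncol = 0))
  dat <- clinical
  if ("er_status" %in% names(dat))
    dat$er_status <- factor(dat$er_status, levels = c("positive", "negative"))
  fml <- as.formula(paste("~", paste(variables, collapse = " + ")))
  mm <- model.matrix(fml, data = dat)
  mm[, colnames(mm) != "(Intercept)", drop = FALSE]
}

# rows of `clinical` usable for a model on `variables` (plus time/event)
.complete_rows <- function(clinical, variables) {
  base <- setdiff(unlist(strsplit(variables, ":", fixed = TRUE)), "")
  cols <- intersect(unique(c("time", "event", base)), names(clinical))
  complete.cases(clinical[, cols, drop = FALSE])
}

.fit_on_vars <- function(clinical, variables, ...) {
  X <- clinical_design(clinical, variables)
  if (ncol(X) == 0) {
    ord <- order(clinical$time, decreasing = TRUE) - 1L
    ll0 <- cpp_cox_loglik(clinical$time, as.integer(clinical$event),
                          matrix(0, nrow(clinical), 1), ord, 0)
    return(list(fit = NULL, loglik = ll0, npar = 0L))
  }
  fit <- fit_cox(clinical$time, clinical$event, X, ...)
  list(fit = fit, loglik = fit$loglik, npar = ncol(X))
}

.criterion_value <- function(loglik, npar, criterion, n_events) {
  if (criterion == "AIC") -2 * loglik + 2 * npar
  else -2 * loglik + npar * log(n_events)
}

#' Select a clinical Cox model by AIC or BIC
#'
#' Searches Cox models over the candidate clinical variables and scores them
#' by AIC (`-2 loglik + 2p`) or BIC (`-2 loglik + p log(d)` with `d` the
#' number of events, the standard effective sample size for censored data).
#' Main effects are searched exhaustively when there are at most
#' `max_exhaustive` candidates (forward-stepwise otherwise); pairwise
#' interactions among the selected main effects are then added greedily
#' while the criterion improves. Ties go to the smaller model, then to
#' lexicographic order of the variable list. Complete cases over the full
#' candidate list are used throughout so all models are scored on the same
#' subjects.
#'
#' @param study an `expression_study` (see [expression_study()]), or a
#'   clinical data.frame with `time` and `event` columns.
#' @param candidates character vector of clinical column names to search.
#' @param criterion `"AIC"` or `"BIC"`.
#' @param interactions search pairwise interactions among selected mains?
#' @param max_exhaustive candidate count up to which the main-effect search
#'   enumerates all subsets.
#' @return `clinical_model` object: `variables`, `criterion`,
#'   `criterion_value`, `fit` (a `cox_fit`, or NULL for the empty model),
#'   `n`, `n_events`.
#' @export
select_clinical_model <- function(study, candidates,
                                  criterion = c("AIC", "BIC"),
                                  interactions = TRUE, max_exhaustive = 10L) {
  criterion <- match.arg(criterion)
  clinical <- if (inherits(study, "expression_study")) study$clinical else study
  .assert(all(candidates %in% names(clinical)),
          "candidate variable(s) absent from clinical table")
  keep <- .complete_rows(clinical, candidates)
  cc <- clinical[keep, , drop = FALSE]
  n_events <- sum(cc$event)
  .assert(n_events >= 10, "fewer than 10 events in complete-case subset")

  score <- function(vars) {
    f <- tryCatch(.fit_on_vars(cc, vars), error = function(e) NULL)
    if (is.null(f)) return(NULL)
    list(vars = vars, fit = f,
         crit = .criterion_value(f$loglik, f$npar, criterion, n_events))
  }
  better <- function(a, b) {  # is a strictly preferred to b?
    if (is.null(a)) return(FALSE)
    if (is.null(b)) return(TRUE)
    if (a$crit != b$crit) return(a$crit < b$crit)
    if (length(a$vars) != length(b$vars)) return(length(a$vars) < length(b$vars))
    paste(sort(a$vars), collapse = "+") < paste(sort(b$vars), collapse = "+")
  }

  best <- score(character(0))
  if (length(candidates) <= max_exhaustive) {
    for (k in seq_along(candidates)) {
      cmb <- combn(length(candidates), k)
      for (idx in seq_len(ncol(cmb))) {
        cand <- score(candidates[cmb[, idx]])
        if (better(cand, best)) best <- cand
      }
    }
  } else {
    repeat {
      remaining <- setdiff(candidates, best$vars)
      if (length(remaining) == 0) break
      step_best <- NULL
      for (v in remaining) {
        cand <- score(c(best$vars, v))
        if (better(cand, step_best)) step_best <- cand
      }
      if (better(step_best, best)) best <- step_best else break
    }
  }
  if (interactions && length(best$vars) >= 2) {
    mains <- best$vars
    pairs <- combn(mains, 2)
    repeat {
      step_best <- NULL
      for (j in seq_len(ncol(pairs))) {
        term <- paste(pairs[, j], collapse = ":")
        if (term %in% best$vars) next
        cand <- score(c(best$vars, term))
        if (better(cand, step_best)) step_best <- cand
      }
      if (better(step_best, best)) best <- step_best else break
    }
  }
  .assert(!is.null(best), "no candidate model could be fitted")
  structure(list(variables = best$vars, criterion = criterion,
                 criterion_value = best$crit, fit = best$fit$fit,
                 loglik = best$fit$loglik, npar = best$fit$npar,
                 n = nrow(cc), n_events = as.integer(n_events)),
            class = "clinical_model")
}

#' @export
print.clinical_model <- function(x, ...) {
  cat(sprintf("Clinical Cox model selected by %s (%.3f); n = %d, events = %d\n",
              x$criterion, x$criterion_value, x$n, x$n_events))
  cat("  variables:", if (length(x$variables)) paste(x$variables, collapse = ", ")
      else "(empty model)", "\n")
  invisible(x)
}
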