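#' Configuration for the restandardized pathway test
#'
#' @param B number of outcome permutations (>= 100 for inference unless
#'   `allow_small_B`; ignored when `exhaustive_permutations`).
#' @param R number of random gene sets per pathway size in the
#'   randomization step (ignored when `exhaustive_randomization`).
#' @param min_set,max_set inclusive pathway size bounds applied after
#'   intersecting each set with the study's genes (defaults 15 and 250).
#' @param alpha generalized family-wise error level.
#' @param u allowed number of false discoveries (gFWER controls the
#'   probability of `u` or more false positives at `alpha`).
#' @param seed integer seed covering permutation and randomization draws.
#' @param covariates clinical adjustment covariates for the per-gene scores
#'   (may be empty for unadjusted scores, e.g. when a study lacks them).
#' @param exhaustive_permutations enumerate all `n!` outcome orderings
#'   (small n only) instead of sampling `B`.
#' @param exhaustive_randomization enumerate all gene subsets of each
#'   pathway size instead of sampling `R` (small universes only).
#' @param allow_small_B permit `B < 100` (exploration only).
#' @return validated `gsa_config` list.
#' @export
gsa_config <- function(B = 1000L, R = 1000L, min_set = 15L, max_set = 250L,
                       alpha = 0.20, u = 5L, seed = 1L,
                       covariates = c("er_status", "tumor_size"),
                       exhaustive_permutations = FALSE,
                       exhaustive_randomization = FALSE,
                       allow_small_B = FALSE) {
  cfg <- list(B = as.integer(B), R = as.integer(R),
              min_set = as.integer(min_set), max_set = as.integer(max_set),
              alpha = alpha, u = as.integer(u), seed = as.integer(seed),
              covariates = as.character(covariates),
              exhaustive_permutations = isTRUE(exhaustive_permutations),
              exhaustive_randomization = isTRUE(exhaustive_randomization),
              allow_small_B = isTRUE(allow_small_B))
  .assert(cfg$min_set <= cfg$max_set, "min_set must be <= max_set")
  .assert(cfg$alpha > 0 && cfg$alpha < 1, "alpha must be in (0,1)")
  .assert(cfg$u >= 1, "u must be >= 1")
  if (!cfg$exhaustive_permutations && !cfg$allow_small_B)
    .assert(cfg$B >= 100,
            "B < 100 is too few permutations for inference (set allow_small_B to override)")
  structure(cfg, class = "gsa_config")
}

#' Covariate-adjusted per-gene survival scores
#'
#' For each gene, fits a Cox model of survival on the gene plus the
#' adjustment covariates (complete cases) and returns the Wald z of the
#' gene coefficient. Non-converged or collinear fits contribute a neutral
#' z = 0 and are flagged.
#'
#' @param study [expression_study()].
#' @param covariates clinical covariate names (possibly empty).
#' @return named numeric vector of z scores with logical attribute
#'   `flagged`.
#' @export
adjusted_gene_scores <- function(study,
                                 covariates = c("er_status", "tumor_size")) {
  .assert(inherits(study, "expression_study"), "study must be an expression_study")
  keep <- .complete_rows(study$clinical, covariates)
  clin <- study$clinical[keep, , drop = FALSE]
  .assert(sum(clin$event) >= 1, "no events in complete-case subset")
  Z <- clinical_design(clin, covariates)
  sc <- .cox_scan_z(clin$time, clin$event, study$expression[, keep, drop = FALSE], Z)
  z <- ifelse(sc$converged, sc$z, 0)
  names(z) <- rownames(study$expression)
  attr(z, "flagged") <- !sc$converged
  z
}

#' The maxmean gene-set summary statistic
#'
#' For member scores z: `s+` is the mean of the positive parts `max(z, 0)`
#' and `s-` the mean of the negative parts `max(-z, 0)`, both averaged over
#' the whole set. Returns `s+` if `s+ >= s-`, else `-s-` (signed by the
#' dominant direction; ties go positive). Positively homogeneous:
#' `maxmean(c z) = c maxmean(z)` for `c > 0`.
#'
#' @param scores nonempty numeric vector of member gene scores.
#' @return the maxmean statistic.
#' @examples
#' maxmean(c(3, -1, -1, 0))  # 0.75
#' @export
maxmean <- function(scores) {
  .assert(length(scores) > 0, "maxmean of an empty set")
  sp <- mean(pmax(scores, 0))
  sn <- mean(pmax(-scores, 0))
  if (sp >= sn) sp else -sn
}

#' Filter pathways by post-intersection size
#'
#' Intersects every set with the study's gene identifiers and keeps sets
#' whose size lies in `[min_set, max_set]` (bounds inclusive).
#'
#' @param db [pathway_db()].
#' @param study_genes character vector of the study's gene identifiers.
#' @param min_set,max_set inclusive size bounds.
#' @return filtered [pathway_db()]; attribute `dropped` is a data.frame of
#'   excluded pathways with their post-intersection sizes.
#' @export
filter_pathways <- function(db, study_genes, min_set = 15L, max_set = 250L) {
  sets <- lapply(db$pathways, intersect, y = study_genes)
  sz <- lengths(sets)
  keep <- sz >= min_set & sz <= max_set
  out <- pathway_db(sets[keep], source_note = db$source_note)
  attr(out, "dropped") <- data.frame(pathway = names(sets)[!keep],
                                     size = unname(sz[!keep]),
                                     stringsAsFactors = FALSE)
  out
}

#' Generalized Sidak-Holm step-down (gFWER control)
#'
#' Step-down multiple testing controlling the generalized family-wise error
#' rate: the probability of `u` or more false rejections is kept at or
#' below `alpha`. Sorted p-values `p(1) <= ... <= p(m)` are compared to
#' Sidak-form critical values of Lehmann-Romano step-down shape,
#' `c_i = 1 - (1-alpha)^(u/m)` for `i <= u` and
#' `c_i = 1 - (1-alpha)^(u/(m+u-i))` for `i > u`; rejection proceeds while
#' `p(i) <= c_i` and stops at the first failure. Ties are resolved by a
#' stable sort, and lowering any p-value can only enlarge the rejection
#' set.
#'
#' @param p p-values in \[0,1\].
#' @param alpha gFWER level in (0,1).
#' @param u allowed false discoveries (>= 1).
#' @return logical rejection flags in the input order.
#' @examples
#' gfwer_sidak_holm(c(0.05, 0.06, 0.07, 0.5, 0.6, 0.7), alpha = 0.2, u = 2)
#' @export
gfwer_sidak_holm <- function(p, alpha = 0.20, u = 5L) {
  .assert(u >= 1, "u must be >= 1")
  .assert(alpha > 0 && alpha < 1, "alpha must be in (0,1)")
  m <- length(p)
  if (m == 0) return(logical(0))
  .assert(all(p >= 0 & p <= 1), "p-values must lie in [0,1]")
  ord <- order(p)                       # stable in R
  i <- seq_len(m)
  crit <- ifelse(i <= u, 1 - (1 - alpha)^(u / m),
                 1 - (1 - alpha)^(u / (m + u - i)))
  ok <- p[ord] <= crit
  n_rej <- if (all(ok)) m else which(!ok)[1] - 1L
  flags <- logical(m)
  if (n_rej > 0) flags[ord[seq_len(n_rej)]] <- TRUE
  flags
}

# All n! orderings of 1..n as an n! x n matrix (lexicographic).
.all_orderings <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_orderings(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(first) {
    rest <- seq_len(n)[-first]
    cbind(first, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# Randomization moments of maxmean over gene sets drawn (without
# replacement within each set) from the scored universe; one (mu, sigma)
# pair per requested set size. exhaustive = all subsets via combn;
# otherwise R sets per size are sampled in compiled code off R's RNG.
.randomization_moments <- function(z, sizes, R, exhaustive = FALSE) {
  m <- length(z)
  if (!exhaustive) {
    mo <- cpp_maxmean_moments(z, as.integer(sizes), as.integer(R))
    out <- lapply(seq_along(sizes), function(i)
      c(mu = mo[i, 1], sigma = mo[i, 2]))
    names(out) <- as.character(sizes)
    return(out)
  }
  out <- lapply(sizes, function(s) {
    .assert(choose(m, s) <= 5e4,
            "exhaustive randomization infeasible for this universe")
    idx <- combn(m, s)
    M <- matrix(z[idx], nrow = s)
    sp <- colMeans(pmax(M, 0))
    sn <- colMeans(pmax(-M, 0))
    mm <- ifelse(sp >= sn, sp, -sn)
    c(mu = mean(mm), sigma = sd(mm))
  })
  names(out) <- as.character(sizes)
  out
}

.restandardize <- function(S, sizes, moments) {
  vapply(seq_along(S), function(k) {
    mo <- moments[[as.character(sizes[k])]]
    if (!is.finite(mo["sigma"]) || mo["sigma"] < 1e-12) return(0)
    (S[k] - mo[["mu"]]) / mo[["sigma"]]
  }, numeric(1))
}

#' Restandardized pathway survival test with permutation p-values
#'
#' The gene-set analysis at the core of the pipeline. Observed step:
#' covariate-adjusted per-gene Cox z scores ([adjusted_gene_scores()]) are
#' summarized per pathway by [maxmean()]; a randomization step draws random
#' gene sets of each pathway's size from the scored universe and
#' standardizes the observed statistic by their mean and SD
#' (`z_restd`). Permutation step: the clinical rows (time, event,
#' covariates) are jointly permuted against the expression columns B times
#' — breaking any expression-outcome association while preserving
#' gene-gene and covariate-outcome structure — and each permutation's
#' restandardized statistics are computed with its own randomization
#' moments. The two-sided p-value is
#' `p = (1 + #\{b : |z_b| >= |z_obs|\}) / (B + 1)`, so `p` lies in
#' `[1/(B+1), 1]`. Pathways are size-filtered first
#' ([filter_pathways()]); rejection flags come from [gfwer_sidak_holm()].
#' Deterministic given `cfg$seed`.
#'
#' @param study [expression_study()].
#' @param db [pathway_db()].
#' @param cfg [gsa_config()].
#' @return data.frame (class `pathway_result`) with `pathway`, `size`,
#'   `maxmean_raw`, `z_restd`, `p_perm`, `gfwer_reject`; attributes
#'   `dropped` (size-filtered pathways) and `B`.
#' @export
restandardized_pathway_test <- function(study, db, cfg = gsa_config()) {
  .assert(inherits(cfg, "gsa_config"), "cfg must be a gsa_config")
  keep <- .complete_rows(study$clinical, cfg$covariates)
  clin <- study$clinical[keep, , drop = FALSE]
  .assert(sum(clin$event) >= 1, "no events in complete-case subset")
  expr <- study$expression[, keep, drop = FALSE]
  n <- nrow(clin)
  Z <- clinical_design(clin, cfg$covariates)

  fdb <- filter_pathways(db, rownames(expr), cfg$min_set, cfg$max_set)
  dropped <- attr(fdb, "dropped")
  small <- lengths(fdb$pathways) < 2
  if (any(small)) {
    dropped <- rbind(dropped, data.frame(
      pathway = names(fdb$pathways)[small],
      size = unname(lengths(fdb$pathways)[small]), stringsAsFactors = FALSE))
    fdb$pathways <- fdb$pathways[!small]
  }
  .assert(length(fdb$pathways) > 0, "no pathways pass the size filter")
  members <- lapply(fdb$pathways, match, table = rownames(expr))
  sizes <- lengths(members)
  usizes <- sort(unique(sizes))

  set.seed(cfg$seed)
  score_z <- function(time, event, Zmat) {
    sc <- .cox_scan_z(time, event, expr, Zmat)
    ifelse(sc$converged, sc$z, 0)
  }
  stat_for <- function(z) {
    S <- vapply(members, function(ix) maxmean(z[ix]), numeric(1))
    mo <- .randomization_moments(z, usizes, cfg$R, cfg$exhaustive_randomization)
    .restandardize(S, sizes, mo)
  }

  z_obs <- score_z(clin$time, clin$event, Z)
  S_obs <- vapply(members, function(ix) maxmean(z_obs[ix]), numeric(1))
  z_restd <- stat_for(z_obs)

  perms <- if (cfg$exhaustive_permutations) {
    .assert(n <= 7, "exhaustive permutations only feasible for n <= 7")
    .all_orderings(n)
  } else {
    t(vapply(seq_len(cfg$B), function(b) sample.int(n), integer(n)))
  }
  B <- nrow(perms)
  count <- numeric(length(members))
  for (b in seq_len(B)) {
    pi <- perms[b, ]
    zb <- score_z(clin$time[pi], clin$event[pi], Z[pi, , drop = FALSE])
    count <- count + (abs(stat_for(zb)) >= abs(z_restd))
  }
  p_perm <- (1 + count) / (B + 1)
  out <- data.frame(pathway = names(fdb$pathways), size = unname(sizes),
                    maxmean_raw = unname(S_obs), z_restd = unname(z_restd),
                    p_perm = unname(p_perm),
                    gfwer_reject = gfwer_sidak_holm(p_perm, cfg$alpha, cfg$u),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "dropped") <- dropped
  attr(out, "B") <- B
  class(out) <- c("pathway_result", "data.frame")
  out
}
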