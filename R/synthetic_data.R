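#' Specify a synthetic multi-study simulation
#'
#' Defines the generating conditions for synthetic expression cohorts with
#' right-censored proportional-hazards survival: several studies with
#' partially overlapping gene universes, ER-status and tumor-size
#' covariates, and pathway-coherent expression shifts that induce survival
#' effects through a per-subject latent activity score.
#'
#' Defaults mirror a typical multi-study breast-cancer design: five cohorts
#' of ~200 patients, a few thousand genes per platform with high cross-
#' platform overlap, ER-positive prevalence 0.7, tumor sizes lognormal with
#' median 2 cm, ER-negative log-hazard 0.6, 0.2 per cm of tumor size, and
#' about 60% censoring over follow-up.
#'
#' @param n_studies number of cohorts.
#' @param n_samples_per_study samples per cohort (scalar or vector recycled
#'   to `n_studies`).
#' @param n_genes size of the global gene universe.
#' @param gene_overlap_fraction fraction of the universe shared by all
#'   studies, in \[0,1\]; the remainder is partitioned across studies.
#' @param n_pathways number of gene sets to generate.
#' @param pathway_size_range integer pair (min, max) of set sizes.
#' @param enriched_pathway_ids names of pathways given a survival-linked
#'   latent activity signal.
#' @param beta_pathway log-hazard per unit latent pathway activity.
#' @param beta_er log-hazard for ER-negative status.
#' @param beta_size log-hazard per cm tumor size.
#' @param baseline_hazard baseline event rate per unit time (scalar or
#'   per-study vector).
#' @param censor_rate target censored fraction in \[0,1).
#' @param noise_sd expression noise standard deviation.
#' @param er_positive_prev ER-positive prevalence.
#' @param tumor_size_meanlog,tumor_size_sdlog lognormal tumor-size
#'   parameters (cm).
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return validated `simulation_spec` list.
#' @export
simulation_spec <- function(n_studies = 5L, n_samples_per_study = 200L,
                            n_genes = 2000L, gene_overlap_fraction = 0.8,
                            n_pathways = 50L, pathway_size_range = c(15L, 250L),
                            enriched_pathway_ids = character(0),
                            beta_pathway = 0, beta_er = 0.6, beta_size = 0.2,
                            baseline_hazard = 0.04, censor_rate = 0.6,
                            noise_sd = 1, er_positive_prev = 0.7,
                            tumor_size_meanlog = log(2), tumor_size_sdlog = 0.5,
                            seed = 1L) {
  spec <- list(n_studies = as.integer(n_studies),
               n_samples_per_study = as.integer(rep_len(n_samples_per_study, n_studies)),
               n_genes = as.integer(n_genes),
               gene_overlap_fraction = gene_overlap_fraction,
               n_pathways = as.integer(n_pathways),
               pathway_size_range = as.integer(pathway_size_range),
               enriched_pathway_ids = as.character(enriched_pathway_ids),
               beta_pathway = beta_pathway, beta_er = beta_er,
               beta_size = beta_size,
               baseline_hazard = rep_len(baseline_hazard, n_studies),
               censor_rate = censor_rate, noise_sd = noise_sd,
               er_positive_prev = er_positive_prev,
               tumor_size_meanlog = tumor_size_meanlog,
               tumor_size_sdlog = tumor_size_sdlog,
               seed = as.integer(seed))
  .assert(spec$n_studies >= 1 && spec$n_genes >= 1 && spec$n_pathways >= 1 &&
            all(spec$n_samples_per_study >= 1), "all counts must be >= 1")
  .assert(length(spec$pathway_size_range) == 2 &&
            spec$pathway_size_range[1] <= spec$pathway_size_range[2] &&
            spec$pathway_size_range[1] >= 1, "invalid pathway_size_range")
  .assert(spec$gene_overlap_fraction >= 0 && spec$gene_overlap_fraction <= 1,
          "gene_overlap_fraction must be in [0,1]")
  .assert(spec$censor_rate >= 0 && spec$censor_rate < 1,
          "censor_rate must be in [0,1)")
  .assert(all(spec$baseline_hazard > 0), "baseline_hazard must be positive")
  .assert(spec$noise_sd > 0, "noise_sd must be positive")
  structure(spec, class = "simulation_spec")
}

.gene_universe <- function(spec) sprintf("g%05d", seq_len(spec$n_genes))

# Per-study gene subsets: a seeded shuffle assigns a shared core of
# round(overlap * n_genes) genes to every study and partitions the remainder
# across studies, so any two studies share exactly the core.
.study_gene_sets <- function(spec) {
  universe <- .gene_universe(spec)
  set.seed(.stream_seed(spec$seed, 0L, "universe"))
  shuffled <- sample(universe)
  k <- round(spec$gene_overlap_fraction * spec$n_genes)
  core <- shuffled[seq_len(k)]
  rest <- shuffled[setdiff(seq_len(spec$n_genes), seq_len(k))]
  blocks <- rep(list(character(0)), spec$n_studies)
  if (length(rest)) {
    asg <- rep_len(seq_len(spec$n_studies), length(rest))
    for (i in seq_len(spec$n_studies)) blocks[[i]] <- rest[asg == i]
  }
  lapply(seq_len(spec$n_studies), function(i) {
    g <- c(core, blocks[[i]])
    universe[universe %in% g]   # stable universe order
  })
}

#' Generate a synthetic pathway database
#'
#' Draws `n_pathways` gene sets with sizes uniform on `pathway_size_range`
#' and members sampled without replacement from the gene universe.
#' Deterministic given the spec seed.
#'
#' @param spec [simulation_spec()].
#' @return [pathway_db()].
#' @export
generate_pathway_db <- function(spec) {
  .assert(inherits(spec, "simulation_spec"), "spec must be a simulation_spec")
  .assert(spec$pathway_size_range[2] <= spec$n_genes,
          "pathway size range exceeds the gene universe")
  universe <- .gene_universe(spec)
  set.seed(.stream_seed(spec$seed, 0L, "pathways"))
  sizes <- sample(seq(spec$pathway_size_range[1], spec$pathway_size_range[2]),
                  spec$n_pathways, replace = TRUE)
  sets <- lapply(sizes, function(s) sample(universe, s))
  names(sets) <- sprintf("pw%03d", seq_len(spec$n_pathways))
  pathway_db(sets, source_note = "synthetic")
}

# Solve for an exponential censoring rate giving an expected censored
# fraction censor_rate when event hazards are h: P(C < T_i) = rc/(rc + h_i).
.censor_rate_for <- function(h, censor_rate) {
  if (censor_rate <= 0) return(0)
  f <- function(logrc) mean(exp(logrc) / (exp(logrc) + h)) - censor_rate
  exp(uniroot(f, c(-30, 30))$root)
}

#' Generate one synthetic study cohort
#'
#' For each subject a standard-normal latent activity score is drawn per
#' enriched pathway; member genes of an enriched pathway get that subject's
#' activity added to their (zero) mean, all genes get Gaussian noise. Event
#' times follow an exponential proportional-hazards model with linear
#' predictor `beta_pathway * sum(activities) + beta_er * I(ER-negative) +
#' beta_size * tumor_size`; independent exponential censoring is calibrated
#' numerically to the target censored fraction.
#'
#' @param spec [simulation_spec()].
#' @param db [pathway_db()] generated from the same spec (gene universe).
#' @param study_index which study (1-based) — selects the study's gene
#'   subset, sample size, baseline hazard and random streams.
#' @return [expression_study()] with diagnostic attribute
#'   `latent_activity` (matrix, enriched pathways x samples).
#' @export
generate_cohort <- function(spec, db, study_index = 1L) {
  .assert(inherits(spec, "simulation_spec"), "spec must be a simulation_spec")
  .assert(study_index >= 1 && study_index <= spec$n_studies,
          "study_index out of range")
  .assert(all(spec$enriched_pathway_ids %in% names(db$pathways)),
          "enriched_pathway_ids absent from pathway database")
  n <- spec$n_samples_per_study[study_index]
  genes <- .study_gene_sets(spec)[[study_index]]
  samples <- sprintf("s%d_%04d", study_index, seq_len(n))

  set.seed(.stream_seed(spec$seed, study_index, "clinical"))
  er <- ifelse(rbinom(n, 1, spec$er_positive_prev) == 1, "positive", "negative")
  size <- rlnorm(n, spec$tumor_size_meanlog, spec$tumor_size_sdlog)
  grade <- sample(1:3, n, replace = TRUE, prob = c(0.25, 0.45, 0.30))
  age <- round(rnorm(n, 60, 10), 1)

  set.seed(.stream_seed(spec$seed, study_index, "expression"))
  X <- matrix(rnorm(length(genes) * n, sd = spec$noise_sd),
              nrow = length(genes), dimnames = list(genes, samples))
  activity <- matrix(0, nrow = length(spec$enriched_pathway_ids), ncol = n,
                     dimnames = list(spec$enriched_pathway_ids, samples))
  for (pid in spec$enriched_pathway_ids) {
    a <- rnorm(n)
    activity[pid, ] <- a
    members <- intersect(db$pathways[[pid]], genes)
    if (length(members))
      X[members, ] <- X[members, ] + rep(a, each = length(members))
  }

  eta <- spec$beta_pathway * colSums(activity) +
    spec$beta_er * (er == "negative") + spec$beta_size * size
  h <- spec$baseline_hazard[study_index] * exp(eta)
  .assert(all(is.finite(h)), "non-finite hazard: check beta values")
  set.seed(.stream_seed(spec$seed, study_index, "survival"))
  T_event <- rexp(n, rate = h)
  if (spec$censor_rate > 0) {
    rc <- .censor_rate_for(h, spec$censor_rate)
    C <- rexp(n, rate = rc)
  } else C <- rep(Inf, n)
  clinical <- data.frame(sample_id = samples,
                         time = pmin(T_event, C),
                         event = as.integer(T_event <= C),
                         er_status = er, tumor_size = size,
                         grade = grade, age = age,
                         stringsAsFactors = FALSE)
  study <- expression_study(sprintf("study%d", study_index), X, clinical)
  attr(study, "latent_activity") <- activity
  study
}

#' Generate a synthetic multi-study collection
#'
#' All studies share the enriched pathways but have study-specific gene
#' subsets (honoring `gene_overlap_fraction`), sample sizes and baseline
#' hazards, each from its own seeded random stream.
#'
#' @param spec [simulation_spec()].
#' @param db optional pre-generated [pathway_db()]; generated from the spec
#'   if missing.
#' @return list with `studies` (list of [expression_study()]) and `db`.
#' @export
generate_multistudy <- function(spec, db = generate_pathway_db(spec)) {
  studies <- lapply(seq_len(spec$n_studies), function(i)
    generate_cohort(spec, db, i))
  names(studies) <- vapply(studies, `[[`, character(1), "study_name")
  list(studies = studies, db = db)
}
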