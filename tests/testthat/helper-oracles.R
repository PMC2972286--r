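# Independent oracles and fixture builders shared across test files.

# Grid-search maximizer of the 1-covariate Breslow partial log-likelihood:
# the brute-force reference for fit_cox on tiny instances.
grid_cox_beta <- function(time, event, x, beta = seq(-5, 5, by = 1e-4)) {
  ll <- numeric(length(beta))
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(rowSums(exp(outer(beta, x[risk]))))
  }
  beta[which.max(ll)]
}

# All n! orderings of 1..n, enumerated independently of the package's
# internal permutation machinery.
perms_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(n - 1L)
  out <- matrix(0L, 0, n)
  for (first in seq_len(n)) {
    rest <- seq_len(n)[-first]
    out <- rbind(out, cbind(first, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}

# direct transcription of the maxmean definition, kept separate from the
# package implementation
maxmean_direct <- function(z) {
  sp <- sum(pmax(z, 0)) / length(z)
  sn <- sum(pmax(-z, 0)) / length(z)
  if (sp >= sn) sp else -sn
}

# hand-built expression study with arbitrary expression and clinical values
make_study <- function(expr, time, event, er = NULL, size = NULL,
                       name = "test") {
  n <- ncol(expr)
  samples <- colnames(expr) %||% sprintf("s%03d", seq_len(n))
  colnames(expr) <- samples
  clin <- data.frame(sample_id = samples, time = time, event = event,
                     stringsAsFactors = FALSE)
  if (!is.null(er)) clin$er_status <- er
  if (!is.null(size)) clin$tumor_size <- size
  expression_study(name, expr, clin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random survival data with no expression-outcome link
null_surv <- function(n, censor = 0.3) {
  t <- rexp(n, 0.1)
  c <- if (censor > 0) rexp(n, 0.1 * censor / (1 - censor)) else rep(Inf, n)
  list(time = pmin(t, c), event = as.integer(t <= c))
}
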