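# Shared fixtures and independent oracles, built in code at test time.

# Small expression matrix with dimnames.
makeExprMatrix <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

# Fisher-z oracle: probability that |r| of a null gene exceeds `thr` with n
# samples (two-sided normal approximation on atanh scale).
fisherZNullPassRate <- function(thr, n) {
  2 * pnorm(-atanh(thr) * sqrt(n - 3))
}

# Closed-form cutpoint for an exponential single-stratum model with hazard
# h0 at DRP = 0: solves 1 - exp(-h0 t0)^{exp(beta50 d / 50)} = target.
closedFormCutpoint <- function(h0, beta50, t0, target) {
  50 * log(-log(1 - target) / (h0 * t0)) / beta50
}

# Deterministic small cohort for exact-edge tests (no simulation).
makeTinyCohort <- function(n = 30, seed = 42) {
  withr::with_seed(seed, {
    data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      drp = round(runif(n, 0, 100), 1),
      ttp_months = round(rexp(n, 0.1), 3),
      progression = runif(n) < 0.7,
      os_months = round(rexp(n, 0.05), 3),
      death = runif(n) < 0.4,
      line = sample(c("1", "2"), n, replace = TRUE),
      age_group = sample(c("<50", "50-60", "60-70", ">70"), n, TRUE),
      er_status = sample(c("positive", "negative"), n, TRUE,
                         prob = c(0.85, 0.15)),
      n_met_sites = sample(c("1", "2", "3", ">3"), n, TRUE),
      ps = sample(c("0-1", "2"), n, TRUE, prob = c(0.9, 0.1)),
      prior_chemo = runif(n) < 0.5,
      prior_anthracycline = runif(n) < 0.2,
      prior_taxane = runif(n) < 0.2,
      stringsAsFactors = FALSE
    )
  })
}
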