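# Shared fixtures, memoized across test files. The acceptance tests run
# first (alphabetically) and populate the expensive slots; the module tests
# reuse them instead of re-fitting cohorts.

with_seed <- specdcm:::with_seed
edge_index <- specdcm:::edge_index

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# invert every subject of a cohort whose label is in `groups`
fit_group <- function(cohort, groups, max_iter = 10) {
  keep <- which(cohort$labels %in% groups)
  posts <- lapply(keep, function(i) {
    fit_vl(cohort$subjects[[i]]$csd, lead = cohort$lead, max_iter = max_iter)
  })
  list(idx = keep, labels = cohort$labels[keep],
       ids = vapply(cohort$subjects[keep], `[[`, "", "id"),
       posteriors = posts)
}

# default study design (11 control / 6 uws / 12 mcs / 5 holdout), seed 1,
# with the control and uws subjects inverted at the reduced iteration cap
default_fit_cu <- function() cached("default_cu", {
  coh <- make_cohort(cohort_config(), seed = 1)
  c(list(cohort = coh), fit_group(coh, c("control", "uws")))
})

# holdout subjects of the same cohort
default_fit_holdout <- function() cached("default_ho", {
  fit_group(default_fit_cu()$cohort, "holdout")
})

# group-level PEB / model search / model average for the default cohort
default_peb <- function() cached("default_peb", {
  fit <- default_fit_cu()
  fit_peb(fit$posteriors, design_matrix(fit$labels))
})

default_space <- function() cached("default_space", {
  model_search(default_peb(), "exhaustive")
})

default_bma <- function() cached("default_bma", bma(default_space()))

# cohort with a strong (-0.8) backward frontoparietal group effect
strong_fit_cu <- function() cached("strong_cu", {
  uws <- numeric(12)
  uws[edge_index(default_dmn(), "mPFC", "lLP")] <- -0.8
  eff <- list(control = numeric(12), uws = uws, mcs = numeric(12))
  coh <- make_cohort(cohort_config(effects = eff), seed = 1)
  c(list(cohort = coh), fit_group(coh, c("control", "uws")))
})

# fabricate a subject-level posterior with the given coupling means; cheap
# stand-in for classification / group-inference unit tests
fake_posterior <- function(a_mean, sd = 0.08) {
  priors <- default_priors()
  mean <- priors$mean
  mean[1:12] <- a_mean
  structure(list(mean = mean, cov = diag(sd^2, 58),
                 prior = list(mean = priors$mean,
                              variance = priors$variance),
                 free = priors$variance > 1e-6,
                 free_energy = 0, trace = 0,
                 hyper = list(lambda = c(re = 4, im = 4))),
            class = "dcm_posterior")
}
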