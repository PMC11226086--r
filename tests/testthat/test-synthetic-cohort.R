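spec <- default_dmn()
constants <- load_constants()

test_that("configuration is validated", {
  expect_error(cohort_config(n_control = 0), "at least 1")
  expect_error(cohort_config(n_epochs = 0), "n_epochs")
  expect_error(cohort_config(sigma_between = -0.1), "non-negative")
  expect_error(cohort_config(effects = list(control = numeric(12),
                                            uws = numeric(11),
                                            mcs = numeric(12))))
  cfg <- cohort_config()
  expect_identical(c(cfg$n_control, cfg$n_uws, cfg$n_mcs, cfg$n_holdout),
                   c(11L, 6L, 12L, 5L))
  expect_identical(cfg$effects$uws[edge_index(spec, "mPFC", "lLP")], -0.6)
  expect_identical(sum(cfg$effects$uws != 0), 1L)
  expect_identical(cfg$effects$control, numeric(12))
})

test_that("finite-epoch sampling is unbiased, Hermitian and reproducible", {
  lead <- make_lead_field(4, seed = 2)
  freqs <- c(5, 10)
  truth <- predict_csd(dcm_params(), spec, lead, freqs, constants)
  draws <- lapply(1:200, function(s) sample_observed_csd(truth, 20, seed = s))
  avg <- Reduce(`+`, lapply(draws, `[[`, "csd")) / 200
  expect_lt(max(abs(avg - truth$csd)) / max(abs(truth$csd)), 0.05)
  one <- draws[[1]]$csd[, , 1]
  expect_lt(max(abs(one - Conj(t(one)))), 1e-12)
  ev <- eigen(one, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(Re(ev)), 0)
  expect_identical(sample_observed_csd(truth, 20, seed = 5)$csd,
                   sample_observed_csd(truth, 20, seed = 5)$csd)
  expect_error(sample_observed_csd(truth, 3), "at least the matrix dimension")
})

test_that("cohort generation is deterministic with the designed structure", {
  cfg <- cohort_config(n_control = 2, n_uws = 2, n_mcs = 2, n_holdout = 1,
                       n_epochs = 12, n_modes = NULL)
  coh1 <- make_cohort(cfg, seed = 3)
  coh2 <- make_cohort(cfg, seed = 3)
  coh3 <- make_cohort(cfg, seed = 4)
  expect_identical(coh1$labels,
                   c("control", "control", "uws", "uws", "mcs", "mcs",
                     "holdout"))
  expect_identical(vec_params(coh1$subjects[[1]]$truth),
                   vec_params(coh2$subjects[[1]]$truth))
  expect_identical(coh1$subjects[[3]]$csd$csd, coh2$subjects[[3]]$csd$csd)
  expect_false(identical(coh1$subjects[[1]]$csd$csd,
                         coh3$subjects[[1]]$csd$csd))
  # subjects differ from one another; non-coupling parameters stay at 0
  expect_false(identical(coh1$subjects[[1]]$truth$a, coh1$subjects[[2]]$truth$a))
  expect_identical(coh1$subjects[[1]]$truth$intrinsic, matrix(0, 4, 8,
    dimnames = list(NULL, c("He", "Hi", "tau_e", "tau_i", paste0("g", 1:4)))))
  # observation space: channels when no mode reduction is requested
  expect_identical(dim(coh1$subjects[[1]]$csd$csd)[1], 8L)
  expect_identical(coh1$lead$matrix, coh1$channel_lead$matrix)
})

test_that("mode projection reduces the observation space consistently", {
  cfg <- cohort_config(n_control = 1, n_uws = 1, n_mcs = 1, n_holdout = 1,
                       n_epochs = 12, n_modes = 4)
  coh <- make_cohort(cfg, seed = 5)
  expect_identical(dim(coh$subjects[[1]]$csd$csd)[1], 4L)
  expect_identical(dim(coh$lead$matrix), c(4L, 4L))
  expect_identical(dim(coh$projection), c(8L, 4L))
  # the projection is orthonormal
  expect_lt(max(abs(Conj(t(coh$projection)) %*% coh$projection - diag(4))),
            1e-10)
})

test_that("cohorts round-trip through the on-disk layout", {
  cfg <- cohort_config(n_control = 1, n_uws = 1, n_mcs = 1, n_holdout = 1,
                       n_epochs = 12, freqs = seq(2, 20, by = 1))
  coh <- make_cohort(cfg, seed = 6)
  td <- tempfile()
  write_cohort(coh, td)
  again <- read_cohort(td)
  expect_identical(again$labels, coh$labels)
  expect_identical(vapply(again$subjects, `[[`, "", "id"),
                   vapply(coh$subjects, `[[`, "", "id"))
  expect_equal(vec_params(again$subjects[[2]]$truth),
               vec_params(coh$subjects[[2]]$truth))
  expect_identical(again$subjects[[2]]$csd$csd, coh$subjects[[2]]$csd$csd)
  expect_equal(again$lead$matrix, coh$lead$matrix)
})
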