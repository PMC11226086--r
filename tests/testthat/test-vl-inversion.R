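spec <- default_dmn()
constants <- load_constants()

test_that("Welch estimation finds a planted spectral peak", {
  sfreq <- 250
  n <- sfreq * 60
  t <- seq_len(n) / sfreq
  set.seed(7)
  X <- rbind(sin(2 * pi * 8 * t) + rnorm(n, 0, 0.3),
             rnorm(n, 0, 0.3))
  rec <- recording(X, sfreq, labels = c("sig", "noise"))
  w <- welch_csd(rec, epoch_len = 2, band = c(1, 30))
  peak <- w$freqs[which.max(Re(w$csd[1, 1, ]))]
  expect_lt(abs(peak - 8), 0.6)
  # planted channel dominates; spectra are Hermitian with positive diagonals
  expect_gt(max(Re(w$csd[1, 1, ])), 10 * max(Re(w$csd[2, 2, ])))
  expect_lt(max(abs(w$csd[1, 2, ] - Conj(w$csd[2, 1, ]))), 1e-12)
})

test_that("feature extraction and the CSD container round-trip", {
  lead <- make_lead_field(8, seed = 1)
  pred <- predict_csd(dcm_params(), spec, lead, default_freqs(), constants)
  f <- featurize_csd(pred)
  back <- defeaturize_csd(f, meta = pred$meta)
  expect_lt(max(abs(back$csd - pred$csd)), 1e-12)
  # real and imaginary blocks are labelled and sized consistently
  expect_identical(length(f$y), length(f$blocks))
  expect_identical(sort(unique(f$blocks)), c("im", "re"))
  td <- tempfile()
  write_csd(pred, td)
  again <- read_csd(td)
  expect_identical(again$csd, pred$csd)
  expect_identical(again$freqs, pred$freqs)
})

test_that("generic variational Laplace improves monotonically on a nonlinear model", {
  set.seed(11)
  n <- 60L
  x <- seq(0, 3, length.out = n)
  y <- exp(0.7 * x) + rnorm(n, 0, 0.4)
  fit <- fit_vl_generic(y, rep("b", n),
                        function(th) exp(th[1] * x),
                        prior_mean = 0, prior_var = 1,
                        hyper = list(mean = 1, var = 4))
  expect_true(all(diff(fit$trace) > -1e-9))
  expect_lt(abs(fit$mean[1] - 0.7), 0.05)
})

test_that("subject inversion recovers structure and reports free energy", {
  fit <- default_fit_cu()
  post <- fit$posteriors[[1]]
  expect_s3_class(post, "dcm_posterior")
  expect_length(post$mean, 58L)
  expect_identical(dim(post$cov), c(58L, 58L))
  # 12 couplings + 4 innovation amplitudes + 2 noise amplitudes are free
  expect_identical(sum(post$free), 18L)
  pinned <- which(!post$free)
  expect_lt(max(abs(post$mean[pinned])), 1e-6)
  expect_true(all(diff(post$trace) > -1e-9))
  # reported free energy is reproducible from the returned mode
  f <- free_energy(post$mean, fit$cohort$subjects[[fit$idx[1]]]$csd,
                   default_priors(), hyper = post$hyper$lambda,
                   lead = fit$cohort$lead)
  expect_lt(abs(f - post$free_energy) / abs(post$free_energy), 0.02)
})

test_that("posterior containers round-trip through disk", {
  post <- default_fit_cu()$posteriors[[1]]
  td <- tempfile()
  write_posterior(post, td)
  again <- read_posterior(td)
  expect_equal(again$mean, post$mean)
  expect_equal(unname(again$cov), unname(post$cov), tolerance = 1e-12)
  expect_equal(again$free_energy, post$free_energy)
  expect_identical(again$free, post$free)
})

test_that("coupling marginals expose matching prior moments", {
  post <- default_fit_cu()$posteriors[[1]]
  cp <- coupling_posterior(post)
  expect_length(cp$mean, 12L)
  expect_identical(dim(cp$cov), c(12L, 12L))
  expect_identical(cp$prior_mean, default_priors()$mean[1:12])
  expect_identical(cp$prior_var, default_priors()$variance[1:12])
  ev <- eigen(cp$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("derived seeds are deterministic, tagged and in range", {
  expect_identical(derive_seed(1L, "cohort"), derive_seed(1L, "cohort"))
  expect_false(derive_seed(1L, "cohort") == derive_seed(2L, "cohort"))
  expect_false(derive_seed(1L, "cohort") == derive_seed(1L, "permutation"))
  s <- vapply(1:50, function(i) derive_seed(i, "x"), integer(1))
  expect_true(all(s >= 1 & s <= 2147483647))
  expect_identical(anyDuplicated(s), 0L)
})
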