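# well separated fabricated cohort on one edge
sep_cohort <- function(edge = 6, delta = -0.8, n_per = 8, seed = 31) {
  with_seed(seed, {
    posts <- list()
    labels <- character(0)
    for (g in c("control", "uws")) {
      centre <- numeric(12)
      if (g == "uws") centre[edge] <- delta
      for (i in seq_len(n_per)) {
        posts[[length(posts) + 1]] <-
          fake_posterior(centre + rnorm(12, 0, 0.05))
        labels <- c(labels, g)
      }
    }
    list(posteriors = posts, labels = labels)
  })
}

test_that("membership probabilities are proper and label-symmetric", {
  s <- sep_cohort()
  p <- predict_membership(s$posteriors[-1], s$labels[-1], s$posteriors[[1]],
                          subset = 6)
  expect_named(p, c("control", "uws"))
  expect_equal(sum(p), 1)
  expect_gt(p[["control"]], 0.9)
  # an unambiguous unconscious-like subject goes the other way
  q <- predict_membership(s$posteriors[-16], s$labels[-16], s$posteriors[[16]],
                          subset = 6)
  expect_gt(q[["uws"]], 0.9)
  expect_error(predict_membership(s$posteriors[1:3], s$labels[c(1, 2, 3)],
                                  s$posteriors[[4]], subset = integer(0)),
               "non-empty")
  expect_error(predict_membership(s$posteriors[1:3], rep("control", 3),
                                  s$posteriors[[4]], subset = 6),
               "both groups")
})

test_that("crossvalidation separates a strong fabricated effect perfectly", {
  s <- sep_cohort()
  cv <- losocv(s$posteriors, s$labels, subset = 6)
  expect_s3_class(cv, "crossval_result")
  expect_identical(cv$accuracy, 1)
  expect_identical(cv$balanced_accuracy, 1)
  expect_identical(nrow(cv$table), 16L)
  expect_identical(cv$positive, "control")
  # folds never contain the held-out subject
  expect_true(all(vapply(seq_along(cv$folds),
                         function(i) !(i %in% cv$folds[[i]]), logical(1))))
  # an uninformative edge cannot separate the groups
  cv0 <- losocv(s$posteriors, s$labels, subset = 2)
  expect_lt(cv0$balanced_accuracy, 0.8)
  expect_error(losocv(s$posteriors, rep("control", 16), subset = 6),
               "two groups")
})

test_that("state generalization scores an unseen group", {
  s <- sep_cohort()
  test <- with_seed(77, lapply(1:4, function(i) {
    fake_posterior(rnorm(12, 0, 0.05))  # conscious-like couplings
  }))
  res <- leave_one_state_out(s$posteriors, s$labels, test, subset = 6,
                             ids = paste0("h", 1:4))
  expect_identical(res$table$id, paste0("h", 1:4))
  expect_true(all(res$table$assigned == "control"))
  expect_identical(unname(res$fractions["control"]), 1)
  expect_error(leave_one_state_out(s$posteriors, s$labels, list(), subset = 6),
               "empty")
})

test_that("stepwise selection finds the discriminative connection first", {
  s <- sep_cohort()
  ranking <- c(6L, 2L, 9L)
  st <- stepwise_subset(s$posteriors, s$labels, ranking)
  expect_identical(st$subset, 6L)
  expect_identical(st$accuracy, 1)
  expect_identical(st$steps$subset[1:3], c("6", "2", "9"))
})

test_that("fitted cohorts separate on the affected frontoparietal edge", {
  fit <- strong_fit_cu()
  cv_true <- losocv(fit$posteriors, fit$labels, subset = 6)
  cv_null <- losocv(fit$posteriors, fit$labels, subset = 11)
  expect_gt(cv_true$balanced_accuracy, cv_null$balanced_accuracy)
  # full-subset classifier also works on this strong effect
  cv_full <- losocv(fit$posteriors, fit$labels, subset = 1:12)
  expect_gte(cv_full$balanced_accuracy, 0.8)
})
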