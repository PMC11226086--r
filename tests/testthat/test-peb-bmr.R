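spec <- default_dmn()

# two fabricated groups of subject posteriors separated by +0.2 on one edge
make_fake_groups <- function(edge, delta = 0.2, n_per = 10, sd_between = 0.05,
                             seed = 21) {
  with_seed(seed, {
    posts <- list()
    labels <- character(0)
    for (g in 1:2) {
      centre <- numeric(12)
      if (g == 2) centre[edge] <- delta
      for (i in seq_len(n_per)) {
        posts[[length(posts) + 1]] <-
          fake_posterior(centre + rnorm(12, 0, sd_between))
        labels <- c(labels, c("g1", "g2")[g])
      }
    }
    list(posteriors = posts, labels = labels)
  })
}

test_that("the design matrix centres a two-level group indicator", {
  X <- design_matrix(factor(c("a", "a", "b", "b", "b")))
  expect_identical(colnames(X), c("commonalities", "group"))
  expect_identical(X[, 1], rep(1, 5))
  expect_lt(abs(sum(X[, 2])), 1e-12)
  expect_identical(attr(X, "levels"), c("a", "b"))
  expect_error(design_matrix(factor(c("a", "a"))), "two group levels")
})

test_that("PEB recovers a planted +0.2 group difference", {
  g <- make_fake_groups(edge = 3)
  peb <- fit_peb(g$posteriors, design_matrix(g$labels))
  expect_s3_class(peb, "peb_posterior")
  diff_row <- peb$beta["group", ]
  expect_lt(abs(diff_row[3] - 0.2), 0.06)
  expect_lt(max(abs(diff_row[-3])), 0.06)
  # commonalities near zero for both groups centred on the prior mean
  expect_lt(max(abs(peb$beta["commonalities", -3])), 0.06)
})

test_that("model averaging concentrates on the true effect", {
  # detection (as opposed to estimation) needs an effect that is large
  # against the fixed random-effects floor (sd 0.125 per coupling), so this
  # fixture plants 0.3 rather than the 0.2 used for the recovery check
  g <- make_fake_groups(edge = 3, delta = 0.3, n_per = 12)
  peb <- fit_peb(g$posteriors, design_matrix(g$labels))
  bm <- bma(model_search(peb, "exhaustive"))
  tab <- bm$effects[bm$effects$covariate == bm$covariate, ]
  expect_gt(tab$pp[tab$edge_index == 3], 0.99)
  expect_gt(tab$effect[tab$edge_index == 3], 0.1)
  expect_lt(max(tab$pp[tab$edge_index != 3]), 0.9)
  thr <- threshold_bma(bm)
  expect_identical(thr$retained$edge_index, 3L)
  rk <- rank_connections(bm)
  expect_identical(rk[1], 3L)
  expect_length(rk, 12L)
})

test_that("greedy backward search lands on the exhaustive optimum", {
  g <- make_fake_groups(edge = 5, n_per = 8)
  peb <- fit_peb(g$posteriors, design_matrix(g$labels))
  ex <- model_search(peb, "exhaustive")
  gr <- model_search(peb, "greedy")
  best_ex <- ex$patterns[which.max(ex$dlogz), ]
  best_gr <- gr$patterns[which.max(gr$dlogz), ]
  expect_identical(unname(best_gr), unname(best_ex))
  expect_lt(abs(max(gr$dlogz) - max(ex$dlogz)), 1e-9)
})

test_that("reduction rejects impossible requests", {
  expect_error(bmr(c(0, 0), diag(-1, 2), c(0, 0), diag(2), c(0, 0), diag(2)),
               "not positive definite")
  expect_error(bmr(c(0, 0), diag(2), c(0, 0), diag(1e-8, 2), c(0, 0),
                   diag(10, 2)),
               "not positive definite")
  expect_error(threshold_bma(default_bma(), pp = 1), "in \\(0, 1\\)")
  expect_error(fit_peb(list(fake_posterior(numeric(12))),
                       matrix(1, 1, 1)), "at least 3 subjects")
})

test_that("subjects with mismatched priors are refused", {
  g <- make_fake_groups(edge = 1, n_per = 2)
  odd <- fake_posterior(numeric(12))
  odd$prior$variance[1:12] <- 99
  expect_error(fit_peb(c(g$posteriors, list(odd)),
                       design_matrix(c(g$labels, "g1"))),
               "mismatched coupling priors")
})
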