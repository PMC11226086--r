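# Predictive classification of group membership from fitted couplings:
# leave-one-subject-out and leave-one-state-out cross-validation over
# hypothesis-driven and data-driven connection subsets.

# multivariate normal log density
mvn_logpdf <- function(x, mu, S) {
  cS <- chol((S + t(S)) / 2)
  z <- backsolve(cS, x - mu, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(cS))) + sum(z^2))
}

#' Posterior probability of group membership for one held-out subject
#'
#' Fits PEB on the training subjects (restricted to an edge subset), forms
#' the label-conditional empirical prior over the held-out subject's
#' couplings for each candidate group, evaluates the held-out subject's
#' model evidence under each, and converts the evidences to membership
#' probabilities by Bayes rule with equal label priors.
#'
#' @param train_posteriors list of `dcm_posterior` for the training subjects.
#' @param train_labels their group labels (two levels present).
#' @param test_posterior `dcm_posterior` of the held-out subject.
#' @param subset integer edge indices used for prediction (non-empty).
#' @param re_scale passed to [fit_peb()].
#' @return Named numeric vector of membership probabilities over the two
#'   training labels (sums to 1).
#' @export
predict_membership <- function(train_posteriors, train_labels, test_posterior,
                               subset = 1:12, re_scale = 1 / 16) {
  if (!length(subset)) stop("subset must be non-empty")
  train_labels <- as.factor(train_labels)
  if (nlevels(droplevels(train_labels)) < 2L) {
    stop("training set must contain both groups")
  }
  X <- design_matrix(droplevels(train_labels))
  peb <- fit_peb(train_posteriors, X, subset = subset, re_scale = re_scale)
  lev <- attr(X, "levels")
  xvals <- attr(X, "level_values")
  q <- length(subset)
  tl <- subject_likelihood(test_posterior, subset = subset)
  logev <- vapply(seq_along(lev), function(g) {
    M <- kronecker(matrix(c(1, xvals[g]), 1, 2), diag(q))  # q x 2q
    mu <- as.numeric(M %*% peb$mean)
    V <- peb$Q + M %*% peb$cov %*% t(M)
    mvn_logpdf(tl$mean, mu, V + tl$cov)
  }, numeric(1))
  w <- exp(logev - max(logev))
  stats::setNames(w / sum(w), lev)
}

#' Leave-one-subject-out cross-validated classification
#'
#' Iteratively holds out each subject, fits PEB on the rest, and predicts
#' the held-out subject's group membership. A posterior probability above 0.5
#' counts as a positive classification for the confusion matrix.
#'
#' @param posteriors list of `dcm_posterior` (one per subject).
#' @param labels group labels (two levels, >= 2 subjects per class).
#' @param subset edge indices used for prediction.
#' @param positive the label treated as the positive class; default the first
#'   level.
#' @param ids optional subject identifiers.
#' @return A `crossval_result`: per-subject probabilities, confusion counts at
#'   the 0.5 cut, accuracy and balanced accuracy, and the per-fold training
#'   membership for leakage auditing.
#' @export
losocv <- function(posteriors, labels, subset = 1:12, positive = NULL,
                   ids = NULL) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two groups required")
  if (any(table(labels) < 2L)) stop("at least 2 subjects per class required")
  n <- length(posteriors)
  stopifnot(length(labels) == n)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  if (is.null(positive)) positive <- levels(labels)[1]
  pp <- numeric(n)
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    p <- predict_membership(posteriors[tr], labels[tr], posteriors[[i]],
                            subset = subset)
    pp[i] <- p[[positive]]
    folds[[i]] <- tr
  }
  truth <- labels == positive
  pred <- pp > 0.5
  confusion <- table(truth = factor(truth, c(TRUE, FALSE)),
                     predicted = factor(pred, c(TRUE, FALSE)))
  sens <- mean(pred[truth])
  spec_ <- mean(!pred[!truth])
  structure(list(table = data.frame(id = ids, label = labels, pp = pp),
                 subset = subset, positive = positive,
                 confusion = confusion,
                 accuracy = mean(pred == truth),
                 balanced_accuracy = (sens + spec_) / 2,
                 folds = folds),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("crossval_result: %d subjects, positive = %s, accuracy %.2f, balanced %.2f\n",
              nrow(x$table), x$positive, x$accuracy, x$balanced_accuracy))
  print(x$confusion)
  invisible(x)
}

#' Leave-one-state-out classification
#'
#' Trains PEB on two labelled groups and scores every subject of an unseen
#' third group, reporting per-subject membership probabilities and the
#' fraction assigned to each training class at the 0.5 cut.
#'
#' @param train_posteriors,train_labels the two labelled training groups.
#' @param test_posteriors list of posteriors for the held-out state (non-empty).
#' @param subset edge indices used for prediction.
#' @param ids optional test-subject identifiers.
#' @return List with `table` (per-test-subject probabilities for both
#'   training labels) and `fractions` (proportion assigned to each label).
#' @export
leave_one_state_out <- function(train_posteriors, train_labels,
                                test_posteriors, subset = 1:12, ids = NULL) {
  if (!length(test_posteriors)) stop("test group is empty")
  if (is.null(ids)) ids <- paste0("t", seq_along(test_posteriors))
  pps <- t(vapply(test_posteriors, function(tp) {
    predict_membership(train_posteriors, train_labels, tp, subset = subset)
  }, numeric(2)))
  lev <- colnames(pps)
  assigned <- lev[max.col(pps)]
  list(table = data.frame(id = ids, pps, assigned = assigned,
                          check.names = FALSE),
       fractions = stats::setNames(colMeans(pps > 0.5), lev))
}

#' Rank connections by group-effect magnitude
#'
#' Orders edges by the absolute expected group-difference effect from a model
#' average, largest first; ties are broken by the lower canonical edge index.
#'
#' @param bma_res a `bma_result`.
#' @return Integer vector of edge indices, most affected first.
#' @export
rank_connections <- function(bma_res) {
  tab <- bma_res$effects[bma_res$effects$covariate == bma_res$covariate, ]
  tab$edge_index[order(-abs(tab$effect), tab$edge_index)]
}

#' Forward stepwise selection of a predictive connection subset
#'
#' Evaluates single connections in effect-rank order by balanced LOSOCV
#' accuracy, then grows the best single greedily (adding remaining
#' connections in order of their single-connection accuracy) and stops at the
#' first addition that fails to improve balanced accuracy. Deterministic
#' given its inputs.
#'
#' @param posteriors,labels the cohort to cross-validate.
#' @param ranking edge indices in descending effect order (from
#'   [rank_connections()]).
#' @param positive positive class passed to [losocv()].
#' @return List with `subset` (the selected edge indices), `accuracy`, and a
#'   `steps` data.frame tracing every evaluation.
#' @export
stepwise_subset <- function(posteriors, labels, ranking, positive = NULL) {
  if (!length(ranking)) stop("ranking must be non-empty")
  singles <- vapply(ranking, function(e) {
    losocv(posteriors, labels, subset = e, positive = positive)$balanced_accuracy
  }, numeric(1))
  steps <- data.frame(subset = as.character(ranking), accuracy = singles)
  ord <- order(-singles, seq_along(ranking))  # ties: earlier rank first
  best <- ranking[ord[1]]
  best_acc <- singles[ord[1]]
  subset <- best
  if (best_acc < 1) {
    for (k in ord[-1]) {
      cand <- c(subset, ranking[k])
      acc <- losocv(posteriors, labels, subset = cand,
                    positive = positive)$balanced_accuracy
      steps <- rbind(steps, data.frame(subset = paste(cand, collapse = "+"),
                                       accuracy = acc))
      if (acc > best_acc) {
        subset <- cand
        best_acc <- acc
      } else break
    }
  }
  list(subset = subset, accuracy = best_acc, steps = steps)
}
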