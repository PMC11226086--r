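# Group-level parametric empirical Bayes over subject coupling posteriors,
# analytic Bayesian model reduction, model-space search and Bayesian model
# averaging.

#' Group design matrix
#'
#' Column 1 is the intercept (commonalities); column 2 a mean-centred group
#' indicator; further covariates are passed through unchanged.
#'
#' @param labels factor (or coercible) of subject group labels with exactly
#'   two levels.
#' @return Numeric matrix with column names `commonalities`, `group`.
#' @export
design_matrix <- function(labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two group levels required")
  ind <- as.numeric(labels == levels(labels)[2])
  X <- cbind(commonalities = 1, group = ind - mean(ind))
  attr(X, "levels") <- levels(labels)
  attr(X, "level_values") <- c(0, 1) - mean(ind)
  X
}

# extract the approximate likelihood of subject couplings by removing the
# prior from the posterior (precisions subtract); eigenvalues floored to keep
# the likelihood proper when the data are uninformative on some direction
subject_likelihood <- function(post, subset = 1:12) {
  cp <- coupling_posterior(post)
  idx <- subset
  S <- cp$cov[idx, idx, drop = FALSE]
  Pi_post <- chol2inv(chol((S + t(S)) / 2))
  Pi0 <- diag(1 / cp$prior_var[idx], length(idx))
  Pl <- Pi_post - Pi0
  E <- eigen((Pl + t(Pl)) / 2, symmetric = TRUE)
  ev <- pmax(E$values, 1e-6)
  Pl <- E$vectors %*% (ev * t(E$vectors))
  h <- Pi_post %*% cp$mean[idx] - Pi0 %*% cp$prior_mean[idx]
  m <- as.numeric(solve(Pl, h))
  list(mean = m, prec = Pl, cov = chol2inv(chol(Pl)))
}

#' Parametric empirical Bayes over subject posteriors
#'
#' Places a GLM over the subjects' extrinsic-coupling estimates: each
#' subject's couplings are modelled as designed group effects plus Gaussian
#' between-subject random effects with fixed diagonal covariance (first-level
#' prior variance / 16 per coupling, configurable). Subjects are weighted by
#' their first-level posterior precisions (with the first-level prior
#' removed), and the model is linear-Gaussian, so the group posterior and the
#' second-level free energy are computed in closed form.
#'
#' @param posteriors list of `dcm_posterior` objects (>= 3 subjects).
#' @param X design matrix from [design_matrix()] (full column rank, one row
#'   per subject).
#' @param subset integer edge indices to model (default all 12).
#' @param re_scale random-effect variance as a fraction of the first-level
#'   prior variance (default 1/16).
#' @param beta_var prior variance of each group-effect coefficient; default is
#'   the first-level coupling prior variance.
#' @return A `peb_posterior` with `beta` (covariates x couplings matrix),
#'   full `cov`, `free_energy`, and the ingredients needed for model reduction
#'   and prediction.
#' @export
fit_peb <- function(posteriors, X, subset = 1:12, re_scale = 1 / 16,
                    beta_var = NULL) {
  n <- length(posteriors)
  if (n < 3L) stop("at least 3 subjects required")
  if (!is.matrix(X) || nrow(X) != n) stop("X must have one row per subject")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  q <- length(subset)
  nc <- ncol(X)
  lik <- lapply(posteriors, subject_likelihood, subset = subset)
  pv <- coupling_posterior(posteriors[[1]])$prior_var[subset]
  for (p in posteriors[-1]) {
    if (!isTRUE(all.equal(coupling_posterior(p)$prior_var[subset], pv))) {
      stop("subjects have mismatched coupling priors")
    }
  }
  Q <- diag(pv * re_scale, q)
  if (is.null(beta_var)) beta_var <- rep(pv, nc)
  if (length(beta_var) == 1L) beta_var <- rep(beta_var, nc * q)
  if (length(beta_var) != nc * q) stop("beta_var must be scalar or length covariates x couplings")
  Sigma0 <- diag(beta_var, nc * q)          # prior over beta, covariate-major
  Pi_beta <- solve(Sigma0)
  h <- numeric(nc * q)
  const <- 0
  quad_data <- 0
  for (i in seq_len(n)) {
    V <- lik[[i]]$cov + Q
    W <- chol2inv(chol((V + t(V)) / 2))
    # precision contribution: (x_i x_i') kron W
    xx <- tcrossprod(X[i, ])
    Pi_beta <- Pi_beta + kronecker(xx, W)
    h <- h + as.numeric(kronecker(X[i, ], W %*% lik[[i]]$mean))
    const <- const - 0.5 * (q * log(2 * pi) + determinant(V)$modulus[1])
    quad_data <- quad_data + as.numeric(t(lik[[i]]$mean) %*% W %*% lik[[i]]$mean)
  }
  Sigma_beta <- chol2inv(chol((Pi_beta + t(Pi_beta)) / 2))
  mu <- as.numeric(Sigma_beta %*% h)
  Fpeb <- const - 0.5 * (quad_data - sum(mu * (Pi_beta %*% mu))) -
    0.5 * (determinant(Sigma0)$modulus[1] + determinant(Pi_beta)$modulus[1])
  beta <- matrix(mu, nc, q, byrow = TRUE,
                 dimnames = list(colnames(X), names(pv)))
  structure(list(beta = beta, mean = mu, cov = Sigma_beta,
                 prior_mean = numeric(nc * q), prior_cov = Sigma0,
                 free_energy = Fpeb, Q = Q, X = X, subset = subset,
                 covariates = colnames(X), prior_var_couplings = pv,
                 n_subjects = n),
            class = "peb_posterior")
}

#' @export
print.peb_posterior <- function(x, ...) {
  cat(sprintf("peb_posterior: %d covariates x %d couplings over %d subjects, F = %.2f\n",
              length(x$covariates), length(x$subset), x$n_subjects,
              x$free_energy))
  invisible(x)
}

#' Bayesian model reduction for Gaussian posteriors
#'
#' Given a full model's Gaussian prior and posterior, computes analytically
#' the change in log evidence and the posterior that would have been obtained
#' under a different ("reduced") prior — typically one with parameters pinned
#' to zero with negligible variance.
#'
#' @param post_mean,post_cov full-model posterior.
#' @param prior_mean,prior_cov full-model prior.
#' @param red_mean,red_cov reduced prior.
#' @return List with `dlogz` (log-evidence change, nats), `mean` and `cov` of
#'   the reduced posterior.
#' @export
bmr <- function(post_mean, post_cov, prior_mean, prior_cov,
                red_mean, red_cov) {
  chk <- function(S, nm) {
    ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop(nm, " covariance is not positive definite")
  }
  chk(post_cov, "posterior"); chk(prior_cov, "prior"); chk(red_cov, "reduced prior")
  Pi <- chol2inv(chol(post_cov))
  Pi0 <- chol2inv(chol(prior_cov))
  Pir <- chol2inv(chol(red_cov))
  Pip <- Pi + Pir - Pi0
  evp <- eigen((Pip + t(Pip)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(evp) <= 0) stop("reduced posterior precision is not positive definite")
  Sp <- chol2inv(chol((Pip + t(Pip)) / 2))
  hh <- Pi %*% post_mean + Pir %*% red_mean - Pi0 %*% prior_mean
  mp <- as.numeric(Sp %*% hh)
  ld <- function(S) determinant(S)$modulus[1]
  dlogz <- 0.5 * (ld(Sp) - ld(post_cov) - ld(red_cov) + ld(prior_cov)) +
    0.5 * (as.numeric(t(hh) %*% Sp %*% hh) -
             as.numeric(t(post_mean) %*% Pi %*% post_mean) -
             as.numeric(t(red_mean) %*% Pir %*% red_mean) +
             as.numeric(t(prior_mean) %*% Pi0 %*% prior_mean))
  list(dlogz = dlogz, mean = mp, cov = Sp)
}

# reduced prior for a PEB posterior with the given group-effect switches off
# (pinned to mean 0, variance pin_var)
reduce_prior <- function(peb, off, pin_var = 1e-8) {
  red_cov <- peb$prior_cov
  red_mean <- peb$prior_mean
  if (length(off)) {
    red_cov[off, ] <- 0; red_cov[, off] <- 0
    diag(red_cov)[off] <- pin_var
    red_mean[off] <- 0
  }
  list(mean = red_mean, cov = red_cov)
}

# indices (into the stacked beta vector, covariate-major) of the switchable
# group-difference effects
switch_indices <- function(peb, covariate = 2L) {
  q <- length(peb$subset)
  (covariate - 1L) * q + seq_len(q)
}

#' Search the space of reduced group models
#'
#' Scores nested models that switch individual group-difference effects off
#' (pinned to zero), either exhaustively over all on/off patterns or by a
#' greedy backward search that keeps discarding the parameter whose removal
#' least harms — and does not decrease — the free energy.
#'
#' @param peb a `peb_posterior`.
#' @param strategy `"exhaustive"` (all `2^k` patterns; `k <= 16`) or
#'   `"greedy"`.
#' @param covariate which covariate's effects are switchable (default 2, the
#'   group difference).
#' @param pin_var variance used to pin a switched-off effect.
#' @return A `model_space`: the scored on/off patterns with their
#'   log-evidence changes relative to the full model.
#' @export
model_search <- function(peb, strategy = c("exhaustive", "greedy"),
                         covariate = 2L, pin_var = 1e-8) {
  strategy <- match.arg(strategy)
  sw <- switch_indices(peb, covariate)
  k <- length(sw)
  score <- function(pattern) {  # pattern: logical, TRUE = on
    off <- sw[!pattern]
    rp <- reduce_prior(peb, off, pin_var)
    bmr(peb$mean, peb$cov, peb$prior_mean, peb$prior_cov, rp$mean, rp$cov)$dlogz
  }
  if (strategy == "exhaustive") {
    if (k > 16L) {
      stop("exhaustive search over ", k,
           " parameters is too large; use strategy = 'greedy'")
    }
    patterns <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), k)))
    colnames(patterns) <- names(sw) <- paste0("e", seq_len(k))
    dlogz <- apply(patterns, 1, score)
  } else {
    cur <- rep(TRUE, k)
    cur_F <- score(cur)
    patterns <- matrix(cur, 1, k)
    dlogz <- cur_F
    repeat {
      on <- which(cur)
      if (!length(on)) break
      cand_F <- vapply(on, function(j) {
        p <- cur; p[j] <- FALSE; score(p)
      }, numeric(1))
      best <- which.max(cand_F)
      if (cand_F[best] >= cur_F) {
        cur[on[best]] <- FALSE
        cur_F <- cand_F[best]
        patterns <- rbind(patterns, cur)
        dlogz <- c(dlogz, cur_F)
      } else break
    }
  }
  structure(list(peb = peb, switch_idx = sw, patterns = patterns,
                 dlogz = as.numeric(dlogz), strategy = strategy,
                 pin_var = pin_var, covariate = covariate),
            class = "model_space")
}

#' Bayesian model average over the best reduced models
#'
#' Averages the reduced posteriors of the highest-evidence models (at most
#' `top`, default 256) weighted by their softmaxed log evidences, and reports
#' for every switchable connection the posterior probability of the effect
#' being present (total probability of the models in which it is on) and its
#' probability-weighted expected effect.
#'
#' @param space a `model_space` from [model_search()].
#' @param top number of best models to average (default 256).
#' @return A `bma_result` with a per-connection `effects` table (covariate,
#'   connection, expected effect, `pp`) and the averaged `models` with their
#'   probabilities (summing to 1).
#' @export
bma <- function(space, top = 256L) {
  stopifnot(inherits(space, "model_space"))
  n_mod <- length(space$dlogz)
  if (!n_mod) stop("empty model space")
  ord <- order(space$dlogz, decreasing = TRUE)
  keep <- ord[seq_len(min(top, n_mod))]
  lz <- space$dlogz[keep]
  w <- exp(lz - max(lz))
  w <- w / sum(w)
  peb <- space$peb
  sw <- space$switch_idx
  q <- length(peb$subset)
  nc <- length(peb$covariates)
  avg_mean <- numeric(nc * q)
  pp_on <- numeric(length(sw))
  for (j in seq_along(keep)) {
    pat <- space$patterns[keep[j], ]
    rp <- reduce_prior(peb, sw[!pat], space$pin_var)
    red <- bmr(peb$mean, peb$cov, peb$prior_mean, peb$prior_cov,
               rp$mean, rp$cov)
    avg_mean <- avg_mean + w[j] * red$mean
    pp_on <- pp_on + w[j] * as.numeric(pat)
  }
  eff <- matrix(avg_mean, nc, q, byrow = TRUE)
  connection <- names(peb$prior_var_couplings)
  tab <- do.call(rbind, lapply(seq_len(nc), function(ci) {
    data.frame(covariate = peb$covariates[ci],
               connection = connection,
               edge_index = peb$subset,
               effect = eff[ci, ],
               pp = if (ci == space$covariate) pp_on else 1)
  }))
  rownames(tab) <- NULL
  structure(list(effects = tab,
                 models = data.frame(
                   pattern = apply(space$patterns[keep, , drop = FALSE], 1,
                                   function(p) paste(as.integer(p), collapse = "")),
                   prob = w),
                 covariate = peb$covariates[space$covariate],
                 subset = peb$subset),
            class = "bma_result")
}

#' @export
print.bma_result <- function(x, ...) {
  cat("bma_result over", nrow(x$models), "models; difference covariate:",
      x$covariate, "\n")
  print(x$effects[x$effects$covariate == x$covariate, ])
  invisible(x)
}

#' Threshold a model average by posterior probability
#'
#' Retains connections whose posterior probability of being present strictly
#' exceeds the threshold; sub-threshold connections are reported separately
#' as "faded".
#'
#' @param bma_res a `bma_result`.
#' @param pp probability threshold in (0, 1); default 0.99, applied strictly.
#' @param covariate covariate whose effects are thresholded (default the
#'   difference covariate).
#' @return List with data.frames `retained` and `faded`.
#' @export
threshold_bma <- function(bma_res, pp = 0.99, covariate = NULL) {
  if (!is.numeric(pp) || pp <= 0 || pp >= 1) stop("threshold must lie in (0, 1)")
  if (is.null(covariate)) covariate <- bma_res$covariate
  tab <- bma_res$effects[bma_res$effects$covariate == covariate, ]
  list(retained = tab[tab$pp > pp, , drop = FALSE],
       faded = tab[tab$pp <= pp, , drop = FALSE])
}
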