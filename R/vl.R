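# Variational Laplace: Gauss-Newton / Levenberg-Marquardt ascent on a
# free-energy bound for a Gaussian observation model with per-block noise
# precisions, plus the spectral-DCM front end that maps couplings to CSD
# features.

# large negative free energy assigned to parameter values whose linearization
# is unstable; graded by the worst eigenvalue so ascent can escape
stability_penalty <- function(max_re) -1e10 - 1e4 * max_re

# feature predictor for a DCM candidate: returns numeric feature vector or
# the stability penalty marker (attribute "penalty"); features per frequency
# are Re(upper triangle incl. diagonal) then Im(strict upper), matching
# featurize_csd
dcm_predictor <- function(spec, lead, freqs, constants, scale = 1) {
  force(spec); force(lead); force(freqs); force(constants); force(scale)
  m <- nrow(lead$matrix)
  ii <- rep(seq_len(m), times = m)
  jj <- rep(seq_len(m), each = m)
  ut_rows <- which(ii <= jj)   # pair rows of the upper triangle, col-major
  uts_rows <- which(ii < jj)
  strict_pos <- match(uts_rows, ut_rows)  # strict pairs within the ut set
  # the transfer function depends only on the dynamical parameters (couplings,
  # intrinsics, sigmoid = entries 1:45); cache it so finite differences on the
  # spectral amplitude parameters skip the eigendecomposition
  tc_key <- NULL
  tc_val <- NULL
  function(theta_full) {
    p <- unvec_params_fast(theta_full)
    key <- theta_full[1:45]
    if (is.null(tc_key) || !identical(key, tc_key)) {
      tc_val <<- tryCatch(transfer_core(p, spec, freqs, constants,
                                        check = FALSE),
                          error = function(e) NULL)
      tc_key <<- key
    }
    raw <- if (is.null(tc_val) || !tc_val$stable) {
      if (is.null(tc_val)) NULL else
        list(stable = FALSE, max_re = tc_val$max_re)
    } else {
      predict_csd_raw(p, spec, lead, freqs, constants, tc = tc_val,
                      check = FALSE, pairs = ut_rows)
    }
    if (is.null(raw) || !raw$stable) {
      mr <- if (is.null(raw)) 1 else raw$max_re
      return(structure(NA_real_, penalty = stability_penalty(mr)))
    }
    feats <- rbind(Re(raw$G), Im(raw$G[strict_pos, , drop = FALSE]))
    as.numeric(feats) * scale
  }
}

#' Free energy of a candidate parameter vector
#'
#' Evaluates the variational (Laplace) free energy at `candidate`: the
#' expected Gaussian log-likelihood of the featurized CSD residuals under the
#' current noise precisions, minus the KL complexity of the Laplace posterior
#' formed at the candidate against the prior. Higher is better. Candidates
#' with an unstable linearization receive a large graded penalty instead of
#' an error.
#'
#' @param candidate full parameter vector (length 58, canonical order).
#' @param data a `csd_data`.
#' @param priors prior list from [default_priors()].
#' @param hyper optional per-block log precisions (named `re`, `im`); default
#'   is the hyperprior mean.
#' @param spec,lead,constants forward-model ingredients.
#' @return Scalar free energy in nats.
#' @export
free_energy <- function(candidate, data, priors, hyper = NULL,
                        spec = default_dmn(), lead,
                        constants = load_constants()) {
  stopifnot(all(is.finite(candidate)))
  feat <- featurize_csd(data)
  w <- csd_feature_weights(data)
  w <- w / sqrt(mean((feat$y * w)^2))
  pred <- dcm_predictor(spec, lead, data$freqs, constants, scale = w)
  if (is.null(hyper)) hyper <- c(re = priors$hyper_mean, im = priors$hyper_mean)
  free <- priors$variance > 1e-6
  g <- pred(candidate)
  if (anyNA(g)) return(attr(g, "penalty"))
  J <- fd_jacobian(pred, candidate, free)
  vl_free_energy(feat$y * w, g, feat$blocks, J,
                 e = candidate[free] - priors$mean[free],
                 prior_var = priors$variance[free], lambda = hyper)
}

# central finite-difference Jacobian over the free parameters (step 1e-4)
fd_jacobian <- function(pred, theta, free, step = 1e-4) {
  idx <- which(free)
  cols <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    tp <- theta; tm <- theta
    tp[idx[k]] <- tp[idx[k]] + step
    tm[idx[k]] <- tm[idx[k]] - step
    gp <- pred(tp); gm <- pred(tm)
    if (anyNA(gp) || anyNA(gm)) return(NULL)
    cols[[k]] <- (gp - gm) / (2 * step)
  }
  do.call(cbind, cols)
}

# per-block sufficient statistics of a linearization: Gram matrices
# A_b = J_b' J_b, residual sums of squares and block sizes; everything the
# free energy and precision updates need without touching J again
vl_stats <- function(r, blocks, J, blk = split(seq_along(r), blocks)) {
  A <- lapply(blk, function(i) crossprod(J[i, , drop = FALSE]))
  rss <- vapply(blk, function(i) sum(r[i]^2), numeric(1))
  n <- lengths(blk)
  list(A = A, rss = rss, n = n, N = length(r), blk = blk)
}

# F = sum_b [ n_b*lam_b/2 - tau_b*E_b/2 ] - N/2 log 2pi
#     - e' Pi0 e / 2 - tr(Pi0 Sigma)/2 + p/2 + log det(Sigma Pi0)/2  (theta KL)
# with E_b = rss_b + tr(A_b Sigma); Sigma = (sum_b tau_b A_b + Pi0)^-1
vl_fe_stats <- function(stats, e, Pi0, lambda, lambda_prior = NULL) {
  P <- diag(Pi0, length(Pi0))
  for (b in names(stats$A)) P <- P + exp(lambda[[b]]) * stats$A[[b]]
  cP <- tryCatch(chol(P), error = function(e) NULL)
  if (is.null(cP)) return(-Inf)
  Sigma <- chol2inv(cP)
  acc <- 0
  for (b in names(stats$A)) {
    Eb <- stats$rss[[b]] + sum(stats$A[[b]] * Sigma)
    acc <- acc + 0.5 * stats$n[[b]] * lambda[[b]] - 0.5 * exp(lambda[[b]]) * Eb
  }
  ldS <- -2 * sum(log(diag(cP)))
  Fth <- -0.5 * sum(e^2 * Pi0) - 0.5 * sum(Pi0 * diag(Sigma)) +
    length(e) / 2 + 0.5 * (ldS + sum(log(Pi0)))
  Flam <- 0
  if (!is.null(lambda_prior)) {
    for (b in names(stats$A)) {
      Flam <- Flam - (lambda[[b]] - lambda_prior$mean)^2 / (2 * lambda_prior$var)
    }
  }
  acc - stats$N / 2 * log(2 * pi) + Fth + Flam
}

# convenience wrapper on raw (y, g, blocks, J) arguments
vl_free_energy <- function(y, g, blocks, J, e, prior_var, lambda,
                           lambda_prior = NULL) {
  stats <- vl_stats(y - g, blocks, J)
  vl_fe_stats(stats, e, 1 / prior_var, lambda, lambda_prior)
}

#' Generic variational-Laplace fit
#'
#' Gauss-Newton/Levenberg-Marquardt ascent on the free energy for an arbitrary
#' differentiable predictor with Gaussian priors and per-block noise
#' precisions updated by Newton steps. Accepted iterations never decrease the
#' free energy; rejected steps shrink the trust region.
#'
#' @param y data feature vector.
#' @param blocks character vector assigning each feature to a precision block.
#' @param predict_fn function mapping the full parameter vector to predicted
#'   features (may return `NA` with a `penalty` attribute).
#' @param prior_mean,prior_var prior mean and (diagonal) variance over the
#'   full parameter vector; entries with variance `<= free_tol` stay pinned.
#' @param hyper list with `mean` and `var` of the log-precision hyperpriors;
#'   `var <= 1e-6` pins the precisions (no hyperparameter updates).
#' @param max_iter,tol iteration cap and free-energy convergence tolerance
#'   (nats).
#' @param free_tol prior-variance threshold below which a parameter is fixed.
#' @return A `dcm_posterior`: posterior `mean` (full vector), `cov`,
#'   `free_energy`, per-iteration `trace`, `hyper` summary and `free` mask.
#' @export
fit_vl_generic <- function(y, blocks, predict_fn, prior_mean, prior_var,
                           hyper = list(mean = 4, var = 16),
                           max_iter = 64L, tol = 1e-2, free_tol = 1e-6) {
  stopifnot(length(prior_mean) == length(prior_var))
  free <- prior_var > free_tol
  if (!any(free)) stop("no free parameters (all prior variances pinned)")
  theta <- prior_mean
  bl <- unique(blocks)
  lambda <- stats::setNames(rep(hyper$mean, length(bl)), bl)
  fit_hyper <- hyper$var > 1e-6
  lam_prior <- if (fit_hyper) list(mean = hyper$mean, var = hyper$var) else NULL
  Pi0 <- 1 / prior_var[free]
  v <- 1 / 128  # LM damping
  trace <- numeric(0)
  warn <- NULL
  g <- predict_fn(theta)
  if (anyNA(g)) stop("predictor failed at the prior mean")
  J <- fd_jacobian(predict_fn, theta, free)
  blk <- split(seq_along(y), blocks)
  stats <- vl_stats(y - g, blocks, J, blk)
  if (fit_hyper) {
    lambda <- update_lambda_stats(stats, lambda, Pi0, hyper, n_newton = 8L)
  }
  F_cur <- vl_fe_stats(stats, theta[free] - prior_mean[free], Pi0,
                       lambda, lam_prior)
  trace <- F_cur
  improved_any <- FALSE
  np <- length(Pi0)
  for (it in seq_len(max_iter)) {
    tau <- exp(lambda)[blocks]
    A <- matrix(0, np, np)
    for (b in names(stats$A)) A <- A + exp(lambda[[b]]) * stats$A[[b]]
    grad <- as.numeric(crossprod(J, (y - g) * tau)) -
      Pi0 * (theta[free] - prior_mean[free])
    accepted <- FALSE
    for (try in 1:8) {
      P <- A + diag(Pi0, np) + v * diag(diag(A) + Pi0, np)
      step <- tryCatch(solve(P, grad), error = function(e) NULL)
      if (!is.null(step)) {
        cand <- theta
        cand[free] <- cand[free] + step
        gc_ <- predict_fn(cand)
        # screen the candidate with the current linearization (one predictor
        # call); only candidates that pass pay for a fresh Jacobian
        if (anyNA(gc_)) {
          F_stale <- attr(gc_, "penalty")
        } else {
          st_stale <- stats
          st_stale$rss <- vapply(blk, function(i) sum((y - gc_)[i]^2),
                                 numeric(1))
          F_stale <- vl_fe_stats(st_stale, cand[free] - prior_mean[free],
                                 Pi0, lambda, lam_prior)
        }
        if (is.finite(F_stale) && F_stale > F_cur - 1e-12) {
          Jc <- fd_jacobian(predict_fn, cand, free)
          if (!is.null(Jc)) {
            stats_c <- vl_stats(y - gc_, blocks, Jc, blk)
            lam_c <- lambda
            if (fit_hyper) {
              lam_c <- update_lambda_stats(stats_c, lam_c, Pi0, hyper)
            }
            F_new <- vl_fe_stats(stats_c, cand[free] - prior_mean[free],
                                 Pi0, lam_c, lam_prior)
            if (is.finite(F_new) && F_new > F_cur - 1e-12) {
              theta <- cand; g <- gc_; J <- Jc; stats <- stats_c
              lambda <- lam_c
              if (F_new > F_cur) improved_any <- TRUE
              dF <- F_new - F_cur
              F_cur <- F_new
              trace <- c(trace, F_cur)
              v <- max(v / 2, 1e-8)
              accepted <- TRUE
              break
            }
          }
        }
      }
      v <- v * 8  # shrink trust region and retry
    }
    if (!accepted) break
    if (accepted && dF < tol && it > 1L) break
  }
  if (!improved_any) {
    warn <- "free energy did not improve from the prior mean"
  }
  P <- diag(Pi0, np)
  for (b in names(stats$A)) P <- P + exp(lambda[[b]]) * stats$A[[b]]
  Sigma_free <- chol2inv(chol(P))
  n_all <- length(prior_mean)
  Sigma <- diag(prior_var, n_all)
  Sigma[free, free] <- Sigma_free
  dimnames(Sigma) <- list(names(prior_mean), names(prior_mean))
  structure(list(mean = theta, cov = Sigma, free_energy = F_cur,
                 trace = trace, hyper = list(lambda = lambda),
                 free = free, warning = warn,
                 prior = list(mean = prior_mean, variance = prior_var)),
            class = "dcm_posterior")
}

# Newton updates of the per-block log precisions (a few steps each)
update_lambda_stats <- function(stats, lambda, Pi0, hyper, n_newton = 4L) {
  for (k in seq_len(n_newton)) {
    P <- diag(Pi0, length(Pi0))
    for (b in names(stats$A)) P <- P + exp(lambda[[b]]) * stats$A[[b]]
    Sigma <- tryCatch(chol2inv(chol(P)), error = function(e) NULL)
    if (is.null(Sigma)) return(lambda)
    for (b in names(stats$A)) {
      Eb <- stats$rss[[b]] + sum(stats$A[[b]] * Sigma)
      tb <- exp(lambda[[b]])
      gr <- stats$n[[b]] / 2 - tb * Eb / 2 - (lambda[[b]] - hyper$mean) / hyper$var
      he <- -tb * Eb / 2 - 1 / hyper$var
      lambda[[b]] <- lambda[[b]] - gr / he
    }
  }
  lambda
}

#' Fit the spectral DCM to observed cross-spectra
#'
#' Inverts the generative model for one subject's CSD by variational Laplace:
#' Gauss-Newton ascent on the free energy over the free parameters (by
#' default the 12 extrinsic couplings plus innovations and channel-noise
#' amplitudes), with noise-precision hyperparameters updated in between.
#'
#' @param data a `csd_data` in the same space as `lead`.
#' @param priors prior list from [default_priors()].
#' @param spec a `dmn_spec`.
#' @param lead a `lead_field` mapping sources to the data's channels/modes.
#' @param constants constants list.
#' @param max_iter,tol convergence controls (defaults 128 iterations,
#'   1e-2 nats).
#' @return A `dcm_posterior`.
#' @export
fit_vl <- function(data, priors = default_priors(), spec = default_dmn(),
                   lead, constants = load_constants(),
                   max_iter = 128L, tol = 1e-2) {
  stopifnot(inherits(data, "csd_data"))
  if (nrow(lead$matrix) != dim(data$csd)[1]) {
    stop("lead field rows must match data channels/modes")
  }
  if (length(priors$mean) != 58L || length(priors$variance) != 58L) {
    stop("priors must cover the 58-dimensional parameter vector")
  }
  feat <- featurize_csd(data)
  w <- csd_feature_weights(data)
  w <- w / sqrt(mean((feat$y * w)^2))   # whiten, then unit overall scale
  pred <- dcm_predictor(spec, lead, data$freqs, constants, scale = w)
  post <- fit_vl_generic(feat$y * w, feat$blocks, pred,
                         prior_mean = priors$mean, prior_var = priors$variance,
                         hyper = list(mean = priors$hyper_mean,
                                      var = priors$hyper_var),
                         max_iter = max_iter, tol = tol)
  post$freqs <- data$freqs
  post
}

#' @export
print.dcm_posterior <- function(x, ...) {
  cat(sprintf("dcm_posterior: %d parameters (%d free), F = %.2f nats, %d accepted steps\n",
              length(x$mean), sum(x$free), x$free_energy, length(x$trace) - 1L))
  if (!is.null(x$warning)) cat("warning:", x$warning, "\n")
  invisible(x)
}

#' Marginal posterior over the extrinsic couplings
#'
#' Extracts the 12-coupling marginal (mean, covariance) and the matching
#' prior moments from a subject-level posterior.
#'
#' @param post a `dcm_posterior`.
#' @return List with `mean`, `cov`, `prior_mean`, `prior_var`.
#' @export
coupling_posterior <- function(post) {
  i <- 1:12
  list(mean = post$mean[i], cov = post$cov[i, i, drop = FALSE],
       prior_mean = post$prior$mean[i],
       prior_var = post$prior$variance[i])
}

#' Serialize a posterior to a container directory
#'
#' JSON metadata plus a binary array file, mirroring the CSD container
#' layout; the round trip is exact.
#' @param post a `dcm_posterior`.
#' @param path directory to create.
#' @export
write_posterior <- function(post, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(n = length(post$mean), names = names(post$mean),
               free_energy = post$free_energy, trace = post$trace,
               lambda = as.list(post$hyper$lambda),
               free = as.logical(post$free))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(path, "arrays.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(c(post$mean, post$cov,
                        post$prior$mean, post$prior$variance)), con, size = 8)
  invisible(path)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  n <- meta$n
  con <- file(file.path(path, "arrays.bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = n + n * n + 2 * n, size = 8)
  if (length(raw) != n + n * n + 2 * n) stop("arrays.bin truncated in ", path)
  mean <- stats::setNames(raw[1:n], meta$names)
  cov <- matrix(raw[(n + 1):(n + n * n)], n, n,
                dimnames = list(meta$names, meta$names))
  pm <- stats::setNames(raw[(n + n * n + 1):(n + n * n + n)], meta$names)
  pv <- stats::setNames(raw[(n + n * n + n + 1):(n + n * n + 2 * n)], meta$names)
  structure(list(mean = mean, cov = cov, free_energy = meta$free_energy,
                 trace = meta$trace,
                 hyper = list(lambda = unlist(meta$lambda)),
                 free = stats::setNames(meta$free, meta$names), warning = NULL,
                 prior = list(mean = pm, variance = pv)),
            class = "dcm_posterior")
}
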