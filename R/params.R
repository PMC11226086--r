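#' Subject-level model parameters
#'
#' All parameters are dimensionless log scalings that multiply the constants
#' table: a value of 0 leaves the corresponding quantity at its prior mean.
#' The fixed vectorization order (see [vec_params()]) is:
#' 12 extrinsic couplings `a` (canonical edge order of the network spec);
#' 32 intrinsic scalings (`He`, `Hi`, `tau_e`, `tau_i`, `g1`..`g4` for each of
#' the 4 sources, source-major); 1 sigmoid-slope scaling; 4 per-source
#' innovations amplitudes; 4 per-source innovations spectral exponents;
#' 1 lead-field gain; and 4 observation-noise scalings (common amplitude,
#' common exponent, channel-specific amplitude, specific exponent). 58 in all.
#'
#' @param a numeric vector of 12 extrinsic coupling log scalings.
#' @param intrinsic 4 x 8 matrix of per-source intrinsic log scalings
#'   (columns He, Hi, tau_e, tau_i, g1..g4).
#' @param sigmoid scalar log scaling of the sigmoid slope.
#' @param innov_amp,innov_exp length-4 per-source innovations log scalings.
#' @param lead_gain scalar log scaling of the lead-field gain.
#' @param noise length-4 vector: common amplitude, common exponent, specific
#'   amplitude, specific exponent log scalings of channel noise.
#' @return An object of class `dcm_params`.
#' @export
dcm_params <- function(a = numeric(12),
                       intrinsic = matrix(0, 4, 8),
                       sigmoid = 0,
                       innov_amp = numeric(4),
                       innov_exp = numeric(4),
                       lead_gain = 0,
                       noise = numeric(4)) {
  intrinsic <- matrix(as.numeric(intrinsic), 4, 8)
  colnames(intrinsic) <- c("He", "Hi", "tau_e", "tau_i", "g1", "g2", "g3", "g4")
  p <- structure(list(a = as.numeric(a), intrinsic = intrinsic,
                      sigmoid = as.numeric(sigmoid),
                      innov_amp = as.numeric(innov_amp),
                      innov_exp = as.numeric(innov_exp),
                      lead_gain = as.numeric(lead_gain),
                      noise = as.numeric(noise)),
                 class = "dcm_params")
  validate_dcm_params(p)
  p
}

validate_dcm_params <- function(p) {
  if (length(p$a) != 12L) stop("a must have 12 entries")
  if (!identical(dim(p$intrinsic), c(4L, 8L))) stop("intrinsic must be 4 x 8")
  if (length(p$innov_amp) != 4L || length(p$innov_exp) != 4L)
    stop("innovations scalings must be per-source (length 4)")
  if (length(p$noise) != 4L) stop("noise must have 4 entries")
  if (length(p$sigmoid) != 1L || length(p$lead_gain) != 1L)
    stop("sigmoid and lead_gain are scalars")
  vals <- vec_params(p)
  if (!all(is.finite(vals))) stop("all parameters must be finite")
  invisible(p)
}

#' Flatten parameters to the canonical vector
#'
#' @param p a `dcm_params` object.
#' @return Named numeric vector of length 58; [unvec_params()] inverts it
#'   losslessly.
#' @export
vec_params <- function(p) {
  v <- c(p$a,
         as.numeric(t(p$intrinsic)),  # source-major: src1 He..g4, src2 ...
         p$sigmoid, p$innov_amp, p$innov_exp, p$lead_gain, p$noise)
  names(v) <- param_names()
  v
}

#' @rdname vec_params
#' @param v numeric vector of length 58 in canonical order.
#' @export
unvec_params <- function(v) {
  stopifnot(length(v) == 58L)
  dcm_params(a = v[1:12],
             intrinsic = matrix(v[13:44], 4, 8, byrow = TRUE),
             sigmoid = v[45],
             innov_amp = v[46:49],
             innov_exp = v[50:53],
             lead_gain = v[54],
             noise = v[55:58])
}

# validation-free unvec for inner optimization loops; the vector has already
# been checked once at entry
unvec_params_fast <- function(v) {
  intr <- matrix(v[13:44], 4, 8, byrow = TRUE)
  colnames(intr) <- c("He", "Hi", "tau_e", "tau_i", "g1", "g2", "g3", "g4")
  structure(list(a = unname(v[1:12]), intrinsic = intr,
                 sigmoid = unname(v[45]),
                 innov_amp = unname(v[46:49]),
                 innov_exp = unname(v[50:53]),
                 lead_gain = unname(v[54]),
                 noise = unname(v[55:58])),
            class = "dcm_params")
}

param_names <- function() {
  c(paste0("a", 1:12),
    paste0(rep(paste0("s", 1:4), each = 8), "_",
           rep(c("He", "Hi", "tau_e", "tau_i", "g1", "g2", "g3", "g4"), 4)),
    "sigmoid",
    paste0("u_amp", 1:4), paste0("u_exp", 1:4),
    "lead_gain", "n_common_amp", "n_common_exp", "n_spec_amp", "n_spec_exp")
}

#' Default Gaussian shrinkage priors over the parameter vector
#'
#' Prior means are 0 (all constants at their table values); variances come
#' from the constants file, with fixed parameters given a negligible variance
#' so they stay pinned during inversion.
#'
#' @param constants constants list from [load_constants()].
#' @param pin_var variance assigned to fixed parameters.
#' @return A list with `mean`, `variance` (diagonal), `hyper_mean`,
#'   `hyper_var`, all in canonical parameter order.
#' @export
default_priors <- function(constants = load_constants(), pin_var = 1e-8) {
  pv <- constants$priors
  expand <- function(x) max(x, pin_var)
  variance <- c(rep(expand(pv$a), 12),
                rep(expand(pv$intrinsic), 32),
                expand(pv$sigmoid),
                rep(expand(pv$innovations_amp), 4),
                rep(expand(pv$innovations_exp), 4),
                expand(pv$lead_gain),
                expand(pv$noise_amp), expand(pv$noise_exp),
                expand(pv$noise_amp), expand(pv$noise_exp))
  names(variance) <- param_names()
  list(mean = stats::setNames(numeric(58), param_names()),
       variance = variance,
       hyper_mean = constants$hyperpriors$mean,
       hyper_var = constants$hyperpriors$variance)
}
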