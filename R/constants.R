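#' Derive a reproducible child seed
#'
#' Hashes a master seed together with a purpose tag into an integer seed in
#' `[1, 2^31 - 2]`, so that independent stages of an analysis obtain
#' decorrelated but fully reproducible random streams from one master seed.
#'
#' @param master integer master seed.
#' @param tag character tag naming the consumer (e.g. `"cohort"`,
#'   `"permutation3"`).
#' @return A positive integer seed.
#' @export
derive_seed <- function(master, tag) {
  stopifnot(length(master) == 1L, is.finite(master), length(tag) == 1L)
  h <- fnv1a32(charToRaw(paste0(tag, ":",
                                format(master, scientific = FALSE))))
  as.integer(h %% 2147483646) + 1L
}

# 32-bit FNV-1a over a raw vector, kept exact in double arithmetic (the
# running hash exceeds the integer range, so xor acts on the low byte only
# and the modular multiply is split into 16-bit halves)
fnv1a32 <- function(bytes) {
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  h
}

#' Load the neural-mass and prior constants table
#'
#' The package ships a versioned YAML file with the biophysical constants of
#' the ERP-convolution (Jansen-Rit) source model, the base gains of the three
#' extrinsic connection types, the innovations and channel-noise spectral
#' parameterization, and the Gaussian shrinkage prior variances of all log
#' scaling parameters. All fitted parameters multiply these constants via
#' `exp(log scaling)`, so a scaling of 0 means "at prior mean".
#'
#' @param path Path to a YAML constants file; default is the file shipped with
#'   the package.
#' @return A validated nested list with elements `neural`, `coupling`,
#'   `innovations`, `observation`, `priors`, `hyperpriors` and `version`.
#' @export
load_constants <- function(path = system.file("constants", "erp_constants.yaml",
                                              package = "specdcm")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("constants file not found: ", path)
  }
  con <- yaml::read_yaml(path)
  validate_constants(con)
  con
}

# schema check: required fields, types, positivity where physical
validate_constants <- function(con) {
  need <- function(x, fields, where) {
    miss <- setdiff(fields, names(x))
    if (length(miss)) stop("constants file missing ", where, ": ",
                           paste(miss, collapse = ", "))
  }
  need(con, c("version", "neural", "coupling", "innovations", "observation",
              "priors", "hyperpriors"), "top-level fields")
  need(con$neural, c("He", "Hi", "tau_e", "tau_i", "gamma", "sigmoid_slope"),
       "neural fields")
  need(con$coupling, c("forward", "backward", "lateral"), "coupling fields")
  need(con$innovations, c("amp", "white_frac"), "innovations fields")
  need(con$observation, c("common_amp", "specific_amp", "white_frac"),
       "observation fields")
  need(con$priors, c("a", "intrinsic", "sigmoid", "innovations_amp",
                     "innovations_exp", "lead_gain", "noise_amp", "noise_exp"),
       "prior fields")
  need(con$hyperpriors, c("mean", "variance"), "hyperprior fields")
  if (length(con$neural$gamma) != 4L) stop("neural$gamma must have 4 entries")
  pos <- c(con$neural$He, con$neural$Hi, con$neural$tau_e, con$neural$tau_i,
           unlist(con$neural$gamma), con$neural$sigmoid_slope,
           con$coupling$forward, con$coupling$backward, con$coupling$lateral,
           con$innovations$amp, con$observation$common_amp,
           con$observation$specific_amp)
  if (!all(is.finite(pos)) || any(pos <= 0)) {
    stop("all physical constants must be finite and positive")
  }
  vars <- unlist(con$priors)
  if (!all(is.finite(vars)) || any(vars < 0)) {
    stop("prior variances must be finite and non-negative")
  }
  wf <- c(con$innovations$white_frac, con$observation$white_frac)
  if (any(wf < 0 | wf > 1)) stop("white_frac must lie in [0, 1]")
  invisible(con)
}
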