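# Biophysical forward model: four ERP-convolution (Jansen-Rit) sources coupled
# by typed extrinsic connections, linearized about their fixed point to give
# source-to-source transfer functions and predicted EEG cross-spectra.
#
# State layout: 8 states per source, source-major —
#   v1,i1 (spiny stellate), v2,i2 (pyramidal excitatory), v3,i3 (pyramidal
#   inhibitory), v7,i7 (inhibitory interneurons); the measured pyramidal
#   depolarization is p = v2 - v3.

# centred sigmoid and its derivative
sigm <- function(v, r) 1 / (1 + exp(-r * v)) - 0.5
dsigm <- function(v, r) {
  s <- sigm(v, r)
  r * (0.25 - s^2)
}

# resolve params + constants into per-source physical values and extrinsic
# gain matrices (target x source)
compile_model <- function(params, spec, constants = load_constants(),
                          check = TRUE) {
  if (check) validate_dcm_params(params)
  ns <- 4L
  He <- constants$neural$He * exp(params$intrinsic[, "He"])
  Hi <- constants$neural$Hi * exp(params$intrinsic[, "Hi"])
  ke <- 1 / (constants$neural$tau_e * exp(params$intrinsic[, "tau_e"]))
  ki <- 1 / (constants$neural$tau_i * exp(params$intrinsic[, "tau_i"]))
  g <- sweep(exp(params$intrinsic[, c("g1", "g2", "g3", "g4")]), 2,
             unlist(constants$neural$gamma), `*`)
  r <- constants$neural$sigmoid_slope * exp(params$sigmoid)
  base <- c(forward = constants$coupling$forward,
            backward = constants$coupling$backward,
            lateral = constants$coupling$lateral)
  AF <- AB <- AL <- matrix(0, ns, ns)
  nodes <- spec$nodes$name
  ti <- match(spec$edges$target, nodes)
  si <- match(spec$edges$source, nodes)
  ty <- spec$edges$type
  w <- base[ty] * exp(params$a)
  # no duplicate (target, source, type) triples (validated in the spec), so
  # direct indexed assignment is safe
  f <- ty == "forward"; AF[cbind(ti[f], si[f])] <- w[f]
  b <- ty == "backward"; AB[cbind(ti[b], si[b])] <- w[b]
  l <- ty == "lateral"; AL[cbind(ti[l], si[l])] <- w[l]
  list(ns = ns, He = He, Hi = Hi, ke = ke, ki = ki, g = g, r = r,
       AF = AF, AB = AB, AL = AL)
}

# state indices for source s: (s-1)*8 + 1..8
st <- function(s, k) (s - 1L) * 8L + k

# dynamics f(x); u is an optional per-source exogenous drive on the granular
# population
erp_f <- function(x, m, u = numeric(4)) {
  ns <- m$ns
  x <- matrix(x, 8, ns)  # states x sources
  v1 <- x[1, ]; i1 <- x[2, ]; v2 <- x[3, ]; i2 <- x[4, ]
  v3 <- x[5, ]; i3 <- x[6, ]; v7 <- x[7, ]; i7 <- x[8, ]
  p <- v2 - v3
  sp <- sigm(p, m$r)
  aff_fl <- as.numeric((m$AF + m$AL) %*% sp)   # to granular
  aff_bl <- as.numeric((m$AB + m$AL) %*% sp)   # to pyramidal + interneurons
  d1 <- m$g[, 1] * sp + aff_fl + u
  d2 <- m$g[, 2] * sigm(v1, m$r) + aff_bl
  d3 <- m$g[, 4] * sigm(v7, m$r)
  d7 <- m$g[, 3] * sp + aff_bl
  dx <- rbind(i1, m$He * m$ke * d1 - 2 * m$ke * i1 - m$ke^2 * v1,
              i2, m$He * m$ke * d2 - 2 * m$ke * i2 - m$ke^2 * v2,
              i3, m$Hi * m$ki * d3 - 2 * m$ki * i3 - m$ki^2 * v3,
              i7, m$He * m$ke * d7 - 2 * m$ke * i7 - m$ke^2 * v7)
  as.numeric(dx)
}

#' Fixed point of the coupled neural-mass dynamics
#'
#' Finds the equilibrium of the deterministic (noise-free, zero-input) source
#' dynamics by Newton iteration from the origin, using the analytic Jacobian.
#' With the centred sigmoid the origin is an exact fixed point at any
#' parameter values, so this typically converges immediately; the solver is
#' kept general for non-centred variants.
#'
#' @param params a `dcm_params` object (all entries finite).
#' @param spec a `dmn_spec`.
#' @param constants constants list from [load_constants()].
#' @param tol convergence tolerance on the max-norm dynamics residual.
#' @param max_iter Newton iteration cap.
#' @return Numeric state vector `x*` of length 32 with
#'   `max(abs(f(x*))) < tol`.
#' @export
equilibrium <- function(params, spec, constants = load_constants(),
                        tol = 1e-8, max_iter = 50L) {
  m <- compile_model(params, spec, constants)
  x <- numeric(8L * m$ns)
  if (max(abs(erp_f(x, m))) < tol) return(x)  # centred sigmoid: exact at 0
  for (it in seq_len(max_iter)) {
    fx <- erp_f(x, m)
    if (max(abs(fx)) < tol) return(x)
    J <- erp_jac(x, m)
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step)) stop("equilibrium: singular Jacobian during Newton solve")
    x <- x + step
  }
  fx <- erp_f(x, m)
  if (max(abs(fx)) < tol) return(x)
  stop(sprintf("equilibrium: Newton did not converge; worst residual %.3e",
               max(abs(fx))))
}

# analytic Jacobian of erp_f at x (vectorized over sources)
erp_jac <- function(x, m) {
  ns <- m$ns
  n <- 8L * ns
  xm <- matrix(x, 8, ns)
  v1 <- xm[1, ]; v2 <- xm[3, ]; v3 <- xm[5, ]; v7 <- xm[7, ]
  dp <- dsigm(v2 - v3, m$r)   # per-source derivative at pyramidal output
  dv1 <- dsigm(v1, m$r)
  dv7 <- dsigm(v7, m$r)
  s <- seq_len(ns)
  ge <- m$He * m$ke
  J <- matrix(0, n, n)
  J[cbind(st(s, 1), st(s, 2))] <- 1
  J[cbind(st(s, 3), st(s, 4))] <- 1
  J[cbind(st(s, 5), st(s, 6))] <- 1
  J[cbind(st(s, 7), st(s, 8))] <- 1
  J[cbind(st(s, 2), st(s, 2))] <- -2 * m$ke; J[cbind(st(s, 2), st(s, 1))] <- -m$ke^2
  J[cbind(st(s, 4), st(s, 4))] <- -2 * m$ke; J[cbind(st(s, 4), st(s, 3))] <- -m$ke^2
  J[cbind(st(s, 6), st(s, 6))] <- -2 * m$ki; J[cbind(st(s, 6), st(s, 5))] <- -m$ki^2
  J[cbind(st(s, 8), st(s, 8))] <- -2 * m$ke; J[cbind(st(s, 8), st(s, 7))] <- -m$ke^2
  # extrinsic + intrinsic drive from the pyramidal output p = v2 - v3:
  # W[s, k] * dp[k] scaled by He_s*ke_s into the second-state rows
  W1 <- ge * (diag(m$g[, 1], ns) + m$AF + m$AL) * rep(dp, each = ns)
  Wb <- ge * (m$AB + m$AL) * rep(dp, each = ns)
  Wi <- ge * (diag(m$g[, 3], ns) + m$AB + m$AL) * rep(dp, each = ns)
  J[st(s, 2), st(s, 3)] <- J[st(s, 2), st(s, 3)] + W1
  J[st(s, 2), st(s, 5)] <- J[st(s, 2), st(s, 5)] - W1
  J[st(s, 4), st(s, 3)] <- J[st(s, 4), st(s, 3)] + Wb
  J[st(s, 4), st(s, 5)] <- J[st(s, 4), st(s, 5)] - Wb
  J[st(s, 8), st(s, 3)] <- J[st(s, 8), st(s, 3)] + Wi
  J[st(s, 8), st(s, 5)] <- J[st(s, 8), st(s, 5)] - Wi
  J[cbind(st(s, 4), st(s, 1))] <- J[cbind(st(s, 4), st(s, 1))] +
    ge * m$g[, 2] * dv1
  J[cbind(st(s, 6), st(s, 7))] <- m$Hi * m$ki * m$g[, 4] * dv7
  J
}

#' Jacobian of the source dynamics at an equilibrium
#'
#' @inheritParams equilibrium
#' @param x_star equilibrium state vector (from [equilibrium()]).
#' @return 32 x 32 Jacobian matrix with attribute `stable` (logical: all
#'   eigenvalue real parts negative) and `max_re` (largest real part).
#' @export
jacobian <- function(params, spec, x_star = NULL,
                     constants = load_constants()) {
  m <- compile_model(params, spec, constants)
  if (is.null(x_star)) x_star <- equilibrium(params, spec, constants)
  J <- erp_jac(x_star, m)
  ev <- eigen(J, only.values = TRUE)$values
  attr(J, "max_re") <- max(Re(ev))
  attr(J, "stable") <- max(Re(ev)) < 0
  J
}

# input/output matrices: innovations drive the granular population with gain
# He*ke; output reads pyramidal depolarization v2 - v3
io_matrices <- function(m) {
  n <- 8L * m$ns
  Cin <- matrix(0, n, m$ns)
  Cout <- matrix(0, m$ns, n)
  for (s in seq_len(m$ns)) {
    Cin[st(s, 2), s] <- m$He[s] * m$ke[s]
    Cout[s, st(s, 3)] <- 1
    Cout[s, st(s, 5)] <- -1
  }
  list(Cin = Cin, Cout = Cout)
}

# eigendecomposition-based transfer evaluation shared by transfer_functions,
# predict_csd and the inversion; returns T as a 16 x F complex matrix
# (column-major source pairs) plus stability info
transfer_core <- function(params, spec, freqs, constants = load_constants(),
                          check = TRUE) {
  m <- compile_model(params, spec, constants, check = check)
  # the centred sigmoid vanishes at 0, so the origin is the exact fixed point
  # at any parameter values (see equilibrium())
  x_star <- numeric(8L * m$ns)
  J <- erp_jac(x_star, m)
  E <- eigen(J)
  lam <- E$values
  max_re <- max(Re(lam))
  io <- io_matrices(m)
  V <- E$vectors
  n <- length(lam)
  Q <- tryCatch(solve(V, io$Cin), error = function(e) NULL)  # n x 4
  if (!is.null(Q)) {
    R <- io$Cout %*% V                 # 4 x n
    # CP[(i,j), k] = R[i,k] * Q[k,j], pair index column-major in (i, j)
    CP <- matrix(0 + 0i, 16L, n)
    for (j in 1:4) CP[((j - 1L) * 4L + 1L):(j * 4L), ] <- R * rep(Q[, j], each = 4L)
    iw <- 2i * pi * freqs
    DEN <- outer(-lam, iw, `+`)                       # n x F, (iw - lam)
    bad <- which(abs(DEN) < 1e-10, arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("singular resolvent at %.3f Hz", freqs[bad[1, 2]]))
    }
    Tmat <- CP %*% (1 / DEN)            # 16 x F
  } else {
    # near-defective Jacobian: fall back to a direct resolvent solve per
    # frequency, T(w) = Cout (iwI - J)^-1 Cin
    Tmat <- matrix(0 + 0i, 16L, length(freqs))
    I <- diag(1 + 0i, n)
    for (f in seq_along(freqs)) {
      S <- tryCatch(solve(2i * pi * freqs[f] * I - J, io$Cin),
                    error = function(e) NULL)
      if (is.null(S)) stop(sprintf("singular resolvent at %.3f Hz", freqs[f]))
      Tmat[, f] <- as.complex(io$Cout %*% S)
    }
  }
  list(T = Tmat, max_re = max_re, stable = max_re < 0, model = m)
}

#' Source-to-source transfer functions
#'
#' Evaluates the linearized mapping from per-source neuronal innovations to
#' pyramidal depolarizations, `T(w) = C_out (iwI - J)^-1 C_in`, on a
#' frequency grid.
#'
#' @inheritParams equilibrium
#' @param freqs frequency grid in Hz.
#' @return Complex array of dimension 4 x 4 x length(freqs); entry `[i, j, f]`
#'   is the response of source `i` to innovations entering source `j`.
#' @export
transfer_functions <- function(params, spec, freqs,
                               constants = load_constants()) {
  tc <- transfer_core(params, spec, freqs, constants)
  if (!tc$stable) {
    stop(sprintf("unstable linearization (max eigenvalue real part %.3f)",
                 tc$max_re))
  }
  array(tc$T, c(4L, 4L, length(freqs)),
        dimnames = list(spec$nodes$name, spec$nodes$name, NULL))
}

# one-sided innovations PSD per source: amp * (wf + (1-wf) f^-beta), 4 x F
innovations_psd <- function(params, freqs, constants = load_constants()) {
  wf <- constants$innovations$white_frac
  amp <- constants$innovations$amp * exp(params$innov_amp)
  beta <- exp(params$innov_exp)
  t(sapply(1:4, function(s) amp[s] * (wf + (1 - wf) * freqs^(-beta[s]))))
}

# channel noise PSD pieces: list(common = F-vector, specific = F-vector)
noise_psd <- function(params, freqs, constants = load_constants()) {
  wf <- constants$observation$white_frac
  shape <- function(amp, bexp) amp * (wf + (1 - wf) * freqs^(-exp(bexp)))
  list(common = shape(constants$observation$common_amp * exp(params$noise[1]),
                      params$noise[2]),
       specific = shape(constants$observation$specific_amp * exp(params$noise[3]),
                        params$noise[4]))
}

# fast path: predicted CSD as a pairs x F complex matrix without container
# validation; used by the inversion. `pairs` selects channel-pair rows
# (column-major indices into the m x m grid); NULL computes all m^2 pairs.
predict_csd_raw <- function(params, spec, lead, freqs,
                            constants = load_constants(), tc = NULL,
                            check = TRUE, pairs = NULL) {
  if (is.null(tc)) tc <- transfer_core(params, spec, freqs, constants,
                                       check = check)
  L <- lead$matrix * exp(params$lead_gain)
  m <- nrow(L)
  nf <- length(freqs)
  B <- array(L %*% matrix(tc$T, 4L, 4L * nf), c(m, 4L, nf))
  gu <- innovations_psd(params, freqs, constants)
  if (is.null(pairs)) pairs <- seq_len(m * m)
  ii <- ((pairs - 1L) %% m) + 1L
  jj <- ((pairs - 1L) %/% m) + 1L
  np <- length(pairs)
  G <- matrix(0 + 0i, np, nf)
  for (s in 1:4) {
    Bs <- matrix(B[, s, ], m, nf)
    G <- G + (Bs[ii, , drop = FALSE] * Conj(Bs[jj, , drop = FALSE])) *
      rep(gu[s, ], each = np)
  }
  gn <- noise_psd(params, freqs, constants)
  G <- G + rep(gn$common, each = np)
  diag_rows <- which(ii == jj)
  G[diag_rows, ] <- G[diag_rows, ] + rep(gn$specific, each = length(diag_rows))
  list(G = G, m = m, pairs = pairs, stable = tc$stable, max_re = tc$max_re)
}

#' Predicted EEG cross-spectral density
#'
#' Computes the generative model's cross-spectrum
#' `G(w) = L T(w) Gu(w) T(w)^H L' + Gn(w)`, where `Gu` is the diagonal
#' per-source innovations spectrum (white + 1/f mixture) and `Gn` channel
#' noise with a common (rank-one, shared across channels) and a
#' channel-specific component.
#'
#' @inheritParams transfer_functions
#' @param lead a `lead_field` (see [make_lead_field()]) mapping the 4 sources
#'   to observation channels.
#' @param freqs frequency grid in Hz; default 1-30 Hz at 0.25 Hz.
#' @return A `csd_data` object (Hermitian PSD matrices per frequency).
#' @export
predict_csd <- function(params, spec, lead, freqs = default_freqs(),
                        constants = load_constants()) {
  tc <- transfer_core(params, spec, freqs, constants)
  if (!tc$stable) {
    stop(sprintf("unstable linearization (max eigenvalue real part %.3f)",
                 tc$max_re))
  }
  raw <- predict_csd_raw(params, spec, lead, freqs, constants, tc = tc)
  m <- raw$m
  nf <- length(freqs)
  arr <- array(raw$G, c(m, m, nf))
  # symmetrize away roundoff
  for (f in seq_len(nf)) arr[, , f] <- (arr[, , f] + Conj(t(arr[, , f]))) / 2
  csd_data(freqs, arr, meta = list(n_epochs = NA_integer_, sfreq = NA_real_,
                                   space = "channels", labels = lead$labels))
}

#' Default analysis frequency grid
#'
#' 1-30 Hz at 0.25 Hz resolution.
#' @return Numeric vector of frequencies in Hz.
#' @export
default_freqs <- function() seq(1, 30, by = 0.25)
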