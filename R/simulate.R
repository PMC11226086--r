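#' Multichannel recording container
#'
#' @param data channels x samples numeric matrix.
#' @param sfreq sampling rate in Hz.
#' @param labels channel labels.
#' @return An object of class `recording`.
#' @export
recording <- function(data, sfreq, labels = NULL) {
  stopifnot(is.matrix(data), is.numeric(sfreq), sfreq > 0)
  if (is.null(labels)) labels <- rownames(data)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  if (length(labels) != nrow(data)) stop("one label per channel required")
  structure(list(data = data, sfreq = sfreq, labels = labels),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("recording: %d channels x %d samples at %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq))
  invisible(x)
}

# colored Gaussian series with one-sided PSD psd_fun(f), band-limited to fmax;
# n samples at rate fs, via FFT shaping. DC is left at zero.
colored_noise <- function(n, fs, psd_fun, fmax = fs / 2) {
  half <- n %/% 2
  f <- (1:half) * fs / n
  S <- ifelse(f <= fmax, psd_fun(f), 0)
  amp <- sqrt(S * fs * n / 2)
  z <- (stats::rnorm(half) + 1i * stats::rnorm(half)) / sqrt(2)
  X <- complex(length.out = n)
  X[2:(half + 1)] <- amp * z
  if (n %% 2 == 0) X[half + 1] <- sqrt(S[half] * fs * n) * Re(z[half]) # real Nyquist bin
  X[n:(n - half + 2)] <- Conj(X[2:half])
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Stochastic time-domain simulation of the coupled sources
#'
#' Integrates the nonlinear source dynamics by the Euler-Maruyama scheme,
#' driven by per-source neuronal innovations whose spectrum matches the
#' generative model's innovations PSD (band-limited to the recording Nyquist),
#' observes the pyramidal depolarizations through the lead field, and adds
#' common and channel-specific observation noise with the model's channel
#' noise spectra. Used as an independent oracle for [predict_csd()].
#'
#' @inheritParams predict_csd
#' @param duration recording length in seconds (>= 10).
#' @param dt integration step in seconds (<= 2e-3).
#' @param seed integer seed; identical seeds give identical output.
#' @param sfreq output sampling rate in Hz (default 250).
#' @param scale_innovations,scale_noise multipliers on the innovations and
#'   observation-noise amplitudes (0 disables them; used for deterministic
#'   checks).
#' @param x0 optional initial state (length 32); default is the equilibrium.
#' @return A `recording` with `n = duration * sfreq` samples.
#' @export
simulate_timeseries <- function(params, spec, lead, duration, dt = 5e-4,
                                seed = 1L, sfreq = 250,
                                constants = load_constants(),
                                scale_innovations = 1, scale_noise = 1,
                                x0 = NULL) {
  if (duration < 10) stop("duration must be at least 10 s")
  if (dt > 2e-3) stop("dt must be at most 2 ms")
  m <- compile_model(params, spec, constants)
  dec <- round(1 / (sfreq * dt))
  if (abs(dec * sfreq * dt - 1) > 1e-8) stop("1/dt must be a multiple of sfreq")
  n_out <- round(duration * sfreq)
  n_steps <- n_out * dec
  fs_fine <- 1 / dt
  # innovations: band-limited to the recording Nyquist so decimation is exact
  U <- with_seed(seed, {
    u <- matrix(0, 4, n_steps)
    if (scale_innovations > 0) {
      gu_amp <- constants$innovations$amp * exp(params$innov_amp) *
        scale_innovations^2
      wf <- constants$innovations$white_frac
      beta <- exp(params$innov_exp)
      for (s in 1:4) {
        u[s, ] <- colored_noise(n_steps, fs_fine,
                                function(f) gu_amp[s] * (wf + (1 - wf) * f^(-beta[s])),
                                fmax = sfreq / 2)
      }
    }
    u
  })
  x <- if (is.null(x0)) equilibrium(params, spec, constants) else x0
  stopifnot(length(x) == 32L)
  # unrolled Euler-Maruyama loop (equivalent to x + dt * erp_f(x, m, u))
  xm <- matrix(x, 8, 4)
  v1 <- xm[1, ]; i1 <- xm[2, ]; v2 <- xm[3, ]; i2 <- xm[4, ]
  v3 <- xm[5, ]; i3 <- xm[6, ]; v7 <- xm[7, ]; i7 <- xm[8, ]
  AFL <- m$AF + m$AL; ABL <- m$AB + m$AL
  HeKe <- m$He * m$ke; HiKi <- m$Hi * m$ki
  ke2 <- m$ke^2; ki2 <- m$ki^2; tke <- 2 * m$ke; tki <- 2 * m$ki
  g1 <- m$g[, 1]; g2 <- m$g[, 2]; g3 <- m$g[, 3]; g4 <- m$g[, 4]
  r <- m$r
  out <- matrix(0, 4, n_out)
  k <- 0L
  for (t in seq_len(n_steps)) {
    sp <- 1 / (1 + exp(-r * (v2 - v3))) - 0.5
    afl <- AFL %*% sp; abl <- ABL %*% sp
    s1 <- 1 / (1 + exp(-r * v1)) - 0.5
    s7 <- 1 / (1 + exp(-r * v7)) - 0.5
    nv1 <- v1 + dt * i1
    ni1 <- i1 + dt * (HeKe * (g1 * sp + afl + U[, t]) - tke * i1 - ke2 * v1)
    nv2 <- v2 + dt * i2
    ni2 <- i2 + dt * (HeKe * (g2 * s1 + abl) - tke * i2 - ke2 * v2)
    nv3 <- v3 + dt * i3
    ni3 <- i3 + dt * (HiKi * (g4 * s7) - tki * i3 - ki2 * v3)
    nv7 <- v7 + dt * i7
    ni7 <- i7 + dt * (HeKe * (g3 * sp + abl) - tke * i7 - ke2 * v7)
    v1 <- nv1; i1 <- ni1; v2 <- nv2; i2 <- ni2
    v3 <- nv3; i3 <- ni3; v7 <- nv7; i7 <- ni7
    if (t %% dec == 0L) {
      k <- k + 1L
      out[, k] <- v2 - v3
      if (anyNA(out[, k]) || max(abs(v2)) > 1e6) {
        stop("simulation diverged; use a smaller dt")
      }
    }
  }
  L <- lead$matrix * exp(params$lead_gain)
  Y <- L %*% out
  if (scale_noise > 0) {
    gn <- list(
      common = c(constants$observation$common_amp * exp(params$noise[1]),
                 exp(params$noise[2])),
      spec = c(constants$observation$specific_amp * exp(params$noise[3]),
               exp(params$noise[4])))
    wf <- constants$observation$white_frac
    noise <- with_seed(seed + 1L, {
      common <- colored_noise(n_out, sfreq, function(f)
        scale_noise^2 * gn$common[1] * (wf + (1 - wf) * f^(-gn$common[2])))
      specific <- t(sapply(seq_len(nrow(L)), function(ch)
        colored_noise(n_out, sfreq, function(f)
          scale_noise^2 * gn$spec[1] * (wf + (1 - wf) * f^(-gn$spec[2])))))
      sweep(specific, 2, common, `+`)
    })
    Y <- Y + noise
  }
  recording(Y, sfreq, labels = lead$labels)
}
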