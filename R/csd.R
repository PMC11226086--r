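#' Cross-spectral density container
#'
#' Holds a strictly increasing frequency grid (Hz) and one complex Hermitian
#' positive semi-definite matrix per frequency, plus provenance metadata.
#'
#' @param freqs strictly increasing numeric vector of frequencies in Hz.
#' @param csd complex array `m x m x length(freqs)`.
#' @param meta list with elements `n_epochs`, `sfreq`, `space` (one of
#'   `"channels"`, `"modes"`, `"sources"`) and `labels`.
#' @param check validate Hermitian/PSD invariants (tolerance 1e-10).
#' @return An object of class `csd_data`.
#' @export
csd_data <- function(freqs, csd, meta = list(), check = TRUE) {
  if (is.matrix(csd)) csd <- array(csd, c(dim(csd), 1L))
  stopifnot(length(dim(csd)) == 3L, dim(csd)[1] == dim(csd)[2],
            dim(csd)[3] == length(freqs))
  meta <- utils::modifyList(list(n_epochs = NA_integer_, sfreq = NA_real_,
                                 space = "channels", labels = NULL), meta)
  x <- structure(list(freqs = as.numeric(freqs), csd = csd, meta = meta),
                 class = "csd_data")
  if (check) validate_csd(x)
  x
}

validate_csd <- function(x, herm_tol = 1e-10, psd_tol = -1e-10) {
  if (any(diff(x$freqs) <= 0)) stop("freqs must be strictly increasing")
  scale <- max(abs(x$csd), 1e-300)
  for (f in seq_along(x$freqs)) {
    G <- x$csd[, , f]
    if (max(abs(G - Conj(t(G)))) > herm_tol * max(scale, 1)) {
      stop(sprintf("CSD at %.3f Hz is not Hermitian", x$freqs[f]))
    }
    ev <- eigen((G + Conj(t(G))) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < psd_tol * max(scale, 1)) {
      stop(sprintf("CSD at %.3f Hz is not positive semi-definite (min eig %.3e)",
                   x$freqs[f], min(ev)))
    }
  }
  invisible(x)
}

#' @export
print.csd_data <- function(x, ...) {
  cat(sprintf("csd_data: %d x %d over %d frequencies (%.2f-%.2f Hz), space=%s\n",
              dim(x$csd)[1], dim(x$csd)[2], length(x$freqs),
              min(x$freqs), max(x$freqs), x$meta$space))
  invisible(x)
}

#' Stack a CSD into a real feature vector
#'
#' Per frequency, stacks the real parts of the upper triangle (including the
#' diagonal) followed by the imaginary parts of the strict upper triangle, so
#' an `m`-channel CSD over `F` frequencies yields `F * m^2` features.
#' [defeaturize_csd()] inverts the map exactly.
#'
#' @param csd a `csd_data` object (must be Hermitian).
#' @return List with `y` (numeric feature vector) and `blocks` (character
#'   vector, `"re"`/`"im"`, marking the noise-precision block of each feature).
#' @export
featurize_csd <- function(csd) {
  validate_csd(csd)
  m <- dim(csd$csd)[1]
  ut <- upper.tri(diag(m), diag = TRUE)
  uts <- upper.tri(diag(m), diag = FALSE)
  nf <- length(csd$freqs)
  y <- numeric(0); blocks <- character(0)
  ylist <- vector("list", nf)
  for (f in seq_len(nf)) {
    G <- csd$csd[, , f]
    ylist[[f]] <- c(Re(G)[ut], Im(G)[uts])
  }
  y <- unlist(ylist)
  blocks <- rep(c(rep("re", sum(ut)), rep("im", sum(uts))), nf)
  list(y = y, blocks = blocks, m = m, freqs = csd$freqs)
}

# Inverse standard-error weights for CSD features. The sampling variance of a
# cross-spectral estimate scales with the product of the auto-spectra at that
# frequency (Wishart / Welch averaging), so dividing each feature by
# sqrt(G_ii * G_jj) makes the residuals approximately homoscedastic across
# frequencies and pairs; the remaining global factor is absorbed by the noise
# precision hyperparameters. The auto-spectra are smoothed across frequency
# (running mean, half-width `half_bw` bins) before use so that the sampling
# noise of the weights is nearly independent of the per-bin residuals; the
# underlying spectra vary smoothly so little heteroscedasticity correction is
# lost. Diagonals are floored to guard near-zero power.
csd_feature_weights <- function(csd, half_bw = 4L) {
  m <- dim(csd$csd)[1]
  ii <- rep(seq_len(m), times = m)
  jj <- rep(seq_len(m), each = m)
  ut <- which(ii <= jj)
  uts <- which(ii < jj)
  nf <- length(csd$freqs)
  dmat <- matrix(0, m, nf)
  for (f in seq_len(nf)) dmat[, f] <- Re(diag(csd$csd[, , f]))
  if (half_bw > 0L && nf > 1L) {
    sm <- dmat
    for (f in seq_len(nf)) {
      lo <- max(1L, f - half_bw); hi <- min(nf, f + half_bw)
      sm[, f] <- rowMeans(dmat[, lo:hi, drop = FALSE])
    }
    dmat <- sm
  }
  wlist <- vector("list", nf)
  for (f in seq_len(nf)) {
    d <- pmax(dmat[, f], 1e-12 * max(dmat[, f], 1e-300))
    se <- sqrt(d[ii] * d[jj])
    wlist[[f]] <- 1 / c(se[ut], se[uts])
  }
  unlist(wlist)
}

#' @rdname featurize_csd
#' @param feat the list returned by [featurize_csd()] (with `y` possibly
#'   replaced by another vector of the same length).
#' @param meta metadata for the reconstructed `csd_data`.
#' @export
defeaturize_csd <- function(feat, meta = list()) {
  m <- feat$m
  ut <- upper.tri(diag(m), diag = TRUE)
  uts <- upper.tri(diag(m), diag = FALSE)
  per <- m^2
  nf <- length(feat$freqs)
  stopifnot(length(feat$y) == per * nf)
  arr <- array(0 + 0i, c(m, m, nf))
  nre <- sum(ut)
  for (f in seq_len(nf)) {
    chunk <- feat$y[((f - 1) * per + 1):(f * per)]
    Gr <- matrix(0, m, m); Gi <- matrix(0, m, m)
    Gr[ut] <- chunk[1:nre]
    Gi[uts] <- chunk[(nre + 1):per]
    G <- Gr + 1i * Gi
    G <- G + Conj(t(G)) - diag(diag(Re(G)), m)
    arr[, , f] <- G
  }
  csd_data(feat$freqs, arr, meta = meta, check = FALSE)
}

#' Synthetic lead field
#'
#' Builds a seeded random, well-conditioned `m x 4` lead field with unit
#' column norms: a random orthonormal basis blended with Gaussian noise, then
#' column-normalized. Stands in for a subject-specific head model, which the
#' package does not compute.
#'
#' @param n_channels number of observation channels `m` (>= 4).
#' @param seed integer seed.
#' @param labels optional channel labels.
#' @return An object of class `lead_field` with elements `matrix`, `labels`,
#'   `provenance`.
#' @export
make_lead_field <- function(n_channels = 8L, seed = 1L, labels = NULL) {
  stopifnot(n_channels >= 4L)
  G <- with_seed(seed, matrix(stats::rnorm(n_channels * 4L), n_channels, 4L))
  Q <- qr.Q(qr(G))
  L <- 0.8 * Q + 0.2 * G / sqrt(n_channels)
  L <- sweep(L, 2, sqrt(colSums(L^2)), `/`)
  if (qr(L)$rank < 4L) stop("lead field is rank-deficient")
  if (is.null(labels)) labels <- paste0("ch", seq_len(n_channels))
  structure(list(matrix = L, labels = labels, provenance = "synthetic"),
            class = "lead_field")
}

#' Wrap a user-supplied lead field
#'
#' @param matrix numeric `m x 4` matrix of full column rank.
#' @param labels optional channel labels.
#' @return A `lead_field` with provenance `"supplied"`.
#' @export
as_lead_field <- function(matrix, labels = NULL) {
  stopifnot(is.matrix(matrix), ncol(matrix) == 4L, nrow(matrix) >= 4L)
  if (qr(matrix)$rank < 4L) stop("lead field must have full column rank")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(matrix)))
  structure(list(matrix = matrix, labels = labels, provenance = "supplied"),
            class = "lead_field")
}

#' Welch cross-spectral estimation
#'
#' Splits a multichannel recording into non-overlapping epochs, applies a Hann
#' taper, and averages per-epoch cross-periodograms into a one-sided
#' cross-spectral density, restricted to a frequency band.
#'
#' @param recording a `recording` object (see [read_timeseries()]) or a
#'   channels-by-samples matrix with attribute `sfreq`.
#' @param epoch_len epoch length in seconds (default 10).
#' @param sfreq sampling rate in Hz (taken from the recording if present).
#' @param band length-2 frequency band in Hz.
#' @return A `csd_data` with `n_epochs` recorded in the metadata.
#' @export
welch_csd <- function(recording, epoch_len = 10, sfreq = NULL,
                      band = c(1, 30)) {
  if (inherits(recording, "recording")) {
    X <- recording$data; sfreq <- recording$sfreq; labels <- recording$labels
  } else {
    X <- recording
    if (is.null(sfreq)) sfreq <- attr(recording, "sfreq")
    labels <- rownames(X)
  }
  if (is.null(sfreq)) stop("sampling rate unknown")
  if (band[2] > sfreq / 2) stop("band exceeds the Nyquist frequency")
  m <- nrow(X)
  nper <- round(epoch_len * sfreq)
  n_ep <- floor(ncol(X) / nper)
  if (n_ep < 2L) stop("recording must contain at least 2 epochs")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann taper
  U <- sfreq * sum(w^2)                                      # PSD normalizer
  freqs_all <- (0:(nper %/% 2)) * sfreq / nper
  keep <- which(freqs_all >= band[1] & freqs_all <= band[2])
  acc <- array(0 + 0i, c(m, m, length(keep)))
  for (e in seq_len(n_ep)) {
    seg <- X[, ((e - 1) * nper + 1):(e * nper), drop = FALSE]
    seg <- seg - rowMeans(seg)
    Fx <- t(apply(seg * rep(w, each = m), 1, stats::fft))   # m x nper
    Fk <- Fx[, keep, drop = FALSE]
    for (f in seq_along(keep)) {
      acc[, , f] <- acc[, , f] + (2 / U) * (Fk[, f] %*% Conj(t(Fk[, f])))
    }
  }
  acc <- acc / n_ep
  csd_data(freqs_all[keep], acc,
           meta = list(n_epochs = n_ep, sfreq = sfreq, space = "channels",
                       labels = labels),
           check = FALSE)
}

#' Project channel data onto leading spatial modes
#'
#' Computes the principal spatial components of the band-limited data (the
#' eigenvectors of the real part of the frequency-summed CSD) and projects the
#' cross-spectra onto the leading `n_modes` of them. The projection matrix is
#' returned for reproducibility and for projecting the lead field into the
#' same space.
#'
#' @param data a `csd_data`.
#' @param n_modes number of spatial modes to retain (1..m).
#' @return List with `data` (reduced `csd_data`, `space = "modes"`) and
#'   `projection` (`m x n_modes` orthonormal matrix).
#' @export
project_modes <- function(data, n_modes) {
  stopifnot(inherits(data, "csd_data"))
  m <- dim(data$csd)[1]
  if (n_modes < 1L) stop("n_modes must be at least 1")
  if (n_modes > m) stop("n_modes cannot exceed the channel count")
  S <- matrix(0, m, m)
  for (f in seq_along(data$freqs)) S <- S + Re(data$csd[, , f])
  U <- eigen((S + t(S)) / 2, symmetric = TRUE)$vectors[, seq_len(n_modes), drop = FALSE]
  arr <- array(0 + 0i, c(n_modes, n_modes, length(data$freqs)))
  for (f in seq_along(data$freqs)) {
    arr[, , f] <- Conj(t(U)) %*% data$csd[, , f] %*% U
  }
  red <- csd_data(data$freqs, arr,
                  meta = utils::modifyList(data$meta,
                                           list(space = "modes",
                                                labels = paste0("mode", seq_len(n_modes)))),
                  check = FALSE)
  list(data = red, projection = U)
}

#' Write / read a CSD container
#'
#' A container is a directory with `meta.json` (frequencies, dimensions,
#' metadata) and `arrays.bin` (doubles: the CSD as interleaved real/imaginary
#' parts, column-major per frequency). The round trip is exact.
#'
#' @param csd a `csd_data`.
#' @param path directory to create.
#' @export
write_csd <- function(csd, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  m <- dim(csd$csd)[1]
  meta <- list(freqs = csd$freqs, m = m, n_freq = length(csd$freqs),
               meta = csd$meta)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(file.path(path, "arrays.bin"), "wb")
  on.exit(close(con))
  vals <- as.vector(csd$csd)
  writeBin(as.numeric(rbind(Re(vals), Im(vals))), con, size = 8)
  invisible(path)
}

#' @rdname write_csd
#' @param path container directory.
#' @export
read_csd <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  n <- meta$m^2 * meta$n_freq
  con <- file(file.path(path, "arrays.bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = 2 * n, size = 8)
  if (length(raw) != 2 * n) stop("arrays.bin truncated in ", path)
  vals <- raw[seq(1, 2 * n, by = 2)] + 1i * raw[seq(2, 2 * n, by = 2)]
  meta_list <- as.list(meta$meta)
  if (!is.null(meta_list$labels)) meta_list$labels <- unlist(meta_list$labels)
  csd_data(meta$freqs, array(vals, c(meta$m, meta$m, meta$n_freq)),
           meta = meta_list, check = FALSE)
}

# seeded evaluation that leaves the global RNG stream untouched
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
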