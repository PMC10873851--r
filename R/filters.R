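# Zero-phase filtering for Recording objects.
#
# The band-pass and anti-alias filters are linear-phase FIR designs with a
# Kaiser window (60 dB stopband). Zero phase is obtained by applying the
# squared-magnitude kernel g = conv(b, rev(b)) in one pass via FFT
# convolution, which is algebraically identical to forward-backward filtering
# of the FIR and keeps topographic timing intact. Edges are handled by odd
# (point-symmetric) reflection padding.

# design a Kaiser-window FIR; returns the coefficient vector (odd length)
kaiser_fir <- function(fs, w, type, trans_hz, atten_db = 60) {
  beta <- if (atten_db > 50) 0.1102 * (atten_db - 8.7)
          else if (atten_db >= 21) 0.5842 * (atten_db - 21)^0.4 +
                 0.07886 * (atten_db - 21)
          else 0
  dw <- 2 * pi * trans_hz / fs
  n <- ceiling((atten_db - 7.95) / (2.285 * dw))
  if (n %% 2 == 1) n <- n + 1  # even order -> odd, symmetric (type I) FIR
  signal::fir1(n, w, type = type, window = signal::kaiser(n + 1, beta),
               scale = TRUE)
}

# zero-phase FIR application: x is samples x channels
fir_zerophase <- function(x, b) {
  g <- stats::convolve(b, rev(b), type = "open")  # symmetric, length 2L-1
  lg <- length(g)
  h <- (lg - 1L) %/% 2L
  nt <- nrow(x)
  p <- min(h, nt - 1L)
  first <- matrix(x[1L, ], p, ncol(x), byrow = TRUE)
  last <- matrix(x[nt, ], p, ncol(x), byrow = TRUE)
  pre <- 2 * first - x[seq(p + 1L, 2L), , drop = FALSE]
  post <- 2 * last - x[seq(nt - 1L, nt - p), , drop = FALSE]
  xp <- rbind(pre, x, post)
  nfull <- nrow(xp) + lg - 1L
  nfft <- stats::nextn(nfull, 2)
  xpad <- rbind(xp, matrix(0, nfft - nrow(xp), ncol(xp)))
  gf <- stats::fft(c(g, rep(0, nfft - lg)))
  y <- Re(stats::mvfft(stats::mvfft(xpad) * gf, inverse = TRUE)) / nfft
  y[(h + p + 1L):(h + p + nt), , drop = FALSE]
}

apply_zerophase <- function(rec, b) {
  rec$data <- t(fir_zerophase(t(rec$data), b))
  rec
}

#' Zero-phase Kaiser band-pass filter
#'
#' Removes the channel DC offsets, then applies a linear-phase FIR band-pass
#' (Kaiser window, 60 dB stopband per pass) forward-backward, so the output is
#' zero phase. The artifact mask is unchanged.
#'
#' @param rec an [recording()].
#' @param lo,hi band edges in Hz, `0 < lo < hi < fs/2`.
#' @param trans transition width in Hz; default
#'   `min(lo, fs/2 - hi, (hi - lo)/3)`.
#' @return Filtered recording.
#' @export
bandpass <- function(rec, lo, hi, trans = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (!(lo > 0 && hi > lo)) stop("need 0 < lo < hi")
  if (hi >= fs / 2) stop("'hi' must be below the Nyquist frequency fs/2")
  if (is.null(trans)) trans <- min(lo, fs / 2 - hi, (hi - lo) / 3)
  rec$data <- rec$data - rowMeans(rec$data)  # explicit DC removal
  b <- kaiser_fir(fs, c(lo, hi) / (fs / 2), "pass", trans)
  apply_zerophase(rec, b)
}

#' Zero-phase notch filter
#'
#' Second-order IIR notch (biquad, quality factor `q`) applied
#' forward-backward per channel. Attenuation at `f0` exceeds 20 dB while
#' bands a few Hz away are preserved.
#'
#' @param rec an [recording()].
#' @param f0 notch frequency in Hz, `0 < f0 < fs/2`.
#' @param q quality factor (stopband narrowness); default 30.
#' @return Filtered recording.
#' @export
notch <- function(rec, f0, q = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (!(f0 > 0 && f0 < fs / 2)) stop("'f0' must lie in (0, fs/2)")
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  b <- b / a[1]; a <- a / a[1]
  rec$data <- t(apply(rec$data, 1, function(ch) {
    signal::filtfilt(signal::Arma(b = b, a = a), ch)
  }))
  rec
}

#' Anti-aliased integer-ratio downsampling
#'
#' Low-pass filters at 80% of the target Nyquist frequency (zero-phase FIR),
#' then keeps every r-th sample, where `r = fs / target_fs` must be an
#' integer. The artifact mask is decimated with a logical OR over each window
#' of r samples, so a window containing any artifact sample stays masked.
#'
#' @param rec an [recording()].
#' @param target_fs target sampling rate in Hz; must divide `fs`.
#' @return Recording at `target_fs`.
#' @export
downsample <- function(rec, target_fs) {
  stopifnot(inherits(rec, "eeg_recording"))
  r <- rec$fs / target_fs
  if (abs(r - round(r)) > 1e-9) {
    stop("'target_fs' must divide the sampling rate (integer ratio)")
  }
  r <- as.integer(round(r))
  if (r == 1L) return(rec)
  cutoff <- 0.8 * (target_fs / 2)
  b <- kaiser_fir(rec$fs, cutoff / (rec$fs / 2), "low",
                  trans_hz = 0.2 * target_fs / 2)
  rec <- apply_zerophase(rec, b)
  nt <- ncol(rec$data)
  keep <- seq(1L, nt, by = r)
  newmask <- vapply(keep, function(i) {
    any(rec$mask[i:min(i + r - 1L, nt)])
  }, logical(1))
  rec$data <- rec$data[, keep, drop = FALSE]
  rec$mask <- newmask
  rec$fs <- target_fs
  rec
}
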