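#' Running-median baseline estimate
#'
#' Cascade of two running medians, 200 ms then 600 ms, the classical ECG
#' baseline-wander estimator: the first window straddles QRS complexes, the
#' second P/T waves, leaving the slow baseline. Window lengths are rounded to
#' the nearest odd sample count (half up); at the edges the window shrinks to
#' the available samples, so output length equals input length.
#'
#' @param signal Numeric amplitude series.
#' @param fs Sampling rate (Hz).
#' @return Baseline estimate, same length as `signal`.
#' @export
median_baseline <- function(signal, fs) {
  stopifnot(fs > 0, length(signal) > 0)
  b <- running_median(signal, odd_window(0.2 * fs))
  running_median(b, odd_window(0.6 * fs))
}

odd_window <- function(w) {
  k <- round_half_up(w)
  if (k %% 2 == 0) k <- k + 1L
  max(1L, as.integer(k))
}

# fixed-odd-window running median; edge windows shrink (clipped to bounds)
running_median <- function(x, k) {
  n <- length(x)
  h <- (k - 1L) %/% 2L
  if (n <= k) {
    return(vapply(seq_len(n), function(i)
      stats::median(x[max(1L, i - h):min(n, i + h)]), numeric(1)))
  }
  out <- as.numeric(stats::runmed(x, k, endrule = "keep"))
  edge <- seq_len(h)
  out[edge] <- vapply(edge, function(i)
    stats::median(x[1L:(i + h)]), numeric(1))
  out[n - edge + 1L] <- vapply(edge, function(i)
    stats::median(x[(n - i + 1L - h):n]), numeric(1))
  out
}

# ---- FIR designs -------------------------------------------------------------

fir_response <- function(h, f, fs) {
  k <- seq_along(h) - 1L
  Mod(vapply(f, function(fi) sum(h * exp(-2i * pi * fi * k / fs)), complex(1)))
}

# 12-tap Hamming windowed-sinc low-pass; cutoff solved so |H(35 Hz)| = -3 dB
design_lowpass_35 <- function(fs, n_taps = 12L) {
  if (fs <= 70) stop("fs = ", fs, " Hz is too low for a 35 Hz corner (need fs > 70)")
  target <- 1 / sqrt(2)
  g <- function(wc) fir_response(signal::fir1(n_taps - 1L, wc), 35, fs) - target
  wc <- stats::uniroot(g, c(35 / (fs / 2) * 0.3, min(0.99, 35 / (fs / 2) * 3)),
                       tol = 1e-10)$root
  signal::fir1(n_taps - 1L, wc)
}

# 1 Hz high-pass as the spectral complement (delta - lowpass) of a 1.5 s
# odd-length linear-phase low-pass; cutoff solved so the complement is -3 dB
# at 1 Hz. A 12-tap FIR cannot place a corner at 1 Hz for ECG sampling rates.
design_highpass_1 <- function(fs) {
  n_taps <- odd_window(1.5 * fs)
  target <- 1 - 1 / sqrt(2)   # complement amplitude at the corner
  design_lp <- function(wc) {
    h <- signal::fir1(n_taps - 1L, wc)
    h / sum(h)                # force exact unit DC gain so the complement
  }                           # rejects DC completely
  wc <- stats::uniroot(function(wc) fir_response(design_lp(wc), 1, fs) - target,
                       c(1e-5, min(0.5, 20 / (fs / 2))), tol = 1e-10)$root
  lp <- design_lp(wc)
  hp <- -lp
  hp[(n_taps + 1L) %/% 2L] <- hp[(n_taps + 1L) %/% 2L] + 1
  hp
}

# convolve and realign by the filter's (floor of the) group delay so output
# length equals input length; zero-padded edges
fir_apply <- function(x, h) {
  n <- length(x)
  full <- stats::convolve(x, rev(h), type = "open")
  d <- (length(h) - 1L) %/% 2L
  full[(1L + d):(n + d)]
}

#' Apply a preprocessing chain to a record
#'
#' Three evaluated chains: `"de_chazal"` subtracts the two-stage
#' [median_baseline()] then applies a 12-tap linear-phase low-pass with -3 dB
#' at 35 Hz; `"common"` applies the same low-pass followed by a high-pass with
#' -3 dB at 1 Hz (realized as the spectral complement of a 1.5 s linear-phase
#' low-pass); `"none"` is the identity. Both leads are filtered identically;
#' group delay is compensated by a forward shift so output length equals input
#' length.
#'
#' @param record An [ecg_record].
#' @param name One of `"de_chazal"`, `"common"`, `"none"`.
#' @return The filtered [ecg_record].
#' @export
ecg_filter <- function(record, name = c("de_chazal", "common", "none")) {
  stopifnot(inherits(record, "ecg_record"))
  name <- match.arg(name)
  if (name == "none") return(record)
  fs <- record$fs
  lp <- design_lowpass_35(fs)
  chain <- switch(name,
    de_chazal = function(x) fir_apply(x - median_baseline(x, fs), lp),
    common = {
      hp <- design_highpass_1(fs)
      function(x) fir_apply(fir_apply(x, lp), hp)
    })
  record$lead_a <- chain(record$lead_a)
  record$lead_b <- chain(record$lead_b)
  record
}
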