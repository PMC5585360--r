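#' Interval features of a beat
#'
#' Rhythm and fiducial-interval features: pre-RR, post-RR and local average RR
#' (seconds); per lead the QRS duration, the T-wave duration (QRS offset to T
#' end) and the P-wave presence flag; plus four normalized RR ratios
#' (pre/local, post/local, pre/post, mean(pre, post)/local) — 13 features.
#' Fiducials are shared across leads here, so the per-lead triple repeats with
#' the same values; the block keeps both copies so its layout matches feature
#' sets whose delineation is lead-specific.
#'
#' @param beat A [beat_window].
#' @return Named numeric vector of length 13 (names prefixed `interval_`).
#' @export
interval_features <- function(beat) {
  stopifnot(inherits(beat, "beat_window"))
  f <- beat$fiducials
  fs <- beat$fs
  qrs_dur <- (f$qrs_offset - f$qrs_onset) / fs
  t_dur <- (f$t_end - f$qrs_offset) / fs
  p_flag <- as.numeric(isTRUE(f$p_wave_present))
  pre <- beat$pre_rr_s; post <- beat$post_rr_s; loc <- beat$local_rr_s
  ratio <- function(num, den) if (den > 0) num / den else 0
  out <- c(pre_rr = pre, post_rr = post, local_rr = loc,
           qrs_dur_a = qrs_dur, t_dur_a = t_dur, p_present_a = p_flag,
           qrs_dur_b = qrs_dur, t_dur_b = t_dur, p_present_b = p_flag,
           pre_over_local = ratio(pre, loc),
           post_over_local = ratio(post, loc),
           pre_over_post = ratio(pre, post),
           mean_rr_over_local = ratio((pre + post) / 2, loc))
  names(out) <- paste0("interval_", names(out))
  out
}

# uniform resampling of signal over 0-based sample span [from, to] to n points
resample_segment <- function(x, from, to, n) {
  from <- max(0, min(from, length(x) - 1L))
  to <- max(0, min(to, length(x) - 1L))
  if (from == to) return(rep(x[from + 1L], n))
  at <- seq(from, to, length.out = n)
  stats::approx(seq_along(x) - 1L, x, xout = at)$y
}

#' Raw-morphology amplitude samples of a beat
#'
#' Per lead, 37 amplitudes resampled uniformly (linear interpolation) from
#' four landmark-anchored segments: 10 across the QRS complex, 9 from QRS end
#' to the T wave, 10 from R - 50 ms to R + 100 ms, and 8 from R + 150 ms to
#' R + 500 ms (clipped to the window). Both the absolute values and the
#' values normalized by the lead's max absolute amplitude in the window are
#' emitted: 2 leads x 37 x 2 = 148 features.
#'
#' @param beat A [beat_window].
#' @return Named numeric vector of length 148 (names prefixed `morph_`).
#' @export
morphology_samples <- function(beat) {
  stopifnot(inherits(beat, "beat_window"))
  f <- beat$fiducials
  fs <- beat$fs
  r <- f$r_index
  ms <- function(x) round_half_up(x / 1000 * fs)
  segs <- list(qrs = c(f$qrs_onset, f$qrs_offset, 10L),
               st = c(f$qrs_offset, f$t_end, 9L),
               peri_r = c(r - ms(50), r + ms(100), 10L),
               late = c(r + ms(150), r + ms(500), 8L))
  one_lead <- function(x, lead) {
    abs_vals <- unlist(lapply(names(segs), function(s) {
      v <- resample_segment(x, segs[[s]][1L], segs[[s]][2L], segs[[s]][3L])
      names(v) <- sprintf("morph_%s_%s_%02d_abs", lead, s, seq_along(v))
      v
    }))
    mx <- max(abs(x))
    norm_vals <- if (mx > 0) abs_vals / mx else abs_vals * 0
    names(norm_vals) <- sub("_abs$", "_norm", names(abs_vals))
    c(abs_vals, norm_vals)
  }
  c(one_lead(beat$lead_a, "a"), one_lead(beat$lead_b, "b"))
}

# one level of the orthonormal Haar DWT; odd trailing sample is dropped
haar_step <- function(x) {
  n2 <- length(x) %/% 2L
  e <- x[seq(1L, by = 2L, length.out = n2)]
  o <- x[seq(2L, by = 2L, length.out = n2)]
  list(a = (e + o) / sqrt(2), d = (e - o) / sqrt(2))
}

# autocorrelation at shift l: sum_{n=l}^{N-1} x[n] x[n-l] (0-based)
autocorr_shift <- function(x, l = 1L) {
  n <- length(x)
  if (n <= l) return(0)
  sum(x[(l + 1L):n] * x[1L:(n - l)])
}

#' Haar-wavelet and autocorrelation features of a beat
#'
#' Two-level orthonormal Haar DWT of lead A gives the detail bands D1, D2 and
#' approximation A2. Each band contributes its lag-1 autocorrelation
#' `sum x(n) x(n-1)` and its relative amplitude `min(x)/max(x)` (0 when
#' `max(x) = 0`); the variance of the lead-A samples across the QRS span
#' completes the block: 7 features.
#'
#' @param beat A [beat_window].
#' @return Named numeric vector of length 7 (names prefixed `wavelet_`).
#' @export
haar_features <- function(beat) {
  stopifnot(inherits(beat, "beat_window"), length(beat$lead_a) >= 4L)
  l1 <- haar_step(beat$lead_a)
  l2 <- haar_step(l1$a)
  bands <- list(d1 = l1$d, d2 = l2$d, a2 = l2$a)
  rel_amp <- function(x) if (max(x) == 0) 0 else min(x) / max(x)
  out <- unlist(lapply(names(bands), function(b)
    stats::setNames(c(autocorr_shift(bands[[b]], 1L), rel_amp(bands[[b]])),
                    paste0(b, c("_ac1", "_relamp")))))
  f <- beat$fiducials
  qrs <- beat$lead_a[(f$qrs_onset + 1L):(f$qrs_offset + 1L)]
  out <- c(out, qrs_var = if (length(qrs) > 1L) stats::var(qrs) else 0)
  names(out) <- paste0("wavelet_", names(out))
  out
}

#' Assemble the full feature vector of a beat
#'
#' Concatenation `[morphology (148), interval (13), wavelet (7),
#' complex-network (m * 5)]`; 178 features with the default `m = 2`,
#' 173 with `m = 1`. Any non-finite value is replaced by 0 (the count is
#' recorded in the `"n_imputed"` attribute) so the vector length is fixed for
#' the selection mask.
#'
#' @param beat A [beat_window].
#' @param t0,tq,m Complex-network threshold parameters.
#' @param subsample_step TVCG subsampling step.
#' @return Named numeric vector.
#' @export
beat_features <- function(beat, t0 = 0.05, tq = 0.5, m = 2L,
                          subsample_step = 2L) {
  cn <- tvcg_features(build_tvcg(beat, subsample_step), t0, tq, m)
  v <- c(morphology_samples(beat), interval_features(beat),
         haar_features(beat), cn)
  bad <- !is.finite(v)
  if (any(bad)) v[bad] <- 0
  attr(v, "n_imputed") <- sum(bad)
  v
}

#' Feature matrix for a list of beats
#'
#' @param beats List of [beat_window] objects.
#' @inheritParams beat_features
#' @return List with `x` (matrix, one row per beat, named columns) and `y`
#'   (character labels).
#' @export
feature_matrix <- function(beats, t0 = 0.05, tq = 0.5, m = 2L,
                           subsample_step = 2L) {
  rows <- lapply(beats, beat_features, t0 = t0, tq = tq, m = m,
                 subsample_step = subsample_step)
  x <- do.call(rbind, rows)
  list(x = x, y = vapply(beats, `[[`, character(1), "label"))
}

#' Fit / apply per-feature z-score standardization
#'
#' `fit_standardizer()` learns per-column means and standard deviations on
#' training data only (zero-variance columns get sd 1 so they map to 0);
#' `apply_standardizer()` reuses them verbatim on any split.
#'
#' @param x Numeric feature matrix.
#' @param sc A standardizer from `fit_standardizer()`.
#' @return `fit_standardizer()`: an object with `center`, `scale`;
#'   `apply_standardizer()`: the standardized matrix.
#' @export
fit_standardizer <- function(x) {
  ctr <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  structure(list(center = ctr, scale = sdv), class = "feat_standardizer")
}

#' @rdname fit_standardizer
#' @export
apply_standardizer <- function(x, sc) {
  stopifnot(inherits(sc, "feat_standardizer"), ncol(x) == length(sc$center))
  out <- sweep(sweep(x, 2L, sc$center, "-"), 2L, sc$scale, "/")
  out[!is.finite(out)] <- 0
  out
}
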