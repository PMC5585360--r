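#' Extract a fixed-length beat window with RR features
#'
#' Cuts the window `[r - 250 ms, r + 450 ms]` around the annotated R point
#' (zero-padded where it overruns the record) and attaches the rhythm
#' features: pre-RR, post-RR and the local average RR (mean pre-RR over the up
#' to 10 beats surrounding the indexed one, shrinking at record edges). The
#' first beat's pre-RR falls back to its post-RR, and symmetrically for the
#' last beat. Fiducials are re-expressed relative to the window start and
#' clipped to it.
#'
#' @param record An [ecg_record].
#' @param fiducials Data frame as returned by [synth_fiducials()] (columns
#'   `r_index`, `qrs_onset`, `qrs_offset`, `t_end`, `p_wave_present`,
#'   `label`), 0-based sample indices.
#' @param beat_index Which beat (1-based row of `fiducials`).
#' @param pre_ms,post_ms Window extent around R in milliseconds.
#' @return A `beat_window` object: `lead_a`, `lead_b`, `fs`, `fiducials`
#'   (window-relative, 0-based), `label`, `pre_rr_s`, `post_rr_s`,
#'   `local_rr_s`.
#' @export
beat_window <- function(record, fiducials, beat_index,
                        pre_ms = 250, post_ms = 450) {
  stopifnot(inherits(record, "ecg_record"))
  n_beats <- nrow(fiducials)
  if (n_beats < 2L)
    stop("RR features are undefined for a record with fewer than 2 beats")
  if (beat_index < 1L || beat_index > n_beats)
    stop("beat_index out of range")
  fs <- record$fs
  pre <- round_half_up(pre_ms / 1000 * fs)
  post <- round_half_up(post_ms / 1000 * fs)
  r <- fiducials$r_index[beat_index]
  idx <- (r - pre):(r + post)            # 0-based sample indices
  pad <- function(x) {
    out <- numeric(length(idx))
    ok <- idx >= 0L & idx < length(x)
    out[ok] <- x[idx[ok] + 1L]
    out
  }

  rr_all <- diff(fiducials$r_index) / fs # rr_all[k] = pre-RR of beat k+1
  pre_rr <- c(NA, rr_all)
  post_rr <- c(rr_all, NA)
  pre_rr[1L] <- post_rr[1L]              # edge fallbacks
  post_rr[n_beats] <- pre_rr[n_beats]
  lo <- max(1L, beat_index - 5L)
  hi <- min(n_beats, beat_index + 5L)
  local_rr <- mean(pre_rr[lo:hi])

  win_start <- r - pre
  clip <- function(s) pmin(pmax(s - win_start, 0L), length(idx) - 1L)
  fid <- list(r_index = clip(r),
              qrs_onset = clip(fiducials$qrs_onset[beat_index]),
              qrs_offset = clip(fiducials$qrs_offset[beat_index]),
              t_end = clip(fiducials$t_end[beat_index]),
              p_wave_present = fiducials$p_wave_present[beat_index])
  structure(list(lead_a = pad(record$lead_a), lead_b = pad(record$lead_b),
                 fs = fs, fiducials = fid,
                 label = fiducials$label[beat_index],
                 pre_rr_s = pre_rr[beat_index],
                 post_rr_s = post_rr[beat_index],
                 local_rr_s = local_rr),
            class = "beat_window")
}

#' All beat windows of a record
#'
#' @inheritParams beat_window
#' @return List of [beat_window] objects, one per fiducial row.
#' @export
beat_windows <- function(record, fiducials, pre_ms = 250, post_ms = 450) {
  lapply(seq_len(nrow(fiducials)), function(i)
    beat_window(record, fiducials, i, pre_ms = pre_ms, post_ms = post_ms))
}

#' Vectorcardiogram of a beat
#'
#' The 2-D representation that plots one lead against the other, discarding
#' time order: point k is `(lead_a[k], lead_b[k])`.
#'
#' @param beat A [beat_window].
#' @return Numeric matrix with columns `x`, `y`, one row per sample.
#' @export
build_vcg <- function(beat) {
  stopifnot(inherits(beat, "beat_window"))
  cbind(x = beat$lead_a, y = beat$lead_b)
}

#' Temporal vectorcardiogram of a beat
#'
#' Adds time as a third axis to the VCG, then min-max normalizes each axis to
#' `[0, 1]` over the beat so that the Euclidean distances feeding the
#' complex-network construction weight the two leads and time comparably. A
#' constant axis maps to all zeros. Samples are taken every `subsample_step`
#' positions to bound the O(n^2) weight matrix.
#'
#' @param beat A [beat_window].
#' @param subsample_step Keep every k-th sample (default 2).
#' @return A `tvcg_points` object: matrix `points` with columns `x`, `y`, `z`
#'   (normalized), and `n_v` the point count.
#' @export
build_tvcg <- function(beat, subsample_step = 2L) {
  stopifnot(inherits(beat, "beat_window"), subsample_step >= 1L)
  keep <- seq(1L, length(beat$lead_a), by = subsample_step)
  if (length(keep) < 2L)
    stop("fewer than 2 points after subsampling (step ", subsample_step, ")")
  norm01 <- function(v) {
    rng <- range(v)
    if (rng[1] == rng[2]) return(rep(0, length(v)))
    (v - rng[1]) / (rng[2] - rng[1])
  }
  pts <- cbind(x = norm01(beat$lead_a[keep]),
               y = norm01(beat$lead_b[keep]),
               z = norm01(as.numeric(keep - 1L)))
  structure(list(points = pts, n_v = nrow(pts)), class = "tvcg_points")
}

#' @export
print.tvcg_points <- function(x, ...) {
  cat(sprintf("tvcg_points: %d points in [0,1]^3\n", x$n_v))
  invisible(x)
}

#' @param x A `tvcg_points` object.
#' @param ... Passed to [graphics::plot()].
#' @rdname build_tvcg
#' @export
plot.tvcg_points <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  p <- x$points
  graphics::plot(p[, "x"], p[, "y"], type = "l", xlab = "lead A",
                 ylab = "lead B", main = "VCG projection", ...)
  graphics::plot(p[, "z"], p[, "x"], type = "l", xlab = "time",
                 ylab = "lead A", main = "lead A vs time", ...)
  graphics::plot(p[, "z"], p[, "y"], type = "l", xlab = "time",
                 ylab = "lead B", main = "lead B vs time", ...)
  invisible(x)
}
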