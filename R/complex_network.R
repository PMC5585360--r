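#' Normalized pairwise-distance weight matrix
#'
#' Euclidean distances between every pair of TVCG points, divided by their
#' maximum so weights lie in `[0, 1]` (all-coincident point sets give the
#' all-zero matrix). This fully connected weighted graph is the "regular
#' network" that threshold evolution turns into a complex network.
#'
#' @param points A `tvcg_points` object from [build_tvcg()], or a numeric
#'   matrix of point coordinates (rows = points).
#' @return Symmetric `n_v x n_v` matrix with zero diagonal, max weight 1.
#' @export
weight_matrix <- function(points) {
  pts <- if (inherits(points, "tvcg_points")) points$points else as.matrix(points)
  if (nrow(pts) < 2L) stop("need at least 2 points")
  w <- as.matrix(stats::dist(pts))
  mx <- max(w)
  if (mx > 0) w <- w / mx
  dimnames(w) <- NULL
  w
}

#' Threshold schedule for network evolution
#'
#' The m evenly spaced limits `T_l = T_0 + l (T_Q - T_0) / (m - 1)`,
#' `l = 0, ..., m-1`. With `m = 1` the schedule is just `T_0`.
#'
#' @param t0 Initial limit, in `[0, 1]`.
#' @param tq Final limit, `t0 <= tq <= 1`.
#' @param m Number of iterations (integer >= 1).
#' @return Numeric vector of length `m`.
#' @examples
#' threshold_schedule(0.1, 0.9, 5)  # 0.1 0.3 0.5 0.7 0.9
#' @export
threshold_schedule <- function(t0, tq, m) {
  if (t0 < 0 || tq > 1) stop("thresholds must lie in [0, 1]")
  if (t0 > tq) stop("t0 (", t0, ") must not exceed tq (", tq, ")")
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  if (m == 1L) return(t0)
  # seq() pins both endpoints, avoiding accumulation in t0 + l (tq - t0)/(m-1)
  seq(t0, tq, length.out = m)
}

#' Threshold a weight matrix into an adjacency matrix
#'
#' Edges with weight above the limit are removed; all vertices remain. The
#' edge `(i, j)` is kept iff `i != j` and `w_ij <= T`, so edge sets nest as
#' `T` grows.
#'
#' @param w Weight matrix from [weight_matrix()].
#' @param threshold Limit in `[0, 1]`.
#' @return Logical adjacency matrix.
#' @export
threshold_graph <- function(w, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  adj <- w <= threshold
  diag(adj) <- FALSE
  adj
}

#' Degree-based descriptors of a thresholded network
#'
#' The five descriptors summarizing connectivity, all normalized to be
#' comparable across beats with different vertex counts:
#' \itemize{
#'   \item mean connectivity degree: `sum(k_i) / n_v^2`
#'   \item maximum connectivity degree: `max(k_i) / n_v`
#'   \item joint degree entropy: `-sum(J log2 J)` (bits) over the joint
#'     degree distribution `J(a, b)`, the fraction of edges whose endpoint
#'     degrees form the unordered pair `{a, b}`
#'   \item joint degree energy: `sum(J^2)`
#'   \item mean joint degree: `sum(J(a, b) (a + b) / 2) / n_v`
#' }
#' An empty graph yields all five equal to 0.
#'
#' @param adj Logical adjacency matrix from [threshold_graph()].
#' @return Named numeric vector of length 5.
#' @export
cn_descriptors <- function(adj) {
  n_v <- nrow(adj)
  stopifnot(n_v >= 2L, ncol(adj) == n_v)
  deg <- rowSums(adj)
  out <- c(mean_degree = 0, max_degree = 0, joint_entropy = 0,
           joint_energy = 0, mean_joint_degree = 0)
  if (!any(adj)) return(out)
  out["mean_degree"] <- sum(deg) / n_v^2
  out["max_degree"] <- max(deg) / n_v
  ut <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  a <- pmin(deg[ut[, 1L]], deg[ut[, 2L]])
  b <- pmax(deg[ut[, 1L]], deg[ut[, 2L]])
  key <- paste(a, b)
  tab <- table(key)
  jj <- as.vector(tab) / nrow(ut)
  half <- (a + b)[match(names(tab), key)] / 2
  out["joint_entropy"] <- -sum(jj * log2(jj))
  out["joint_energy"] <- sum(jj^2)
  out["mean_joint_degree"] <- sum(jj * half) / n_v
  out
}

#' Complex-network feature vector of a beat's TVCG
#'
#' Concatenates [cn_descriptors()] over the [threshold_schedule()], lowest
#' threshold first, descriptor order as in [cn_descriptors()]; length `m * 5`.
#'
#' @param points A `tvcg_points` object (or coordinate matrix).
#' @param t0,tq,m Threshold-schedule parameters.
#' @return Named numeric vector of length `m * 5`.
#' @export
tvcg_features <- function(points, t0 = 0.05, tq = 0.5, m = 2L) {
  w <- weight_matrix(points)
  tvcg_features_from_w(w, t0, tq, m)
}

# split out so optimization can reuse precomputed weight matrices
tvcg_features_from_w <- function(w, t0, tq, m) {
  ts <- threshold_schedule(t0, tq, m)
  out <- unlist(lapply(seq_along(ts), function(l) {
    d <- cn_descriptors(threshold_graph(w, ts[l]))
    names(d) <- sprintf("tvcg_l%d_%s", l, names(d))
    d
  }))
  out
}
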