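#' Linearly decreasing inertia weight
#'
#' `w(t) = 0.9 - (t - 1) / (T - 1) * 0.5`, so the swarm explores early
#' (w = 0.9 at t = 1) and exploits late (w = 0.4 at t = T); a single-iteration
#' run uses 0.9.
#'
#' @param t Iteration, `1 <= t <= total`.
#' @param total Total iterations.
#' @param from,to Endpoints of the schedule.
#' @return Inertia weight.
#' @export
pso_inertia <- function(t, total, from = 0.9, to = 0.4) {
  stopifnot(t >= 1, t <= total)
  if (total == 1) return(from)
  from - (t - 1) / (total - 1) * (from - to)
}

#' Swarm configuration
#'
#' @param lower,upper Numeric bounds per dimension.
#' @param n_particles Swarm size (>= 2).
#' @param n_iter Iterations.
#' @param c1,c2 Acceleration constants (cognitive / social), default 2.05.
#' @param inertia Length-2 schedule endpoints (start, end).
#' @param vmax_frac Velocity clamp as a fraction of the box width per
#'   dimension.
#' @return A `swarm_config` list.
#' @export
swarm_config <- function(lower, upper, n_particles = 30L, n_iter = 100L,
                         c1 = 2.05, c2 = 2.05, inertia = c(0.9, 0.4),
                         vmax_frac = 0.5) {
  stopifnot(length(lower) == length(upper), all(lower < upper),
            n_particles >= 2L, n_iter >= 1L)
  structure(list(lower = lower, upper = upper,
                 n_particles = as.integer(n_particles),
                 n_iter = as.integer(n_iter), c1 = c1, c2 = c2,
                 inertia = inertia, vmax = vmax_frac * (upper - lower)),
            class = "swarm_config")
}

#' One synchronous swarm update
#'
#' Velocity update `v <- w(t) v + c1 g1 (pbest - x) + c2 g2 (gbest - x)` with
#' fresh uniform(0,1) draws `g1`, `g2` per particle and component, clamped to
#' `±vmax`; then `x <- x + v` clipped to the bounds. Uses R's global RNG
#' stream — seed the caller for reproducibility.
#'
#' @param swarm List with matrices `position`, `velocity`, `pbest`
#'   (n_particles x d).
#' @param gbest Best known position (length d).
#' @param cfg A [swarm_config()].
#' @param t Current iteration (for the inertia schedule).
#' @return The updated swarm.
#' @export
pso_step <- function(swarm, gbest, cfg, t) {
  n <- nrow(swarm$position)
  d <- ncol(swarm$position)
  w <- pso_inertia(t, cfg$n_iter, cfg$inertia[1], cfg$inertia[2])
  g1 <- matrix(stats::runif(n * d), n, d)
  g2 <- matrix(stats::runif(n * d), n, d)
  v <- w * swarm$velocity +
    cfg$c1 * g1 * (swarm$pbest - swarm$position) +
    cfg$c2 * g2 * (matrix(gbest, n, d, byrow = TRUE) - swarm$position)
  v <- pmin(pmax(v, matrix(-cfg$vmax, n, d, byrow = TRUE)),
            matrix(cfg$vmax, n, d, byrow = TRUE))
  x <- swarm$position + v
  x <- pmin(pmax(x, matrix(cfg$lower, n, d, byrow = TRUE)),
            matrix(cfg$upper, n, d, byrow = TRUE))
  swarm$velocity <- v
  swarm$position <- x
  swarm
}

#' Particle swarm maximization over a box
#'
#' Synchronous PSO with linearly decreasing inertia: every particle is
#' evaluated, then personal and global bests are updated once per iteration.
#' Non-finite objective values are treated as `-Inf`. The returned trace is
#' the best-so-far fitness per iteration (monotone non-decreasing).
#'
#' @param objective Function mapping a position vector to a scalar fitness
#'   (maximized).
#' @param cfg A [swarm_config()].
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#' @param repair Optional function applied to each candidate position before
#'   evaluation (e.g. swapping inverted threshold pairs); must return a
#'   position inside the box.
#' @return A `pso_result`: `best_position`, `best_fitness`, `trace`.
#' @examples
#' res <- pso_maximize(function(x) -sum(x^2),
#'                     swarm_config(rep(-5, 2), rep(5, 2), 20, 50), seed = 1)
#' res$best_fitness
#' @export
pso_maximize <- function(objective, cfg, seed = NULL, repair = NULL) {
  stopifnot(inherits(cfg, "swarm_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_particles
  d <- length(cfg$lower)
  lo <- matrix(cfg$lower, n, d, byrow = TRUE)
  hi <- matrix(cfg$upper, n, d, byrow = TRUE)
  position <- lo + matrix(stats::runif(n * d), n, d) * (hi - lo)
  velocity <- matrix(stats::runif(n * d, -1, 1), n, d) *
    matrix(cfg$vmax, n, d, byrow = TRUE)
  eval_all <- function(pos) {
    vapply(seq_len(nrow(pos)), function(i) {
      p <- pos[i, ]
      if (!is.null(repair)) p <- repair(p)
      f <- objective(p)
      if (!is.finite(f)) -Inf else f
    }, numeric(1))
  }
  fit <- eval_all(position)
  swarm <- list(position = position, velocity = velocity,
                pbest = position, pbest_fit = fit)
  gi <- which.max(fit)
  gbest <- position[gi, ]
  gbest_fit <- fit[gi]
  trace <- numeric(cfg$n_iter)
  for (t in seq_len(cfg$n_iter)) {
    if (t > 1L) {
      swarm <- pso_step(swarm, gbest, cfg, t)
      fit <- eval_all(swarm$position)
      better <- fit > swarm$pbest_fit
      swarm$pbest[better, ] <- swarm$position[better, ]
      swarm$pbest_fit[better] <- fit[better]
      gi <- which.max(swarm$pbest_fit)
      if (swarm$pbest_fit[gi] > gbest_fit) {
        gbest <- swarm$pbest[gi, ]
        gbest_fit <- swarm$pbest_fit[gi]
      }
    }
    trace[t] <- gbest_fit
  }
  if (!is.null(repair)) gbest <- repair(gbest)
  structure(list(best_position = gbest, best_fitness = gbest_fit,
                 trace = trace), class = "pso_result")
}

#' @export
print.pso_result <- function(x, ...) {
  cat(sprintf("pso_result: best fitness %.6g after %d iterations\n",
              x$best_fitness, length(x$trace)))
  cat("  best position:", paste(signif(x$best_position, 5), collapse = " "), "\n")
  invisible(x)
}

sigmoid <- function(v) 1 / (1 + exp(-v))

#' One binary-PSO swarm update
#'
#' Velocities follow the continuous update (default without inertia,
#' `w = 1`, which worked better empirically for the feature-selection stage);
#' each bit is then resampled as 1 with probability `sigmoid(v)`.
#'
#' @param swarm List with `position` (0/1 matrix), `velocity`, `pbest`.
#' @param gbest Best known bit vector.
#' @param cfg A [swarm_config()] (bounds are ignored; `vmax` clamps v).
#' @param inertia Inertia weight (default 1 = none).
#' @return Updated swarm.
#' @export
bpso_step <- function(swarm, gbest, cfg, inertia = 1) {
  n <- nrow(swarm$position)
  d <- ncol(swarm$position)
  g1 <- matrix(stats::runif(n * d), n, d)
  g2 <- matrix(stats::runif(n * d), n, d)
  v <- inertia * swarm$velocity +
    cfg$c1 * g1 * (swarm$pbest - swarm$position) +
    cfg$c2 * g2 * (matrix(gbest, n, d, byrow = TRUE) - swarm$position)
  vmax <- cfg$vmax[1]
  v <- pmin(pmax(v, -vmax), vmax)
  swarm$velocity <- v
  swarm$position <- (matrix(stats::runif(n * d), n, d) < sigmoid(v)) + 0
  swarm
}

#' Binary particle swarm maximization
#'
#' BPSO over bit vectors for wrapper feature selection. The initial
#' population defaults to all-ones (use every feature) with small seeded
#' bit-flip noise on all but the first particle for diversity. Candidate
#' masks are memoized so re-visited masks are not re-evaluated.
#'
#' @param objective Function mapping a 0/1 vector to a scalar fitness
#'   (maximized); all-zero masks should return `-Inf`.
#' @param n_bits Mask length.
#' @param n_particles,n_iter Swarm size and iterations.
#' @param c1,c2 Acceleration constants.
#' @param vmax Velocity clamp (sigmoid saturates near `±4`).
#' @param inertia Inertia weight (default 1, i.e. none).
#' @param init `"ones"` (all features, with flip noise) or `"random"`.
#' @param flip_prob Per-bit flip probability for the noisy initial particles.
#' @param seed Integer seed.
#' @param memoize Cache fitness by mask (results unchanged, evaluations
#'   saved).
#' @return A `pso_result` with a 0/1 `best_position`.
#' @export
bpso_maximize <- function(objective, n_bits, n_particles = 40L, n_iter = 60L,
                          c1 = 2.05, c2 = 2.05, vmax = 4, inertia = 1,
                          init = c("ones", "random"), flip_prob = 0.05,
                          seed = NULL, memoize = TRUE) {
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_particles)
  cfg <- swarm_config(rep(0, n_bits), rep(1, n_bits), n_particles = n,
                      n_iter = n_iter, c1 = c1, c2 = c2,
                      vmax_frac = vmax)   # vmax = vmax_frac * (1 - 0)
  position <- if (init == "ones") {
    p <- matrix(1, n, n_bits)
    if (n > 1L) {
      flips <- matrix(stats::runif((n - 1L) * n_bits) < flip_prob,
                      n - 1L, n_bits)
      p[-1L, ][flips] <- 0
    }
    p
  } else {
    matrix((stats::runif(n * n_bits) < 0.5) + 0, n, n_bits)
  }
  velocity <- matrix(stats::runif(n * n_bits, -1, 1), n, n_bits)
  cache <- new.env(parent = emptyenv())
  eval_mask <- function(b) {
    if (!memoize) {
      f <- objective(b)
      return(if (is.finite(f)) f else -Inf)
    }
    key <- paste(b, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- objective(b)
    if (!is.finite(f)) f <- -Inf
    cache[[key]] <- f
    f
  }
  fit <- apply(position, 1L, eval_mask)
  swarm <- list(position = position, velocity = velocity,
                pbest = position, pbest_fit = fit)
  gi <- which.max(fit)
  gbest <- position[gi, ]
  gbest_fit <- fit[gi]
  trace <- numeric(n_iter)
  for (t in seq_len(n_iter)) {
    if (t > 1L) {
      swarm <- bpso_step(swarm, gbest, cfg, inertia = inertia)
      fit <- apply(swarm$position, 1L, eval_mask)
      better <- fit > swarm$pbest_fit
      swarm$pbest[better, ] <- swarm$position[better, ]
      swarm$pbest_fit[better] <- fit[better]
      gi <- which.max(swarm$pbest_fit)
      if (swarm$pbest_fit[gi] > gbest_fit) {
        gbest <- swarm$pbest[gi, ]
        gbest_fit <- swarm$pbest_fit[gi]
      }
    }
    trace[t] <- gbest_fit
  }
  structure(list(best_position = gbest, best_fitness = gbest_fit,
                 trace = trace), class = "pso_result")
}

# ---- fitness plumbing shared by the stages ----------------------------------

# train a weighted SVM on (xtr, ytr), return mean F-score fitness on (xva, yva)
svm_valid_fitness <- function(xtr, ytr, xva, yva, class_weights,
                              feature_mask = NULL) {
  fit <- tryCatch(
    tvcg_svm(xtr, ytr, class_weights = class_weights,
             feature_mask = feature_mask),
    error = function(e) NULL)
  if (is.null(fit)) return(-Inf)
  pred <- predict(fit, xva)
  cn_fitness(confusion(yva, pred, classes = c("N", "S", "V")))$fitness
}

#' Stage 1: optimize the complex-network parameters
#'
#' Searches `(T_0, T_Q, m)` — `T_0` in `[0.001, 0.2]`, `T_Q` in `[0.1, 1]`,
#' `m` continuous in `[1, 10]` rounded half-up at evaluation — maximizing the
#' validation mean F-score of a weighted SVM trained on complex-network
#' features plus the three RR features only, with the fixed stage-1 class
#' weights `(w1 = 6, w2 = 100, w3 = 15)`. Positions with `T_0 > T_Q` are
#' repaired by swapping. Weight matrices are precomputed per beat, so each
#' candidate only re-runs thresholding and the degree descriptors.
#'
#' @param train_beats,valid_beats Lists of [beat_window]s from disjoint
#'   patients (training / validation).
#' @param n_particles,n_iter Swarm size and iterations (full-campaign settings
#'   are 100 and 50; use small values for desk-scale runs).
#' @param class_weights Fixed stage-1 class weights.
#' @param subsample_step TVCG subsampling step.
#' @param seed Integer seed.
#' @return List `t0`, `tq`, `m`, plus the underlying `pso_result`.
#' @export
optimize_cn_params <- function(train_beats, valid_beats,
                               n_particles = 10L, n_iter = 5L,
                               class_weights = c(N = 6, S = 100, V = 15),
                               subsample_step = 2L, seed = 1L) {
  wtr <- lapply(train_beats, function(b)
    weight_matrix(build_tvcg(b, subsample_step)))
  wva <- lapply(valid_beats, function(b)
    weight_matrix(build_tvcg(b, subsample_step)))
  rr <- function(beats) t(vapply(beats, function(b)
    c(pre_rr = b$pre_rr_s, post_rr = b$post_rr_s, local_rr = b$local_rr_s),
    numeric(3)))
  rrtr <- rr(train_beats)
  rrva <- rr(valid_beats)
  ytr <- vapply(train_beats, `[[`, character(1), "label")
  yva <- vapply(valid_beats, `[[`, character(1), "label")
  build_x <- function(wlist, rrmat, p) {
    cn <- t(vapply(wlist, function(w)
      tvcg_features_from_w(w, p[1], p[2], p[3]),
      numeric(as.integer(p[3]) * 5L)))
    cbind(cn, rrmat)
  }
  repair <- function(p) {
    if (p[1] > p[2]) p[c(1, 2)] <- p[c(2, 1)]
    p
  }
  objective <- function(p) {
    m <- round_half_up(p[3])
    p <- c(max(p[1], 0), min(p[2], 1), m)
    svm_valid_fitness(build_x(wtr, rrtr, p), ytr,
                      build_x(wva, rrva, p), yva, class_weights)
  }
  cfg <- swarm_config(lower = c(0.001, 0.1, 1), upper = c(0.2, 1, 10),
                      n_particles = n_particles, n_iter = n_iter)
  res <- pso_maximize(objective, cfg, seed = seed, repair = repair)
  list(t0 = res$best_position[1], tq = res$best_position[2],
       m = as.integer(round_half_up(res$best_position[3])),
       result = res)
}

#' Stage 2: optimize the SVM class weights
#'
#' Searches `(w1, w2, w3)` for classes N, S, V in the box
#' `[1,5] x [10,200] x [5,100]`, maximizing validation mean F-score of the
#' SVM trained on the full feature vectors.
#'
#' @param train,valid Lists with `x` (feature matrix) and `y` (labels), e.g.
#'   from [feature_matrix()], built from disjoint patients.
#' @param n_particles,n_iter Swarm size and iterations (full-campaign settings: 100 and
#'   100).
#' @param seed Integer seed.
#' @return List `class_weights` (named) and `result` (`pso_result`).
#' @export
optimize_class_weights <- function(train, valid, n_particles = 10L,
                                   n_iter = 5L, seed = 1L) {
  objective <- function(p)
    svm_valid_fitness(train$x, train$y, valid$x, valid$y,
                      class_weights = c(N = p[1], S = p[2], V = p[3]))
  cfg <- swarm_config(lower = c(1, 10, 5), upper = c(5, 200, 100),
                      n_particles = n_particles, n_iter = n_iter)
  res <- pso_maximize(objective, cfg, seed = seed)
  list(class_weights = c(N = res$best_position[1], S = res$best_position[2],
                         V = res$best_position[3]),
       result = res)
}

#' Stage 3: wrapper feature selection by binary PSO
#'
#' Starting from the full feature set, finds the 0/1 mask maximizing
#' validation mean F-score of the weighted SVM; all-zero masks score `-Inf`.
#'
#' @param train,valid Lists with `x` and `y` from disjoint patients.
#' @param class_weights Class weights from stage 2.
#' @param n_particles,n_iter Swarm size and iterations (full-campaign settings: 300 and
#'   100).
#' @param seed Integer seed.
#' @return List `mask` (logical) and `result` (`pso_result`).
#' @export
select_features <- function(train, valid, class_weights,
                            n_particles = 20L, n_iter = 10L, seed = 1L) {
  objective <- function(b) {
    if (!any(b == 1)) return(-Inf)
    svm_valid_fitness(train$x, train$y, valid$x, valid$y,
                      class_weights = class_weights,
                      feature_mask = b == 1)
  }
  res <- bpso_maximize(objective, n_bits = ncol(train$x),
                       n_particles = n_particles, n_iter = n_iter,
                       seed = seed)
  list(mask = res$best_position == 1, result = res)
}

#' Final inter-patient evaluation
#'
#' Trains the weighted SVM once on all training patients and evaluates on the
#' held-out patients, refusing to run if any record id appears on both sides
#' (the inter-patient guard). Records are preprocessed with the requested
#' filter chain before feature extraction.
#'
#' @param train_corpus,test_corpus Lists of `list(record, fiducials)` entries,
#'   e.g. from [synth_corpus()].
#' @param t0,tq,m Complex-network parameters (stage 1).
#' @param class_weights Class weights (stage 2).
#' @param feature_mask Optional selection mask (stage 3).
#' @param filter Preprocessing chain name for [ecg_filter()].
#' @param subsample_step TVCG subsampling step.
#' @return List: `model`, `confusion`, `metrics` ([aami_metrics()]),
#'   `fitness` ([cn_fitness()]).
#' @export
evaluate_interpatient <- function(train_corpus, test_corpus,
                                  t0 = 0.05, tq = 0.5, m = 2L,
                                  class_weights = c(N = 6, S = 100, V = 15),
                                  feature_mask = NULL,
                                  filter = c("none", "de_chazal", "common"),
                                  subsample_step = 2L) {
  filter <- match.arg(filter)
  ids <- function(corpus) vapply(corpus, function(p)
    p$record$record_id, character(1))
  overlap <- intersect(ids(train_corpus), ids(test_corpus))
  if (length(overlap))
    stop("inter-patient guard: record(s) in both train and test: ",
         paste(overlap, collapse = ", "))
  corpus_features <- function(corpus) {
    beats <- unlist(lapply(corpus, function(p) {
      rec <- ecg_filter(p$record, filter)
      beat_windows(rec, p$fiducials)
    }), recursive = FALSE)
    feature_matrix(beats, t0 = t0, tq = tq, m = m,
                   subsample_step = subsample_step)
  }
  tr <- corpus_features(train_corpus)
  te <- corpus_features(test_corpus)
  model <- tvcg_svm(tr$x, tr$y, class_weights = class_weights,
                    feature_mask = feature_mask)
  pred <- predict(model, te$x)
  cm <- confusion(te$y, pred, classes = c("N", "S", "V"))
  list(model = model, confusion = cm, metrics = aami_metrics(cm),
       fitness = cn_fitness(cm))
}
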