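test_that("the inertia schedule is linear from 0.9 to 0.4", {
  expect_equal(pso_inertia(1, 50), 0.9)
  expect_equal(pso_inertia(50, 50), 0.4)
  expect_equal(pso_inertia(25.5, 50), 0.65)
  expect_equal(pso_inertia(1, 1), 0.9)
})

test_that("the velocity update has the stated fixed point and decay", {
  cfg <- swarm_config(rep(-1, 2), rep(1, 2), n_particles = 3, n_iter = 10)
  x <- matrix(0.3, 3, 2)
  swarm <- list(position = x, velocity = matrix(0, 3, 2), pbest = x)
  # pbest = gbest = x and v = 0: nothing moves
  out <- pso_step(swarm, gbest = c(0.3, 0.3), cfg, t = 5)
  expect_equal(out$position, x)
  expect_equal(out$velocity, matrix(0, 3, 2))

  # zero attraction (c1 = c2 = 0): v scales by w(t) each step
  cfg0 <- swarm_config(rep(-10, 2), rep(10, 2), n_particles = 3, n_iter = 10,
                       c1 = 0, c2 = 0, inertia = c(0.5, 0.5))
  swarm <- list(position = x, velocity = matrix(1, 3, 2), pbest = x)
  out <- pso_step(swarm, c(0, 0), cfg0, t = 2)
  expect_equal(out$velocity, matrix(0.5, 3, 2))
  out2 <- pso_step(out, c(0, 0), cfg0, t = 3)
  expect_equal(out2$velocity, matrix(0.25, 3, 2))
})

test_that("PSO is seed-reproducible with a monotone best-so-far trace", {
  obj <- function(x) -sum((x - 0.5)^2)
  cfg <- swarm_config(rep(-2, 3), rep(2, 3), n_particles = 15, n_iter = 30)
  r1 <- pso_maximize(obj, cfg, seed = 123)
  r2 <- pso_maximize(obj, cfg, seed = 123)
  expect_identical(r1, r2)
  expect_false(is.unsorted(r1$trace))
  expect_equal(r1$best_position, rep(0.5, 3), tolerance = 0.05)

  # one iteration returns the best of the initial population
  cfg1 <- swarm_config(rep(-2, 3), rep(2, 3), n_particles = 15, n_iter = 1)
  r3 <- pso_maximize(obj, cfg1, seed = 9)
  expect_length(r3$trace, 1)
  expect_equal(r3$best_fitness, r3$trace[1])

  # non-finite objective values are demoted, not propagated
  holed <- function(x) if (x[1] > 0) NaN else -sum(x^2)
  r4 <- pso_maximize(holed, cfg, seed = 4)
  expect_true(is.finite(r4$best_fitness))
})

test_that("BPSO bit resampling follows the sigmoid", {
  expect_equal(tvcgbeat:::sigmoid(0), 0.5)
  expect_gt(tvcgbeat:::sigmoid(10), 0.9999)
  set.seed(5)
  cfg <- swarm_config(rep(0, 4), rep(1, 4), n_particles = 3, n_iter = 5,
                      vmax_frac = 50)   # effectively unclamped
  x <- matrix(1, 3, 4)
  swarm <- list(position = x, velocity = matrix(30, 3, 4), pbest = x)
  out <- bpso_step(swarm, rep(1, 4), cfg)
  expect_true(all(out$position[out$velocity > 20] == 1))  # p -> 1 as v -> Inf
  r1 <- bpso_maximize(function(b) sum(b), 8, n_particles = 6, n_iter = 10,
                      seed = 7)
  r2 <- bpso_maximize(function(b) sum(b), 8, n_particles = 6, n_iter = 10,
                      seed = 7)
  expect_identical(r1, r2)
  expect_false(is.unsorted(r1$trace))
  expect_equal(unname(r1$best_position), rep(1, 8))
})

test_that("stage optimizers return in-bounds parameters that re-evaluate", {
  corp <- synth_corpus(n_patients = 4, beats_per_patient = 20, seed = 3)
  get_beats <- function(ps) unlist(lapply(ps, function(p)
    beat_windows(p$record, p$fiducials)), recursive = FALSE)
  tr_beats <- get_beats(corp[1:2])
  va_beats <- get_beats(corp[3:4])
  s1 <- optimize_cn_params(tr_beats, va_beats, n_particles = 4, n_iter = 2,
                           seed = 6)
  expect_gte(s1$t0, 0.001); expect_lte(s1$t0, 0.2)
  expect_gte(s1$tq, 0.1); expect_lte(s1$tq, 1)
  expect_lte(s1$t0, s1$tq)
  expect_true(s1$m %in% 1:10)
  # same seed reproduces the stage
  s1b <- optimize_cn_params(tr_beats, va_beats, n_particles = 4, n_iter = 2,
                            seed = 6)
  expect_identical(s1[c("t0", "tq", "m")], s1b[c("t0", "tq", "m")])

  tr <- feature_matrix(tr_beats, t0 = s1$t0, tq = s1$tq, m = s1$m)
  va <- feature_matrix(va_beats, t0 = s1$t0, tq = s1$tq, m = s1$m)
  s2 <- optimize_class_weights(tr, va, n_particles = 4, n_iter = 2, seed = 6)
  w <- s2$class_weights
  expect_true(w["N"] >= 1 && w["N"] <= 5)
  expect_true(w["S"] >= 10 && w["S"] <= 200)
  expect_true(w["V"] >= 5 && w["V"] <= 100)
  # re-evaluating the returned parameters reproduces the reported fitness
  refit <- tvcg_svm(tr$x, tr$y, class_weights = w)
  cm <- confusion(va$y, predict(refit, va$x), classes = c("N", "S", "V"))
  expect_equal(cn_fitness(cm)$fitness, s2$result$best_fitness,
               tolerance = 1e-12)
})

test_that("feature selection masks what it claims to mask", {
  toy <- make_planted_toy(1, n_per_class = 30)
  sel <- select_features(toy$train, toy$valid, class_weights = c(N = 1, S = 1, V = 1),
                         n_particles = 10, n_iter = 5, seed = 2)
  expect_length(sel$mask, 20)
  expect_true(any(sel$mask))
  # the fitted model only sees the selected columns
  fit <- tvcg_svm(toy$train$x, toy$train$y, feature_mask = sel$mask)
  expect_equal(fit$n_features, sum(sel$mask))
  # all-zero masks are rejected outright
  expect_error(tvcg_svm(toy$train$x, toy$train$y,
                        feature_mask = rep(FALSE, 20)), "no features")
})

test_that("the inter-patient guard refuses overlapping records", {
  corp <- small_corpus()
  expect_error(evaluate_interpatient(corp[1:2], corp[2:3]),
               "inter-patient guard")
  ev <- evaluate_interpatient(corp[1:2], corp[3:4])
  expect_s3_class(ev$metrics, "aami_metrics")
  expect_equal(sum(ev$confusion), 60)
})
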