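test_that("weight matrix normalizes pairwise distances to max 1", {
  w <- weight_matrix(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(w[1, 2], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(w[1, 3], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(w[2, 3], 1, tolerance = 1e-12)
  expect_equal(diag(w), rep(0, 3))
  expect_equal(w, t(w))

  # coincident points: the degenerate all-zero matrix
  expect_equal(weight_matrix(rbind(c(1, 2, 3), c(1, 2, 3))),
               matrix(0, 2, 2))

  set.seed(41)
  for (k in 1:10) {
    pts <- matrix(stats::runif(3 * sample(4:12, 1)), ncol = 3)
    expect_equal(weight_matrix(pts), naive_weight_matrix(pts),
                 tolerance = 1e-12)
  }
})

test_that("threshold schedule is the stated linear sweep", {
  expect_equal(threshold_schedule(0.1, 0.9, 5), c(0.1, 0.3, 0.5, 0.7, 0.9))
  expect_equal(threshold_schedule(0.2, 0.2, 3), c(0.2, 0.2, 0.2))
  expect_equal(threshold_schedule(0.1, 0.9, 1), 0.1)
  expect_error(threshold_schedule(0.9, 0.1, 5), "must not exceed")
  expect_error(threshold_schedule(-0.1, 0.5, 2), "\\[0, 1\\]")
})

test_that("thresholding removes edges above the limit, keeping vertices", {
  w <- weight_matrix(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(sum(threshold_graph(w, 0.8)) / 2, 2)   # two edges kept
  expect_equal(sum(threshold_graph(w, 1)) / 2, 3)     # complete graph
  expect_equal(sum(threshold_graph(w, 0)) / 2, 0)     # empty graph
  expect_false(any(diag(threshold_graph(w, 1))))
})

test_that("descriptors match hand computations and closed forms", {
  w <- weight_matrix(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  d <- cn_descriptors(threshold_graph(w, 0.8))
  # degrees (2,1,1); both edges have endpoint pair {1,2}
  expect_equal(unname(d), c(4 / 9, 2 / 3, 0, 1, 0.5), tolerance = 1e-12)

  empty <- matrix(FALSE, 4, 4)
  expect_equal(unname(cn_descriptors(empty)), rep(0, 5))

  for (n in c(3, 5, 9)) {   # complete graph: closed forms for regular graphs
    adj <- matrix(TRUE, n, n); diag(adj) <- FALSE
    d <- cn_descriptors(adj)
    expect_equal(unname(d[1:4]), c((n - 1) / n, (n - 1) / n, 0, 1),
                 tolerance = 1e-12)
    expect_equal(unname(d[5]), (n - 1) / n, tolerance = 1e-12)
  }
})

test_that("descriptors agree with the brute-force oracle on random point sets", {
  set.seed(42)
  for (k in 1:50) {
    pts <- matrix(stats::runif(3 * sample(3:12, 1)), ncol = 3)
    w <- weight_matrix(pts)
    for (T in c(0.25, 0.6, 0.9)) {
      adj <- threshold_graph(w, T)
      expect_equal(unname(cn_descriptors(adj)), naive_descriptors(adj),
                   tolerance = 1e-12)
    }
  }
})

test_that("descriptors are invariant under rigid rotation of the points", {
  set.seed(43)
  theta <- 0.71
  rot <- rbind(c(cos(theta), -sin(theta), 0),
               c(sin(theta), cos(theta), 0),
               c(0, 0, 1))
  for (k in 1:5) {
    pts <- matrix(stats::rnorm(3 * 10), ncol = 3)
    f1 <- tvcg_features(pts, 0.05, 0.8, 3)
    f2 <- tvcg_features(pts %*% t(rot), 0.05, 0.8, 3)
    expect_equal(f1, f2, tolerance = 1e-10)
  }
})

test_that("edge sets nest and mean degree is monotone in the threshold", {
  set.seed(44)
  for (k in 1:50) {
    pts <- matrix(stats::runif(3 * 10), ncol = 3)
    w <- weight_matrix(pts)
    ts <- sort(stats::runif(4))
    adjs <- lapply(ts, function(T) threshold_graph(w, T))
    for (i in 1:3)
      expect_true(all(adjs[[i + 1]][adjs[[i]]])) # nesting
    md <- vapply(adjs, function(a) cn_descriptors(a)[["mean_degree"]],
                 numeric(1))
    expect_true(all(diff(md) >= 0))
    mx <- vapply(adjs, function(a) cn_descriptors(a)[["max_degree"]],
                 numeric(1))
    expect_true(all(diff(mx) >= 0))
  }
})

test_that("the feature vector stacks descriptors over the schedule", {
  b <- clean_beats()$beats[[1]]
  p <- build_tvcg(b, 2)
  f2 <- tvcg_features(p, 0.05, 0.5, 2)
  expect_length(f2, 10)
  expect_length(tvcg_features(p, 0.05, 0.5, 1), 5)
  # deterministic: identical input, identical output
  expect_identical(f2, tvcg_features(p, 0.05, 0.5, 2))
  # block l is exactly the descriptors at T_l
  w <- weight_matrix(p)
  ts <- threshold_schedule(0.05, 0.5, 2)
  expect_equal(unname(f2[6:10]),
               unname(cn_descriptors(threshold_graph(w, ts[2]))))
})
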