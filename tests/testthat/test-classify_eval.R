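make_blobs <- function(seed = 7, n = 50, sep = 4) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(2 * n), n),
             matrix(stats::rnorm(2 * n, mean = sep), n))
  list(x = x, y = rep(c("N", "V"), each = n))
}

test_that("the weighted SVM separates blobs and is deterministic", {
  bl <- make_blobs()
  fit <- tvcg_svm(bl$x, bl$y)
  expect_equal(mean(predict(fit, bl$x) == bl$y), 1)
  expect_equal(fit$gamma, 1 / 2)
  # duplicating every training point leaves decisions unchanged
  fit2 <- tvcg_svm(rbind(bl$x, bl$x), c(bl$y, bl$y))
  probe <- matrix(stats::runif(40, -2, 6), 20)
  expect_identical(predict(fit, probe), predict(fit2, probe))
  # refitting is bit-stable
  expect_identical(predict(tvcg_svm(bl$x, bl$y), probe), predict(fit, probe))
  expect_error(tvcg_svm(bl$x, rep("N", nrow(bl$x))), "single class")
  expect_error(tvcg_svm(cbind(bl$x, NA), bl$y), "NA")
})

test_that("raising a minority-class weight does not reduce its recall", {
  set.seed(8)
  # imbalanced overlapping toy: 150 N vs 15 S
  x <- rbind(matrix(stats::rnorm(2 * 150), 150),
             matrix(stats::rnorm(2 * 15, mean = 1.2), 15))
  y <- rep(c("N", "S"), c(150, 15))
  recall_s <- function(w) {
    fit <- tvcg_svm(x, y, class_weights = c(N = 1, S = w))
    pred <- predict(fit, x)
    mean(pred[y == "S"] == "S")
  }
  expect_gte(recall_s(10), recall_s(1))
})

test_that("prediction contract: empty input, dimension check, row independence", {
  bl <- make_blobs()
  fit <- tvcg_svm(bl$x, bl$y)
  expect_identical(predict(fit, bl$x[0, , drop = FALSE]), character(0))
  expect_error(predict(fit, matrix(0, 3, 5)), "expected 2")
  probe <- matrix(stats::runif(40, -2, 6), 20)
  perm <- sample(20)
  expect_identical(predict(fit, probe[perm, ]), predict(fit, probe)[perm])
})

test_that("confusion matrix matches a naive counting loop", {
  expect_equal(unname(confusion(c("N", "S", "V"), c("N", "S", "V"))),
               diag(3))
  set.seed(12)
  for (k in 1:5) {
    truth <- sample(c("N", "S", "V"), 60, replace = TRUE)
    pred <- sample(c("N", "S", "V"), 60, replace = TRUE)
    cm <- confusion(truth, pred)
    expect_equal(sum(cm), 60)
    for (a in c("N", "S", "V")) for (b in c("N", "S", "V"))
      expect_equal(cm[a, b], sum(truth == a & pred == b))
  }
  expect_error(confusion("N", c("N", "S")), "equal length")
})

test_that("AAMI metrics recover the published values from the printed matrix", {
  m <- aami_metrics(published_confusion())
  pc <- m$per_class
  rounded <- function(x) floor(x * 10 + 0.5) / 10
  expect_equal(rounded(pc$se[pc$class == "N"]), 94.0)
  expect_equal(rounded(pc$ppv[pc$class == "N"]), 98.0)
  expect_equal(rounded(pc$ppv[pc$class == "S"]), 53.0)
  expect_equal(rounded(pc$se[pc$class == "V"]), 87.3)
  expect_equal(rounded(pc$fpr[pc$class == "S"]), 2.1)
})

test_that("AAMI metric invariants hold on arbitrary matrices", {
  set.seed(13)
  for (k in 1:10) {
    cm <- matrix(sample(0:50, 9, replace = TRUE), 3,
                 dimnames = list(c("N", "S", "V"), c("N", "S", "V")))
    if (sum(cm) == 0) next
    m <- aami_metrics(cm)
    expect_true(all(unlist(m$per_class[, c("se", "ppv", "fpr")]) >= 0))
    expect_true(all(unlist(m$per_class[, c("se", "ppv", "fpr")]) <= 100))
    # scale invariance of Se / +P / Acc
    m3 <- aami_metrics(cm * 3L)
    expect_equal(m3$per_class$se, m$per_class$se)
    expect_equal(m3$per_class$ppv, m$per_class$ppv)
    expect_equal(m3$acc, m$acc)
  }
  # identity matrix: perfect metrics
  m <- aami_metrics(diag(3) * 10)
  expect_equal(m$per_class$se, rep(100, 3))
  expect_equal(m$per_class$ppv, rep(100, 3))
  expect_equal(m$per_class$fpr, rep(0, 3))
  expect_equal(m$acc, 100)
})

test_that("5-class input excludes fusion beats from V's +P and FP", {
  cm <- matrix(0, 5, 5, dimnames = list(c("N", "S", "V", "F", "Q"),
                                        c("N", "S", "V", "F", "Q")))
  cm["N", "N"] <- 80; cm["S", "S"] <- 10; cm["V", "V"] <- 20
  cm["F", "V"] <- 5                        # fusion predicted ventricular
  cm["N", "V"] <- 5
  m <- aami_metrics(cm)
  # +P_V = 20 / (20 + 5) once the F->v cell is excluded
  expect_equal(m$per_class$ppv[m$per_class$class == "V"], 100 * 20 / 25)
  # without the exclusion it would be 20/30
  cm3 <- cm[1:3, 1:3]
  m3 <- aami_metrics(cm3)
  expect_equal(m3$per_class$ppv[m3$per_class$class == "V"], 100 * 20 / 25)
})

test_that("F-score and fitness behave as the harmonic-mean objective", {
  expect_equal(f_score(0.4, 0.4), 0.4)
  expect_equal(f_score(0.62, 0.53), 2 * 0.62 * 0.53 / (0.62 + 0.53))
  expect_equal(f_score(0, 0), 0)
  # identity matrix: fitness 1
  cmI <- diag(3) * 5
  dimnames(cmI) <- list(c("N", "S", "V"), c("N", "S", "V"))
  expect_equal(cn_fitness(cmI)$fitness, 1)
  # all predictions one class: the other two F-scores are 0
  cm1 <- matrix(0, 3, 3, dimnames = dimnames(cmI))
  cm1[, "N"] <- c(10, 5, 5)
  fs <- cn_fitness(cm1)$per_class
  expect_equal(unname(fs[c("S", "V")]), c(0, 0))
  # composition oracle on the published matrix
  m <- aami_metrics(published_confusion())
  want <- mean(f_score(m$per_class$se / 100, m$per_class$ppv / 100))
  expect_equal(cn_fitness(published_confusion())$fitness, want)
  # weighted variant
  w <- c(N = 1, S = 2, V = 1)
  fsv <- f_score(m$per_class$se / 100, m$per_class$ppv / 100)
  expect_equal(cn_fitness(published_confusion(), weights = w)$fitness,
               sum(w * fsv) / sum(w))
})
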