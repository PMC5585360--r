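#' Fit the class-weighted RBF support vector classifier
#'
#' The classifier contract behind the pipeline: a C-support-vector classifier
#' (libSVM via e1071) with RBF kernel, `C = 1` and `gamma = 1/ncol(x)` by
#' default, one-against-one multi-class voting, and per-class penalties
#' `C * class_weights` to counter the heavy class imbalance of ambulatory ECG
#' (weights w1, w2, w3 for N, S, V). Features are z-scored with statistics
#' fitted on the training rows (the standardizer and optional selection mask
#' are stored and re-applied at prediction).
#'
#' @param x Numeric feature matrix (one row per beat).
#' @param y Labels (character or factor over N/S/V).
#' @param class_weights Named positive weights, e.g. `c(N = 1, S = 50, V = 10)`.
#' @param cost Penalty constant C.
#' @param gamma RBF width; default `1/ncol(x)` (after masking).
#' @param feature_mask Optional logical/0-1 vector selecting columns.
#' @param standardize Fit and apply a z-score standardizer (default TRUE).
#' @return An object of class `tvcg_svm`.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 3), 20))
#' y <- rep(c("N", "V"), each = 20)
#' fit <- tvcg_svm(x, y)
#' table(predict(fit, x), y)
#' @export
tvcg_svm <- function(x, y, class_weights = NULL, cost = 1, gamma = NULL,
                     feature_mask = NULL, standardize = TRUE) {
  x <- as.matrix(x)
  y <- factor(as.character(y))
  if (nlevels(y) < 2L) stop("training labels contain a single class")
  if (anyNA(x)) stop("feature matrix contains NA")
  if (nrow(x) != length(y)) stop("nrow(x) must match length(y)")
  if (!is.null(class_weights)) {
    if (any(class_weights <= 0)) stop("class weights must be positive")
    class_weights <- class_weights[names(class_weights) %in% levels(y)]
  }
  sc <- NULL
  if (standardize) {
    sc <- fit_standardizer(x)
    x <- apply_standardizer(x, sc)
  }
  if (!is.null(feature_mask)) {
    feature_mask <- as.logical(feature_mask)
    if (length(feature_mask) != ncol(x))
      stop("feature_mask length (", length(feature_mask),
           ") must equal feature count (", ncol(x), ")")
    if (!any(feature_mask)) stop("feature_mask selects no features")
    x <- x[, feature_mask, drop = FALSE]
  }
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                    cost = cost, gamma = gamma, class.weights = class_weights,
                    scale = FALSE)
  structure(list(svm = fit, levels = levels(y), standardizer = sc,
                 feature_mask = feature_mask, cost = cost, gamma = gamma,
                 class_weights = class_weights, n_features = ncol(x),
                 n_train = nrow(x)),
            class = "tvcg_svm")
}

#' @export
print.tvcg_svm <- function(x, ...) {
  cat(sprintf(paste0("tvcg_svm: weighted RBF C-SVC on %d beats, %d features",
                     " (C = %g, gamma = %g)\n"),
              x$n_train, x$n_features, x$cost, x$gamma))
  if (!is.null(x$class_weights))
    cat("  class weights:",
        paste(sprintf("%s=%g", names(x$class_weights), x$class_weights),
              collapse = " "), "\n")
  cat("  classes:", paste(x$levels, collapse = ", "),
      "| support vectors:", nrow(x$svm$SV), "\n")
  invisible(x)
}

#' @export
summary.tvcg_svm <- function(object, ...) {
  print(object)
  if (!is.null(object$feature_mask))
    cat("  feature mask:", sum(object$feature_mask), "of",
        length(object$feature_mask), "features selected\n")
  invisible(object)
}

#' Predict beat classes
#'
#' @param object A fitted [tvcg_svm].
#' @param newdata Feature matrix with the training column count (pre-mask).
#' @param ... Unused.
#' @return Character vector of predicted labels, one per row.
#' @export
predict.tvcg_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  expected <- if (is.null(object$feature_mask)) object$n_features else
    length(object$feature_mask)
  if (nrow(newdata) == 0L) return(character(0))
  if (ncol(newdata) != expected)
    stop("newdata has ", ncol(newdata), " columns; expected ", expected)
  if (!is.null(object$standardizer))
    newdata <- apply_standardizer(newdata, object$standardizer)
  if (!is.null(object$feature_mask))
    newdata <- newdata[, object$feature_mask, drop = FALSE]
  as.character(stats::predict(object$svm, newdata))
}

#' Confusion matrix
#'
#' @param true,pred Equal-length label vectors.
#' @param classes Class order for rows/columns; defaults to N, S, V plus any
#'   other observed labels.
#' @return Integer matrix `counts[true, predicted]`.
#' @export
confusion <- function(true, pred, classes = NULL) {
  if (length(true) != length(pred))
    stop("true and pred must have equal length")
  if (is.null(classes))
    classes <- union(intersect(c("N", "S", "V", "F", "Q"), c(true, pred)),
                     unique(c(true, pred)))
  m <- table(factor(true, levels = classes), factor(pred, levels = classes))
  m <- unclass(m)
  names(dimnames(m)) <- c("true", "predicted")
  m
}

#' AAMI per-class classification metrics
#'
#' For each class c: sensitivity `Se = TP / (beats of c)`, positive
#' predictivity `+P = TP / (beats predicted c)` and false positive rate
#' `FPR = FP / (beats not of c)`, plus overall accuracy `trace / total`, all
#' expressed as percentages. For 5-class input, fusion (F) beats predicted as
#' V are excluded from V's false positives and from its +P denominator — the
#' usual convention, since fusion beats contain genuine ventricular activity.
#' Any zero-denominator metric is reported as 0 and listed in the
#' `"undefined"` attribute. Rounding happens only at printing.
#'
#' @param cm Confusion matrix (`counts[true, predicted]`), 3- or 5-class,
#'   e.g. from [confusion()] or [published_confusion()].
#' @return An `aami_metrics` object: data frame `per_class` with columns
#'   `class`, `se`, `ppv`, `fpr` (percent) and scalar `acc`.
#' @examples
#' aami_metrics(published_confusion())
#' @export
aami_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0)) stop("confusion matrix counts must be >= 0")
  classes <- rownames(cm)
  if (is.null(classes)) {
    classes <- c("N", "S", "V", "F", "Q")[seq_len(nrow(cm))]
    dimnames(cm) <- list(classes, classes)
  }
  main <- intersect(c("N", "S", "V"), classes)
  total <- sum(cm)
  undefined <- character(0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      undefined <<- c(undefined, what)
      return(0)
    }
    num / den
  }
  rows <- lapply(main, function(cl) {
    tp <- cm[cl, cl]
    row_sum <- sum(cm[cl, ])
    col_sum <- sum(cm[, cl])
    fp <- col_sum - tp
    neg <- total - row_sum
    if (cl == "V" && "F" %in% classes) {   # fusion exclusion
      col_sum <- col_sum - cm["F", "V"]
      fp <- fp - cm["F", "V"]
    }
    data.frame(class = cl,
               se = 100 * safe_div(tp, row_sum, paste0("Se_", cl)),
               ppv = 100 * safe_div(tp, col_sum, paste0("+P_", cl)),
               fpr = 100 * safe_div(fp, neg, paste0("FPR_", cl)))
  })
  out <- structure(list(per_class = do.call(rbind, rows),
                        acc = 100 * safe_div(sum(diag(cm)), total, "Acc"),
                        n_beats = total),
                   class = "aami_metrics")
  attr(out, "undefined") <- undefined
  out
}

#' @export
print.aami_metrics <- function(x, digits = 1, ...) {
  cat(sprintf("AAMI metrics over %d beats; Acc = %s%%\n", x$n_beats,
              formatC(round_half_up(x$acc * 10^digits) / 10^digits,
                      format = "f", digits = digits)))
  df <- x$per_class
  for (col in c("se", "ppv", "fpr"))
    df[[col]] <- round_half_up(df[[col]] * 10^digits) / 10^digits
  names(df) <- c("class", "Se%", "+P%", "FPR%")
  print(df, row.names = FALSE)
  und <- attr(x, "undefined")
  if (length(und)) cat("  undefined (zero denominator):",
                       paste(und, collapse = ", "), "\n")
  invisible(x)
}

#' F-score (harmonic mean of sensitivity and positive predictivity)
#'
#' @param se,pp Proportions in `[0, 1]`; both 0 gives 0.
#' @return `2 * se * pp / (se + pp)`.
#' @export
f_score <- function(se, pp) {
  stopifnot(all(se >= 0 & se <= 1), all(pp >= 0 & pp <= 1))
  ifelse(se + pp == 0, 0, 2 * se * pp / (se + pp))
}

#' Optimization fitness from a confusion matrix
#'
#' The (optionally weighted) mean of the per-class F-scores over N, S, V —
#' the objective every optimization stage maximizes.
#'
#' @param cm 3-class confusion matrix.
#' @param weights Optional per-class weights for a weighted mean, named.
#' @return List with `per_class` (named F-scores in `[0, 1]`) and `fitness`.
#' @export
cn_fitness <- function(cm, weights = NULL) {
  m <- aami_metrics(cm)
  fs <- f_score(m$per_class$se / 100, m$per_class$ppv / 100)
  names(fs) <- m$per_class$class
  fitness <- if (is.null(weights)) mean(fs) else {
    w <- weights[names(fs)]
    sum(w * fs) / sum(w)
  }
  list(per_class = fs, fitness = fitness)
}
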