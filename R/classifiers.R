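# The four classification algorithms: a deterministic muscle-ordering rule,
# Gaussian LDA with pooled covariance, a CART classification tree, and a
# majority-else-deterministic voting scheme.

#' Deterministic rule classifier over window aggregates
#'
#' Classifies a window from the per-channel aggregates (sums of normalized
#' envelope samples over the window) via the strict-inequality predicates
#' p = S_TA > S_MG, q = S_TA > S_LG, r = S_MG > S_LG:
#' class 1 (dorsiflexion) if p and q; class 3 (plantarflexion) if not-p and
#' not-q; class 4 (eversion) if p, not-r, not-q; class 5 (inversion) if q, r,
#' not-p; otherwise class 2 (foot flat). The branches are mutually exclusive.
#' Ties make predicates false. Note that for real-valued aggregates the
#' "otherwise" branch is unreachable (transitivity of the strict order
#' forbids the remaining predicate patterns), so foot flat is never emitted;
#' this is a faithful property of the rule itself, and the evaluation
#' reports the resulting foot-flat misclassification rather than hiding it.
#'
#' @param s_ta,s_mg,s_lg Numeric vectors of window aggregates (finite,
#'   non-negative), recycled to a common length.
#' @return Integer vector of predicted classes in 1..5.
#' @export
deterministic_classify <- function(s_ta, s_mg, s_lg) {
  n <- max(length(s_ta), length(s_mg), length(s_lg))
  s_ta <- rep_len(s_ta, n); s_mg <- rep_len(s_mg, n); s_lg <- rep_len(s_lg, n)
  if (!all(is.finite(c(s_ta, s_mg, s_lg)))) {
    stop_config("aggregates must be finite (no NaN/NA/Inf)")
  }
  p <- s_ta > s_mg
  q <- s_ta > s_lg
  r <- s_mg > s_lg
  out <- rep(2L, n)
  out[p & q] <- 1L
  out[!p & !q] <- 3L
  out[p & !r & !q] <- 4L
  out[q & r & !p] <- 5L
  out
}

check_training <- function(x, y) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  if (nrow(x) != length(y)) stop_config("features and labels length differ")
  if (anyNA(x) || anyNA(y) || !all(is.finite(x))) {
    stop_config("training data contains missing or non-finite values")
  }
  if (length(unique(y)) < 2) stop_config("need >= 2 classes to train")
  list(x = x, y = y)
}

#' Linear discriminant analysis with pooled covariance
#'
#' Standard multiclass Gaussian LDA: class means, shrinkage-free pooled
#' within-class covariance, empirical priors. If the pooled covariance is
#' singular, a ridge `eps * mean(diag(cov))` is added (escalating tenfold
#' until the Cholesky factorization succeeds) and a message is emitted.
#' Discriminant-score ties are broken toward the lower class code.
#'
#' @param x Feature matrix or data frame (rows = windows).
#' @param y Integer class labels.
#' @param ridge Relative ridge used on singular pooled covariance.
#' @return An object of class `emg_lda` (means, covariance, priors, and
#'   precomputed linear discriminant coefficients).
#' @export
fit_lda <- function(x, y, ridge = 1e-6) {
  d <- check_training(x, y)
  x <- d$x; y <- d$y
  classes <- sort(unique(y))
  n <- nrow(x); p <- ncol(x)
  means <- t(vapply(classes,
                    function(k) colMeans(x[y == k, , drop = FALSE]),
                    numeric(p)))
  centered <- x - means[match(y, classes), , drop = FALSE]
  cov <- crossprod(centered) / max(1L, n - length(classes))
  priors <- as.numeric(table(factor(y, levels = classes))) / n
  lam <- ridge * mean(diag(cov))
  covinv <- NULL
  used_ridge <- 0
  for (i in 0:12) {
    covinv <- tryCatch(chol2inv(chol(cov + diag(used_ridge, p))),
                       error = function(e) NULL)
    if (!is.null(covinv)) break
    used_ridge <- if (used_ridge == 0) max(lam, 1e-300) else used_ridge * 10
  }
  if (is.null(covinv)) stop_config("pooled covariance could not be inverted")
  if (used_ridge > 0) {
    message(sprintf("fit_lda: singular pooled covariance, ridge %.3g applied",
                    used_ridge))
  }
  coef <- covinv %*% t(means)                    # p x K
  const <- -0.5 * rowSums((means %*% covinv) * means) + log(priors)
  structure(list(classes = classes, means = means, covariance = cov,
                 priors = priors, coef = coef, const = const,
                 features = colnames(x), ridge_used = used_ridge),
            class = "emg_lda")
}

#' @rdname fit_lda
#' @param model A fitted `emg_lda`.
#' @return For `predict_lda`, an integer vector of predicted class codes.
#' @export
predict_lda <- function(model, x) {
  x <- as.matrix(x)
  if (!is.null(model$features) && !is.null(colnames(x))) {
    if (!all(model$features %in% colnames(x))) {
      stop_config("feature columns do not match the training mask")
    }
    x <- x[, model$features, drop = FALSE]
  }
  scores <- x %*% model$coef +
    matrix(model$const, nrow(x), length(model$const), byrow = TRUE)
  model$classes[max.col(scores, ties.method = "first")]
}

#' CART classification tree (Gini impurity)
#'
#' Binary classification tree grown with Gini impurity via `rpart`, with
#' cross-validation disabled so the fit is deterministic given the data.
#'
#' @param x Feature matrix or data frame.
#' @param y Integer class labels.
#' @param max_depth Maximum tree depth.
#' @param min_leaf Minimum observations per leaf.
#' @param cp Complexity parameter (kept small; depth and leaf size are the
#'   operative controls).
#' @return An object of class `emg_tree`.
#' @export
fit_tree <- function(x, y, max_depth = 8, min_leaf = 5, cp = 1e-4) {
  d <- check_training(x, y)
  df <- as.data.frame(d$x)
  if (is.null(colnames(d$x))) names(df) <- paste0("f", seq_len(ncol(d$x)))
  df$.y <- factor(d$y)
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        maxdepth = max_depth, minbucket = min_leaf,
                        minsplit = max(2L * min_leaf, 4L), cp = cp,
                        xval = 0))
  structure(list(fit = fit, classes = sort(unique(d$y)),
                 features = setdiff(names(df), ".y")),
            class = "emg_tree")
}

#' @rdname fit_tree
#' @param model A fitted `emg_tree`.
#' @return For `predict_tree`, an integer vector of predicted class codes.
#' @export
predict_tree <- function(model, x) {
  df <- as.data.frame(as.matrix(x))
  if (!all(model$features %in% names(df))) {
    stop_config("feature columns do not match the training mask")
  }
  as.integer(as.character(stats::predict(model$fit, newdata = df,
                                         type = "class")))
}

#' Voting scheme across the three classifiers
#'
#' Returns the agreed class whenever any two of the LDA, tree and
#' deterministic outputs agree; otherwise defaults to the deterministic
#' output. (If LDA and tree agree, that class wins; every other agreement
#' pattern, and full disagreement, resolves to the deterministic output.)
#'
#' @param c_lda,c_tree,c_det Integer class codes per window.
#' @return Integer vector of voted class codes.
#' @export
vote <- function(c_lda, c_tree, c_det) {
  n <- length(c_det)
  if (length(c_lda) != n || length(c_tree) != n) {
    stop_config("classifier outputs must have equal length")
  }
  out <- as.integer(c_det)
  agree <- c_lda == c_tree
  out[agree] <- as.integer(c_lda[agree])
  out
}

#' Serialize a fitted model to JSON
#'
#' LDA models are written with classes, priors, means and pooled covariance
#' (and can be reloaded with [lda_from_json()]); trees are written as their
#' frame and split tables for inspection. No binary serialization is used.
#'
#' @param model An `emg_lda` or `emg_tree`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when `path` is given).
#' @export
model_to_json <- function(model, path = NULL) {
  obj <- if (inherits(model, "emg_lda")) {
    list(algorithm = "lda", classes = model$classes, priors = model$priors,
         features = model$features, means = model$means,
         covariance = model$covariance)
  } else if (inherits(model, "emg_tree")) {
    fr <- model$fit$frame
    list(algorithm = "tree", classes = model$classes,
         features = model$features,
         frame = cbind(node = as.integer(rownames(fr)),
                       fr[c("var", "n", "yval")]),
         splits = as.data.frame(model$fit$splits))
  } else {
    stop_config("unsupported model class")
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname model_to_json
#' @export
lda_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$algorithm, "lda")) stop_config("not a serialized LDA")
  means <- as.matrix(obj$means)
  cov <- as.matrix(obj$covariance)
  covinv <- chol2inv(chol(cov))
  coef <- covinv %*% t(means)
  const <- -0.5 * rowSums((means %*% covinv) * means) + log(obj$priors)
  structure(list(classes = as.integer(obj$classes), means = means,
                 covariance = cov, priors = obj$priors, coef = coef,
                 const = const, features = obj$features, ridge_used = 0),
            class = "emg_lda")
}
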