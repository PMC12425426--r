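#' Default classifier hyperparameters
#'
#' Conservative defaults for the five-model roster, all overridable through
#' the `hyperparams` argument of [train_classifier()] or the run config:
#' RBF support vector machine with cost 1; 300-tree random forest; gradient
#' boosting with 150 depth-2 trees, learning rate 0.1 and row/column
#' subsampling (sized for cohorts of a few hundred windows); a single-
#' hidden-layer neural network with 16 units, weight decay 1e-3 and a
#' 500-iteration cap.
#'
#' @return Named list of per-model hyperparameter lists.
#' @export
default_hyperparams <- function() {
  list(
    logistic = list(strategy = "multinomial"),
    svm = list(kernel = "radial", cost = 1, gamma = NULL),
    random_forest = list(ntree = 300L),
    gradient_boosting = list(nrounds = 150L, max_depth = 2L, eta = 0.1,
                             subsample = 0.8, colsample_bytree = 0.8,
                             min_child_weight = 5),
    neural_net = list(size = 16L, decay = 1e-3, maxit = 500L)
  )
}

#' Names of the classifier roster
#' @return Character vector of the five model names.
#' @export
classifier_names <- function() {
  c("logistic", "svm", "random_forest", "gradient_boosting", "neural_net")
}

#' Train one classifier of the roster
#'
#' Fits one of the five models — logistic regression (multinomial or
#' one-vs-rest for more than two classes), support vector machine, random
#' forest, gradient-boosted trees, or a feed-forward neural network — on a
#' standardized feature matrix. Training is deterministic given the seed and
#' hyperparameters; the fitted object predicts both hard labels and class
#' probabilities through [predict.actidep_model()].
#'
#' @param name One of [classifier_names()].
#' @param X Numeric feature matrix (standardized).
#' @param y Integer class labels (0/1 or 0/1/2).
#' @param hyperparams Optional list overriding [default_hyperparams()] for
#'   this model.
#' @param seed Integer seed for the stochastic learners.
#' @return An `actidep_model`.
#' @export
train_classifier <- function(name, X, y, hyperparams = NULL, seed = 1L) {
  if (!name %in% classifier_names()) {
    stop_actidep("unknown classifier '%s'", name,
                 class = "actidep_validation_error")
  }
  classes <- sort(unique(y))
  if (length(classes) < 2) {
    stop_actidep("training labels contain a single class",
                 class = "actidep_validation_error")
  }
  hp <- utils::modifyList(default_hyperparams()[[name]], hyperparams %||% list())
  X <- as.matrix(X)
  yf <- factor(y, levels = classes)
  fit <- with_seed(seed, switch(
    name,
    logistic = {
      df <- data.frame(X, .y = yf, check.names = FALSE)
      if (length(classes) == 2) {
        stats::glm(.y ~ ., data = df, family = stats::binomial())
      } else if (identical(hp$strategy, "ovr")) {
        lapply(classes, function(cls) {
          df1 <- df
          df1$.y <- factor(as.integer(y == cls), levels = c(0, 1))
          stats::glm(.y ~ ., data = df1, family = stats::binomial())
        })
      } else {
        nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 200)
      }
    },
    svm = e1071::svm(X, yf, kernel = hp$kernel, cost = hp$cost,
                     gamma = hp$gamma %||% (1 / ncol(X)),
                     probability = TRUE, scale = FALSE),
    random_forest = randomForest::randomForest(X, yf, ntree = hp$ntree),
    gradient_boosting = {
      k <- length(classes)
      params <- list(max_depth = hp$max_depth, eta = hp$eta,
                     subsample = hp$subsample %||% 1,
                     colsample_bytree = hp$colsample_bytree %||% 1,
                     min_child_weight = hp$min_child_weight %||% 1,
                     nthread = 1)
      if (k == 2) {
        params$objective <- "binary:logistic"
      } else {
        params$objective <- "multi:softprob"
        params$num_class <- k
      }
      params$seed <- seed
      dtrain <- xgboost::xgb.DMatrix(X, label = match(y, classes) - 1)
      xgboost::xgb.train(params = params, data = dtrain,
                         nrounds = hp$nrounds, verbose = 0)
    },
    neural_net = nnet::nnet(X, nnet::class.ind(yf), size = hp$size,
                            decay = hp$decay, maxit = hp$maxit,
                            softmax = TRUE, trace = FALSE,
                            MaxNWts = 10000)
  ))
  structure(list(name = name, fit = fit, classes = classes,
                 features = colnames(X), hyperparams = hp, seed = seed),
            class = "actidep_model")
}

#' Predict labels or class probabilities
#'
#' @param object An `actidep_model`.
#' @param newdata Numeric matrix with the training feature columns.
#' @param type `"class"` for hard labels (on the original label scale) or
#'   `"prob"` for a class-probability matrix.
#' @param ... Unused.
#' @return Label vector or probability matrix (columns named by class).
#' @export
predict.actidep_model <- function(object, newdata,
                                  type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  classes <- object$classes
  k <- length(classes)
  prob <- switch(
    object$name,
    logistic = {
      if (k == 2) {
        p1 <- stats::predict(object$fit,
                             newdata = data.frame(newdata, check.names = FALSE),
                             type = "response")
        cbind(1 - p1, p1)
      } else if (is.list(object$fit) && !inherits(object$fit, "multinom")) {
        raw <- vapply(object$fit, function(m) {
          stats::predict(m, newdata = data.frame(newdata, check.names = FALSE),
                         type = "response")
        }, numeric(nrow(newdata)))
        raw <- matrix(raw, nrow = nrow(newdata))
        raw / rowSums(raw)
      } else {
        as.matrix(stats::predict(object$fit,
                                 newdata = data.frame(newdata, check.names = FALSE),
                                 type = "probs"))
      }
    },
    svm = {
      pr <- stats::predict(object$fit, newdata, probability = TRUE)
      attr(pr, "probabilities")[, as.character(classes), drop = FALSE]
    },
    random_forest = stats::predict(object$fit, newdata, type = "prob"),
    gradient_boosting = {
      raw <- stats::predict(object$fit, newdata)
      if (is.matrix(raw)) raw
      else if (k == 2) cbind(1 - raw, raw)
      else matrix(raw, ncol = k, byrow = TRUE)
    },
    neural_net = {
      p <- stats::predict(object$fit, newdata, type = "raw")
      matrix(p, nrow = nrow(newdata))
    }
  )
  prob <- matrix(as.numeric(prob), nrow = nrow(newdata))
  colnames(prob) <- as.character(classes)
  if (type == "prob") return(prob)
  classes[max.col(prob, ties.method = "first")]
}

#' @export
print.actidep_model <- function(x, ...) {
  cat(sprintf("<actidep_model> %s; %d classes; %d features\n",
              x$name, length(x$classes), length(x$features)))
  invisible(x)
}
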