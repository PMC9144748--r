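step_algorithms <- function() {
  c("random_forest", "hist_gradient_boost", "svm", "mlp", "knn", "ensemble")
}

#' Model specification
#'
#' Describes one model of the two-stage step counter: its algorithm, its
#' role (carrying-position classifier or per-position step-count
#' regressor), hyperparameters and RNG seed. Defaults follow the
#' reference configuration of the method: 200-tree random forest for
#' classification, 500-tree random forest for regression, linear-kernel
#' SVM, single-hidden-layer perceptron, histogram-style gradient boosting
#' and k-nearest neighbours at library defaults. `"ensemble"` is valid
#' only as a regressor and denotes the weighted average of the SVM, MLP
#' and random-forest regressors.
#'
#' @param algorithm One of `random_forest`, `hist_gradient_boost`, `svm`,
#'   `mlp`, `knn`, `ensemble`.
#' @param role `"classifier"` or `"regressor"`.
#' @param hyperparams Named list overriding the algorithm defaults. For
#'   `ensemble`, `weights` is a named non-negative vector over
#'   `svm`/`mlp`/`random_forest` summing to 1.
#' @param seed Integer seed used when fitting this model.
#'
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(algorithm, role = c("regressor", "classifier"),
                       hyperparams = list(), seed = 1L) {
  role <- match.arg(role)
  algorithm <- match.arg(algorithm, step_algorithms())
  if (algorithm == "ensemble" && role != "regressor")
    stop("model_spec: the ensemble model is a regressor", call. = FALSE)
  hp <- utils::modifyList(default_hyperparams(algorithm, role), hyperparams)
  if (algorithm == "ensemble") {
    w <- hp$weights
    if (is.null(names(w)) || !setequal(names(w), c("svm", "mlp", "random_forest")))
      stop("model_spec: ensemble weights must be named over svm, mlp, random_forest",
           call. = FALSE)
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
      stop("model_spec: ensemble weights must be non-negative and sum to 1",
           call. = FALSE)
  }
  structure(list(algorithm = algorithm, role = role, hyperparams = hp,
                 seed = as.integer(seed)),
            class = "model_spec")
}

default_hyperparams <- function(algorithm, role) {
  switch(algorithm,
    random_forest = if (role == "classifier") list(ntree = 200) else list(ntree = 500),
    hist_gradient_boost = list(nrounds = 100, eta = 0.1, max_depth = 6),
    svm = list(kernel = "linear", cost = 1),
    mlp = list(size = 40, decay = 1e-3, maxit = 300),
    knn = list(k = 5),
    ensemble = list(weights = c(svm = 1 / 3, mlp = 1 / 3, random_forest = 1 / 3))
  )
}

#' Default model specifications
#'
#' The standard bank: a random-forest position classifier plus, for each
#' position, SVM, MLP and random-forest regressors and their weighted
#' average. Pass `algorithms` to request a different regressor subset.
#'
#' @param algorithms Regressor algorithms to include.
#' @param seed Base seed; each spec gets a distinct derived seed.
#' @return List of [model_spec()] objects (one classifier, rest
#'   regressors).
#' @export
default_model_specs <- function(algorithms = c("svm", "mlp", "random_forest", "ensemble"),
                                seed = 1L) {
  seed <- as.integer(seed)
  specs <- list(model_spec("random_forest", "classifier", seed = seed))
  for (i in seq_along(algorithms))
    specs <- c(specs, list(model_spec(algorithms[i], "regressor", seed = seed + i)))
  specs
}

# Window summary statistics appended to every model's feature vector:
# window mean, window SD, and the number of upward crossings of the
# window mean (a cadence proxy that linear models can exploit).
augment_features <- function(X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  mu <- rowMeans(X)
  sdv <- apply(X, 1, stats::sd)
  centred <- X - mu
  cross <- rowSums(centred[, -1, drop = FALSE] >= 0 &
                   centred[, -ncol(X), drop = FALSE] < 0)
  out <- cbind(X, mu, sdv, cross)
  colnames(out) <- c(paste0("f", seq_len(ncol(X)) - 1L),
                     "win_mean", "win_sd", "win_cross")
  out
}

# ---- fitting backends -------------------------------------------------
# Each backend takes an augmented feature matrix X and a target y
# (factor for classifiers, numeric for regressors) and returns a fitted
# object wrapped with its algorithm tag; predict_bank() dispatches on it.

fit_bank_model <- function(spec, X, y) {
  hp <- spec$hyperparams
  fit <- withr::with_seed(spec$seed, switch(spec$algorithm,
    # regression targets are small integer counts; silence randomForest's
    # few-unique-values advisory
    random_forest = suppressWarnings(
      randomForest::randomForest(x = X, y = y, ntree = hp$ntree)),
    hist_gradient_boost = fit_hgb(X, y, hp, spec$role),
    svm = e1071::svm(x = X, y = y, kernel = hp$kernel, cost = hp$cost,
                     scale = TRUE),
    mlp = fit_mlp(X, y, hp, spec$role),
    knn = fit_knn(X, y, hp, spec$role),
    stop("fit_bank_model: cannot fit algorithm ", spec$algorithm, call. = FALSE)
  ))
  structure(list(algorithm = spec$algorithm, role = spec$role, fit = fit),
            class = "sc_model")
}

fit_hgb <- function(X, y, hp, role) {
  if (role == "classifier") {
    lev <- levels(y)
    dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
    params <- list(objective = "multi:softmax", num_class = length(lev),
                   eta = hp$eta, max_depth = hp$max_depth,
                   tree_method = "hist", nthread = 1)
    fit <- xgboost::xgb.train(params, dtrain, nrounds = hp$nrounds, verbose = 0)
    list(booster = fit, levels = lev)
  } else {
    dtrain <- xgboost::xgb.DMatrix(X, label = y)
    params <- list(objective = "reg:squarederror", eta = hp$eta,
                   max_depth = hp$max_depth, tree_method = "hist", nthread = 1)
    list(booster = xgboost::xgb.train(params, dtrain, nrounds = hp$nrounds,
                                      verbose = 0))
  }
}

fit_mlp <- function(X, y, hp, role) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  if (role == "classifier") {
    lev <- levels(y)
    fit <- nnet::nnet(Xs, nnet::class.ind(y), size = hp$size, decay = hp$decay,
                      maxit = hp$maxit, softmax = TRUE, MaxNWts = 1e5,
                      trace = FALSE)
    list(net = fit, center = ctr, scale = scl, levels = lev, yscale = NULL)
  } else {
    yscale <- max(abs(y), 1)
    fit <- nnet::nnet(Xs, y / yscale, size = hp$size, decay = hp$decay,
                      maxit = hp$maxit, linout = TRUE, MaxNWts = 1e5,
                      trace = FALSE)
    list(net = fit, center = ctr, scale = scl, levels = NULL, yscale = yscale)
  }
}

fit_knn <- function(X, y, hp, role) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  if (role == "classifier") {
    list(X = Xs, y = y, k = hp$k, center = ctr, scale = scl)
  } else {
    list(knn = caret::knnreg(Xs, y, k = hp$k), center = ctr, scale = scl)
  }
}

predict_bank <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  fit <- model$fit
  switch(model$algorithm,
    random_forest = {
      p <- stats::predict(fit, X)
      if (model$role == "classifier") as.character(p) else as.numeric(p)
    },
    hist_gradient_boost = {
      p <- stats::predict(fit$booster, xgboost::xgb.DMatrix(X))
      if (model$role == "classifier") fit$levels[as.integer(p) + 1L] else as.numeric(p)
    },
    svm = {
      p <- stats::predict(fit, X)
      if (model$role == "classifier") as.character(p) else as.numeric(p)
    },
    mlp = {
      Xs <- scale(X, center = fit$center, scale = fit$scale)
      p <- stats::predict(fit$net, Xs)
      if (model$role == "classifier") fit$levels[max.col(p)]
      else as.numeric(p) * fit$yscale
    },
    knn = {
      Xs <- scale(X, center = fit$center, scale = fit$scale)
      if (model$role == "classifier")
        as.character(class::knn(fit$X, Xs, fit$y, k = fit$k))
      else as.numeric(stats::predict(fit$knn, Xs))
    },
    stop("predict_bank: unknown algorithm ", model$algorithm, call. = FALSE)
  )
}
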