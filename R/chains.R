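# Feature-selection chains and the logistic signature model. Each chain is
# a left-to-right composition of stages; every stage returns a (non-strict)
# subset of its input feature set, so chains are monotone by construction.

#' The nine supported feature-selection chains
#'
#' Names of the selection-chain compositions understood by
#' [reduce_features()]; stages are separated by `+` and applied left to
#' right.
#'
#' @format Character vector of length 9.
#' @export
omr_chain_names <- c(
  "corr+lasso", "lr+lasso", "corr+lasso+stepwise", "lr+lasso+stepwise",
  "xgboost+lasso+stepwise", "rf+lasso+stepwise", "gbm+lasso+stepwise",
  "svm+lasso+stepwise", "lasso+stepwise"
)

# run expr under a local, seeded RNG without disturbing the caller's stream
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# deterministic derived seed; keeps every derived seed under 2^31
derive_seed <- function(seed, ...) {
  parts <- c(...)
  h <- as.double(seed %% 2147483647L)
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p)) else as.double(p)
    h <- (h * 1000003 + v + 12345) %% 2147483647
  }
  as.integer(h)
}

check_xy <- function(X, y) {
  if (length(unique(y)) < 2)
    stop("input error: labels contain a single class", call. = FALSE)
  stopifnot(nrow(X) == length(y))
}

stage_correlation <- function(X, y, features, r_max = 0.90) {
  if (length(features) < 2) return(features)
  M <- X[, features, drop = FALSE]
  cm <- suppressWarnings(stats::cor(M))
  cm[is.na(cm)] <- 0
  lab_cor <- abs(suppressWarnings(stats::cor(M, y)))
  lab_cor[is.na(lab_cor)] <- 0
  keep <- rep(TRUE, length(features))
  pairs <- which(upper.tri(cm) & abs(cm) > r_max, arr.ind = TRUE)
  if (nrow(pairs)) {
    ord <- order(-abs(cm[pairs]))
    for (r in ord) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (!keep[i] || !keep[j]) next
      drop_j <- lab_cor[j] <= lab_cor[i]  # tie: keep the earlier column
      if (drop_j) keep[j] <- FALSE else keep[i] <- FALSE
    }
  }
  features[keep]
}

stage_univariate <- function(X, y, features, alpha = 0.05) {
  p <- vapply(features, function(f) {
    fit <- suppressWarnings(stats::glm(y ~ X[, f], family = stats::binomial()))
    co <- summary(fit)$coefficients
    if (nrow(co) < 2 || is.na(co[2, 4])) 1 else co[2, 4]
  }, 0)
  features[p < alpha]
}

stratified_foldid <- function(y, folds) {
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    rows <- which(y == cls)
    foldid[rows] <- sample(rep_len(seq_len(folds), length(rows)))
  }
  foldid
}

stage_lasso <- function(X, y, features, folds = 10) {
  if (length(features) == 0) return(features)
  if (length(features) == 1) return(features)   # glmnet needs >= 2 columns
  M <- as.matrix(X[, features, drop = FALSE])
  nf <- min(folds, min(table(y)))
  if (nf < 3) nf <- 3
  foldid <- stratified_foldid(y, nf)
  cv <- glmnet::cv.glmnet(M, y, family = "binomial", foldid = foldid,
                          type.measure = "deviance", standardize = TRUE)
  co <- as.matrix(stats::coef(cv, s = "lambda.1se"))[-1, 1]
  features[co != 0]
}

stage_stepwise <- function(X, y, features, max_steps = 30) {
  if (length(features) == 0) return(features)
  df <- data.frame(X[, features, drop = FALSE], .y = y, check.names = FALSE)
  full <- suppressWarnings(stats::glm(
    stats::reformulate(sprintf("`%s`", features), ".y"),
    data = df, family = stats::binomial()))
  sel <- suppressWarnings(MASS::stepAIC(
    full, direction = "both", trace = 0, steps = max_steps))
  kept <- attr(stats::terms(sel), "term.labels")
  gsub("`", "", kept)
}

ranker_importance <- function(X, y, features, method) {
  M <- as.matrix(X[, features, drop = FALSE])
  imp <- switch(method,
    rf = {
      fit <- randomForest::randomForest(M, factor(y), ntree = 300)
      fit$importance[, "MeanDecreaseGini"]
    },
    xgboost = {
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3,
                      eta = 0.3, nthread = 1),
        data = xgboost::xgb.DMatrix(M, label = y, nthread = 1),
        nrounds = 50, verbose = 0)
      tab <- xgboost::xgb.importance(model = fit)
      v <- stats::setNames(rep(0, length(features)), features)
      v[tab$Feature] <- tab$Gain
      v
    },
    gbm = {
      # classic stochastic gradient boosting configuration: shallow trees,
      # slow learning rate, row subsampling
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 2,
                      eta = 0.1, subsample = 0.5, nthread = 1),
        data = xgboost::xgb.DMatrix(M, label = y, nthread = 1),
        nrounds = 100, verbose = 0)
      tab <- xgboost::xgb.importance(model = fit)
      v <- stats::setNames(rep(0, length(features)), features)
      v[tab$Feature] <- tab$Gain
      v
    },
    svm = {
      fit <- e1071::svm(M, factor(y), kernel = "linear", scale = TRUE)
      w <- t(fit$coefs) %*% fit$SV
      stats::setNames(abs(as.vector(w)), colnames(M))
    },
    stop("unknown ranker ", method, call. = FALSE))
  imp
}

stage_ranker <- function(X, y, features, method, top_k = 20) {
  if (length(features) <= 1) return(features)
  imp <- ranker_importance(X, y, features, method)
  k <- min(top_k, length(features))
  # ties broken by original column order (stable sort)
  features[order(-imp[features])[seq_len(k)]]
}

parse_chain <- function(chain) {
  if (inherits(chain, "omr_chain")) return(chain)
  if (!chain %in% omr_chain_names)
    stop("unknown selection chain: ", chain, "; choices are ",
         paste(omr_chain_names, collapse = ", "), call. = FALSE)
  structure(list(name = chain, stages = strsplit(chain, "+", fixed = TRUE)[[1]]),
            class = "omr_chain")
}

#' Reduce a feature set through a named selection chain
#'
#' Applies the stages of one of the nine supported chains left to right on
#' the training rows. Stage semantics: `corr` drops one of each pair with
#' `|Pearson r| > 0.90` (keeping the member with the larger absolute
#' point-biserial correlation with the label); `lr` keeps features with
#' univariate logistic Wald `p < .05`; `lasso` keeps features with nonzero
#' coefficients in an L1-penalized logistic model with the penalty chosen
#' by 10-fold cross-validation under the 1-SE rule; `stepwise` runs
#' bidirectional AIC selection on an unpenalized logistic model;
#' `xgboost`/`rf`/`gbm`/`svm` rank features by the method's importance
#' (linear-kernel `|weight|` for svm) and keep the top `min(20, p)` before
#' the subsequent lasso. An empty intermediate set short-circuits to an
#' empty result with a warning.
#'
#' @param X data.frame or matrix of training features (numeric columns).
#' @param y binary labels (0/1), both classes present.
#' @param chain one of [omr_chain_names].
#' @param seed integer seed controlling CV folds and stochastic rankers.
#' @return Character vector of retained feature names (possibly empty).
#' @export
reduce_features <- function(X, y, chain = "lasso+stepwise", seed = 1L) {
  ch <- parse_chain(chain)
  X <- as.data.frame(X)
  y <- as.integer(y)
  check_xy(X, y)
  features <- colnames(X)
  if (length(features) < 1) stop("input error: no features", call. = FALSE)
  with_local_seed(derive_seed(seed, ch$name), {
    for (st in ch$stages) {
      if (length(features) == 0) break
      features <- switch(st,
        corr = stage_correlation(X, y, features),
        lr = stage_univariate(X, y, features),
        lasso = stage_lasso(X, y, features),
        stepwise = stage_stepwise(X, y, features),
        xgboost = , rf = , gbm = , svm = stage_ranker(X, y, features, st),
        stop("unknown stage ", st, call. = FALSE))
    }
  })
  if (length(features) == 0)
    warning("selection chain '", ch$name, "' returned an empty feature set")
  features
}

#' Fit a logistic radiomics signature
#'
#' Standardizes the selected features by training mean and SD, fits a
#' maximum-likelihood logistic model, and defines the signature score as
#' the linear predictor (log-odds). Separable data fall back to a small
#' ridge penalty (1e-4) with a message.
#'
#' @param X training features (data.frame/matrix).
#' @param y binary labels (0/1).
#' @param features nonempty character vector of columns of `X`.
#' @return An object of class `omr_signature` with elements `features`,
#'   `center`, `scale`, `intercept`, `coef`.
#' @export
fit_logistic_signature <- function(X, y, features) {
  if (length(features) == 0)
    stop("input error: empty feature list", call. = FALSE)
  X <- as.data.frame(X)
  if (!all(features %in% colnames(X)))
    stop("input error: features missing from X", call. = FALSE)
  y <- as.integer(y)
  check_xy(X, y)
  M <- as.matrix(X[, features, drop = FALSE])
  center <- colMeans(M)
  scale <- apply(M, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  Z <- sweep(sweep(M, 2, center), 2, scale, "/")
  fit <- suppressWarnings(stats::glm.fit(cbind(1, Z), y,
                                         family = stats::binomial()))
  beta <- fit$coefficients
  separable <- !fit$converged || any(!is.finite(beta)) || any(abs(beta) > 15)
  if (separable) {
    message("separable training data; refitting with ridge penalty 1e-4")
    if (ncol(Z) == 1) {
      rf <- glmnet::glmnet(cbind(Z, 0), y, family = "binomial", alpha = 0,
                           lambda = 1e-4, standardize = FALSE)
      co <- as.matrix(stats::coef(rf))[, 1]
      beta <- c(co[1], co[2])
    } else {
      rf <- glmnet::glmnet(Z, y, family = "binomial", alpha = 0,
                           lambda = 1e-4, standardize = FALSE)
      beta <- as.matrix(stats::coef(rf))[, 1]
    }
  }
  structure(list(features = features, center = center, scale = scale,
                 intercept = unname(beta[1]),
                 coef = stats::setNames(unname(beta[-1]), features),
                 ridge_fallback = separable),
            class = "omr_signature")
}

#' Score a feature table with a fitted signature
#'
#' @param object an `omr_signature`.
#' @param newdata data.frame/matrix containing the signature's features.
#' @param ... unused.
#' @return Numeric vector of signature scores (linear predictor / log-odds).
#' @export
predict.omr_signature <- function(object, newdata, ...) {
  M <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  Z <- sweep(sweep(M, 2, object$center), 2, object$scale, "/")
  as.vector(object$intercept + Z %*% object$coef)
}

#' @export
print.omr_signature <- function(x, ...) {
  cat("<omr_signature>", length(x$features), "features\n")
  print(round(c("(Intercept)" = x$intercept, x$coef), 4))
  invisible(x)
}

#' Cross-validated AUC of a selection chain
#'
#' Stratified k-fold cross-validation in which feature selection AND model
#' fitting are re-run inside each training fold; the validation scores of
#' each fold give one per-fold AUC. A fold whose selection comes back empty
#' scores every sample identically (AUC 0.5). Deterministic for a fixed
#' seed.
#'
#' @inheritParams reduce_features
#' @param folds number of folds (default 10).
#' @return List with `mean_auc`, `fold_auc`, `foldid`.
#' @export
crossval_auc <- function(X, y, chain = "lasso+stepwise", folds = 10, seed = 1L) {
  X <- as.data.frame(X)
  y <- as.integer(y)
  check_xy(X, y)
  if (min(table(y)) < folds)
    stop("folding error: smallest class (", min(table(y)),
         ") cannot be stratified into ", folds, " folds", call. = FALSE)
  foldid <- with_local_seed(derive_seed(seed, "folds"),
                            stratified_foldid(y, folds))
  fold_auc <- vapply(seq_len(folds), function(f) {
    tr <- foldid != f
    sel <- suppressWarnings(
      reduce_features(X[tr, , drop = FALSE], y[tr], chain,
                      seed = derive_seed(seed, "fold", f)))
    if (length(sel) == 0) return(0.5)
    sig <- suppressMessages(
      fit_logistic_signature(X[tr, , drop = FALSE], y[tr], sel))
    sc <- predict(sig, X[!tr, , drop = FALSE])
    if (length(unique(y[!tr])) < 2) return(NA_real_)
    auc_mw(sc, y[!tr])
  }, 0)
  list(mean_auc = mean(fold_auc, na.rm = TRUE), fold_auc = fold_auc,
       foldid = foldid)
}
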