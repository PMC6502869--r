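#' Elastic-net objective function
#'
#' The penalized least-squares objective minimized by the tumor-fraction
#' regression:
#' \deqn{\frac{1}{2m}\|X\omega - y\|_2^2 + \alpha\rho\|\omega\|_1 +
#'   \frac{\alpha(1-\rho)}{2}\|\omega\|_2^2}
#' where `m` is the number of training examples, `alpha >= 0` the overall
#' penalty strength and `rho` in `[0, 1]` the L1 mixing fraction. An optional
#' (unpenalized) intercept can be supplied for evaluating fitted models.
#'
#' @param X m x n feature matrix.
#' @param y Length-m response (% malignant epithelium, 0-100).
#' @param omega Length-n weight vector.
#' @param alpha,rho Penalty parameters.
#' @param intercept Optional scalar intercept (default 0).
#' @return Non-negative scalar objective value.
#' @export
enet_objective <- function(X, y, omega, alpha, rho, intercept = 0) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (length(omega) != ncol(X)) stop("length(omega) must equal ncol(X)")
  if (alpha < 0) stop("alpha must be >= 0")
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  m <- nrow(X)
  r <- y - intercept - drop(X %*% omega)
  sum(r^2) / (2 * m) + alpha * rho * sum(abs(omega)) +
    alpha * (1 - rho) / 2 * sum(omega^2)
}

.soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' Fit an elastic-net regression of % malignant epithelium
#'
#' Minimizes [enet_objective()] by cyclic coordinate descent with
#' soft-thresholding, starting from `omega = 0`, stopping when the largest
#' per-cycle weight change falls below `tol`. Features are standardized to
#' zero mean and unit (population) variance by default, with an unpenalized
#' intercept; the response stays on its 0-100 scale. Constant features get
#' weight 0.
#'
#' @param X m x n feature matrix (m >= 2) or data frame.
#' @param y Length-m response vector.
#' @param alpha,rho Penalty parameters (see [enet_objective()]).
#' @param standardize Standardize columns before penalization (default TRUE).
#' @param intercept Include an unpenalized intercept (default TRUE).
#' @param feature_set Optional named feature-set label carried in the object.
#' @param tol Convergence threshold on the max weight change (default 1e-8).
#' @param max_iter Maximum coordinate-descent cycles.
#' @param init Optional warm-start weight vector on the standardized scale
#'   (used internally for pathwise fits; the default cold start is
#'   `omega = 0`).
#' @return An object of class `stainmap_enet` with elements `omega`
#'   (weights on the standardized scale), `intercept`, `center`, `scale`,
#'   `alpha`, `rho`, `feature_names`, `feature_set`, `iterations`,
#'   `converged`.
#' @export
enet_fit <- function(X, y, alpha = 0, rho = 0.5, standardize = TRUE,
                     intercept = TRUE, feature_set = NULL,
                     tol = 1e-8, max_iter = 100000L, init = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  m <- nrow(X); n <- ncol(X)
  if (m < 1L) stop("need at least one training example")
  if (length(y) != m) stop("length(y) must equal nrow(X)")
  if (alpha < 0 || rho < 0 || rho > 1) stop("require alpha >= 0 and rho in [0, 1]")
  fnames <- colnames(X)
  if (is.null(fnames)) fnames <- paste0("x", seq_len(n))

  center <- if (standardize) colMeans(X) else rep(0, n)
  sds <- sqrt(colMeans(sweep(X, 2L, colMeans(X))^2))
  constant <- sds < 1e-12
  if (any(constant) && alpha > 0) {
    message(sprintf("constant feature(s) %s: weight fixed at 0",
                    paste(fnames[constant], collapse = ", ")))
  }
  scale_ <- if (standardize) ifelse(constant, 1, sds) else rep(1, n)
  Xs <- sweep(sweep(X, 2L, center), 2L, scale_, "/")
  b <- if (intercept) mean(y) else 0
  yc <- y - b
  if (intercept && !standardize) {
    # center X too so the intercept stays unpenalized and exact
    center <- colMeans(X)
    Xs <- sweep(X, 2L, center)
  }

  w0 <- if (is.null(init)) numeric(0) else as.numeric(init)
  sol <- .enet_cd(Xs, yc, alpha, rho, constant, tol, as.integer(max_iter), w0)
  w <- sol$w
  it <- sol$iterations
  converged <- sol$converged
  structure(list(omega = stats::setNames(w, fnames), intercept = b,
                 center = stats::setNames(center, fnames),
                 scale = stats::setNames(scale_, fnames),
                 alpha = alpha, rho = rho,
                 feature_names = fnames, feature_set = feature_set,
                 standardize = standardize, has_intercept = intercept,
                 iterations = it, converged = converged,
                 m = m, call = match.call()),
            class = "stainmap_enet")
}

#' @export
print.stainmap_enet <- function(x, ...) {
  cat(sprintf("Elastic-net tumor-fraction model (alpha = %.4g, rho = %.2f%s)\n",
              x$alpha, x$rho,
              if (is.null(x$feature_set)) "" else paste0(", feature set: ", x$feature_set)))
  cat(sprintf("  fitted on %d squares in %d coordinate-descent cycles%s\n",
              x$m, x$iterations, if (x$converged) "" else " (NOT converged)"))
  cat("  standardized weights:\n")
  print(round(x$omega, 4))
  cat(sprintf("  intercept: %.4f\n", x$intercept))
  invisible(x)
}

#' @export
coef.stainmap_enet <- function(object, scale = c("standardized", "original"), ...) {
  scale <- match.arg(scale)
  if (scale == "standardized") {
    return(c("(Intercept)" = object$intercept, object$omega))
  }
  beta <- object$omega / object$scale
  b0 <- object$intercept - sum(object$center * beta)
  c("(Intercept)" = unname(b0), beta)
}

#' @export
summary.stainmap_enet <- function(object, ...) {
  out <- list(model = object,
              n_active = sum(object$omega != 0),
              l1 = sum(abs(object$omega)))
  class(out) <- "summary.stainmap_enet"
  out
}

#' @export
print.summary.stainmap_enet <- function(x, ...) {
  print(x$model)
  cat(sprintf("  active weights: %d of %d; ||omega||_1 = %.4f\n",
              x$n_active, length(x$model$omega), x$l1))
  invisible(x)
}

#' Predict % malignant epithelium for new squares
#'
#' Applies the stored standardization and weights. Raw predictions are
#' unclipped (they are the ROC scores); `type = "clipped"` truncates to
#' `[0, 100]` for map rendering.
#'
#' @param object A `stainmap_enet`.
#' @param newdata Matrix or data frame containing the model's feature
#'   columns.
#' @param type `"raw"` (default) or `"clipped"`.
#' @param ... Unused.
#' @return Numeric prediction vector.
#' @export
predict.stainmap_enet <- function(object, newdata, type = c("raw", "clipped"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    missing_cols <- setdiff(object$feature_names, names(newdata))
    if (length(missing_cols)) {
      stop("newdata is missing feature column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    newdata <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  } else {
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != length(object$feature_names)) {
      stop("newdata must have one column per model feature")
    }
  }
  Xs <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/")
  pred <- object$intercept + drop(Xs %*% object$omega)
  if (type == "clipped") pred <- pmin(pmax(pred, 0), 100) else pred
}

#' @export
residuals.stainmap_enet <- function(object, X, y, ...) {
  y - predict(object, X)
}

#' Grouped (leave-one-slide-pair-out) cross-validation
#'
#' Folds are the groups: each fold holds out all analysis squares of one WSI
#' pair. For each fold the model is fitted on the remaining groups
#' (standardization parameters computed on the training portion only) and
#' the criterion is evaluated on the held-out fold: either the full
#' penalized objective (the default, matching the training criterion) or the
#' held-out mean squared error.
#'
#' @param X,y Training features and response.
#' @param groups Length-m WSI-pair identifiers.
#' @param alpha,rho Penalty parameters.
#' @param criterion `"objective"` or `"mse"`.
#' @param ... Passed to [enet_fit()].
#' @return List with `folds` (data frame `group`, `value`, `n`) and `mean`.
#' @export
enet_cv <- function(X, y, groups, alpha, rho,
                    criterion = c("objective", "mse"), ...) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  if (length(groups) != nrow(X)) stop("length(groups) must equal nrow(X)")
  gids <- unique(groups)
  if (length(gids) < 2L) stop("grouped cross-validation needs at least two groups")
  vals <- numeric(length(gids)); ns <- integer(length(gids))
  for (i in seq_along(gids)) {
    test <- groups == gids[i]
    if (length(unique(y[test])) == 1L) {
      message(sprintf("fold '%s' has constant response; fold retained", gids[i]))
    }
    fit <- enet_fit(X[!test, , drop = FALSE], y[!test], alpha = alpha, rho = rho, ...)
    if (criterion == "objective") {
      Xs <- sweep(sweep(X[test, , drop = FALSE], 2L, fit$center), 2L, fit$scale, "/")
      vals[i] <- enet_objective(Xs, y[test], fit$omega, alpha, rho,
                                intercept = fit$intercept)
    } else {
      vals[i] <- mean((y[test] - predict(fit, X[test, , drop = FALSE]))^2)
    }
    ns[i] <- sum(test)
  }
  list(folds = data.frame(group = gids, value = vals, n = ns),
       mean = mean(vals))
}

#' Select elastic-net hyperparameters by grouped cross-validation
#'
#' Evaluates every `(alpha, rho)` grid point with [enet_cv()] and returns
#' the point minimizing the mean criterion across folds. Exact ties are
#' broken toward larger `alpha`, then larger `rho` (the sparser model).
#'
#' @param X,y,groups As in [enet_cv()].
#' @param alpha_grid,rho_grid Candidate values.
#' @param criterion `"objective"` (default) or `"mse"`.
#' @param ... Passed to [enet_fit()].
#' @return List `alpha`, `rho`, `table` (grid point x mean CV value).
#' @export
select_hyperparameters <- function(X, y, groups,
                                   alpha_grid = 10^seq(-4, 1, length.out = 13),
                                   rho_grid = c(0.1, 0.3, 0.5, 0.7, 0.9, 1.0),
                                   criterion = c("objective", "mse"), ...) {
  criterion <- match.arg(criterion)
  if (!length(alpha_grid) || !length(rho_grid)) stop("grids must be non-empty")
  X <- as.matrix(X)
  gids <- unique(groups)
  if (length(gids) < 2L) stop("grouped cross-validation needs at least two groups")
  # pathwise evaluation: within each fold and rho, walk alpha from largest to
  # smallest with warm starts (identical minima, far fewer cycles on the
  # strongly collinear feature sets)
  alphas <- sort(unique(alpha_grid), decreasing = TRUE)
  rhos <- unique(rho_grid)
  vals <- array(NA_real_, c(length(alphas), length(rhos), length(gids)))
  for (gi in seq_along(gids)) {
    test <- groups == gids[gi]
    Xtr <- X[!test, , drop = FALSE]; ytr <- y[!test]
    Xte <- X[test, , drop = FALSE]; yte <- y[test]
    for (ri in seq_along(rhos)) {
      w_prev <- NULL
      for (ai in seq_along(alphas)) {
        fit <- suppressMessages(enet_fit(Xtr, ytr, alpha = alphas[ai],
                                         rho = rhos[ri], init = w_prev, ...))
        w_prev <- fit$omega
        vals[ai, ri, gi] <- if (criterion == "objective") {
          Xs <- sweep(sweep(Xte, 2L, fit$center), 2L, fit$scale, "/")
          enet_objective(Xs, yte, fit$omega, alphas[ai], rhos[ri],
                         intercept = fit$intercept)
        } else {
          mean((yte - predict(fit, Xte))^2)
        }
      }
    }
  }
  mean_vals <- apply(vals, c(1, 2), mean)
  tab <- expand.grid(alpha = alpha_grid, rho = rho_grid)
  tab$mean_cv <- mean_vals[cbind(match(tab$alpha, alphas), match(tab$rho, rhos))]
  best_val <- min(tab$mean_cv)
  cand <- tab[tab$mean_cv == best_val, , drop = FALSE]
  cand <- cand[order(-cand$alpha, -cand$rho), , drop = FALSE]
  list(alpha = cand$alpha[1], rho = cand$rho[1], table = tab)
}

#' Train a tumor-fraction model on a feature table
#'
#' Convenience wrapper: subsets the feature columns of the requested feature
#' set, selects hyperparameters by leave-one-WSI-pair-out cross-validation,
#' and refits on all training squares.
#'
#' @param features Data frame containing the columns of
#'   [feature_set_columns()] for `feature_set`.
#' @param y Ground-truth % malignant epithelium.
#' @param groups WSI-pair identifiers.
#' @param feature_set Feature-set name (see [feature_set_columns()]).
#' @param alpha_grid,rho_grid,criterion Passed to
#'   [select_hyperparameters()].
#' @param ... Passed to [enet_fit()].
#' @return A `stainmap_enet` with the CV table in `$cv_table`.
#' @export
train_tumor_model <- function(features, y, groups, feature_set = "full",
                              alpha_grid = 10^seq(-4, 1, length.out = 13),
                              rho_grid = c(0.1, 0.3, 0.5, 0.7, 0.9, 1.0),
                              criterion = c("objective", "mse"), ...) {
  criterion <- match.arg(criterion)
  cols <- feature_set_columns(feature_set)
  X <- as.matrix(features[, cols, drop = FALSE])
  sel <- select_hyperparameters(X, y, groups, alpha_grid, rho_grid,
                                criterion = criterion, ...)
  fit <- enet_fit(X, y, alpha = sel$alpha, rho = sel$rho,
                  feature_set = feature_set, ...)
  fit$cv_table <- sel$table
  fit
}

#' Serialize a fitted model to JSON
#'
#' @param fit A `stainmap_enet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(fit, path) {
  jsonlite::write_json(
    list(omega = as.list(fit$omega), intercept = fit$intercept,
         center = as.list(fit$center), scale = as.list(fit$scale),
         alpha = fit$alpha, rho = fit$rho,
         feature_set = fit$feature_set, feature_names = fit$feature_names,
         standardize = fit$standardize, has_intercept = fit$has_intercept),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path Path written by [write_model_json()].
#' @return A `stainmap_enet`.
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  fnames <- j$feature_names
  structure(list(omega = stats::setNames(unlist(j$omega)[fnames], fnames),
                 intercept = j$intercept,
                 center = stats::setNames(unlist(j$center)[fnames], fnames),
                 scale = stats::setNames(unlist(j$scale)[fnames], fnames),
                 alpha = j$alpha, rho = j$rho,
                 feature_names = fnames, feature_set = j$feature_set,
                 standardize = j$standardize, has_intercept = j$has_intercept,
                 iterations = NA_integer_, converged = NA, m = NA_integer_,
                 call = NULL),
            class = "stainmap_enet")
}
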