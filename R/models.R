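# Sample-set partitioning, the three regression methods and their metrics.

#' Grouped Kennard-Stone calibration/prediction split
#'
#' Within each storage-time group, selects `ceiling(3/4 * group size)` rows
#' for the calibration set by the Kennard-Stone max-min rule: the first pair
#' is the two most distant rows; each following pick maximizes its minimum
#' Euclidean distance to the already-chosen set. Distances are computed on
#' the group's column z-scores. Ties are broken toward the lower sample id,
#' which makes the split invariant to row order. The remainder forms the
#' prediction set.
#'
#' @param X samples x features matrix.
#' @param ids sample labels, unique.
#' @param groups group label per sample.
#' @param ratio calibration fraction, default 3/4 (a 3:1 split).
#' @return object of class `split_plan` with `calibration_ids`,
#'   `prediction_ids`, `ratio`, `grouping`.
#' @export
kennard_stone_split <- function(X, ids, groups = NULL, ratio = 3 / 4) {
  X <- as.matrix(X)
  ids <- as.character(ids)
  stopifnot(nrow(X) == length(ids), !anyDuplicated(ids))
  if (is.null(groups)) groups <- rep(0L, length(ids))
  cal <- character(0)
  for (g in unique(groups)) {
    sel <- which(groups == g)
    if (length(sel) < 4) stop("each group needs at least 4 samples")
    # stable ordering by id so tie-breaks are row-order invariant
    sel <- sel[order(ids[sel])]
    Xg <- X[sel, , drop = FALSE]
    sdv <- apply(Xg, 2, stats::sd)
    Z <- sweep(Xg, 2, colMeans(Xg), "-")
    nz <- sdv > 0
    Z[, nz] <- sweep(Z[, nz, drop = FALSE], 2, sdv[nz], "/")
    D <- as.matrix(stats::dist(Z))
    m <- length(sel)
    k <- ceiling(ratio * m)
    # first pair: maximum distance; which.max scans column-major so the
    # first (lowest-id) of tied pairs wins
    start <- arrayInd(which.max(D), dim(D))
    chosen <- sort(c(start[1], start[2]))
    while (length(chosen) < k) {
      rest <- setdiff(seq_len(m), chosen)
      mind <- apply(D[rest, chosen, drop = FALSE], 1, min)
      chosen <- c(chosen, rest[which.max(mind)])
    }
    cal <- c(cal, ids[sel][chosen])
  }
  structure(list(calibration_ids = sort(cal),
                 prediction_ids = sort(setdiff(ids, cal)),
                 ratio = ratio, grouping = groups), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan: %d calibration / %d prediction (ratio %.2f)\n",
              length(x$calibration_ids), length(x$prediction_ids), x$ratio))
  invisible(x)
}

#' Partial least-squares regression (SIMPLS)
#'
#' Mean-centred univariate-response PLSR by the SIMPLS algorithm. With
#' `n_components` equal to the rank of the centred predictor matrix the fit
#' coincides with ordinary least squares.
#'
#' @param X calibration predictors (samples x features).
#' @param y calibration response.
#' @param n_components number of latent variables, between 1 and
#'   `min(rows - 1, cols)`.
#' @return object of class `plsr_model` (also `regression_model`).
#' @export
fit_plsr <- function(X, y, n_components = 10L) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  A <- as.integer(n_components)
  if (A < 1 || A > min(nrow(X) - 1, ncol(X)))
    stop("n_components must be in 1..min(rows - 1, cols)")
  xm <- colMeans(X); ym <- mean(y)
  X0 <- sweep(X, 2, xm, "-"); y0 <- y - ym
  p <- ncol(X0)
  S <- crossprod(X0, y0)
  R <- matrix(0, p, A); Q <- numeric(A); V <- matrix(0, p, A)
  for (a in seq_len(A)) {
    r <- S
    t <- X0 %*% r
    nt <- sqrt(sum(t^2))
    if (nt < 1e-12) { A <- a - 1L; break }   # rank exhausted
    t <- t / nt; r <- r / nt
    pa <- crossprod(X0, t)
    Q[a] <- sum(y0 * t)
    v <- pa
    if (a > 1) v <- v - V[, seq_len(a - 1), drop = FALSE] %*%
        crossprod(V[, seq_len(a - 1), drop = FALSE], pa)
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; V[, a] <- v
  }
  if (A < 1) stop("predictor matrix has rank 0 after centring")
  coef <- R[, seq_len(A), drop = FALSE] %*% Q[seq_len(A)]
  structure(list(method = "plsr", coefficients = as.numeric(coef),
                 intercept = ym - sum(xm * coef), n_components = A,
                 x_mean = xm, y_mean = ym, n_features = p),
            class = c("plsr_model", "regression_model"))
}

#' @export
predict.plsr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop(sprintf("model expects %d features, got %d",
                 object$n_features, ncol(newdata)))
  as.numeric(newdata %*% object$coefficients + object$intercept)
}

#' Support vector regression (RBF)
#'
#' Epsilon-insensitive SVR through libsvm. When `C`, `gamma` or `epsilon`
#' are `NULL` they are chosen by a seeded k-fold grid search over a small
#' documented grid (`C` in 1/10/100, `gamma` in (0.1, 1, 10)/p, `epsilon`
#' in 0.01/0.1) minimizing RMSECV.
#'
#' @param X calibration predictors.
#' @param y calibration response.
#' @param C,gamma,epsilon hyperparameters, or `NULL` to tune.
#' @param folds folds for the tuning search.
#' @param seed seed for the tuning fold assignment.
#' @return object of class `svr_model` (also `regression_model`).
#' @export
fit_svr <- function(X, y, C = NULL, gamma = NULL, epsilon = NULL,
                    folds = 5L, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  p <- ncol(X)
  if (stats::var(y) == 0) {
    # every point sits inside any epsilon tube; libsvm returns an empty
    # model, so degrade to the constant predictor explicitly
    return(structure(list(method = "svr", fit = NULL, constant = y[1],
                          hyperparameters = list(C = C, gamma = gamma,
                                                 epsilon = epsilon),
                          n_features = p),
                     class = c("svr_model", "regression_model")))
  }
  grid <- expand.grid(
    C = if (is.null(C)) c(1, 10, 100) else C,
    gamma = if (is.null(gamma)) c(0.1, 1, 10) / p else gamma,
    epsilon = if (is.null(epsilon)) c(0.01, 0.1) else epsilon)
  if (nrow(grid) > 1) {
    fold_of <- .make_folds(nrow(X), folds, seed)
    cv <- vapply(seq_len(nrow(grid)), function(i) {
      pred <- numeric(nrow(X))
      for (f in seq_len(folds)) {
        hold <- fold_of == f
        fit <- e1071::svm(X[!hold, , drop = FALSE], y[!hold],
                          type = "eps-regression", kernel = "radial",
                          cost = grid$C[i], gamma = grid$gamma[i],
                          epsilon = grid$epsilon[i], scale = TRUE)
        pred[hold] <- predict(fit, X[hold, , drop = FALSE])
      }
      sqrt(mean((y - pred)^2))
    }, numeric(1))
    best <- grid[which.min(cv), ]
  } else best <- grid[1, ]
  # libsvm standardizes x and y; a zero-variance response would divide by 0
  fit <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                    cost = best$C, gamma = best$gamma,
                    epsilon = best$epsilon, scale = stats::var(y) > 0)
  structure(list(method = "svr", fit = fit, hyperparameters = as.list(best),
                 n_features = p),
            class = c("svr_model", "regression_model"))
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop(sprintf("model expects %d features, got %d",
                 object$n_features, ncol(newdata)))
  if (is.null(object$fit)) return(rep(object$constant, nrow(newdata)))
  as.numeric(predict(object$fit, newdata))
}

#' Locally weighted regression
#'
#' For each query row: find the nearest calibration rows in a principal-
#' component compression of the calibration predictors (components kept to
#' `var_kept` of the variance), weight them by a distance kernel, fit a
#' weighted linear regression in that space and evaluate it at the query.
#' With all rows as neighbours and an infinite bandwidth this reduces to
#' ordinary least squares in the PC space. Singular weighted normal
#' equations fall back to a small ridge jitter.
#'
#' @param X_cal,y_cal calibration data.
#' @param X_query rows to predict.
#' @param n_neighbors local neighbourhood size; default `min(30, n_cal)`.
#' @param kernel `"gaussian"` (`exp(-d^2 / (2 h^2))`) or `"uniform"`.
#' @param bandwidth kernel scale h; `NULL` uses the median neighbour
#'   distance per query (adaptive).
#' @param var_kept variance fraction kept by the PC compression.
#' @return numeric predictions, one per query row.
#' @export
lwr_predict <- function(X_cal, y_cal, X_query, n_neighbors = NULL,
                        kernel = c("gaussian", "uniform"), bandwidth = NULL,
                        var_kept = 0.99) {
  kernel <- match.arg(kernel)
  X_cal <- as.matrix(X_cal); X_query <- as.matrix(X_query)
  y_cal <- as.numeric(y_cal)
  n <- nrow(X_cal)
  if (is.null(n_neighbors)) n_neighbors <- min(30L, n)
  if (n_neighbors > n) stop("n_neighbors exceeds calibration rows")
  if (!is.null(bandwidth) && bandwidth <= 0) stop("bandwidth must be positive")
  pc <- stats::prcomp(X_cal, center = TRUE, scale. = FALSE)
  keep <- which(cumsum(pc$sdev^2) / sum(pc$sdev^2) >= var_kept)[1]
  keep <- max(1L, min(keep, n - 2L))
  T_cal <- pc$x[, seq_len(keep), drop = FALSE]
  T_q <- sweep(X_query, 2, pc$center, "-") %*%
    pc$rotation[, seq_len(keep), drop = FALSE]
  vapply(seq_len(nrow(T_q)), function(i) {
    d <- sqrt(rowSums(sweep(T_cal, 2, T_q[i, ], "-")^2))
    nb <- order(d)[seq_len(n_neighbors)]
    h <- if (is.null(bandwidth)) max(stats::median(d[nb]), 1e-8) else bandwidth
    w <- if (kernel == "gaussian") exp(-d[nb]^2 / (2 * h^2)) else
      rep(1, length(nb))
    A <- cbind(1, T_cal[nb, , drop = FALSE])
    WA <- A * w
    M <- crossprod(WA, A)
    rhs <- crossprod(WA, y_cal[nb])
    beta <- tryCatch(solve(M, rhs), error = function(e) {
      message("lwr: singular local system, ridge jitter 1e-8 applied")
      solve(M + diag(1e-8, ncol(M)), rhs)
    })
    sum(c(1, T_q[i, ]) * beta)
  }, numeric(1))
}

#' Evaluation metrics on calibration and prediction sets
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` and
#' `RMSE = sqrt(mean((y - yhat)^2))`, each set scored against its own mean.
#'
#' @param y_cal,yhat_cal calibration observed/predicted.
#' @param y_pred,yhat_pred prediction-set observed/predicted.
#' @return object of class `evaluation_report`: `rc2`, `rmsec`, `rp2`,
#'   `rmsep`, `n_cal`, `n_pred`.
#' @export
evaluate <- function(y_cal, yhat_cal, y_pred, yhat_pred) {
  r2 <- function(y, yh) {
    ss <- sum((y - mean(y))^2)
    if (ss == 0) stop("zero variance in y: R^2 undefined")
    1 - sum((y - yh)^2) / ss
  }
  rmse <- function(y, yh) sqrt(mean((y - yh)^2))
  structure(list(rc2 = r2(y_cal, yhat_cal), rmsec = rmse(y_cal, yhat_cal),
                 rp2 = r2(y_pred, yhat_pred), rmsep = rmse(y_pred, yhat_pred),
                 n_cal = length(y_cal), n_pred = length(y_pred)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Rc2 %.4f  RMSEC %.4f  |  Rp2 %.4f  RMSEP %.4f  (n %d/%d)\n",
              x$rc2, x$rmsec, x$rp2, x$rmsep, x$n_cal, x$n_pred))
  invisible(x)
}

# Seeded shuffled contiguous fold assignment.
.make_folds <- function(n, folds, seed) {
  if (folds < 2) stop("folds must be >= 2")
  if (n < 2 * folds) stop("a fold would have fewer than 2 rows")
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  sizes <- rep(n %/% folds, folds) + c(rep(1, n %% folds),
                                       rep(0, folds - n %% folds))
  out <- integer(n)
  out[perm] <- rep(seq_len(folds), sizes)
  out
}

#' Root mean square error of cross-validation
#'
#' Pools the out-of-fold PLSR predictions over all rows and computes one
#' RMSE. Fold assignment is a seeded shuffle into contiguous folds.
#'
#' @param X predictors.
#' @param y response.
#' @param folds number of folds (>= 2).
#' @param n_components PLSR components (capped at what each training fold
#'   supports).
#' @param seed fold-assignment seed.
#' @return scalar RMSECV.
#' @export
rmsecv <- function(X, y, folds = 5L, n_components = 10L, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  fold_of <- .make_folds(nrow(X), folds, seed)
  pred <- numeric(nrow(X))
  for (f in seq_len(folds)) {
    hold <- fold_of == f
    A <- min(n_components, sum(!hold) - 1, ncol(X))
    fit <- fit_plsr(X[!hold, , drop = FALSE], y[!hold], A)
    pred[hold] <- predict(fit, X[hold, , drop = FALSE])
  }
  sqrt(mean((y - pred)^2))
}

#' Choose a PLSR component count by RMSECV
#' @param X,y data.
#' @param max_components search cap.
#' @param folds,seed cross-validation settings.
#' @return integer component count minimizing RMSECV.
#' @export
choose_components <- function(X, y, max_components = 15L, folds = 5L,
                              seed = 1L) {
  kmax <- min(max_components, nrow(as.matrix(X)) - ceiling(nrow(as.matrix(X)) / folds) - 1,
              ncol(as.matrix(X)))
  errs <- vapply(seq_len(kmax), function(a) rmsecv(X, y, folds, a, seed),
                 numeric(1))
  which.min(errs)
}
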