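# Variable selection: competitive adaptive reweighted sampling (CARS) and
# uninformative variable elimination (UVE), both built on PLSR coefficients.

.as_feature_matrix <- function(X) {
  if (inherits(X, "feature_table")) X$F
  else if (inherits(X, "spectra_table")) X$X
  else as.matrix(X)
}

#' Competitive adaptive reweighted sampling
#'
#' Iterative variable elimination driven by PLSR coefficient magnitudes. At
#' Monte-Carlo run i, a PLSR model is fitted on a random `mc_fraction` of
#' the rows using the currently retained variables; variable weights are the
#' normalized absolute regression coefficients. An exponentially decreasing
#' schedule (from keeping all p variables at run 1 down to 2 at the final
#' run) fixes how many top-weighted variables survive, and adaptive
#' reweighted sampling (weighted draws with replacement, probability
#' proportional to weight) competitively thins that set. Each run's retained
#' set is scored by k-fold RMSECV on the full data; the set with the lowest
#' RMSECV wins.
#'
#' @param X feature matrix (or `spectra_table` / `feature_table`).
#' @param y response.
#' @param runs Monte-Carlo runs (>= 2).
#' @param mc_fraction row fraction per run.
#' @param mc_fits subsample fits averaged into each run's weights; values
#'   above 1 damp the coefficient-ranking noise of a single subsample fit
#'   (with hundreds of variables and fewer rows a lone fit can rank a true
#'   predictor below noise and eliminate it irrecoverably).
#' @param folds RMSECV folds.
#' @param n_components PLSR components; `NULL` chooses once up front by
#'   RMSECV over 1..15 and holds the choice fixed across runs.
#' @param seed seed controlling sampling and fold assignment.
#' @return object of class `selection_result`: sorted `selected` indices,
#'   aggregated `weights` (sum 1 over all variables), `rmsecv_trace`,
#'   `best_iteration`, `retained_sizes`, `method`, `seed`.
#' @export
cars <- function(X, y, runs = 50L, mc_fraction = 0.8, mc_fits = 10L,
                 folds = 5L, n_components = NULL, seed = 1L) {
  X <- .as_feature_matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n == length(y), runs >= 2, n >= folds)
  set.seed(as.integer(seed))
  if (is.null(n_components))
    n_components <- choose_components(X, y, 15L, folds, seed)
  # exponentially decreasing retention schedule r_i = a exp(-k i), with
  # r_1 = 1 (all variables) and r_runs = 2/p (two variables)
  k <- log(p / 2) / (runs - 1)
  a <- exp(k)
  ratios <- a * exp(-k * seq_len(runs))
  retained <- seq_len(p)
  trace <- numeric(runs)
  sizes <- integer(runs)
  sets <- vector("list", runs)
  agg_weights <- numeric(p)
  n_mc <- max(2L, round(mc_fraction * n))
  for (i in seq_len(runs)) {
    A <- min(n_components, n_mc - 1, length(retained))
    w <- numeric(length(retained))
    for (f in seq_len(mc_fits)) {
      rows <- sample.int(n, n_mc)
      fit <- fit_plsr(X[rows, retained, drop = FALSE], y[rows], A)
      wf <- abs(fit$coefficients)
      if (sum(wf) > 0) w <- w + wf / sum(wf)
    }
    if (sum(w) == 0) w <- rep(1, length(w))
    w <- w / sum(w)
    agg_weights[retained] <- agg_weights[retained] + w
    # enforced decreasing forced-retention count, never below 2
    keep_n <- max(2L, min(ceiling(ratios[i] * p), length(retained)))
    top <- retained[order(w, decreasing = TRUE)[seq_len(keep_n)]]
    w_top <- w[match(top, retained)]
    # adaptive reweighted sampling among the survivors: 5p draws with
    # replacement so the exponential schedule, not the draw count, governs
    # the shrinkage; competition only weeds out low-weight stragglers
    drawn <- unique(sample(top, size = 5L * p, replace = TRUE,
                           prob = w_top / sum(w_top)))
    if (length(drawn) < 2) drawn <- top[seq_len(2)]
    retained <- sort(drawn)
    sizes[i] <- length(retained)
    sets[[i]] <- retained
    # rmsecv reseeds the RNG for its fold assignment; shield the Monte-Carlo
    # sampling stream so successive runs keep drawing fresh row subsets
    mc_state <- .Random.seed
    trace[i] <- rmsecv(X[, retained, drop = FALSE], y, folds,
                       min(n_components, length(retained)), seed)
    assign(".Random.seed", mc_state, envir = globalenv())
    if (!is.finite(trace[i])) stop("non-finite RMSECV in CARS run ", i)
  }
  best <- which.min(trace)
  structure(list(selected = sets[[best]],
                 weights = agg_weights / sum(agg_weights),
                 rmsecv_trace = trace, best_iteration = best,
                 retained_sizes = sizes, method = "cars",
                 n_components = n_components, seed = as.integer(seed)),
            class = "selection_result")
}

#' Uninformative variable elimination
#'
#' Appends p artificial noise variables of negligible amplitude to the real
#' predictors, runs leave-one-out PLSR, and computes each variable's
#' stability `c_j = mean(b_j) / sd(b_j)` over the ensemble of coefficient
#' vectors. The cutoff is the `cutoff_quantile` of |c| over the noise block;
#' real variables whose |c| exceeds it are retained. When nothing survives,
#' the full variable set is returned with a warning (flagged in the result).
#'
#' @param X feature matrix (or table).
#' @param y response.
#' @param n_components PLSR components.
#' @param cutoff_quantile quantile of the noise-block |stability|.
#' @param noise_amplitude noise scale relative to the mean column s.d.
#' @param seed seed for the noise draw.
#' @return `selection_result` (indices refer to real columns only) with
#'   `stability`, `cutoff` and `fallback` flag.
#' @export
uve <- function(X, y, n_components = 10L, cutoff_quantile = 0.99,
                noise_amplitude = 1e-10, seed = 1L) {
  X <- .as_feature_matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n >= 3, n == length(y))
  set.seed(as.integer(seed))
  scale_sd <- mean(apply(X, 2, stats::sd))
  if (scale_sd == 0) scale_sd <- 1
  noise <- matrix(stats::runif(n * p, -1, 1) * noise_amplitude * scale_sd,
                  n, p)
  XX <- cbind(X, noise)
  B <- matrix(NA_real_, n, 2 * p)
  for (i in seq_len(n)) {
    A <- min(n_components, n - 2, ncol(XX))
    B[i, ] <- fit_plsr(XX[-i, , drop = FALSE], y[-i], A)$coefficients
  }
  mb <- colMeans(B)
  sb <- apply(B, 2, stats::sd)
  stab <- ifelse(sb == 0, ifelse(mb == 0, 0, Inf), mb / sb)
  if (any(sb == 0 & mb != 0))
    message("uve: ", sum(sb == 0 & mb != 0),
            " variable(s) with zero coefficient spread treated as infinitely stable")
  cutoff <- stats::quantile(abs(stab[p + seq_len(p)]), cutoff_quantile,
                            names = FALSE)
  selected <- which(abs(stab[seq_len(p)]) > cutoff)
  fallback <- length(selected) == 0
  if (fallback) {
    warning("uve: no variable exceeded the noise cutoff; keeping the full set")
    selected <- seq_len(p)
  }
  structure(list(selected = selected, weights = abs(stab[seq_len(p)]),
                 stability = stab[seq_len(p)], cutoff = cutoff,
                 rmsecv_trace = NULL, best_iteration = NA_integer_,
                 fallback = fallback, method = "uve",
                 seed = as.integer(seed)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result [%s]: %d variables selected", x$method,
              length(x$selected)))
  if (!is.null(x$rmsecv_trace))
    cat(sprintf(", best RMSECV %.4g at run %d",
                min(x$rmsecv_trace), x$best_iteration))
  cat("\n")
  invisible(x)
}

#' CARS band-weight ranking for texture wavelength picking
#'
#' Accumulates the normalized absolute PLSR coefficient weights over all
#' CARS Monte-Carlo runs and returns the per-band weights (sum 1) together
#' with the k wavelengths of largest weight, in descending weight order.
#'
#' @param spectra `spectra_table` (or matrix plus `wavelengths`).
#' @param y response.
#' @param k wavelengths to return.
#' @param wavelengths needed when `spectra` is a bare matrix.
#' @param ... passed to [cars()].
#' @return list with `weights` (per band), `wavelengths` (the top k) and the
#'   underlying `selection_result`.
#' @export
rank_band_weights <- function(spectra, y, k = 2L, wavelengths = NULL, ...) {
  if (inherits(spectra, "spectra_table")) {
    wavelengths <- spectra$wavelengths
    X <- spectra$X
  } else X <- as.matrix(spectra)
  if (is.null(wavelengths) || length(wavelengths) != ncol(X))
    stop("wavelengths must accompany the spectra")
  res <- cars(X, y, ...)
  ord <- order(res$weights, decreasing = TRUE)
  list(weights = res$weights, wavelengths = wavelengths[ord[seq_len(k)]],
       selection = res)
}

#' Serialize a selection result to JSON
#' @param result `selection_result`.
#' @param path output file.
#' @param wavelengths optional per-variable wavelengths to record.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(result, path, wavelengths = NULL) {
  stopifnot(inherits(result, "selection_result"))
  obj <- list(method = result$method, selected = result$selected,
              weights = result$weights, rmsecv_trace = result$rmsecv_trace,
              best_iteration = result$best_iteration, seed = result$seed)
  if (!is.null(wavelengths))
    obj$selected_wavelengths <- wavelengths[result$selected]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
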