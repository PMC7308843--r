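# Independent brute-force oracles and shared fixtures for the suite.

# Brute-force GLGCM oracle: explicit per-pixel Sobel, quantization, joint
# table accumulation and statistic formulas written as plain loops.
glgcm_oracle <- function(img, L = 16L, K = 16L) {
  nr <- nrow(img); nc <- ncol(img)
  at <- function(r, c) img[min(max(r, 1), nr), min(max(c, 1), nc)]
  grad <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    gx <- (at(r - 1, c + 1) + 2 * at(r, c + 1) + at(r + 1, c + 1)) -
          (at(r - 1, c - 1) + 2 * at(r, c - 1) + at(r + 1, c - 1))
    gy <- (at(r + 1, c - 1) + 2 * at(r + 1, c) + at(r + 1, c + 1)) -
          (at(r - 1, c - 1) + 2 * at(r - 1, c) + at(r - 1, c + 1))
    grad[r, c] <- sqrt(gx^2 + gy^2)
  }
  qz <- function(x, lev) {
    mx <- max(x)
    if (mx <= 0) matrix(0L, nrow(x), ncol(x)) else
      matrix(as.integer(round(x * (lev - 1) / mx)), nrow(x), ncol(x))
  }
  gi <- qz(img, L); gj <- qz(grad, K)
  H <- matrix(0, L, K)
  for (r in seq_len(nr)) for (c in seq_len(nc))
    H[gi[r, c] + 1, gj[r, c] + 1] <- H[gi[r, c] + 1, gj[r, c] + 1] + 1
  p <- H / sum(H)
  pi_ <- rowSums(p); pj_ <- colSums(p)
  mu_i <- 0; for (i in 1:L) mu_i <- mu_i + i * pi_[i]
  mu_j <- 0; for (j in 1:K) mu_j <- mu_j + j * pj_[j]
  var_i <- 0; for (i in 1:L) var_i <- var_i + (i - mu_i)^2 * pi_[i]
  var_j <- 0; for (j in 1:K) var_j <- var_j + (j - mu_j)^2 * pj_[j]
  sg <- bg <- en <- corr <- inert <- homog <- ment <- 0
  for (i in 1:L) for (j in 1:K) {
    sg <- sg + p[i, j] / j^2
    bg <- bg + p[i, j] * j^2
    en <- en + p[i, j]^2
    corr <- corr + (i - mu_i) * (j - mu_j) * p[i, j]
    inert <- inert + (i - j)^2 * p[i, j]
    homog <- homog + p[i, j] / (1 + (i - j)^2)
    if (p[i, j] > 0) ment <- ment - p[i, j] * log2(p[i, j])
  }
  corr <- if (var_i > 0 && var_j > 0) corr / sqrt(var_i * var_j) else 0
  he <- function(q) { s <- 0; for (v in q) if (v > 0) s <- s - v * log2(v); s }
  c(sg, bg, sum(pi_^2), sum(pj_^2), en, mu_i, mu_j, var_i, var_j, corr,
    he(pi_), he(pj_), ment, inert, homog)
}

# OLS prediction oracle
ols_oracle <- function(X, y, Xnew) {
  beta <- stats::lm.fit(cbind(1, X), y)$coefficients
  as.numeric(cbind(1, Xnew) %*% beta)
}

# Shared 120-sample dataset (built once per test run; ~15 s).
shared_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_dataset(120L, 5L, seed = 101L)
    cache
  }
})

# Smaller dataset with color/texture blocks extracted (cached per seed).
shared_image_dataset <- local({
  cache <- list()
  function(seed = 11L) {
    key <- as.character(seed)
    if (is.null(cache[[key]]))
      cache[[key]] <<- generate_dataset(40L, 5L, seed = seed,
                                        extract_images = TRUE)
    cache[[key]]
  }
})

# Small scene used by image-level tests.
small_scene <- function(seed = 5L, noise = scene_config()) {
  generate_scene(latent_quality(6.8, 3.0, 0.63, 1L), noise, seed)
}
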