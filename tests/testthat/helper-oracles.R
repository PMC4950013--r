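# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the grid search enumerates the parameter box
# directly, and the optim oracle runs base R's bounded quasi-Newton on the
# raw 4-parameter SSR.

# dense grid search over (a, b, c, d), refined once around the best cell.
# SSR over the (a, b) grid is evaluated through the exact quadratic
# expansion, which is an algebraic identity, not a model fit.
grid_search_ssr <- function(y, n_grid = 40, K = length(y)) {
  x <- seq_len(K)
  c_box <- c(0.85, 0.95) * 2 * pi / K
  d_box <- c(-pi, pi)
  a_box <- c(-1, 1)
  b_box <- c(-1, 1)
  best <- Inf
  best_par <- NULL
  sy <- sum(y); syy <- sum(y^2)
  for (level in 1:2) {
    cs <- seq(c_box[1], c_box[2], length.out = n_grid)
    ds <- seq(d_box[1], d_box[2], length.out = n_grid)
    as <- seq(a_box[1], a_box[2], length.out = n_grid)
    bs <- seq(b_box[1], b_box[2], length.out = n_grid)
    a_part <- as^2 * K - 2 * as * sy            # terms in a only
    for (cc in cs) {
      for (dd in ds) {
        s <- sin(cc * x + dd)
        ss <- sum(s); sss <- sum(s^2); sys <- sum(y * s)
        b_part <- bs^2 * sss - 2 * bs * sys     # terms in b only
        M <- outer(a_part, b_part, "+") + syy + 2 * outer(as, bs) * ss
        i <- arrayInd(which.min(M), dim(M))
        if (M[i] < best) {
          best <- M[i]
          best_par <- c(a = as[i[1]], b = bs[i[2]], c = cc, d = dd)
        }
      }
    }
    step <- c((a_box[2] - a_box[1]), (b_box[2] - b_box[1]),
              (c_box[2] - c_box[1]), (d_box[2] - d_box[1])) / (n_grid - 1)
    a_box <- pmax(-1, pmin(1, best_par["a"] + c(-1, 1) * step[1]))
    b_box <- pmax(-1, pmin(1, best_par["b"] + c(-1, 1) * step[2]))
    c_box <- pmax(0.85 * 2 * pi / K,
                  pmin(0.95 * 2 * pi / K, best_par["c"] + c(-1, 1) * step[3]))
    d_box <- best_par["d"] + c(-1, 1) * step[4]
  }
  best
}

# bounded quasi-Newton on the raw 4-parameter problem from many starts
optim_ssr <- function(y, n_d = 16, K = length(y)) {
  x <- seq_len(K)
  obj <- function(p) sum((y - p[1] - p[2] * sin(p[3] * x + p[4]))^2)
  c_lo <- 0.85 * 2 * pi / K
  c_hi <- 0.95 * 2 * pi / K
  best <- Inf
  for (d0 in seq(-pi, pi, length.out = n_d + 1)[-(n_d + 1)]) {
    for (b0 in c(-0.5, 0.5)) {
      fit <- tryCatch(
        stats::optim(c(mean(y), b0, (c_lo + c_hi) / 2, d0), obj,
                     method = "L-BFGS-B",
                     lower = c(-1, -1, c_lo, -pi - 1),
                     upper = c(1, 1, c_hi, pi + 1),
                     control = list(factr = 1e3, maxit = 500)),
        error = function(e) NULL)
      if (!is.null(fit) && fit$value < best) best <- fit$value
    }
  }
  best
}

# plain covariance-form Cronbach's alpha
alpha_oracle <- function(m) {
  k <- ncol(m)
  S <- stats::cov(m)
  k / (k - 1) * (1 - sum(diag(S)) / sum(S))
}

# textbook Pearson correlation from first principles
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
           sqrt(sum((y - mean(y))^2) / (n - 1)))
}
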