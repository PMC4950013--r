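#' @useDynLib valuewave, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor sd var complete.cases rnorm runif rbinom setNames
#' @importFrom utils read.delim write.table head
NULL

#' Circular order of the ten Schwartz value types
#'
#' The conventional ordering of the ten value types around the motivational
#' circle, starting at conformity. Correlation profiles are arranged in this
#' order before sinusoid fitting, so that angular position maps onto the
#' x-axis.
#'
#' @return character vector of length 10.
#' @export
#' @examples
#' schwartz_value_order()
schwartz_value_order <- function() {
  c("conformity", "tradition", "benevolence", "universalism",
    "self-direction", "stimulation", "hedonism", "achievement",
    "power", "security")
}

#' Construct an ordered correlation profile
#'
#' A correlation profile is the ordered vector of correlations between K
#' constructs arranged on a circle (by default the ten Schwartz value types)
#' and one external variable. Positions are re-indexed 1..K so that the
#' sinusoid's angular frequency is expressed per unit position.
#'
#' @param r numeric vector of correlations, each in \[-1, 1\].
#' @param labels optional character labels, same length as `r`; defaults to
#'   [schwartz_value_order()] when K = 10, otherwise `"v1".."vK"`.
#' @return object of class `correlation_profile`: a data.frame with columns
#'   `label`, `position`, `r`.
#' @export
#' @examples
#' correlation_profile(c(0.2, 0.1, -0.05, -0.2, -0.25, -0.1, 0, 0.1, 0.2, 0.25))
correlation_profile <- function(r, labels = NULL) {
  r <- as.numeric(r)
  K <- length(r)
  if (K < 4) {
    stop("a correlation profile needs at least 4 points (K = ", K, ")")
  }
  if (K == 4) {
    warning("K = 4 points saturate the 4-parameter sinusoid; the fit is exact ",
            "by construction and carries no evidence")
  }
  if (anyNA(r)) stop("correlation profile contains missing values")
  if (any(abs(r) > 1)) stop("correlations must lie in [-1, 1]")
  if (is.null(labels)) {
    labels <- if (K == 10) schwartz_value_order() else paste0("v", seq_len(K))
  }
  if (length(labels) != K) stop("labels must match the number of correlations")
  if (anyDuplicated(labels)) stop("profile labels must be unique")
  out <- data.frame(label = as.character(labels), position = seq_len(K),
                    r = r, stringsAsFactors = FALSE)
  class(out) <- c("correlation_profile", "data.frame")
  out
}

#' Evaluate the circumplex sinusoid
#'
#' Computes `a + b * sin(c * x + d)`, the model for the correlation between
#' the value type at circular position `x` and an external variable.
#'
#' @param x numeric position(s) on the circle (1..K for K value types).
#' @param params named list or vector with elements `a` (y-offset), `b`
#'   (amplitude), `c` (angular frequency, radians per position) and `d`
#'   (phase offset).
#' @return numeric vector of predicted correlations.
#' @export
#' @examples
#' sine_model(1:10, list(a = 0, b = 0.3, c = 0.9 * 2 * pi / 10, d = 0))
sine_model <- function(x, params) {
  p <- as.list(params)
  for (nm in c("a", "b", "c", "d")) {
    if (is.null(p[[nm]])) stop("params must contain '", nm, "'")
  }
  p$a + p$b * sin(p$c * x + p$d)
}

#' Sinusoidal Fit Index
#'
#' The SFI is the residual sum of squares of a fitted profile divided by the
#' total sum of squares of the observed profile (the 1/(K-1) factors of the
#' variance form cancel). 0 means a perfect sinusoid; 1 means the fit is no
#' better than the profile mean.
#'
#' @param y observed correlations.
#' @param y_hat fitted values, same length.
#' @return the SFI, a single non-negative number.
#' @export
#' @examples
#' y <- c(0.3, 0.1, -0.2, -0.3, -0.1, 0.2)
#' compute_sfi(y, y)          # 0: perfect fit
#' compute_sfi(y, rep(mean(y), 6))  # 1: mean-only fit
compute_sfi <- function(y, y_hat) {
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  if (length(y) != length(y_hat)) stop("y and y_hat must have equal length")
  if (length(y) < 2) stop("need at least 2 points")
  if (anyNA(y) || anyNA(y_hat)) stop("missing values in profile or fit")
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) stop("profile has zero variance; SFI is undefined")
  sum((y - y_hat)^2) / tss
}

# frequency bounds for a K-point circle; the circle is read as one notional
# full wave, so "85% to 95% of a full wave" bounds c at that fraction of
# 2*pi/K radians per position. The alternative reading (period between
# 0.85*K and 0.95*K positions) is kept as an explicit convention switch.
sine_c_bounds <- function(K, wave_fraction = c(0.85, 0.95),
                          c_convention = c("fraction_of_circle",
                                           "period_units")) {
  c_convention <- match.arg(c_convention)
  if (length(wave_fraction) != 2 || wave_fraction[1] > wave_fraction[2] ||
      wave_fraction[1] <= 0) {
    stop("wave_fraction must be an increasing positive pair")
  }
  if (c_convention == "fraction_of_circle") {
    wave_fraction * 2 * pi / K
  } else {
    sort(2 * pi / (wave_fraction * K))
  }
}

#' Fit the constrained sinusoid to a correlation profile
#'
#' Minimises the residual sum of squares of `y = a + b * sin(c * x + d)`
#' over the box `a, b` in \[-1, 1\], `c` between 85% and 95% of a full wave
#' across the K positions, and `d` unrestricted in phase. Because the model
#' is linear in `(a, b)`, those two parameters are solved exactly for every
#' candidate `(c, d)`; the outer search runs a damped Gauss-Newton descent
#' from `n_starts` deterministic phase offsets (nested van der Corput grid,
#' so increasing `n_starts` can only improve the fit) with `c` started at
#' the bound midpoint. The fit is deterministic for a given profile and
#' `n_starts`.
#'
#' @param profile a [correlation_profile()] (or numeric vector of
#'   correlations, which is promoted to one).
#' @param n_starts number of phase starts (default 16).
#' @param wave_fraction lower and upper bound on the fraction of a full wave
#'   the sinusoid may span across the circle; default `c(0.85, 0.95)`.
#' @param c_convention how the wave fraction maps to the angular frequency
#'   bound: `"fraction_of_circle"` (default) bounds `c` in
#'   `wave_fraction * 2 * pi / K`; `"period_units"` instead bounds the period
#'   in `wave_fraction * K` positions.
#' @param max_iter,tol Gauss-Newton iteration cap and SSR improvement
#'   tolerance per accepted step.
#' @return object of class `sine_fit`: list with `params` (a, b, c, d),
#'   `fitted`, `residuals`, `ssr`, `sfi`, `profile`, `n_starts`,
#'   `n_converged`, `converged`.
#' @export
#' @examples
#' true <- list(a = 0, b = 0.3, c = 0.9 * 2 * pi / 10, d = 1)
#' prof <- correlation_profile(sine_model(1:10, true))
#' fit <- fit_sine(prof)
#' fit$sfi   # ~0: noiseless sinusoid is recovered
fit_sine <- function(profile, n_starts = 16, wave_fraction = c(0.85, 0.95),
                     c_convention = c("fraction_of_circle", "period_units"),
                     max_iter = 200, tol = 1e-10) {
  if (!inherits(profile, "correlation_profile")) {
    profile <- correlation_profile(profile)
  }
  c_convention <- match.arg(c_convention)
  y <- profile$r
  K <- length(y)
  if (var(y) == 0) stop("profile has zero variance; SFI is undefined")
  cb <- sine_c_bounds(K, wave_fraction, c_convention)
  res <- sine_fit_batch_cpp(matrix(y, nrow = 1), cb[1], cb[2],
                            as.integer(n_starts), as.integer(max_iter), tol)
  params <- list(a = unname(res[1, "a"]), b = unname(res[1, "b"]),
                 c = unname(res[1, "c"]), d = unname(res[1, "d"]))
  fitted <- sine_model(profile$position, params)
  out <- list(
    params = params,
    fitted = fitted,
    residuals = y - fitted,
    ssr = unname(res[1, "ssr"]),
    sfi = unname(res[1, "sfi"]),
    profile = profile,
    c_bounds = cb,
    n_starts = as.integer(n_starts),
    n_converged = as.integer(res[1, "n_converged"]),
    converged = res[1, "n_converged"] > 0
  )
  if (!out$converged) {
    stop("no optimisation start converged (", n_starts, " starts); ",
         "profile variance = ", signif(var(y), 4))
  }
  class(out) <- "sine_fit"
  out
}

#' @export
print.sine_fit <- function(x, ...) {
  cat("Constrained sinusoid fit (K =", nrow(x$profile), "points)\n")
  cat(sprintf("  y = %.4f + %.4f * sin(%.4f * x + %.4f)\n",
              x$params$a, x$params$b, x$params$c, x$params$d))
  cat(sprintf("  SSR = %.6g   SFI = %.4f   (%d/%d starts converged)\n",
              x$ssr, x$sfi, x$n_converged, x$n_starts))
  invisible(x)
}

#' Correlate value-type scores with an external variable
#'
#' Computes the Pearson correlation between each value type's scores and an
#' external per-participant variable, arranged in circular order, yielding
#' the profile that the sinusoid is fitted to.
#'
#' @param value_scores a `value_type_scores` object (see
#'   [aggregate_value_types()]) or a numeric matrix/data.frame of
#'   participants x value types with column names.
#' @param external numeric vector, one value per participant (row).
#' @param order character vector giving the circular order of the value
#'   types; defaults to [schwartz_value_order()].
#' @return a [correlation_profile()].
#' @export
correlate_profile <- function(value_scores, external,
                              order = schwartz_value_order()) {
  scores <- if (inherits(value_scores, "value_type_scores")) {
    value_scores$scores
  } else {
    as.matrix(value_scores)
  }
  if (nrow(scores) != length(external)) {
    stop("external variable length (", length(external),
         ") does not match the number of participants (", nrow(scores), ")")
  }
  missing_types <- setdiff(order, colnames(scores))
  if (length(missing_types) > 0) {
    stop("value types absent from scores: ",
         paste(missing_types, collapse = ", "))
  }
  r <- vapply(order, function(type) {
    v <- scores[, type]
    ok <- complete.cases(v, external)
    if (sum(ok) < 3) {
      stop("fewer than 3 complete pairs for value type '", type, "'")
    }
    if (sd(v[ok]) == 0) {
      stop("value type '", type, "' is constant; correlation undefined")
    }
    if (sd(external[ok]) == 0) {
      stop("external variable is constant; correlation undefined")
    }
    cor(v[ok], external[ok])
  }, numeric(1))
  correlation_profile(unname(r), labels = order)
}

#' Read a correlation profile from a delimited file
#'
#' Expects a header and columns `label`, `position`, `r`; rows are sorted by
#' position and re-indexed 1..K.
#'
#' @param path file path (TSV by default).
#' @param sep field separator.
#' @return a [correlation_profile()].
#' @export
read_correlation_profile <- function(path, sep = "\t") {
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("label", "position", "r")
  if (!all(need %in% names(tab))) {
    stop("profile file must have columns: ", paste(need, collapse = ", "))
  }
  tab <- tab[order(tab$position), ]
  correlation_profile(tab$r, labels = tab$label)
}

#' Write a fit report
#'
#' Writes the fitted parameters, SSR and SFI as JSON and the per-position
#' fitted values as TSV.
#'
#' @param fit a `sine_fit` object.
#' @param json_path,tsv_path output paths; either may be `NULL` to skip.
#' @return invisibly, the report list.
#' @export
write_sine_fit <- function(fit, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(fit, "sine_fit"))
  report <- list(params = fit$params, ssr = fit$ssr, sfi = fit$sfi,
                 n_starts = fit$n_starts, n_converged = fit$n_converged,
                 converged = fit$converged)
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_path)) {
    tab <- data.frame(label = fit$profile$label,
                      position = fit$profile$position,
                      r = fit$profile$r, fitted = fit$fitted,
                      residual = fit$residuals)
    write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}
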