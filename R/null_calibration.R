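#' Specify a null distribution for correlation profiles
#'
#' Random correlation profiles emulate a variable with no systematic
#' relationship to the value circle: K independent draws either uniform on
#' `(lo, hi)` (default -0.5..0.5, the interval where correlations of values
#' with external variables usually fall) or normal with mean `mean` and
#' standard deviation `sd`, with draws beyond +-1 clamped to -1 or 1.
#'
#' @param distribution `"uniform"` or `"normal"`.
#' @param lo,hi support of the uniform null.
#' @param mean,sd parameters of the normal null (before clamping).
#' @param k profile length (number of value types, default 10).
#' @param n_samples Monte-Carlo sample count (default 100000).
#' @param seed integer seed for the profile stream.
#' @return a `null_spec` list.
#' @export
null_spec <- function(distribution = c("uniform", "normal"), lo = -0.5,
                      hi = 0.5, mean = 0, sd = 0.1, k = 10,
                      n_samples = 100000, seed = 1) {
  distribution <- match.arg(distribution)
  if (k < 4) stop("profile length k must be at least 4")
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (distribution == "uniform" && lo >= hi) stop("need lo < hi")
  if (distribution == "normal" && sd <= 0) stop("need sd > 0")
  out <- list(distribution = distribution, lo = lo, hi = hi, mean = mean,
              sd = sd, k = as.integer(k), n_samples = as.integer(n_samples),
              seed = as.integer(seed))
  class(out) <- "null_spec"
  out
}

#' Sample null correlation profiles
#'
#' Draws `n` profiles row-by-row from the spec's distribution. The stream
#' is sequential in profile order, so the first half of a run with `2n`
#' samples is identical to a run with `n` samples under the same seed.
#'
#' @param spec a [null_spec()].
#' @param n number of profiles (defaults to `spec$n_samples`).
#' @return numeric matrix, `n` x `spec$k`; values clamped to \[-1, 1\].
#' @export
sample_null_profiles <- function(spec, n = spec$n_samples) {
  stopifnot(inherits(spec, "null_spec"))
  set.seed(spec$seed)
  draws <- if (spec$distribution == "uniform") {
    runif(n * spec$k, spec$lo, spec$hi)
  } else {
    rnorm(n * spec$k, spec$mean, spec$sd)
  }
  draws <- pmin(pmax(draws, -1), 1)
  matrix(draws, nrow = n, ncol = spec$k, byrow = TRUE)
}

#' Sample one null profile
#'
#' @param spec a [null_spec()].
#' @return a [correlation_profile()] with `spec$k` points.
#' @export
sample_null_profile <- function(spec) {
  correlation_profile(as.numeric(sample_null_profiles(spec, n = 1)))
}

#' Monte-Carlo calibration of SFI false-positive rates
#'
#' Fits the constrained sinusoid to each of `spec$n_samples` random
#' profiles and reports, for each threshold `t`, the false-positive rate
#' `#{SFI < t} / n` (strict inequality) with its binomial Monte-Carlo
#' standard error. Raw SFI samples are retained so exact empirical
#' p-values can be evaluated afterwards.
#'
#' @param spec a [null_spec()].
#' @param thresholds SFI thresholds, ascending (default
#'   `c(0.05, 0.10, 0.15, 0.20)`).
#' @param n_starts passed to the sinusoid fit (default 16).
#' @param keep_samples retain the raw SFI draws (default `TRUE`).
#' @param ... further arguments to the fitter (`wave_fraction`,
#'   `c_convention`).
#' @return an `sfi_calibration` object: list with `spec`, `thresholds`,
#'   `rates` (data.frame threshold / fp_rate / mc_se / n), and
#'   `sfi_samples` (or `NULL`).
#' @export
#' @examples
#' calib <- calibrate_sfi(null_spec(n_samples = 200, seed = 7))
#' calib$rates
calibrate_sfi <- function(spec, thresholds = c(0.05, 0.10, 0.15, 0.20),
                          n_starts = 16, keep_samples = TRUE, ...) {
  stopifnot(inherits(spec, "null_spec"))
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly ascending")
  }
  profiles <- sample_null_profiles(spec)
  sfi <- fit_sine_batch(profiles, n_starts = n_starts, ...)[, "sfi"]
  n <- length(sfi)
  fp <- vapply(thresholds, function(t) mean(sfi < t), numeric(1))
  rates <- data.frame(threshold = thresholds, fp_rate = fp,
                      mc_se = sqrt(fp * (1 - fp) / n), n = n)
  out <- list(spec = spec, thresholds = thresholds, rates = rates,
              sfi_samples = if (keep_samples) sfi else NULL)
  class(out) <- "sfi_calibration"
  out
}

#' Batch sinusoid fits over profile rows
#'
#' Lower-level interface used by [calibrate_sfi()]: fits every row of a
#' profile matrix with the same deterministic start grid as [fit_sine()]
#' and returns the parameter/fit summary per row. Looping [fit_sine()]
#' over the rows gives identical results.
#'
#' @param profiles numeric matrix, one K-point profile per row.
#' @inheritParams fit_sine
#' @return matrix with columns `a`, `b`, `c`, `d`, `ssr`, `sfi`,
#'   `n_converged`.
#' @export
fit_sine_batch <- function(profiles, n_starts = 16,
                           wave_fraction = c(0.85, 0.95),
                           c_convention = c("fraction_of_circle",
                                            "period_units"),
                           max_iter = 200, tol = 1e-10) {
  profiles <- as.matrix(profiles)
  c_convention <- match.arg(c_convention)
  cb <- sine_c_bounds(ncol(profiles), wave_fraction, c_convention)
  sine_fit_batch_cpp(profiles, cb[1], cb[2], as.integer(n_starts),
                     as.integer(max_iter), tol)
}

#' @export
print.sfi_calibration <- function(x, ...) {
  cat("SFI null calibration:", x$spec$distribution, "null, K =", x$spec$k,
      ", n =", x$spec$n_samples, ", seed =", x$spec$seed, "\n")
  tab <- x$rates
  tab$fp_pct <- sprintf("%.3f%%", 100 * tab$fp_rate)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Empirical p-value of an observed SFI
#'
#' The left-tail mass of the calibrated null at the observed statistic:
#' smaller SFI means a better sinusoidal fit, so the false-positive rate of
#' an observed fit is the fraction of null profiles that fit at least as
#' well.
#'
#' @param observed_sfi the observed SFI.
#' @param calibration an [calibrate_sfi()] result with raw samples
#'   retained.
#' @return list with `p` (the empirical rate), `mc_se`, and `n`.
#' @export
empirical_pvalue <- function(observed_sfi, calibration) {
  stopifnot(inherits(calibration, "sfi_calibration"))
  if (is.null(calibration$sfi_samples)) {
    stop("calibration was run with keep_samples = FALSE; re-run retaining ",
         "raw SFI samples to evaluate empirical p-values")
  }
  s <- calibration$sfi_samples
  p <- mean(s < observed_sfi)
  list(p = p, mc_se = sqrt(p * (1 - p) / length(s)), n = length(s))
}

#' Write a calibration table to TSV
#'
#' @param calibration an `sfi_calibration` object.
#' @param path output path for the rate table.
#' @param samples_path optional path for the raw SFI samples (one per
#'   line).
#' @return invisibly, the rate table.
#' @export
write_calibration <- function(calibration, path, samples_path = NULL) {
  stopifnot(inherits(calibration, "sfi_calibration"))
  write.table(calibration$rates, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(samples_path)) {
    if (is.null(calibration$sfi_samples)) {
      stop("no raw samples retained to write")
    }
    writeLines(format(calibration$sfi_samples, digits = 17), samples_path)
  }
  invisible(calibration$rates)
}
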