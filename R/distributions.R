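#' Sentinel for the "no MWH stay" scenario
#'
#' The move-date variable d is measured in days relative to the expected due
#' date (EDD); not moving to a maternity waiting home at all corresponds to
#' d = +Inf, for which the onset CDF F is defined to equal exactly 1.
#'
#' @return `Inf`.
#' @export
no_mwh <- function() Inf

parity_levels <- c("nulliparous", "multiparous")

match_parity <- function(parity) {
  match.arg(tolower(as.character(parity)), parity_levels)
}

new_sba_dist <- function(mix, kind, parity = NULL, source = "unspecified",
                         n_samples = NA_integer_, bandwidth = NULL) {
  kind <- match.arg(kind, c("onset", "latent"))
  if (kind == "latent") {
    if (is.null(parity)) stop("latent-phase distributions need a `parity`")
    parity <- match_parity(parity)
    if (mix$support[1] < 0)
      stop("latent-phase support must be non-negative (durations in hours)")
  } else {
    parity <- NULL
  }
  structure(
    list(mix = mix, kind = kind, parity = parity, source = source,
         n_samples = n_samples, bandwidth = bandwidth),
    class = "sba_dist"
  )
}

#' Gaussian kernel density estimate of an input distribution
#'
#' Estimates the labour-onset offset distribution F (days relative to EDD)
#' or a parity-specific latent-phase duration distribution Gk (hours) from
#' an empirical sample, as an equal-weight sum of Gaussian kernels centred
#' at the sample points, truncated to the stated value range and
#' renormalised so the CDF runs from 0 to 1 across the range.
#'
#' The bandwidth parameter is, by default, the kernel SD itself in days or
#' hours (`bandwidth_type = "absolute"`; the default 0.3 gives a light
#' smoothing whose bias stays well below the sampling error of the source
#' cohorts, which keeps bootstrap confidence intervals near nominal
#' coverage).  Pass `bandwidth_type = "relative"` to use `bandwidth` as a
#' multiplicative factor on the sample standard deviation instead, as many
#' KDE interfaces parameterise their smoothing.
#'
#' @param samples Numeric vector of at least 2 observations, all inside
#'   `support`, with non-zero variance.
#' @param kind `"onset"` (days, ADD - EDD) or `"latent"` (hours).
#' @param parity For `kind = "latent"`, `"nulliparous"` or `"multiparous"`.
#' @param bandwidth Positive smoothing parameter (default 0.3).
#' @param support Value range `c(lo, hi)`; defaults to `c(-30, 30)` days for
#'   onset, `c(0, 30)` h for nulliparous and `c(0, 16)` h for multiparous
#'   latent phases.
#' @param bandwidth_type `"relative"` (factor on the sample SD) or
#'   `"absolute"`.
#' @return An `sba_dist` object.
#' @examples
#' set.seed(1)
#' f <- kde_estimate(rnorm(200, -1.5, 9), kind = "onset")
#' cdf(f, 0)
#' @export
kde_estimate <- function(samples, kind = c("onset", "latent"), parity = NULL,
                         bandwidth = 0.3, support = NULL,
                         bandwidth_type = c("absolute", "relative")) {
  kind <- match.arg(kind)
  bandwidth_type <- match.arg(bandwidth_type)
  samples <- as.numeric(samples)
  if (length(samples) < 2L || anyNA(samples))
    stop("need at least 2 non-missing samples for a KDE")
  if (!is.finite(bandwidth) || bandwidth <= 0)
    stop("`bandwidth` must be a positive number")
  if (is.null(support)) {
    support <- if (kind == "onset") c(-30, 30)
    else if (match_parity(parity) == "nulliparous") c(0, 30) else c(0, 16)
  }
  if (any(samples < support[1] | samples > support[2]))
    stop("all samples must lie within the support interval [",
         support[1], ", ", support[2], "]")
  s <- sd(samples)
  if (s == 0) stop("samples have zero variance; a KDE needs spread")
  h <- if (bandwidth_type == "relative") bandwidth * s else bandwidth
  n <- length(samples)
  mix <- tnmix(rep(1 / n, n), samples, rep(h, n), support)
  d <- new_sba_dist(mix, kind, parity, source = "kde", n_samples = n,
                    bandwidth = c(value = h, parameter = bandwidth))
  d$kde_samples <- samples  # retained so bootstrap CIs can resample
  d
}

#' Wrap a calibrated mixture as an input distribution
#'
#' @param mix A [tnmix()] surrogate.
#' @param kind,parity As in [kde_estimate()].
#' @param source Label recorded on the object (e.g. a preset name).
#' @return An `sba_dist` object.
#' @export
surrogate_dist <- function(mix, kind = c("onset", "latent"), parity = NULL,
                           source = "surrogate") {
  kind <- match.arg(kind)
  new_sba_dist(mix, kind, parity, source = source)
}

#' Cumulative distribution function of a model input distribution
#'
#' Total on the reals plus the no-MWH sentinel: values below the support
#' give 0, above give 1, and `Inf` (see [no_mwh()]) gives exactly 1.
#'
#' @param dist An `sba_dist` object.
#' @param x Numeric vector of evaluation points (days for onset, hours for
#'   latent).
#' @return Probabilities in `[0, 1]`.
#' @export
cdf <- function(dist, x) UseMethod("cdf")

#' @export
cdf.sba_dist <- function(dist, x) ptnmix(x, dist$mix)

#' @export
#' @method quantile sba_dist
#' @rdname cdf
#' @param probs Probabilities strictly inside (0, 1).
#' @param ... Unused.
quantile.sba_dist <- function(x, probs, ...) {
  if (any(probs <= 0 | probs >= 1))
    stop("`probs` must lie strictly inside (0, 1)")
  qtnmix(probs, x$mix)
}

#' @export
print.sba_dist <- function(x, ...) {
  unit <- if (x$kind == "onset") "days relative to EDD" else "hours"
  lab <- if (x$kind == "onset") "Labour-onset offset distribution F"
  else sprintf("Latent-phase duration distribution G (%s)", x$parity)
  cat(lab, "\n", sep = "")
  cat(sprintf("  source: %s; support [%g, %g] %s\n", x$source,
              x$mix$support[1], x$mix$support[2], unit))
  if (identical(x$source, "kde"))
    cat(sprintf("  KDE over %d samples, kernel sd %.4g\n",
                x$n_samples, x$bandwidth[["value"]]))
  mo <- tnmix_moments(x$mix)
  cat(sprintf("  mean %.3f, sd %.3f, median %.3f\n",
              mo$mean, mo$sd, qtnmix(0.5, x$mix)))
  invisible(x)
}

#' Read an empirical sample file
#'
#' Plain-CSV dialect used throughout: UTF-8, "." decimal separator, one
#' numeric column headed `value`, and (for latent-phase files) an optional
#' `parity` column holding `nulliparous`/`multiparous` labels.
#'
#' @param path CSV file path.
#' @return A data frame with columns `value` and, when present, `parity`.
#' @export
read_samples_csv <- function(path) {
  if (!file.exists(path)) stop("sample file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"value" %in% names(df))
    stop("sample file must have a `value` column: ", path)
  if (!is.numeric(df$value))
    stop("`value` column must be numeric: ", path)
  if ("parity" %in% names(df)) {
    df$parity <- vapply(df$parity, match_parity, character(1), USE.NAMES = FALSE)
    df[c("value", "parity")]
  } else {
    df["value"]
  }
}

#' Write an empirical sample file
#'
#' Inverse of [read_samples_csv()]; used by the cohort simulator and the
#' command-line `simulate` subcommand.
#'
#' @param values Numeric vector.
#' @param path Output CSV path.
#' @param parity Optional parity label recycled along `values`.
#' @return `path`, invisibly.
#' @export
write_samples_csv <- function(values, path, parity = NULL) {
  df <- data.frame(value = format(as.numeric(values), digits = 17,
                                  trim = TRUE, scientific = FALSE))
  if (!is.null(parity)) df$parity <- rep_len(match_parity(parity), nrow(df))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
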