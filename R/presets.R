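# Session cache: calibrating a preset costs a few seconds of optimisation,
# so each calibrated mixture is kept for the life of the R session.
.preset_cache <- new.env(parent = emptyenv())

#' Cohort presets
#'
#' The model's input distributions come from published cohorts whose raw
#' data are not deposited; only summary statistics are printed.  Each preset
#' names such a cohort and carries a truncated-normal-mixture surrogate
#' calibrated to its printed statistics:
#'
#' * `khambalia` — labour-onset offset ADD−EDD, mean −1.48 d, SD 9.21 d,
#'   66% of deliveries within ±7 d of the EDD (cohort of 10,243 women).
#' * `mongelli` — onset offset, mean −1.79 d, SD 11.3 d (34,249 pregnancies).
#' * `friedman_nulliparous` — latent-phase duration, mean 7.1 h, SD 4.0 h,
#'   95th percentile 20 h (500 observations).
#' * `friedman_multiparous` — latent-phase duration, mean 5.3 h, SD 4.1 h,
#'   95th percentile 14 h (500 observations).
#'
#' `sba_preset()` returns the calibrated preset (mixture included),
#' calibrating on first use and caching for the session; the calibration is
#' re-verified against its spec at load.  `preset_names()` lists the
#' registry.
#'
#' @param name Preset name.
#' @param registry Optional path to a YAML registry file; defaults to the
#'   registry shipped with the package.
#' @return `sba_preset()`: a `cohort_preset` object with fields `name`,
#'   `kind`, `parity`, `mixture`, `default_n` and `spec`.
#' @examples
#' \donttest{
#' p <- sba_preset("mongelli")
#' tnmix_moments(p$mixture)
#' }
#' @export
sba_preset <- function(name, registry = NULL) {
  key <- paste0(name, "@", if (is.null(registry)) "builtin" else registry)
  if (!is.null(.preset_cache[[key]])) return(.preset_cache[[key]])
  reg <- load_preset_registry(registry)
  if (!name %in% names(reg))
    stop("unknown preset `", name, "`; available: ",
         paste(names(reg), collapse = ", "))
  entry <- reg[[name]]
  spec <- calibration_spec(
    target_mean = entry$target_mean,
    target_sd = entry$target_sd,
    support = unlist(entry$support),
    n_components = as.integer(entry$n_components),
    interval = if (!is.null(entry$interval)) unlist(entry$interval),
    interval_mass = entry$interval_mass,
    quantile_prob = entry$quantile_prob,
    quantile_value = entry$quantile_value
  )
  mix <- calibrate_mixture(spec)  # errors if constraints not met to 1e-3
  preset <- structure(
    list(name = name, kind = entry$kind,
         parity = entry$parity, mixture = mix,
         default_n = as.integer(entry$default_n), spec = spec),
    class = "cohort_preset"
  )
  .preset_cache[[key]] <- preset
  preset
}

#' @rdname sba_preset
#' @export
preset_names <- function(registry = NULL) names(load_preset_registry(registry))

load_preset_registry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "presets.yaml", package = "sbarisk",
                        mustWork = TRUE)
  yaml::read_yaml(path)
}

#' @export
print.cohort_preset <- function(x, ...) {
  cat(sprintf("Cohort preset `%s` (%s%s), default n = %d\n", x$name, x$kind,
              if (!is.null(x$parity)) paste0(", ", x$parity) else "",
              x$default_n))
  cat(sprintf("  calibrated to mean %g, sd %g", x$spec$target_mean,
              x$spec$target_sd))
  if (!is.null(x$spec$interval))
    cat(sprintf(", mass %g on [%g, %g]", x$spec$interval_mass,
                x$spec$interval[1], x$spec$interval[2]))
  if (!is.null(x$spec$quantile_prob))
    cat(sprintf(", p%g quantile %g", 100 * x$spec$quantile_prob,
                x$spec$quantile_value))
  cat(sprintf("; support [%g, %g]\n", x$spec$support[1], x$spec$support[2]))
  invisible(x)
}

#' Input distribution from a preset
#'
#' Wraps a preset's calibrated surrogate mixture as an `sba_dist` usable
#' wherever a KDE-estimated distribution is.
#'
#' @inheritParams sba_preset
#' @return An `sba_dist` object.
#' @export
preset_dist <- function(name, registry = NULL) {
  p <- sba_preset(name, registry)
  surrogate_dist(p$mixture, kind = p$kind, parity = p$parity, source = p$name)
}
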