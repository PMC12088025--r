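#' Bootstrap configuration
#'
#' Controls the resampling procedure behind the confidence intervals: the
#' cap on iterations, the convergence monitor (the bootstrap stops early
#' once the running SDs of all recomputed P(SBA) values have stabilised),
#' the seed, and the CI level.
#'
#' @param max_iterations Maximum bootstrap replicates (default 2000, which
#'   stabilises the 2.5/97.5 percentiles to about ±0.01).
#' @param convergence_window Iterations between convergence checks and the
#'   span over which the running-SD change is measured (default 100).
#' @param convergence_tol Absolute running-SD change below which a cell
#'   counts as stable (default 1e-3).
#' @param seed Integer seed; identical seed and inputs give identical CIs.
#' @param alpha CI level: the interval spans the `alpha/2` and
#'   `1 - alpha/2` percentiles (default 0.05 for 95% CIs).
#' @return A `bootstrap_config` object.
#' @export
bootstrap_config <- function(max_iterations = 2000L,
                             convergence_window = 100L,
                             convergence_tol = 1e-3,
                             seed = 1L, alpha = 0.05) {
  stopifnot(max_iterations >= 1, convergence_window >= 1,
            convergence_window < max_iterations,
            convergence_tol > 0, alpha > 0, alpha < 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 convergence_window = as.integer(convergence_window),
                 convergence_tol = convergence_tol,
                 seed = as.integer(seed), alpha = alpha),
            class = "bootstrap_config")
}

#' Running-SD convergence monitor
#'
#' The bootstrap tracks, for every table cell, the running sample SD of the
#' recomputed P(SBA) values.  Convergence is declared once, for every cell,
#' the running SD has changed by less than `tol` over the last `window`
#' iterations (measured as the range of the running-SD sequence across that
#' window, so both drift and oscillation count against convergence).
#'
#' @param history Numeric matrix (iterations x cells) or vector of
#'   per-iteration estimates.
#' @param window Number of trailing iterations over which stability is
#'   required.
#' @param tol Maximum allowed running-SD change.
#' @return `TRUE` or `FALSE`.
#' @export
running_sd_converged <- function(history, window, tol) {
  if (is.vector(history)) history <- matrix(history, ncol = 1)
  n <- nrow(history)
  if (n < window) stop("history (", n, ") is shorter than the window (",
                       window, ")")
  if (n < 3L) stop("need at least 3 iterations to track a running SD")
  # running SD after i iterations, per cell, via cumulative sums
  cs <- apply(history, 2, cumsum)
  cs2 <- apply(history^2, 2, cumsum)
  i <- seq_len(n)
  rsd <- sqrt(pmax(sweep(cs2 - cs^2 / i, 1, i - 1, "/"), 0))
  rsd <- rsd[-1, , drop = FALSE]  # SD undefined at i = 1
  tail_rows <- max(1L, nrow(rsd) - window + 1L):nrow(rsd)
  change <- apply(rsd[tail_rows, , drop = FALSE], 2,
                  function(col) diff(range(col)))
  all(change < tol)
}

# Fast KDE CDF used inside the bootstrap loop: same estimator as
# kde_estimate() (bandwidth convention, truncation, renormalisation)
# without object-construction overhead.
kde_cdf_fast <- function(samples, bandwidth, support, at,
                         bandwidth_type = "absolute") {
  h <- if (bandwidth_type == "absolute") bandwidth
  else bandwidth * sd(samples)
  if (h == 0) h <- .Machine$double.eps  # degenerate resample: step CDF
  plo <- mean(pnorm(support[1], samples, h))
  phi <- mean(pnorm(support[2], samples, h))
  z <- phi - plo
  vapply(at, function(x) {
    if (x >= support[2]) 1
    else if (x <= support[1]) 0
    else min(1, max(0, (mean(pnorm(x, samples, h)) - plo) / z))
  }, numeric(1))
}

#' Bootstrap percentile confidence intervals for P(SBA)
#'
#' Repeatedly resamples the onset and latent-phase datasets with
#' replacement (independently, at their original sizes), re-estimates F and
#' Gk with the same Gaussian KDE settings as the point estimate, and
#' recomputes P(SBA) for every scenario.  The CI for each cell is the
#' percentile interval of the replicates; the loop stops early once the
#' running SDs of all cells have stabilised (see
#' [running_sd_converged()]), and otherwise at `max_iterations` with
#' `converged = FALSE` (reported, not an error).
#'
#' @param onset_samples Numeric vector of onset offsets (days).
#' @param latent_samples Named list of latent-duration vectors (hours),
#'   keyed by parity, covering every parity present in `scenarios`.
#' @param scenarios Data frame with columns `parity`, `access_time` and
#'   `move_date` (one row per cell; `access_time` should already be the
#'   conservative evaluation point).
#' @param config A [bootstrap_config()].
#' @param bandwidth,bandwidth_type,onset_support,latent_supports KDE
#'   settings, matching the point estimate (defaults: absolute bandwidth
#'   0.3; `c(-30, 30)` days; `c(0, 30)` / `c(0, 16)` hours).
#' @return List with `ci` (data frame `lower`/`upper` per scenario row),
#'   `n_iterations`, `converged`, and the replicate `history` matrix.
#' @export
bootstrap_cis <- function(onset_samples, latent_samples, scenarios, config,
                          bandwidth = 0.3,
                          bandwidth_type = c("absolute", "relative"),
                          onset_support = c(-30, 30),
                          latent_supports = list(nulliparous = c(0, 30),
                                                 multiparous = c(0, 16))) {
  bandwidth_type <- match.arg(bandwidth_type)
  stopifnot(inherits(config, "bootstrap_config"),
            is.numeric(onset_samples), length(onset_samples) >= 1,
            is.list(latent_samples), is.data.frame(scenarios))
  parities <- unique(vapply(scenarios$parity, match_parity, character(1)))
  if (!all(parities %in% names(latent_samples)))
    stop("latent samples missing for: ",
         paste(setdiff(parities, names(latent_samples)), collapse = ", "))
  sc <- validate_scenario(scenarios$parity, scenarios$access_time,
                          scenarios$move_date)
  n_cells <- nrow(scenarios)
  # unique evaluation points keep each iteration cheap
  d_pts <- sort(unique(sc$move_date[is.finite(sc$move_date)]))
  t_pts <- lapply(setNames(parities, parities), function(k)
    sort(unique(sc$access_time[sc$parity == k])))
  d_idx <- match(sc$move_date, d_pts)  # NA for no-MWH rows (F = 1)
  history <- matrix(NA_real_, nrow = config$max_iterations, ncol = n_cells)
  used <- 0L
  converged <- FALSE
  with_seed(config$seed, {
    for (b in seq_len(config$max_iterations)) {
      ob <- sample(onset_samples, replace = TRUE)
      f_at <- if (length(d_pts))
        kde_cdf_fast(ob, bandwidth, onset_support, d_pts, bandwidth_type)
      else numeric(0)
      f_cell <- ifelse(is.na(d_idx), 1, f_at[d_idx])
      g_cell <- numeric(n_cells)
      for (k in parities) {
        lb <- sample(latent_samples[[k]], replace = TRUE)
        g_at <- kde_cdf_fast(lb, bandwidth, latent_supports[[k]], t_pts[[k]],
                             bandwidth_type)
        rows <- sc$parity == k
        g_cell[rows] <- g_at[match(sc$access_time[rows], t_pts[[k]])]
      }
      history[b, ] <- 1 - g_cell * f_cell
      used <- b
      if (b %% config$convergence_window == 0L &&
          b >= 2L * config$convergence_window) {
        if (running_sd_converged(history[seq_len(b), , drop = FALSE],
                                 config$convergence_window,
                                 config$convergence_tol)) {
          converged <- TRUE
          break
        }
      }
    }
  })
  reps <- history[seq_len(used), , drop = FALSE]
  probs <- c(config$alpha / 2, 1 - config$alpha / 2)
  qs <- apply(reps, 2, quantile, probs = probs, type = 7, names = FALSE)
  list(ci = data.frame(lower = pmax(0, qs[1, ]), upper = pmin(1, qs[2, ])),
       n_iterations = used, converged = converged, history = reps)
}
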