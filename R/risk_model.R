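#' Fit the skilled-birth-attendance risk model
#'
#' Assembles the two model inputs — the labour-onset offset distribution F
#' (days relative to the EDD) and the parity-specific latent-phase duration
#' distributions Gk (hours) — into a fitted model object for the risk
#' equation
#' \deqn{P(SBA) = 1 - G_k(t)\,F(d),}
#' where t is the woman's time to access a skilled birth attendant from the
#' first signs of labour and d the day (relative to EDD) she plans to move
#' to a maternity waiting home; d = +Inf encodes no MWH stay, for which
#' F(d) = 1 and the equation reduces to \eqn{1 - G_k(t)}.
#'
#' Each input may be given as a preset name (calibrated surrogate, see
#' [sba_preset()]), a numeric sample vector (estimated by Gaussian KDE with
#' the given bandwidth, see [kde_estimate()]), or a ready-made `sba_dist`.
#'
#' @param onset Onset-offset input: preset name, numeric samples (days), or
#'   `sba_dist` of kind `"onset"`.
#' @param latent_nulliparous,latent_multiparous Latent-phase inputs per
#'   parity: preset name, numeric samples (hours), or `sba_dist` of kind
#'   `"latent"`.
#' @param bandwidth KDE bandwidth factor for sample inputs (default 0.3).
#' @param bandwidth_type Passed to [kde_estimate()].
#' @return An object of class `sba_model` with elements `F` (onset
#'   `sba_dist`) and `G` (named list of latent `sba_dist` per parity).
#' @examples
#' \donttest{
#' m <- sba_model()
#' predict(m, data.frame(parity = "multiparous",
#'                       access_time = 10.25, move_date = -14))
#' }
#' @export
sba_model <- function(onset = "khambalia",
                      latent_nulliparous = "friedman_nulliparous",
                      latent_multiparous = "friedman_multiparous",
                      bandwidth = 0.3,
                      bandwidth_type = c("absolute", "relative")) {
  bandwidth_type <- match.arg(bandwidth_type)
  resolve <- function(x, kind, parity = NULL) {
    if (inherits(x, "sba_dist")) {
      if (x$kind != kind)
        stop("expected a ", kind, " distribution")
      if (kind == "latent" && !identical(x$parity, parity))
        stop("parity mismatch: distribution is ", x$parity,
             " but was supplied as ", parity)
      x
    } else if (is.character(x) && length(x) == 1L) {
      d <- preset_dist(x)
      if (d$kind != kind)
        stop("preset `", x, "` is a ", d$kind, " preset, not ", kind)
      if (kind == "latent" && !identical(d$parity, parity))
        stop("preset `", x, "` is for ", d$parity, " women, not ", parity)
      d
    } else if (is.numeric(x)) {
      kde_estimate(x, kind = kind, parity = parity, bandwidth = bandwidth,
                   bandwidth_type = bandwidth_type)
    } else stop("cannot interpret a ", class(x)[1], " as a ", kind, " input")
  }
  structure(
    list(F = resolve(onset, "onset"),
         G = list(nulliparous = resolve(latent_nulliparous, "latent", "nulliparous"),
                  multiparous = resolve(latent_multiparous, "latent", "multiparous")),
         bandwidth = bandwidth, bandwidth_type = bandwidth_type,
         call = match.call()),
    class = "sba_model"
  )
}

validate_scenario <- function(parity, access_time, move_date,
                              max_move_date = 0) {
  parity <- vapply(parity, match_parity, character(1), USE.NAMES = FALSE)
  if (any(!is.finite(access_time) | access_time < 0))
    stop("`access_time` must be a non-negative number of hours")
  bad <- is.finite(move_date) & move_date > max_move_date
  if (any(bad))
    stop("`move_date` must be at most ", max_move_date,
         " days relative to EDD, or Inf (no MWH stay)")
  list(parity = parity, access_time = access_time, move_date = move_date)
}

#' Probability of skilled birth attendance for one scenario
#'
#' Evaluates \eqn{P(SBA) = 1 - G_k(t) F(d)} for a single woman's scenario.
#' With `move_date = Inf` (no MWH stay) the onset term is exactly 1 and the
#' result is \eqn{1 - G_k(t)}.
#'
#' @param model A fitted [sba_model()].
#' @param parity `"nulliparous"` or `"multiparous"`.
#' @param access_time Time t to access an SBA, in hours (>= 0).
#' @param move_date Planned MWH move day d relative to EDD (<= 0), or `Inf`
#'   for no MWH stay (see [no_mwh()]).
#' @return A `risk_estimate` list: `p_sba`, `gk_of_t`, `f_of_d`,
#'   `category`.
#' @examples
#' \donttest{
#' p_sba(sba_model(), "multiparous", access_time = 10.25, move_date = -14)
#' }
#' @export
p_sba <- function(model, parity, access_time, move_date = no_mwh()) {
  stopifnot(inherits(model, "sba_model"), length(parity) == 1L,
            length(access_time) == 1L, length(move_date) == 1L)
  sc <- validate_scenario(parity, access_time, move_date)
  g <- cdf(model$G[[sc$parity]], sc$access_time)
  f <- cdf(model$F, sc$move_date)
  p <- 1 - g * f
  structure(
    list(p_sba = p, gk_of_t = g, f_of_d = f, category = risk_category(p),
         parity = sc$parity, access_time = sc$access_time,
         move_date = sc$move_date),
    class = "risk_estimate"
  )
}

#' @export
print.risk_estimate <- function(x, ...) {
  d_lab <- if (is.infinite(x$move_date)) "no MWH stay"
  else sprintf("MWH move on EDD%+g d", x$move_date)
  cat(sprintf("P(SBA) = %.4f (%s)\n", x$p_sba, x$category))
  cat(sprintf("  %s, t = %g h, %s;  Gk(t) = %.4f, F(d) = %.4f\n",
              x$parity, x$access_time, d_lab, x$gk_of_t, x$f_of_d))
  invisible(x)
}

#' Risk colour category for a P(SBA) value
#'
#' The device and tables band probabilities into three colours:
#' salmon for P(SBA) < 0.90, light green for 0.90 <= P(SBA) < 0.95 and
#' dark green for P(SBA) >= 0.95 (half-open bands partitioning `[0, 1]`).
#'
#' @param p Probability vector in `[0, 1]`.
#' @return Factor with levels `salmon`, `light_green`, `dark_green`.
#' @export
risk_category <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("`p` must be a probability in [0, 1]")
  factor(ifelse(p >= 0.95, "dark_green",
                ifelse(p >= 0.90, "light_green", "salmon")),
         levels = c("salmon", "light_green", "dark_green"))
}

#' Recommend an MWH move date against a risk threshold
#'
#' Walks the candidate move dates from least burdensome (no MWH stay) to
#' most (earliest move before EDD) and recommends the first whose P(SBA)
#' meets the threshold — the worked-example rule: a multiparous woman
#' 10 h 15 min from an SBA at threshold 0.90 is advised to move 2 weeks
#' before her EDD.  When no candidate meets the threshold the candidate
#' with maximal P(SBA) is returned flagged `met = FALSE`.
#'
#' @inheritParams p_sba
#' @param threshold Minimum acceptable P(SBA), in (0, 1].
#' @param candidates Move dates to consider; the default is the device's
#'   scenario set `Inf, 0, -7, -14, -21, -28`.  Candidates are evaluated in
#'   order of increasing burden regardless of input order.
#' @return A `move_recommendation` list: `move_date`, `p_sba`, `met`, the
#'   threshold, and the per-candidate evaluation table.
#' @examples
#' \donttest{
#' recommend_move_date(sba_model(), "multiparous", access_time = 10.25,
#'                     threshold = 0.90)
#' }
#' @export
recommend_move_date <- function(model, parity, access_time, threshold = 0.90,
                                candidates = c(no_mwh(), 0, -7, -14, -21, -28)) {
  if (length(candidates) == 0L) stop("`candidates` must be non-empty")
  if (!is.finite(threshold) && threshold != 1 || threshold <= 0 || threshold > 1)
    stop("`threshold` must lie in (0, 1]")
  candidates <- sort(unique(candidates), decreasing = TRUE)  # Inf, 0, -7, ...
  evals <- lapply(candidates, function(d)
    p_sba(model, parity, access_time, d))
  p <- vapply(evals, `[[`, numeric(1), "p_sba")
  tab <- data.frame(move_date = candidates, p_sba = p,
                    category = risk_category(p))
  hit <- which(p >= threshold)
  if (length(hit)) {
    chosen <- hit[1]; met <- TRUE
  } else {
    chosen <- which.max(p); met <- FALSE
  }
  structure(
    list(move_date = candidates[chosen], p_sba = p[chosen], met = met,
         threshold = threshold, parity = evals[[chosen]]$parity,
         access_time = access_time, candidates = tab),
    class = "move_recommendation"
  )
}

#' @export
print.move_recommendation <- function(x, ...) {
  d <- x$move_date
  lab <- if (is.infinite(d)) "no MWH stay needed"
  else if (d == 0) "move to the MWH on the EDD"
  else sprintf("move to the MWH %g week(s) (%g days) before the EDD", -d / 7, -d)
  cat(sprintf("Recommendation (%s, t = %g h, threshold %.2f): %s\n",
              x$parity, x$access_time, x$threshold, lab))
  cat(sprintf("  achieved P(SBA) = %.4f%s\n", x$p_sba,
              if (x$met) "" else "  [threshold NOT met by any candidate]"))
  invisible(x)
}

#' @export
print.sba_model <- function(x, ...) {
  cat("Skilled-birth-attendance risk model: P(SBA) = 1 - Gk(t) F(d)\n\n")
  print(x$F)
  for (k in parity_levels) print(x$G[[k]])
  invisible(x)
}

#' @export
summary.sba_model <- function(object, ...) {
  moF <- tnmix_moments(object$F$mix)
  rows <- list(data.frame(
    distribution = "onset offset F", unit = "days", source = object$F$source,
    mean = moF$mean, sd = moF$sd, median = qtnmix(0.5, object$F$mix),
    p95 = qtnmix(0.95, object$F$mix)))
  for (k in parity_levels) {
    g <- object$G[[k]]
    mo <- tnmix_moments(g$mix)
    rows <- c(rows, list(data.frame(
      distribution = paste("latent phase G,", k), unit = "hours",
      source = g$source, mean = mo$mean, sd = mo$sd,
      median = qtnmix(0.5, g$mix), p95 = qtnmix(0.95, g$mix))))
  }
  out <- do.call(rbind, rows)
  structure(list(inputs = out), class = "summary.sba_model")
}

#' @export
print.summary.sba_model <- function(x, ...) {
  cat("Model inputs:\n")
  df <- x$inputs
  df[sapply(df, is.numeric)] <- lapply(df[sapply(df, is.numeric)], round, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Predict P(SBA) for a set of scenarios
#'
#' @param object A fitted [sba_model()].
#' @param newdata Data frame with columns `parity`, `access_time` (hours)
#'   and optionally `move_date` (days relative to EDD or `Inf`; default no
#'   MWH stay).
#' @param ... Unused.
#' @return `newdata` with columns `gk_of_t`, `f_of_d`, `p_sba` and
#'   `category` appended.
#' @export
predict.sba_model <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata),
            all(c("parity", "access_time") %in% names(newdata)))
  if (!"move_date" %in% names(newdata)) newdata$move_date <- no_mwh()
  sc <- validate_scenario(newdata$parity, newdata$access_time,
                          newdata$move_date)
  g <- numeric(nrow(newdata))
  for (k in parity_levels) {
    idx <- sc$parity == k
    if (any(idx)) g[idx] <- cdf(object$G[[k]], sc$access_time[idx])
  }
  f <- cdf(object$F, sc$move_date)
  out <- newdata
  out$parity <- sc$parity
  out$gk_of_t <- g
  out$f_of_d <- f
  out$p_sba <- 1 - g * f
  out$category <- risk_category(out$p_sba)
  out
}

#' Simulate labour timing from the model inputs
#'
#' Draws joint (onset offset, latent-phase duration) pairs from the model's
#' input distributions; the two are drawn independently, matching the
#' model's independence assumption.
#'
#' @param object A fitted [sba_model()].
#' @param nsim Number of simulated women per parity.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame with columns `parity`, `onset_offset` (days) and
#'   `latent_hours`.
#' @export
simulate.sba_model <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    do.call(rbind, lapply(parity_levels, function(k) {
      data.frame(parity = k,
                 onset_offset = rtnmix(nsim, object$F$mix),
                 latent_hours = rtnmix(nsim, object$G[[k]]$mix))
    }))
  })
}

#' Plot the model's input distributions
#'
#' Two-panel base-graphics display: the onset-offset CDF F (days relative
#' to EDD) and the latent-phase CDFs Gk for both parities (hours).
#'
#' @param x A fitted [sba_model()].
#' @param ... Unused.
#' @export
plot.sba_model <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  sF <- x$F$mix$support
  g1 <- seq(sF[1], sF[2], length.out = 401)
  plot(g1, cdf(x$F, g1), type = "l", xlab = "ADD - EDD (days)",
       ylab = "F(d)", main = "Labour onset vs EDD")
  graphics::abline(v = 0, lty = 3)
  sups <- range(sapply(x$G, function(g) g$mix$support))
  g2 <- seq(sups[1], sups[2], length.out = 401)
  plot(g2, cdf(x$G$nulliparous, g2), type = "l", col = "blue",
       xlab = "latent phase (hours)", ylab = "Gk(t)",
       main = "Latent phase duration")
  graphics::lines(g2, cdf(x$G$multiparous, g2), col = "purple")
  graphics::legend("bottomright", legend = parity_levels,
                   col = c("blue", "purple"), lty = 1, bty = "n")
  invisible(x)
}
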