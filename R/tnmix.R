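#' Truncated normal mixture
#'
#' Construct a finite mixture of normal components truncated to a common
#' closed support interval and renormalised.  This single family backs both
#' the calibrated parametric surrogates for unpublished cohort data and the
#' Gaussian kernel density estimator (a KDE is an equal-weight mixture whose
#' components sit at the sample points and share one bandwidth).
#'
#' All distribution functions are closed-form in `pnorm`/`qnorm` terms, so a
#' mixture with thousands of components (a KDE over a full cohort) is still
#' cheap to evaluate.
#'
#' @param weights Numeric vector of non-negative mixture weights summing
#'   to 1 (tolerance 1e-12); recycled against `means`.
#' @param means Numeric vector of component locations (days or hours).
#' @param sds Numeric vector of strictly positive component scales.
#' @param support Length-2 numeric vector `c(lo, hi)` with `lo < hi`; the
#'   mixture density is clipped to this interval and renormalised.
#' @return An object of class `tnmix`.
#' @examples
#' m <- tnmix(c(0.5, 0.5), c(-2, 2), c(1, 1), support = c(-10, 10))
#' ptnmix(0, m)   # 0.5 by symmetry
#' @export
tnmix <- function(weights, means, sds, support) {
  k <- max(length(weights), length(means), length(sds))
  weights <- rep_len(as.numeric(weights), k)
  means <- rep_len(as.numeric(means), k)
  sds <- rep_len(as.numeric(sds), k)
  support <- as.numeric(support)
  if (length(support) != 2L || !all(is.finite(support)) || support[1] >= support[2])
    stop("`support` must be a finite interval c(lo, hi) with lo < hi")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("mixture weights must be finite and non-negative")
  if (abs(sum(weights) - 1) > 1e-12)
    stop("mixture weights must sum to 1 (within 1e-12)")
  if (any(!is.finite(sds)) || any(sds <= 0))
    stop("component sds must be finite and strictly positive")
  if (any(!is.finite(means)))
    stop("component means must be finite")
  # per-component mass retained by the truncation, and the overall normaliser
  z_comp <- pnorm(support[2], means, sds) - pnorm(support[1], means, sds)
  z <- sum(weights * z_comp)
  if (!is.finite(z) || z <= 0)
    stop("mixture has no mass on the support interval")
  structure(
    list(weights = weights, means = means, sds = sds, support = support,
         z_comp = z_comp, z = z),
    class = "tnmix"
  )
}

is_tnmix <- function(x) inherits(x, "tnmix")

#' @export
print.tnmix <- function(x, ...) {
  k <- length(x$weights)
  cat(sprintf("Truncated normal mixture: %d component%s on [%g, %g]\n",
              k, if (k == 1L) "" else "s", x$support[1], x$support[2]))
  if (k <= 8L) {
    tab <- data.frame(weight = signif(x$weights, 4),
                      mean = signif(x$means, 4),
                      sd = signif(x$sds, 4))
    print(tab, row.names = FALSE)
  } else {
    cat(sprintf("  (component locations span [%g, %g]; shared-scale range [%g, %g])\n",
                min(x$means), max(x$means), min(x$sds), max(x$sds)))
  }
  mo <- tnmix_moments(x)
  cat(sprintf("  mean %.4g, sd %.4g\n", mo$mean, mo$sd))
  invisible(x)
}

#' Distribution functions of a truncated normal mixture
#'
#' `ptnmix` evaluates the renormalised CDF (0 below the support, 1 above;
#' `Inf` maps to exactly 1), `dtnmix` the density, `qtnmix` the quantile
#' function (by monotone bisection, tolerance 1e-9), and `rtnmix` draws
#' exact samples via component choice followed by an inverse-CDF truncated
#' normal draw.
#'
#' @param q,x Numeric vector of evaluation points.
#' @param p Numeric vector of probabilities in (0, 1).
#' @param n Number of draws.
#' @param mix A [tnmix()] object.
#' @return Numeric vector.
#' @export
ptnmix <- function(q, mix) {
  stopifnot(is_tnmix(mix))
  out <- numeric(length(q))
  out[is.na(q)] <- NA_real_
  lo <- mix$support[1]; hi <- mix$support[2]
  below <- !is.na(q) & q <= lo
  above <- !is.na(q) & q >= hi  # includes +Inf
  mid <- !is.na(q) & !below & !above
  out[below] <- 0
  out[above] <- 1
  if (any(mid)) {
    qm <- q[mid]
    k <- length(mix$weights)
    # sum_i w_i (Phi_i(x) - Phi_i(lo)) / z; loop over whichever of
    # {components, points} is shorter so a many-kernel KDE stays fast
    acc <- numeric(length(qm))
    if (k <= length(qm)) {
      for (i in seq_len(k)) {
        acc <- acc + mix$weights[i] *
          (pnorm(qm, mix$means[i], mix$sds[i]) - pnorm(lo, mix$means[i], mix$sds[i]))
      }
    } else {
      plo <- sum(mix$weights * pnorm(lo, mix$means, mix$sds))
      for (j in seq_along(qm)) {
        acc[j] <- sum(mix$weights * pnorm(qm[j], mix$means, mix$sds)) - plo
      }
    }
    out[mid] <- pmin(1, pmax(0, acc / mix$z))
  }
  out
}

#' @rdname ptnmix
#' @export
dtnmix <- function(x, mix) {
  stopifnot(is_tnmix(mix))
  out <- numeric(length(x))
  out[is.na(x)] <- NA_real_
  inside <- !is.na(x) & x >= mix$support[1] & x <= mix$support[2]
  if (any(inside)) {
    xi <- x[inside]
    k <- length(mix$weights)
    acc <- numeric(length(xi))
    if (k <= length(xi)) {
      for (i in seq_len(k)) {
        acc <- acc + mix$weights[i] * dnorm(xi, mix$means[i], mix$sds[i])
      }
    } else {
      for (j in seq_along(xi)) {
        acc[j] <- sum(mix$weights * dnorm(xi[j], mix$means, mix$sds))
      }
    }
    out[inside] <- acc / mix$z
  }
  out
}

#' @rdname ptnmix
#' @export
qtnmix <- function(p, mix) {
  stopifnot(is_tnmix(mix))
  if (any(!is.na(p) & (p <= 0 | p >= 1)))
    stop("probabilities must lie strictly inside (0, 1)")
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_real_)
    uniroot(function(x) ptnmix(x, mix) - pp,
            interval = mix$support, tol = 1e-9)$root
  }, numeric(1))
}

#' @rdname ptnmix
#' @export
rtnmix <- function(n, mix) {
  stopifnot(is_tnmix(mix))
  if (n < 1) stop("`n` must be at least 1")
  # posterior component probabilities after truncation
  v <- mix$weights * mix$z_comp / mix$z
  comp <- sample.int(length(v), n, replace = TRUE, prob = v)
  lo <- mix$support[1]; hi <- mix$support[2]
  m <- mix$means[comp]; s <- mix$sds[comp]
  plo <- pnorm(lo, m, s); phi <- pnorm(hi, m, s)
  u <- runif(n)
  x <- qnorm(plo + u * (phi - plo), m, s)
  pmin(hi, pmax(lo, x))  # guard against floating-point spill at the edges
}

#' Moments and summary statistics of a truncated normal mixture
#'
#' Computes the mean and SD of the truncated, renormalised mixture, plus
#' optional interval masses and quantiles.  The default uses the closed-form
#' truncated-normal moment identities; `method = "quadrature"` integrates
#' the density with [stats::integrate()] instead, which serves as an
#' independent numerical check.
#'
#' @param mix A [tnmix()] object.
#' @param intervals Optional list of length-2 vectors; for each, the mixture
#'   mass on the interval is returned.
#' @param probs Optional vector of probabilities; the corresponding
#'   quantiles are returned.
#' @param method `"closed"` (default) or `"quadrature"`.
#' @return A list with `mean`, `sd`, and optionally `interval_mass` and
#'   `quantiles`.
#' @export
tnmix_moments <- function(mix, intervals = NULL, probs = NULL,
                          method = c("closed", "quadrature")) {
  stopifnot(is_tnmix(mix))
  method <- match.arg(method)
  lo <- mix$support[1]; hi <- mix$support[2]
  if (method == "closed") {
    v <- mix$weights * mix$z_comp / mix$z
    a <- (lo - mix$means) / mix$sds
    b <- (hi - mix$means) / mix$sds
    zc <- mix$z_comp
    # standard truncated-normal mean/variance per component
    dphi <- dnorm(a) - dnorm(b)
    m_i <- mix$means + mix$sds * dphi / zc
    v_i <- mix$sds^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / zc - (dphi / zc)^2)
    mean_mix <- sum(v * m_i)
    ex2 <- sum(v * (v_i + m_i^2))
    var_mix <- max(0, ex2 - mean_mix^2)
  } else {
    f <- function(x) dtnmix(x, mix)
    # split the range at the component locations so the adaptive rule
    # cannot step over a narrow component
    cuts <- sort(unique(c(lo, pmin(hi, pmax(lo, mix$means)), hi)))
    piecewise <- function(g) {
      sum(vapply(seq_len(length(cuts) - 1L), function(i) {
        integrate(g, cuts[i], cuts[i + 1L], rel.tol = 1e-10,
                  subdivisions = 500L)$value
      }, numeric(1)))
    }
    mass <- piecewise(f)
    mean_mix <- piecewise(function(x) x * f(x)) / mass
    ex2 <- piecewise(function(x) x^2 * f(x)) / mass
    var_mix <- max(0, ex2 - mean_mix^2)
  }
  out <- list(mean = mean_mix, sd = sqrt(var_mix))
  if (!is.null(intervals)) {
    out$interval_mass <- vapply(intervals, function(iv) {
      ptnmix(iv[2], mix) - ptnmix(iv[1], mix)
    }, numeric(1))
  }
  if (!is.null(probs)) {
    out$quantiles <- qtnmix(probs, mix)
    names(out$quantiles) <- paste0("p", format(probs * 100, trim = TRUE))
  }
  out
}
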