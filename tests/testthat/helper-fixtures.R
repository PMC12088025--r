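# Shared fixtures built in code.  Preset calibration is deterministic and
# cached inside the package for the session, so repeated sba_model() calls
# are cheap after the first.

preset_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- sba_model()
    cache
  }
})

# A nearly uniform distribution on [lo, hi]: one huge-sd component.
flat_mix <- function(lo = 0, hi = 10) tnmix(1, (lo + hi) / 2, 1e3, c(lo, hi))

# Standard-normal-backed mixture truncated to a wide interval.
std_mix <- function() tnmix(1, 0, 1, c(-30, 30))

# Printed multiparous risk table (Table 2 of the source cohort study):
# columns no_mwh, on_edd, -7, -14, -21, -28 for the 22-row interval grid.
table2_printed <- function() {
  m <- matrix(c(
    0.93, 0.96, 0.98, 0.99, 0.99, 0.99,
    0.82, 0.91, 0.95, 0.98, 0.99, 0.99,
    0.69, 0.84, 0.92, 0.96, 0.98, 0.99,
    0.62, 0.80, 0.91, 0.96, 0.98, 0.99,
    0.56, 0.77, 0.89, 0.95, 0.98, 0.99,
    0.50, 0.74, 0.88, 0.95, 0.97, 0.99,
    0.44, 0.71, 0.87, 0.94, 0.97, 0.99,
    0.39, 0.69, 0.85, 0.94, 0.97, 0.99,
    0.35, 0.66, 0.84, 0.93, 0.97, 0.99,
    0.30, 0.64, 0.83, 0.93, 0.97, 0.99,
    0.26, 0.62, 0.82, 0.92, 0.96, 0.99,
    0.23, 0.60, 0.81, 0.92, 0.96, 0.99,
    0.19, 0.59, 0.81, 0.92, 0.96, 0.99,
    0.16, 0.57, 0.80, 0.91, 0.96, 0.99,
    0.14, 0.56, 0.79, 0.91, 0.96, 0.99,
    0.12, 0.55, 0.79, 0.91, 0.96, 0.99,
    0.10, 0.54, 0.78, 0.91, 0.96, 0.99,
    0.08, 0.53, 0.78, 0.90, 0.96, 0.99,
    0.06, 0.52, 0.78, 0.90, 0.95, 0.99,
    0.05, 0.51, 0.77, 0.90, 0.95, 0.99,
    0.04, 0.51, 0.77, 0.90, 0.95, 0.99,
    0.03, 0.51, 0.77, 0.90, 0.95, 0.99),
    ncol = 6, byrow = TRUE)
  colnames(m) <- c("no_mwh", "on_edd", "minus_7", "minus_14", "minus_21",
                   "minus_28")
  m
}
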