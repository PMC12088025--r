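#' Access-time interval grid of the printed tables and wheel device
#'
#' A woman's travel time to a skilled birth attendant is uncertain, so the
#' tables bin it into intervals: 1-hour rows up to 3 h, then half-hour rows
#' up to 12.5 h — 22 rows in all.  Intervals are treated as half-open
#' `(lower, upper]`; the conservative reporting convention evaluates each
#' row at its upper bound only, which by monotonicity of P(SBA) in t is the
#' interval minimum.
#'
#' @return Data frame with columns `lower`, `upper` (hours) and `label`.
#' @examples
#' nrow(default_interval_grid())  # 22
#' @export
default_interval_grid <- function() {
  lower <- c(0, 1, 2, seq(3, 12, by = 0.5))
  upper <- c(1, 2, 3, seq(3.5, 12.5, by = 0.5))
  data.frame(lower = lower, upper = upper,
             label = paste0(sub("\\.?0+$", "", format(lower, trim = TRUE)),
                            "-",
                            sub("\\.?0+$", "", format(upper, trim = TRUE))))
}

scenario_label <- function(d) {
  vapply(d, function(di) {
    if (is.infinite(di)) "no_mwh"
    else if (di == 0) "on_edd"
    else paste0("minus_", abs(di))
  }, character(1))
}

#' Conservative cell value for one access-time interval
#'
#' Reports, for a travel-time interval, the lowest P(SBA) within the
#' interval — by monotonicity in t this is the value at the interval's
#' upper bound.
#'
#' @param model A fitted [sba_model()].
#' @param interval Length-2 numeric `c(lower, upper)` in hours, or one row
#'   of [default_interval_grid()].
#' @param parity,move_date As in [p_sba()].
#' @return A `risk_estimate` (see [p_sba()]) evaluated at the upper bound.
#' @export
cell_value <- function(model, interval, parity, move_date = no_mwh()) {
  if (is.data.frame(interval)) interval <- c(interval$lower, interval$upper)
  if (length(interval) != 2L || interval[1] < 0 || interval[1] >= interval[2])
    stop("`interval` must be c(lower, upper) with 0 <= lower < upper")
  p_sba(model, parity, access_time = interval[2], move_date = move_date)
}

#' Build a full risk table
#'
#' Evaluates P(SBA) for every access-time interval and MWH move-date
#' scenario, under the conservative upper-bound convention, optionally with
#' bootstrap percentile confidence intervals (which require the model's
#' input distributions to be KDEs so their samples can be resampled; see
#' [bootstrap_cis()]).
#'
#' @param model A fitted [sba_model()].
#' @param parity `"nulliparous"` or `"multiparous"`.
#' @param grid Interval grid data frame (default [default_interval_grid()]).
#' @param move_dates Scenario columns, default `Inf, 0, -7, -14, -21, -28`.
#' @param ci `FALSE` (default) or a [bootstrap_config()] to attach CIs.
#' @return An `sba_risk_table`: long-format data frame with one row per
#'   (interval, scenario) holding `p_sba`, `category` and, with CIs,
#'   `ci_low`/`ci_high`; attributes carry parity, grid and scenario order.
#' @examples
#' \donttest{
#' tab <- build_risk_table(sba_model(), "multiparous")
#' print(tab)
#' }
#' @export
build_risk_table <- function(model, parity,
                             grid = default_interval_grid(),
                             move_dates = c(no_mwh(), 0, -7, -14, -21, -28),
                             ci = FALSE) {
  stopifnot(inherits(model, "sba_model"))
  parity <- match_parity(parity)
  if (nrow(grid) == 0L) stop("`grid` must be non-empty")
  if (length(move_dates) == 0L) stop("`move_dates` must be non-empty")
  g <- cdf(model$G[[parity]], grid$upper)
  f <- cdf(model$F, move_dates)
  cells <- expand.grid(row = seq_len(nrow(grid)),
                       col = seq_along(move_dates))
  out <- data.frame(
    access_time = grid$label[cells$row],
    lower = grid$lower[cells$row],
    upper = grid$upper[cells$row],
    move_date = move_dates[cells$col],
    scenario = scenario_label(move_dates)[cells$col],
    p_sba = 1 - g[cells$row] * f[cells$col]
  )
  out$category <- risk_category(out$p_sba)
  if (!isFALSE(ci)) {
    if (!inherits(ci, "bootstrap_config"))
      stop("`ci` must be FALSE or a bootstrap_config()")
    if (!identical(model$F$source, "kde") ||
        !identical(model$G[[parity]]$source, "kde"))
      stop("bootstrap CIs need KDE inputs fitted from samples; ",
           "surrogate presets have no data to resample")
    scen <- data.frame(parity = parity, access_time = out$upper,
                       move_date = out$move_date)
    cis <- bootstrap_cis(
      onset_samples = model$F$kde_samples,
      latent_samples = setNames(list(model$G[[parity]]$kde_samples), parity),
      scenarios = scen, config = ci,
      bandwidth = model$bandwidth,
      bandwidth_type = model$bandwidth_type,
      onset_support = model$F$mix$support,
      latent_supports = setNames(list(model$G[[parity]]$mix$support), parity))
    out$ci_low <- cis$ci$lower
    out$ci_high <- cis$ci$upper
    attr(out, "bootstrap") <- cis[c("n_iterations", "converged")]
  }
  structure(out, parity = parity, grid = grid, move_dates = move_dates,
            class = c("sba_risk_table", "data.frame"))
}

risk_table_matrix <- function(table, value = "p_sba") {
  grid <- attr(table, "grid")
  move_dates <- attr(table, "move_dates")
  m <- matrix(table[[value]], nrow = nrow(grid),
              dimnames = list(grid$label, scenario_label(move_dates)))
  m
}

#' @export
print.sba_risk_table <- function(x, digits = 2, ...) {
  cat(sprintf("P(SBA) risk table (%s), conservative upper-bound convention\n",
              attr(x, "parity")))
  m <- round(risk_table_matrix(x), digits)  # display precision only
  if (!is.null(x$ci_low)) {
    lo <- round(risk_table_matrix(x, "ci_low"), digits)
    hi <- round(risk_table_matrix(x, "ci_high"), digits)
    disp <- matrix(sprintf("%.*f [%.*f, %.*f]", digits, m, digits, lo,
                           digits, hi),
                   nrow = nrow(m), dimnames = dimnames(m))
    print(as.data.frame(disp))
  } else {
    print(as.data.frame(m))
  }
  invisible(x)
}

#' Export and re-import risk tables
#'
#' `export_risk_table` writes a table as CSV (one row per interval; per
#' scenario a `p_sba` column plus, when present, CI bounds and category) or
#' JSON (nested rows/columns, plus a `rings` view grouping the scenario
#' columns as the concentric data rings of the wheel device, keyed by
#' interval label).  Numeric cells are written at full precision so
#' `read_risk_table` reproduces them exactly.
#'
#' @param table An `sba_risk_table`.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`; defaults from the file extension.
#' @return `path` invisibly for the writer; an `sba_risk_table` for the
#'   reader.
#' @export
export_risk_table <- function(table, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(table, "sba_risk_table"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("csv", "json"))
      stop("cannot infer format from extension `", ext, "`")
    format <- ext
  }
  grid <- attr(table, "grid")
  move_dates <- attr(table, "move_dates")
  scen <- scenario_label(move_dates)
  if (format == "csv") {
    wide <- data.frame(access_time = grid$label,
                       lower = grid$lower, upper = grid$upper)
    num <- function(v) format(v, digits = 17, trim = TRUE, scientific = FALSE)
    pm <- risk_table_matrix(table)
    for (j in seq_along(scen)) wide[[scen[j]]] <- num(pm[, j])
    if (!is.null(table$ci_low)) {
      lo <- risk_table_matrix(table, "ci_low")
      hi <- risk_table_matrix(table, "ci_high")
      for (j in seq_along(scen)) {
        wide[[paste0("ci_low_", scen[j])]] <- num(lo[, j])
        wide[[paste0("ci_high_", scen[j])]] <- num(hi[, j])
      }
    }
    cm <- matrix(as.character(table$category), nrow = nrow(grid))
    for (j in seq_along(scen)) wide[[paste0("category_", scen[j])]] <- cm[, j]
    wide$parity <- attr(table, "parity")
    wide$move_date <- NULL
    utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  } else {
    pm <- risk_table_matrix(table)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      cells <- lapply(seq_along(scen), function(j) {
        cell <- list(scenario = scen[j],
                     move_date = if (is.infinite(move_dates[j])) "no_mwh"
                                 else move_dates[j],
                     p_sba = pm[i, j],
                     category = as.character(table$category)[(j - 1) * nrow(grid) + i])
        if (!is.null(table$ci_low)) {
          cell$ci_low <- risk_table_matrix(table, "ci_low")[i, j]
          cell$ci_high <- risk_table_matrix(table, "ci_high")[i, j]
        }
        cell
      })
      list(label = grid$label[i], lower = grid$lower[i], upper = grid$upper[i],
           cells = cells)
    })
    rings <- lapply(seq_along(scen), function(j)
      as.list(setNames(pm[, j], grid$label)))
    names(rings) <- scen
    obj <- list(parity = attr(table, "parity"),
                move_dates = ifelse(is.infinite(move_dates), "no_mwh",
                                    move_dates),
                rows = rows, rings = rings)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname export_risk_table
#' @export
read_risk_table <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  if (format == "csv") {
    wide <- utils::read.csv(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    scen <- setdiff(names(wide),
                    c("access_time", "lower", "upper", "parity",
                      grep("^(ci_low_|ci_high_|category_)", names(wide),
                           value = TRUE)))
    move_dates <- vapply(scen, function(s) {
      if (s == "no_mwh") Inf
      else if (s == "on_edd") 0
      else -as.numeric(sub("minus_", "", s))
    }, numeric(1))
    grid <- data.frame(lower = wide$lower, upper = wide$upper,
                       label = wide$access_time)
    cells <- expand.grid(row = seq_len(nrow(grid)), col = seq_along(scen))
    out <- data.frame(
      access_time = grid$label[cells$row],
      lower = grid$lower[cells$row], upper = grid$upper[cells$row],
      move_date = unname(move_dates)[cells$col],
      scenario = scen[cells$col],
      p_sba = unlist(lapply(scen, function(s) as.numeric(wide[[s]])),
                     use.names = FALSE)
    )
    out$category <- risk_category(out$p_sba)
    if (paste0("ci_low_", scen[1]) %in% names(wide)) {
      out$ci_low <- unlist(lapply(scen, function(s)
        as.numeric(wide[[paste0("ci_low_", s)]])), use.names = FALSE)
      out$ci_high <- unlist(lapply(scen, function(s)
        as.numeric(wide[[paste0("ci_high_", s)]])), use.names = FALSE)
    }
    structure(out, parity = wide$parity[1], grid = grid,
              move_dates = unname(move_dates),
              class = c("sba_risk_table", "data.frame"))
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    grid <- data.frame(
      lower = vapply(obj$rows, function(r) r$lower, numeric(1)),
      upper = vapply(obj$rows, function(r) r$upper, numeric(1)),
      label = vapply(obj$rows, function(r) r$label, character(1)))
    scen <- vapply(obj$rows[[1]]$cells, function(c) c$scenario, character(1))
    move_dates <- vapply(obj$rows[[1]]$cells, function(c)
      if (identical(c$move_date, "no_mwh") || is.null(c$move_date)) Inf
      else as.numeric(c$move_date), numeric(1))
    has_ci <- !is.null(obj$rows[[1]]$cells[[1]]$ci_low)
    cells <- expand.grid(row = seq_len(nrow(grid)), col = seq_along(scen))
    get_cell <- function(i, j, field)
      as.numeric(obj$rows[[i]]$cells[[j]][[field]])
    out <- data.frame(
      access_time = grid$label[cells$row],
      lower = grid$lower[cells$row], upper = grid$upper[cells$row],
      move_date = move_dates[cells$col], scenario = scen[cells$col],
      p_sba = mapply(get_cell, cells$row, cells$col,
                     MoreArgs = list(field = "p_sba")))
    out$category <- risk_category(out$p_sba)
    if (has_ci) {
      out$ci_low <- mapply(get_cell, cells$row, cells$col,
                           MoreArgs = list(field = "ci_low"))
      out$ci_high <- mapply(get_cell, cells$row, cells$col,
                            MoreArgs = list(field = "ci_high"))
    }
    structure(out, parity = obj$parity, grid = grid, move_dates = move_dates,
              class = c("sba_risk_table", "data.frame"))
  }
}
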