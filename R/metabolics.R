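#' Enhancement factor of a metabolite
#'
#' `EF = mean(treatment amounts) / mean(control amounts)`: the ratio of
#' the mean metabolite amount in a microparticle run to the mean in the
#' particle-free control. The confidence band comes from the delta
#' method on the log-ratio (treatment and control means treated as
#' independent) with Student-t quantiles at `min(n_t, n_c) - 1` degrees
#' of freedom; the p-value is the two-sided Welch t-test on the
#' replicate amounts. With a single replicate on either side the band
#' and p-value are `NA`.
#'
#' @param treatment Replicate amounts from the microparticle run,
#'   n >= 1.
#' @param control Replicate amounts from the control run, n >= 1, with
#'   positive mean.
#' @param alpha Significance level of the band (default 0.05).
#' @return A list of class `ef_result`: `ef`, `ci_lo`, `ci_hi`,
#'   `p_value`, `n_treatment`, `n_control`, `alpha`.
#' @examples
#' enhancement_factor(c(9, 9.2, 8.8, 9.1), c(1, 1.1, 0.9, 1.05))
#' @export
enhancement_factor <- function(treatment, control, alpha = 0.05) {
  treatment <- as.numeric(treatment)
  control <- as.numeric(control)
  if (length(treatment) < 1L || length(control) < 1L) {
    stop("need at least one replicate in each arm", call. = FALSE)
  }
  if (any(!is.finite(treatment)) || any(!is.finite(control))) {
    stop("amounts must be finite", call. = FALSE)
  }
  mc <- mean(control)
  if (mc <= 0) {
    stop("control mean must be > 0", call. = FALSE)
  }
  mt <- mean(treatment)
  ef <- mt / mc
  nt <- length(treatment)
  nc <- length(control)
  if (nt < 2L || nc < 2L || mt <= 0) {
    return(structure(
      list(
        ef = ef, ci_lo = NA_real_, ci_hi = NA_real_,
        p_value = NA_real_, n_treatment = nt, n_control = nc,
        alpha = alpha
      ),
      class = "ef_result"
    ))
  }
  # delta method on log(EF): var = cv_t^2/n_t + cv_c^2/n_c
  se_log <- sqrt(
    var(treatment) / (nt * mt^2) + var(control) / (nc * mc^2)
  )
  tq <- qt(1 - alpha / 2, df = min(nt, nc) - 1L)
  structure(
    list(
      ef = ef,
      ci_lo = ef * exp(-tq * se_log),
      ci_hi = ef * exp(tq * se_log),
      p_value = t_test_p(treatment, control),
      n_treatment = nt, n_control = nc, alpha = alpha
    ),
    class = "ef_result"
  )
}

#' @export
print.ef_result <- function(x, ...) {
  cat(sprintf(
    "EF = %.4g (%.0f%% CI %s-%s), p = %s [n = %d vs %d]\n",
    x$ef, 100 * (1 - x$alpha), format(x$ci_lo, digits = 3),
    format(x$ci_hi, digits = 3), format.pval(x$p_value, digits = 3),
    x$n_treatment, x$n_control
  ))
  invisible(x)
}

#' Enhancement factors for a whole culture time series
#'
#' Computes [enhancement_factor()] for every metabolite, time point and
#' non-control condition of a replicate time-series table (layout of
#' [make_timeseries()] or [read_timeseries_csv()]).
#'
#' @param ts A `culture_timeseries` data.frame.
#' @param control_condition The talc concentration identifying the
#'   control run (default 0).
#' @param metabolites Metabolite columns to use; defaults to every
#'   column that is not `talc_g_per_L`, `replicate`, `time_h` or
#'   `glucose_g_per_L`.
#' @param alpha Significance level of the bands.
#' @return A data.frame with columns `metabolite`, `time_h`,
#'   `talc_g_per_L`, `EF`, `ci_lo`, `ci_hi`, `p_value`.
#' @export
enhancement_table <- function(ts, control_condition = 0,
                              metabolites = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(ts))
  reserved <- c("talc_g_per_L", "replicate", "time_h", "glucose_g_per_L")
  if (is.null(metabolites)) {
    metabolites <- setdiff(names(ts), reserved)
  }
  conds <- setdiff(unique(ts$talc_g_per_L), control_condition)
  times <- sort(unique(ts$time_h))
  rows <- list()
  for (m in metabolites) {
    for (t in times) {
      ctrl <- ts[ts$talc_g_per_L == control_condition & ts$time_h == t, m]
      for (cond in conds) {
        trt <- ts[ts$talc_g_per_L == cond & ts$time_h == t, m]
        r <- enhancement_factor(trt, ctrl, alpha)
        rows[[length(rows) + 1L]] <- data.frame(
          metabolite = m, time_h = t, talc_g_per_L = cond,
          EF = r$ef, ci_lo = r$ci_lo, ci_hi = r$ci_hi,
          p_value = r$p_value
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit a cubic spline to a concentration curve
#'
#' Cubic spline through the per-time mean concentrations, the basis of
#' the uptake-rate calculation. The default end condition
#' (`method = "cubic"`) matches an exact cubic through the four points
#' nearest each end, so any cubic polynomial sampled at the data times
#' is reproduced exactly; `method = "natural"` uses zero second
#' derivatives at the ends instead. For noisy data a smoothing variant
#' (`method = "smooth"`, penalised regression spline via
#' [stats::smooth.spline()]) is available.
#'
#' @param times Strictly increasing times, h; at least 4 distinct
#'   values. Duplicate times are allowed only with equal concentrations
#'   (replicates must be averaged upstream).
#' @param concentrations Concentrations at `times`, finite.
#' @param method `"cubic"` (default), `"natural"` or `"smooth"`.
#' @param spar Smoothing parameter passed to [stats::smooth.spline()]
#'   when `method = "smooth"`.
#' @return An object of class `conc_spline` with a [predict()] method
#'   (`deriv = 0` or `1`).
#' @examples
#' sp <- fit_concentration_spline(c(0, 24, 48, 72, 96), 20 - 0.1 * c(0, 24, 48, 72, 96))
#' predict(sp, 36)
#' @export
fit_concentration_spline <- function(times, concentrations,
                                     method = c("cubic", "natural", "smooth"),
                                     spar = NULL) {
  method <- match.arg(method)
  if (length(times) != length(concentrations)) {
    stop("'times' and 'concentrations' must have equal length", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(!is.finite(concentrations))) {
    stop("times and concentrations must be finite", call. = FALSE)
  }
  o <- order(times)
  times <- times[o]
  concentrations <- concentrations[o]
  if (anyDuplicated(times)) {
    agg <- tapply(concentrations, times, function(v) {
      if (diff(range(v)) > 1e-9 * max(1, abs(mean(v)))) {
        stop("duplicate times with conflicting concentrations; ",
          "average replicates upstream",
          call. = FALSE
        )
      }
      v[1]
    })
    times <- as.numeric(names(agg))
    concentrations <- as.numeric(agg)
  }
  if (length(times) < 4L) {
    stop("need at least 4 distinct time points", call. = FALSE)
  }
  fun <- switch(method,
    cubic = splinefun(times, concentrations, method = "fmm"),
    natural = splinefun(times, concentrations, method = "natural"),
    smooth = {
      fit <- smooth.spline(times, concentrations, spar = spar)
      function(x, deriv = 0) predict(fit, x, deriv = deriv)$y
    }
  )
  structure(
    list(
      fun = fun, times = times, concentrations = concentrations,
      method = method, degree = 3L
    ),
    class = "conc_spline"
  )
}

#' @export
#' @rdname fit_concentration_spline
#' @param object A `conc_spline`.
#' @param t Evaluation times within the fitted range.
#' @param deriv Derivative order, 0 or 1.
#' @param ... Unused.
predict.conc_spline <- function(object, t, deriv = 0, ...) {
  object$fun(t, deriv = deriv)
}

#' @export
print.conc_spline <- function(x, ...) {
  cat(sprintf(
    "<conc_spline> cubic (%s end conditions), %d knots on [%g, %g] h\n",
    x$method, length(x$times), min(x$times), max(x$times)
  ))
  invisible(x)
}

#' Volumetric substrate uptake rate from a fitted spline
#'
#' Differentiates the fitted concentration spline and reports
#' `rate(t) = -dc/dt`, positive for consumption, in g L^-1 h^-1 when
#' the concentrations are g/L and times are hours. By construction the
#' integral of the rate over the fitted range equals
#' `c(first) - c(last)` of the fitted means.
#'
#' @param spline A [fit_concentration_spline()] result.
#' @param grid Evaluation times within the fitted range (default: the
#'   knot times).
#' @return A data.frame of class `uptake_profile`: `time_h`,
#'   `rate_g_per_L_h`.
#' @examples
#' sp <- fit_concentration_spline(c(0, 24, 48, 72, 96), 20 - 0.1 * c(0, 24, 48, 72, 96))
#' uptake_rate(sp)
#' @export
uptake_rate <- function(spline, grid = spline$times) {
  stopifnot(inherits(spline, "conc_spline"))
  rng <- range(spline$times)
  if (any(grid < rng[1] - 1e-9) || any(grid > rng[2] + 1e-9)) {
    stop("evaluation grid outside the fitted time range", call. = FALSE)
  }
  out <- data.frame(
    time_h = grid,
    rate_g_per_L_h = -predict(spline, grid, deriv = 1)
  )
  class(out) <- c("uptake_profile", "data.frame")
  attr(out, "spline") <- spline
  out
}

#' Glucose uptake-rate profiles per condition
#'
#' Averages replicate glucose concentrations per (condition, time),
#' fits the concentration spline and differentiates it.
#'
#' @param ts A `culture_timeseries` data.frame with columns
#'   `talc_g_per_L`, `time_h`, `glucose_g_per_L`.
#' @param method,spar Passed to [fit_concentration_spline()].
#' @return A data.frame with columns `talc_g_per_L`, `time_h`,
#'   `rate_g_per_L_h`.
#' @export
glucose_uptake_table <- function(ts, method = "cubic", spar = NULL) {
  stopifnot(is.data.frame(ts))
  rows <- lapply(sort(unique(ts$talc_g_per_L)), function(cond) {
    sub <- ts[ts$talc_g_per_L == cond, ]
    mu <- aggregate(glucose_g_per_L ~ time_h, data = sub, FUN = mean)
    sp <- fit_concentration_spline(mu$time_h, mu$glucose_g_per_L,
      method = method, spar = spar
    )
    up <- uptake_rate(sp)
    data.frame(
      talc_g_per_L = cond, time_h = up$time_h,
      rate_g_per_L_h = up$rate_g_per_L_h
    )
  })
  do.call(rbind, rows)
}

#' Read / write replicate time-series tables
#'
#' CSV layout: `talc_g_per_L`, `replicate`, `time_h`, one column per
#' metabolite, `glucose_g_per_L`.
#'
#' @param path CSV file path.
#' @return `read_timeseries_csv`: a `culture_timeseries` data.frame.
#' @export
read_timeseries_csv <- function(path) {
  ts <- read.csv(path, check.names = FALSE)
  need <- c("talc_g_per_L", "replicate", "time_h", "glucose_g_per_L")
  miss <- setdiff(need, names(ts))
  if (length(miss)) {
    stop(
      "time-series CSV lacks column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  class(ts) <- c("culture_timeseries", "data.frame")
  ts
}

#' @rdname read_timeseries_csv
#' @param ts A `culture_timeseries` data.frame.
#' @export
write_timeseries_csv <- function(ts, path) {
  write.csv(as.data.frame(ts), path, row.names = FALSE)
  invisible(path)
}
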