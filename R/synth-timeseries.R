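## Seeded generator for replicate culture time series with known effect
## sizes and glucose depletion curves.

default_metabolites <- function() {
  c(
    "oxytetracycline",
    "acetyl_decarboxamido_oxytetracycline",
    "rimocidin",
    "rimocidin_ce108",
    "rimocidin_27_ethyl",
    "milbemycin_a3_4o",
    "milbemycin_b11_4o"
  )
}

# default per-condition true enhancement factors at the final sampling
# times, shaped after the effect structure seen in talc-amended
# S. rimosus runs (strong oxytetracycline/ADOTC enhancement at moderate
# talc doses, mild enhancement or suppression elsewhere); EF ramps from
# 1 at inoculation to the stated value at 72-96 h
default_ef_table <- function(metabolites, conditions, times) {
  peak <- rbind(
    oxytetracycline = c(1, 2, 9, 4, 3),
    acetyl_decarboxamido_oxytetracycline = c(1, 2, 7, 3.5, 2.5),
    rimocidin = c(1, 1, 1, 1, 1),
    rimocidin_ce108 = c(1, 1.2, 1.3, 1.5, 1.3),
    rimocidin_27_ethyl = c(1, 0.9, 0.7, 0.6, 0.6),
    milbemycin_a3_4o = c(1, 1.5, 2, 3.2, 2.5),
    milbemycin_b11_4o = c(1, 0.8, 0.6, 0.5, 0.5)
  )
  colnames(peak) <- as.character(c(0, 0.5, 5, 10, 12))
  ef <- array(
    1,
    dim = c(length(metabolites), length(times), length(conditions)),
    dimnames = list(metabolites, as.character(times), as.character(conditions))
  )
  ramp <- pmin(1, times / 72) # reach the peak EF by 72 h, hold after
  for (m in metabolites) {
    for (ci in seq_along(conditions)) {
      pk <- if (m %in% rownames(peak) &&
        as.character(conditions[ci]) %in% colnames(peak)) {
        peak[m, as.character(conditions[ci])]
      } else {
        1
      }
      ef[m, , ci] <- 1 + (pk - 1) * ramp
    }
  }
  ef
}

# default control-run mean amounts: oxytetracycline in mg/L rising to
# ~0.7 mg/L by 72 h; the others in arbitrary ion-peak-area units
default_control_means <- function(metabolites, times) {
  prof <- pmax(0.02, pmin(1, (times / 72)^2)) # slow rise, plateau
  base <- c(0.7, 40, 120, 80, 60, 25, 30)
  base <- rep_len(base, length(metabolites))
  out <- outer(base, prof)
  dimnames(out) <- list(metabolites, as.character(times))
  out
}

#' Time-series specification for the synthetic culture generator
#'
#' Describes replicate shake-flask time series: per-condition true
#' enhancement factors (EF) and control means for each secondary
#' metabolite, multiplicative lognormal replicate noise with a given
#' coefficient of variation, and per-condition non-increasing glucose
#' depletion curves: a stretched-exponential consumption ramp
#' normalised so the noiseless curve runs from `glucose_initial` at 0 h
#' exactly to the stated final concentration at the last sampling time.
#'
#' @param metabolites Character vector of metabolite ids. Defaults to
#'   the seven compounds followed in talc-amended *S. rimosus* runs.
#' @param conditions Talc concentrations, g/L (first one = control 0).
#' @param times Sampling times, h (default every 24 h from 0 to 96).
#' @param replicates Replicates per condition (default 4).
#' @param control_means Metabolite x time matrix of control mean
#'   amounts, all > 0.
#' @param true_ef Metabolite x time x condition array of true EFs, > 0
#'   (control condition must be 1).
#' @param cv Replicate coefficient of variation of amounts, >= 0.
#' @param glucose_initial Initial glucose concentration, g/L (medium
#'   recipe default 22).
#' @param glucose_final Named (by condition) final concentrations,
#'   g/L.
#' @param glucose_tau,glucose_shape Depletion curve time scale (h) and
#'   shape exponent.
#' @param glucose_sd Additive replicate noise SD on glucose, g/L
#'   (clipped at 0).
#' @param seed Integer seed.
#' @return A list of class `timeseries_spec`.
#' @export
timeseries_spec <- function(metabolites = default_metabolites(),
                            conditions = c(0, 0.5, 5, 10, 12),
                            times = c(0, 24, 48, 72, 96),
                            replicates = 4L,
                            control_means = default_control_means(
                              metabolites, times
                            ),
                            true_ef = default_ef_table(
                              metabolites, conditions, times
                            ),
                            cv = 0.1,
                            glucose_initial = 22,
                            glucose_final = c(
                              "0" = 7.45, "0.5" = 7.47, "5" = 10.56,
                              "10" = 10.95, "12" = 11.44
                            ),
                            glucose_tau = 55,
                            glucose_shape = 2,
                            glucose_sd = 0.3,
                            seed = 1L) {
  control_means <- as.matrix(control_means)
  if (any(control_means <= 0)) {
    stop("control means must be > 0", call. = FALSE)
  }
  if (any(true_ef <= 0)) {
    stop("true enhancement factors must be > 0", call. = FALSE)
  }
  stop_if_not_scalar_num(cv, "cv", 0)
  stop_if_not_scalar_num(glucose_sd, "glucose_sd", 0)
  if (replicates < 1L) {
    stop("'replicates' must be >= 1", call. = FALSE)
  }
  gf <- glucose_final[as.character(conditions)]
  gf[is.na(gf)] <- mean(glucose_final)
  names(gf) <- as.character(conditions)
  if (any(gf > glucose_initial)) {
    stop("glucose curves must be non-increasing", call. = FALSE)
  }
  structure(
    list(
      metabolites = metabolites, conditions = conditions, times = times,
      replicates = as.integer(replicates), control_means = control_means,
      true_ef = true_ef, cv = cv,
      glucose_initial = glucose_initial, glucose_final = gf,
      glucose_tau = glucose_tau, glucose_shape = glucose_shape,
      glucose_sd = glucose_sd, seed = as.integer(seed)
    ),
    class = "timeseries_spec"
  )
}

#' Noiseless glucose depletion curve of a spec
#'
#' @param spec A [timeseries_spec()].
#' @param condition One of `spec$conditions`.
#' @param t Times, h.
#' @return Glucose concentration, g/L (non-increasing in `t`).
#' @export
glucose_curve <- function(spec, condition, t) {
  cf <- unname(spec$glucose_final[as.character(condition)])
  c0 <- spec$glucose_initial
  tmax <- max(spec$times)
  ramp <- 1 - exp(-(t / spec$glucose_tau)^spec$glucose_shape)
  ramp_end <- 1 - exp(-(tmax / spec$glucose_tau)^spec$glucose_shape)
  c0 - (c0 - cf) * ramp / ramp_end
}

#' Generate replicate culture time series
#'
#' For every condition, replicate and time point, draws each metabolite
#' amount as `control_mean * true_EF * lognormal noise` (unit-mean
#' lognormal with the spec's CV, so the expected treatment/control ratio
#' equals the true EF; `cv = 0` is noiseless), and glucose as the
#' spec's non-increasing depletion curve plus Gaussian noise clipped at
#' zero.
#'
#' @param spec A [timeseries_spec()].
#' @return A data.frame of class `culture_timeseries` in long-replicate
#'   layout: `talc_g_per_L`, `replicate`, `time_h`, one column per
#'   metabolite, `glucose_g_per_L`.
#' @examples
#' ts <- make_timeseries(timeseries_spec(replicates = 2, seed = 3))
#' head(ts)
#' @export
make_timeseries <- function(spec) {
  stopifnot(inherits(spec, "timeseries_spec"))
  sdlog <- sqrt(log(1 + spec$cv^2))
  meanlog <- -sdlog^2 / 2
  with_seed(spec$seed, {
    grid <- expand.grid(
      replicate = seq_len(spec$replicates),
      time_h = spec$times,
      talc_g_per_L = spec$conditions,
      KEEP.OUT.ATTRS = FALSE
    )
    grid <- grid[, c("talc_g_per_L", "replicate", "time_h")]
    n <- nrow(grid)
    ti <- match(grid$time_h, spec$times)
    ci <- match(grid$talc_g_per_L, spec$conditions)
    for (m in spec$metabolites) {
      mi <- match(m, spec$metabolites)
      mu <- spec$control_means[mi, ti] * spec$true_ef[cbind(mi, ti, ci)]
      noise <- if (spec$cv > 0) rlnorm(n, meanlog, sdlog) else rep(1, n)
      grid[[m]] <- as.numeric(mu * noise)
    }
    gmu <- mapply(
      function(cond, t) glucose_curve(spec, cond, t),
      grid$talc_g_per_L, grid$time_h
    )
    gn <- if (spec$glucose_sd > 0) rnorm(n, 0, spec$glucose_sd) else 0
    grid$glucose_g_per_L <- pmax(0, gmu + gn)
    class(grid) <- c("culture_timeseries", "data.frame")
    attr(grid, "spec") <- spec
    grid
  })
}
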