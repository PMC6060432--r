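#' Kinetic parameters of the glucose transport and consumption model
#'
#' Intracellular glucose G evolves as a balance between facilitative carrier
#' transport and saturable consumption:
#'
#' \deqn{dG/dt = v_T \left(\frac{G_{ext}}{K_T + G_{ext}} -
#'   \frac{G}{K_T + G}\right) - g_{HK}(t)\,\big(v_{gly} + v_{ppp}(t) +
#'   v_{hbp}(t)\big)\,\frac{G}{K_C + G}}
#'
#' where the symmetric carrier term models a facilitative transporter (GluT1
#' and GluT3, lumped) working in both directions, and consumption lumps the
#' glycolytic, pentose phosphate (PPP) and hexosamine (HBP) fluxes behind a
#' common hexokinase gate. IAA (a glyceraldehyde-3-phosphate dehydrogenase
#' inhibitor) progressively closes the hexokinase gate as glucose-6-phosphate
#' builds up, with time constant `tau_hk_inhibition`, and simultaneously
#' discloses a transient hexosamine flux of peak size
#' `v_hbp_max * hbp_transient_scale` that decays with `tau_hbp_transient`.
#' 6-AN zeroes the PPP flux from its application time onwards.
#'
#' Defaults are read from the packaged config
#' (`system.file("extdata", "kinetic_defaults.yaml", package = "glucofret")`)
#' and differ between genotypes only through the three scale factors. The
#' wild-type (`nonTg`) defaults are calibrated to give about -2 %/min
#' relative-ratio slope in the 2-7 min window of a 2.5 to 0.2 mM restriction
#' and about +10% at 50 min of a 2.5 to 10 mM step.
#'
#' @param genotype `"nonTg"` or `"3xTgAD"`. Selects the genotype scale
#'   factors from the config.
#' @param ... Named overrides for any parameter field.
#' @param config_file Optional path to an alternative YAML config.
#'
#' @return An object of class `kinetic_params`: a list with fields
#'   `v_transport`, `k_transport`, `v_glycolysis`, `v_ppp`, `v_hbp_max`,
#'   `k_consume`, `tau_hk_inhibition`, `tau_hbp_transient`, `genotype`,
#'   `glycolysis_scale`, `ppp_scale`, `hbp_transient_scale`.
#' @export
#' @examples
#' kinetic_params("3xTgAD")
#' kinetic_params("nonTg", v_transport = 0.05)
kinetic_params <- function(genotype = c("nonTg", "3xTgAD"), ...,
                           config_file = NULL) {
  genotype <- match.arg(genotype)
  if (is.null(config_file)) {
    config_file <- system.file("extdata", "kinetic_defaults.yaml",
      package = "glucofret"
    )
  }
  cfg <- yaml::read_yaml(config_file)
  p <- c(cfg$kinetics, cfg$genotypes[[genotype]], list(genotype = genotype))
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(p))
  if (length(bad) > 0) {
    abort(paste0("unknown kinetic parameter(s): ", paste(bad, collapse = ", ")))
  }
  p[names(overrides)] <- overrides
  numeric_fields <- setdiff(names(p), "genotype")
  vals <- unlist(p[numeric_fields])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("all kinetic rates, constants and scale factors must be finite and >= 0")
  }
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> genotype %s\n", x$genotype))
  flds <- setdiff(names(x), "genotype")
  cat(paste0(
    "  ", format(flds), " = ",
    vapply(x[flds], function(v) format(v), character(1)), "\n"
  ), sep = "")
  invisible(x)
}

#' FRET glucose sensor response parameters
#'
#' The biosensor's YFP/CFP ratio follows a single-site binding curve of
#' intracellular glucose, `R(G) = r_min + (r_max - r_min) * G / (k_d + G)`.
#' The half-saturation default of 0.7 mM follows the nominal affinity of the
#' "700"-series sensor; `r_min`/`r_max` are arbitrary positive defaults since
#' only baseline-relative ratios enter downstream analyses.
#'
#' @param k_d Half-saturation glucose concentration in mM.
#' @param r_min,r_max Ratio bounds at zero and saturating glucose; must
#'   satisfy `r_max > r_min > 0`.
#' @param config_file Optional path to an alternative YAML config supplying
#'   the defaults.
#' @return An object of class `sensor_params`.
#' @export
sensor_params <- function(k_d = NULL, r_min = NULL, r_max = NULL,
                          config_file = NULL) {
  if (is.null(config_file)) {
    config_file <- system.file("extdata", "kinetic_defaults.yaml",
      package = "glucofret"
    )
  }
  cfg <- yaml::read_yaml(config_file)$sensor
  k_d <- k_d %||% cfg$k_d
  r_min <- r_min %||% cfg$r_min
  r_max <- r_max %||% cfg$r_max
  if (!(r_max > r_min && r_min > 0)) abort("need r_max > r_min > 0")
  if (k_d <= 0) abort("k_d must be > 0")
  structure(list(k_d = k_d, r_min = r_min, r_max = r_max),
    class = "sensor_params"
  )
}

#' Sensor ratio as a function of glucose
#'
#' @param g Intracellular glucose in mM (vectorized, must be >= 0).
#' @param sensor A [sensor_params()] object.
#' @return Dimensionless YFP/CFP ratio, monotone increasing in `g`, bounded
#'   in `[r_min, r_max)`.
#' @export
#' @examples
#' s <- sensor_params()
#' sensor_ratio(c(0, s$k_d), s) # r_min and the midpoint
sensor_ratio <- function(g, sensor = sensor_params()) {
  stopifnot(inherits(sensor, "sensor_params"))
  if (any(g < 0)) abort("glucose concentration must be >= 0")
  sensor$r_min + (sensor$r_max - sensor$r_min) * g / (sensor$k_d + g)
}

#' Resting steady-state intracellular glucose
#'
#' Solves the transport/consumption balance at a fixed extracellular glucose
#' concentration (no inhibitors). Used as the default initial condition so
#' simulated baselines are flat.
#'
#' @param params A [kinetic_params()] object.
#' @param glucose_ext Extracellular glucose in mM.
#' @return Steady-state intracellular glucose in mM.
#' @export
steady_state_glucose <- function(params, glucose_ext = 2.5) {
  stopifnot(inherits(params, "kinetic_params"))
  consumption <- params$v_glycolysis * params$glycolysis_scale +
    params$v_ppp * params$ppp_scale
  flux <- function(g) {
    params$v_transport * (glucose_ext / (params$k_transport + glucose_ext) -
      g / (params$k_transport + g)) -
      consumption * g / (params$k_consume + g)
  }
  if (consumption == 0) {
    return(glucose_ext) # pure transport equilibrates at Gext
  }
  if (glucose_ext == 0 || flux(1e-12) <= 0) {
    return(0)
  }
  uniroot(flux, c(1e-12, glucose_ext), tol = 1e-12)$root
}

#' Simulate intracellular glucose under a superfusion protocol
#'
#' Integrates the transport/consumption model (see [kinetic_params()]) with a
#' fixed-step fourth-order Runge-Kutta scheme at a 1 s internal step and
#' resamples the solution on the protocol's imaging grid. The fixed step
#' keeps the trajectory deterministic; the rates involved are far from stiff
#' at these time scales.
#'
#' @param params A [kinetic_params()] object.
#' @param protocol A [protocol()] object.
#' @param g0 Initial intracellular glucose in mM. Defaults to the resting
#'   steady state under the baseline condition.
#' @param internal_dt_s Internal integration step in seconds (default 1).
#' @return A tibble with columns `time_min` and `glucose_mM`; glucose is
#'   non-negative throughout.
#' @export
#' @examples
#' p <- make_paper_protocols()$restriction
#' g <- simulate_glucose(kinetic_params("nonTg"), p)
#' head(g)
simulate_glucose <- function(params, protocol, g0 = NULL, internal_dt_s = 1) {
  stopifnot(inherits(params, "kinetic_params"), inherits(protocol, "fret_protocol"))
  if (is.null(g0)) g0 <- steady_state_glucose(params, protocol$events$glucose_mM[1])
  if (length(g0) != 1 || !is.finite(g0) || g0 < 0) abort("`g0` must be a finite scalar >= 0")

  dt <- internal_dt_s / 60
  t_iaa <- protocol_onset(protocol, "iaa")
  t_6an <- protocol_onset(protocol, "six_an")
  ev_t <- protocol$events$time_min
  ev_g <- protocol$events$glucose_mM

  deriv <- function(tt, g) {
    gext <- ev_g[max(1L, findInterval(tt, ev_t))]
    gate <- if (tt >= t_iaa) exp(-(tt - t_iaa) / params$tau_hk_inhibition) else 1
    hbp <- if (tt >= t_iaa) {
      params$v_hbp_max * params$hbp_transient_scale *
        exp(-(tt - t_iaa) / params$tau_hbp_transient)
    } else {
      0
    }
    ppp <- if (tt >= t_6an) 0 else params$v_ppp * params$ppp_scale
    consumption <- gate * (params$v_glycolysis * params$glycolysis_scale + ppp + hbp)
    params$v_transport * (gext / (params$k_transport + gext) -
      g / (params$k_transport + g)) -
      consumption * g / (params$k_consume + g)
  }

  n_steps <- ceiling(protocol$duration_min / dt)
  t_grid <- seq(0, by = dt, length.out = n_steps + 1)
  g <- numeric(n_steps + 1)
  g[1] <- g0
  for (i in seq_len(n_steps)) {
    tt <- t_grid[i]
    gi <- g[i]
    k1 <- deriv(tt, gi)
    k2 <- deriv(tt + dt / 2, gi + dt / 2 * k1)
    k3 <- deriv(tt + dt / 2, gi + dt / 2 * k2)
    k4 <- deriv(tt + dt, gi + dt * k3)
    g[i + 1] <- max(0, gi + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
  }
  if (any(!is.finite(g))) {
    abort("glucose integration produced non-finite values; check parameters")
  }
  out_t <- protocol_times(protocol)
  tibble(
    time_min = out_t,
    glucose_mM = approx(t_grid, g, xout = pmin(out_t, max(t_grid)))$y
  )
}

#' Simulate a ground-truth sensor ratio trace
#'
#' Convenience wrapper: integrates the glucose model and maps the
#' concentration series through the sensor response.
#'
#' @inheritParams simulate_glucose
#' @param sensor A [sensor_params()] object.
#' @param cell_id Identifier attached to the output trace.
#' @return A tibble with columns `cell_id`, `time_min`, `ratio`.
#' @export
simulate_ratio_trace <- function(params, protocol, sensor = sensor_params(),
                                 g0 = NULL, cell_id = "cell_1") {
  g <- simulate_glucose(params, protocol, g0 = g0)
  tibble(
    cell_id = cell_id,
    time_min = g$time_min,
    ratio = sensor_ratio(g$glucose_mM, sensor)
  )
}

#' @importFrom stats approx
NULL
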