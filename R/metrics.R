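#' Volume waveform from a flow waveform
#'
#' Integrates midpoint flows over the cycle (rectangle rule) to the
#' cumulative regional volume above the end-expiratory baseline: knots at
#' t = 0, dt, ..., period with V(0) = 0, shifted so the minimum is zero.
#'
#' @param flow numeric vector of flows (uL/s) at interval midpoints
#' @param protocol a [ventilation_protocol()]
#' @return list of class `volume_waveform`: `times` (s), `v` (uL)
#' @export
volume_waveform <- function(flow, protocol) {
  if (length(flow) != protocol$n_frames)
    stop("need one flow value per frame interval")
  dt <- protocol$period / protocol$n_frames
  v <- c(0, cumsum(flow * dt))
  v <- v - min(v)
  structure(list(times = c(frame_times(protocol), protocol$period), v = v),
            class = "volume_waveform")
}

#' Tidal volume of a volume waveform
#'
#' The volume moved per breath: max minus min of the regional volume
#' waveform. Zero for a non-ventilated (e.g. obstructed) region.
#'
#' @param vol a `volume_waveform`
#' @return tidal volume (uL)
#' @export
tidal_volume <- function(vol) max(vol$v) - min(vol$v)

#' Peak expiratory flow
#'
#' Maximum magnitude of outward (negative) flow during the expiration
#' window `(t_insp, period]`, returned as a positive number; 0 (flagged)
#' when no outward flow occurs.
#'
#' @param flow numeric vector of flows (uL/s) at interval midpoints
#' @param protocol a [ventilation_protocol()]
#' @return PEF (uL/s) with attribute `flagged`
#' @export
peak_expiratory_flow <- function(flow, protocol) {
  tm <- interval_midpoints(protocol)
  win <- tm > protocol$t_insp
  neg <- -flow[win]
  pef <- max(c(neg, 0))
  structure(max(pef, 0), flagged = pef <= 0)
}

#' Expiratory time constant of a volume waveform
#'
#' The time after expiration onset at which the expelled volume reaches
#' `threshold` (default the exact 1 - 1/e, approximately 63.2 percent) of
#' the tidal volume. Expiration onset is the waveform maximum (nominally
#' the end of inspiration); the crossing is located by linear interpolation
#' between volume knots. For a region emptying as a single exponential with
#' time constant tau = RC, the crossing time equals tau. If the threshold
#' is not reached by the end of the cycle the estimate is censored at
#' `t_exp` and flagged.
#'
#' @param vol a `volume_waveform` (any knot times are accepted)
#' @param protocol a [ventilation_protocol()]
#' @param threshold expelled fraction of tidal volume defining the time
#'   constant (default `1 - exp(-1)`)
#' @return tau_exp (s) with attributes `censored` and `flagged`
#' @export
expiratory_time_constant <- function(vol, protocol, threshold = 1 - exp(-1)) {
  tv <- tidal_volume(vol)
  if (!is.finite(tv) || tv <= 0)
    return(structure(NA_real_, censored = FALSE, flagged = TRUE))
  i0 <- which.max(vol$v)
  t0 <- vol$times[i0]
  target <- vol$v[i0] - threshold * tv
  if (i0 < length(vol$v)) {
    for (i in (i0 + 1):length(vol$v)) {
      if (vol$v[i] <= target) {
        v1 <- vol$v[i - 1]; v2 <- vol$v[i]
        t1 <- vol$times[i - 1]; t2 <- vol$times[i]
        tc <- t1 + (v1 - target) / (v1 - v2) * (t2 - t1)
        return(structure(tc - t0, censored = FALSE, flagged = FALSE))
      }
    }
  }
  structure(protocol$t_exp, censored = TRUE, flagged = TRUE)
}

#' Global expiratory time constant
#'
#' The expiratory time constant of the whole lung: the trachea's volume
#' waveform (the sum of all regional waveforms) analysed exactly like a
#' regional one.
#'
#' @param trachea_vol `volume_waveform` of the trachea (root segment)
#' @param protocol a [ventilation_protocol()]
#' @param threshold see [expiratory_time_constant()]
#' @return tau_exp (s)
#' @export
global_time_constant <- function(trachea_vol, protocol,
                                 threshold = 1 - exp(-1)) {
  expiratory_time_constant(trachea_vol, protocol, threshold)
}

#' Per-endpoint function metrics table
#'
#' Derives, for every endpoint: tidal volume (TV), peak expiratory flow
#' (PEF), expiratory time constant (tau_exp), supplied tissue volume at end
#' expiration (V_ee), and the normalized forms used for cohort analysis -
#' `pef_norm = PEF / TV` (1/s) and `tv_norm = TV / V_ee`. Endpoints with a
#' missing waveform get NA metrics and a flag; non-ventilated endpoints
#' (TV = 0) are flagged.
#'
#' @param flows a `flow_set` of endpoint waveforms
#' @param v_ee supplied tissue volume at end expiration per endpoint (uL),
#'   e.g. `assignment$volumes`
#' @param protocol a [ventilation_protocol()]
#' @return data frame (one row per endpoint): `endpoint_id`, `tv`, `pef`,
#'   `tau_exp`, `v_ee`, `pef_norm`, `tv_norm`, `censored`, `nonventilated`,
#'   `missing`
#' @export
endpoint_metrics_table <- function(flows, v_ee, protocol) {
  n <- nrow(flows$flows)
  stopifnot(length(v_ee) == n)
  out <- data.frame(endpoint_id = flows$endpoint_ids,
                    tv = NA_real_, pef = NA_real_, tau_exp = NA_real_,
                    v_ee = v_ee, pef_norm = NA_real_, tv_norm = NA_real_,
                    censored = FALSE, nonventilated = FALSE,
                    missing = flows$missing)
  for (i in seq_len(n)) {
    if (flows$missing[i]) next
    fl <- flows$flows[i, ]
    vw <- volume_waveform(fl, protocol)
    tv <- tidal_volume(vw)
    pef <- peak_expiratory_flow(fl, protocol)
    tau <- expiratory_time_constant(vw, protocol)
    out$tv[i] <- tv
    out$pef[i] <- as.numeric(pef)
    out$tau_exp[i] <- as.numeric(tau)
    out$censored[i] <- isTRUE(attr(tau, "censored"))
    out$nonventilated[i] <- tv <= 0
    if (tv > 0) out$pef_norm[i] <- as.numeric(pef) / tv
    if (tv > 0 && v_ee[i] > 0) out$tv_norm[i] <- tv / v_ee[i]
  }
  out
}
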