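#' Pressure-controlled ventilation protocol
#'
#' Describes the square-wave pressure-controlled ventilation cycle used both
#' by the synthetic phantom and by the timing of the analysis: peak
#' inspiratory pressure (PIP), positive end-expiratory pressure (PEEP),
#' cycle period, inspiration/expiration split and the number of image frames
#' acquired per cycle. Defaults correspond to small-animal pressure-controlled
#' ventilation at 12/2 cmH2O and 133 breaths per minute (0.45 s cycle with
#' 0.15 s inspiration and 0.30 s expiration) imaged at 16 frames per cycle.
#'
#' @param pip peak inspiratory pressure (cmH2O)
#' @param peep positive end-expiratory pressure (cmH2O)
#' @param period respiratory cycle duration (s)
#' @param t_insp inspiration time (s)
#' @param t_exp expiration time (s); `t_insp + t_exp` must equal `period`
#' @param n_frames number of image frames per cycle (>= 4)
#' @return an object of class `ventilation_protocol`
#' @examples
#' p <- ventilation_protocol()
#' frame_times(p)
#' @export
ventilation_protocol <- function(pip = 12, peep = 2, period = 0.45,
                                 t_insp = 0.15, t_exp = 0.30, n_frames = 16L) {
  if (pip <= peep) stop("pip must exceed peep")
  if (abs(t_insp + t_exp - period) > 1e-9)
    stop("t_insp + t_exp must equal period")
  if (t_insp <= 0 || t_exp <= 0) stop("phase durations must be positive")
  n_frames <- as.integer(n_frames)
  if (n_frames < 4L) stop("n_frames must be at least 4")
  structure(list(pip = pip, peep = peep, period = period,
                 t_insp = t_insp, t_exp = t_exp, n_frames = n_frames),
            class = "ventilation_protocol")
}

#' @export
print.ventilation_protocol <- function(x, ...) {
  cat(sprintf(
    "Ventilation protocol: %g/%g cmH2O, period %g s (insp %g s / exp %g s), %d frames/cycle\n",
    x$pip, x$peep, x$period, x$t_insp, x$t_exp, x$n_frames))
  invisible(x)
}

#' Frame acquisition times of a protocol
#'
#' Frames are acquired at equal spacing across the cycle, the first frame at
#' t = 0 (end expiration, the reference state).
#'
#' @param protocol a [ventilation_protocol()]
#' @return numeric vector of `n_frames` times in seconds
#' @export
frame_times <- function(protocol) {
  dt <- protocol$period / protocol$n_frames
  (seq_len(protocol$n_frames) - 1) * dt
}

#' Frame-interval midpoint times
#'
#' Displacement between successive frames (including the cyclic pair last
#' frame -> first frame) is attributed to the midpoint of each interval;
#' flow waveforms are indexed to these times.
#'
#' @param protocol a [ventilation_protocol()]
#' @return numeric vector of `n_frames` midpoint times in seconds
#' @export
interval_midpoints <- function(protocol) {
  dt <- protocol$period / protocol$n_frames
  (seq_len(protocol$n_frames) - 0.5) * dt
}

#' Airway pressure waveform
#'
#' Ideal square wave: PIP during inspiration, PEEP during expiration,
#' periodic with the cycle.
#'
#' @param protocol a [ventilation_protocol()]
#' @param t time or vector of times (s)
#' @return pressures (cmH2O)
#' @export
airway_pressure <- function(protocol, t) {
  tm <- t %% protocol$period
  ifelse(tm < protocol$t_insp, protocol$pip, protocol$peep)
}
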