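#' Disease configuration for the synthetic lung
#'
#' Describes how regional mechanics are drawn for a synthetic subject.
#' Every terminal airway (endpoint) supplies a single-compartment region
#' whose expiratory time constant tau = R*C is drawn from a healthy normal
#' distribution; endpoints supplying `diseased_volume_fraction` of the total
#' resting volume draw tau from the diseased distribution instead, and
#' `blockage_fraction` of endpoints are fully obstructed (zero flow).
#' Defaults emulate a homogeneous healthy population (mean 0.12 s,
#' sd 0.022 s) with a slower diseased mode at 0.22 s (sd 0.037 s), the
#' regime observed in muco-obstructive transgenic mice.
#'
#' @param diseased_volume_fraction fraction of total resting volume supplied
#'   by endpoints drawing from the diseased tau distribution, in `[0, 1]`
#' @param healthy_tau_mean,healthy_tau_sd healthy tau distribution (s)
#' @param diseased_tau_mean,diseased_tau_sd diseased tau distribution (s)
#' @param blockage_fraction fraction of endpoints fully obstructed (zero
#'   flow), in `[0, 1]`; obstructed endpoints are drawn from the diseased
#'   region first (mucus plugs form in diseased lobes), spilling into
#'   healthy endpoints only beyond the diseased fraction
#' @param seed integer seed controlling all draws
#' @return an object of class `disease_config`
#' @export
disease_config <- function(diseased_volume_fraction = 0,
                           healthy_tau_mean = 0.12, healthy_tau_sd = 0.022,
                           diseased_tau_mean = 0.22, diseased_tau_sd = 0.037,
                           blockage_fraction = 0, seed = 1L) {
  stopifnot(diseased_volume_fraction >= 0, diseased_volume_fraction <= 1,
            blockage_fraction >= 0, blockage_fraction <= 1,
            healthy_tau_mean > 0, healthy_tau_sd >= 0,
            diseased_tau_mean > 0, diseased_tau_sd >= 0)
  structure(list(diseased_volume_fraction = diseased_volume_fraction,
                 healthy_tau_mean = healthy_tau_mean,
                 healthy_tau_sd = healthy_tau_sd,
                 diseased_tau_mean = diseased_tau_mean,
                 diseased_tau_sd = diseased_tau_sd,
                 blockage_fraction = blockage_fraction,
                 seed = as.integer(seed)),
            class = "disease_config")
}

#' Periodic steady state of a single RC compartment
#'
#' Solves dV/dt = (P_aw(t) - V/C) / R for a square-wave airway pressure
#' between PIP and PEEP in closed form (piecewise exponential), returning the
#' periodic steady-state cycle. Volumes are absolute regional volumes with
#' `rest_volume` the volume at end expiration (t = 0).
#'
#' @param R airflow resistance (cmH2O s / uL), positive
#' @param C compliance (uL / cmH2O), positive
#' @param protocol a [ventilation_protocol()]
#' @param rest_volume regional volume at end expiration (uL)
#' @return list with vectorized functions `V(t)` (uL) and `Q(t)` (uL/s,
#'   inspiratory positive), the time constant `tau`, and the steady-state
#'   tidal volume `tidal_volume`
#' @export
compartment_steady_state <- function(R, C, protocol, rest_volume = 0) {
  if (R <= 0 || C <= 0) stop("R and C must be positive")
  tau <- R * C
  ti <- protocol$t_insp; te <- protocol$t_exp; T <- protocol$period
  vi <- C * protocol$pip   # elastic equilibrium volumes (above recoil zero)
  ve <- C * protocol$peep
  E1 <- exp(-ti / tau); E2 <- exp(-te / tau)
  # periodicity: v0 at start of inspiration equals v at end of expiration
  v0 <- (ve * (1 - E2) + vi * E2 * (1 - E1)) / (1 - E1 * E2)
  v1 <- vi + (v0 - vi) * E1
  vfun <- function(t) {
    tm <- t %% T
    ifelse(tm < ti,
           vi + (v0 - vi) * exp(-tm / tau),
           ve + (v1 - ve) * exp(-(tm - ti) / tau))
  }
  list(
    V = function(t) rest_volume + vfun(t) - v0,
    Q = function(t) (airway_pressure(protocol, t) - vfun(t) / C) / R,
    tau = tau,
    tidal_volume = v1 - v0,
    v0 = v0, v1 = v1
  )
}

#' Simulate regional mechanics for every endpoint of an airway tree
#'
#' Attaches one single-compartment model to each endpoint of `tree`, draws
#' expiratory time constants according to `disease`, and evaluates the
#' periodic steady-state flow and volume waveforms on the protocol's frame
#' grid. Compliance is set proportional to resting volume
#' (`compliance_per_volume`, with log-normal jitter so that normalized tidal
#' volume varies between endpoints as it does between real lung regions) and
#' resistance follows from R = tau / C.
#'
#' @param tree an `airway_tree`
#' @param protocol a [ventilation_protocol()]
#' @param disease a [disease_config()]
#' @param rest_volumes optional vector of resting (end-expiratory) regional
#'   volumes (uL), one per endpoint in [find_endpoints()] order; default
#'   equal shares of `total_rest_volume`
#' @param total_rest_volume total resting volume (uL) when `rest_volumes`
#'   is not given
#' @param compliance_per_volume compliance per unit resting volume
#'   (uL/cmH2O per uL); the default gives a tidal fraction of about 8
#'   percent at healthy time constants
#' @param compliance_jitter sd of log-normal jitter on compliance
#' @return list with elements `compartments` (data frame: endpoint_id, R, C,
#'   tau, obstructed, diseased, rest_volume, cx, cy, cz), `flows` (endpoints
#'   x n_frames matrix, uL/s at interval midpoints), `volumes` (endpoints x
#'   n_frames+1 matrix, uL at knot times 0..period), `times_mid`,
#'   `times_knots`, and `frame_volumes` (total volume at knot times)
#' @export
simulate_compartments <- function(tree, protocol, disease = disease_config(),
                                  rest_volumes = NULL,
                                  total_rest_volume = 500,
                                  compliance_per_volume = 0.012,
                                  compliance_jitter = 0.15) {
  eps <- find_endpoints(tree)
  n <- length(eps)
  if (n < 1) stop("tree has no endpoints")
  if (is.null(rest_volumes)) rest_volumes <- rep(total_rest_volume / n, n)
  if (length(rest_volumes) != n) stop("need one rest volume per endpoint")
  if (any(rest_volumes <= 0)) stop("rest volumes must be positive")

  draws <- with_seed(disease$seed, {
    tau_h <- pmax(stats::rnorm(n, disease$healthy_tau_mean, disease$healthy_tau_sd), 0.02)
    tau_d <- pmax(stats::rnorm(n, disease$diseased_tau_mean, disease$diseased_tau_sd), 0.02)
    jit <- exp(stats::rnorm(n, 0, compliance_jitter))
    ord <- sample.int(n)
    ord2 <- sample.int(n)
    list(tau_h = tau_h, tau_d = tau_d, jit = jit, ord = ord, ord2 = ord2)
  })

  # mark endpoints as diseased, in random order, until they supply the
  # requested fraction of total resting volume (closest achievable)
  diseased <- rep(FALSE, n)
  if (disease$diseased_volume_fraction > 0) {
    target <- disease$diseased_volume_fraction * sum(rest_volumes)
    acc <- 0
    for (i in draws$ord) {
      new_acc <- acc + rest_volumes[i]
      if (abs(new_acc - target) <= abs(acc - target)) {
        diseased[i] <- TRUE
        acc <- new_acc
      }
      if (acc >= target) break
    }
  }
  tau <- ifelse(diseased, draws$tau_d, draws$tau_h)
  # mucus plugs form in the diseased region: obstructed endpoints are drawn
  # diseased-first (random within each stratum), spilling over to healthy
  # endpoints only if the blockage fraction exceeds the diseased fraction
  n_block <- round(disease$blockage_fraction * n)
  pick_order <- c(draws$ord2[diseased[draws$ord2]], draws$ord2[!diseased[draws$ord2]])
  obstructed <- seq_len(n) %in% pick_order[seq_len(n_block)]

  C <- compliance_per_volume * rest_volumes * draws$jit
  R <- tau / C

  tips <- t(vapply(eps, function(s) segment_tip(tree, s), numeric(3)))
  tm <- interval_midpoints(protocol)
  tk <- c(frame_times(protocol), protocol$period)
  flows <- matrix(0, n, protocol$n_frames)
  vols <- matrix(0, n, protocol$n_frames + 1L)
  for (i in seq_len(n)) {
    if (obstructed[i]) {
      vols[i, ] <- rest_volumes[i]
    } else {
      ss <- compartment_steady_state(R[i], C[i], protocol, rest_volumes[i])
      flows[i, ] <- ss$Q(tm)
      vols[i, ] <- ss$V(tk)
    }
  }
  comp <- data.frame(endpoint_id = eps, R = R, C = C, tau = tau,
                     obstructed = obstructed, diseased = diseased,
                     rest_volume = rest_volumes,
                     cx = tips[, 1], cy = tips[, 2], cz = tips[, 3])
  list(compartments = comp, flows = flows, volumes = vols,
       times_mid = tm, times_knots = tk,
       frame_volumes = colSums(vols))
}
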