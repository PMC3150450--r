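#' Mechanistic phage-host parameters
#'
#' Parameters of the within-day lytic infection model: logistic host growth
#' to a nutrient-limited plateau, mass-action adsorption, an Erlang-staged
#' latent period, and burst. Defaults describe the ancestral pairing of the
#' emulated system: specific growth rate 0.382 per hour, stationary plateau
#' 3e8 CFU/ml (OD600 0.4), adsorption rate constant 1.4e-9 ml/cells/min,
#' one-hour latent period realised as 5 sequential stages, and a burst size
#' calibrated so that a phage-only passage at MOI 0.5 amplifies about
#' 1,000-fold in 6 h (see [tune_burst_size()]).
#'
#' @param mu specific growth rate, per hour.
#' @param carrying_capacity stationary cell density, cells/ml.
#' @param od_per_cell OD600 units per (cells/ml); default 0.4 / 3e8.
#' @param k_ads adsorption rate constant, ml/cells/min (converted to
#'   per-hour internally).
#' @param latent_period latent period in hours, realised as `n_latent`
#'   sequential stages (per-stage rate `n_latent / latent_period`).
#' @param n_latent number of latent stages (Erlang shape).
#' @param burst_size phage released per lysed cell (>= 1).
#' @param resistance_factor multiplicative reduction of `k_ads` for a
#'   partially resistant host, in (0, 1].
#' @param stationary_refractory logical; when `TRUE`, cells at the
#'   stationary plateau (total cells >= 95% of `carrying_capacity`) no
#'   longer adsorb phage.
#' @return A list of class `phage_host_params`.
#' @export
phage_host_params <- function(mu = 0.382,
                              carrying_capacity = 3e8,
                              od_per_cell = 0.4 / 3e8,
                              k_ads = 1.4e-9,
                              latent_period = 1,
                              n_latent = 5L,
                              burst_size = 416,
                              resistance_factor = 1,
                              stationary_refractory = TRUE) {
  if (any(c(mu, carrying_capacity, od_per_cell, k_ads, latent_period) < 0)) {
    coevo_stop("rates and capacities must be >= 0", "coevo_parameter_error")
  }
  if (burst_size < 1) coevo_stop("burst_size must be >= 1", "coevo_parameter_error")
  if (resistance_factor <= 0 || resistance_factor > 1) {
    coevo_stop("resistance_factor must be in (0, 1]", "coevo_parameter_error")
  }
  structure(
    list(mu = mu, carrying_capacity = carrying_capacity,
         od_per_cell = od_per_cell, k_ads = k_ads,
         latent_period = latent_period, n_latent = as.integer(n_latent),
         lysis_rate = n_latent / latent_period,
         burst_size = burst_size, resistance_factor = resistance_factor,
         stationary_refractory = stationary_refractory),
    class = "phage_host_params"
  )
}

#' Serial-passage protocol
#'
#' @param regime `"copropagation"` (cells and phage transferred together,
#'   about 24 h per passage, diluted to a target OD) or `"phage_only"`
#'   (phage filtered from the culture daily and used to infect fresh
#'   ancestral cells, about 6 h per passage).
#' @param duration passage duration, hours.
#' @param dilution_rule `"to_target_od"` (dilute so the next passage starts
#'   at `target` OD600) or `"fixed_factor"` (dilute by `target`-fold).
#' @param target target OD (default 0.05) or fold factor.
#' @param initial_cells starting cell density, CFU/ml.
#' @param initial_phage starting free-phage density, PFU/ml (phage-only
#'   regime re-infects to this density daily).
#' @return A list of class `passage_protocol`.
#' @export
passage_protocol <- function(regime = c("copropagation", "phage_only"),
                             duration = if (regime == "phage_only") 6 else 24,
                             dilution_rule = c("to_target_od", "fixed_factor"),
                             target = 0.05,
                             initial_cells = 1e7,
                             initial_phage = 1.5e7) {
  regime <- match.arg(regime)
  dilution_rule <- match.arg(dilution_rule)
  if (duration <= 0) coevo_stop("duration must be > 0", "coevo_parameter_error")
  if (target <= 0) coevo_stop("dilution target must be > 0", "coevo_parameter_error")
  structure(
    list(regime = regime, duration = duration, dilution_rule = dilution_rule,
         target = target, initial_cells = initial_cells,
         initial_phage = initial_phage),
    class = "passage_protocol"
  )
}

# per-hour adsorption constant, including partial resistance
k_per_hour <- function(params) params$k_ads * 60 * params$resistance_factor

sim_rhs <- function(t, state, params) {
  S <- state[1L]
  E <- state[2:(1L + params$n_latent)]
  P <- state[length(state)]
  I <- sum(E)
  K <- params$carrying_capacity
  refractory <- params$stationary_refractory && (S + I) >= 0.95 * K
  ads <- if (refractory) 0 else k_per_hour(params) * S * P
  growth <- params$mu * S * (1 - (S + I) / K)
  delta <- params$lysis_rate
  dE <- delta * c(ads / delta - E[1L],
                  if (params$n_latent > 1L) E[-params$n_latent] - E[-1L])
  # written so that dE1 = ads - delta*E1 and dEi = delta*(E[i-1] - E[i])
  dS <- growth - ads
  dP <- params$burst_size * delta * E[params$n_latent] - ads
  list(c(dS, dE, dP))
}

sim_day_deterministic <- function(params, state, duration, grid) {
  times <- seq(0, duration, by = grid)
  # lsoda: the adsorption term k*S*P turns stiff once hosts are exhausted
  # at high phage density, where an explicit fixed-step scheme blows up
  out <- deSolve::ode(y = state, times = times, func = sim_rhs,
                      parms = params, method = "lsoda",
                      rtol = 1e-9, atol = 1e-4)
  if (any(!is.finite(out[, -1L]))) {
    bad <- which(!complete.cases(is.finite(out[, -1L])))[1L]
    coevo_stop(sprintf("non-finite state at t = %.3f h", out[bad, 1L]),
               "coevo_integration_error")
  }
  out[, -1L][out[, -1L] < 0] <- 0  # clip integrator undershoot at zero
  out
}

sim_day_stochastic <- function(params, state, duration, grid, volume_ml) {
  n_steps <- ceiling(duration / grid)
  nE <- params$n_latent
  counts <- round(state * volume_ml)
  out <- matrix(0, n_steps + 1L, length(state) + 1L)
  out[1L, ] <- c(0, counts / volume_ml)
  delta <- params$lysis_rate
  kh <- k_per_hour(params) / volume_ml  # per (count x count) per hour
  K_count <- params$carrying_capacity * volume_ml
  for (step in seq_len(n_steps)) {
    S <- counts[1L]; E <- counts[2:(1L + nE)]; P <- counts[length(counts)]
    I <- sum(E)
    refractory <- params$stationary_refractory && (S + I) >= 0.95 * K_count
    ads_rate <- if (refractory) 0 else kh * S * P
    growth_rate <- max(0, params$mu * S * (1 - (S + I) / K_count))
    births <- rpois(1L, growth_rate * grid)
    ads <- min(rpois(1L, ads_rate * grid), S, P)
    stage <- rpois(nE, delta * E * grid)
    stage <- pmin(stage, E)
    S <- S + births - ads
    Enew <- E
    Enew[1L] <- E[1L] + ads - stage[1L]
    if (nE > 1L) {
      for (i in 2:nE) Enew[i] <- E[i] + stage[i - 1L] - stage[i]
    }
    P <- P - ads + round(params$burst_size) * stage[nE]
    counts <- pmax(c(S, Enew, P), 0)
    out[step + 1L, ] <- c(step * grid, counts / volume_ml)
  }
  colnames(out) <- c("time", names(state))
  out
}

state_names <- function(n_latent) c("S", paste0("E", seq_len(n_latent)), "P")

#' Simulate one day of lytic copropagation
#'
#' Integrates susceptible cells S, staged infected cells E1..En, and free
#' phage P:
#' \deqn{dS/dt = \mu S (1 - (S+I)/K) - k S P,\quad
#'       dE_1/dt = k S P - \delta E_1,\quad
#'       dE_i/dt = \delta (E_{i-1} - E_i),\quad
#'       dP/dt = b \delta E_n - k S P}
#' with `I = sum(E_i)`, adsorption constant `k` converted to per-hour and
#' optionally shut off once total cells reach the stationary plateau.
#' Deterministic mode is fixed-step RK4; stochastic mode is a seeded
#' tau-leap of the same rates on particle counts in `volume_ml`.
#'
#' @param params a [phage_host_params()].
#' @param protocol a [passage_protocol()] supplying initial densities and
#'   duration (overridable via `duration`).
#' @param grid time step in hours (<= 0.1).
#' @param seed integer seed; `NULL` selects the deterministic integrator.
#' @param duration hours; defaults to `protocol$duration`.
#' @param volume_ml culture volume for the stochastic mode.
#' @return A list of class `within_day_sim`: `time_courses` (named list of
#'   [time_course()] objects: `free_phage`, `infected_cells`,
#'   `total_cells`, `od600`), `final_state`, and the raw trajectory.
#' @export
simulate_within_day <- function(params, protocol, grid = 0.01, seed = NULL,
                                duration = protocol$duration, volume_ml = 3) {
  if (grid > 0.1) coevo_stop("grid must be <= 0.1 h", "coevo_parameter_error")
  state <- c(protocol$initial_cells, rep(0, params$n_latent),
             protocol$initial_phage)
  names(state) <- state_names(params$n_latent)
  traj <- sim_state_run(params, state, duration, grid, seed, volume_ml)
  list_out <- traj_to_time_courses(traj, params)
  structure(
    list(time_courses = list_out,
         final_state = traj[nrow(traj), -1L],
         trajectory = traj),
    class = "within_day_sim"
  )
}

sim_state_run <- function(params, state, duration, grid, seed, volume_ml) {
  if (is.null(seed)) {
    sim_day_deterministic(params, state, duration, grid)
  } else {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
    sim_day_stochastic(params, state, duration, grid, volume_ml)
  }
}

traj_to_time_courses <- function(traj, params) {
  nE <- params$n_latent
  t <- traj[, 1L]
  S <- traj[, 2L]
  I <- if (nE == 1L) traj[, 3L] else rowSums(traj[, 3:(2L + nE)])
  P <- traj[, ncol(traj)]
  list(
    free_phage = time_course("free_phage", t, P),
    infected_cells = time_course("infected_cells", t, I),
    total_cells = time_course("total_cells", t, S + I),
    od600 = time_course("od600", t, (S + I) * params$od_per_cell)
  )
}

#' Run a serial-passage experiment
#'
#' Repeats [simulate_within_day()] day after day under a
#' [passage_protocol()]. In the copropagation regime the whole culture
#' (cells, infected cells, phage) is diluted into fresh medium; in the
#' phage-only regime the phage are separated from the culture, diluted to
#' the protocol's initial titre, and used to infect fresh ancestral cells.
#' The initial density of day `d+1` equals the final density of day `d`
#' divided by that day's dilution factor. A population falling below one
#' particle per culture volume is reported as an extinction event, not an
#' error.
#'
#' @param params a [phage_host_params()].
#' @param protocol a [passage_protocol()].
#' @param days number of passages (>= 1).
#' @param seed integer seed for the stochastic integrator; `NULL` for the
#'   deterministic one. Day `d` uses `seed + d - 1`.
#' @param grid time step, hours.
#' @param volume_ml culture volume.
#' @param keep_time_courses store the within-day series of every day.
#' @return A list of class `serial_passage_sim`: `records` (a
#'   `passage_record` tibble), `events` (tibble `day_index`, `entity` for
#'   extinctions), `phage_generations` (the simulator's own cumulative
#'   log2 amplification counter), and optionally `time_courses`.
#' @export
run_serial_passages <- function(params, protocol, days, seed = NULL,
                                grid = 0.01, volume_ml = 3,
                                keep_time_courses = FALSE) {
  if (days < 1L) coevo_stop("days must be >= 1", "coevo_parameter_error")
  nE <- params$n_latent
  state <- c(protocol$initial_cells, rep(0, nE), protocol$initial_phage)
  names(state) <- state_names(nE)
  records <- vector("list", days)
  events <- list()
  tcs <- if (keep_time_courses) vector("list", days) else NULL
  gen_counter <- 0
  prev_dilution <- 2  # nominal for day 1 (records require > 1)
  for (d in seq_len(days)) {
    day_seed <- if (is.null(seed)) NULL else seed + d - 1L
    traj <- sim_state_run(params, state, protocol$duration, grid, day_seed,
                          volume_ml)
    final <- traj[nrow(traj), -1L]
    S0 <- state[1L]; I0 <- sum(state[2:(1L + nE)]); P0 <- state[length(state)]
    S1 <- final[1L]; I1 <- sum(final[2:(1L + nE)]); P1 <- final[length(final)]
    records[[d]] <- tibble::tibble(
      day_index = d, lineage_id = "sim", regime = protocol$regime,
      n_i_phage = unname(P0), n_f_phage = unname(P1),
      n_i_cell = unname(S0 + I0), n_f_cell = unname(S1 + I1),
      dilution_factor = prev_dilution, duration = protocol$duration
    )
    if (keep_time_courses) tcs[[d]] <- traj_to_time_courses(traj, params)
    if (P0 > 0 && P1 > 0) gen_counter <- gen_counter + unname(log2(P1 / P0))
    threshold <- 1 / volume_ml
    if (P1 < threshold) events[[length(events) + 1L]] <-
      tibble::tibble(day_index = d, entity = "phage")
    if (S1 + I1 < threshold) events[[length(events) + 1L]] <-
      tibble::tibble(day_index = d, entity = "cells")
    # transfer into day d + 1
    if (d < days) {
      if (protocol$regime == "copropagation") {
        od_end <- (S1 + I1) * params$od_per_cell
        factor <- if (protocol$dilution_rule == "to_target_od") {
          od_end / protocol$target
        } else protocol$target
        factor <- max(factor, 1 + 1e-9)
        state <- final / factor
      } else {
        factor <- max(P1 / protocol$initial_phage, 1 + 1e-9)
        state <- c(protocol$initial_cells, rep(0, nE), P1 / factor)
        names(state) <- state_names(nE)
      }
      prev_dilution <- factor
    }
  }
  records <- validate_passage_records(do.call(rbind, records))
  structure(
    list(records = records,
         events = if (length(events)) do.call(rbind, events) else
           tibble::tibble(day_index = integer(), entity = character()),
         phage_generations = gen_counter,
         time_courses = tcs),
    class = "serial_passage_sim"
  )
}

#' Simulate an adsorption assay
#'
#' Unadsorbed free phage in a fixed excess of cells decays as
#' \eqn{P(t) = P_0 e^{-k C t}} (t in minutes). Optional multiplicative
#' lognormal measurement noise with the given coefficient of variation is
#' mean-preserving and seeded.
#'
#' @param k_ads adsorption rate constant, ml/cells/min.
#' @param cell_density cells/ml.
#' @param times sampling times in minutes (>= 0).
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (0 for a noiseless assay).
#' @param seed integer seed (required when `noise_cv > 0` for
#'   reproducibility; `NULL` leaves the RNG state alone).
#' @param p0 initial titre, PFU/ml.
#' @return A [time_course()] of entity `free_phage` with times in minutes.
#' @export
simulate_adsorption_assay <- function(k_ads, cell_density, times,
                                      noise_cv = 0, seed = NULL, p0 = 1e7) {
  if (noise_cv < 0) coevo_stop("noise_cv must be >= 0", "coevo_parameter_error")
  if (any(times < 0)) coevo_stop("times must be >= 0", "coevo_parameter_error")
  expected <- p0 * exp(-k_ads * cell_density * times)
  values <- expected
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    noise <- if (is.null(seed)) {
      rnorm(length(times), 0, sdlog)
    } else {
      old_seed <- if (exists(".Random.seed", envir = globalenv())) {
        get(".Random.seed", envir = globalenv())
      } else NULL
      on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
      set.seed(seed)
      rnorm(length(times), 0, sdlog)
    }
    values <- expected * exp(noise - sdlog^2 / 2)
  }
  time_course("free_phage", times, values, time_unit = "minutes")
}

#' Calibrate the burst size against a target amplification
#'
#' Bisects the burst size so that a deterministic [simulate_within_day()]
#' run under the given protocol amplifies free phage by `target_fold`.
#' Amplification is monotone in the burst size, so bisection converges.
#'
#' @param params a [phage_host_params()]; its `burst_size` is ignored.
#' @param protocol a [passage_protocol()].
#' @param target_fold target final/initial free-phage ratio.
#' @param interval search interval for the burst size.
#' @param grid integration step, hours.
#' @param tol relative tolerance on the achieved fold.
#' @return The calibrated burst size.
#' @export
tune_burst_size <- function(params, protocol, target_fold = 1000,
                            interval = c(1.5, 5000), grid = 0.01,
                            tol = 0.01) {
  fold_for <- function(b) {
    p <- params
    p$burst_size <- b
    sim <- simulate_within_day(p, protocol, grid = grid)
    tc <- sim$time_courses$free_phage
    tc$values[length(tc$values)] / tc$values[1L]
  }
  lo <- interval[1L]; hi <- interval[2L]
  f_lo <- fold_for(lo); f_hi <- fold_for(hi)
  if ((f_lo - target_fold) * (f_hi - target_fold) > 0) {
    coevo_stop("target fold not bracketed by the burst-size interval",
               "coevo_parameter_error")
  }
  for (i in 1:60) {
    mid <- sqrt(lo * hi)
    f_mid <- fold_for(mid)
    if (abs(f_mid - target_fold) / target_fold < tol) return(mid)
    if ((f_mid - target_fold) * (f_lo - target_fold) > 0) {
      lo <- mid; f_lo <- f_mid
    } else {
      hi <- mid; f_hi <- f_mid
    }
  }
  mid
}

#' Packaged long-run copropagation scenario
#'
#' A copropagation parameterisation that sustains host and phage through
#' >= 50 daily passages: the partially resistant host (adsorption reduced
#' by `resistance_factor = 3e-4`) paired with a reduced-burst
#' (reduced-virulence) phage, the configuration the emulated experiment
#' converged to. Daily phage amplification lands in the experimentally
#' observed 2-20-fold range while the host stays at its plateau.
#'
#' @param resistance_factor adsorption reduction of the resistant host.
#' @param burst_size burst size of the coexisting phage.
#' @return A list with elements `params` ([phage_host_params()]) and
#'   `protocol` ([passage_protocol()]).
#' @export
coexistence_scenario <- function(resistance_factor = 3e-4, burst_size = 40) {
  list(
    params = phage_host_params(resistance_factor = resistance_factor,
                               burst_size = burst_size),
    protocol = passage_protocol("copropagation", duration = 24,
                                target = 0.05, initial_cells = 1.6e7,
                                initial_phage = 1.7e7)
  )
}
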