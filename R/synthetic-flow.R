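# Synthetic flow-cytometry event streams and competition experiments.

#' Construct a flow-cytometry event stream
#'
#' @param acq_time_s acquisition times (seconds), non-decreasing.
#' @param marker_au constitutive-label channel values (au).
#' @param reporter_au starvation-reporter channel values (au).
#' @return A data.frame of class `event_stream` with columns `event_index`,
#'   `acq_time_s`, `marker_au`, `reporter_au`.
#' @export
event_stream <- function(acq_time_s, marker_au, reporter_au) {
  n <- length(acq_time_s)
  if (length(marker_au) != n || length(reporter_au) != n)
    stop_param("channel vectors must have the same length as acq_time_s")
  if (n && any(diff(acq_time_s) < 0))
    stop_param("acq_time_s must be non-decreasing")
  if (n && (any(!is.finite(marker_au)) || any(!is.finite(reporter_au))))
    stop_param("channel values must be finite")
  structure(
    data.frame(event_index = seq_len(n), acq_time_s = acq_time_s,
               marker_au = marker_au, reporter_au = reporter_au),
    class = c("event_stream", "data.frame"))
}

#' Simulate a two-population flow-cytometry event stream
#'
#' Events are a two-component Gaussian mixture on the marker channel
#' (labeled fraction `frac_labeled`), ordered by acquisition time. A leading
#' `carryover_frac` of events models acquisition carryover from the previous
#' sample: they are drawn from a contaminant distribution shifted by
#' `contaminant_shift_sd` reference SDs on both channels. At most the first
#' 40% of events can be contaminated, since the artifact filter references
#' the last 60%.
#'
#' @param frac_labeled fraction of marker-positive (labeled) cells in
#'   `[0, 1]`.
#' @param reporter_means length-2 vector: reporter channel mean for the
#'   labeled and unlabeled populations (au).
#' @param n_events number of events (default 50,000).
#' @param carryover_frac fraction of leading contaminant events, in
#'   `[0, 0.4]`.
#' @param contaminant_shift_sd contaminant shift in units of the channel SD.
#' @param marker_means,marker_sd,reporter_sd mixture-component parameters
#'   (au).
#' @param acquisition_s total acquisition duration (seconds).
#' @param seed integer seed.
#' @return An [event_stream()].
#' @examples
#' s <- simulate_flow_stream(0.5, n_events = 1000, seed = 1)
#' mean(s$marker_au > 2500)  # ~0.5
#' @export
simulate_flow_stream <- function(frac_labeled, reporter_means = c(3000, 300),
                                 n_events = 50000, carryover_frac = 0,
                                 contaminant_shift_sd = 10,
                                 marker_means = c(5000, 500),
                                 marker_sd = 400, reporter_sd = 150,
                                 acquisition_s = 60, seed = 1) {
  check_scalar(frac_labeled, "frac_labeled", 0, 1)
  check_scalar(n_events, "n_events", lower = 0)
  if (!is.numeric(carryover_frac) || length(carryover_frac) != 1L ||
      !is.finite(carryover_frac) || carryover_frac < 0 ||
      carryover_frac > 0.4)
    stop("carryover_frac must be in [0, 0.4]: the filter references the ",
         "last 60% of events and cannot remove more than the first 40%")
  n <- as.integer(n_events)
  if (n == 0L)
    return(event_stream(numeric(0), numeric(0), numeric(0)))
  with_seed(seed, {
    n_carry <- round(n * carryover_frac)
    n_main <- n - n_carry
    lab <- stats::runif(n_main) < frac_labeled
    marker <- stats::rnorm(n_main, ifelse(lab, marker_means[1],
                                          marker_means[2]), marker_sd)
    reporter <- stats::rnorm(n_main, ifelse(lab, reporter_means[1],
                                            reporter_means[2]), reporter_sd)
    if (n_carry > 0L) {
      # shift in units of the channel's overall SD (mixture, not component),
      # the scale the 3-SD artifact filter works on
      shift_m <- contaminant_shift_sd * max(stats::sd(marker), marker_sd)
      shift_r <- contaminant_shift_sd * max(stats::sd(reporter), reporter_sd)
      c_lab <- stats::runif(n_carry) < frac_labeled
      marker <- c(stats::rnorm(n_carry, ifelse(c_lab, marker_means[1],
                                               marker_means[2]) + shift_m,
                               marker_sd), marker)
      reporter <- c(stats::rnorm(n_carry, ifelse(c_lab, reporter_means[1],
                                                 reporter_means[2]) + shift_r,
                                 reporter_sd), reporter)
    }
    times <- sort(stats::runif(n, 0, acquisition_s))
    event_stream(times, marker, reporter)
  })
}

# Growth rate (doublings/hour) of one genotype in one competition phase.
# Without an intact starvation program cells grow slower under limitation
# and resume growth late during recovery.
genotype_phase_rate <- function(genotype, phase, pi_mM, params) {
  r <- params$max_rate
  if (genotype$induction_enabled) return(r)
  if (phase == "depletion" && pi_mM < 0.5) r - 0.15
  else if (phase == "recovery") r - 0.1
  else r
}

#' Simulate a two-strain competition across a starvation/recovery schedule
#'
#' Both strains grow exponentially within each phase at genotype- and
#' phase-specific rates; the mutant frequency follows the closed-form
#' exponential competition. The returned trajectory records mutant fraction
#' and cumulative generations (doublings of the co-culture OD) at each
#' sampling time, plus the per-phase truth selection coefficients (log2
#' odds slope per co-culture generation) for estimator-recovery tests.
#' Optionally attaches a flow event stream per sampling time.
#'
#' @param genotypes list of two [genotype_spec()]s: `reference` (labeled
#'   wild type) and `mutant`.
#' @param schedule data.frame with one row per phase and columns `phase`
#'   (`"depletion"`/`"recovery"`), `pi_mM`, `duration_h`; optional columns
#'   `rate_ref`, `rate_mut` override the genotype-derived rates
#'   (doublings/hour).
#' @param params a [sim_params()].
#' @param seed integer seed.
#' @param initial_mutant_fraction starting mutant fraction (default 0.5,
#'   a 1:1 mix).
#' @param samples_per_phase sampling times per phase (default 4, evenly
#'   spaced including the phase end).
#' @param n_events if > 0, also draw an [event_stream()] of this many
#'   events at each sampling time (binomially sampling the mutant
#'   fraction).
#' @return A list of class `competition_sim`: `trajectory` (data.frame of
#'   class `competition_trajectory` with `sample_time_h`, `mutant_fraction`,
#'   `generations`, `phase`), `truth` (per-phase rates and selection
#'   coefficients), and `streams` (list of event streams or `NULL`).
#' @export
simulate_competition <- function(genotypes, schedule, params = sim_params(),
                                 seed = params$seed,
                                 initial_mutant_fraction = 0.5,
                                 samples_per_phase = 4, n_events = 0) {
  if (!is.data.frame(schedule) || !nrow(schedule) ||
      !all(c("phase", "pi_mM", "duration_h") %in% names(schedule)))
    stop_param("schedule must be a non-empty data.frame with columns ",
               "phase, pi_mM, duration_h")
  stopifnot(is.list(genotypes), length(genotypes) == 2L)
  ref <- genotypes[[1]]; mut <- genotypes[[2]]
  check_scalar(initial_mutant_fraction, "initial_mutant_fraction", 1e-9,
               1 - 1e-9)
  od_ref <- (1 - initial_mutant_fraction)
  od_mut <- initial_mutant_fraction
  t_abs <- 0; gens <- 0
  rows <- list(); truth <- list()
  for (i in seq_len(nrow(schedule))) {
    ph <- schedule$phase[i]
    r_ref <- schedule$rate_ref[i] %||%
      genotype_phase_rate(ref, ph, schedule$pi_mM[i], params)
    r_mut <- schedule$rate_mut[i] %||%
      genotype_phase_rate(mut, ph, schedule$pi_mM[i], params)
    if (is.na(r_ref)) r_ref <- genotype_phase_rate(ref, ph,
                                                   schedule$pi_mM[i], params)
    if (is.na(r_mut)) r_mut <- genotype_phase_rate(mut, ph,
                                                   schedule$pi_mM[i], params)
    dur <- schedule$duration_h[i]
    check_scalar(dur, "duration_h", lower = 1e-9)
    ts <- seq(0, dur, length.out = samples_per_phase + 1L)[-1L]
    od0_tot <- od_ref + od_mut
    for (t in ts) {
      oR <- od_ref * 2^(r_ref * t)
      oM <- od_mut * 2^(r_mut * t)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_time_h = t_abs + t, mutant_fraction = oM / (oR + oM),
        generations = gens + log2((oR + oM) / od0_tot), phase = ph)
    }
    gens_phase <- log2((od_ref * 2^(r_ref * dur) + od_mut * 2^(r_mut * dur)) /
                         od0_tot)
    truth[[i]] <- data.frame(
      phase = ph, pi_mM = schedule$pi_mM[i], rate_ref = r_ref,
      rate_mut = r_mut,
      s_per_generation = (r_mut - r_ref) * dur / gens_phase)
    od_ref <- od_ref * 2^(r_ref * dur)
    od_mut <- od_mut * 2^(r_mut * dur)
    t_abs <- t_abs + dur
    gens <- gens + gens_phase
  }
  traj <- do.call(rbind, rows)
  traj <- rbind(data.frame(sample_time_h = 0,
                           mutant_fraction = initial_mutant_fraction,
                           generations = 0, phase = schedule$phase[1]), traj)
  class(traj) <- c("competition_trajectory", "data.frame")
  streams <- NULL
  if (n_events > 0) {
    streams <- lapply(seq_len(nrow(traj)), function(k) {
      simulate_flow_stream(traj$mutant_fraction[k], n_events = n_events,
                           seed = derive_seed(seed, paste0("events", k)))
    })
    names(streams) <- paste0("t", format(traj$sample_time_h, trim = TRUE), "h")
  }
  structure(list(trajectory = traj, truth = do.call(rbind, truth),
                 streams = streams),
            class = "competition_sim")
}
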