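#' Configuration for the synthetic NREM session generator
#'
#' Builds a validated parameter set for [simulateSession()]. The generator
#' plants single-cycle slow-oscillation (SO) half-wave pairs, waxing-waning
#' spindles and ripple bursts (the latter riding a brief negative sharp
#' wave) on a 1/f Gaussian background, and emits inhomogeneous-Poisson
#' multiunit spike trains whose rate is gain-modulated inside the planted
#' events.
#'
#' Event rates (`so_rate`, `spindle_rate`, `ripple_rate`) are the rates of
#' *independently* planted events per minute; on top of these, each SO
#' nests a spindle with probability `p_spindle_in_so` (spindle center in the
#' SO up-state) and each spindle nests a ripple with probability
#' `p_ripple_in_spindle` (ripple strictly inside the spindle span, centered
#' in the waxing phase by default). `event_snr` scales each kernel's
#' amplitude relative to the background standard deviation *within that
#' event's detection band*, so `event_snr = 5` plants events five times
#' larger than the band-limited background fluctuations the detectors
#' compete against.
#'
#' @param duration_s session length, seconds.
#' @param fs sampling rate, Hz (>= 200).
#' @param n_contacts number of macro contacts.
#' @param n_wires_per_contact microwires per contact.
#' @param region_labels region per contact (recycled over AH, PH, A, EC,
#'   PHC); @param hemispheres hemisphere per contact (default: first half
#'   L, second half R).
#' @param so_rate,spindle_rate,ripple_rate independent events per minute.
#' @param p_spindle_in_so,p_ripple_in_spindle nesting probabilities.
#' @param so_spindle_lag_s mean lag of nested spindle centers relative to
#'   the SO up-state maximum, s.
#' @param spindle_ripple_lag_s mean lag of nested ripple centers relative
#'   to the spindle center, s (negative = waxing phase).
#' @param so_spindle_lag_sd_s,spindle_ripple_lag_sd_s s.d. of the truncated
#'   normal the nesting lags are drawn from.
#' @param so_freq SO frequency, Hz (0.3-1.25; kernel duration = 1/so_freq).
#' @param spindle_freq,ripple_freq oscillation frequencies, Hz.
#' @param spindle_duration_s,ripple_duration_s planted kernel durations
#'   (must respect the detectors' admissible ranges: spindle 0.4-3 s,
#'   ripple 0.038-0.2 s; SO duration 1/so_freq must lie in 0.8-2 s).
#' @param background_exponent 1/f^exponent slope of the background.
#' @param background_sd broadband background s.d., microvolts.
#' @param event_snr kernel amplitude over in-band background s.d.
#' @param baseline_spike_rate per-wire baseline firing rate, Hz.
#' @param gain_so,gain_spindle,gain_ripple multiplicative firing-rate gains
#'   inside the SO up-state, the spindle span and the ripple span.
#' @param gain_so_down gain inside the SO down-state (< 1 emulates the OFF
#'   period).
#' @param ripple_ramp_s duration of the linear pre-ripple firing ramp, s
#'   (0 disables it).
#' @param cofire_jitter_ms named numeric (so, spindle, ripple): s.d. of the
#'   pairwise co-spike jitter injected by [plantCofiring()], ms.
#' @param cofire_pairs_per_event synchronous cross-wire spike pairs
#'   injected per planted event by [plantCofiring()].
#' @param cross_sync_prob probability that a planted event is mirrored on
#'   each other same-hemisphere contact; @param cross_sync_jitter_s s.d. of
#'   the mirror-center scatter, s.
#' @param contact_gain_spread s.d. of a log-normal per-contact factor
#'   applied to the firing-rate gain excesses and nesting probabilities
#'   (0 = homogeneous contacts).
#' @param artifact_rate planted high-amplitude transients per minute.
#' @param wake_blocks number of 1-min wake blocks inserted into the
#'   otherwise all-N2/N3 hypnogram.
#' @param seed integer RNG seed.
#' @return a list of class `SimConfig`.
#' @examples
#' cfg <- simConfig(duration_s = 120, n_contacts = 1, seed = 7)
#' @export
simConfig <- function(duration_s,
                      fs = 1000,
                      n_contacts = 2,
                      n_wires_per_contact = 8,
                      region_labels = NULL,
                      hemispheres = NULL,
                      so_rate = 5,
                      spindle_rate = 3,
                      ripple_rate = 4,
                      p_spindle_in_so = 0.5,
                      p_ripple_in_spindle = 0.5,
                      so_spindle_lag_s = 0,
                      spindle_ripple_lag_s = -0.15,
                      so_spindle_lag_sd_s = 0.1,
                      spindle_ripple_lag_sd_s = 0.25,
                      so_freq = 0.75,
                      spindle_freq = 13,
                      ripple_freq = 90,
                      spindle_duration_s = 1.5,
                      ripple_duration_s = 0.15,
                      background_exponent = 1,
                      background_sd = 15,
                      event_snr = 5,
                      baseline_spike_rate = 5,
                      gain_so = 1.5,
                      gain_so_down = 0.2,
                      gain_spindle = 2,
                      gain_ripple = 3,
                      ripple_ramp_s = 0.5,
                      cofire_jitter_ms = c(so = 12, spindle = 6, ripple = 2),
                      cofire_pairs_per_event = 3,
                      cross_sync_prob = 0.3,
                      cross_sync_jitter_s = 0.01,
                      contact_gain_spread = 0,
                      artifact_rate = 0.2,
                      wake_blocks = 0,
                      seed = 1) {
  if (is.null(region_labels)) {
    region_labels <- rep(.REGIONS, length.out = n_contacts)
  }
  if (is.null(hemispheres)) {
    hemispheres <- rep(c("L", "R"), each = ceiling(n_contacts / 2),
                       length.out = n_contacts)
  }
  cfg <- list(
    duration_s = duration_s, fs = fs, n_contacts = n_contacts,
    n_wires_per_contact = n_wires_per_contact,
    region_labels = region_labels, hemispheres = hemispheres,
    so_rate = so_rate, spindle_rate = spindle_rate,
    ripple_rate = ripple_rate,
    p_spindle_in_so = p_spindle_in_so,
    p_ripple_in_spindle = p_ripple_in_spindle,
    so_spindle_lag_s = so_spindle_lag_s,
    spindle_ripple_lag_s = spindle_ripple_lag_s,
    so_spindle_lag_sd_s = so_spindle_lag_sd_s,
    spindle_ripple_lag_sd_s = spindle_ripple_lag_sd_s,
    so_freq = so_freq, spindle_freq = spindle_freq,
    ripple_freq = ripple_freq,
    spindle_duration_s = spindle_duration_s,
    ripple_duration_s = ripple_duration_s,
    background_exponent = background_exponent,
    background_sd = background_sd, event_snr = event_snr,
    baseline_spike_rate = baseline_spike_rate,
    gain_so = gain_so, gain_so_down = gain_so_down,
    gain_spindle = gain_spindle, gain_ripple = gain_ripple,
    ripple_ramp_s = ripple_ramp_s,
    cofire_jitter_ms = cofire_jitter_ms,
    cofire_pairs_per_event = cofire_pairs_per_event,
    cross_sync_prob = cross_sync_prob,
    cross_sync_jitter_s = cross_sync_jitter_s,
    contact_gain_spread = contact_gain_spread,
    artifact_rate = artifact_rate, wake_blocks = wake_blocks,
    seed = as.integer(seed)
  )
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

#' Validate a SimConfig
#'
#' Checks rates, probabilities, the sampling-rate floor and that the
#' planted kernel durations respect the detectors' admissible ranges
#' (SO 0.8-2 s, spindle 0.4-3 s, ripple 38-200 ms).
#'
#' @param cfg a `SimConfig` list.
#' @return `cfg`, invisibly; errors on violation.
#' @export
validateSimConfig <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  chkRate <- function(x, nm) {
    if (length(x) != 1 || is.na(x) || x < 0) {
      stop(nm, " must be a single nonnegative number")
    }
  }
  for (nm in c("so_rate", "spindle_rate", "ripple_rate", "artifact_rate",
               "baseline_spike_rate", "background_sd", "event_snr")) {
    chkRate(cfg[[nm]], nm)
  }
  for (nm in c("p_spindle_in_so", "p_ripple_in_spindle",
               "cross_sync_prob")) {
    p <- cfg[[nm]]
    if (p < 0 || p > 1) stop(nm, " must lie in [0, 1]")
  }
  if (cfg$fs < 200) stop("fs must be at least 200 Hz")
  if (cfg$duration_s <= 2 * .EPOCH_S) {
    stop("duration_s must exceed two 30-s hypnogram epochs")
  }
  soDur <- 1 / cfg$so_freq
  if (soDur < 0.8 || soDur > 2) {
    stop("1/so_freq = ", signif(soDur, 3),
         " s falls outside the admissible SO duration range [0.8, 2] s")
  }
  if (cfg$spindle_duration_s < 0.4 || cfg$spindle_duration_s > 3) {
    stop("spindle_duration_s outside admissible range [0.4, 3] s")
  }
  if (cfg$ripple_duration_s < 0.038 || cfg$ripple_duration_s > 0.2) {
    stop("ripple_duration_s outside admissible range [0.038, 0.2] s")
  }
  if (cfg$spindle_duration_s * cfg$spindle_freq < 6) {
    stop("planted spindles would have fewer than 6 cycles")
  }
  if (cfg$ripple_duration_s * cfg$ripple_freq < 3) {
    stop("planted ripples would have fewer than 3 cycles")
  }
  if (any(cfg$cofire_jitter_ms < 0)) stop("cofire_jitter_ms must be >= 0")
  if (length(cfg$region_labels) != cfg$n_contacts ||
      length(cfg$hemispheres) != cfg$n_contacts) {
    stop("region_labels and hemispheres must have one entry per contact")
  }
  invisible(cfg)
}
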