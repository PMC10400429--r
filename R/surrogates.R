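# Matched non-event surrogates: duration-matched, event-free, artifact-free
# NREM epochs drawn near each event with center-weighted probability.

#' Draw matched non-event surrogates
#'
#' For each event, draws an epoch of identical duration from a +/-
#' `windowS` interval around the event, with the time offset drawn from a
#' zero-mean normal of s.d. `sdS` truncated at +/- `windowS` (so epochs
#' close to the event are preferred). A candidate epoch is accepted when it
#' lies inside the recording, contains only artifact-free NREM samples, no
#' detected event of the paired type intersects the epoch extended by
#' `padS` on each side, and it does not overlap a previously assigned
#' surrogate. Events for which no feasible epoch is found within
#' `maxTries` draws are omitted (and reported in the `omitted` attribute).
#'
#' @param events data.frame of the events needing surrogates.
#' @param allEvents data.frame of all detected events of the same type on
#'   the channel (used for the event-free check; defaults to `events`).
#' @param durationS recording duration, s.
#' @param good logical sample mask ([nremSamples()]) or NULL.
#' @param fs sampling rate of `good`, Hz.
#' @param seed integer seed for reproducible draws.
#' @param windowS search half-window, s. @param sdS sampler s.d., s.
#' @param padS event-free padding per side, s.
#' @param maxTries draws attempted per event.
#' @return data.frame: `paired_event_id` (row index into `events`),
#'   `contact_id`, `onset_s`, `center_s`, `offset_s`; attribute `omitted`
#'   lists event ids without a surrogate.
#' @export
matchSurrogates <- function(events, allEvents = events, durationS,
                            good = NULL, fs = 1000, seed = 1,
                            windowS = 600, sdS = 150, padS = 1.5,
                            maxTries = 500) {
  if (!nrow(events)) {
    out <- data.frame(paired_event_id = integer(), contact_id = integer(),
                      onset_s = numeric(), center_s = numeric(),
                      offset_s = numeric())
    attr(out, "omitted") <- integer()
    return(out)
  }
  evIv <- cbind(allEvents$onset_s, allEvents$offset_s)
  .withSeed(seed, {
    taken <- matrix(numeric(), 0, 2)
    rows <- list()
    omitted <- integer()
    for (k in seq_len(nrow(events))) {
      e <- events[k, ]
      dur <- e$offset_s - e$onset_s
      found <- FALSE
      for (tr in seq_len(maxTries)) {
        shift <- .rtruncnorm(1, 0, sdS, -windowS, windowS)
        on <- e$onset_s + shift
        off <- on + dur
        if (on < 0 || off > durationS) next
        if (!is.null(good)) {
          i1 <- floor(on * fs) + 1L; i2 <- min(length(good),
                                               ceiling(off * fs))
          if (!all(good[i1:i2])) next
        }
        if (nrow(evIv) &&
            any(evIv[, 1] < off + padS & evIv[, 2] > on - padS)) next
        if (nrow(taken) &&
            any(taken[, 1] < off & taken[, 2] > on)) next
        taken <- rbind(taken, c(on, off))
        rows[[length(rows) + 1L]] <- data.frame(
          paired_event_id = k, contact_id = e$contact_id,
          onset_s = on, center_s = (on + off) / 2, offset_s = off)
        found <- TRUE
        break
      }
      if (!found) omitted <- c(omitted, k)
    }
    out <- if (length(rows)) do.call(rbind, rows)
           else data.frame(paired_event_id = integer(),
                           contact_id = integer(), onset_s = numeric(),
                           center_s = numeric(), offset_s = numeric())
    if (length(omitted)) {
      message(length(omitted), " event(s) without a feasible surrogate ",
              "epoch were omitted")
    }
    attr(out, "omitted") <- omitted
    out
  })
}
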