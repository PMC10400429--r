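# Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtureCache[[key]])) assign(key, force(expr), .fixtureCache)
  get(key, .fixtureCache)
}

# 10-min two-contact session with artifacts, plus detection output
detectedSession <- function() {
  cached("detected", {
    sess <- simulateSession(simConfig(duration_s = 600, n_contacts = 2,
                                      seed = 42))
    rec <- detectArtifacts(sess$recording)
    list(sess = sess, rec = rec, events = detectEvents(rec))
  })
}

# quiet single-contact session for quick structural checks
smallSession <- function() {
  cached("small", {
    simulateSession(simConfig(duration_s = 120, n_contacts = 1,
                              so_rate = 2, spindle_rate = 2,
                              ripple_rate = 2, artifact_rate = 0,
                              cross_sync_prob = 0, seed = 5))
  })
}

# a recording wrapper around a plain matrix, all-N2 hypnogram
quickRecording <- function(x, fs = 1000, region = "AH", hemi = "L") {
  x <- as.matrix(x)
  nEp <- ceiling(nrow(x) / fs / 30)
  SleepRecording(
    x, fs,
    channels = data.frame(contact_id = seq_len(ncol(x)),
                          region = rep(region, length.out = ncol(x)),
                          hemisphere = rep(hemi, length.out = ncol(x))),
    hypnogram = data.frame(epoch_start_s = (seq_len(nEp) - 1) * 30,
                           stage = "N2"))
}
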