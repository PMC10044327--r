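# Shared fixtures: sessions are generated in code, once per test run,
# and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, make(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

pcm_session_30 <- function() {
  fixture("pcm30", function() {
    generate_session(session_config("pcm", duration_s = 30, seed = 11))
  })
}

sm_session_40 <- function() {
  fixture("sm40", function() {
    generate_session(session_config("sm", duration_s = 40, seed = 12))
  })
}

pcm_features_30 <- function() {
  fixture("pcm30_feat", function() preprocess_session(pcm_session_30()))
}

# dominant frequency of a series by periodogram
dominant_freq <- function(x, fs) {
  sp <- stats::spec.pgram(x - mean(x), plot = FALSE, taper = 0.1)
  sp$freq[which.max(sp$spec)] * fs
}

# fraction of spectral power inside [lo, hi] Hz
band_power_fraction <- function(x, fs, lo, hi) {
  sp <- stats::spec.pgram(x - mean(x), plot = FALSE, taper = 0)
  f <- sp$freq * fs
  sum(sp$spec[f >= lo & f <= hi]) / sum(sp$spec)
}
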