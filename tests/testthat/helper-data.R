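## Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures))
    assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

## Constant-rate pulse train rendered directly (no rhythm labels involved),
## with drift-free cumulative placement as in simulate_ppg().
const_hr_ppg <- function(hr_bpm, dur_s, fs = 100, model = pulse_model()) {
  rr <- 60 / hr_bpm
  n_beats <- ceiling(dur_s / rr)
  bounds <- round(cumsum(c(0, rep(rr, n_beats))) * fs)
  x <- numeric(bounds[n_beats + 1])
  for (i in seq_len(n_beats)) {
    n_i <- bounds[i + 1] - bounds[i]
    if (n_i < 1) next
    x[(bounds[i] + 1):bounds[i + 1]] <-
      x[(bounds[i] + 1):bounds[i + 1]] + render_pulse(model, rr, fs, n_i)
  }
  ppg_signal(x[seq_len(round(dur_s * fs))], fs)
}

## A 5-s segment (500 samples) of a constant-rate pulse train.
const_hr_segment <- function(hr_bpm, fs = 100) {
  const_hr_ppg(hr_bpm, 10, fs)$samples[501:1000]
}

## Pure tone segment of 5 s.
tone_segment <- function(freq_hz, fs = 100, amp = 1) {
  amp * sin(2 * pi * freq_hz * (0:499) / fs)
}
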