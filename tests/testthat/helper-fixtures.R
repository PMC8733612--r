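# Lightweight fixtures built in code.

# A small multichannel recording of 1/f noise (cheap; no oscillations).
quick_recording <- function(n_channels = 19, duration = 30, fs = 200,
                            seed = 1, labels = channels_1020()[seq_len(n_channels)]) {
  set.seed(seed)
  n <- duration * fs
  sig <- t(vapply(seq_len(n_channels), function(ch) {
    sp <- signal_spec(duration, fs, band = NULL, aperiodic_beta = 1.3,
                      aperiodic_offset = 1, seed = seed * 1000 + ch)
    generate_band_signal(sp)
  }, numeric(n)))
  eeg_recording(sig, fs, labels,
                subject = list(id = sprintf("T%03d", seed), group = "control",
                               age = 8))
}
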