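# Shared fixtures: post-contrast group-mean tissues and a small protocol
# helper used across test files.

chronic_tissues <- function() {
  list(
    mi = tissue_relaxation(441, 43.8),
    remote = tissue_relaxation(668, 42.4),
    blood = tissue_relaxation(466, 142.4)
  )
}

chronic_reference <- function(LGEb = -0.5) {
  t <- chronic_tissues()
  tissue_reference_from_times(t$remote, t$blood, LGEb = LGEb)
}

# Noise-free signal vector for one tissue under a protocol, built directly
# from the exported single-event signal model (independent of the internal
# vectorized path used by simulate_series / fit_maps).
signals_by_event <- function(protocol, A, T1, T2) {
  ev <- protocol$events
  vapply(seq_len(nrow(ev)), function(j) {
    msasha_signal(ev$kind[j], TS = ev$TS[j], TE_prep = ev$TE_prep[j],
                  recovery_duration = ev$recovery_beats[j] * protocol$RR + ev$TS[j],
                  A = A, T1 = T1, T2 = T2)
  }, numeric(1))
}

vial_reference_t1t2 <- function() {
  data.frame(
    T1 = c(439, 1111, 464, 572, 1361, 1527, 303, 814, 258),
    T2 = c(40.0, 44.3, 181.0, 42.5, 46.6, 234.4, 41.9, 44.8, 154.2)
  )
}
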