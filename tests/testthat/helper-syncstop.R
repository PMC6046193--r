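# Brute-force scanner: independently verifies every schedule constraint by
# walking the sequence, without reusing the generator's placement logic.
scan_schedule <- function(kinds, cfg) {
  problems <- character(0)
  if (length(kinds) != cfg$n_trials) problems <- c(problems, "length")
  if (sum(kinds == "stop") != cfg$n_stop) problems <- c(problems, "n_stop")
  if (cfg$n_familiarization > 0 &&
      any(kinds[seq_len(cfg$n_familiarization)] != "go")) {
    problems <- c(problems, "familiarization")
  }
  stops <- which(kinds == "stop")
  if (length(stops) >= 2) {
    gaps <- diff(stops) - 1L
    if (any(gaps < cfg$min_go_after_stop)) problems <- c(problems, "min_gap")
    if (any(gaps > cfg$max_go_after_stop)) problems <- c(problems, "max_gap")
  }
  problems
}

# Small, fast cohort for pipeline tests.
tiny_cohort <- function(n = 4, seed = 1, ...) {
  generate_cohort(n_participants = n, seed = seed, ...)
}
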