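# Shared fixtures for the test suite. Everything is built in code; the
# default objects are cheap to construct.

default_arena <- make_default_arena()
default_swim <- swim_params()
default_learning <- learning_params()

# A cohort of single trials under a fixed learning state; returns latencies.
cohort_latencies <- function(state, n, seed, arena = default_arena,
                             swim = default_swim, forced_cue = NULL) {
  starts <- arena$start_positions
  vapply(seq_len(n), function(rat) {
    set.seed(derive_seed(seed, rat))
    simulate_trial(state, arena, swim,
                   starts[(rat - 1L) %% length(starts) + 1L],
                   forced_cue = forced_cue,
                   record_trajectory = FALSE)$latency
  }, numeric(1))
}

# Learning state with one channel of one cue set, everything else zero.
channel_state <- function(cue, channel, strength, arena = default_arena) {
  state <- learning_state(names(arena$cues))
  if (channel == "direction") state$V_dir[cue] <- strength
  else state$V_dist[cue] <- strength
  state
}
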