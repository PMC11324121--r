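# shared fixtures, built in code at test time

default_state <- function(noise_sd = 0.05, wander_amp = 0.1) {
  list(beat = beat_params(), projection = LEAD_PROJECTION,
       noise_sd = noise_sd, wander_amp = wander_amp, wander_freq = 0.33)
}

test_record <- function(seed = 1, ...) {
  synth_record(default_state(...), seed = seed,
               record_id = paste0("rec", seed))
}

# a tiny model cheap enough for per-test construction
tiny_model <- function(seed = 1) {
  build_mae(encoder_config("tiny"), decoder_config(64L, 1L, 4L), seed = seed)
}

# minimal model for gradient-level tests
micro_model <- function(seed = 1) {
  build_mae(encoder_config("custom", embed_dim = 32L, depth = 2L,
                           n_heads = 2L),
            decoder_config(16L, 1L, 2L), seed = seed)
}
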