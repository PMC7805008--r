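# Seed plumbing. Every generator draws from a private substream seeded by a
# stable hash of (global seed, stream label), so adding a state to a config
# never perturbs the panels of the other states, and identical (config, seed)
# always yields bit-identical output.

# Set the RNG to `seed`; returns a restorer closure for on.exit().
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

# Stable polynomial hash of (seed, label) into [1, 2^31 - 2]. Pure integer
# arithmetic in doubles (all intermediates < 2^53), platform-independent.
stable_hash <- function(seed, label) {
  m <- 2147483647  # 2^31 - 1
  h <- as.numeric(seed %% m)
  for (code in utf8ToInt(as.character(label))) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h %% (m - 1) + 1)
}
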