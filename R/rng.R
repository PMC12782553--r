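# Deterministic fan-out of one master seed into independent named streams so
# that toggling one randomness source (e.g. spikes) does not shift another
# (e.g. weights).

stream_offsets <- c(weights = 101L, seed_pathway = 211L, noise = 307L,
                    spikes = 401L, inputs = 503L, task = 601L,
                    feedforward = 701L)

stream_seed <- function(master, stream) {
  if (!stream %in% names(stream_offsets))
    stop("unknown rng stream: ", stream)
  # keep within 32-bit integer range
  as.integer((as.numeric(master) * 7919 + stream_offsets[[stream]]) %%
               2147483647)
}

with_stream <- function(master, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(master, stream))
  expr
}
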