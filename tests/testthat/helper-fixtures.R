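# A single null RSN-like series: band-limited signal plus white noise,
# standardised.  Draws from the current RNG stream.
band_limited_pair <- function(n = 297, sampling_interval = 2) {
  x <- fnconn:::band_limited_noise(n, sampling_interval) + 0.5 * rnorm(n)
  as.numeric(scale(x))
}

# Zero-coupling graph on k nodes (independent time-courses).
null_graph <- function(k = 10) {
  coupling_graph(matrix(0, k, k))
}
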