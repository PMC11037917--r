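# Shared small fixtures for the test suite. Everything is generated in code
# with fixed seeds; nothing is read from disk.

# A quick, small division movie (3 z-slices; the pipeline projects the two
# central slices, so the reduced z-count does not change what is measured).
small_movie_params <- function(...) {
  args <- list(...)
  if (is.null(args$n_z)) args$n_z <- 3
  do.call(cell_sim_params, args)
}

# Disk mask of radius r centred in an n x n image, 0-based pixel centres.
disk_mask <- function(n = 51, r = 20) {
  c0 <- (n - 1) / 2
  x <- matrix(rep(0:(n - 1), each = n), n, n)
  y <- matrix(rep(0:(n - 1), times = n), n, n)
  sqrt((x - c0)^2 + (y - c0)^2) <= r
}

# A default synthetic locus shared across genotyping tests.
test_target <- function() synthetic_target(seed = 20)
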