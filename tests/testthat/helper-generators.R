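# Random inputs for property-style tests (all drawn under the caller's seed).

random_demography <- function() {
  n_ep <- sample(1:3, 1)
  if (n_ep == 1L) {
    return(demography(data.frame(start = 0, end = Inf,
                                 size = runif(1, 100, 5000), growth = 0)))
  }
  bounds <- sort(runif(n_ep - 1, 10, 400))
  start <- c(0, bounds)
  end <- c(bounds, Inf)
  size <- runif(n_ep, 100, 5000)
  growth <- c(runif(n_ep - 1, -0.02, 0.02), 0)
  # keep sizes >= 2 everywhere within finite epochs
  dur <- end - start
  bad <- is.finite(dur) & (size * exp(growth * dur) < 2)
  growth[bad] <- 0
  demography(data.frame(start = start, end = end, size = size,
                        growth = growth))
}

random_regime <- function() {
  regime_config(use_kingman_tail = runif(1) < 0.7,
                use_poisson_limit = runif(1) < 0.2,
                pseudocode_rule = runif(1) < 0.2)
}

# data.frame view for bit-exact segment comparisons
seg_df <- function(x) {
  if (inherits(x, "ibd_result")) x <- x$segments
  as.data.frame(x)
}

expect_same_segments <- function(a, b) {
  expect_identical(seg_df(a), seg_df(b))
}
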