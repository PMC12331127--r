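# Shared fixtures, built in code. Small vertex counts keep the suite fast;
# every EcD-type result is provably independent of the body used.

test_arch <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_arch(arch_spec(vertex_count = 600, seed = 3))
    }
    cache
  }
})

test_cloud <- function(n = 40, seed = 42, scale = 30) {
  generate_control("random_cloud", n = n, seed = seed, scale = scale)
}

random_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

random_axis <- function(span = 50) {
  axis3d(runif(3, -span, span), random_unit(), canonical = FALSE)
}

# a unit vector perpendicular to u
random_perp <- function(u) {
  v <- rnorm(3)
  v <- v - sum(v * u) * u
  v / sqrt(sum(v^2))
}

expect_vec_equal <- function(actual, expected, tol = 1e-9) {
  expect_lt(max(abs(actual - expected)), tol)
}
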