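# Independent oracles used by the tests only.

# Brute-force rejection sampler for uniform points in the nucleoplasm
# shell: uniform in the bounding cube, accept inside the shell. Independent
# of the package's inverse-CDF sampler.
sample_shell_rejection <- function(r, r_prime, n) {
  out <- matrix(numeric(0), 0, 3)
  while (nrow(out) < n) {
    m <- 2 * (n - nrow(out)) + 100
    p <- matrix(stats::runif(3 * m, -r, r), m, 3)
    rho2 <- rowSums(p^2)
    ok <- rho2 <= r^2 & rho2 > r_prime^2
    out <- rbind(out, p[ok, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# Restricted r^3-law CDF of the radial coordinate in the shell.
shell_radius_cdf <- function(r, r_prime) {
  force(r); force(r_prime)
  function(x) pmin(1, pmax(0, (x^3 - r_prime^3) / (r^3 - r_prime^3)))
}
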