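# Independent oracles used across the suite.

# Mean absorption time of the discrete nearest-neighbour Markov chain on the
# profile grid, with flux-matching detailed-balance rates
# w+ = D/h^2 * dF/(e^dF - 1), reflecting at the left grid edge and absorbing
# beyond the last point. Solved exactly by a dense linear system.
chain_mfpt_oracle <- function(xi, f, start_index, diffusivity = 1) {
  h <- xi[2] - xi[1]
  m <- length(xi)
  d <- diff(f)
  wup <- diffusivity / h^2 * ifelse(abs(d) < 1e-10, 1 - d / 2, d / (exp(d) - 1))
  wdn <- diffusivity / h^2 * ifelse(abs(d) < 1e-10, 1 + d / 2, d / (1 - exp(-d)))
  n <- m - 1
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    out <- wup[i]
    if (i < n) A[i, i + 1] <- wup[i]
    if (i > 1) {
      A[i, i - 1] <- wdn[i - 1]
      out <- out + wdn[i - 1]
    }
    A[i, i] <- -out
  }
  solve(A, rep(-1, n))[start_index]
}

# Shoelace area of the closed polygon formed by the two loop branches
# (forward left-to-right, backward right-to-left).
branch_shoelace_oracle <- function(loop) {
  ok <- !is.na(loop$I_forward) & !is.na(loop$I_backward)
  v <- loop$V[ok]
  px <- c(v, rev(v))
  py <- c(loop$I_forward[ok], rev(loop$I_backward[ok]))
  x2 <- c(px[-1], px[1])
  y2 <- c(py[-1], py[1])
  abs(sum(px * y2 - x2 * py)) / 2
}

# Deterministic noiseless recording from a trace with current attached.
as_recording <- function(trace) {
  recorded_trace(trace$t, trace$V, trace$I,
    sampling_rate = 1 / (trace$t[2] - trace$t[1])
  )
}

# Reference rate curves scaled to slow, stochastic-friendly kinetics.
scaled_reference_rates <- function(scale = 1e-5) {
  rates <- reference_fixture()$rates
  rates$k_wet <- rates$k_wet * scale
  rates$k_dry <- rates$k_dry * scale
  rates
}
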