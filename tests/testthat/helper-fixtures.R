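# Small lattice configurations and canned states used across test files.

tiny_config <- function(..., L = 30L, N_sir_total = 15L, t_burn = 1,
                        t_record = 10, locus_window = c(2L, 10L), seed = 1L) {
  sim_config(L = L, N_sir_total = N_sir_total, t_burn = t_burn,
             t_record = t_record, locus_window = locus_window, seed = seed,
             ...)
}

# rate set with only the named rates non-zero
sparse_rates <- function(...) {
  args <- list(...)
  base <- list(k_basal_acetyl = 0, k_sir_deacetyl = 0, k_txn_feedback = 0,
               k_sir_bind = 0, k_activation = 0, k_sir_unbind = 0,
               k_mark_loss = 0)
  base[names(args)] <- args
  do.call(rate_set, base)
}

explicit_state <- function(config, labels) {
  init_lattice(config, "explicit", sites = labels)
}

# closed-form two-state Markov chain via eigendecomposition of the 2x2
# transition matrix; the independent oracle for evolve_off_fraction
markov_closed_form <- function(f0, a, b, g) {
  # states (off, on); off->on prob a, on->off prob b; the decay factor is
  # computed via log1p/expm1 so the comparison is meaningful at 1e-12
  if (a + b == 0) return(f0)
  p_stat <- b / (a + b)
  rg <- exp(g * log1p(-(a + b)))
  p_stat * -expm1(g * log1p(-(a + b))) + f0 * rg
}

# draw colonies from a known two-component spherical mixture
two_blob_sample <- function(n_per, mu1, mu2, sd, seed) {
  set.seed(seed)
  x1 <- matrix(rnorm(n_per * 3, 0, sd), n_per, 3) +
    matrix(mu1, n_per, 3, byrow = TRUE)
  x2 <- matrix(rnorm(n_per * 3, 0, sd), n_per, 3) +
    matrix(mu2, n_per, 3, byrow = TRUE)
  rbind(x1, x2)
}
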