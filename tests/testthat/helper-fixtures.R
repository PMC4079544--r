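# shared fixtures, all generated in code

lysozyme_params <- function() soak_params(o_max = 0.903, tau = 0.794)
thermolysin_params <- function() soak_params(o_max = 0.930, tau = 0.284)

# noiseless table lying exactly on the model curve
exact_table <- function(params, n = 50, seed = 1) {
  set.seed(seed)
  L <- runif(n, 20, 400)
  t <- runif(n, 10, 800)
  occ <- occupancy_calc(L, t, params)
  occ <- pmin(pmax(occ, 0.01), 0.99)
  soak_observations(L, t, occ, system_label = "exact")
}

# four-point case for arithmetic oracles, values chosen by hand
hand_case <- function() {
  list(o_refine = c(0.20, 0.45, 0.70, 0.85),
       o_calc   = c(0.25, 0.40, 0.75, 0.80))
}
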