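# numeric argmax oracle over a grid refined by optimize()
grid_argmax <- function(f, lower, upper) {
  grid <- seq(lower, upper, length.out = 2001)
  vals <- vapply(grid, f, numeric(1))
  i <- which.max(vals)
  optimize(f, c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)]),
           maximum = TRUE)
}

# iterate the planning dynamics to convergence with held inputs
converge_plan <- function(params, v, s = 1, n = 6000,
                          cfg = dynamics_config()) {
  actor <- actor_state()
  for (k in seq_len(n)) {
    actor <- plan_step(actor, params, s = s, r_sig = 0, v = v, cfg)
  }
  actor
}
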