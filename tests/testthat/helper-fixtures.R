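# shared helpers for building tiny in-code fixtures

hct116 <- function() cell_line_fixture("HCT116")
sw480 <- function() cell_line_fixture("SW480")

# noiseless fraction trajectories from both pure starts
pure_start_trajectories <- function(params, times = c(0, 3, 7, 14, 21, 28)) {
  list(
    hi = simulate_deterministic(params, c(hi = 1, lo = 0), times),
    lo = simulate_deterministic(params, c(hi = 0, lo = 1), times)
  )
}

# deterministic toy matrix with named genes/cells
toy_matrix <- function(n_genes = 6, n_cells = 8, seed = 42) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, 10), n_genes, n_cells,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("c%02d", seq_len(n_cells))))
  m
}
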