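# The full dysthymia grid is the most expensive fixture; compute it once per
# test run and share it across the blocks that need it.
.grid_cache <- new.env(parent = emptyenv())

acceptance_dys_grid <- function() {
  if (is.null(.grid_cache$dys)) {
    .grid_cache$dys <- run_grid(disorders = "dys", predictor_sets = "own",
                                replicates = 10, n = 20000,
                                master_seed = 20260303)
  }
  .grid_cache$dys
}
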