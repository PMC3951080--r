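# Shared fixtures: kept tiny so unit tests stay fast; statistically heavy
# checks live in test-acceptance.R.

water <- function() get_material("water")

# small mid-band Bragg basis used by the unfolding unit tests (built once
# per test run, cached in the session)
.test_env <- new.env()
small_basis <- function() {
  if (is.null(.test_env$basis)) {
    .test_env$basis <- build_basis(
      seq(30, 60, 10),
      cube = make_slab_phantom("water", 8, 0.1),
      cfg = transport_config(n_histories = 3000, base_seed = 42))
  }
  .test_env$basis
}

# dose grid with prescribed values on a named slab geometry
fake_dose <- function(values, size = 2, voxel = 0.2) {
  g <- make_slab_phantom("water", size, voxel)
  dose_grid(array(values, g$dims), g, histories = 1)
}
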