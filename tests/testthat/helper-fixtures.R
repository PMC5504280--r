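# Shared fixtures, built once per test run. Sizes are kept small so the
# whole suite runs in minutes on one core.

test_cfg <- function(...) {
  cluster_config(n_init_runs = 100, seed = 11, ...)
}

# default 7-region crossing-fiber phantom at SNR 30
.cache <- new.env(parent = emptyenv())
cached <- function(key, make) {
  if (is.null(.cache[[key]])) .cache[[key]] <- make()
  .cache[[key]]
}

fixture_phantom <- function() {
  cached("phantom", function() generate_phantom(phantom_spec(), seed = 1))
}

# rim-free variant: seven orientation-distinct regions only
fixture_phantom_clean <- function() {
  cached("phantom_clean", function()
    generate_phantom(phantom_spec(csf_rim = 0, capsule_rim = 0), seed = 1))
}

fixture_odf_field <- function() {
  cached("odf_field", function() {
    ph <- fixture_phantom_clean()
    fit_odf_field(ph$dwi, ph$mask, seed = 5)
  })
}

# small toy labeling on a 6x6x4 grid: k blocks along x
toy_labeling <- function(k = 3, dims = c(6, 6, 4), voxel = c(1, 1, 1)) {
  lab <- array(0L, dims)
  cuts <- round(seq(0, dims[1], length.out = k + 1))
  for (j in seq_len(k))
    lab[(cuts[j] + 1):cuts[j + 1], , ] <- j
  new_labeling(lab, voxel)
}

relabel <- function(L, perm) {
  lab <- L$labels
  out <- lab
  for (j in seq_along(perm)) out[lab == j] <- perm[j]
  new_labeling(out, L$voxel_size, L$affine)
}
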