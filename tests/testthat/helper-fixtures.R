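# Shared fixtures, built lazily and cached for the session.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# a small scene + source stack at zero source noise
fix_scene <- function() cached("scene", {
  generate_scene(7, scene_layout(size = 32, n_seeds = 12))
})

# tiny model config / weights for shape and probe tests
fix_tiny_config <- function() mtsvit_config(
  embed_dim = 16, heads = 2, spatial_depth = 1, temporal_depth = 1,
  decoder_depth = 1, mlp_dim = 32, image_size = 16)

fix_tiny_sample <- function() cached("tiny_sample", {
  generate_scene(3, scene_layout(size = 16, n_seeds = 6))$sample
})

fix_tiny_weights <- function() cached("tiny_weights", {
  mtsvit_init(fix_tiny_config(), seed = 5)
})

# the desk-scale trained ensemble and its held-out scenes (slow; built once)
fix_desk_run <- function() cached("desk_run", {
  preset <- desk_preset(seed = 42)
  scenes <- lapply(seq_len(preset$n_train + preset$n_test),
                   function(i) generate_scene(1000 + i, preset$layout)$sample)
  train <- scenes[seq_len(preset$n_train)]
  test <- scenes[preset$n_train + seq_len(preset$n_test)]
  ens <- fit_mtsvit(train, preset$train_config, preset$model_config)
  list(ensemble = ens, train = train, test = test, preset = preset)
})

# validation CSV mirroring the released composition: 800 natural + 1272 other
fix_validation_csv <- function() cached("validation_csv", {
  n_nat <- 800; n_oth <- 1272
  df <- data.frame(
    plot_id = sprintf("v%04d", seq_len(n_nat + n_oth)),
    lon = round(stats::runif(n_nat + n_oth, -180, 180), 5),
    lat = round(stats::runif(n_nat + n_oth, -60, 75), 5),
    ref_label = c(rep(1L, n_nat), rep(0L, n_oth)),
    stratum = rep(rep(1:4, length.out = n_nat + n_oth)),
    region = "global")
  path <- tempfile(fileext = ".csv")
  write_validation_csv(df, path)
  path
})
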