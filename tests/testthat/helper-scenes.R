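# Shared synthetic fixtures, cached per test run (scenes are deterministic
# in their specs, so caching only saves render time).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- make()
  .fixture_cache[[key]]
}

mild_distortion <- function() {
  matrix(c(0.93, 0.03, -0.02,
           0.01, 0.90,  0.04,
          -0.02, 0.03,  0.95), 3, 3, byrow = TRUE)
}

clean_scene <- function() {
  cached("clean", function() render_scene(scene_spec(seed = 7, noise_sd = 0)))
}

distorted_scene <- function() {
  cached("distorted", function()
    render_scene(scene_spec(seed = 11, distortion = mild_distortion(),
                            noise_sd = 2)))
}

clear_water_scene <- function() {
  # ample clear water: no foam; board and waterwheel in the upper part only
  cached("clearwater", function()
    render_scene(scene_spec(seed = 3, n_foam = 0,
                            waterwheel = c(360, 30, 456, 80), noise_sd = 2)))
}
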