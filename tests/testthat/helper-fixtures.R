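# Shared small fixtures, built in code at test time.

small_grid <- function(nlon = 20, nlat = 10) fire_grid(nlon, nlat)

# cached default dataset reused across test files (1250 cells)
fixture_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_dataset(fire_grid(50, 25), seed = 42)
    cache
  }
})

fixture_ba_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- fixture_dataset()
      cache <<- fit_fire_glm(d$predictors, d$fire$BA, "BA")
    }
    cache
  }
})

# dataset with no zero-inflation: the generative mean model then matches the
# GLM assumptions exactly, so truth recovery is well defined
recovery_truth <- function(zero_fraction = 0) {
  tr <- default_ground_truth()
  tr$zero_fraction <- zero_fraction
  tr
}
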