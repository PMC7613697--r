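# Shared synthetic world + pipeline run, generated once per test session.
world_cache <- new.env()

test_world <- function() {
  if (is.null(world_cache$w)) {
    world_cache$w <- generate_world(world_spec(
      seed = 42,
      target_adequacy = tibble::tibble(country = "CA",
                                       nutrient = "vitamin_a_mcg",
                                       percent_gap = -10)
    ))
  }
  world_cache$w
}

test_pipeline <- function() {
  if (is.null(world_cache$res)) {
    world_cache$res <- run_pipeline(
      test_world(),
      variants = c("raw", "processing_only", "flw_cooking_only", "final_best"),
      mc_draws = 100, seed = 42
    )
  }
  world_cache$res
}

max_rel_err <- function(a, b) {
  max(abs(a - b) / pmax(abs(b), 1e-12))
}
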