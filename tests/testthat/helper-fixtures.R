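# Shared fixtures, built once per test run.

# a clean centered-pupil native frame and its spec
clean_spec <- function(...) scene_spec(noise_sigma = 0, ...)

# small cached datasets so several test files can reuse them
fixture_env <- new.env()

small_suite <- function() {
  if (is.null(fixture_env$small)) {
    profile <- stats::setNames(rep(5L, 6), eye_labels())
    fixture_env$small <- generate_dataset(profile, seed = 424242L)
  }
  fixture_env$small
}
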