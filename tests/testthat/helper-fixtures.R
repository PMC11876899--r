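# Shared fixtures, built once per test run.  Everything is generated in
# code; nothing is read from disk.

fixture_env <- new.env()

# A 120-trial design (status-stratified subset of the 300-trial schedule)
# plus one option set, reused across likelihood/fit tests.
small_design <- function() {
  if (is.null(fixture_env$design)) {
    sched <- rstddm:::subset_schedule(generate_feedback_schedule(401), 120)
    opts <- generate_option_set(120, seed = 402)
    fixture_env$design <- list(schedule = sched, options = opts)
  }
  fixture_env$design
}

# One simulated prosocial-preset subject over the small design.
small_subject <- function() {
  if (is.null(fixture_env$subject)) {
    d <- small_design()
    fixture_env$subject <- generate_synthetic_subject(
      group_preset("prosocial"), 2, d$schedule, d$options, seed = 403,
      subject_id = "fix1")
  }
  fixture_env$subject
}

# Desk-scale fitting profile with a fixed seed for tests that fit.
test_profile <- function(seed = 404) fit_profile("desk", seed = seed)
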