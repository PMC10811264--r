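# Shared fixtures, built once per test run.

test_stps <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- stp_set_from_combined(combine_sources(generate_stp_fixture(1)))
    val
  }
})

test_plant <- function(...) head_neck_plant(...)
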