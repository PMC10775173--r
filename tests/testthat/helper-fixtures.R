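# Canonical form of a criteria string: parse + reformat, so suffix synonyms
# ("PVS1-PS", "PP3-PM") and spacing do not affect comparisons.
norm_criteria <- function(x) {
  vapply(parse_criteria(x), format_criteria, character(1))
}

fixture_classified <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- classify_variants(hem_fixture("variants"), hem_fixture("patients"))
    }
    cache
  }
})
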