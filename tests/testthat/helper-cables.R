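# Shared lazily-built cables so expensive builds happen once per test run.
.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

control_cable <- function() cached("control", function() {
  discretize(axon_spec("control"))
})

aoe1_cable <- function() cached("aoe1", function() {
  discretize(axon_spec("AOE1"))
})

aoe2_cable <- function() cached("aoe2", function() {
  discretize(axon_spec("AOE2"))
})

# long uniform passive cylinder (bare membrane), for analytic cable checks
long_passive_spec <- function(length_um = 6000) {
  axonwave:::new_axon_spec(
    tibble::tibble(kind = "axon", node = NA_integer_, inr = NA_integer_,
                   aoe = FALSE, length = length_um, diameter = 1.25,
                   cm_specific = 1, g_leak = 0.2, g_na = 0, g_ht = 0, g_lt = 0),
    condition = "long-passive")
}

# leak-only single compartment with direct access to R and tau
passive_single_spec <- function(g_leak = 0.2) {
  axonwave:::new_axon_spec(
    tibble::tibble(kind = "axon", node = NA_integer_, inr = NA_integer_,
                   aoe = FALSE, length = 10, diameter = 1.25,
                   cm_specific = 1, g_leak = g_leak, g_na = 0, g_ht = 0,
                   g_lt = 0),
    condition = "passive-single")
}
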