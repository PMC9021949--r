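# Shared fixtures, all built in code.

tiny_schema <- function() {
  new_schema(
    names = c("Complexion", "Tongue color", "Tone", "Pain site", "Sleep",
              "Pulse condition"),
    categories = c("inspection", "inspection", "listening_smelling",
                   "inquiry", "inquiry", "palpation"),
    cardinalities = c(3L, 4L, 2L, 5L, 3L, 2L)
  )
}

# Small architecture compatible with the 6-field schema: heights 6 -> 3 -> 1.
tiny_config <- function(...) {
  cfgcnn_config(k = 2L, cross_layers = 2L, conv_channels = c(2L, 3L),
                kernel_height = 2L, pool = 2L, maps_per_row = 2L,
                fgcnn_mlp = c(8L, 6L), head_hidden = c(10L, 8L), ...)
}

tiny_dataset <- function(n = 40L, schema = tiny_schema(), q = 0.9,
                         rho = 0.2, seed = 5L) {
  prof <- make_profiles(schema, seed = seed)
  generate_dataset(
    generator_config(n, signal_strength = q, missing_rate = rho,
                     seed = seed + 1L),
    schema, prof
  )
}

random_record <- function(schema, p_missing = 0.4) {
  card <- schema$fields$cardinality
  codes <- vapply(card, function(m) {
    if (stats::runif(1) < p_missing) -1L else sample.int(m, 1L) - 1L
  }, integer(1))
  names(codes) <- schema$fields$name
  codes
}
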