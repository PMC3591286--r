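# shared geometries built in code

# pentagon with the nest outside the polygon, as in the field layouts
pentagon_field <- function(side = 5, nest = c(0, -7)) {
  flower_array(nest, regular_polygon_array(5, side)$flowers)
}

# four flowers on the corners of the unit square, nest at the centre
unit_square_array <- function() {
  flower_array(c(0.5, 0.5),
               rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
}

# cohort driver returning per-bee flags without the full cohort machinery
run_bees <- function(array, params, n_bees, seed, l_opt = NULL, ...) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_bees)
  lapply(seeds, function(s) {
    p <- params
    p$rng_seed <- s
    run_bee(array, p, l_opt = l_opt, ...)
  })
}
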