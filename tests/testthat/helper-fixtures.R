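# Small in-code fixtures shared across test files.

tiny_counts <- function() {
  m <- matrix(c(10L, 20L, 30L,
                40L, 50L, 60L), nrow = 3,
              dimnames = list(c("OTU_a", "OTU_b", "OTU_c"),
                              c("lib1", "lib2")))
  m
}

tiny_metadata <- function() {
  tibble::tibble(
    library_id = c("lib1", "lib2"),
    treatment = c("13C", "unlabeled"),
    replicate = c(1L, 1L),
    fraction_label = c("1H", "2H"),
    buoyant_density = c(1.805, 1.798)
  )
}

# Scaled-down gradient scenario for fast end-to-end tests.
small_scenario <- function(seed = 1, ...) {
  sip_scenario(n_otus = 40, depth = 8000,
               incorporator_excess = c(0.99, 0.9),
               incorporator_abundance = c(0.02, 0.01),
               seed = seed, ...)
}

# Null gradients: two unlabeled gradients from the same truth, one
# relabeled as 13C. Returns counts/metadata plus the expected per-OTU
# composition used to decide testability.
simulate_null_gradients <- function(scenario) {
  set.seed(scenario$seed)
  truth <- simulation_truth(scenario)
  comp <- fraction_composition(truth, "unlabeled", scenario$windows)
  a <- sequence_fractions(comp, scenario, "13C")
  b <- sequence_fractions(comp, scenario, "unlabeled")
  list(counts = cbind(a$counts, b$counts),
       metadata = rbind(a$metadata, b$metadata),
       composition = comp)
}
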