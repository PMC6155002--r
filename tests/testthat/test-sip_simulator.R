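test_that("community simulation is a valid, seed-deterministic abundance vector", {
  expect_equal(simulate_community(2, 0), c(0.5, 0.5))
  a <- simulate_community(100, 2, seed = 42)
  b <- simulate_community(100, 2, seed = 42)
  expect_identical(a, b)
  expect_equal(sum(a), 1, tolerance = 1e-12)
  expect_true(all(a > 0))
  expect_error(simulate_community(1, 2), ">= 2")
  # sigma = 2 spans >= 3 orders of magnitude for a 500-OTU community
  for (s in 1:5) {
    x <- simulate_community(500, 2, seed = s)
    expect_gte(max(x) / min(x), 1e3)
  }
})

test_that("unlabeled rRNA stays light: heavy windows are near-empty", {
  set.seed(21)
  sc <- sip_scenario()
  truth <- simulation_truth(sc)
  fc <- fraction_composition(truth, "unlabeled", sc$windows)
  # per-OTU 1H window integral is a tiny share of each OTU's total mass
  # (the densest unlabeled OTUs, truncated at 1.782 g/ml, reach ~4e-3)
  expect_true(all(fc$integrals[, "1H"] < 5e-3))
  # ... so the whole 1H fraction falls below the amplification floor
  expect_lt(fc$window_mass[["1H"]], sc$amplification_floor)
  # while the light window tracks the baseline composition
  expect_gt(cor(fc$composition[, "L"], truth$otus$baseline), 0.99)
  expect_lt(sum(abs(fc$composition[, "L"] - truth$otus$baseline)) / 2, 0.1)
})

test_that("a heavily labeled OTU is enriched in the heaviest window", {
  set.seed(22)
  sc <- sip_scenario()
  truth <- simulation_truth(sc)
  fc <- fraction_composition(truth, "13C", sc$windows)
  top <- which(truth$otus$excess == 0.99)
  expect_gte(fc$composition[top, "1H"], 3 * truth$otus$baseline[top])
})

test_that("window integrals over a partition of the axis sum to 1 per OTU", {
  set.seed(23)
  sc <- sip_scenario(n_otus = 20)
  truth <- simulation_truth(sc)
  part <- list(H = c(1.84 + 1e-9, 1.90), M = c(1.77 + 1e-9, 1.84),
               L = c(1.60, 1.77))
  fc <- fraction_composition(truth, "13C", part)
  expect_equal(unname(rowSums(fc$integrals)), rep(1, 20), tolerance = 1e-4)
})

test_that("gradient sequencing is seed-deterministic with full library depth", {
  sc <- small_scenario(seed = 9)
  sim1 <- simulate_gradients(sc)
  sim2 <- simulate_gradients(sc)
  expect_identical(sim1$counts, sim2$counts)
  expect_identical(sim1$metadata, sim2$metadata)
  expect_equal(unname(colSums(sim1$counts)), rep(sc$depth, ncol(sim1$counts)))
  # the unlabeled 1H fraction is never amplified
  md <- sim1$metadata
  expect_false(any(md$treatment == "unlabeled" & md$fraction_label == "1H"))
  # the labeled OTUs keep the heaviest and third-heaviest windows amplifiable
  expect_true(all(c("1H", "3H", "L") %in%
                    md$fraction_label[md$treatment == "13C"]))
  # buoyant densities lie inside their windows
  for (i in seq_len(nrow(md))) {
    w <- sc$windows[[md$fraction_label[i]]]
    expect_true(md$buoyant_density[i] >= w[1] && md$buoyant_density[i] <= w[2])
  }
})

test_that("the full study-scale scenario amplifies the expected fractions", {
  sim <- simulate_gradients(sip_scenario(seed = 1))
  md <- sim$metadata
  expect_setequal(unique(md$fraction_label[md$treatment == "13C"]),
                  c("1H", "2H", "3H", "L"))
  expect_setequal(unique(md$fraction_label[md$treatment == "unlabeled"]),
                  c("3H", "L"))
  expect_equal(nrow(md), 3 * (4 + 2))
})

test_that("sequencing counts match multinomial moments for an abundant OTU", {
  set.seed(31)
  sc <- sip_scenario(seed = 31)
  sim <- simulate_gradients(sc)
  truth <- sim$truth
  comp <- fraction_composition(truth, "unlabeled", sc$windows)
  p <- comp$composition[, "L"]
  otu <- names(which.max(p))  # the dominant incorporator at ~2% baseline
  libs <- sim$metadata$library_id[sim$metadata$treatment == "unlabeled" &
                                    sim$metadata$fraction_label == "L"]
  expected <- sc$depth * p[otu]
  sd3 <- 3 * sqrt(sc$depth * p[otu] * (1 - p[otu]))
  expect_true(all(abs(sim$counts[otu, libs] - expected) < sd3 + 2))
})

test_that("simulated chemistry closes its 13C mass balance exactly", {
  chem <- simulate_chemistry()
  tr <- chem$truth
  expect_equal(tr$gaseous_13c_mmol + tr$dissolved_13c_mmol +
                 tr$residual_13c_mmol, tr$degraded_13c_mmol,
               tolerance = 1e-12)
  n <- nrow(tr)
  b <- tracer_budget(tr$degraded_13c_mmol[n], tr$gaseous_13c_mmol[n],
                     tr$dissolved_13c_mmol[n])
  expect_equal(b$recovery_percent, 100 * tr$mineralization_fraction[n],
               tolerance = 1e-9)
})

test_that("the chemistry analysis pipeline recovers the mineralized tracer", {
  chem <- simulate_chemistry(mineralization_fraction = 0.74)
  res <- analyze_chemistry(chem$samples)
  k <- sip_constants()
  # excess-based recovery equals (a_tracer - a_bg)/100 x mineralized
  expect_equal(res$budget$recovery_percent,
               (k$tracer_atom_percent - k$background_atom_percent) * 0.74,
               tolerance = 1e-6)
  expect_equal(res$budget$recovery_percent, 74, tolerance = 0.04)
  # dioxane declines ~50 mg/l over the 8-h incubation
  lab <- chem$samples[chem$samples$treatment == "13C", ]
  expect_equal(lab$dioxane_mg_per_l[1] - lab$dioxane_mg_per_l[5], 50,
               tolerance = 0.01)
})

test_that("zero degradation gives flat dioxane and background CO2 isotopes", {
  chem <- simulate_chemistry(rate_mg_per_l_h = 0)
  lab <- chem$samples[chem$samples$treatment == "13C", ]
  expect_true(all(lab$dioxane_mg_per_l == 200))
  a <- delta_to_atom_percent(lab$delta13c_co2_per_mil)
  expect_true(all(a <= 1.1 + 1e-9))
  expect_lt(diff(range(a)), 0.005)
  expect_error(simulate_chemistry(times = c(2, 1)), "ascending")
  expect_error(simulate_chemistry(rate_mg_per_l_h = -1), ">= 0")
})

test_that("expression simulation honors shapes, seeds and library depth", {
  shapes <- tibble::tibble(
    otu_id = c("a", "b", "c"),
    shape = c("linear_increase", "two_step", "none"),
    baseline_copies_per_ml = c(1e9, 2e9, 5e8))
  noiseless <- simulate_expression(shapes, noise_sigma = 0, seed = 4)
  t <- c(0, 2, 4, 6, 8)
  expect_equal(unname(noiseless$copies["a", ]), 1e9 * (1 + 0.5 * t))
  expect_equal(unname(noiseless$copies["b", ]), 2e9 * 3^c(0, 0, 1, 1, 2))
  expect_equal(unname(noiseless$copies["c", ]), rep(5e8, 5))
  s1 <- simulate_expression(shapes, seed = 7)
  s2 <- simulate_expression(shapes, seed = 7)
  expect_identical(s1$counts, s2$counts)
  expect_equal(unname(colSums(s1$counts)), rep(64000, 5))
  bad <- shapes; bad$shape[1] <- "exponential"
  expect_error(simulate_expression(bad), "unknown shape")
})
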