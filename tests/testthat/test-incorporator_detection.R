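test_that("libraries are assigned to fraction windows by buoyant density", {
  md <- tibble::tibble(
    library_id = paste0("l", 1:4), treatment = "13C", replicate = 1:4,
    fraction_label = "unassigned",
    buoyant_density = c(1.805, 1.780, 1.790, 1.770))
  got <- assign_fraction_windows(md)
  expect_identical(got$fraction_label, c("1H", "unassigned", "3H", "L"))
  expect_error(
    assign_fraction_windows(md, list(A = c(1.80, 1.81), B = c(1.805, 1.82))),
    "overlap")
})

test_that("comparator selection matches same label, falls back lighter, never L", {
  expect_identical(select_comparator("1H", c("2H", "3H", "L")), "2H")
  expect_identical(select_comparator("2H", c("2H", "3H", "L")), "2H")
  expect_identical(select_comparator("1H", c("3H", "L")), "3H")
  expect_warning(got <- select_comparator("1H", "L"), "skipping")
  expect_identical(got, NA_character_)
  expect_warning(select_comparator("3H", c("L")), "skipping")
  expect_error(select_comparator("1H", character(0)), "no available")
})

test_that("the pooled-variance t comparison reproduces the worked example", {
  call <- compare_otu("x", c(2.0, 2.2, 1.8), c(1.0, 1.1, 0.9))
  expect_equal(call$fold_change, 2.0)
  expect_equal(call$t_statistic, 7.746, tolerance = 1e-4)
  expect_equal(call$df, 4)
  expect_equal(call$p_value, 0.0015, tolerance = 0.05)
  expect_true(call$significant)
})

test_that("degenerate comparisons behave per contract", {
  same <- compare_otu("x", c(10, 10, 10), c(10, 10, 10))
  expect_equal(same$fold_change, 1.0)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  floor <- compare_otu("x", c(0.5, 0.6, 0.4), c(0, 0, 0),
                       pseudo_abundance = 0.001)
  expect_equal(floor$fold_change, 500)
  expect_true(floor$significant)  # t-test on the raw values decides
  zero_var <- compare_otu("x", c(1, 1, 1), c(0, 0, 0))
  expect_identical(zero_var$t_statistic, Inf)
  expect_equal(zero_var$p_value, 0)
})

test_that("the t statistic matches the independent stats::t.test oracle", {
  withr::with_seed(17, {
    for (i in 1:200) {
      x <- round(runif(sample(2:5, 1), 0, 5), 3)
      y <- round(runif(sample(2:5, 1), 0, 5), 3)
      if (var(x) == 0 && var(y) == 0) next
      ours <- compare_otu("o", x, y)
      ref <- t.test(x, y, var.equal = TRUE)
      expect_equal(ours$t_statistic, unname(ref$statistic), tolerance = 1e-6)
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-6)
      one <- compare_otu("o", x, y, one_sided = TRUE)
      ref1 <- t.test(x, y, var.equal = TRUE, alternative = "greater")
      expect_equal(one$p_value, ref1$p.value, tolerance = 1e-6)
    }
  })
})

test_that("detection recovers seeded incorporators end-to-end", {
  sim <- simulate_gradients(small_scenario(seed = 5))
  res <- suppressWarnings(detect_incorporators(sim$counts, sim$metadata,
                                               sip_config()))
  inc <- sim$truth$otus$otu_id[sim$truth$otus$excess > 0]
  called <- res$summary$otu_id[res$summary$is_incorporator]
  expect_true(all(inc %in% called))
  # summary is sorted by confirmations then fold change
  expect_true(!is.unsorted(rev(res$summary$n_confirmations)))
  expect_true(all(res$summary$is_incorporator ==
                    (res$summary$n_confirmations >= 1)))
  expect_true(all(res$summary$multi_fraction_confirmed ==
                    (res$summary$n_confirmations >= 2)))
  # calls respect the significance invariant
  cfg <- sip_config()
  expect_identical(res$calls$significant,
                   res$calls$p_value < cfg$alpha &
                     res$calls$fold_change > cfg$min_fold)
})

test_that("detection errors without an unlabeled treatment", {
  sim <- simulate_gradients(small_scenario(seed = 6))
  keep <- sim$metadata$treatment == "13C"
  expect_error(
    detect_incorporators(sim$counts[, sim$metadata$library_id[keep]],
                         sim$metadata[keep, ], sip_config()),
    "unlabeled")
})

test_that("a single-OTU table yields fold 1 and no significance", {
  md <- tibble::tibble(
    library_id = paste0("lib", 1:6),
    treatment = rep(c("13C", "unlabeled"), each = 3),
    replicate = rep(1:3, 2),
    fraction_label = "3H",
    buoyant_density = 1.790)
  one <- matrix(c(120L, 80L, 95L, 100L, 110L, 130L), nrow = 1,
                dimnames = list("solo", md$library_id))
  res <- suppressWarnings(detect_incorporators(one, md, sip_config()))
  expect_true(all(res$calls$fold_change == 1))
  expect_true(all(!res$calls$significant))
})

test_that("calls are invariant to rescaling any single library's depth", {
  sim <- simulate_gradients(small_scenario(seed = 12))
  res1 <- suppressWarnings(detect_incorporators(sim$counts, sim$metadata,
                                                sip_config()))
  scaled <- sim$counts
  scaled[, 4] <- scaled[, 4] * 7L
  res2 <- suppressWarnings(detect_incorporators(scaled, sim$metadata,
                                                sip_config()))
  expect_equal(res1$calls$p_value, res2$calls$p_value)
  expect_equal(res1$calls$fold_change, res2$calls$fold_change)
})

test_that("raising an OTU's heavy 13C counts never lowers its fold change", {
  sim <- simulate_gradients(small_scenario(seed = 13))
  md <- sim$metadata
  libs <- md$library_id[md$treatment == "13C" & md$fraction_label == "3H"]
  otu <- rownames(sim$counts)[10]
  folds <- vapply(c(0L, 50L, 500L, 5000L), function(add) {
    m <- sim$counts; m[otu, libs] <- m[otu, libs] + add
    res <- suppressWarnings(detect_incorporators(m, md, sip_config()))
    res$calls$fold_change[res$calls$otu_id == otu &
                            res$calls$fraction_label == "3H"]
  }, numeric(1))
  expect_true(all(diff(folds) >= 0))
})

test_that("the vectorized caller agrees with the scalar comparison", {
  sim <- simulate_gradients(small_scenario(seed = 14))
  cfg <- sip_config()
  res <- suppressWarnings(detect_incorporators(sim$counts, sim$metadata, cfg))
  rel <- relative_abundance(sim$counts)
  md <- sim$metadata
  some <- res$calls[unique(round(seq(1, nrow(res$calls), length.out = 15))), ]
  for (i in seq_len(nrow(some))) {
    row <- some[i, ]
    l13 <- md$library_id[md$treatment == "13C" &
                           md$fraction_label == row$fraction_label]
    lun <- md$library_id[md$treatment == "unlabeled" &
                           md$fraction_label == row$comparator_fraction_label]
    ref <- compare_otu(row$otu_id, rel[row$otu_id, l13], rel[row$otu_id, lun],
                       cfg$alpha, cfg$min_fold, cfg$pseudo_abundance)
    expect_equal(row$t_statistic, ref$t_statistic, tolerance = 1e-9)
    expect_equal(row$p_value, ref$p_value, tolerance = 1e-9)
    expect_equal(row$fold_change, ref$fold_change, tolerance = 1e-9)
  }
})
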