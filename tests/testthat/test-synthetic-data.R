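test_that("screen design enforces the assay geometry", {
  pairs <- edges_df("A", "B")
  expect_error(screen_design(pairs, combos_per_pair = 6),
               class = "peroxnet_bad_design")
  expect_error(screen_design(pairs, duplicates_per_combo = 0),
               class = "peroxnet_bad_design")
  d <- screen_design(pairs, seed = 3)
  expect_s3_class(d, "screen_design")
  expect_identical(d$combos_per_pair, 8L)
})

test_that("noise model validates its parameters", {
  expect_error(noise_model(ratio_noise_sd = -0.1), class = "peroxnet_bad_noise")
  expect_error(noise_model(positive_ratio_range = c(0.05, 0.5)),
               class = "peroxnet_bad_noise")
  expect_error(noise_model(positive_ratio_range = c(0.5, 0.2)),
               class = "peroxnet_bad_noise")
})

test_that("simulated plates have the documented schema and controls", {
  d <- screen_design(edges_df("A", "B", "A", "C"), seed = 11)
  plates <- simulate_screen_plates(d, edges_df("A", "B"))
  expect_named(plates, c("experiment_id", "plate_id", "well_id",
                         "donor_construct", "acceptor_construct",
                         "donor_terminus", "acceptor_terminus", "replicate",
                         "intensity_535", "intensity_475", "well_class"))
  # 2 pairs x 8 combos x 2 duplicates sample wells
  expect_identical(sum(plates$well_class == "sample"), 32L)
  expect_true(all(c("donor_control", "positive_control", "fusion_control")
                  %in% plates$well_class))
  # every sample donor construct has correction-factor wells
  expect_true(all(unique(plates$donor_construct[plates$well_class == "sample"])
                  %in% plates$donor_construct[plates$well_class == "donor_control"]))
})

test_that("a fixed seed reproduces the plate table byte-identically", {
  d <- screen_design(edges_df("A", "B", "A", "C"), seed = 7)
  t1 <- simulate_screen_plates(d, edges_df("A", "B"))
  t2 <- simulate_screen_plates(d, edges_df("A", "B"))
  expect_identical(t1, t2)
  d2 <- screen_design(edges_df("A", "B", "A", "C"), seed = 8)
  expect_false(identical(t1, simulate_screen_plates(d2, edges_df("A", "B"))))
})

test_that("truth pairs missing from the design are rejected", {
  d <- screen_design(edges_df("A", "B"), seed = 1)
  expect_error(simulate_screen_plates(d, edges_df("A", "Z")),
               class = "peroxnet_truth_not_in_design")
})

test_that("zero-noise plates are decoded exactly back to the truth set", {
  # small two-pair design
  d <- screen_design(edges_df("A", "B", "A", "C"), seed = 7)
  plates <- simulate_screen_plates(d, edges_df("A", "B"),
                                   noise_model(ratio_noise_sd = 0))
  calls <- bret_call(plates)
  expect_identical(positive_partners(calls, "A"), "B")

  # property: arbitrary random truth sets over a larger library
  lib <- paste0("P", sprintf("%02d", 1:25))
  for (seed in c(2, 5, 9)) {
    set.seed(seed)
    truth <- sample(lib, sample(3:10, 1))
    plates <- simulate_library_screen("BAIT", lib, truth,
                                      noise_model(ratio_noise_sd = 0),
                                      seed = seed)
    calls <- run_screen(plates, "BAIT", lib)
    expect_setequal(positive_partners(calls, "BAIT"), truth)
  }
})

test_that("the 90-protein library screen recovers the 18 WT partners", {
  plates <- simulate_library_screen("PEX26", fx$library90$protein,
                                    fx$wt_partners$partner,
                                    noise_model(ratio_noise_sd = 0), seed = 1)
  calls <- run_screen(plates, "PEX26", fx$library90$protein)
  expect_identical(sum(calls$positive), 18L)
  expect_setequal(positive_partners(calls, "PEX26"), fx$wt_partners$partner)
})

test_that("false-positive rate grows with ratio noise", {
  # expected false-call count is monotone in sd (checked by simulation)
  lib <- paste0("Q", 1:12)
  fp_rate <- function(sd, seeds) {
    mean(vapply(seeds, function(s) {
      plates <- simulate_library_screen("BAIT", lib, "Q1",
                                        noise_model(ratio_noise_sd = sd),
                                        seed = s)
      calls <- bret_call(plates)
      sum(setdiff(positive_partners(calls, "BAIT"), "Q1") %in% lib)
    }, numeric(1)))
  }
  seeds <- 1:40
  rates <- vapply(c(0, 0.03, 0.12), fp_rate, numeric(1), seeds = seeds)
  expect_true(all(diff(rates) >= 0))
  expect_identical(rates[1], 0)
  expect_gt(rates[3], rates[1])
})

test_that("fixture bundle loads and enforces its invariants", {
  expect_s3_class(fx, "perox_fixture_bundle")
  expect_identical(nrow(fx$variant_matrix), 8L)
  expect_identical(ncol(fx$variant_matrix) - 1L, 18L)
  # p.Leu153Val keeps 14 of 18 partners
  l153 <- fx$variant_matrix[fx$variant_matrix$variant_id == "p.Leu153Val", -1]
  expect_identical(sum(l153 == 1, na.rm = TRUE), 14L)

  # a truncated library must be refused, naming the invariant
  bad <- fx
  bad$library90 <- bad$library90[-1, ]
  expect_error(peroxnet:::validate_fixture_bundle(bad),
               regexp = "library90 must have exactly 90")

  # a broken conserved column must be refused
  bad2 <- fx
  bad2$variant_matrix$PEX5[3] <- 0L
  expect_error(peroxnet:::validate_fixture_bundle(bad2),
               regexp = "PEX5, PEX14, PEX19")
})

test_that("missing fixture files give a named load error", {
  tmp <- withr::local_tempdir()
  expect_error(perox_fixtures(tmp), class = "peroxnet_fixture_missing")
})
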