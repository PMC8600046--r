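test_that("correction factor is the mean control-well ratio", {
  one <- tibble::tibble(experiment_id = "E1", well_class = "donor_control",
                        donor_construct = "X-N",
                        intensity_535 = 50, intensity_475 = 1000)
  expect_equal(bret_correction_factors(one)$cf, 0.05)

  two <- tibble::tibble(experiment_id = "E1", well_class = "donor_control",
                        donor_construct = "X-N",
                        intensity_535 = c(50, 70), intensity_475 = 1000)
  expect_equal(bret_correction_factors(two)$cf, 0.06)

  zero_id <- dplyr::mutate(one, intensity_475 = 0)
  expect_error(bret_correction_factors(zero_id),
               class = "peroxnet_bad_intensity")
  expect_error(bret_correction_factors(dplyr::filter(one, FALSE)),
               class = "peroxnet_no_controls")
})

test_that("the ratio formula is I_A / I_D - cf", {
  expect_equal(bret_ratio(1100, 1000, 0.1), 1.0)
  expect_equal(bret_ratio(94, 1000, 0), 0.094)
  expect_equal(bret_ratio(100, 1000, 0.1), 0.0)
  expect_error(bret_ratio(100, 0, 0), class = "peroxnet_bad_intensity")
  expect_error(bret_ratio(100, -5, 0), class = "peroxnet_bad_intensity")
})

test_that("a pair is positive iff any combo mean exceeds the threshold strictly", {
  # all combos below threshold -> negative
  low <- plates_from_ratios(c(-0.01, 0.02, 0.05, 0.03, 0.01, 0.04, 0.0, 0.02))
  expect_false(bret_call(low)$positive)

  # one hot combo among seven null ones -> positive
  hot <- plates_from_ratios(c(0.12, 0.01, 0.0, 0.02, 0.01, 0.0, 0.03, 0.01))
  expect_true(bret_call(hot)$positive)
  expect_identical(bret_call(hot)$n_positive_combos, 1L)

  # ratio exactly at the threshold is negative (strict inequality)
  boundary <- plates_from_ratios(c(0.094, 0.01, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0))
  expect_false(bret_call(boundary)$positive)
})

test_that("duplicates are averaged per combination before thresholding", {
  # one combo with duplicates 0.05 / 0.2: mean 0.125 > threshold
  p <- plates_from_ratios(c(0.05))
  p2 <- dplyr::mutate(p, replicate = 2L,
                      intensity_535 = ifelse(well_class == "sample", 200, intensity_535),
                      well_id = "B01")
  both <- dplyr::bind_rows(p, p2)
  call <- bret_call(both)
  expect_true(call$positive)
  expect_equal(call$max_ratio, 0.125)
})

test_that("an unknown donor construct is reported by name", {
  p <- plates_from_ratios(c(0.2))
  p_bad <- dplyr::filter(p, well_class == "sample")  # drop its cf wells
  extra_ctrl <- dplyr::mutate(dplyr::filter(p, well_class == "donor_control"),
                              donor_construct = "OTHER-N")
  expect_error(bret_call(dplyr::bind_rows(p_bad, extra_ctrl)),
               regexp = "AAA-", class = "peroxnet_missing_cf")
})

test_that("calling is invariant to well order and channel scaling", {
  d <- screen_design(edges_df("A", "B", "A", "C", "B", "C"), seed = 5)
  plates <- simulate_screen_plates(d, edges_df("A", "B", "B", "C"),
                                   noise_model(ratio_noise_sd = 0.01))
  ref <- bret_call(plates)
  shuffled <- plates[sample(nrow(plates)), ]
  expect_equal(bret_call(shuffled), ref)
  scaled <- dplyr::mutate(plates, intensity_535 = intensity_535 * 3.7,
                          intensity_475 = intensity_475 * 3.7)
  expect_equal(bret_call(scaled), ref)
})

test_that("confirmation needs a positive primary and two positive replicates", {
  d <- screen_design(edges_df("A", "B", "A", "C"), seed = 2)
  nm <- noise_model(ratio_noise_sd = 0)
  truth <- edges_df("A", "B")
  primary <- bret_call(simulate_screen_plates(d, truth, nm, experiment_id = "E1"))
  rep_pos <- lapply(c("E2", "E3"), function(e)
    bret_call(simulate_screen_plates(d, truth, nm, experiment_id = e)))
  rep_neg <- bret_call(simulate_screen_plates(d, edges_df("A", "C"), nm,
                                              experiment_id = "E4"))

  two <- confirm_calls(primary, rep_pos)
  confirmed_pair <- two[two$confirmed, c("pair_a", "pair_b")]
  expect_identical(nrow(confirmed_pair), 1L)
  expect_setequal(unlist(confirmed_pair), c("A", "B"))

  one <- confirm_calls(primary, rep_pos[1])
  expect_false(any(one$confirmed))

  # a primary-negative pair stays unconfirmed however many replicates agree
  neg <- confirm_calls(primary, list(rep_neg, rep_neg, rep_neg))
  ac <- dplyr::filter(neg, pair_a == "A", pair_b == "C")
  expect_false(ac$positive)
  expect_false(ac$confirmed)
})

test_that("the splice-variant screen yields 9 of the 18 partners", {
  plates <- simulate_library_screen("PEX26DEX5", fx$wt_partners$partner,
                                    fx$dex5_partners$partner,
                                    noise_model(ratio_noise_sd = 0), seed = 4)
  calls <- run_screen(plates, "PEX26DEX5", fx$wt_partners$partner)
  expect_identical(sum(calls$positive), 9L)
  expect_setequal(positive_partners(calls, "PEX26DEX5"), fx$dex5_partners$partner)
})

test_that("an empty library yields an empty call table", {
  p <- plates_from_ratios(c(0.2))
  out <- run_screen(p, "AAA", character(0))
  expect_identical(nrow(out), 0L)
  expect_true(attr(out, "screen_valid"))
})

test_that("a failed positive control flags the screen invalid", {
  d <- screen_design(edges_df("A", "B"), seed = 6)
  plates <- simulate_screen_plates(d, edges_df("A", "B"),
                                   noise_model(ratio_noise_sd = 0))
  # sabotage the positive-control wells: acceptor channel at background
  pc <- plates$well_class == "positive_control"
  plates$intensity_535[pc] <- plates$intensity_475[pc] * 0.05
  expect_warning(out <- run_screen(plates, "A", "B"),
                 regexp = "positive-control")
  expect_false(attr(out, "screen_valid"))
})
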