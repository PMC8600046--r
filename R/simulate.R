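#' Define a BRET screen design
#'
#' A screen tests every listed protein pair in all eight fusion
#' combinations (which protein carries the luciferase donor, crossed with
#' N- or C-terminal fusion of donor and acceptor), each combination in
#' duplicate wells. Every plate additionally carries, per donor construct,
#' negative-control wells (donor co-expressed with free acceptor, used for
#' the correction factor), the positive-control interaction pair
#' bJun-bFos, and the acceptor-donor fusion control YFP-Rluc.
#'
#' @param pairs Data frame with columns `protein_a`, `protein_b`:
#'   unordered protein pairs to test.
#' @param combos_per_pair Number of fusion combinations per pair. The
#'   assay geometry fixes this at 8; other values are rejected.
#' @param duplicates_per_combo Wells per combination (>= 1).
#' @param seed Integer seed; a fixed seed makes the simulated plate table
#'   byte-identical across runs.
#' @return A `screen_design` object.
#' @examples
#' d <- screen_design(data.frame(protein_a = "PEX26", protein_b = "PEX6"), seed = 1)
#' @export
screen_design <- function(pairs, combos_per_pair = 8L, duplicates_per_combo = 2L,
                          seed = 1L) {
  stop_missing_cols(pairs, c("protein_a", "protein_b"), "`pairs`")
  if (combos_per_pair != 8L) {
    abort("combos_per_pair must be exactly 8 (N/C fusion terminus of each partner x donor/acceptor role)",
          class = "peroxnet_bad_design")
  }
  if (duplicates_per_combo < 1L) {
    abort("duplicates_per_combo must be >= 1", class = "peroxnet_bad_design")
  }
  pairs <- tibble(
    protein_a = norm_symbol(pairs$protein_a),
    protein_b = norm_symbol(pairs$protein_b)
  ) |>
    mutate(key = pair_key(.data$protein_a, .data$protein_b)) |>
    distinct(.data$key, .keep_all = TRUE)
  structure(
    list(pairs = pairs, combos_per_pair = 8L,
         duplicates_per_combo = as.integer(duplicates_per_combo),
         control_pairs = c(positive = "BJUN|BFOS", fusion = "YFP-RLUC"),
         seed = as.integer(seed)),
    class = "screen_design")
}

#' Define the noise model of the synthetic screen
#'
#' Donor-channel intensities are drawn log-normal (plate luminescence is
#' positive and right-skewed). The acceptor channel of each well is
#' generated as `I_D * (cf + r + e)` where `cf` is the construct's
#' background ratio, `r` the underlying interaction ratio and
#' `e ~ Normal(0, ratio_noise_sd)`; this keeps the generative model exactly
#' invertible by the ratio formula used for calling. True pairs draw `r`
#' uniformly from `positive_ratio_range` in the combinations where the
#' orientation supports energy transfer; false pairs and non-supporting
#' combinations use `r = 0`.
#'
#' @param donor_meanlog,donor_sdlog Log-normal parameters of the donor
#'   (475 nm) intensity, arbitrary luminescence units.
#' @param baseline_cf Background acceptor/donor ratio of a donor construct
#'   with free acceptor (dimensionless).
#' @param ratio_noise_sd Standard deviation of the additive ratio noise;
#'   0 gives a noise-free screen whose calls equal the ground truth.
#' @param positive_ratio_range Range (low, high) of underlying ratios for
#'   true interactions; `low` must exceed the calling threshold so that a
#'   noise-free screen is calibrated.
#' @param threshold Calling threshold the range is validated against.
#' @return A `bret_noise_model` object.
#' @export
noise_model <- function(donor_meanlog = log(2e4), donor_sdlog = 0.4,
                        baseline_cf = 0.05, ratio_noise_sd = 0.02,
                        positive_ratio_range = c(0.15, 0.6),
                        threshold = 0.094) {
  if (ratio_noise_sd < 0) {
    abort("ratio_noise_sd must be >= 0", class = "peroxnet_bad_noise")
  }
  if (length(positive_ratio_range) != 2L ||
      positive_ratio_range[1] > positive_ratio_range[2]) {
    abort("positive_ratio_range must be c(low, high) with low <= high",
          class = "peroxnet_bad_noise")
  }
  if (positive_ratio_range[1] <= threshold) {
    abort("positive_ratio_range low end must exceed the calling threshold",
          class = "peroxnet_bad_noise")
  }
  structure(
    list(donor_meanlog = donor_meanlog, donor_sdlog = donor_sdlog,
         baseline_cf = baseline_cf, ratio_noise_sd = ratio_noise_sd,
         positive_ratio_range = positive_ratio_range),
    class = "bret_noise_model")
}

#' Simulate raw plate readings for a screen with known ground truth
#'
#' Emits one well record per pair x combination x duplicate, plus the
#' per-donor-construct control wells and the control pairs, in the same
#' table layout a plate reader export would be parsed into.
#'
#' @param design A [screen_design()].
#' @param truth Data frame (`protein_a`, `protein_b`) of truly interacting
#'   pairs; must be a subset of the design's pairs.
#' @param noise A [noise_model()].
#' @param experiment_id Identifier stamped on every well.
#' @return Tibble with columns `experiment_id`, `plate_id`, `well_id`,
#'   `donor_construct`, `acceptor_construct`, `donor_terminus`,
#'   `acceptor_terminus`, `replicate`, `intensity_535`, `intensity_475`,
#'   `well_class`.
#' @examples
#' d <- screen_design(data.frame(protein_a = "A", protein_b = c("B", "C")), seed = 7)
#' tr <- data.frame(protein_a = "A", protein_b = "B")
#' plates <- simulate_screen_plates(d, tr, noise_model(ratio_noise_sd = 0))
#' @export
simulate_screen_plates <- function(design, truth, noise = noise_model(),
                                   experiment_id = "EXP1") {
  stopifnot(inherits(design, "screen_design"), inherits(noise, "bret_noise_model"))
  stop_missing_cols(truth, c("protein_a", "protein_b"), "`truth`")
  truth_keys <- unique(pair_key(truth$protein_a, truth$protein_b))
  unknown <- setdiff(truth_keys, design$pairs$key)
  if (length(unknown)) {
    abort(paste0("truth pair(s) absent from design: ",
                 paste(gsub("\\|", "-", unknown), collapse = ", ")),
          class = "peroxnet_truth_not_in_design")
  }

  # per-pair grid: 8 combos = donor role (2) x donor terminus (2) x acceptor terminus (2)
  combos <- tidyr::expand_grid(
    donor_is_a = c(TRUE, FALSE),
    donor_terminus = c("N", "C"),
    acceptor_terminus = c("N", "C"))

  set.seed(design$seed)
  wells <- tidyr::expand_grid(design$pairs, combos,
                              replicate = seq_len(design$duplicates_per_combo)) |>
    mutate(
      donor_protein = ifelse(.data$donor_is_a, .data$protein_a, .data$protein_b),
      acceptor_protein = ifelse(.data$donor_is_a, .data$protein_b, .data$protein_a),
      combo_id = paste0(ifelse(.data$donor_is_a, "AB", "BA"),
                        .data$donor_terminus, .data$acceptor_terminus),
      well_class = "sample")

  # choose, per true pair, a non-empty subset of orientation-supporting combos
  combo_levels <- unique(wells$combo_id)
  pos_combos <- lapply(setNames(truth_keys, truth_keys), function(k) {
    n_pos <- sample.int(8L, 1L)
    sample(combo_levels, n_pos)
  })
  r_true <- function(n) stats::runif(n, noise$positive_ratio_range[1],
                                     noise$positive_ratio_range[2])
  wells <- wells |>
    mutate(is_true = .data$key %in% truth_keys) |>
    group_by(.data$key, .data$combo_id) |>
    mutate(combo_positive = .data$is_true[1] &&
             .data$combo_id[1] %in% pos_combos[[.data$key[1]]]) |>
    mutate(ratio_true = if (.data$combo_positive[1]) r_true(1) else 0) |>
    ungroup()

  # per-donor-construct correction-factor wells (donor + free acceptor);
  # the control constructs get their own cf wells too
  donor_constructs <- unique(c(paste0(wells$donor_protein, "-", wells$donor_terminus),
                               "BJUN-N", "YFP-RLUC"))
  ctrl <- tidyr::expand_grid(
    donor_construct = donor_constructs,
    replicate = seq_len(design$duplicates_per_combo)) |>
    mutate(acceptor_construct = "YFP-free",
           donor_terminus = sub("^.*-", "", .data$donor_construct),
           acceptor_terminus = NA_character_,
           well_class = "donor_control", ratio_true = 0)

  # fixed control pairs present on every plate
  ctl_pairs <- tibble(
    donor_construct = c("BJUN-N", "YFP-RLUC"),
    acceptor_construct = c("BFOS-N", "YFP-RLUC"),
    donor_terminus = c("N", "N"), acceptor_terminus = c("N", "N"),
    well_class = c("positive_control", "fusion_control"),
    ratio_true = c(mean(noise$positive_ratio_range), 1.0)) |>
    tidyr::expand_grid(replicate = seq_len(design$duplicates_per_combo))

  sample_wells <- wells |>
    mutate(donor_construct = paste0(.data$donor_protein, "-", .data$donor_terminus),
           acceptor_construct = paste0(.data$acceptor_protein, "-",
                                       .data$acceptor_terminus)) |>
    select("donor_construct", "acceptor_construct", "donor_terminus",
           "acceptor_terminus", "replicate", "well_class", "ratio_true")

  all_wells <- bind_rows(sample_wells, ctrl, ctl_pairs)
  n <- nrow(all_wells)
  i_d <- rlnorm(n, noise$donor_meanlog, noise$donor_sdlog)
  eps <- if (noise$ratio_noise_sd > 0) rnorm(n, 0, noise$ratio_noise_sd) else 0
  i_a <- i_d * pmax(noise$baseline_cf + all_wells$ratio_true + eps, 0)

  wells_per_plate <- 96L
  all_wells |>
    mutate(
      experiment_id = experiment_id,
      intensity_475 = round(i_d, 1),
      intensity_535 = round(i_a, 1),
      plate_id = paste0("P", sprintf("%03d", (row_number() - 1L) %/% wells_per_plate + 1L)),
      well_id = sprintf("%s%02d",
                        LETTERS[((row_number() - 1L) %% wells_per_plate) %/% 12L + 1L],
                        (row_number() - 1L) %% 12L + 1L)) |>
    select("experiment_id", "plate_id", "well_id", "donor_construct",
           "acceptor_construct", "donor_terminus", "acceptor_terminus",
           "replicate", "intensity_535", "intensity_475", "well_class")
}

#' Simulate a complete bait-versus-library screen
#'
#' Convenience wrapper: builds the design for one bait against a protein
#' library and simulates its plates.
#'
#' @param bait Bait protein symbol.
#' @param library Character vector of library protein symbols.
#' @param true_partners Symbols of library proteins that truly interact
#'   with the bait.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param experiment_id Identifier stamped on every well.
#' @return Plate tibble as from [simulate_screen_plates()].
#' @export
simulate_library_screen <- function(bait, library, true_partners,
                                    noise = noise_model(), seed = 1L,
                                    experiment_id = "EXP1") {
  design <- screen_design(
    tibble(protein_a = bait, protein_b = setdiff(norm_symbol(library), norm_symbol(bait))),
    seed = seed)
  truth <- tibble(protein_a = bait, protein_b = true_partners)
  simulate_screen_plates(design, truth, noise, experiment_id = experiment_id)
}
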