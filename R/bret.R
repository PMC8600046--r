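#' Correction factors from donor-only control wells
#'
#' For each donor construct the background ratio (the correction factor,
#' `cf`) is the mean, over its control wells (donor co-expressed with free
#' acceptor), of the 535 nm / 475 nm intensity ratio.
#'
#' @param plates Plate tibble (see [simulate_screen_plates()] for the
#'   schema). Only rows with `well_class == "donor_control"` are used.
#' @return Tibble `experiment_id`, `donor_construct`, `cf`, `n_wells`.
#'   Negative `cf` values are kept but flagged in a `flagged` column.
#' @examples
#' ctrl <- tibble::tibble(experiment_id = "E1", well_class = "donor_control",
#'                        donor_construct = "X-N",
#'                        intensity_535 = c(50, 70), intensity_475 = 1000)
#' bret_correction_factors(ctrl)
#' @export
bret_correction_factors <- function(plates) {
  stop_missing_cols(plates, c("experiment_id", "donor_construct", "well_class",
                              "intensity_535", "intensity_475"), "`plates`")
  ctrl <- plates |> filter(.data$well_class == "donor_control")
  if (nrow(ctrl) == 0) {
    abort("no donor control wells (well_class == 'donor_control') in input",
          class = "peroxnet_no_controls")
  }
  if (any(ctrl$intensity_475 <= 0)) {
    abort("control wells with non-positive 475 nm intensity are not evaluable",
          class = "peroxnet_bad_intensity")
  }
  ctrl |>
    group_by(.data$experiment_id, .data$donor_construct) |>
    summarise(cf = mean(.data$intensity_535 / .data$intensity_475),
              n_wells = n(), .groups = "drop") |>
    mutate(flagged = .data$cf < 0)
}

#' BRET ratio of a single well
#'
#' `R = I_A / I_D - cf`, where `I_A` is the acceptor-channel (535 nm)
#' intensity, `I_D` the donor-channel (475 nm) intensity, and `cf` the
#' donor construct's correction factor.
#'
#' @param i_a,i_d Acceptor and donor channel intensities (vectors allowed).
#' @param cf Correction factor(s).
#' @return Numeric vector of BRET ratios.
#' @examples
#' bret_ratio(1100, 1000, 0.1) # 1.0
#' bret_ratio(94, 1000, 0)     # 0.094
#' @export
bret_ratio <- function(i_a, i_d, cf) {
  if (any(i_d <= 0)) {
    abort("donor-channel intensity (I_D) must be > 0",
          class = "peroxnet_bad_intensity")
  }
  i_a / i_d - cf
}

# internal: sample wells with per-well ratios and combo labels
ratio_wells <- function(plates, cfs) {
  samples <- plates |>
    filter(.data$well_class == "sample") |>
    inner_join(cfs |> select("experiment_id", "donor_construct", "cf"),
               by = c("experiment_id", "donor_construct"))
  missing_cf <- plates |>
    filter(.data$well_class == "sample") |>
    anti_join(cfs, by = c("experiment_id", "donor_construct")) |>
    distinct(.data$donor_construct)
  if (nrow(missing_cf)) {
    abort(paste0("no correction factor for donor construct(s): ",
                 paste(missing_cf$donor_construct, collapse = ", ")),
          class = "peroxnet_missing_cf")
  }
  samples |>
    mutate(
      ratio = bret_ratio(.data$intensity_535, .data$intensity_475, .data$cf),
      protein_a_raw = sub("-[NC]$", "", .data$donor_construct),
      protein_b_raw = sub("-[NC]$", "", .data$acceptor_construct),
      pair = pair_key(.data$protein_a_raw, .data$protein_b_raw),
      combo = paste0(ifelse(.data$protein_a_raw <= .data$protein_b_raw, "AB", "BA"),
                     .data$donor_terminus, .data$acceptor_terminus))
}

#' Call interactions from plate readings
#'
#' Duplicate wells of each fusion combination are averaged into one ratio
#' per combination; a pair is called positive when at least one of its
#' combinations has a mean ratio strictly above the threshold. A ratio
#' exactly at the threshold is negative. Pairs observed with fewer than 8
#' combinations are still called, flagged via `n_combos`.
#'
#' @param plates Plate tibble.
#' @param cfs Optional correction-factor table; computed from the plates'
#'   donor-control wells when omitted.
#' @param threshold Calling threshold (method-specific; default 0.094).
#' @return Tibble `pair_a`, `pair_b`, `max_ratio`, `n_positive_combos`,
#'   `n_combos`, `positive` (one row per unordered pair), ordered by pair.
#' @export
bret_call <- function(plates, cfs = NULL, threshold = 0.094) {
  cfs <- cfs %||% bret_correction_factors(plates)
  rw <- ratio_wells(plates, cfs)
  rw |>
    group_by(.data$pair, .data$combo) |>
    summarise(combo_ratio = mean(.data$ratio), .groups = "drop") |>
    group_by(.data$pair) |>
    summarise(
      max_ratio = max(.data$combo_ratio),
      n_positive_combos = sum(.data$combo_ratio > threshold),
      n_combos = n(),
      positive = .data$n_positive_combos >= 1L,
      .groups = "drop") |>
    tidyr::separate_wider_delim("pair", "|", names = c("pair_a", "pair_b")) |>
    arrange(.data$pair_a, .data$pair_b)
}

#' Confirm primary calls against additional independent experiments
#'
#' An interaction is confirmed when it is positive in the primary screen
#' and positive in at least two additional independent experiments (any
#' fusion combination counts).
#'
#' @param primary Call table from [bret_call()] for the primary experiment.
#' @param replicates List of call tables, one per additional independent
#'   experiment, or a single tibble with an `experiment_id` column.
#' @param n_required Number of positive additional experiments required
#'   (default 2).
#' @return `primary` with `confirmations` and `confirmed` columns added.
#' @export
confirm_calls <- function(primary, replicates, n_required = 2L) {
  if (is.data.frame(replicates)) {
    stop_missing_cols(replicates, "experiment_id", "`replicates`")
    replicates <- split(replicates, replicates$experiment_id)
  }
  pk <- pair_key(primary$pair_a, primary$pair_b)
  conf <- rep(0L, nrow(primary))
  for (rep_calls in replicates) {
    rk <- pair_key(rep_calls$pair_a, rep_calls$pair_b)
    conf <- conf + as.integer(pk %in% rk[rep_calls$positive])
  }
  primary |>
    mutate(confirmations = conf,
           confirmed = .data$positive & conf >= n_required)
}

#' Run a full bait-versus-library screen from plate readings
#'
#' Computes correction factors, calls every bait-library pair, and
#' evaluates the plate controls: the positive-control pair must call
#' positive, otherwise the screen is flagged invalid (with a warning).
#'
#' @param plates Plate tibble containing sample and control wells.
#' @param bait Bait protein symbol.
#' @param library Character vector of library symbols screened against the
#'   bait. Pairs involving other proteins are ignored.
#' @param threshold Calling threshold.
#' @return Call tibble restricted to bait-library pairs, with attributes
#'   `screen_valid` (logical) and `controls` (control evaluation tibble).
#' @export
run_screen <- function(plates, bait, library, threshold = 0.094) {
  bait <- norm_symbol(bait)
  if (length(library) == 0) {
    out <- tibble(pair_a = character(), pair_b = character(),
                  max_ratio = numeric(), n_positive_combos = integer(),
                  n_combos = integer(), positive = logical())
    attr(out, "screen_valid") <- TRUE
    return(out)
  }
  library <- norm_symbol(library)
  cfs <- bret_correction_factors(plates)
  calls <- bret_call(plates, cfs, threshold)

  # evaluate the positive-control pair on its own wells
  ctl <- plates |> filter(.data$well_class == "positive_control")
  ctl_ok <- NA
  if (nrow(ctl)) {
    ctl_cf <- cfs |> filter(.data$donor_construct %in% ctl$donor_construct)
    cf_val <- if (nrow(ctl_cf)) ctl_cf$cf[1] else 0
    ctl_ratio <- mean(bret_ratio(ctl$intensity_535, ctl$intensity_475, cf_val))
    ctl_ok <- ctl_ratio > threshold
  }
  if (isFALSE(ctl_ok)) {
    warn("positive-control pair failed to call positive; screen flagged invalid")
  }

  keys <- pair_key(rep(bait, length(library)), library)
  out <- calls |>
    filter(pair_key(.data$pair_a, .data$pair_b) %in% keys)
  attr(out, "screen_valid") <- !isFALSE(ctl_ok)
  attr(out, "controls") <- tibble(control = "positive_control",
                                  passed = ctl_ok)
  out
}

#' Positive partners from a call table
#'
#' @param calls Call tibble from [bret_call()] or [run_screen()].
#' @param bait Bait symbol to report partners of.
#' @return Character vector of partner symbols called positive.
#' @export
positive_partners <- function(calls, bait) {
  bait <- norm_symbol(bait)
  pos <- calls |> filter(.data$positive)
  sort(ifelse(pos$pair_a == bait, pos$pair_b, pos$pair_a)[
    pos$pair_a == bait | pos$pair_b == bait])
}
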