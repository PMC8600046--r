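#' Literature-based biochemical score
#'
#' Summarises the biochemical phenotype of a genotype as a single score:
#' protein stability contributes 30 points (wild-type-like), 15 (reduced
#' but residual) or 0 (absent); catalase import, PTS1-dependent import
#' and PTS2-dependent import each contribute up to 10 points, linearly in
#' the measured import percentage (100% -> 10). A wild-type-like profile
#' with full import totals 60.
#'
#' @param profiles Data frame with columns `variant_id`,
#'   `protein_amount_class` (one of `"wt_like"`, `"reduced"`, `"absent"`),
#'   `catalase_import_pct`, `pts1_import_pct`, `pts2_import_pct`
#'   (0-100 each).
#' @return Tibble with the component scores (`stability_score`,
#'   `catalase_score`, `pts1_score`, `pts2_score`) and `total` per
#'   genotype.
#' @examples
#' biochemical_score(data.frame(variant_id = "WT",
#'   protein_amount_class = "wt_like", catalase_import_pct = 100,
#'   pts1_import_pct = 100, pts2_import_pct = 100))
#' @export
biochemical_score <- function(profiles) {
  stop_missing_cols(profiles, c("variant_id", "protein_amount_class",
                                "catalase_import_pct", "pts1_import_pct",
                                "pts2_import_pct"), "`profiles`")
  pct <- c(profiles$catalase_import_pct, profiles$pts1_import_pct,
           profiles$pts2_import_pct)
  if (any(is.na(pct)) || any(pct < 0 | pct > 100)) {
    abort("import percentages must lie in [0, 100]",
          class = "peroxnet_bad_percentage")
  }
  stab_map <- c(wt_like = 30, reduced = 15, absent = 0)
  cls <- profiles$protein_amount_class
  if (any(!cls %in% names(stab_map))) {
    abort("protein_amount_class must be one of wt_like, reduced, absent",
          class = "peroxnet_bad_input")
  }
  as_tibble(profiles) |>
    mutate(
      stability_score = unname(stab_map[.data$protein_amount_class]),
      catalase_score = 10 * .data$catalase_import_pct / 100,
      pts1_score = 10 * .data$pts1_import_pct / 100,
      pts2_score = 10 * .data$pts2_import_pct / 100,
      total = .data$stability_score + .data$catalase_score +
        .data$pts1_score + .data$pts2_score) |>
    select("variant_id", "stability_score", "catalase_score", "pts1_score",
           "pts2_score", "total")
}

#' Correlate maintained interactions with the biochemical score
#'
#' Pearson correlation plus least-squares line between the number of
#' maintained protein-protein interactions per genotype and the
#' biochemical score. The two-sided p-value uses the t distribution with
#' n - 2 degrees of freedom.
#'
#' @param data Data frame with one row per genotype.
#' @param n_ppi,score Column names (unquoted tidy-select style not
#'   required; defaults `"n_maintained"` and `"total"`).
#' @return A `ppi_score_cor` object; [tidy()] gives the per-genotype data,
#'   [glance()] the estimates (`r`, `p_value`, `slope`, `intercept`,
#'   `n`).
#' @examples
#' d <- data.frame(g = 1:3, n_maintained = c(1, 2, 3), total = c(10, 20, 30))
#' glance(correlate_ppi_score(d))
#' @export
correlate_ppi_score <- function(data, n_ppi = "n_maintained", score = "total") {
  stop_missing_cols(data, c(n_ppi, score), "`data`")
  x <- data[[n_ppi]]
  y <- data[[score]]
  if (length(x) < 3) {
    abort("need at least 3 paired observations", class = "peroxnet_bad_input")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation is undefined for a constant vector",
          class = "peroxnet_bad_input")
  }
  ct <- cor.test(x, y, method = "pearson")
  fit <- lm(y ~ x)
  structure(
    list(data = as_tibble(data), n_ppi = n_ppi, score = score,
         r = unname(ct$estimate), p_value = ct$p.value,
         conf_int = unname(ct$conf.int),
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         n = length(x), fit = fit),
    class = "ppi_score_cor")
}

#' @export
print.ppi_score_cor <- function(x, ...) {
  cat(sprintf("<ppi_score_cor> Pearson r = %.3f (p = %.3g, n = %d)\n",
              x$r, x$p_value, x$n))
  cat(sprintf("  linear fit: score = %.2f + %.2f * n_PPI\n",
              x$intercept, x$slope))
  invisible(x)
}

#' @rdname correlate_ppi_score
#' @param x A `ppi_score_cor`.
#' @param ... Unused.
#' @export
tidy.ppi_score_cor <- function(x, ...) x$data

#' @rdname correlate_ppi_score
#' @export
glance.ppi_score_cor <- function(x, ...) {
  tibble(r = x$r, p_value = x$p_value, slope = x$slope,
         intercept = x$intercept, n = x$n,
         conf_low = x$conf_int[1], conf_high = x$conf_int[2])
}

#' Relative expression by the comparative CT method (2^-ddCT)
#'
#' For each sample, `dCT = CT_target - CT_reference`; `ddCT` subtracts the
#' mean `dCT` of the calibrator group; the fold change is `2^-ddCT`. By
#' construction the calibrator group's geometric mean fold change is 1.
#'
#' @param ct_records Data frame with columns `sample_id`, `group`,
#'   `target_ct`, `reference_ct`, and either a logical `calibrator` column
#'   or a `group` value matching `calibrator_group`.
#' @param calibrator_group Name of the calibrator group (ignored when a
#'   `calibrator` column is present).
#' @return Tibble with `dct`, `ddct`, `fold_change` per sample.
#' @examples
#' ct <- data.frame(sample_id = c("c1", "c2", "p1"),
#'                  group = c("ctrl", "ctrl", "pat"),
#'                  target_ct = c(24, 24, 26), reference_ct = c(17, 17, 17),
#'                  calibrator = c(TRUE, TRUE, FALSE))
#' relative_expression_ddct(ct)
#' @export
relative_expression_ddct <- function(ct_records, calibrator_group = NULL) {
  stop_missing_cols(ct_records, c("sample_id", "group", "target_ct",
                                  "reference_ct"), "`ct_records`")
  ct <- as_tibble(ct_records)
  bad <- !is.finite(ct$target_ct) | !is.finite(ct$reference_ct) |
    ct$target_ct <= 0 | ct$reference_ct <= 0
  if (any(bad)) {
    abort("CT values must be finite and positive for every sample",
          class = "peroxnet_bad_ct")
  }
  if ("calibrator" %in% names(ct)) {
    cal <- ct$calibrator
  } else {
    if (is.null(calibrator_group)) {
      abort("either a `calibrator` column or `calibrator_group` is required",
            class = "peroxnet_bad_input")
    }
    cal <- ct$group == calibrator_group
  }
  if (!any(cal)) {
    abort("calibrator group is empty", class = "peroxnet_bad_input")
  }
  ct |>
    mutate(dct = .data$target_ct - .data$reference_ct,
           ddct = .data$dct - mean(.data$dct[cal]),
           fold_change = 2^(-.data$ddct))
}

#' Compare expression between two groups (classic unpaired t test)
#'
#' Thin utility over [stats::t.test()] with `var.equal = TRUE` (the
#' classic unpaired t test, no Welch correction), applied to the fold
#' changes of two sample groups.
#'
#' @param folds Output of [relative_expression_ddct()].
#' @param group_a,group_b The two `group` values to compare.
#' @return Tibble with group means, the mean ratio, `t`, `df`, `p_value`.
#' @export
compare_expression <- function(folds, group_a, group_b) {
  a <- folds$fold_change[folds$group == group_a]
  b <- folds$fold_change[folds$group == group_b]
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs at least two samples", class = "peroxnet_bad_input")
  }
  tt <- t.test(a, b, var.equal = TRUE)
  tibble(group_a = group_a, group_b = group_b,
         mean_a = mean(a), mean_b = mean(b),
         ratio = mean(b) / mean(a),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
}
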