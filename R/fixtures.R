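#' Load the packaged peroxisomal fixture bundle
#'
#' Reads the fixture tables shipped with the package and validates them
#' against the structural invariants of the PEX26 screen: a 90-protein
#' peroxisomal library (87 annotated proteins plus the candidates MFF,
#' MPV17L2 and PXT1), the 18 wild-type PEX26 partners (4 previously known:
#' PEX6, PEX19, PEX14, PEX13), the 8 x 18 variant-by-partner interaction
#' matrix, the 9 splice-variant (PEX26delta-ex5) partners, the truncated
#' fragment binding annotation, the functional building-block mapping of
#' the partners, 67 curated protein-protein interactions, 65 gene-phenotype
#' relationships over 40 clinical phenotypes, and per-variant biochemical
#' profiles.
#'
#' Files whose names carry a `synthetic_` prefix are reconstructions: the
#' underlying tables are not published as machine-readable data, so they
#' were rebuilt to reproduce the aggregate values reported for the screen
#' (counts, degrees, centralities, component sizes). See the methods
#' vignette for what that does and does not guarantee.
#'
#' @param source_dir Directory holding the fixture TSVs. Defaults to the
#'   copy installed with the package.
#' @return A named list of tibbles of class `perox_fixture_bundle` with
#'   elements `library90`, `wt_partners`, `known_partners`, `dex5_partners`,
#'   `variant_matrix`, `fragment_matrix`, `building_blocks`, `known_ppi`,
#'   `novel_ppi`, `phenotype_gene`, `biochem_profiles`, `fis1_qpcr`.
#' @examples
#' fx <- perox_fixtures()
#' nrow(fx$library90)
#' @export
perox_fixtures <- function(source_dir = NULL) {
  dir <- source_dir %||% system.file("extdata", package = "peroxnet")
  req <- c(library90 = "synthetic_library90.tsv",
           wt_partners = "wt_partners.tsv",
           dex5_partners = "dex5_partners.tsv",
           variant_matrix = "variant_matrix.tsv",
           fragment_matrix = "fragment_matrix.tsv",
           building_blocks = "building_blocks.tsv",
           known_ppi = "synthetic_known_ppi.tsv",
           novel_ppi = "novel_ppi.tsv",
           phenotype_gene = "synthetic_phenotype_gene.tsv",
           biochem_profiles = "synthetic_biochem_profiles.tsv",
           fis1_qpcr = "synthetic_fis1_qpcr.tsv")
  paths <- file.path(dir, req)
  missing <- req[!file.exists(paths)]
  if (length(missing)) {
    abort(paste0("fixture file(s) missing from ", dir, ": ",
                 paste(missing, collapse = ", ")),
          class = "peroxnet_fixture_missing")
  }
  fx <- lapply(setNames(paths, names(req)), function(p) {
    as_tibble(read.delim(p, check.names = FALSE, stringsAsFactors = FALSE))
  })
  fx$known_partners <- fx$wt_partners |>
    filter(.data$provenance == "curated") |>
    pull("partner")
  validate_fixture_bundle(fx)
  structure(fx, class = c("perox_fixture_bundle", "list"))
}

# Invariant checks; each failure names the violated invariant.
validate_fixture_bundle <- function(fx) {
  fail <- function(msg) abort(paste0("fixture invariant violated: ", msg),
                              class = "peroxnet_fixture_invalid")
  if (nrow(fx$library90) != 90)
    fail(sprintf("library90 must have exactly 90 entries (got %d)",
                 nrow(fx$library90)))
  extras <- c("MFF", "MPV17L2", "PXT1")
  if (!all(extras %in% fx$library90$protein))
    fail("library90 must contain the candidate proteins MFF, MPV17L2, PXT1")
  if (sum(!fx$library90$protein %in% extras) != 87)
    fail("library90 must contain 87 annotated peroxisomal proteins")

  if (nrow(fx$wt_partners) != 18)
    fail(sprintf("wt_partners must list 18 partners (got %d)", nrow(fx$wt_partners)))
  if (!setequal(fx$known_partners, c("PEX6", "PEX19", "PEX14", "PEX13")))
    fail("known_partners must be PEX6, PEX19, PEX14, PEX13")
  if (nrow(fx$dex5_partners) != 9)
    fail("dex5_partners must list 9 partners")

  vm <- fx$variant_matrix
  pcols <- setdiff(names(vm), "variant_id")
  if (nrow(vm) != 8 || length(pcols) != 18)
    fail(sprintf("variant_matrix must be 8 x 18 (got %d x %d)",
                 nrow(vm), length(pcols)))
  if (!setequal(pcols, fx$wt_partners$partner))
    fail("variant_matrix columns must equal the 18 WT partners")
  wt <- vm[vm$variant_id == "WT", pcols]
  if (nrow(wt) != 1 || !all(wt == 1, na.rm = FALSE))
    fail("WT row of variant_matrix must be all 1")
  conserved_pos <- c("PEX5", "PEX14", "PEX19", "ECH1", "FIS1", "PXMP2")
  if (!all(vm[, conserved_pos] == 1, na.rm = TRUE))
    fail("columns PEX5, PEX14, PEX19, ECH1, FIS1, PXMP2 must be all 1")
  conserved_neg <- c("PEX16", "ABCD3", "ACBD5")
  if (!all(vm[vm$variant_id != "WT", conserved_neg] == 0, na.rm = TRUE))
    fail("columns PEX16, ABCD3, ACBD5 must be all 0 for the 7 variants")

  bb <- fx$building_blocks
  want <- list(
    "matrix protein import" = c("PEX5", "PEX6", "PEX12", "PEX13", "PEX14"),
    "membrane assembly" = c("PEX16", "PEX19"),
    "division and proliferation" = c("PEX11B", "PEX11G", "FIS1"),
    "fatty acid metabolism" = c("ABCD1", "ABCD3", "ACBD5", "ALDH3A2", "ECH1", "FAR1"),
    "unknown" = c("PXMP2", "PXMP4"))
  for (blk in names(want)) {
    got <- bb$partner[bb$block == blk]
    if (!setequal(got, want[[blk]]))
      fail(sprintf("building_blocks: block '%s' must contain {%s}",
                   blk, paste(want[[blk]], collapse = ", ")))
  }

  if (nrow(fx$known_ppi) != 67)
    fail(sprintf("known_ppi must have 67 edges (got %d)", nrow(fx$known_ppi)))
  if (nrow(fx$novel_ppi) != 14)
    fail("novel_ppi must have 14 edges")
  if (nrow(fx$phenotype_gene) != 65)
    fail(sprintf("phenotype_gene must have 65 relationships (got %d)",
                 nrow(fx$phenotype_gene)))
  if (n_distinct(fx$phenotype_gene$phenotype) != 40)
    fail("phenotype_gene must cover 40 distinct clinical phenotypes")
  if (anyDuplicated(fx$phenotype_gene[, c("gene", "phenotype")]))
    fail("phenotype_gene pairs must be unique")
  if (nrow(fx$biochem_profiles) != 8)
    fail("biochem_profiles must cover WT plus the 7 missense variants")
  invisible(fx)
}

#' @export
print.perox_fixture_bundle <- function(x, ...) {
  cat("<perox_fixture_bundle>\n")
  cat("  library proteins :", nrow(x$library90), "\n")
  cat("  WT partners      :", nrow(x$wt_partners),
      sprintf("(%d curated, %d novel)\n",
              sum(x$wt_partners$provenance == "curated"),
              sum(x$wt_partners$provenance == "novel")))
  cat("  variant matrix   :", nrow(x$variant_matrix), "x",
      ncol(x$variant_matrix) - 1L, "\n")
  cat("  curated PPIs     :", nrow(x$known_ppi), "\n")
  cat("  gene-phenotype   :", nrow(x$phenotype_gene), "relationships,",
      n_distinct(x$phenotype_gene$phenotype), "phenotypes\n")
  invisible(x)
}

#' Variant interaction matrix in long (tidy) form
#'
#' @param bundle A [perox_fixtures()] bundle.
#' @return Tibble with columns `variant_id`, `partner`, `call` (1, 0 or NA).
#' @export
variant_matrix_long <- function(bundle) {
  bundle$variant_matrix |>
    tidyr::pivot_longer(-"variant_id", names_to = "partner", values_to = "call")
}
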