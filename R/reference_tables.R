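#' Curated reference table: Lp(a)/LDL enrichment, discovery and replication
#'
#' The 15 proteins reported as preferentially carried by lipoprotein(a)
#' rather than LDL in a paired discovery (6 subjects) / replication
#' (9 subjects) isolation study, with the published mean Lp(a)/LDL intensity
#' ratios and paired-test P values for both phases. Shipped as a plain TSV
#' fixture; used to replay the discovery/replication logic
#' ([replicate_diff()]) against known results.
#'
#' @return data.frame with columns `gene`, `protein`, `discovery_ratio`,
#'   `discovery_p`, `replication_ratio`, `replication_p`.
#' @export
ref_enrichment_table <- function() {
  path <- system.file("extdata", "lpa_ldl_enrichment_reference.tsv",
                      package = "lipoproteomr", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Curated reference table: MR screen of the plasma proteome
#'
#' Published inverse-variance-weighted MR estimates (beta, SE, P) for plasma
#' proteins screened against lifelong Lp(a) exposure (top 18 nominal
#' associations, none Bonferroni-significant) and LDL-cholesterol exposure
#' (the 18 Bonferroni-significant associations at 0.05/3283). Used to replay
#' the Bonferroni screening rule against known pass counts.
#'
#' @return data.frame with columns `exposure` (`"LPA"`/`"LDL"`), `protein`,
#'   `beta`, `se`, `pvalue`.
#' @export
ref_mr_table <- function() {
  path <- system.file("extdata", "mr_screen_reference.tsv",
                      package = "lipoproteomr", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
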