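#' Discovery/replication logic for differential-enrichment results
#'
#' A protein counts as replicated iff (i) it meets the discovery-phase
#' significance criterion, (ii) its replication-phase P value is below
#' `alpha`, and (iii) the direction of enrichment (ratio vs 1) agrees between
#' phases. The discovery criterion defaults to the moderated q value below
#' `1e-4`; when the discovery table carries no `q` column (e.g. when
#' replaying published ratio/P tables) set `discovery_stat = "p"`.
#'
#' @param discovery,replication data.frames sharing a `protein_id` namespace,
#'   each with a `ratio` column and the chosen statistic column(s).
#' @param alpha replication significance level.
#' @param discovery_alpha discovery-phase threshold (default `1e-4`,
#'   the conventional stringent limma-corrected q cut for discovery calls).
#' @param discovery_stat which discovery column to threshold, `"q"` or `"p"`.
#' @return data.frame with one row per protein present in both phases:
#'   ratios, the replication flag and the direction (`"LPA"` for ratio > 1,
#'   `"LDL"` for ratio < 1).
#' @export
replicate_diff <- function(discovery, replication, alpha = 0.05,
                           discovery_alpha = 1e-4,
                           discovery_stat = c("q", "p")) {
  discovery_stat <- match.arg(discovery_stat)
  assert_scalar_num(alpha, "alpha", lower = 0, upper = 1,
                    strict_lower = TRUE)
  assert_scalar_num(discovery_alpha, "discovery_alpha", lower = 0, upper = 1,
                    strict_lower = TRUE)
  for (nm in c("protein_id", "ratio")) {
    if (!nm %in% names(discovery) || !nm %in% names(replication)) {
      stop_("both phases need a `%s` column", nm)
    }
  }
  if (!discovery_stat %in% names(discovery)) {
    stop_("discovery table has no `%s` column", discovery_stat)
  }
  if (!"p" %in% names(replication)) {
    stop_("replication table needs a `p` column")
  }
  common <- intersect(discovery$protein_id, replication$protein_id)
  if (length(common) == 0L) {
    out <- data.frame(protein_id = character(0), discovery_ratio = numeric(0),
                      replication_ratio = numeric(0), direction = character(0),
                      replicated = logical(0), stringsAsFactors = FALSE)
    return(out)
  }
  di <- discovery[match(common, discovery$protein_id), , drop = FALSE]
  re <- replication[match(common, replication$protein_id), , drop = FALSE]
  disc_sig <- di[[discovery_stat]] < discovery_alpha
  rep_sig <- re$p < alpha
  same_dir <- (di$ratio > 1 & re$ratio > 1) | (di$ratio < 1 & re$ratio < 1)
  data.frame(
    protein_id = common,
    discovery_ratio = di$ratio,
    replication_ratio = re$ratio,
    direction = ifelse(di$ratio > 1, "LPA", ifelse(di$ratio < 1, "LDL", "none")),
    replicated = disc_sig & rep_sig & same_dir,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
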