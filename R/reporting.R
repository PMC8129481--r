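#' Volcano-plot table
#'
#' Emits the deterministic table behind a volcano plot: effect on the log2
#' scale, `-log10(P)` and a significance flag at the caller's declared
#' threshold. Rows are ordered by ascending P value, then identifier, so
#' re-runs are byte-identical.
#'
#' @param results data.frame of results.
#' @param id_col,effect_col,p_col column names for the identifier, effect and
#'   P value.
#' @param threshold significance threshold applied to `p_col` (strict `<`).
#' @param effect_is_ratio when TRUE (default) the effect column is a ratio
#'   and is log2-transformed; when FALSE it is used as is.
#' @return data.frame with `id`, `log2_effect`, `neg_log10_p`, `significant`.
#' @export
volcano_table <- function(results, id_col = "protein_id",
                          effect_col = "ratio", p_col = "p_mod",
                          threshold = 0.05, effect_is_ratio = TRUE) {
  for (nm in c(id_col, effect_col, p_col)) {
    if (!nm %in% names(results)) stop_("results have no `%s` column", nm)
  }
  p <- results[[p_col]]
  eff <- results[[effect_col]]
  out <- data.frame(
    id = as.character(results[[id_col]]),
    log2_effect = if (effect_is_ratio) log2(eff) else eff,
    neg_log10_p = -log10(p),
    significant = p < threshold,
    stringsAsFactors = FALSE
  )
  out <- out[order(p, out$id, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pipeline defaults
#'
#' One place for every stage default, each matching the published protocol
#' value where one exists: the 67% replicate-presence rule with 2 peptides
#' per protein, BH control for the enrichment phase, the genome-wide
#' significance (5e-8) and LD-independence (r^2 < 0.1) instrument rules, and
#' the Bonferroni denominators 3283 (aptamer panel) and 41 (cytokine panel).
#'
#' @param ... overrides as `name = value` pairs.
#' @return named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    lfq_frac = 2 / 3,   # the "67%" rule read exactly: 4 of 6, 6 of 9
    lfq_min_peptides = 2L,
    lfq_log_transform = TRUE,
    lfq_alpha = 0.05,
    lfq_discovery_q = 1e-4,
    prm_r2_threshold = 0.98,
    prm_weighting = "none",
    mr_p_threshold = 5e-8,
    mr_r2_threshold = 0.1,
    mr_alpha = 0.05,
    mr_m_somascan = 3283L,
    mr_m_cytokine = 41L,
    log_level = "info",
    out_dir = "."
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop_("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read a flat key-value configuration file
#'
#' Parses the flat `key: value` subset of YAML (one scalar per line, `#`
#' comments and blank lines ignored) — no nesting, lists or anchors. Values
#' are type-converted (logical/integer/double where possible) and validated
#' against the known [run_config()] keys.
#'
#' @param path config file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", lines))
  bad <- which(vapply(kv, length, integer(1)) != 3L)
  if (length(bad)) {
    stop_("malformed config line(s): %s", paste(bad, collapse = ", "))
  }
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  parsed <- lapply(vals, function(v) {
    utils::type.convert(v, as.is = TRUE)
  })
  names(parsed) <- keys
  do.call(run_config, parsed)
}
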