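# Shared fixture builders. Everything is generated in code; no binary data.

# tiny paired matrix from explicit per-condition value matrices
make_paired_matrix <- function(lpa, ldl, peptide_counts = NULL) {
  stopifnot(nrow(lpa) == nrow(ldl), ncol(lpa) == ncol(ldl))
  k <- ncol(lpa)
  x <- cbind(lpa, ldl)
  colnames(x) <- c(sprintf("LPA_%d", seq_len(k)), sprintf("LDL_%d", seq_len(k)))
  rownames(x) <- sprintf("prot_%03d", seq_len(nrow(x)))
  if (is.null(peptide_counts)) peptide_counts <- rep(3L, nrow(x))
  intensity_matrix(
    x,
    condition = rep(c("LPA", "LDL"), each = k),
    pair_id = rep(seq_len(k), 2L),
    peptide_counts = peptide_counts
  )
}

# matrix whose paired log2 differences are exactly `d` for one protein,
# with `extra` undifferentiated proteins to make normalization a no-op
make_diff_matrix <- function(d, base = 20) {
  k <- length(d)
  lpa <- rbind(2^(base + d), matrix(2^base, 3, k))
  ldl <- rbind(2^rep(base, k), matrix(2^base, 3, k))
  make_paired_matrix(lpa, ldl)
}

# discovery/replication frames from the shipped reference enrichment table
ref_as_phases <- function() {
  tab <- ref_enrichment_table()
  list(
    discovery = data.frame(protein_id = tab$gene, ratio = tab$discovery_ratio,
                           p = tab$discovery_p, stringsAsFactors = FALSE),
    replication = data.frame(protein_id = tab$gene, ratio = tab$replication_ratio,
                             p = tab$replication_p, stringsAsFactors = FALSE)
  )
}

# brute-force BH step-up: literal definition on the sorted vector
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# mean silhouette of cluster `a` against cluster `b` on a score matrix
silhouette_ab <- function(scores, a, b) {
  d <- as.matrix(stats::dist(scores))
  sil <- vapply(a, function(i) {
    within <- mean(d[i, setdiff(a, i)])
    between <- mean(d[i, b])
    (between - within) / max(between, within)
  }, numeric(1))
  mean(sil)
}
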