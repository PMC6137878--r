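# Independent oracles used by the property tests. These re-derive expected
# behaviour from first principles (literal rule transcription, brute-force
# predicate conjunction) and must stay decoupled from the implementation
# they check.

# Literal transcription of the 2015 combining-rule list, clause by clause,
# over applied-strength counts (vs = very strong, s = strong, m = moderate,
# p = supporting). Pathogenic is checked before likely pathogenic.
oracle_tier <- function(vs, s, m, p) {
  # Pathogenic:
  #  (i)  1 very strong AND (>=1 strong | >=2 moderate |
  #                          1 moderate + 1 supporting | >=2 supporting)
  if (vs == 1 && s >= 1) return("pathogenic")
  if (vs == 1 && m >= 2) return("pathogenic")
  if (vs == 1 && m == 1 && p == 1) return("pathogenic")
  if (vs == 1 && p >= 2) return("pathogenic")
  #  (ii) >=2 strong
  if (s >= 2) return("pathogenic")
  #  (iii) 1 strong AND (>=3 moderate | 2 moderate + >=2 supporting |
  #                      1 moderate + >=4 supporting)
  if (s == 1 && m >= 3) return("pathogenic")
  if (s == 1 && m == 2 && p >= 2) return("pathogenic")
  if (s == 1 && m == 1 && p >= 4) return("pathogenic")
  # Likely pathogenic:
  #  (i) 1 very strong + 1 moderate
  if (vs == 1 && m == 1) return("likely_pathogenic")
  #  (ii) 1 strong + 1-2 moderate
  if (s == 1 && m >= 1 && m <= 2) return("likely_pathogenic")
  #  (iii) 1 strong + >=2 supporting
  if (s == 1 && p >= 2) return("likely_pathogenic")
  #  (iv) >=3 moderate
  if (m >= 3) return("likely_pathogenic")
  #  (v) 2 moderate + >=2 supporting
  if (m == 2 && p >= 2) return("likely_pathogenic")
  #  (vi) 1 moderate + >=4 supporting
  if (m == 1 && p >= 4) return("likely_pathogenic")
  "uncertain"
}

# Evidence token sets realizing a given strength-count vector, built from
# distinct base codes so duplicate-base constraints never interfere.
# vs <= 1, s <= 4, m <= 6, p <= 6 are representable with native codes alone.
tokens_for_counts <- function(vs, s, m, p) {
  c(if (vs >= 1) "PVS1",
    if (s >= 1) paste0("PS", seq_len(s)),
    if (m >= 1) paste0("PM", seq_len(m)),
    if (p >= 1) paste0("PP", seq_len(p)))
}

# Brute-force conjunction of the four filter predicates, evaluated per call
# on a plain annotated calls table (columns gene, zygosity, consequence
# is_ptm, popmax_maf, clinvar_status, hgmd_status).
oracle_survivor_calls <- function(calls, policies, fp) {
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    g <- calls$gene[i]
    row <- policies[!is.na(g) & policies$gene_symbol == g, , drop = FALSE]
    on_list <- nrow(row) == 1
    ar <- on_list && as.character(row$inheritance) == "AR"
    maf <- calls$popmax_maf[i]
    if (is.na(maf)) maf <- 0
    zyg_ok <- !ar || calls$zygosity[i] == "hom"
    freq_ok <- maf <= fp$maf_threshold ||
      (ar && calls$zygosity[i] == "hom" && maf <= fp$ar_hom_maf_threshold)
    ret_ok <- calls$hgmd_status[i] %in% fp$retained_hgmd_statuses ||
      calls$clinvar_status[i] %in% fp$retained_assertions ||
      calls$is_ptm[i]
    keep[i] <- on_list && zyg_ok && freq_ok && ret_ok
  }
  keep
}

tier_rank <- function(tier) {
  match(tier, c("uncertain", "likely_pathogenic", "pathogenic"))
}
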