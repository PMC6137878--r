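# The automatic filtering cascade: gene-list restriction -> AR zygosity rule
# -> popmax rarity filter (with the AR-homozygote exception) -> retention of
# asserted or protein-truncating variants. Stages are per-call predicates;
# the ordered cascade equals their conjunction, and run_cascade() keeps a
# per-variant audit trail of every decision.

# Join knowledge-base fields onto calls (idempotent).
join_knowledge <- function(calls, kb) {
  if (!"popmax_maf" %in% names(calls)) {
    rec <- kb_lookup(kb, calls$variant_key)
    calls$popmax_maf <- rec$popmax_maf
    calls$clinvar_status <- rec$clinvar_status
    calls$hgmd_status <- rec$hgmd_status
    calls$previously_reported <- rec$previously_reported
  }
  calls
}

stage_gene_pass <- function(calls, policies) {
  !is.na(calls$gene) & calls$gene %in% policies$gene_symbol
}

stage_zygosity_pass <- function(calls, policies) {
  inh <- policy_inheritance(policies, calls$gene)
  is.na(inh) | inh != "AR" | calls$zygosity == "hom"
}

stage_frequency_pass <- function(calls, kb, fp, policies) {
  calls <- join_knowledge(calls, kb)
  maf <- ifelse(is.na(calls$popmax_maf), 0, calls$popmax_maf)
  inh <- policy_inheritance(policies, calls$gene)
  ar_hom <- !is.na(inh) & inh == "AR" & calls$zygosity == "hom"
  maf <= fp$maf_threshold | (ar_hom & maf <= fp$ar_hom_maf_threshold)
}

stage_retention_reasons <- function(calls, kb, fp) {
  calls <- join_knowledge(calls, kb)
  data.frame(
    hgmd_dm = calls$hgmd_status %in% fp$retained_hgmd_statuses,
    clinvar_plp = calls$clinvar_status %in% fp$retained_assertions,
    ptm = calls$is_ptm
  )
}

#' Cascade stages as standalone filters
#'
#' Each stage is a per-call predicate; [run_cascade()] composes them in the
#' protocol order (gene, zygosity, frequency, retention), but because they
#' are predicates the final survivor set is order-independent.
#'
#' * `apply_gene_filter()` keeps calls whose gene is on the policy list.
#' * `apply_zygosity_filter()` keeps only homozygous calls in
#'   autosomal-recessive genes; het, hom and hemi all pass for AD/XL genes.
#' * `apply_frequency_filter()` keeps calls with popmax MAF at most
#'   `maf_threshold` (absent popmax counts as 0: a variant unobserved in
#'   population data cannot exceed a frequency ceiling), or homozygotes in AR
#'   genes up to `ar_hom_maf_threshold`.
#' * `apply_retention_filter()` keeps calls with an HGMD `DM`/`DM?` label, a
#'   ClinVar pathogenic/likely-pathogenic assertion, or a protein-truncating
#'   consequence, and aggregates survivors into candidate variants.
#'
#' @param calls Calls data frame ([read_cohort_vcf()]).
#' @param policies Gene policy table ([load_gene_policies()]).
#' @param kb Knowledge base ([load_knowledge_base()]).
#' @param fp Thresholds ([filter_policy()]).
#' @return The filtered calls data frame; `apply_retention_filter()` returns
#'   a candidate-variant data frame (one row per distinct variant, with
#'   carriers and `retention_reason`).
#' @name cascade_stages
NULL

#' @rdname cascade_stages
#' @export
apply_gene_filter <- function(calls, policies) {
  calls[stage_gene_pass(calls, policies), , drop = FALSE]
}

#' @rdname cascade_stages
#' @export
apply_zygosity_filter <- function(calls, policies) {
  calls[stage_zygosity_pass(calls, policies), , drop = FALSE]
}

#' @rdname cascade_stages
#' @export
apply_frequency_filter <- function(calls, kb, fp = filter_policy(),
                                   policies = default_gene_policies()) {
  calls <- join_knowledge(calls, kb)
  calls[stage_frequency_pass(calls, kb, fp, policies), , drop = FALSE]
}

#' @rdname cascade_stages
#' @export
apply_retention_filter <- function(calls, kb, fp = filter_policy()) {
  calls <- join_knowledge(calls, kb)
  reasons <- stage_retention_reasons(calls, kb, fp)
  collapse_candidates(calls[rowSums(reasons) > 0, , drop = FALSE],
                      reasons[rowSums(reasons) > 0, , drop = FALSE])
}

# Aggregate surviving calls to one row per distinct normalized variant.
collapse_candidates <- function(calls, reasons) {
  reason_str <- apply(reasons, 1, function(r) {
    paste(c("hgmd_dm", "clinvar_plp", "ptm")[as.logical(r)], collapse = ",")
  })
  if (nrow(calls) == 0) reason_str <- character(0)
  keys <- unique(calls$variant_key)
  rows <- lapply(keys, function(k) {
    sub <- calls[calls$variant_key == k, , drop = FALSE]
    ord <- order(sub$sample_id)
    data.frame(
      variant_key = k,
      gene = sub$gene[1], transcript = sub$transcript[1],
      hgvs_c = sub$hgvs_c[1], hgvs_p = sub$hgvs_p[1],
      consequence = sub$consequence[1], is_ptm = sub$is_ptm[1],
      retention_reason = reason_str[calls$variant_key == k][1],
      carrier_count = nrow(sub),
      carrier_ids = paste(sub$sample_id[ord], collapse = ","),
      carrier_zygosities = paste(sub$zygosity[ord], collapse = ","),
      popmax_maf = sub$popmax_maf[1],
      clinvar_status = sub$clinvar_status[1],
      hgmd_status = sub$hgmd_status[1],
      previously_reported = sub$previously_reported[1],
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    variant_key = character(), gene = character(), transcript = character(),
    hgvs_c = character(), hgvs_p = character(), consequence = character(),
    is_ptm = logical(), retention_reason = character(),
    carrier_count = integer(), carrier_ids = character(),
    carrier_zygosities = character(), popmax_maf = numeric(),
    clinvar_status = character(), hgmd_status = character(),
    previously_reported = logical(), stringsAsFactors = FALSE)
  class(out) <- c("candidate_set", class(out))
  out
}

#' Run the full automatic filtering cascade
#'
#' Composes the four stages in protocol order and returns the candidate
#' variants that reach manual assessment, together with a per-variant audit
#' trail: for every distinct input variant and every stage it reached, the
#' number of carrier calls in and out, the triggering rule, and the values
#' compared. Nothing is dropped silently.
#'
#' @inheritParams cascade_stages
#' @param cohort_size Number of individuals in the cohort; defaults to the
#'   number of distinct samples observed in `calls`. Used for the
#'   candidates-per-individual summary.
#' @return A list of class `cascade_result`:
#'   \describe{
#'     \item{candidates}{candidate-variant data frame (distinct variants
#'       surviving all stages, with carriers and retention reasons)}
#'     \item{audit}{audit-trail data frame (`variant_key`, `stage`, `passed`,
#'       `n_calls_in`, `n_calls_out`, `detail`)}
#'     \item{n_distinct}{distinct candidate variants}
#'     \item{per_individual}{`n_distinct / cohort_size`, raw fraction}
#'     \item{cohort_size}{as supplied}
#'   }
#' @examples
#' \dontrun{
#' res <- run_cascade(calls, default_gene_policies(), kb)
#' res$n_distinct
#' subset(res$audit, !passed)
#' }
#' @export
run_cascade <- function(calls, policies, kb, fp = filter_policy(),
                        cohort_size = length(unique(calls$sample_id))) {
  calls <- join_knowledge(calls, kb)
  maf_eff <- ifelse(is.na(calls$popmax_maf), 0, calls$popmax_maf)
  inh <- policy_inheritance(policies, calls$gene)
  reasons <- stage_retention_reasons(calls, kb, fp)

  pass <- list(
    gene = stage_gene_pass(calls, policies),
    zygosity = stage_zygosity_pass(calls, policies),
    frequency = stage_frequency_pass(calls, kb, fp, policies),
    retention = rowSums(reasons) > 0
  )
  detail <- list(
    gene = ifelse(pass$gene, paste0("gene ", calls$gene, " on policy list"),
                  paste0("gene ", ifelse(is.na(calls$gene), "<unannotated>",
                                         calls$gene), " not on policy list")),
    zygosity = ifelse(is.na(inh) | inh != "AR",
                      "no zygosity restriction (non-AR gene)",
                      paste0("AR gene requires hom, call is ",
                             calls$zygosity)),
    frequency = paste0("popmax ", ifelse(is.na(calls$popmax_maf), "absent",
                                         calls$popmax_maf),
                       " vs threshold ", fp$maf_threshold,
                       ifelse(!is.na(inh) & inh == "AR" &
                                calls$zygosity == "hom",
                              paste0(" (AR hom ceiling ",
                                     fp$ar_hom_maf_threshold, ")"), "")),
    retention = ifelse(pass$retention,
                       paste0("retained: ",
                              apply(reasons, 1, function(r)
                                paste(c("hgmd_dm", "clinvar_plp",
                                        "ptm")[as.logical(r)],
                                      collapse = ","))),
                       "no assertion (DM/DM?/P/LP) and not protein-truncating")
  )

  keys <- unique(calls$variant_key)
  alive <- rep(TRUE, nrow(calls))
  audit <- list()
  for (stage in c("gene", "zygosity", "frequency", "retention")) {
    p <- pass[[stage]]
    for (k in keys) {
      sel <- alive & calls$variant_key == k
      n_in <- sum(sel)
      if (n_in == 0) next
      n_out <- sum(sel & p)
      audit[[length(audit) + 1L]] <- data.frame(
        variant_key = k, stage = stage, passed = n_out > 0,
        n_calls_in = n_in, n_calls_out = n_out,
        detail = detail[[stage]][sel][1],
        stringsAsFactors = FALSE
      )
    }
    alive <- alive & p
  }
  audit <- if (length(audit)) do.call(rbind, audit) else data.frame(
    variant_key = character(), stage = character(), passed = logical(),
    n_calls_in = integer(), n_calls_out = integer(), detail = character(),
    stringsAsFactors = FALSE)

  candidates <- collapse_candidates(calls[alive, , drop = FALSE],
                                    reasons[alive, , drop = FALSE])
  structure(list(
    candidates = candidates,
    audit = audit,
    n_distinct = nrow(candidates),
    per_individual = if (cohort_size > 0) nrow(candidates) / cohort_size
                     else NA_real_,
    cohort_size = cohort_size
  ), class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("Automatic filtering cascade\n")
  cat("  cohort size:        ", x$cohort_size, "\n")
  cat("  candidate variants: ", x$n_distinct, "\n")
  if (!is.na(x$per_individual)) {
    cat("  per individual:     ",
        sprintf("%.2f", round_half_up(x$per_individual, 2)), "\n")
  }
  invisible(x)
}

#' Write the candidate table emitted by the cascade
#'
#' @param candidates Candidate data frame (`run_cascade()$candidates`).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  cols <- c("variant_key", "gene", "transcript", "hgvs_c", "hgvs_p",
            "consequence", "is_ptm", "retention_reason", "carrier_count",
            "carrier_ids", "carrier_zygosities", "popmax_maf",
            "clinvar_status", "hgmd_status", "previously_reported")
  write_tsv(as.data.frame(candidates)[, cols], path)
}

#' Read a candidate table previously written by [write_candidates()]
#'
#' @param path Candidate TSV path.
#' @return Candidate data frame.
#' @export
read_candidates <- function(path) {
  df <- read_tsv_strict(path, c("variant_key", "gene", "consequence",
                                "is_ptm", "retention_reason", "carrier_count",
                                "carrier_ids", "popmax_maf", "clinvar_status",
                                "hgmd_status", "previously_reported"))
  df$is_ptm <- parse_logical(df$is_ptm, "is_ptm")
  df$previously_reported <- parse_logical(df$previously_reported,
                                          "previously_reported")
  df$carrier_count <- as.integer(df$carrier_count)
  df$popmax_maf <- suppressWarnings(as.numeric(df$popmax_maf))
  class(df) <- c("candidate_set", class(df))
  df
}
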