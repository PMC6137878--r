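#' Run the whole screening pipeline on a file bundle
#'
#' Convenience wrapper tying the modules together: read the cohort VCF and
#' annotations, run the automatic filter cascade, classify the surviving
#' candidates with the curator evidence, and summarize reportable findings
#' over the sample groups. Accepts exactly the bundle layout that
#' [generate_cohort()] / [table1_fixture()] emit.
#'
#' @param vcf,annotations,genes,kb_freq,kb_clinvar,kb_hgmd,groups,evidence
#'   File paths; `genes = NULL` uses [default_gene_policies()], and
#'   `evidence = NULL` classifies with empty evidence sets.
#' @param fp [filter_policy()].
#' @param use_suggestions Passed to [classify_candidates()].
#' @return List with `calls`, `cascade` ([run_cascade()] result),
#'   `classified`, `summary` ([summarize_cohort()]), and `breakdown`
#'   ([consequence_breakdown()] of the candidates).
#' @examples
#' \dontrun{
#' b <- table1_fixture(tempfile("fix"))
#' res <- screen_cohort(b$vcf, b$annotations, b$genes, b$kb_freq,
#'                      b$kb_clinvar, b$kb_hgmd, b$groups, b$evidence)
#' res$summary
#' }
#' @export
screen_cohort <- function(vcf, annotations, genes = NULL, kb_freq, kb_clinvar,
                          kb_hgmd, groups, evidence = NULL,
                          fp = filter_policy(), use_suggestions = FALSE) {
  policies <- if (is.null(genes)) default_gene_policies()
              else load_gene_policies(genes)
  kb <- load_knowledge_base(kb_freq, kb_clinvar, kb_hgmd)
  grp <- read_sample_groups(groups)
  calls <- read_cohort_vcf(vcf, annotations)
  cascade <- run_cascade(calls, policies, kb, fp,
                         cohort_size = nrow(grp))
  ev <- if (is.null(evidence)) {
    data.frame(variant_key = character(), codes = character(),
               curator_id = character(), note = character(),
               stringsAsFactors = FALSE)
  } else {
    read_evidence(evidence)
  }
  classified <- classify_candidates(cascade$candidates, ev, policies,
                                    use_suggestions = use_suggestions,
                                    fp = fp)
  list(calls = calls,
       cascade = cascade,
       classified = classified,
       summary = summarize_cohort(classified, grp),
       breakdown = consequence_breakdown(cascade$candidates))
}
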