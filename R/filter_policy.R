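#' Filtering thresholds for the automatic cascade
#'
#' Bundles the tunable thresholds of the rarity and retention filters. The
#' defaults reproduce the screening protocol: variants with popmax minor
#' allele frequency at most 0.005 in any reference population are considered
#' rare; homozygotes in autosomal-recessive genes are admitted up to 0.02
#' (recessive alleles circulate at higher carrier frequencies, so the rare-
#' variant ceiling is relaxed for the homozygous state the screen actually
#' reports); and a filtered variant is retained for manual assessment when it
#' carries an HGMD `DM`/`DM?` label, a ClinVar pathogenic/likely-pathogenic
#' assertion, or is protein-truncating. Comparisons are inclusive (`<=`).
#'
#' @param maf_threshold Rarity ceiling on popmax MAF, a fraction in `[0, 1]`.
#' @param ar_hom_maf_threshold Relaxed ceiling for homozygous calls in
#'   autosomal-recessive genes; must be at least `maf_threshold`.
#' @param retained_hgmd_statuses HGMD status labels that satisfy retention.
#' @param retained_assertions ClinVar status labels that satisfy retention.
#' @return A `filter_policy` list with the four fields above.
#' @examples
#' filter_policy()
#' filter_policy(maf_threshold = 0.001)
#' @export
filter_policy <- function(maf_threshold = 0.005,
                          ar_hom_maf_threshold = 0.02,
                          retained_hgmd_statuses = c("DM", "DM?"),
                          retained_assertions = c("pathogenic",
                                                  "likely_pathogenic")) {
  stopifnot(is.numeric(maf_threshold), length(maf_threshold) == 1,
            is.numeric(ar_hom_maf_threshold), length(ar_hom_maf_threshold) == 1)
  if (maf_threshold < 0 || maf_threshold > 1 ||
      ar_hom_maf_threshold > 1 || maf_threshold > ar_hom_maf_threshold) {
    stop("need 0 <= maf_threshold <= ar_hom_maf_threshold <= 1", call. = FALSE)
  }
  structure(list(maf_threshold = maf_threshold,
                 ar_hom_maf_threshold = ar_hom_maf_threshold,
                 retained_hgmd_statuses = retained_hgmd_statuses,
                 retained_assertions = retained_assertions),
            class = "filter_policy")
}
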