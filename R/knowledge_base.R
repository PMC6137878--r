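CLINVAR_LEVELS <- c("pathogenic", "likely_pathogenic", "vus", "benign",
                    "likely_benign", "conflicting", "absent")
HGMD_LEVELS <- c("DM", "DM?", "other", "absent")

#' Load the external-assertion knowledge base
#'
#' Builds the keyed lookup that stands in for gnomAD popmax frequencies and
#' ClinVar/HGMD assertions during filtering and categorization. Each table is
#' a TSV keyed by the normalized variant key `chrom:pos:ref:alt` (1-based
#' positions as in VCF). Variants absent from a table are still queryable:
#' lookup never fails, and an absent key yields `popmax_maf = NA`,
#' `clinvar_status = "absent"`, `hgmd_status = "absent"` and
#' `previously_reported = FALSE`.
#'
#' `previously_reported` is derived, true exactly when either assertion
#' status is non-absent; it is what separates known-pathogenic (KP) from
#' expected-pathogenic (EP) candidates downstream.
#'
#' @param freq_path TSV with columns `variant_key`, `popmax_maf` (fraction in
#'   `[0, 1]`; empty means unobserved in population data).
#' @param clinvar_path TSV with columns `variant_key`, `status` (one of
#'   `r paste(CLINVAR_LEVELS, collapse = ", ")`).
#' @param hgmd_path TSV with columns `variant_key`, `status` (one of
#'   `r paste(HGMD_LEVELS, collapse = ", ")`).
#' @return A `knowledge_base` object; query it with [kb_lookup()].
#' @seealso [kb_lookup()], [run_cascade()]
#' @export
load_knowledge_base <- function(freq_path, clinvar_path, hgmd_path) {
  freq <- read_tsv_strict(freq_path, c("variant_key", "popmax_maf"))
  clv <- read_tsv_strict(clinvar_path, c("variant_key", "status"))
  hgmd <- read_tsv_strict(hgmd_path, c("variant_key", "status"))

  check_dup <- function(df, what) {
    dup <- duplicated(df$variant_key)
    if (any(dup)) {
      stop("duplicate variant_key '", df$variant_key[dup][1],
           "' in ", what, " table", call. = FALSE)
    }
  }
  check_dup(freq, "frequency")
  check_dup(clv, "clinvar")
  check_dup(hgmd, "hgmd")

  maf <- suppressWarnings(as.numeric(freq$popmax_maf))
  bad <- (is.na(maf) & nzchar(freq$popmax_maf)) |
    (!is.na(maf) & (maf < 0 | maf > 1))
  if (any(bad)) {
    stop("unparsable popmax_maf value '", freq$popmax_maf[bad][1],
         "' for ", freq$variant_key[bad][1], call. = FALSE)
  }
  check_status <- function(df, levels, what) {
    unknown <- !df$status %in% levels
    if (any(unknown)) {
      stop("unknown ", what, " status '", df$status[unknown][1],
           "' for ", df$variant_key[unknown][1], call. = FALSE)
    }
  }
  check_status(clv, CLINVAR_LEVELS, "clinvar")
  check_status(hgmd, HGMD_LEVELS, "hgmd")

  structure(list(
    freq = setNames(maf, freq$variant_key),
    clinvar = setNames(clv$status, clv$variant_key),
    hgmd = setNames(hgmd$status, hgmd$variant_key)
  ), class = "knowledge_base")
}

#' Query the knowledge base
#'
#' Vectorized lookup of popmax MAF and assertion statuses for normalized
#' variant keys. Lookup of any key is total: keys missing from all tables
#' return the absent-valued record rather than an error.
#'
#' @param kb A `knowledge_base` from [load_knowledge_base()].
#' @param variant_keys Character vector of `chrom:pos:ref:alt` keys.
#' @return A data frame with one row per key: `variant_key`, `popmax_maf`
#'   (`NA` when unobserved), `clinvar_status`, `hgmd_status`,
#'   `previously_reported`.
#' @examples
#' \dontrun{
#' kb_lookup(kb, c("1:100:A:G", "1:200:C:T"))
#' }
#' @export
kb_lookup <- function(kb, variant_keys) {
  stopifnot(inherits(kb, "knowledge_base"))
  maf <- unname(kb$freq[variant_keys])
  clv <- unname(kb$clinvar[variant_keys])
  clv[is.na(clv)] <- "absent"
  hg <- unname(kb$hgmd[variant_keys])
  hg[is.na(hg)] <- "absent"
  data.frame(
    variant_key = variant_keys,
    popmax_maf = maf,
    clinvar_status = clv,
    hgmd_status = hg,
    previously_reported = clv != "absent" | hg != "absent",
    stringsAsFactors = FALSE
  )
}

# Build a knowledge base directly from in-memory vectors (used by the
# synthetic generator and by tests; same invariants as the file loader).
kb_from_vectors <- function(keys, popmax_maf, clinvar_status, hgmd_status) {
  stopifnot(!anyDuplicated(keys))
  obs <- !is.na(popmax_maf)
  structure(list(
    freq = setNames(popmax_maf[obs], keys[obs]),
    clinvar = setNames(clinvar_status[clinvar_status != "absent"],
                       keys[clinvar_status != "absent"]),
    hgmd = setNames(hgmd_status[hgmd_status != "absent"],
                    keys[hgmd_status != "absent"])
  ), class = "knowledge_base")
}
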