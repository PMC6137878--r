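# ACMG/AMP 2015 evidence combination with modified strength levels, and the
# KP/EP/others categorization used for secondary-findings reporting.

EVIDENCE_BASES <- c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6),
                    paste0("PP", 1:5))
STRENGTH_LEVELS <- c("very_strong", "strong", "moderate", "supporting")
TIER_LEVELS <- c("pathogenic", "likely_pathogenic", "uncertain")
CATEGORY_LEVELS <- c("KP", "EP", "others")

native_strength <- function(base) {
  out <- rep(NA_character_, length(base))
  out[base == "PVS1"] <- "very_strong"
  out[grepl("^PS", base)] <- "strong"
  out[grepl("^PM", base)] <- "moderate"
  out[grepl("^PP", base)] <- "supporting"
  out
}

#' Parse ACMG/AMP evidence code tokens
#'
#' Tokens are a base criterion (`PVS1`, `PS1`–`PS4`, `PM1`–`PM6`,
#' `PP1`–`PP5`) optionally followed by a strength modifier
#' (`_VeryStrong`, `_Strong`, `_Moderate`, `_Supporting`), e.g.
#' `"PS4_Supporting"` is PS4 applied at supporting strength and `"PP1_Strong"`
#' is PP1 promoted to strong (as expert-panel gene-specific adaptations
#' express their rules). A bare code carries its native strength. Duplicate
#' base codes within one set are rejected.
#'
#' @param tokens Character vector of code tokens, or a single
#'   comma-separated string.
#' @return An `evidence_set`: data frame with columns `code`, `base`,
#'   `applied_strength`.
#' @examples
#' parse_evidence(c("PVS1", "PS4_Supporting"))
#' parse_evidence("PS4, PP1_Strong, PM1, PM2, PP3")
#' @export
parse_evidence <- function(tokens) {
  if (length(tokens) == 1 && grepl(",", tokens)) {
    tokens <- strsplit(tokens, ",", fixed = TRUE)[[1]]
  }
  tokens <- trimws(tokens)
  tokens <- tokens[nzchar(tokens)]
  pat <- "^(PVS1|PS[1-4]|PM[1-6]|PP[1-5])(_(VeryStrong|Strong|Moderate|Supporting))?$"
  bad <- !grepl(pat, tokens)
  if (any(bad)) {
    stop("invalid evidence code token: '", tokens[bad][1], "'", call. = FALSE)
  }
  base <- sub(pat, "\\1", tokens)
  if (anyDuplicated(base)) {
    stop("duplicate base code in evidence set: ",
         base[duplicated(base)][1], call. = FALSE)
  }
  mod <- sub(pat, "\\3", tokens)
  strength <- c(VeryStrong = "very_strong", Strong = "strong",
                Moderate = "moderate", Supporting = "supporting")[mod]
  strength <- ifelse(is.na(strength) | mod == "", native_strength(base),
                     strength)
  out <- data.frame(code = tokens, base = base,
                    applied_strength = unname(strength),
                    stringsAsFactors = FALSE)
  class(out) <- c("evidence_set", class(out))
  out
}

# Applied-strength counts (vs, s, m, p) of a parsed set.
strength_counts <- function(ev) {
  tab <- table(factor(ev$applied_strength, levels = STRENGTH_LEVELS))
  setNames(as.integer(tab), c("vs", "s", "m", "p"))
}

#' Combine evidence codes into a pathogenicity tier
#'
#' Applies the 2015 ACMG/AMP combining rules to the applied-strength counts
#' of an evidence set. With `vs`, `s`, `m`, `p` the numbers of very-strong,
#' strong, moderate and supporting criteria met:
#'
#' * **Pathogenic**: 1 very strong and (>=1 strong, or >=2 moderate, or
#'   1 moderate + 1 supporting, or >=2 supporting); or >=2 strong; or
#'   1 strong and (>=3 moderate, or 2 moderate + >=2 supporting, or
#'   1 moderate + >=4 supporting).
#' * **Likely pathogenic**: 1 very strong + 1 moderate; or 1 strong +
#'   1–2 moderate; or 1 strong + >=2 supporting; or >=3 moderate; or
#'   2 moderate + >=2 supporting; or 1 moderate + >=4 supporting.
#' * otherwise **uncertain**.
#'
#' Rules are checked pathogenic-first, so the highest achievable tier wins.
#' The result depends only on the strength-count vector: a code applied at
#' supporting strength contributes exactly as a native supporting code.
#' Benign-side criteria are intentionally absent — everything failing the
#' pathogenic/likely-pathogenic rules collapses to `uncertain`, matching the
#' three-category reporting simplification (KP/EP/others).
#'
#' @param evidence An `evidence_set` from [parse_evidence()], a character
#'   vector / comma-separated string of tokens, or a named count vector
#'   `c(vs = , s = , m = , p = )` giving the applied-strength tallies
#'   directly.
#' @return One of `"pathogenic"`, `"likely_pathogenic"`, `"uncertain"`.
#' @examples
#' combine_evidence("PVS1, PS4, PM2")                    # pathogenic
#' combine_evidence("PVS1, PM2")                         # likely_pathogenic
#' combine_evidence("PM1, PM2, PM5, PP3, PS4_Supporting") # likely_pathogenic
#' combine_evidence(c(vs = 0, s = 2, m = 0, p = 0))      # pathogenic
#' combine_evidence(character(0))                        # uncertain
#' @export
combine_evidence <- function(evidence) {
  if (is.numeric(evidence)) {
    stopifnot(all(c("vs", "s", "m", "p") %in% names(evidence)),
              all(evidence >= 0))
    n <- evidence
  } else {
    if (!inherits(evidence, "evidence_set")) {
      evidence <- parse_evidence(evidence)
    }
    n <- strength_counts(evidence)
  }
  vs <- n[["vs"]]; s <- n[["s"]]; m <- n[["m"]]; p <- n[["p"]]
  pathogenic <-
    (vs >= 1 && (s >= 1 || m >= 2 || (m >= 1 && p >= 1) || p >= 2)) ||
    s >= 2 ||
    (s >= 1 && (m >= 3 || (m >= 2 && p >= 2) || (m >= 1 && p >= 4)))
  if (pathogenic) return("pathogenic")
  likely <-
    (vs >= 1 && m >= 1) ||
    (s >= 1 && m >= 1) ||
    (s >= 1 && p >= 2) ||
    m >= 3 ||
    (m >= 2 && p >= 2) ||
    (m >= 1 && p >= 4)
  if (likely) return("likely_pathogenic")
  "uncertain"
}

#' Assign the KP/EP/others reporting category
#'
#' A candidate is **KP** (known pathogenic) when it has been previously
#' reported (any non-absent ClinVar or HGMD assertion) and its combined tier
#' is pathogenic or likely pathogenic — KP spans both tiers. It is **EP**
#' (expected pathogenic) when it is a *novel* protein-truncating variant in a
#' gene whose policy marks novel truncating variants reportable
#' (`ep_eligible`) and its tier is pathogenic or likely pathogenic.
#' Everything else — including a novel non-truncating variant regardless of
#' its evidence — is `others` and is not reportable.
#'
#' @param previously_reported Logical: any non-absent assertion on record.
#' @param is_ptm Logical: protein-truncating consequence.
#' @param ep_eligible Logical: gene policy allows novel-PTM reporting.
#' @param tier Tier string from [combine_evidence()].
#' @return `"KP"`, `"EP"`, or `"others"` (vectorized).
#' @examples
#' categorize(TRUE, FALSE, TRUE, "pathogenic")          # KP
#' categorize(FALSE, TRUE, TRUE, "likely_pathogenic")   # EP
#' categorize(FALSE, FALSE, TRUE, "pathogenic")         # others (novel non-PTM)
#' @export
categorize <- function(previously_reported, is_ptm, ep_eligible, tier) {
  plp <- tier %in% c("pathogenic", "likely_pathogenic")
  ifelse(plp & previously_reported, "KP",
         ifelse(plp & !previously_reported & is_ptm & ep_eligible, "EP",
                "others"))
}

#' Advisory evidence suggestions from pipeline data
#'
#' The pipeline itself can justify at most two codes: a PVS1 candidate flag
#' for a protein-truncating variant in a gene where loss of function is the
#' reportable mechanism (`ep_eligible`), and PM2 when the variant is absent
#' from population data or below the rarity threshold. All other codes are
#' curator knowledge. Suggestions are advisory: [classify_candidates()] uses
#' them only for candidates the curator file does not cover.
#'
#' @param is_ptm Logical scalar: protein-truncating consequence.
#' @param ep_eligible Logical scalar: gene policy allows novel-PTM reporting.
#' @param popmax_maf Popmax MAF (`NA` = absent from population data).
#' @param fp [filter_policy()] supplying the rarity threshold.
#' @return Character vector of suggested tokens (possibly empty).
#' @examples
#' suggest_evidence(TRUE, TRUE, NA)     # c("PVS1", "PM2")
#' suggest_evidence(FALSE, TRUE, 0.004) # "PM2"
#' suggest_evidence(FALSE, TRUE, 0.05)  # character(0)
#' @export
suggest_evidence <- function(is_ptm, ep_eligible, popmax_maf,
                             fp = filter_policy()) {
  out <- character(0)
  if (isTRUE(is_ptm) && isTRUE(ep_eligible)) out <- c(out, "PVS1")
  if (is.na(popmax_maf) || popmax_maf <= fp$maf_threshold) {
    out <- c(out, "PM2")
  }
  out
}

#' Read a curator evidence table
#'
#' @param path TSV with columns `variant_key`, `codes` (comma-separated
#'   tokens, may be empty), and optionally `curator_id`, `note`.
#' @return Data frame `variant_key`, `codes`, `curator_id`, `note`; every
#'   code string is validated by [parse_evidence()].
#' @export
read_evidence <- function(path) {
  df <- read_tsv_strict(path, c("variant_key", "codes"))
  if (anyDuplicated(df$variant_key)) {
    stop("duplicate variant_key in evidence file: ",
         df$variant_key[duplicated(df$variant_key)][1], call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    if (nzchar(df$codes[i])) parse_evidence(df$codes[i])  # validation only
  }
  data.frame(variant_key = df$variant_key, codes = df$codes,
             curator_id = df$curator_id %||% rep("", nrow(df)),
             note = df$note %||% rep("", nrow(df)),
             stringsAsFactors = FALSE)
}

#' Classify candidate variants into tiers and reporting categories
#'
#' Joins curator evidence onto the cascade's candidate set by variant key,
#' combines each evidence set into a tier ([combine_evidence()]), and
#' assigns the KP/EP/others category ([categorize()]). Candidates without a
#' curator row get an empty evidence set (tier `uncertain`) unless
#' `use_suggestions = TRUE`, in which case the advisory
#' [suggest_evidence()] codes fill the gap; curator rows always override
#' suggestions.
#'
#' @param candidates Candidate data frame (`run_cascade()$candidates` or
#'   [read_candidates()]).
#' @param evidence Evidence data frame ([read_evidence()]).
#' @param policies Gene policy table.
#' @param use_suggestions Fill evidence for uncovered candidates from
#'   [suggest_evidence()]; default `FALSE`.
#' @param fp [filter_policy()] (only used for suggestions).
#' @return The candidate data frame with columns `codes`, `tier`,
#'   `category`, and `condition` appended.
#' @examples
#' \dontrun{
#' classified <- classify_candidates(res$candidates, evidence, policies)
#' table(classified$category)
#' }
#' @export
classify_candidates <- function(candidates, evidence, policies,
                                use_suggestions = FALSE,
                                fp = filter_policy()) {
  candidates <- as.data.frame(candidates)
  idx <- match(candidates$variant_key, evidence$variant_key)
  codes <- ifelse(is.na(idx), NA_character_, evidence$codes[idx])
  ep_ok <- policy_ep_eligible(policies, candidates$gene)
  if (use_suggestions) {
    for (i in which(is.na(codes))) {
      codes[i] <- paste(
        suggest_evidence(candidates$is_ptm[i], ep_ok[i],
                         candidates$popmax_maf[i], fp),
        collapse = ",")
    }
  }
  codes[is.na(codes)] <- ""
  tier <- vapply(codes, function(x) combine_evidence(x), character(1),
                 USE.NAMES = FALSE)
  candidates$codes <- codes
  candidates$tier <- tier
  candidates$category <- categorize(candidates$previously_reported,
                                    candidates$is_ptm, ep_ok, tier)
  candidates$condition <- policy_condition(policies, candidates$gene)
  candidates
}

#' Compare two curators' evidence files
#'
#' Flags every variant on which two independently curated evidence files
#' disagree: differing code sets (and the tiers each implies), or coverage
#' gaps where one curator assessed a variant the other did not. Identical
#' files yield an empty report. Used to surface interpersonal discordance
#' before sign-off; resolution stays with the curators.
#'
#' @param curator_a,curator_b Evidence data frames ([read_evidence()]) or
#'   file paths.
#' @return A `discordance_report` data frame: `variant_key`, `kind`
#'   (`codes_differ` / `missing_in_a` / `missing_in_b`), `codes_a`,
#'   `codes_b`, `tier_a`, `tier_b`, `only_in_a`, `only_in_b`.
#' @export
check_concordance <- function(curator_a, curator_b) {
  if (is.character(curator_a) && length(curator_a) == 1) {
    curator_a <- read_evidence(curator_a)
  }
  if (is.character(curator_b) && length(curator_b) == 1) {
    curator_b <- read_evidence(curator_b)
  }
  keys <- union(curator_a$variant_key, curator_b$variant_key)
  rows <- lapply(keys, function(k) {
    a <- curator_a$codes[match(k, curator_a$variant_key)]
    b <- curator_b$codes[match(k, curator_b$variant_key)]
    if (is.na(a)) {
      return(data.frame(variant_key = k, kind = "missing_in_a",
                        codes_a = "", codes_b = b, tier_a = "",
                        tier_b = combine_evidence(b), only_in_a = "",
                        only_in_b = b, stringsAsFactors = FALSE))
    }
    if (is.na(b)) {
      return(data.frame(variant_key = k, kind = "missing_in_b",
                        codes_a = a, codes_b = "",
                        tier_a = combine_evidence(a), tier_b = "",
                        only_in_a = a, only_in_b = "",
                        stringsAsFactors = FALSE))
    }
    set_a <- parse_evidence(a)$code
    set_b <- parse_evidence(b)$code
    if (setequal(set_a, set_b)) return(NULL)
    data.frame(variant_key = k, kind = "codes_differ",
               codes_a = a, codes_b = b,
               tier_a = combine_evidence(a), tier_b = combine_evidence(b),
               only_in_a = paste(setdiff(set_a, set_b), collapse = ","),
               only_in_b = paste(setdiff(set_b, set_a), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    variant_key = character(), kind = character(), codes_a = character(),
    codes_b = character(), tier_a = character(), tier_b = character(),
    only_in_a = character(), only_in_b = character(),
    stringsAsFactors = FALSE)
  class(out) <- c("discordance_report", class(out))
  out
}
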