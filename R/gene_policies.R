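#' Load an actionable-gene policy table
#'
#' Reads the per-gene reporting policy that drives the filter cascade and the
#' EP categorization: one row per gene with its inheritance mode (`AD`, `AR`,
#' or `XL`), whether novel protein-truncating variants are reportable in it
#' (`ep_eligible`), and the associated condition. The shipped default table
#' ([default_gene_policies()]) transcribes the ACMG SF v2.0 59-gene
#' recommendation; the policy is data, so list revisions never require code
#' changes.
#'
#' Under the screening model only `AR` genes restrict zygosity (homozygotes
#' only, with a relaxed allele-frequency ceiling); `XL` entries are carried
#' for bookkeeping and treated like `AD` by the zygosity filter.
#'
#' @param path Path to a UTF-8, tab-separated file with header columns
#'   `gene_symbol`, `inheritance`, `ep_eligible`, `condition`.
#' @return A `gene_policy_table`: a data frame with columns `gene_symbol`
#'   (character, unique), `inheritance` (factor `AD`/`AR`/`XL`),
#'   `ep_eligible` (logical), `condition` (character).
#' @examples
#' policies <- default_gene_policies()
#' nrow(policies)                       # 59
#' subset(policies, inheritance == "AR")$gene_symbol
#' @seealso [run_cascade()], [categorize()]
#' @export
load_gene_policies <- function(path) {
  df <- read_tsv_strict(path, c("gene_symbol", "inheritance",
                                "ep_eligible", "condition"))
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad_inh <- !df$inheritance %in% c("AD", "AR", "XL")
  if (any(bad_inh)) {
    stop("unknown inheritance value '", df$inheritance[bad_inh][1],
         "' for gene ", df$gene_symbol[bad_inh][1],
         " (line ", line[bad_inh][1], "); expected AD, AR or XL",
         call. = FALSE)
  }
  dup <- duplicated(df$gene_symbol)
  if (any(dup)) {
    stop("duplicate gene symbol '", df$gene_symbol[dup][1],
         "' (line ", line[dup][1], ")", call. = FALSE)
  }
  out <- data.frame(
    gene_symbol = df$gene_symbol,
    inheritance = factor(df$inheritance, levels = c("AD", "AR", "XL")),
    ep_eligible = parse_logical(df$ep_eligible, "ep_eligible", line),
    condition   = df$condition,
    stringsAsFactors = FALSE
  )
  class(out) <- c("gene_policy_table", class(out))
  out
}

#' @rdname load_gene_policies
#' @export
default_gene_policies <- function() {
  load_gene_policies(system.file("extdata", "acmg_sf2_gene_policies.tsv",
                                 package = "sfscreen", mustWork = TRUE))
}

# Fast lookups used by the cascade; absent genes return NA / FALSE.
policy_inheritance <- function(policies, genes) {
  as.character(policies$inheritance[match(genes, policies$gene_symbol)])
}

policy_ep_eligible <- function(policies, genes) {
  out <- policies$ep_eligible[match(genes, policies$gene_symbol)]
  out[is.na(out)] <- FALSE
  out
}

policy_condition <- function(policies, genes) {
  out <- policies$condition[match(genes, policies$gene_symbol)]
  out[is.na(out)] <- ""
  out
}
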