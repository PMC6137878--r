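# Cohort-level aggregation of classified findings: per-group and overall
# reportable rates, consequence breakdown, and per-individual variant load.
# All computation uses raw fractions; rounding (half-up, two decimals) is
# applied only when rendering, so it never propagates.

#' Summarize reportable findings over a cohort
#'
#' Counts the individuals carrying at least one reportable (KP or EP)
#' finding — an individual carrying several findings counts once — and
#' derives the reportable rate overall and per group as
#' `100 * carriers / size`. Raw fractions are preserved alongside the
#' two-decimal, round-half-up rendering (so 3 carriers of 96 renders 3.13).
#'
#' @param classified Classified candidate data frame
#'   ([classify_candidates()]); rows with `category` other than KP/EP are
#'   ignored.
#' @param groups Sample-to-group data frame ([read_sample_groups()]); must
#'   cover every carrier sample.
#' @param cohort_size Number of individuals; defaults to `nrow(groups)`.
#' @return A `cohort_summary` list: `cohort_size`, `n_findings` (distinct
#'   KP/EP variants), `carriers`, `cohort_rate_raw`, `cohort_rate`,
#'   `per_group` (data frame `group`, `size`, `carriers`, `rate_raw`,
#'   `rate`), `genes_affected`, `shared_variants`, `singleton_variants`
#'   (over the findings), and `carrier_ids`.
#' @examples
#' \dontrun{
#' s <- summarize_cohort(classified, groups)
#' s$cohort_rate        # e.g. 2.85
#' s$per_group
#' }
#' @export
summarize_cohort <- function(classified, groups,
                             cohort_size = nrow(groups)) {
  stopifnot(cohort_size > 0)
  findings <- classified[classified$category %in% c("KP", "EP"), ,
                         drop = FALSE]
  carrier_ids <- sort(unique(unlist(
    strsplit(findings$carrier_ids, ",", fixed = TRUE))))
  unknown <- setdiff(carrier_ids, groups$sample_id)
  if (length(unknown) > 0) {
    stop("carrier sample(s) missing from the group table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  carrier_groups <- groups$group[match(carrier_ids, groups$sample_id)]

  per_group <- do.call(rbind, lapply(GROUP_LEVELS, function(g) {
    size <- sum(groups$group == g)
    carr <- sum(carrier_groups == g)
    raw <- if (size > 0) carr / size else NA_real_
    data.frame(group = g, size = size, carriers = carr,
               rate_raw = raw,
               rate = round_half_up(100 * raw, 2),
               stringsAsFactors = FALSE)
  }))

  raw <- length(carrier_ids) / cohort_size
  structure(list(
    cohort_size = cohort_size,
    n_findings = nrow(findings),
    carriers = length(carrier_ids),
    carrier_ids = carrier_ids,
    cohort_rate_raw = raw,
    cohort_rate = round_half_up(100 * raw, 2),
    per_group = per_group,
    genes_affected = length(unique(findings$gene)),
    shared_variants = sum(findings$carrier_count >= 2),
    singleton_variants = sum(findings$carrier_count == 1)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort secondary-findings summary\n")
  cat(sprintf("  %d reportable variant(s) in %d of %d individuals (%.2f%%)\n",
              x$n_findings, x$carriers, x$cohort_size, x$cohort_rate))
  for (i in seq_len(nrow(x$per_group))) {
    cat(sprintf("  %-8s %3d carriers / %3d individuals = %.2f%%\n",
                x$per_group$group[i], x$per_group$carriers[i],
                x$per_group$size[i], x$per_group$rate[i]))
  }
  invisible(x)
}

#' Consequence-class breakdown of candidate variants
#'
#' Tabulates distinct candidate variants by consequence class, pooling
#' frameshift and in-frame insertions/deletions into one `indel` class and
#' stop-gain with start-loss into `stop_gain_start_loss`, the classes used
#' in cohort reporting. Percentages are of distinct candidates, rendered
#' half-up to two decimals; raw fractions are kept alongside.
#'
#' @param candidates Candidate data frame (one row per distinct variant).
#' @return Data frame `class`, `count`, `fraction`, `percent` (classes with
#'   zero counts are kept, so the table shape is stable).
#' @examples
#' df <- data.frame(consequence = c("missense", "frameshift", "synonymous"))
#' consequence_breakdown(df)
#' @export
consequence_breakdown <- function(candidates) {
  pooled <- c(missense = "missense", synonymous = "synonymous",
              frameshift = "indel", inframe_indel = "indel",
              stop_gain = "stop_gain_start_loss",
              start_loss = "stop_gain_start_loss",
              splicing = "splicing", other = "other")
  classes <- c("missense", "synonymous", "indel", "stop_gain_start_loss",
               "splicing", "other")
  cls <- unname(pooled[candidates$consequence])
  cls[is.na(cls)] <- "other"
  n <- nrow(candidates)
  counts <- vapply(classes, function(k) sum(cls == k), integer(1))
  frac <- if (n > 0) counts / n else rep(NA_real_, length(classes))
  data.frame(class = classes, count = unname(counts),
             fraction = unname(frac),
             percent = round_half_up(100 * unname(frac), 2),
             stringsAsFactors = FALSE)
}

#' Mean candidate variants per individual
#'
#' Distinct candidate count divided by cohort size, rendered half-up to two
#' decimals (135 distinct over 421 individuals gives 0.32).
#'
#' @param candidates Candidate data frame, or directly a distinct-variant
#'   count.
#' @param cohort_size Number of individuals (> 0).
#' @return List with `n_distinct`, `raw`, and two-decimal `mean`.
#' @examples
#' variants_per_individual(135, 421)$mean  # 0.32
#' @export
variants_per_individual <- function(candidates, cohort_size) {
  if (cohort_size <= 0) stop("cohort_size must be positive", call. = FALSE)
  n <- if (is.data.frame(candidates)) {
    length(unique(candidates$variant_key))
  } else {
    as.numeric(candidates)
  }
  raw <- n / cohort_size
  list(n_distinct = n, raw = raw, mean = round_half_up(raw, 2))
}

#' Write the cohort summary as TSV and JSON
#'
#' @param summary A `cohort_summary` ([summarize_cohort()]).
#' @param breakdown Optional breakdown table ([consequence_breakdown()]).
#' @param tsv_path,json_path Output paths (`NULL` skips that format).
#' @return Invisibly, the list written to JSON.
#' @export
write_summary <- function(summary, breakdown = NULL, tsv_path = NULL,
                          json_path = NULL) {
  out <- list(
    cohort_size = summary$cohort_size,
    n_findings = summary$n_findings,
    carriers = summary$carriers,
    cohort_rate = summary$cohort_rate,
    per_group = summary$per_group,
    genes_affected = summary$genes_affected,
    shared_variants = summary$shared_variants,
    singleton_variants = summary$singleton_variants
  )
  if (!is.null(breakdown)) out$consequence_breakdown <- breakdown
  if (!is.null(tsv_path)) {
    tab <- summary$per_group
    tab <- rbind(tab, data.frame(group = "cohort",
                                 size = summary$cohort_size,
                                 carriers = summary$carriers,
                                 rate_raw = summary$cohort_rate_raw,
                                 rate = summary$cohort_rate))
    write_tsv(tab, tsv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(out)
}
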