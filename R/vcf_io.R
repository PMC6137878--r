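ZYGOSITY_LEVELS <- c("het", "hom", "hemi")
GROUP_LEVELS <- c("normal", "obesity", "chd")

empty_calls <- function() {
  data.frame(sample_id = character(), variant_key = character(),
             chrom = character(), pos = integer(), ref = character(),
             alt = character(), zygosity = character(), gene = character(),
             transcript = character(), hgvs_c = character(),
             hgvs_p = character(), consequence = character(),
             is_ptm = logical(), stringsAsFactors = FALSE)
}

#' Read a variant annotation table
#'
#' @param path TSV with columns `variant_key`, `gene`, `transcript`,
#'   `hgvs_c`, `hgvs_p`, `consequence_term`; keyed by the normalized variant
#'   key (`chrom:pos:ref:alt`, [variant_key()]).
#' @return Data frame with the consequence class and PTM flag resolved via
#'   [classify_consequence()].
#' @export
read_annotations <- function(path) {
  df <- read_tsv_strict(path, c("variant_key", "gene", "transcript",
                                "hgvs_c", "hgvs_p", "consequence_term"))
  dup <- duplicated(df$variant_key)
  if (any(dup)) {
    stop("annotation key collision: '", df$variant_key[dup][1],
         "' appears more than once", call. = FALSE)
  }
  cc <- classify_consequence(df$consequence_term)
  data.frame(variant_key = df$variant_key, gene = df$gene,
             transcript = df$transcript, hgvs_c = df$hgvs_c,
             hgvs_p = df$hgvs_p, consequence = cc$consequence,
             is_ptm = cc$is_ptm, stringsAsFactors = FALSE)
}

#' Read the sample-to-group assignment
#'
#' @param path TSV with columns `sample_id`, `group`; groups are `normal`,
#'   `obesity`, or `chd`, and each sample appears exactly once.
#' @return Data frame `sample_id`, `group`.
#' @export
read_sample_groups <- function(path) {
  df <- read_tsv_strict(path, c("sample_id", "group"))
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in group table: ",
         df$sample_id[duplicated(df$sample_id)][1], call. = FALSE)
  }
  bad <- !df$group %in% GROUP_LEVELS
  if (any(bad)) {
    stop("unknown group '", df$group[bad][1], "' for sample ",
         df$sample_id[bad][1], "; expected ",
         paste(GROUP_LEVELS, collapse = "/"), call. = FALSE)
  }
  data.frame(sample_id = df$sample_id, group = df$group,
             stringsAsFactors = FALSE)
}

# Zygosity of one sample for alt index k, from a raw GT string.
# Returns "hom", "het", "hemi", or NA (no call of this alt / missing).
gt_zygosity <- function(gt, k) {
  gt <- sub(":.*$", "", gt)
  if (is.na(gt) || gt == "." || gt == "./." || gt == ".|.") return(NA_character_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  hits <- sum(alleles == as.character(k))
  if (hits == 0) return(NA_character_)
  if (length(alleles) == 1) return("hemi")
  if (hits == length(alleles)) return("hom")
  if (any(alleles == ".")) {
    warning("half-call genotype '", gt, "' treated as het", call. = FALSE)
  }
  "het"
}

#' Read a multi-sample cohort VCF into genotype calls
#'
#' Parses a VCF v4.2 (plain or bgzipped) with per-sample `GT`, splits
#' multi-allelic records into one call per ALT allele, normalizes each
#' allele pair ([normalize_variant()]), derives zygosity from `GT` alone
#' (phased and unphased treated alike; haploid calls become `hemi`;
#' half-calls like `./1` are kept as `het` with a warning; `0/0` and `./.`
#' are excluded), and joins the annotation table by normalized variant key.
#' Variants without an annotation row carry `gene = NA` and
#' `consequence = "other"`.
#'
#' @param path VCF file path.
#' @param annotation_path Optional annotation TSV ([read_annotations()]);
#'   `NULL` leaves all calls unannotated.
#' @return A calls data frame, one row per (sample, variant): `sample_id`,
#'   `variant_key`, `chrom`, `pos`, `ref`, `alt`, `zygosity`, `gene`,
#'   `transcript`, `hgvs_c`, `hgvs_p`, `consequence`, `is_ptm`.
#' @seealso [run_cascade()], [write_cohort_vcf()]
#' @export
read_cohort_vcf <- function(path, annotation_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  ann <- if (!is.null(annotation_path)) read_annotations(annotation_path)

  if (nrow(vcf@fix) == 0) return(empty_calls())
  if (ncol(vcf@gt) < 2) {
    stop("VCF has no sample columns", call. = FALSE)
  }
  fmt <- vcf@gt[, "FORMAT"]
  if (any(!vapply(strsplit(fmt, ":", fixed = TRUE),
                  function(f) "GT" %in% f, logical(1)))) {
    stop("missing GT in FORMAT field", call. = FALSE)
  }
  if (any(sub(":.*$", "", fmt) != "GT")) {
    stop("GT must be the first FORMAT field", call. = FALSE)
  }
  samples <- colnames(vcf@gt)[-1]
  fix <- vcf@fix

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    gts <- vcf@gt[i, -1]
    rec <- list()
    for (k in seq_along(alts)) {
      if (alts[k] %in% c("*", ".") || grepl("[<\\[]", alts[k])) next
      zyg <- vapply(gts, gt_zygosity, character(1), k = k)
      carriers <- which(!is.na(zyg))
      if (length(carriers) == 0) next
      v <- normalize_variant(fix[i, "CHROM"], as.integer(fix[i, "POS"]),
                             fix[i, "REF"], alts[k])
      rec[[length(rec) + 1L]] <- data.frame(
        sample_id = samples[carriers],
        variant_key = paste(v$chrom, v$pos, v$ref, v$alt, sep = ":"),
        chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
        zygosity = unname(zyg[carriers]),
        stringsAsFactors = FALSE
      )
    }
    rows[[i]] <- if (length(rec)) do.call(rbind, rec)
  }
  calls <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(calls) || nrow(calls) == 0) return(empty_calls())

  if (!is.null(ann) && nrow(ann) > 0) {
    ann_chrom <- sub(":.*$", "", ann$variant_key)
    if (length(intersect(unique(calls$chrom), unique(ann_chrom))) == 0) {
      warning("contig names in the VCF (", paste(unique(calls$chrom),
              collapse = ","), ") share nothing with the annotation table (",
              paste(unique(ann_chrom), collapse = ","),
              "); annotations will not join", call. = FALSE)
    }
  }
  idx <- if (is.null(ann)) rep(NA_integer_, nrow(calls)) else
    match(calls$variant_key, ann$variant_key)
  calls$gene <- if (is.null(ann)) NA_character_ else ann$gene[idx]
  calls$transcript <- if (is.null(ann)) NA_character_ else ann$transcript[idx]
  calls$hgvs_c <- if (is.null(ann)) NA_character_ else ann$hgvs_c[idx]
  calls$hgvs_p <- if (is.null(ann)) NA_character_ else ann$hgvs_p[idx]
  calls$consequence <- ifelse(is.na(idx), "other",
                              if (is.null(ann)) "other" else ann$consequence[idx])
  calls$is_ptm <- ifelse(is.na(idx), FALSE,
                         if (is.null(ann)) FALSE else ann$is_ptm[idx])
  rownames(calls) <- NULL
  calls
}

#' Write genotype calls back to a multi-sample VCF
#'
#' Emits a plain-text VCF v4.2 with one biallelic record per distinct
#' normalized variant and `GT`-only genotypes (`0/1` het, `1/1` hom, `1`
#' hemi, `0/0` non-carrier). Records are sorted by contig, position, and
#' alleles; the sample column order is the sorted set of sample ids unless
#' given. Reading the file back with [read_cohort_vcf()] reproduces the
#' identical call set.
#'
#' @param calls A calls data frame as returned by [read_cohort_vcf()].
#' @param path Output file path.
#' @param samples Optional character vector fixing the sample columns (must
#'   cover every carrier in `calls`).
#' @return The path, invisibly.
#' @export
write_cohort_vcf <- function(calls, path, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(calls$sample_id))
  if (!all(calls$sample_id %in% samples)) {
    stop("calls contain samples not in the requested column set", call. = FALSE)
  }
  header <- c("##fileformat=VCFv4.2",
              "##source=sfscreen",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  lines <- character(0)
  if (nrow(calls) > 0) {
    vars <- unique(calls[, c("chrom", "pos", "ref", "alt", "variant_key")])
    vars <- vars[order(vars$chrom, vars$pos, vars$ref, vars$alt), , drop = FALSE]
    gt_code <- c(het = "0/1", hom = "1/1", hemi = "1")
    lines <- vapply(seq_len(nrow(vars)), function(i) {
      keep <- calls$variant_key == vars$variant_key[i]
      gt <- rep("0/0", length(samples))
      gt[match(calls$sample_id[keep], samples)] <-
        gt_code[calls$zygosity[keep]]
      paste(c(vars$chrom[i], vars$pos[i], ".", vars$ref[i], vars$alt[i],
              ".", "PASS", ".", "GT", gt), collapse = "\t")
    }, character(1))
  }
  writeLines(c(header, lines), path)
  invisible(path)
}
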