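CONSEQUENCE_LEVELS <- c("missense", "synonymous", "frameshift", "stop_gain",
                        "start_loss", "splicing", "inframe_indel", "other")
PTM_CLASSES <- c("frameshift", "stop_gain", "start_loss", "splicing")

#' Normalize a variant to its parsimonious representation
#'
#' Trims the shared suffix, then the shared prefix, of the REF/ALT allele
#' pair (advancing the 1-based position as leading bases are removed), so
#' that padded spellings of the same event collapse to one representation:
#' `100 CAA>CA` and `100 CA>C` both normalize to `100 CA>C`. At least one
#' base is always kept on each allele. The operation is idempotent.
#'
#' Variant identity throughout the package is the normalized key
#' `chrom:pos:ref:alt` ([variant_key()]); distinct-variant counts, knowledge
#' base joins and annotation joins all use it.
#'
#' @param chrom,pos,ref,alt Parallel vectors describing the raw alleles
#'   (`pos` 1-based, VCF convention).
#' @return A data frame with normalized `chrom`, `pos`, `ref`, `alt`.
#' @examples
#' normalize_variant("1", 100, "CAA", "CA")   # 1:100 CA>C
#' normalize_variant("1", 100, "TG", "CG")    # suffix trimmed: T>C
#' @export
normalize_variant <- function(chrom, pos, ref, alt) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(chrom) == n, length(pos) == n)
  pos <- as.integer(pos)
  ref <- toupper(ref)
  alt <- toupper(alt)
  if (any(ref == alt)) {
    stop("ref and alt alleles are identical at ",
         chrom[ref == alt][1], ":", pos[ref == alt][1], call. = FALSE)
  }
  for (i in seq_len(n)) {
    r <- strsplit(ref[i], "", fixed = TRUE)[[1]]
    a <- strsplit(alt[i], "", fixed = TRUE)[[1]]
    # shared suffix
    while (length(r) > 1 && length(a) > 1 &&
           r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    # shared prefix
    while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
      r <- r[-1]
      a <- a[-1]
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- paste(r, collapse = "")
    alt[i] <- paste(a, collapse = "")
  }
  data.frame(chrom = as.character(chrom), pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' Render the normalized variant key
#'
#' @param chrom,pos,ref,alt Raw allele description (normalized internally).
#' @return Character vector of `chrom:pos:ref:alt` keys.
#' @examples
#' variant_key("1", 100, "CAA", "CA")  # "1:100:CA:C"
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  v <- normalize_variant(chrom, pos, ref, alt)
  paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
}

#' Map an annotation consequence term to a consequence class
#'
#' Collapses the controlled vocabulary of the annotation table onto the
#' consequence classes the screen reasons about, and flags the
#' protein-truncating classes (frameshift, stop-gain, start-loss, splicing)
#' that satisfy the retention filter and are eligible for the
#' expected-pathogenic category. Unknown terms map to `other` with a warning,
#' never an error, so a sloppy annotation line degrades one variant, not the
#' run.
#'
#' @param annotation_term Character vector of terms, e.g.
#'   `"frameshift_variant"`, `"missense_variant"` (Sequence Ontology-style or
#'   plain class names).
#' @return Data frame with columns `consequence` (one of
#'   `r paste(CONSEQUENCE_LEVELS, collapse = ", ")`) and `is_ptm` (logical).
#' @examples
#' classify_consequence(c("frameshift_variant", "missense_variant"))
#' @export
classify_consequence <- function(annotation_term) {
  term_map <- c(
    missense_variant = "missense", missense = "missense",
    synonymous_variant = "synonymous", synonymous = "synonymous",
    frameshift_variant = "frameshift", frameshift = "frameshift",
    stop_gained = "stop_gain", stop_gain = "stop_gain",
    stop_gain_variant = "stop_gain",
    start_lost = "start_loss", start_loss = "start_loss",
    initiator_codon_variant = "start_loss",
    splice_acceptor_variant = "splicing", splice_donor_variant = "splicing",
    splice_region_variant = "splicing", splicing = "splicing",
    inframe_insertion = "inframe_indel", inframe_deletion = "inframe_indel",
    inframe_indel = "inframe_indel",
    other = "other"
  )
  cons <- unname(term_map[annotation_term])
  unknown <- is.na(cons) & !is.na(annotation_term)
  if (any(unknown)) {
    warning("unknown consequence term(s) mapped to 'other': ",
            paste(unique(annotation_term[unknown]), collapse = ", "),
            call. = FALSE)
    cons[unknown] <- "other"
  }
  cons[is.na(cons)] <- "other"
  data.frame(consequence = cons, is_ptm = cons %in% PTM_CLASSES,
             stringsAsFactors = FALSE)
}
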