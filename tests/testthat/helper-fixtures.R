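# In-code fixture builders shared across test files.

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A small hand-written multi-sample VCF exercising GT corner cases.
tiny_vcf <- function() {
  write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "sampleA", "sampleB", "sampleC"), collapse = "\t"),
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1\t0/0",
    "1\t200\t.\tA\tG,T\t.\tPASS\t.\tGT\t1/2\t0/2\t./.",
    "1\t300\t.\tCAA\tCA\t.\tPASS\t.\tGT\t0/1\t./1\t0/0",
    "X\t400\t.\tC\tT\t.\tPASS\t.\tGT\t1\t0/1\t0",
    "1\t500\t.\tG\tC\t.\tPASS\t.\tGT\t1|1\t0|1\t0/0"
  ), ext = ".vcf")
}

# Build an annotated calls table directly (one row per sample-variant), the
# in-memory shape read_cohort_vcf() produces after the annotation join.
make_calls <- function(df) {
  n <- nrow(df)
  cc <- suppressWarnings(classify_consequence(df$consequence_term))
  out <- data.frame(
    sample_id = df$sample_id,
    variant_key = df$variant_key,
    chrom = sub(":.*", "", df$variant_key),
    pos = as.integer(vapply(strsplit(df$variant_key, ":"), `[`,
                            character(1), 2)),
    ref = vapply(strsplit(df$variant_key, ":"), `[`, character(1), 3),
    alt = vapply(strsplit(df$variant_key, ":"), `[`, character(1), 4),
    zygosity = df$zygosity,
    gene = df$gene,
    transcript = rep("NM_000000", n),
    hgvs_c = rep("", n), hgvs_p = rep("", n),
    consequence = cc$consequence, is_ptm = cc$is_ptm,
    stringsAsFactors = FALSE)
  out
}

# Randomized in-memory screening case: annotated calls + matching knowledge
# base, spanning on/off-list genes, all zygosities, boundary MAFs, and all
# assertion statuses.
random_screen_case <- function(seed, n_variants = 20, n_samples = 12) {
  set.seed(seed)
  genes <- c("MYH7", "BRCA2", "MUTYH", "ATP7B", "GLA", "RYR1", "APOB",
             "TTN", "NOTCH1", NA)
  terms <- c("missense_variant", "synonymous_variant", "frameshift_variant",
             "stop_gained", "splice_donor_variant", "inframe_deletion")
  mafs <- c(NA, 1e-04, 0.004, 0.005, 0.0051, 0.01, 0.02, 0.0201, 0.05)
  samples <- sprintf("P%02d", seq_len(n_samples))
  rows <- do.call(rbind, lapply(seq_len(n_variants), function(i) {
    carriers <- sample(samples, sample(1:3, 1))
    data.frame(sample_id = carriers,
               variant_key = sprintf("1:%d:A:G", 1000 * i),
               gene = sample(genes, 1),
               consequence_term = sample(terms, 1),
               zygosity = sample(c("het", "hom", "hemi"), length(carriers),
                                 replace = TRUE),
               popmax_maf = sample(mafs, 1),
               clinvar_status = sample(c("pathogenic", "likely_pathogenic",
                                         "vus", "benign", "conflicting",
                                         "absent"), 1),
               hgmd_status = sample(c("DM", "DM?", "other", "absent"), 1),
               stringsAsFactors = FALSE)
  }))
  calls <- make_calls(rows)
  calls$popmax_maf <- rows$popmax_maf
  calls$clinvar_status <- rows$clinvar_status
  calls$hgmd_status <- rows$hgmd_status
  calls$previously_reported <- rows$clinvar_status != "absent" |
    rows$hgmd_status != "absent"
  vars <- rows[!duplicated(rows$variant_key), ]
  kb <- kb_from_vectors(vars$variant_key, vars$popmax_maf,
                        vars$clinvar_status, vars$hgmd_status)
  list(calls = calls, kb = kb)
}

# Write a minimal knowledge base (possibly empty) to temp files.
tmp_kb <- function(freq = data.frame(variant_key = character(),
                                     popmax_maf = character()),
                   clinvar = data.frame(variant_key = character(),
                                        status = character()),
                   hgmd = data.frame(variant_key = character(),
                                     status = character())) {
  fp <- tempfile(fileext = ".tsv"); cp <- tempfile(fileext = ".tsv")
  hp <- tempfile(fileext = ".tsv")
  utils::write.table(freq, fp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(clinvar, cp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(hgmd, hp, sep = "\t", quote = FALSE, row.names = FALSE)
  load_knowledge_base(fp, cp, hp)
}
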