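test_that("padded spellings of one indel normalize to one key", {
  # canonical event: deletion of one A from CA at 1:100
  base_key <- variant_key("1", 100, "CA", "C")
  expect_equal(base_key, "1:100:CA:C")
  # right-padded spellings append the same bases to both alleles
  for (pad in c("A", "AG", "AGT")) {
    expect_equal(variant_key("1", 100, paste0("CA", pad), paste0("C", pad)),
                 base_key)
  }
  # left-padded spellings prepend context with a shifted position
  for (ctx in c("T", "GT")) {
    expect_equal(variant_key("1", 100 - nchar(ctx),
                             paste0(ctx, "CA"), paste0(ctx, "C")),
                 base_key)
  }
  # exhaustive small oracle: every combined padding collapses to base_key
  for (left in c("", "G", "TG")) {
    for (right in c("", "A", "AC")) {
      key <- variant_key("1", 100 - nchar(left),
                         paste0(left, "CA", right),
                         paste0(left, "C", right))
      expect_equal(key, base_key)
    }
  }
})

test_that("normalization is idempotent and never equates ref with alt", {
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  for (i in 1:50) {
    ref <- paste(sample(bases, sample(1:5, 1), replace = TRUE),
                 collapse = "")
    alt <- paste(sample(bases, sample(1:5, 1), replace = TRUE),
                 collapse = "")
    if (ref == alt) next
    v1 <- normalize_variant("7", 1000, ref, alt)
    v2 <- normalize_variant(v1$chrom, v1$pos, v1$ref, v1$alt)
    expect_identical(v1, v2)
    expect_false(v1$ref == v1$alt)
  }
  expect_error(normalize_variant("1", 5, "AA", "AA"), "identical")
})

test_that("consequence terms map to classes with correct PTM flags", {
  res <- classify_consequence(c("frameshift_variant", "missense_variant",
                                "synonymous_variant", "stop_gained",
                                "start_lost", "splice_donor_variant",
                                "splice_acceptor_variant",
                                "inframe_deletion"))
  expect_equal(res$consequence,
               c("frameshift", "missense", "synonymous", "stop_gain",
                 "start_loss", "splicing", "splicing", "inframe_indel"))
  expect_equal(res$is_ptm, c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
                             FALSE))
  expect_warning(out <- classify_consequence("upstream_gene_variant"),
                 "unknown consequence")
  expect_equal(out$consequence, "other")
  expect_false(out$is_ptm)
})

test_that("GT field semantics: zygosity, exclusions, multi-allelic split", {
  vcf <- tiny_vcf()
  expect_warning(read_cohort_vcf(vcf), "half-call")
  calls <- suppressWarnings(read_cohort_vcf(vcf))

  at <- function(key, sample) {
    calls$zygosity[calls$variant_key == key & calls$sample_id == sample]
  }
  expect_equal(at("1:100:A:G", "sampleA"), "het")
  expect_equal(at("1:100:A:G", "sampleB"), "hom")
  # sampleC is 0/0 there: excluded
  expect_equal(sum(calls$variant_key == "1:100:A:G" &
                     calls$sample_id == "sampleC"), 0)

  # multi-allelic A->G,T with GT 1/2: two het calls, one per split alt
  expect_equal(at("1:200:A:G", "sampleA"), "het")
  expect_equal(at("1:200:A:T", "sampleA"), "het")
  expect_equal(at("1:200:A:T", "sampleB"), "het")
  # ./. excluded entirely
  expect_equal(sum(calls$sample_id == "sampleC" &
                     grepl("^1:200", calls$variant_key)), 0)

  # right-padded indel record normalizes: CAA>CA at 300 keys as 1:300:CA:C
  expect_equal(at("1:300:CA:C", "sampleA"), "het")
  expect_equal(at("1:300:CA:C", "sampleB"), "het")  # half-call ./1 kept

  # haploid X call becomes hemi; diploid het stays het; "0" excluded
  expect_equal(at("X:400:C:T", "sampleA"), "hemi")
  expect_equal(at("X:400:C:T", "sampleB"), "het")
  expect_equal(sum(calls$variant_key == "X:400:C:T" &
                     calls$sample_id == "sampleC"), 0)

  # phased genotypes treated like unphased
  expect_equal(at("1:500:G:C", "sampleA"), "hom")
  expect_equal(at("1:500:G:C", "sampleB"), "het")
})

test_that("multi-allelic decomposition conserves the call count", {
  vcf <- tiny_vcf()
  calls <- suppressWarnings(read_cohort_vcf(vcf))
  # record 1:200 A->G,T: sampleA 1/2 contributes two calls, sampleB 0/2 one
  expect_equal(sum(grepl("^1:200", calls$variant_key)), 3)
})

test_that("VCF round-trip reproduces the identical call set", {
  calls <- suppressWarnings(read_cohort_vcf(tiny_vcf()))
  out <- tempfile(fileext = ".vcf")
  write_cohort_vcf(calls, out)
  back <- read_cohort_vcf(out)
  key <- function(df) {
    df <- df[order(df$sample_id, df$variant_key), ]
    paste(df$sample_id, df$variant_key, df$zygosity)
  }
  expect_identical(key(back), key(calls))
  # and a second bounce is byte-stable
  out2 <- tempfile(fileext = ".vcf")
  write_cohort_vcf(back, out2)
  expect_identical(readLines(out), readLines(out2))
})

test_that("annotation join handles unannotated variants, collisions, contig mismatch", {
  ann <- write_lines_tmp(c(
    "variant_key\tgene\ttranscript\thgvs_c\thgvs_p\tconsequence_term",
    "1:100:A:G\tMYH7\tNM_000257\tc.1G>A\tp.A1T\tmissense_variant"))
  calls <- suppressWarnings(read_cohort_vcf(tiny_vcf(), ann))
  expect_equal(unique(calls$gene[calls$variant_key == "1:100:A:G"]), "MYH7")
  un <- calls[calls$variant_key == "1:500:G:C", ]
  expect_true(all(is.na(un$gene)))
  expect_true(all(un$consequence == "other"))
  expect_false(any(un$is_ptm))

  coll <- write_lines_tmp(c(
    "variant_key\tgene\ttranscript\thgvs_c\thgvs_p\tconsequence_term",
    "1:100:A:G\tMYH7\tNM_000257\tc.1G>A\tp.A1T\tmissense_variant",
    "1:100:A:G\tMYH6\tNM_002471\tc.1G>A\tp.A1T\tmissense_variant"))
  expect_error(read_cohort_vcf(tiny_vcf(), coll), "collision")

  other_contig <- write_lines_tmp(c(
    "variant_key\tgene\ttranscript\thgvs_c\thgvs_p\tconsequence_term",
    "chr9:100:A:G\tMYH7\tNM_000257\tc.1G>A\tp.A1T\tmissense_variant"))
  w <- capture_warnings(read_cohort_vcf(tiny_vcf(), other_contig))
  expect_true(any(grepl("contig", w)))
})

test_that("a VCF without GT is rejected", {
  bad <- write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"),
    "1\t100\t.\tA\tG\t.\tPASS\t.\tDP\t10"), ext = ".vcf")
  expect_error(read_cohort_vcf(bad), "GT")
})
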