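policies <- default_gene_policies()
fp <- filter_policy()

stage_calls <- function(...) {
  rows <- data.frame(..., stringsAsFactors = FALSE)
  calls <- make_calls(rows)
  calls$popmax_maf <- rows$popmax_maf
  calls$clinvar_status <- rows$clinvar_status
  calls$hgmd_status <- rows$hgmd_status
  calls$previously_reported <- rows$clinvar_status != "absent" |
    rows$hgmd_status != "absent"
  calls
}

one_call <- function(gene, zygosity = "het", popmax_maf = NA,
                     clinvar = "absent", hgmd = "absent",
                     term = "missense_variant", key = "1:1000:A:G") {
  stage_calls(sample_id = "P01", variant_key = key, gene = gene,
              consequence_term = term, zygosity = zygosity,
              popmax_maf = popmax_maf, clinvar_status = clinvar,
              hgmd_status = hgmd)
}

test_that("gene filter keeps only policy-list genes", {
  expect_equal(nrow(apply_gene_filter(one_call("BRCA2"), policies)), 1)
  expect_equal(nrow(apply_gene_filter(one_call("TTN"), policies)), 0)
  expect_equal(nrow(apply_gene_filter(one_call(NA), policies)), 0)
  empty <- policies[0, ]
  expect_equal(nrow(apply_gene_filter(one_call("BRCA2"), empty)), 0)
})

test_that("zygosity filter restricts AR genes to homozygotes only", {
  expect_equal(nrow(apply_zygosity_filter(one_call("ATP7B", "het"),
                                          policies)), 0)
  expect_equal(nrow(apply_zygosity_filter(one_call("MUTYH", "hom"),
                                          policies)), 1)
  expect_equal(nrow(apply_zygosity_filter(one_call("MYH7", "het"),
                                          policies)), 1)
  # X-linked genes carry no zygosity restriction; hemizygotes pass
  expect_equal(nrow(apply_zygosity_filter(one_call("GLA", "hemi"),
                                          policies)), 1)
})

test_that("frequency filter is inclusive at both thresholds with the AR-hom exception", {
  kb <- tmp_kb()  # frequencies already on the calls
  run <- function(call) nrow(apply_frequency_filter(call, kb, fp, policies))
  expect_equal(run(one_call("MYH7", popmax_maf = 0.005)), 1)   # boundary in
  expect_equal(run(one_call("MYH7", popmax_maf = 0.0051)), 0)
  expect_equal(run(one_call("MYH7", popmax_maf = 0.05)), 0)
  expect_equal(run(one_call("MYH7", popmax_maf = NA)), 1)      # absent = rare
  expect_equal(run(one_call("ATP7B", "hom", popmax_maf = 0.01)), 1)
  expect_equal(run(one_call("ATP7B", "hom", popmax_maf = 0.02)), 1)
  expect_equal(run(one_call("ATP7B", "hom", popmax_maf = 0.0201)), 0)
  # the relaxed ceiling is only for AR homozygotes
  expect_equal(run(one_call("MYH7", "hom", popmax_maf = 0.01)), 0)
})

test_that("retention keeps DM/DM?, P/LP, or PTM, recording every reason", {
  kb <- tmp_kb()
  ret <- function(call) apply_retention_filter(call, kb, fp)
  novel_fs <- ret(one_call("BRCA2", term = "frameshift_variant"))
  expect_equal(novel_fs$retention_reason, "ptm")
  dm_mis <- ret(one_call("MYH7", hgmd = "DM?"))
  expect_equal(dm_mis$retention_reason, "hgmd_dm")
  both <- ret(one_call("BRCA2", term = "frameshift_variant",
                       clinvar = "pathogenic", hgmd = "DM"))
  expect_equal(both$retention_reason, "hgmd_dm,clinvar_plp,ptm")
  expect_equal(nrow(ret(one_call("MYH7"))), 0)  # novel missense dropped
  # ClinVar "conflicting" does not satisfy retention
  expect_equal(nrow(ret(one_call("MYH7", clinvar = "conflicting"))), 0)
})

test_that("cascade survivors equal the brute-force predicate conjunction", {
  for (seed in 1:60) {
    case <- random_screen_case(seed)
    res <- run_cascade(case$calls, policies, case$kb, fp)
    keep <- oracle_survivor_calls(case$calls, policies, fp)
    expect_setequal(res$candidates$variant_key,
                    unique(case$calls$variant_key[keep]))
  }
})

test_that("the survivor set is order-independent across commuting stages", {
  for (seed in c(3, 17, 29)) {
    case <- random_screen_case(seed)
    res <- run_cascade(case$calls, policies, case$kb, fp)
    reordered <- apply_zygosity_filter(
      apply_gene_filter(
        apply_frequency_filter(case$calls, case$kb, fp, policies),
        policies),
      policies)
    cand <- apply_retention_filter(reordered, case$kb, fp)
    expect_setequal(cand$variant_key, res$candidates$variant_key)
  }
})

test_that("tightening the MAF threshold or shrinking the gene list never enlarges the survivor set", {
  for (seed in c(5, 11)) {
    case <- random_screen_case(seed)
    base <- run_cascade(case$calls, policies, case$kb, fp)
    tight <- run_cascade(case$calls, policies, case$kb,
                         filter_policy(maf_threshold = 0.001,
                                       ar_hom_maf_threshold = 0.01))
    expect_true(all(tight$candidates$variant_key %in%
                      base$candidates$variant_key))
    shrunk <- policies[policies$gene_symbol != "MYH7", ]
    fewer <- run_cascade(case$calls, shrunk, case$kb, fp)
    expect_true(all(fewer$candidates$variant_key %in%
                      base$candidates$variant_key))
  }
})

test_that("audit trail covers every variant with monotone stage counts", {
  case <- random_screen_case(8)
  res <- run_cascade(case$calls, policies, case$kb, fp)
  keys <- unique(case$calls$variant_key)
  # every input variant appears in the trail, at most once per stage
  expect_setequal(unique(res$audit$variant_key), keys)
  expect_false(any(duplicated(res$audit[, c("variant_key", "stage")])))
  per_stage <- table(factor(res$audit$stage,
                            levels = c("gene", "zygosity", "frequency",
                                       "retention")))
  expect_true(all(diff(as.integer(per_stage)) <= 0))
  # retained candidates always carry carriers and reasons
  expect_true(all(res$candidates$carrier_count >= 1))
  expect_true(all(nzchar(res$candidates$retention_reason)))
  # eliminated variants have a failed stage with the comparison recorded
  gone <- setdiff(keys, res$candidates$variant_key)
  for (k in gone) {
    rows <- res$audit[res$audit$variant_key == k, ]
    expect_true(any(!rows$passed))
    expect_true(all(nzchar(rows$detail)))
  }
})

test_that("empty inputs yield empty candidate sets and trails", {
  res <- run_cascade(make_calls(data.frame(
    sample_id = character(), variant_key = character(), gene = character(),
    consequence_term = character(), zygosity = character())),
    policies, tmp_kb(), fp, cohort_size = 0)
  expect_equal(res$n_distinct, 0)
  expect_equal(nrow(res$audit), 0)
})

test_that("candidate tables survive a write/read round trip", {
  case <- random_screen_case(13)
  res <- run_cascade(case$calls, policies, case$kb, fp)
  path <- tempfile(fileext = ".tsv")
  write_candidates(res$candidates, path)
  back <- read_candidates(path)
  expect_setequal(back$variant_key, res$candidates$variant_key)
  m <- match(res$candidates$variant_key, back$variant_key)
  expect_equal(back$retention_reason[m], res$candidates$retention_reason)
  expect_equal(back$carrier_count[m], res$candidates$carrier_count)
  expect_equal(back$is_ptm[m], res$candidates$is_ptm)
})
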