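test_that("evidence tokens parse with native and modified strengths", {
  ev <- parse_evidence("PS4, PP1_Strong, PM1, PM2, PP3")
  expect_equal(ev$base, c("PS4", "PP1", "PM1", "PM2", "PP3"))
  expect_equal(ev$applied_strength,
               c("strong", "strong", "moderate", "moderate", "supporting"))
  one <- parse_evidence("PS4_Supporting")
  expect_equal(one$base, "PS4")
  expect_equal(one$applied_strength, "supporting")
  expect_equal(parse_evidence("PVS1")$applied_strength, "very_strong")
  expect_equal(parse_evidence("PVS1_Strong")$applied_strength, "strong")
  expect_error(parse_evidence("PS9"), "invalid evidence code")
  expect_error(parse_evidence("PM2_Weak"), "invalid evidence code")
  expect_error(parse_evidence(c("PM2", "PM2_Supporting")), "duplicate base")
  expect_equal(nrow(parse_evidence(character(0))), 0)
})

test_that("combining rules reproduce the worked evidence sets", {
  expect_equal(combine_evidence("PVS1,PS4,PM2"), "pathogenic")
  expect_equal(combine_evidence("PVS1,PM2"), "likely_pathogenic")
  expect_equal(combine_evidence("PS3,PS4,PP3"), "pathogenic")
  expect_equal(combine_evidence("PS4,PP1_Strong,PM1,PM2,PP3"), "pathogenic")
  expect_equal(combine_evidence("PM1,PM2,PM5,PP3,PS4_Supporting"),
               "likely_pathogenic")
  expect_equal(combine_evidence("PS4,PM2,PM5,PP3,PS3_Supporting"),
               "pathogenic")
  expect_equal(combine_evidence(character(0)), "uncertain")
  expect_equal(combine_evidence("PM2,PP3"), "uncertain")
})

test_that("engine tier equals the literal rule-table oracle over the count grid", {
  for (vs in 0:1) for (s in 0:4) for (m in 0:6) for (p in 0:6) {
    expect_equal(combine_evidence(c(vs = vs, s = s, m = m, p = p)),
                 oracle_tier(vs, s, m, p),
                 info = sprintf("vs=%d s=%d m=%d p=%d", vs, s, m, p))
  }
})

test_that("token sets and their strength-count vectors agree", {
  # every grid point realizable with distinct native codes
  for (vs in 0:1) for (s in 0:4) for (m in 0:6) for (p in 0:5) {
    tok <- tokens_for_counts(vs, s, m, p)
    expect_equal(combine_evidence(tok),
                 combine_evidence(c(vs = vs, s = s, m = m, p = p)))
  }
})

test_that("adding evidence never demotes the tier", {
  bumps <- list(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1))
  for (vs in 0:1) for (s in 0:3) for (m in 0:5) for (p in 0:5) {
    base <- tier_rank(combine_evidence(c(vs = vs, s = s, m = m, p = p)))
    for (b in bumps) {
      if (vs + b[1] > 1) next
      up <- combine_evidence(c(vs = vs + b[1], s = s + b[2], m = m + b[3],
                               p = p + b[4]))
      expect_gte(tier_rank(up), base)
    }
  }
})

test_that("tier depends only on the strength-count vector, not the base codes", {
  # same counts realized by different base codes / modified strengths
  equivalents <- list(
    c("PS1", "PM1", "PM2"),
    c("PS4", "PM5", "PM6"),
    c("PP1_Strong", "PM1", "PS2_Moderate"),
    c("PS3", "PP3_Moderate", "PM4")
  )
  tiers <- vapply(equivalents, combine_evidence, character(1))
  expect_true(all(tiers == tiers[1]))
  # a promoted supporting code behaves exactly as a native one of that level
  expect_equal(combine_evidence(c("PS4", "PP1_Strong")),
               combine_evidence(c("PS4", "PS1")))
  expect_equal(combine_evidence(c("PM1", "PM2", "PS4_Supporting", "PP3")),
               combine_evidence(c("PM1", "PM2", "PP1", "PP3")))
})

test_that("categorization follows the KP/EP/others rules", {
  expect_equal(categorize(TRUE, FALSE, TRUE, "pathogenic"), "KP")
  expect_equal(categorize(TRUE, TRUE, TRUE, "likely_pathogenic"), "KP")
  expect_equal(categorize(FALSE, TRUE, TRUE, "likely_pathogenic"), "EP")
  # novel PTM in a gene not eligible for novel-PTM reporting
  expect_equal(categorize(FALSE, TRUE, FALSE, "likely_pathogenic"), "others")
  # novel non-PTM is always others, whatever the evidence implies
  expect_equal(categorize(FALSE, FALSE, TRUE, "pathogenic"), "others")
  expect_equal(categorize(TRUE, FALSE, TRUE, "uncertain"), "others")
  expect_equal(categorize(c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE),
                          c("pathogenic", "pathogenic")), c("KP", "EP"))
})

test_that("advisory suggestions fire only on their stated triggers", {
  expect_equal(suggest_evidence(TRUE, TRUE, NA), c("PVS1", "PM2"))
  expect_equal(suggest_evidence(FALSE, TRUE, 0.004), "PM2")
  expect_equal(suggest_evidence(FALSE, TRUE, 0.05), character(0))
  expect_equal(suggest_evidence(TRUE, FALSE, 0.05), character(0))
})

test_that("classification joins curator evidence and honours suggestions only as fallback", {
  policies <- default_gene_policies()
  case <- data.frame(
    variant_key = c("1:1:A:G", "1:2:A:G"),
    gene = c("BRCA2", "FBN1"),
    consequence = c("frameshift", "frameshift"),
    is_ptm = c(TRUE, TRUE),
    popmax_maf = c(NA_real_, NA_real_),
    carrier_ids = c("P01", "P02"), carrier_count = c(1L, 1L),
    previously_reported = c(FALSE, FALSE),
    stringsAsFactors = FALSE)
  ev <- data.frame(variant_key = "1:1:A:G", codes = "PVS1,PM2",
                   curator_id = "a", note = "", stringsAsFactors = FALSE)
  res <- classify_candidates(case, ev, policies)
  expect_equal(res$tier, c("likely_pathogenic", "uncertain"))
  expect_equal(res$category, c("EP", "others"))
  res2 <- classify_candidates(case, ev, policies, use_suggestions = TRUE)
  expect_equal(res2$codes[2], "PVS1,PM2")
  expect_equal(res2$category, c("EP", "EP"))
  # curator row overrides any suggestion
  ev3 <- data.frame(variant_key = c("1:1:A:G", "1:2:A:G"),
                    codes = c("PVS1,PM2", "PM2"), curator_id = "a",
                    note = "", stringsAsFactors = FALSE)
  res3 <- classify_candidates(case, ev3, policies, use_suggestions = TRUE)
  expect_equal(res3$codes[2], "PM2")
  expect_equal(res3$category[2], "others")
})

test_that("concordance checking flags code and coverage differences", {
  a <- data.frame(variant_key = c("k1", "k2"),
                  codes = c("PVS1,PM2", "PS3,PS4,PP3"),
                  stringsAsFactors = FALSE)
  expect_equal(nrow(check_concordance(a, a)), 0)

  b <- a
  b$codes[1] <- "PVS1,PM2,PP3"
  rep1 <- check_concordance(a, b)
  expect_equal(rep1$kind, "codes_differ")
  expect_equal(rep1$tier_a, "likely_pathogenic")
  expect_equal(rep1$tier_b, "pathogenic")
  expect_equal(rep1$only_in_b, "PP3")

  rep2 <- check_concordance(a, a[1, , drop = FALSE])
  expect_equal(rep2$kind, "missing_in_b")
  expect_equal(rep2$variant_key, "k2")
})
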