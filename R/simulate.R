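# Synthetic cohort generation with fully known ground truth. A bundle is the
# complete set of files the pipeline consumes (multi-sample VCF, annotation
# TSV, knowledge-base TSVs, sample groups, curator evidence, gene policies)
# plus a truth TSV stating, for every emitted variant, the cascade stage that
# should eliminate it (or "none"), the expected tier and the expected
# category — so pipeline(generate(config)) can be checked exactly.

# Evaluate seed-preserving expressions: the generator never perturbs the
# caller's RNG stream, and the same seed always yields the same bundle.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Build a simulation configuration
#'
#' Describes a synthetic screening cohort: how many individuals per group
#' (defaults mirror the study design of 96 phenotypically normal, 96
#' juvenile-obesity and 229 congenital-heart-disease children), and the
#' variants to plant. Each planted variant row fixes gene, consequence term,
#' zygosity, popmax MAF (`NA` = absent from population data), ClinVar/HGMD
#' status, curator evidence codes, and how many carriers to draw from each
#' group. Reportable findings and stage-targeted decoys are both just rows;
#' the ground truth is derived, not declared.
#'
#' @param variants Data frame with columns `label`, `gene`,
#'   `consequence_term`, `zygosity`, `popmax_maf`, `clinvar_status`,
#'   `hgmd_status`, `codes`, `carriers_normal`, `carriers_obesity`,
#'   `carriers_chd`.
#' @param n_samples Cohort size; must equal `sum(group_sizes)`.
#' @param group_sizes Named integer vector over `normal`, `obesity`, `chd`.
#' @param seed Integer seed; identical seeds yield byte-identical bundles.
#' @return A `simulation_config` list.
#' @seealso [generate_cohort()], [study_variants()], [table1_fixture()]
#' @export
simulation_config <- function(variants,
                              n_samples = 421,
                              group_sizes = c(normal = 96, obesity = 96,
                                              chd = 229),
                              seed = 1) {
  stopifnot(all(c("normal", "obesity", "chd") %in% names(group_sizes)))
  if (sum(group_sizes) != n_samples) {
    stop("group sizes (", sum(group_sizes), ") must sum to n_samples (",
         n_samples, ")", call. = FALSE)
  }
  need <- c("label", "gene", "consequence_term", "zygosity", "popmax_maf",
            "clinvar_status", "hgmd_status", "codes",
            "carriers_normal", "carriers_obesity", "carriers_chd")
  missing <- setdiff(need, names(variants))
  if (length(missing)) {
    stop("variants table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(variants$zygosity %in% ZYGOSITY_LEVELS)) {
    stop("invalid zygosity in variants table", call. = FALSE)
  }
  if (!all(variants$clinvar_status %in% CLINVAR_LEVELS) ||
      !all(variants$hgmd_status %in% HGMD_LEVELS)) {
    stop("invalid assertion status in variants table", call. = FALSE)
  }
  # planted carriers are distinct individuals: the per-group total across
  # all variants may not exceed the group, except that one individual never
  # carries two planted variants (sharing is expressed by one variant with
  # several carriers)
  for (g in c("normal", "obesity", "chd")) {
    col <- variants[[paste0("carriers_", g)]]
    if (sum(col) > group_sizes[[g]]) {
      stop("more ", g, " carriers requested than the group holds",
           call. = FALSE)
    }
  }
  if (any(variants$carriers_normal + variants$carriers_obesity +
          variants$carriers_chd < 1)) {
    stop("every planted variant needs at least one carrier", call. = FALSE)
  }
  structure(list(variants = variants, n_samples = n_samples,
                 group_sizes = group_sizes, seed = seed),
            class = "simulation_config")
}

# Deterministic synthetic coordinates and alleles for variant i of a bundle.
# A toy contig carries everything; variant identity lives in the key and the
# HGVS strings, so real genome context is never required.
synth_alleles <- function(i, consequence_term) {
  bases <- c("A", "C", "G", "T")
  b <- bases[(i - 1L) %% 4L + 1L]
  alt_snv <- bases[i %% 4L + 1L]
  pos <- 5000L * i
  if (consequence_term %in% c("frameshift_variant", "inframe_deletion")) {
    list(pos = pos, ref = paste0(b, "CTG"), alt = b)        # 3bp deletion
  } else if (consequence_term %in% c("inframe_insertion")) {
    list(pos = pos, ref = b, alt = paste0(b, "GGC"))
  } else {
    list(pos = pos, ref = b, alt = alt_snv)
  }
}

# Shared emitter: explicit carriers per variant -> file bundle + truth.
emit_bundle <- function(samples, variants, carriers, outdir,
                        policies = default_gene_policies(),
                        fp = filter_policy()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  n_var <- nrow(variants)
  stopifnot(length(carriers) == n_var)

  al <- lapply(seq_len(n_var), function(i)
    synth_alleles(i, variants$consequence_term[i]))
  chrom <- rep("1", n_var)
  pos <- vapply(al, `[[`, integer(1), "pos")
  ref <- vapply(al, `[[`, character(1), "ref")
  alt <- vapply(al, `[[`, character(1), "alt")
  key <- variant_key(chrom, pos, ref, alt)

  calls <- do.call(rbind, lapply(seq_len(n_var), function(i) {
    data.frame(sample_id = carriers[[i]], variant_key = key[i],
               chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alt[i],
               zygosity = variants$zygosity[i], stringsAsFactors = FALSE)
  }))

  paths <- list(
    vcf = file.path(outdir, "cohort.vcf"),
    annotations = file.path(outdir, "annotations.tsv"),
    genes = file.path(outdir, "genes.tsv"),
    kb_freq = file.path(outdir, "kb_freq.tsv"),
    kb_clinvar = file.path(outdir, "kb_clinvar.tsv"),
    kb_hgmd = file.path(outdir, "kb_hgmd.tsv"),
    groups = file.path(outdir, "groups.tsv"),
    evidence = file.path(outdir, "evidence.tsv"),
    truth = file.path(outdir, "truth.tsv")
  )

  write_cohort_vcf(calls, paths$vcf, samples = samples$sample_id)

  tx <- variants$transcript %||% sprintf("NM_%06d", seq_len(n_var))
  hc <- variants$hgvs_c %||% sprintf("c.%d%s>%s", pos, ref, alt)
  hp <- variants$hgvs_p %||% rep("", n_var)
  write_tsv(data.frame(variant_key = key, gene = variants$gene,
                       transcript = tx, hgvs_c = hc, hgvs_p = hp,
                       consequence_term = variants$consequence_term),
            paths$annotations)

  pol_out <- as.data.frame(policies)
  pol_out$inheritance <- as.character(pol_out$inheritance)
  pol_out$ep_eligible <- tolower(as.character(pol_out$ep_eligible))
  write_tsv(pol_out, paths$genes)

  obs <- !is.na(variants$popmax_maf)
  write_tsv(data.frame(variant_key = key[obs],
                       popmax_maf = variants$popmax_maf[obs]),
            paths$kb_freq)
  has_clv <- variants$clinvar_status != "absent"
  write_tsv(data.frame(variant_key = key[has_clv],
                       status = variants$clinvar_status[has_clv]),
            paths$kb_clinvar)
  has_hgmd <- variants$hgmd_status != "absent"
  write_tsv(data.frame(variant_key = key[has_hgmd],
                       status = variants$hgmd_status[has_hgmd]),
            paths$kb_hgmd)

  write_tsv(samples, paths$groups)

  has_ev <- nzchar(variants$codes)
  write_tsv(data.frame(variant_key = key[has_ev],
                       codes = variants$codes[has_ev],
                       curator_id = rep("curatorA", sum(has_ev)),
                       note = rep("", sum(has_ev))),
            paths$evidence)

  # Ground truth by direct, per-variant evaluation of the four filter rules
  # and the combining rules.
  cc <- classify_consequence(variants$consequence_term)
  inh <- policy_inheritance(policies, variants$gene)
  ep_ok <- policy_ep_eligible(policies, variants$gene)
  maf_eff <- ifelse(is.na(variants$popmax_maf), 0, variants$popmax_maf)
  gene_pass <- variants$gene %in% policies$gene_symbol
  zyg_pass <- is.na(inh) | inh != "AR" | variants$zygosity == "hom"
  freq_pass <- maf_eff <= fp$maf_threshold |
    (!is.na(inh) & inh == "AR" & variants$zygosity == "hom" &
       maf_eff <= fp$ar_hom_maf_threshold)
  reported <- variants$clinvar_status != "absent" |
    variants$hgmd_status != "absent"
  ret_pass <- variants$hgmd_status %in% fp$retained_hgmd_statuses |
    variants$clinvar_status %in% fp$retained_assertions | cc$is_ptm
  eliminated_at <- ifelse(!gene_pass, "gene",
                   ifelse(!zyg_pass, "zygosity",
                   ifelse(!freq_pass, "frequency",
                   ifelse(!ret_pass, "retention", "none"))))
  tier <- vapply(variants$codes, function(x) combine_evidence(x),
                 character(1), USE.NAMES = FALSE)
  category <- categorize(reported, cc$is_ptm, ep_ok, tier)
  tier[eliminated_at != "none"] <- ""
  category[eliminated_at != "none"] <- ""

  truth <- data.frame(
    variant_key = key, label = variants$label, gene = variants$gene,
    consequence = cc$consequence, zygosity = variants$zygosity,
    carrier_ids = vapply(carriers, function(x)
      paste(sort(x), collapse = ","), character(1)),
    eliminated_at = eliminated_at, expected_tier = tier,
    expected_category = category, stringsAsFactors = FALSE)
  write_tsv(truth, paths$truth)

  invisible(c(paths, list(truth_table = truth)))
}

#' Generate a synthetic cohort bundle
#'
#' Materializes a [simulation_config()] as a complete, self-contained file
#' bundle: `cohort.vcf` (all cohort samples, GT-only), `annotations.tsv`,
#' `genes.tsv` (the gene policy table), `kb_freq.tsv` / `kb_clinvar.tsv` /
#' `kb_hgmd.tsv`, `groups.tsv`, `evidence.tsv`, and `truth.tsv` with the
#' derived per-variant expectations. Carrier individuals are drawn from the
#' requested groups with the config's seed; the same seed reproduces every
#' file byte for byte.
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths plus `truth_table`.
#' @examples
#' \dontrun{
#' cfg <- simulation_config(study_variants(), seed = 7)
#' bundle <- generate_cohort(cfg, tempfile("sim"))
#' }
#' @export
generate_cohort <- function(config, outdir) {
  stopifnot(inherits(config, "simulation_config"))
  gs <- config$group_sizes
  samples <- data.frame(
    sample_id = sprintf("S%04d", seq_len(config$n_samples)),
    group = rep(c("normal", "obesity", "chd"),
                times = c(gs[["normal"]], gs[["obesity"]], gs[["chd"]])),
    stringsAsFactors = FALSE)
  v <- config$variants
  # carriers are distinct individuals: draw each group's total need without
  # replacement, then deal the draw out in variant order
  carriers <- with_seed(config$seed, {
    drawn <- lapply(c(normal = "normal", obesity = "obesity", chd = "chd"),
                    function(g) {
      need <- sum(v[[paste0("carriers_", g)]])
      pool <- samples$sample_id[samples$group == g]
      sample(pool, need)
    })
    taken <- c(normal = 0L, obesity = 0L, chd = 0L)
    lapply(seq_len(nrow(v)), function(i) {
      picked <- character(0)
      for (g in c("normal", "obesity", "chd")) {
        k <- v[[paste0("carriers_", g)]][i]
        if (k > 0) {
          picked <- c(picked, drawn[[g]][taken[[g]] + seq_len(k)])
          taken[[g]] <<- taken[[g]] + k
        }
      }
      picked
    })
  })
  emit_bundle(samples, v, carriers, outdir)
}

#' The transcribed reportable-variant set of the study
#'
#' The 11 secondary findings the screening protocol reports on its cohort —
#' gene, transcript, HGVS, consequence, the curator evidence codes (with the
#' expert-panel modified strengths, e.g. `PP1_Strong`, `PS4_Supporting`,
#' `PS3_Supporting`), knowledge-base assertions, the carrier group(s), and
#' the expected tier and KP/EP category — plus, when `include_decoys = TRUE`,
#' engineered decoys that each fail exactly one cascade stage or fail
#' classification (novel missense with PM2 only, a truncating variant in a
#' gene not eligible for novel-PTM reporting, a common variant, a
#' heterozygous call in a recessive gene, an off-list gene, an
#' AR-homozygote rescued by the relaxed ceiling but with insufficient
#' evidence).
#'
#' @param include_decoys Append the decoy rows; default `TRUE`.
#' @return A variants data frame in [simulation_config()] layout, with extra
#'   columns `transcript`, `hgvs_c`, `hgvs_p`, `expected_tier`,
#'   `expected_category`.
#' @export
study_variants <- function(include_decoys = TRUE) {
  f <- function(label, gene, tx, hc, hp, term, zyg, maf, clv, hgmd, codes,
                cn, co, cc, tier, cat) {
    data.frame(label = label, gene = gene, transcript = tx, hgvs_c = hc,
               hgvs_p = hp, consequence_term = term, zygosity = zyg,
               popmax_maf = maf, clinvar_status = clv, hgmd_status = hgmd,
               codes = codes, carriers_normal = cn, carriers_obesity = co,
               carriers_chd = cc, expected_tier = tier,
               expected_category = cat, stringsAsFactors = FALSE)
  }
  reportable <- rbind(
    f("APOB_p.Arg3527Trp", "APOB", "NM_000384", "c.10579C>T", "p.Arg3527Trp",
      "missense_variant", "het", NA, "pathogenic", "DM",
      "PS3,PS4,PP3", 1L, 0L, 1L, "pathogenic", "KP"),
    f("BRCA2_p.Lys936fs", "BRCA2", "NM_000059", "c.2806_2809del",
      "p.Lys936fs", "frameshift_variant", "het", NA, "pathogenic", "DM",
      "PVS1,PS4,PM2", 0L, 1L, 0L, "pathogenic", "KP"),
    f("DSP_p.Gln90Ter", "DSP", "NM_004415", "c.268C>T", "p.Gln90Ter",
      "stop_gained", "het", NA, "absent", "DM",
      "PVS1,PM2,PP3", 0L, 1L, 0L, "pathogenic", "KP"),
    f("MYH7_p.Arg663His", "MYH7", "NM_000257", "c.1988G>A", "p.Arg663His",
      "missense_variant", "het", 1e-05, "pathogenic", "DM",
      "PS4,PP1_Strong,PM1,PM2,PP3", 1L, 0L, 0L, "pathogenic", "KP"),
    f("MYH7_p.Arg403Trp", "MYH7", "NM_000257", "c.1207C>T", "p.Arg403Trp",
      "missense_variant", "het", NA, "pathogenic", "DM",
      "PS4,PP1_Strong,PM1,PM2,PM5,PP3", 1L, 0L, 0L, "pathogenic", "KP"),
    f("PMS2_c.498+2T>C", "PMS2", "NM_001322010", "c.498+2T>C", "",
      "splice_donor_variant", "het", NA, "likely_pathogenic", "DM",
      "PVS1,PS3,PM2,PP3", 0L, 0L, 1L, "pathogenic", "KP"),
    f("SDHB_p.Arg242Cys", "SDHB", "NM_003000", "c.724C>T", "p.Arg242Cys",
      "missense_variant", "het", NA, "absent", "DM?",
      "PS4,PM2,PM5,PP3,PS3_Supporting", 0L, 0L, 1L, "pathogenic", "KP"),
    f("LDLR_p.Phe153fs", "LDLR", "NM_000527", "c.459delC", "p.Phe153fs",
      "frameshift_variant", "het", NA, "pathogenic", "DM",
      "PVS1,PM2", 1L, 0L, 0L, "likely_pathogenic", "KP"),
    f("MYH7_p.Arg870Cys", "MYH7", "NM_000257", "c.2608C>T", "p.Arg870Cys",
      "missense_variant", "het", 1e-05, "absent", "DM",
      "PM1,PM2,PM5,PP3,PS4_Supporting", 0L, 1L, 0L,
      "likely_pathogenic", "KP"),
    f("BRCA2_p.Ile982fs", "BRCA2", "NM_000059", "c.2944_2945del",
      "p.Ile982fs", "frameshift_variant", "het", NA, "absent", "absent",
      "PVS1,PM2", 1L, 0L, 0L, "likely_pathogenic", "EP"),
    f("FBN1_p.Ala1015fs", "FBN1", "NM_000138", "c.3042dupT", "p.Ala1015fs",
      "frameshift_variant", "het", NA, "absent", "absent",
      "PVS1,PM2", 1L, 0L, 0L, "likely_pathogenic", "EP")
  )
  if (!include_decoys) return(reportable)
  decoys <- rbind(
    f("decoy_offlist_gene", "TTN", "NM_001267550", "c.2T>C", "p.Met1?",
      "missense_variant", "het", 0.001, "pathogenic", "DM",
      "", 1L, 0L, 0L, "", ""),
    f("decoy_ar_het", "ATP7B", "NM_000053", "c.2333G>T", "p.Arg778Leu",
      "missense_variant", "het", 0.004, "pathogenic", "DM",
      "", 0L, 1L, 0L, "", ""),
    f("decoy_common", "MYBPC3", "NM_000256", "c.1000C>T", "p.Arg334Trp",
      "missense_variant", "het", 0.05, "pathogenic", "DM",
      "", 0L, 0L, 1L, "", ""),
    f("decoy_novel_missense", "MYBPC3", "NM_000256", "c.2000G>A",
      "p.Gly667Asp", "missense_variant", "het", 1e-04, "absent", "absent",
      "", 1L, 0L, 0L, "", ""),
    f("decoy_ar_hom_weak", "ATP7B", "NM_000053", "c.3207C>A",
      "p.His1069Gln", "missense_variant", "hom", 0.01, "absent", "DM",
      "PM2", 0L, 0L, 1L, "", ""),
    f("decoy_ptm_non_ep_gene", "RYR1", "NM_000540", "c.100del",
      "p.Val34fs", "frameshift_variant", "het", NA, "absent", "absent",
      "PVS1,PM2", 0L, 1L, 0L, "", ""),
    f("decoy_reported_weak_missense", "SCN5A", "NM_198056", "c.3911C>T",
      "p.Thr1304Met", "missense_variant", "het", 0.002, "vus", "DM?",
      "PM2,PP3", 0L, 0L, 1L, "", ""),
    f("decoy_reported_synonymous", "KCNQ1", "NM_000218", "c.1032G>A",
      "p.Ala344Ala", "synonymous_variant", "het", 0.001, "absent", "DM",
      "", 1L, 0L, 0L, "", "")
  )
  rbind(reportable, decoys)
}

#' Emit the worked-example fixture bundle
#'
#' Writes the fully deterministic bundle for the 11 transcribed reportable
#' variants plus the engineered decoys of [study_variants()], with the
#' carrier layout of the study: six normal-group carriers, three obesity,
#' three CHD — twelve individuals in all, the shared variant (APOB) carried
#' by one normal and one CHD child. No random number is drawn: carriers are
#' the first free sample slots of each group, so repeated calls are
#' byte-identical.
#'
#' @param outdir Output directory.
#' @return Invisibly, the file-path list of [generate_cohort()], with
#'   `truth_table` carrying the expected tier/category per variant.
#' @examples
#' \dontrun{
#' bundle <- table1_fixture(tempfile("fix"))
#' read.delim(bundle$truth)
#' }
#' @export
table1_fixture <- function(outdir) {
  gs <- c(normal = 96, obesity = 96, chd = 229)
  samples <- data.frame(
    sample_id = sprintf("S%04d", 1:421),
    group = rep(c("normal", "obesity", "chd"), times = gs),
    stringsAsFactors = FALSE)
  v <- study_variants(include_decoys = TRUE)
  # deterministic carrier assignment: next free slot within each group
  pools <- list(normal = samples$sample_id[samples$group == "normal"],
                obesity = samples$sample_id[samples$group == "obesity"],
                chd = samples$sample_id[samples$group == "chd"])
  used <- c(normal = 0L, obesity = 0L, chd = 0L)
  carriers <- lapply(seq_len(nrow(v)), function(i) {
    picked <- character(0)
    for (g in c("normal", "obesity", "chd")) {
      k <- v[[paste0("carriers_", g)]][i]
      if (k > 0) {
        picked <- c(picked, pools[[g]][used[[g]] + seq_len(k)])
        used[[g]] <<- used[[g]] + k
      }
    }
    picked
  })
  emit_bundle(samples, v, carriers, outdir)
}

#' Random screening cohorts for property testing
#'
#' Draws a small cohort whose variants uniformly exercise every cascade
#' stage: genes on and off the policy list (including the recessive and
#' X-linked entries), all zygosities, popmax MAFs straddling both thresholds
#' (including exact boundary values), all assertion statuses, and evidence
#' sets of varying strength. Used for closure and oracle-equivalence
#' properties; ground truth is derived by [generate_cohort()].
#'
#' @param seed Integer seed.
#' @param n_variants Number of variants to draw.
#' @param group_sizes Named sizes for `normal`/`obesity`/`chd`.
#' @return A [simulation_config()].
#' @export
random_simulation_config <- function(seed, n_variants = 20,
                                     group_sizes = c(normal = 8,
                                                     obesity = 8,
                                                     chd = 14)) {
  genes <- c("MYH7", "BRCA2", "LDLR", "MUTYH", "ATP7B", "GLA", "OTC",
             "RYR1", "APOB", "FBN1", "TTN", "NOTCH1", "GATA4")
  terms <- c("missense_variant", "synonymous_variant", "frameshift_variant",
             "stop_gained", "start_lost", "splice_donor_variant",
             "inframe_deletion", "other")
  mafs <- c(NA, 1e-05, 0.001, 0.004, 0.005, 0.008, 0.01, 0.02, 0.03, 0.05)
  code_pool <- c("", "PM2", "PVS1,PM2", "PS4,PM2,PP3", "PS1,PS4",
                 "PM1,PM2,PM5,PP3,PS4_Supporting", "PVS1,PS4,PM2",
                 "PP1,PP3", "PS3_Supporting,PM2,PP3",
                 "PVS1,PP1_Strong", "PM1,PM2,PM6", "PS4_Supporting,PP3")
  stopifnot(n_variants <= sum(group_sizes))
  with_seed(seed, {
    v <- data.frame(
      label = sprintf("rv%03d", seq_len(n_variants)),
      gene = sample(genes, n_variants, replace = TRUE),
      consequence_term = sample(terms, n_variants, replace = TRUE),
      zygosity = sample(ZYGOSITY_LEVELS, n_variants, replace = TRUE,
                        prob = c(0.7, 0.2, 0.1)),
      popmax_maf = sample(mafs, n_variants, replace = TRUE),
      clinvar_status = sample(CLINVAR_LEVELS, n_variants, replace = TRUE),
      hgmd_status = sample(HGMD_LEVELS, n_variants, replace = TRUE),
      codes = sample(code_pool, n_variants, replace = TRUE),
      carriers_normal = 0L, carriers_obesity = 0L, carriers_chd = 0L,
      stringsAsFactors = FALSE)
    # carriers are distinct individuals, so draw against the remaining
    # capacity of each group; most variants are singletons, some shared
    cap <- c(normal = group_sizes[["normal"]],
             obesity = group_sizes[["obesity"]],
             chd = group_sizes[["chd"]])
    spare <- sum(cap) - n_variants
    for (i in seq_len(n_variants)) {
      k <- if (spare > 0 && stats::runif(1) < 0.25) 2L else 1L
      spare <- spare - (k - 1L)
      for (j in seq_len(k)) {
        open <- names(cap)[cap > 0]
        g <- if (length(open) == 1) open else
          sample(open, 1, prob = cap[open])
        col <- paste0("carriers_", g)
        v[[col]][i] <- v[[col]][i] + 1L
        cap[[g]] <- cap[[g]] - 1L
      }
    }
    simulation_config(v, n_samples = sum(group_sizes),
                      group_sizes = group_sizes, seed = seed)
  })
}
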