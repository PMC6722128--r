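# Candidate filter: affected-only retention (ANY affected sibling carries,
# no unaffected sibling does), exact cross-family matching, functional
# class filtering, parental origin.

fam1 <- nuclear_family("F1", n_aff = 2, n_un = 1)

test_that("a variant in one of two affected sibs and no unaffected sib is retained", {
  geno <- matrix(0L, nrow = 1, ncol = 5,
                 dimnames = list(NULL, fam1$member_id))
  geno[1, "F1_C1"] <- 1L
  hits <- family_private_variants(fam1, make_table(geno))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$affected_carriers, "F1_C1")
})

test_that("a variant carried by an unaffected sibling is excluded", {
  geno <- matrix(0L, nrow = 1, ncol = 5,
                 dimnames = list(NULL, fam1$member_id))
  geno[1, c("F1_C1", "F1_C3")] <- 1L  # C3 is unaffected
  expect_equal(nrow(family_private_variants(fam1, make_table(geno))), 0)
})

test_that("parents' genotypes do not enter the sibling-level step", {
  geno <- matrix(0L, nrow = 1, ncol = 5,
                 dimnames = list(NULL, fam1$member_id))
  geno[1, c("F1_F", "F1_C1")] <- 1L  # carrier father must not block
  expect_equal(nrow(family_private_variants(fam1, make_table(geno))), 1)
})

test_that("retention equals truth-table evaluation over all dosage patterns", {
  # 2 affected + 1 unaffected sibling; enumerate all 27 sibling dosage
  # patterns plus missing variants of the unaffected slot
  pats <- expand.grid(a1 = 0:2, a2 = 0:2, u1 = c(0:2, NA))
  geno <- matrix(0L, nrow = nrow(pats), ncol = 5,
                 dimnames = list(NULL, fam1$member_id))
  geno[, "F1_C1"] <- pats$a1
  geno[, "F1_C2"] <- pats$a2
  geno[, "F1_C3"] <- pats$u1
  tab <- make_table(geno)
  oracle <- (pats$a1 >= 1 | pats$a2 >= 1) & (is.na(pats$u1) | pats$u1 == 0)
  lenient <- family_private_variants(fam1, tab, "lenient")
  expect_setequal(lenient$pos, tab$variants$pos[oracle])
  oracle_strict <- oracle & !is.na(pats$u1)
  strict <- family_private_variants(fam1, tab, "strict")
  expect_setequal(strict$pos, tab$variants$pos[oracle_strict])
  # lenient mode records which unaffected genotypes were missing
  miss <- lenient$missing_unaffected[match(tab$variants$pos[oracle & is.na(pats$u1)],
                                           lenient$pos)]
  expect_true(all(miss == "F1_C3"))
})

test_that("other-diagnosis siblings constrain neither side", {
  fam <- nuclear_family("F2", n_aff = 2, n_un = 1)
  fam$phenotype[fam$member_id == "F2_C3"] <- "other_diagnosis"
  fam <- rbind(fam, data.frame(
    family_id = "F2", member_id = "F2_C4", father_id = "F2_F",
    mother_id = "F2_M", sex = "unknown", phenotype = "unaffected",
    has_genotype = TRUE, stringsAsFactors = FALSE))
  geno <- matrix(0L, nrow = 1, ncol = 6, dimnames = list(NULL, fam$member_id))
  geno[1, c("F2_C1", "F2_C3")] <- 1L  # other-diagnosis carrier must not block
  expect_equal(nrow(family_private_variants(fam, make_table(geno))), 1)
})

test_that("a family with no genotyped affected siblings is an error", {
  fam <- nuclear_family("F3", n_aff = 1, n_un = 1)
  fam$has_genotype[fam$member_id == "F3_C1"] <- FALSE
  geno <- matrix(0L, nrow = 1, ncol = 3,
                 dimnames = list(NULL, c("F3_F", "F3_M", "F3_C2")))
  expect_error(family_private_variants(fam, make_table(geno)), "affected")
})

test_that("cross-family matching equals a nested-loop oracle", {
  set.seed(12)
  n <- 60
  hits <- data.frame(
    chrom = "1", pos = sample(1:15, n, replace = TRUE) * 10L,
    ref = "A", alt = "T", rsid = NA_character_,
    family_id = sample(sprintf("F%02d", 1:8), n, replace = TRUE),
    affected_carriers = "", missing_unaffected = "",
    stringsAsFactors = FALSE
  )
  for (mf in 1:3) {
    got <- cross_family_match(hits, min_families = mf)
    # oracle: count distinct families per position the slow way
    oracle <- sapply(unique(hits$pos), function(p) {
      length(unique(hits$family_id[hits$pos == p]))
    })
    names(oracle) <- unique(hits$pos)
    expect_setequal(got$pos, as.integer(names(oracle)[oracle >= mf]))
    expect_equal(got$n_families,
                 unname(oracle[as.character(got$pos)]))
  }
  # min_families = 1 returns every distinct variant
  expect_equal(nrow(cross_family_match(hits, 1)), length(unique(hits$pos)))
})

test_that("matching is independent of hit row order", {
  set.seed(13)
  hits <- data.frame(
    chrom = "1", pos = rep(c(10L, 20L, 30L), each = 2),
    ref = "A", alt = "T", rsid = NA_character_,
    family_id = c("F1", "F2", "F1", "F1", "F2", "F3"),
    affected_carriers = "", missing_unaffected = "",
    stringsAsFactors = FALSE
  )
  a <- cross_family_match(hits, 2)
  b <- cross_family_match(hits[sample(nrow(hits)), ], 2)
  expect_equal(a, b)
})

test_that("functional filtering respects keep-class presets and monotonicity", {
  cand <- data.frame(
    chrom = "1", pos = c(10L, 20L, 30L, 40L), ref = "A", alt = "T",
    rsid = NA_character_, n_families = 2L, families = "F1,F2",
    stringsAsFactors = FALSE
  )
  ann <- data.frame(
    chrom = "1", pos = c(10L, 20L, 30L), ref = "A", alt = "T",
    gene = c("G1", "G2", "G3"),
    func_class = c("frameshift_del", "synonymous", "stopgain"),
    protein_change = NA_character_, stringsAsFactors = FALSE
  )
  default_keep <- filter_functional(cand, ann)
  expect_equal(default_keep$pos, 10L)
  lof <- filter_functional(cand, ann, keep_classes = lof_classes())
  expect_setequal(lof$pos, c(10L, 30L))
  # synonymous never retained by frameshift / LoF / LoF+nonsyn presets
  for (k in list(c("frameshift_ins", "frameshift_del"), lof_classes(),
                 c(lof_classes(), "nonsynonymous"))) {
    expect_false(20L %in% filter_functional(cand, ann, keep_classes = k)$pos)
  }
  # enlarging keep_classes never removes candidates
  expect_true(all(default_keep$pos %in% lof$pos))
  # unannotated candidate appears only when "other" is kept
  expect_false(40L %in% lof$pos)
  expect_true(40L %in% filter_functional(cand, ann, keep_classes = "other")$pos)
})

test_that("parental origin distinguishes inherited, de novo and undetermined", {
  fam <- nuclear_family("F1", n_aff = 2, n_un = 1)
  base <- matrix(0L, nrow = 1, ncol = 5, dimnames = list(NULL, fam$member_id))

  g <- base; g[1, c("F1_F", "F1_C1")] <- 1L
  expect_equal(assess_parental_origin(fam, make_table(g), "1", 100, "A", "T"),
               "inherited")

  g <- base; g[1, "F1_C1"] <- 1L
  expect_equal(assess_parental_origin(fam, make_table(g), "1", 100, "A", "T"),
               "putative_de_novo")

  # mother ungenotyped: undetermined even though father is non-carrier
  fam2 <- fam
  fam2$has_genotype[fam2$member_id == "F1_M"] <- FALSE
  g2 <- base[, setdiff(colnames(base), "F1_M"), drop = FALSE]
  g2[1, "F1_C1"] <- 1L
  expect_equal(assess_parental_origin(fam2, make_table(g2), "1", 100, "A", "T"),
               "undetermined")
})

test_that("end-to-end selection recovers the planted variant and no unaffected-carried decoy", {
  sim <- simulate_cohort(cohort_config(n_background_snps = 100, n_x_snps = 10,
                                       n_decoy_variants = 12), seed = 19)
  cand <- select_candidates(sim$cohort, sim$table, sim$annotations,
                            min_families = 2)
  v <- sim$ledger$causal_variant
  hit <- cand[cand$chrom == v$chrom & cand$pos == v$pos, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$n_families, 2)
  expect_setequal(strsplit(hit$families, ",")[[1]], sim$ledger$causal_families)
  bad <- sim$ledger$decoys[sim$ledger$decoys$type == "unaffected_carrier", ]
  expect_false(any(paste(cand$chrom, cand$pos) %in% paste(bad$chrom, bad$pos)))
})

test_that("selection output is independent of family processing order", {
  sim <- simulate_cohort(cohort_config(n_background_snps = 50, n_x_snps = 5,
                                       n_decoy_variants = 6), seed = 29)
  a <- select_candidates(sim$cohort, sim$table, sim$annotations)
  rev_cohort <- sim$cohort
  rev_cohort$members <- do.call(rbind, rev(split(rev_cohort$members,
    factor(rev_cohort$members$family_id,
           levels = unique(rev_cohort$members$family_id)))))
  rownames(rev_cohort$members) <- NULL
  b <- select_candidates(rev_cohort, sim$table, sim$annotations)
  expect_equal(a[, c("chrom", "pos", "ref", "alt", "families")],
               b[, c("chrom", "pos", "ref", "alt", "families")])
})
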