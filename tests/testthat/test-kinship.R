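# Direct-evaluation cases use the centered cross-product formula by hand;
# simulation cases compare against the sampling behaviour of known
# relationships (parent-offspring shares exactly one allele per marker).

test_that("centered-IBS matches hand-evaluated small cases", {
  # two samples heterozygous everywhere with p = 0.5: numerator identically 0
  geno <- matrix(1L, nrow = 1500, ncol = 2, dimnames = list(NULL, c("a", "b")))
  kin <- centered_ibs_kinship(make_table(geno), maf_floor = 0.01,
                              min_markers = 1000)
  expect_equal(kin$K["a", "b"], 0)

  # dosage 0 at p = 0.5: diagonal contribution (0 - 1)^2 / 0.5 = 2
  # (frequency fixed by surrounding samples: two samples at 0 and 2)
  geno2 <- matrix(c(0L, 2L), nrow = 1500, ncol = 2, byrow = TRUE,
                  dimnames = list(NULL, c("x", "y")))
  kin2 <- centered_ibs_kinship(make_table(geno2), min_markers = 1000)
  expect_equal(unname(kin2$K["x", "x"]), 2)
  expect_equal(unname(kin2$K["x", "y"]), -2)
})

test_that("kinship is invariant to marker order and permutes with samples", {
  set.seed(31)
  p <- runif(1200, 0.1, 0.5)
  geno <- sapply(1:6, function(i) rbinom(1200, 2, p))
  colnames(geno) <- letters[1:6]
  k1 <- centered_ibs_kinship(make_table(geno), min_markers = 1000)
  perm <- sample(1200)
  k2 <- centered_ibs_kinship(make_table(geno[perm, ]), min_markers = 1000)
  expect_equal(k1$K, k2$K)
  sperm <- c("c", "a", "f", "b", "e", "d")
  k3 <- centered_ibs_kinship(make_table(geno[, sperm]), min_markers = 1000)
  expect_equal(k3$K[letters[1:6], letters[1:6]], k1$K)
})

test_that("too few markers after MAF filtering is an error", {
  geno <- matrix(0L, nrow = 500, ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_error(centered_ibs_kinship(make_table(geno), min_markers = 1000),
               "markers")
})

simulate_po_pairs <- function(n_pairs, n_markers, seed) {
  set.seed(seed)
  p <- runif(n_markers, 0.05, 0.5)
  cols <- list()
  for (i in seq_len(n_pairs)) {
    parent <- rbinom(n_markers, 2, p)
    other <- rbinom(n_markers, 2, p)  # unrelated co-parent
    child <- rbinom(n_markers, 1, parent / 2) + rbinom(n_markers, 1, other / 2)
    cols[[paste0("P", i)]] <- parent
    cols[[paste0("C", i)]] <- child
    cols[[paste0("U", i)]] <- rbinom(n_markers, 2, p)  # unrelated
  }
  do.call(cbind, cols)
}

test_that("parent-offspring pairs estimate near 0.5 and unrelated near 0", {
  n_pairs <- 100
  geno <- simulate_po_pairs(n_pairs, 5000, seed = 17)
  kin <- centered_ibs_kinship(make_table(geno), min_markers = 1000)
  po <- vapply(seq_len(n_pairs), function(i) {
    kin$K[paste0("P", i), paste0("C", i)]
  }, numeric(1))
  un <- vapply(seq_len(n_pairs), function(i) {
    kin$K[paste0("P", i), paste0("U", i)]
  }, numeric(1))
  # mean within 3 standard errors of the replicate spread
  expect_lt(abs(mean(po) - 0.5), 3 * sd(po) / sqrt(n_pairs) + 0.02)
  expect_lt(abs(mean(un)), 3 * sd(un) / sqrt(n_pairs) + 0.02)
})

test_that("classify_pair bands behave and sib pairs classify first degree", {
  expect_equal(classify_pair(0.5), "first_degree")
  expect_equal(classify_pair(0.0), "unrelated")
  expect_equal(classify_pair(c(0.95, 0.25)), c("duplicate_mz", "second_degree"))

  set.seed(23)
  n_pairs <- 200
  n_markers <- 5000
  p <- runif(n_markers, 0.05, 0.5)
  cols <- list()
  for (i in seq_len(n_pairs)) {
    f <- rbinom(n_markers, 2, p); m <- rbinom(n_markers, 2, p)
    s1 <- rbinom(n_markers, 1, f / 2) + rbinom(n_markers, 1, m / 2)
    s2 <- rbinom(n_markers, 1, f / 2) + rbinom(n_markers, 1, m / 2)
    cols[[paste0("A", i)]] <- s1
    cols[[paste0("B", i)]] <- s2
  }
  kin <- centered_ibs_kinship(make_table(do.call(cbind, cols)),
                              min_markers = 1000)
  calls <- vapply(seq_len(n_pairs), function(i) {
    classify_pair(kin$K[paste0("A", i), paste0("B", i)])
  }, character(1))
  expect_gte(mean(calls == "first_degree"), 0.95)
})

test_that("family assignment checks flag planted errors and pass clean cohorts", {
  sim <- simulate_cohort(cohort_config(n_background_snps = 5000, n_x_snps = 50,
                                       n_decoy_variants = 0), seed = 3)
  aut <- sim$table$variants$chrom != "X"
  bg <- famseg:::new_variant_table(sim$table$variants[aut, ],
                                   sim$table$geno[aut, ], sim$table$sample_ids)
  kin <- centered_ibs_kinship(bg)
  expect_equal(nrow(verify_family_assignment(sim$cohort, kin)), 0)

  # plant an unrelated individual
  set.seed(44)
  p <- rowMeans(bg$geno) / 2
  bg2 <- bg
  bg2$geno[, "FAM05_C1"] <- rbinom(nrow(bg2$geno), 2, p)
  f <- verify_family_assignment(sim$cohort, centered_ibs_kinship(bg2))
  expect_true("FAM05_C1" %in% f$member_id[f$kind == "unrelated_to_family"])
  expect_false(any(setdiff(unique(f$member_id), "FAM05_C1") %in%
                   f$member_id[f$kind == "unrelated_to_family"]))

  # swap two children between families
  bg3 <- bg
  tmp <- bg3$geno[, "FAM02_C1"]
  bg3$geno[, "FAM02_C1"] <- bg3$geno[, "FAM07_C1"]
  bg3$geno[, "FAM07_C1"] <- tmp
  f3 <- verify_family_assignment(sim$cohort, centered_ibs_kinship(bg3))
  bm <- f3[f3$kind == "better_family_match", ]
  expect_true(all(c("FAM02_C1", "FAM07_C1") %in% bm$member_id))
  expect_true(any(grepl("FAM07", bm$detail[bm$member_id == "FAM02_C1"])))
  expect_true(any(grepl("FAM02", bm$detail[bm$member_id == "FAM07_C1"])))
})

test_that("sex inference recovers hemizygous males and HWE females", {
  # 500 X markers, zero heterozygous calls: male
  geno <- matrix(rep(c(0L, 2L), 250), ncol = 1, dimnames = list(NULL, "m1"))
  tab <- make_table(geno, chrom = "X")
  sx <- infer_sex(tab)
  expect_equal(sx$inferred, "male")
  expect_equal(sx$x_het_rate, 0)

  # simulated females at p ~ U(0.1, 0.5): expected het rate >> 0.20
  set.seed(9)
  n_rep <- 100
  p <- runif(400, 0.1, 0.5)
  females <- sapply(seq_len(n_rep), function(i) rbinom(400, 2, p))
  colnames(females) <- paste0("f", seq_len(n_rep))
  calls <- infer_sex(make_table(females, chrom = "X"))
  expect_gte(mean(calls$inferred == "female"), 0.99)

  # dead zone: 12 het of 100 is ambiguous (and below default marker minimum)
  amb <- matrix(c(rep(1L, 12), rep(0L, 88)), ncol = 1,
                dimnames = list(NULL, "a1"))
  sxa <- infer_sex(make_table(amb, chrom = "X"), min_markers = 50)
  expect_equal(sxa$inferred, "ambiguous")

  expect_error(infer_sex(make_table(geno, chrom = "3")), "X-chromosome")
})

test_that("ledger sexes are recovered on generated cohorts", {
  sim <- simulate_cohort(cohort_config(n_background_snps = 50, n_x_snps = 500,
                                       n_decoy_variants = 0), seed = 21)
  sx <- infer_sex(sim$table)
  truth <- sim$ledger$true_sexes[sx$sample_id]
  expect_gte(mean(sx$inferred == truth), 0.99)
})
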