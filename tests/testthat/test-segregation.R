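# Segregation test: closed-form limits, agreement of the two exact paths
# (full enumeration vs peeling), behaviour in q, marginalisation, and
# convergence of gene-dropping to the exact joint probability.

test_that("closed-form limits hold exactly", {
  fam <- nuclear_family("F1", n_aff = 2, n_un = 1)
  # q = 0 with an affected member: no alt allele can enter the pedigree
  expect_equal(family_segregation_prob(fam, 0), 0)
  # q = 0 with only unaffected constraints: vacuously certain
  un <- nuclear_family("F2", n_aff = 0, n_un = 2)
  expect_equal(family_segregation_prob(un, 0), 1)
  # single affected founder at q: HWE carrier probability 2q - q^2
  single <- data.frame(member_id = "A", father_id = NA_character_,
                       mother_id = NA_character_, phenotype = "affected",
                       stringsAsFactors = FALSE)
  expect_equal(family_segregation_prob(single, 0.1), 2 * 0.1 - 0.1^2)
  expect_equal(family_segregation_prob(single, 0.5), 0.75)
  expect_error(family_segregation_prob(single, -0.1), "q must")
  expect_error(family_segregation_prob(single, 1.5), "q must")
})

test_that("enumeration and peeling agree to 1e-12 on random pedigrees", {
  set.seed(15)
  for (i in 1:25) {
    fam <- random_pedigree(max_members = 12)
    q <- runif(1, 0.005, 0.3)
    p_enum <- family_segregation_prob(fam, q, method = "enumerate")
    p_peel <- family_segregation_prob(fam, q, method = "peeling")
    expect_equal(p_peel, p_enum, tolerance = 1e-12)
  }
})

test_that("a nuclear family matches the exhaustive configuration sum", {
  # independent oracle: direct sum over all 3^5 configurations written out
  # without the package's enumeration helper
  fam <- nuclear_family("F1", n_aff = 2, n_un = 1,
                        parent_pheno = c("unknown", "unknown"))
  q <- 0.01
  prior <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  trans <- function(gc, gf, gm) {
    pf <- gf / 2; pm <- gm / 2
    c((1 - pf) * (1 - pm), pf * (1 - pm) + (1 - pf) * pm, pf * pm)[gc + 1]
  }
  total <- 0
  for (gf in 0:2) for (gm in 0:2) for (c1 in 0:2) for (c2 in 0:2) for (c3 in 0:2) {
    if (c1 >= 1 && c2 >= 1 && c3 == 0) {
      total <- total + prior[gf + 1] * prior[gm + 1] *
        trans(c1, gf, gm) * trans(c2, gf, gm) * trans(c3, gf, gm)
    }
  }
  expect_equal(family_segregation_prob(fam, q), total, tolerance = 1e-14)
})

test_that("a child listing one parent marginalises an implicit founder", {
  # oracle: child allele from the absent parent is a population draw
  fam <- data.frame(
    member_id = c("M", "C"), father_id = c(NA, NA_character_),
    mother_id = c(NA, "M"), phenotype = c("unknown", "affected"),
    stringsAsFactors = FALSE
  )
  fam$father_id[2] <- NA  # only mother listed
  q <- 0.05
  prior <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  p_oracle <- sum(vapply(0:2, function(gm) {
    pm <- gm / 2
    p_carry <- 1 - (1 - pm) * (1 - q)  # one maternal draw, one population draw
    prior[gm + 1] * p_carry
  }, numeric(1)))
  expect_equal(family_segregation_prob(fam, q), p_oracle, tolerance = 1e-14)
})

test_that("probability is monotone in q for one-sided constraints", {
  qs <- seq(0.01, 0.5, length.out = 8)
  aff <- nuclear_family("F1", n_aff = 3, n_un = 0)
  p_aff <- vapply(qs, function(q) family_segregation_prob(aff, q), numeric(1))
  expect_true(all(diff(p_aff) > 0))
  un <- nuclear_family("F2", n_aff = 0, n_un = 3)
  p_un <- vapply(qs, function(q) family_segregation_prob(un, q), numeric(1))
  expect_true(all(diff(p_un) < 0))
})

test_that("adding an unconstrained leaf never changes the probability", {
  set.seed(77)
  for (i in 1:8) {
    fam <- random_pedigree(max_members = 9)
    q <- runif(1, 0.01, 0.3)
    p0 <- family_segregation_prob(fam, q)
    extra <- data.frame(
      family_id = fam$family_id[1], member_id = "EXTRA_LEAF",
      father_id = fam$member_id[1], mother_id = fam$member_id[2],
      sex = "unknown", phenotype = "unknown", has_genotype = TRUE,
      stringsAsFactors = FALSE
    )
    p1 <- family_segregation_prob(rbind(fam, extra), q)
    expect_equal(p1, p0, tolerance = 1e-12)
  }
})

test_that("observed-genotype clamping overrides phenotype constraints", {
  fam <- nuclear_family("F1", n_aff = 2, n_un = 1)
  q <- 0.1
  p_free <- family_segregation_prob(fam, q)
  # clamping an affected child to het shrinks the event to that configuration
  p_clamp <- family_segregation_prob(fam, q, observed = c(F1_C1 = 1L))
  expect_lt(p_clamp, p_free)
  # clamping an unaffected child to 0 is implied by its constraint already
  p_same <- family_segregation_prob(fam, q, observed = c(F1_C3 = 0L))
  expect_equal(p_same, p_free, tolerance = 1e-12)
})

test_that("conditioning on variant presence rescales by the founder carrier mass", {
  fam <- nuclear_family("F1", n_aff = 2, n_un = 1)
  q <- 0.05
  p <- family_segregation_prob(fam, q)
  pc <- family_segregation_prob(fam, q, condition_on_presence = TRUE)
  expect_equal(pc, p / (1 - (1 - q)^4), tolerance = 1e-12)
  un <- nuclear_family("F2", n_aff = 0, n_un = 1)
  expect_error(family_segregation_prob(un, q, condition_on_presence = TRUE),
               "affected")
})

test_that("joint probability is the product and is order invariant", {
  expect_equal(joint_segregation_prob(c(f1 = 0.0012, f2 = 0.0006)), 7.2e-7)
  expect_equal(joint_segregation_prob(0.25), 0.25)
  p <- c(0.1, 0.02, 0.5)
  expect_equal(joint_segregation_prob(p), joint_segregation_prob(rev(p)))
  expect_lte(joint_segregation_prob(p), min(p))
  expect_error(joint_segregation_prob(numeric(0)), "no per-family")
  expect_error(joint_segregation_prob(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("gene dropping converges to the exact joint probability", {
  set.seed(55)
  fams <- list(nuclear_family("F1", n_aff = 2, n_un = 1),
               nuclear_family("F2", n_aff = 2, n_un = 2))
  for (q in c(0.05, 0.1)) {
    exact <- joint_segregation_prob(
      vapply(fams, family_segregation_prob, numeric(1), q = q))
    n_sims <- 1e6
    est <- gene_drop_p(fams, q, n_sims, seed = round(q * 1000))
    tol <- 3 * sqrt(exact * (1 - exact) / n_sims)
    expect_lt(abs(est - exact), tol + 2 / n_sims)
  }
})

test_that("gene dropping hits the estimator floor at q = 0 and is deterministic", {
  fam <- nuclear_family("F1", n_aff = 2, n_un = 1)
  n <- 5000
  expect_equal(gene_drop_p(list(fam), 0, n, seed = 1), 1 / (n + 1))
  expect_equal(gene_drop_p(list(fam), 0.1, n, seed = 9),
               gene_drop_p(list(fam), 0.1, n, seed = 9))
})

test_that("cycles are rejected", {
  loop <- data.frame(member_id = c("A", "B"), father_id = c("B", "A"),
                     mother_id = c(NA, NA), phenotype = "unknown",
                     stringsAsFactors = FALSE)
  expect_error(family_segregation_prob(loop, 0.1), "cycle|not in family")
})

test_that("run_segregation reports per-family, joint and simulated values", {
  sim <- simulate_cohort(cohort_config(n_background_snps = 20, n_x_snps = 5,
                                       n_decoy_variants = 0), seed = 2)
  fams <- sim$ledger$causal_families
  res <- run_segregation(sim$cohort, q = 0.05, families = fams,
                         n_sims = 2e5, seed = 4)
  expect_named(res$per_family, fams)
  expect_equal(res$joint, prod(res$per_family))
  tol <- 3 * sqrt(res$joint * (1 - res$joint) / res$n_sims)
  expect_lt(abs(res$sim_p - res$joint), tol + 2 / res$n_sims)
})
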