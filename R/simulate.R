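# Synthetic cohort generator emulating an affected-sib-pair rare-variant
# study design: nuclear families ascertained for >=2 affected and >=1
# unaffected siblings, with one or both parents sampled; a rare heterozygous
# loss-of-function variant planted in a configurable number of families; a
# panel of common autosomal background markers and X markers for kinship and
# sex inference; and decoy variants exercising each arm of the candidate
# filter. Every run returns a ground-truth ledger describing exactly what
# was emitted.

#' Synthetic cohort configuration
#'
#' Defaults mirror the emulated study design: 20 families, 2-3 affected and
#' 1-2 unaffected siblings each, 8 families with both parents sampled and
#' the rest with one, a causal variant at population frequency 0.00076
#' forced into 2 families, complete penetrance, no phenocopies.
#'
#' @param n_families Number of families.
#' @param affected_sibs_range,unaffected_sibs_range Integer `c(min, max)`
#'   per-family sibling counts.
#' @param families_with_both_parents Families with both parents genotyped;
#'   the rest have one ungenotyped parent.
#' @param causal_q Population alternate-allele frequency of the causal
#'   variant.
#' @param n_causal_families Families the causal variant is forced into
#'   (rejection-sampled to respect ascertainment); `0` draws causal founder
#'   genotypes at Hardy-Weinberg proportions instead (frequency-calibration
#'   mode — at realistic `causal_q` the variant is almost always absent).
#' @param penetrance P(affected | carrier) within causal families.
#' @param phenocopy_rate P(affected | non-carrier) within causal families.
#' @param n_background_snps Autosomal background markers (MAF uniform on
#'   `background_maf`).
#' @param background_maf `c(min, max)` background allele-frequency range.
#' @param n_x_snps X-chromosome markers (males emitted hemizygous as
#'   homozygous diploid calls).
#' @param n_decoy_variants Decoy variants split across the three filter arms
#'   (single-family hits, unaffected-carrier hits, wrong-class hits).
#' @param max_attempts Rejection-sampling cap per causal family.
#' @return A config list of class `cohort_config`.
#' @export
cohort_config <- function(n_families = 20,
                          affected_sibs_range = c(2, 3),
                          unaffected_sibs_range = c(1, 2),
                          families_with_both_parents = 8,
                          causal_q = 0.00076,
                          n_causal_families = 2,
                          penetrance = 1.0,
                          phenocopy_rate = 0.0,
                          n_background_snps = 5000,
                          background_maf = c(0.05, 0.5),
                          n_x_snps = 500,
                          n_decoy_variants = 30,
                          max_attempts = 1000) {
  stopifnot(families_with_both_parents <= n_families,
            n_causal_families <= n_families,
            penetrance >= 0, penetrance <= 1,
            phenocopy_rate >= 0, phenocopy_rate <= 1,
            causal_q >= 0, causal_q <= 1)
  structure(as.list(environment()), class = "cohort_config")
}

sample_range <- function(rng) {
  if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
}

# Pedigree structure only (no genotypes): members of every family, true
# sexes, which parent (if any) is ungenotyped.
simulate_structure <- function(cfg) {
  if (cfg$n_families < 1) stop("n_families must be at least 1")
  rows <- list()
  for (f in seq_len(cfg$n_families)) {
    fid <- sprintf("FAM%02d", f)
    n_aff <- sample_range(cfg$affected_sibs_range)
    n_un <- sample_range(cfg$unaffected_sibs_range)
    n_kids <- n_aff + n_un
    father <- paste0(fid, "_F")
    mother <- paste0(fid, "_M")
    both <- f <= cfg$families_with_both_parents
    missing_parent <- if (both) NA_character_ else sample(c(father, mother), 1)
    kid_ids <- sprintf("%s_C%d", fid, seq_len(n_kids))
    kid_sex <- sample(c("male", "female"), n_kids, replace = TRUE)
    rows[[f]] <- data.frame(
      family_id = fid,
      member_id = c(father, mother, kid_ids),
      father_id = c(NA, NA, rep(father, n_kids)),
      mother_id = c(NA, NA, rep(mother, n_kids)),
      sex = c("male", "female", kid_sex),
      phenotype = "unknown",
      has_genotype = c(!identical(missing_parent, father),
                       !identical(missing_parent, mother),
                       rep(TRUE, n_kids)),
      n_aff_target = n_aff,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Simulate a synthetic family cohort
#'
#' Founder genotypes are Hardy-Weinberg draws per marker and children follow
#' Mendelian transmission. In causal families one parent is a heterozygous
#' carrier; sibling transmissions are rejection-sampled until the family
#' meets the ascertainment constraints (at least two affected and one
#' unaffected sibling) with phenotypes assigned from carrier status via
#' `penetrance`/`phenocopy_rate`. Non-causal families receive their affected
#' labels by design (disease of other origin), matching a study in which the
#' modeled variant explains a minority of ascertained families. Carrier
#' parents are labelled `other_diagnosis` (unconstrained downstream);
#' non-carrier parents `unaffected`.
#'
#' @param cfg A [cohort_config()].
#' @param seed Integer seed; the run is fully reproducible given (cfg, seed).
#' @return List with `cohort`, `table` (variant table over genotyped
#'   members), `annotations` (data.frame) and `ledger` (ground truth: causal
#'   variant, carriers, causal families, decoy placements, true sexes).
#' @export
simulate_cohort <- function(cfg = cohort_config(), seed = 1) {
  set.seed(seed)
  members <- simulate_structure(cfg)
  causal_fams <- if (cfg$n_causal_families > 0) {
    sort(sample(unique(members$family_id), cfg$n_causal_families))
  } else character(0)

  causal <- data.frame(chrom = "7", pos = 5000000L, ref = "TCA", alt = "T",
                       rsid = "rs0000001", stringsAsFactors = FALSE)
  causal_dos <- stats::setNames(rep(0L, nrow(members)), members$member_id)
  carrier_parent <- character(0)

  for (fid in unique(members$family_id)) {
    fam <- members[members$family_id == fid, ]
    kids <- fam$member_id[!is.na(fam$father_id)]
    n_kids <- length(kids)
    n_aff_target <- fam$n_aff_target[1]
    if (fid %in% causal_fams) {
      cp <- sample(fam$member_id[is.na(fam$father_id)], 1)
      carrier_parent[fid] <- cp
      causal_dos[cp] <- 1L
      ok <- FALSE
      for (attempt in seq_len(cfg$max_attempts)) {
        kid_dos <- stats::rbinom(n_kids, 1, 0.5)
        aff <- ifelse(kid_dos >= 1,
                      stats::rbinom(n_kids, 1, cfg$penetrance),
                      stats::rbinom(n_kids, 1, cfg$phenocopy_rate)) == 1
        if (sum(aff) >= 2 && sum(!aff) >= 1) { ok <- TRUE; break }
      }
      if (!ok) {
        stop(sprintf("ascertainment unsatisfiable for family %s after %d attempts",
                     fid, cfg$max_attempts))
      }
      causal_dos[kids] <- kid_dos
      members$phenotype[match(kids, members$member_id)] <-
        ifelse(aff, "affected", "unaffected")
      members$phenotype[match(fam$member_id[is.na(fam$father_id)], members$member_id)] <-
        ifelse(fam$member_id[is.na(fam$father_id)] == cp, "other_diagnosis", "unaffected")
    } else {
      if (cfg$n_causal_families == 0 && cfg$causal_q > 0) {
        founders <- fam$member_id[is.na(fam$father_id)]
        causal_dos[founders] <- stats::rbinom(length(founders), 2, cfg$causal_q)
        for (k in kids) {
          i <- match(k, fam$member_id)
          gf <- causal_dos[fam$father_id[i]]; gm <- causal_dos[fam$mother_id[i]]
          causal_dos[k] <- stats::rbinom(1, 1, gf / 2) + stats::rbinom(1, 1, gm / 2)
        }
      }
      aff_kids <- kids[seq_len(min(n_aff_target, n_kids))]
      members$phenotype[match(kids, members$member_id)] <-
        ifelse(kids %in% aff_kids, "affected", "unaffected")
      members$phenotype[match(fam$member_id[is.na(fam$father_id)], members$member_id)] <-
        "unaffected"
    }
  }

  cohort <- new_cohort(members[, c("family_id", "member_id", "father_id",
                                   "mother_id", "sex", "phenotype",
                                   "has_genotype")])
  geno_ids <- sample_order(cohort)

  # background autosomal markers
  n_bg <- cfg$n_background_snps
  bg_p <- stats::runif(n_bg, cfg$background_maf[1], cfg$background_maf[2])
  bg_dos <- matrix(0L, nrow = n_bg, ncol = nrow(members),
                   dimnames = list(NULL, members$member_id))
  for (fid in unique(members$family_id)) {
    fam <- members[members$family_id == fid, ]
    founders_ix <- fam$member_id[is.na(fam$father_id)]
    for (id in founders_ix) bg_dos[, id] <- stats::rbinom(n_bg, 2, bg_p)
    kids <- fam$member_id[!is.na(fam$father_id)]
    for (k in kids) {
      i <- match(k, fam$member_id)
      gf <- bg_dos[, fam$father_id[i]]; gm <- bg_dos[, fam$mother_id[i]]
      bg_dos[, k] <- stats::rbinom(n_bg, 1, gf / 2) + stats::rbinom(n_bg, 1, gm / 2)
    }
  }
  bg_var <- data.frame(
    chrom = as.character(sample(1:22, n_bg, replace = TRUE)),
    pos = sort(sample.int(2.5e8, n_bg)),
    ref = sample(c("A", "C", "G", "T"), n_bg, replace = TRUE),
    alt = "N", rsid = NA_character_, stringsAsFactors = FALSE
  )
  bg_var$alt <- vapply(bg_var$ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1)
  }, character(1))

  # X markers: males hemizygous, emitted as homozygous diploid
  n_x <- cfg$n_x_snps
  x_p <- stats::runif(n_x, 0.1, 0.5)
  x_al <- matrix(0L, nrow = n_x, ncol = 2 * nrow(members))  # two allele slots
  colnames(x_al) <- paste(rep(members$member_id, each = 2), 1:2, sep = ".")
  slot <- function(id, a) paste(id, a, sep = ".")
  for (fid in unique(members$family_id)) {
    fam <- members[members$family_id == fid, ]
    for (id in fam$member_id[is.na(fam$father_id)]) {
      sx <- fam$sex[match(id, fam$member_id)]
      x_al[, slot(id, 1)] <- stats::rbinom(n_x, 1, x_p)
      x_al[, slot(id, 2)] <- if (sx == "male") x_al[, slot(id, 1)]
                             else stats::rbinom(n_x, 1, x_p)
    }
    for (k in fam$member_id[!is.na(fam$father_id)]) {
      i <- match(k, fam$member_id)
      fa <- fam$father_id[i]; mo <- fam$mother_id[i]
      mo_pick <- stats::rbinom(n_x, 1, 0.5)
      from_mo <- ifelse(mo_pick == 1, x_al[, slot(mo, 1)], x_al[, slot(mo, 2)])
      if (fam$sex[i] == "male") {
        x_al[, slot(k, 1)] <- from_mo
        x_al[, slot(k, 2)] <- from_mo
      } else {
        x_al[, slot(k, 1)] <- x_al[, slot(fa, 1)]  # father's single X
        x_al[, slot(k, 2)] <- from_mo
      }
    }
  }
  x_dos <- x_al[, slot(members$member_id, 1), drop = FALSE] +
           x_al[, slot(members$member_id, 2), drop = FALSE]
  colnames(x_dos) <- members$member_id
  x_var <- data.frame(
    chrom = "X", pos = sort(sample.int(1.5e8, n_x)),
    ref = sample(c("A", "C", "G", "T"), n_x, replace = TRUE),
    alt = "N", rsid = NA_character_, stringsAsFactors = FALSE
  )
  x_var$alt <- vapply(x_var$ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1)
  }, character(1))

  # decoy variants across the three filter arms
  decoys <- simulate_decoys(cfg, cohort)

  all_var <- rbind(causal, decoys$variants, bg_var, x_var)
  all_dos <- rbind(matrix(causal_dos, nrow = 1,
                          dimnames = list(NULL, members$member_id)),
                   decoys$dosage, t(t(bg_dos)), x_dos)
  table <- new_variant_table(all_var, all_dos[, geno_ids, drop = FALSE], geno_ids)

  annotations <- rbind(
    data.frame(chrom = causal$chrom, pos = causal$pos, ref = causal$ref,
               alt = causal$alt, gene = "GENE_CAUSAL",
               func_class = "frameshift_del",
               protein_change = "p.Ser2fsTer10", stringsAsFactors = FALSE),
    decoys$annotations
  )

  ledger <- list(
    config = cfg, seed = seed,
    causal_variant = causal,
    causal_families = causal_fams,
    carrier_parent = carrier_parent,
    carrier_ids = names(causal_dos)[causal_dos >= 1],
    decoys = decoys$ledger,
    true_sexes = stats::setNames(members$sex, members$member_id)
  )
  list(cohort = cohort, table = table, annotations = annotations, ledger = ledger)
}

simulate_decoys <- function(cfg, cohort) {
  m <- cohort$members
  n_dec <- cfg$n_decoy_variants
  empty <- list(
    variants = data.frame(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          rsid = character(0), stringsAsFactors = FALSE),
    dosage = matrix(0L, nrow = 0, ncol = nrow(m),
                    dimnames = list(NULL, m$member_id)),
    annotations = data.frame(chrom = character(0), pos = integer(0),
                             ref = character(0), alt = character(0),
                             gene = character(0), func_class = character(0),
                             protein_change = character(0),
                             stringsAsFactors = FALSE),
    ledger = data.frame(chrom = character(0), pos = integer(0),
                        type = character(0), func_class = character(0),
                        families = character(0), carriers = character(0),
                        stringsAsFactors = FALSE)
  )
  if (n_dec == 0) return(empty)
  types <- rep(c("single_family", "unaffected_carrier", "wrong_class"),
               length.out = n_dec)
  fams <- unique(m$family_id)
  vrows <- list(); drows <- list(); arows <- list(); lrows <- list()
  pos0 <- 10000000L
  kid_of <- function(fid, pheno) {
    fam <- m[m$family_id == fid, ]
    ids <- fam$member_id[!is.na(fam$father_id) & fam$phenotype == pheno &
                         fam$has_genotype]
    ids
  }
  for (d in seq_len(n_dec)) {
    dos <- stats::setNames(rep(0L, nrow(m)), m$member_id)
    type <- types[d]
    if (type == "single_family") {
      fid <- sample(fams, 1)
      aff <- kid_of(fid, "affected")
      carriers <- sample(aff, 1)
      dfams <- fid
      cls <- "frameshift_ins"
    } else if (type == "unaffected_carrier") {
      dfams <- sort(sample(fams, 2))
      carriers <- character(0)
      for (fid in dfams) {
        aff <- kid_of(fid, "affected"); un <- kid_of(fid, "unaffected")
        carriers <- c(carriers, sample(aff, 1), sample(un, 1))
      }
      cls <- "frameshift_del"
    } else {
      dfams <- sort(sample(fams, 2))
      carriers <- vapply(dfams, function(fid) sample(kid_of(fid, "affected"), 1),
                         character(1))
      cls <- sample(c("synonymous", "nonsynonymous"), 1)
    }
    dos[carriers] <- 1L
    vrows[[d]] <- data.frame(chrom = "9", pos = pos0 + d * 1000L, ref = "G",
                             alt = "GT", rsid = NA_character_,
                             stringsAsFactors = FALSE)
    drows[[d]] <- dos
    arows[[d]] <- data.frame(chrom = "9", pos = pos0 + d * 1000L, ref = "G",
                             alt = "GT", gene = sprintf("DECOY%02d", d),
                             func_class = cls,
                             protein_change = NA_character_,
                             stringsAsFactors = FALSE)
    lrows[[d]] <- data.frame(chrom = "9", pos = pos0 + d * 1000L, type = type,
                             func_class = cls,
                             families = paste(dfams, collapse = ","),
                             carriers = paste(carriers, collapse = ","),
                             stringsAsFactors = FALSE)
  }
  list(variants = do.call(rbind, vrows),
       dosage = do.call(rbind, drows),
       annotations = do.call(rbind, arows),
       ledger = do.call(rbind, lrows))
}

#' Calibration check of the causal founder allele frequency
#'
#' Draws `reps` independent pre-ascertainment founder genotype sets at the
#' configured causal frequency and checks that the mean founder
#' alternate-allele frequency is within three binomial standard errors of
#' `causal_q`.
#'
#' @param cfg A [cohort_config()].
#' @param reps Number of replicate cohorts.
#' @param seed Integer seed.
#' @return List with `mean_freq`, `expected`, `se`, `z`, `within_3se`,
#'   `n_founder_alleles`.
#' @export
plant_frequency_check <- function(cfg = cohort_config(), reps = 200, seed = 1) {
  stopifnot(reps >= 1)
  set.seed(seed)
  q <- cfg$causal_q
  freqs <- numeric(reps)
  n_all <- NA_integer_
  for (r in seq_len(reps)) {
    members <- simulate_structure(cfg)
    founders <- members$member_id[is.na(members$father_id)]
    n_all <- 2L * length(founders)
    alt <- sum(stats::rbinom(length(founders), 2, q))
    freqs[r] <- alt / n_all
  }
  se <- sqrt(q * (1 - q) / (n_all * reps))
  m <- mean(freqs)
  z <- if (se > 0) (m - q) / se else 0
  list(mean_freq = m, expected = q, se = se, z = z,
       within_3se = abs(z) <= 3 || se == 0, n_founder_alleles = n_all)
}

#' Write the simulated cohort as plain-text files
#'
#' Emits `cohort.ped`, `genotypes.vcf`, `annotations.tsv` and
#' `ledger_decoys.tsv` under `dir`.
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_cohort_files <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_ped(sim$cohort, file.path(dir, "cohort.ped"))
  write_vcf(sim$table, file.path(dir, "genotypes.vcf"))
  utils::write.table(sim$annotations, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$ledger$decoys, file.path(dir, "ledger_decoys.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
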