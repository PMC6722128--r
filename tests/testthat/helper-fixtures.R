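# Shared fixtures built in code: small pedigrees, tiny VCF/PED text files,
# and random-pedigree generators for property-style tests.

nuclear_family <- function(fid = "F1", n_aff = 2, n_un = 1,
                           parent_pheno = c("unknown", "unknown")) {
  kids <- sprintf("%s_C%d", fid, seq_len(n_aff + n_un))
  data.frame(
    family_id = fid,
    member_id = c(paste0(fid, "_F"), paste0(fid, "_M"), kids),
    father_id = c(NA, NA, rep(paste0(fid, "_F"), length(kids))),
    mother_id = c(NA, NA, rep(paste0(fid, "_M"), length(kids))),
    sex = c("male", "female", rep("unknown", length(kids))),
    phenotype = c(parent_pheno,
                  rep("affected", n_aff), rep("unaffected", n_un)),
    has_genotype = TRUE,
    stringsAsFactors = FALSE
  )
}

# random acyclic pedigree: a chain of nuclear units, <= max_members members
random_pedigree <- function(max_members = 12, p_aff = 0.3, p_un = 0.3) {
  n_kids1 <- sample(1:3, 1)
  fam <- nuclear_family("R", n_aff = 0, n_un = 0)
  fam <- fam[1:2, ]
  kids <- sprintf("R_C%d", seq_len(n_kids1))
  fam <- rbind(fam, data.frame(
    family_id = "R", member_id = kids, father_id = "R_F", mother_id = "R_M",
    sex = "unknown", phenotype = "unknown", has_genotype = TRUE,
    stringsAsFactors = FALSE))
  # optionally extend one child into a second generation
  if (nrow(fam) + 3 <= max_members && stats::runif(1) < 0.5) {
    spouse <- "R_S1"
    gkids <- sprintf("R_G%d", seq_len(sample(1:2, 1)))
    fam <- rbind(fam,
      data.frame(family_id = "R", member_id = spouse, father_id = NA,
                 mother_id = NA, sex = "female", phenotype = "unknown",
                 has_genotype = TRUE, stringsAsFactors = FALSE),
      data.frame(family_id = "R", member_id = gkids, father_id = kids[1],
                 mother_id = spouse, sex = "unknown", phenotype = "unknown",
                 has_genotype = TRUE, stringsAsFactors = FALSE))
  }
  u <- stats::runif(nrow(fam))
  fam$phenotype <- ifelse(u < p_aff, "affected",
                   ifelse(u < p_aff + p_un, "unaffected",
                   sample(c("other_diagnosis", "unknown"), nrow(fam), TRUE)))
  fam
}

# build a variant_table directly from a dosage matrix
make_table <- function(geno, chrom = "1", pos = NULL) {
  n <- nrow(geno)
  variants <- data.frame(
    chrom = rep(chrom, length.out = n),
    pos = if (is.null(pos)) seq_len(n) * 100L else pos,
    ref = "A", alt = "T", rsid = NA_character_, stringsAsFactors = FALSE
  )
  famseg:::new_variant_table(variants, geno, colnames(geno))
}

write_mini_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}
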