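# Allele-count association of a rare variant against reference populations.
#
# Two counting scenarios reflect the family design: related carriers share
# transmissions, so each family contributes one representative individual.
# Scenario "case" pools one affected carrier per family over a denominator of
# 2 alleles/family; scenario "carrier" treats the two parents as the at-risk
# pool, 4 alleles/family, counting one (possibly obligate) carrier parent.
# Significance comes from the Yates-corrected chi-square and from a
# fixed-margins Monte-Carlo null with an exact hypergeometric counterpart.

#' Effective allele counts for a scenario
#'
#' `"case"`: denominator 2 alleles per family; for each family with at least
#' one affected carrier of the variant, the dosage of one representative
#' affected carrier (first in pedigree order; 1 if heterozygous, 2 if
#' homozygous) is added. `"carrier"`: denominator 4 alleles per family (both
#' parental genomes form the at-risk pool whether or not both parents were
#' sampled); for each family where the variant segregates, the dosage of one
#' carrier parent is added — a genotyped carrier parent's observed dosage,
#' or 1 for an obligate carrier parent inferred from a carrier child.
#'
#' @param cohort A cohort object.
#' @param table A variant table.
#' @param chrom,pos,ref,alt Variant coordinates.
#' @param scenario `"case"` or `"carrier"`.
#' @return List with `alt_alleles` and `total_alleles`.
#' @export
scenario_allele_counts <- function(cohort, table, chrom, pos, ref, alt,
                                   scenario = c("case", "carrier")) {
  scenario <- match.arg(scenario)
  i <- variant_index(table, chrom, pos, ref, alt)
  dos <- table$geno[i, ]
  fams <- family_ids(cohort)
  n_fam <- length(fams)
  alt_count <- 0L
  for (fid in fams) {
    fam <- family_members(cohort, fid)
    kids <- fam[!is.na(fam$father_id) | !is.na(fam$mother_id), , drop = FALSE]
    kid_ids <- intersect(kids$member_id, names(dos))
    kid_dos <- dos[kid_ids]
    aff_ids <- kid_ids[kids$phenotype[match(kid_ids, kids$member_id)] == "affected"]
    aff_carriers <- aff_ids[!is.na(dos[aff_ids]) & dos[aff_ids] >= 1]
    if (scenario == "case") {
      if (length(aff_carriers) > 0) {
        alt_count <- alt_count + dos[[aff_carriers[1]]]
      }
    } else {
      parent_ids <- unique(c(kids$father_id, kids$mother_id))
      parent_ids <- parent_ids[!is.na(parent_ids)]
      gpar <- intersect(parent_ids, names(dos))
      gpar_carriers <- gpar[!is.na(dos[gpar]) & dos[gpar] >= 1]
      if (length(gpar_carriers) > 0) {
        alt_count <- alt_count + dos[[gpar_carriers[1]]]
      } else {
        any_kid_carrier <- any(!is.na(kid_dos) & kid_dos >= 1)
        if (any_kid_carrier) alt_count <- alt_count + 1L  # obligate carrier parent
      }
    }
  }
  total <- if (scenario == "case") 2L * n_fam else 4L * n_fam
  list(alt_alleles = as.integer(alt_count), total_alleles = total)
}

#' Build a 2x2 allele-count contingency table
#'
#' Rows: study group, reference population. Columns: alternate alleles,
#' other alleles.
#'
#' @param study_alt,study_total Study-group alternate and total allele counts.
#' @param ref_alt,ref_total Reference-population counts.
#' @return Integer 2x2 matrix with dimnames.
#' @export
allele_table <- function(study_alt, study_total, ref_alt, ref_total) {
  stopifnot(study_alt <= study_total, ref_alt <= ref_total,
            study_alt >= 0, ref_alt >= 0)
  matrix(c(study_alt, ref_alt, study_total - study_alt, ref_total - ref_alt),
         nrow = 2, dimnames = list(c("study", "reference"), c("alt", "other")))
}

pearson_expected <- function(O) {
  outer(rowSums(O), colSums(O)) / sum(O)
}

#' Yates-corrected chi-square test for a 2x2 table
#'
#' Statistic `sum((|O - E| - c)^2 / E)` with the continuity correction
#' `c = min(0.5, |O - E|)` (in a 2x2 table all four `|O - E|` are equal, so
#' the clamp applies uniformly and the statistic never goes negative).
#' The upper tail is evaluated on the log scale, resolving p-values far
#' below 1e-80.
#'
#' @param O A 2x2 matrix of observed counts with strictly positive margins.
#' @return List with `stat`, `p`, `expected`.
#' @export
yates_chisq_2x2 <- function(O) {
  stopifnot(is.matrix(O), all(dim(O) == 2), all(O >= 0))
  if (any(rowSums(O) == 0) || any(colSums(O) == 0)) {
    stop("chi-square test undefined: zero margin")
  }
  E <- pearson_expected(O)
  d <- abs(O - E)
  corr <- pmin(0.5, d)
  stat <- sum((d - corr)^2 / E)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(stat = stat, p = p, expected = E)
}

pearson_stat_2x2 <- function(O) {
  E <- pearson_expected(O)
  sum((O - E)^2 / E)
}

# Pearson statistic for every value of the (1,1) cell under fixed margins.
pearson_stat_by_x11 <- function(x11, r1, r2, c1) {
  N <- r1 + r2
  c2 <- N - c1
  E <- outer(c(r1, r2), c(c1, c2)) / N
  x12 <- r1 - x11
  x21 <- c1 - x11
  x22 <- r2 - x21
  (x11 - E[1, 1])^2 / E[1, 1] + (x12 - E[1, 2])^2 / E[1, 2] +
    (x21 - E[2, 1])^2 / E[2, 1] + (x22 - E[2, 2])^2 / E[2, 2]
}

#' Monte-Carlo simulated p-value with both margins fixed
#'
#' Draws `B` tables with the observed row and column totals (for a 2x2 the
#' (1,1) cell is hypergeometric), computes the uncorrected Pearson statistic
#' for each, and returns `(1 + b) / (B + 1)` where `b` counts simulated
#' statistics at least as large as the observed one.
#'
#' @param O A 2x2 matrix with positive margins.
#' @param B Number of replicates.
#' @param seed Optional integer seed for reproducibility.
#' @return The simulated p-value.
#' @export
mc_simulated_p <- function(O, B = 1e6, seed = NULL) {
  stopifnot(is.matrix(O), all(dim(O) == 2), B >= 1)
  if (any(rowSums(O) == 0) || any(colSums(O) == 0)) {
    stop("simulation undefined: zero margin")
  }
  if (!is.null(seed)) set.seed(seed)
  r1 <- sum(O[1, ]); r2 <- sum(O[2, ]); c1 <- sum(O[, 1])
  obs <- pearson_stat_2x2(O)
  x11 <- stats::rhyper(B, r1, r2, c1)
  stats_sim <- pearson_stat_by_x11(x11, r1, r2, c1)
  b <- sum(stats_sim >= obs - 1e-9)
  (1 + b) / (B + 1)
}

#' Exact fixed-margins tail probability for a 2x2 table
#'
#' Enumerates every table with the observed margins and sums the
#' hypergeometric probabilities of those whose Pearson statistic is at least
#' the observed one. This is the `B -> Inf` limit of [mc_simulated_p()].
#'
#' @param O A 2x2 matrix with positive margins.
#' @return The exact tail probability.
#' @export
exact_fixed_margins_p <- function(O) {
  stopifnot(is.matrix(O), all(dim(O) == 2))
  if (any(rowSums(O) == 0) || any(colSums(O) == 0)) {
    stop("exact test undefined: zero margin")
  }
  r1 <- sum(O[1, ]); r2 <- sum(O[2, ]); c1 <- sum(O[, 1])
  obs <- pearson_stat_2x2(O)
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(ks, r1, r2, c1)
  stats_all <- pearson_stat_by_x11(ks, r1, r2, c1)
  min(1, sum(probs[stats_all >= obs - 1e-9]))
}

#' Read a reference-population allele-count table
#'
#' Tab-delimited with columns `name`, `alt_alleles`, `total_alleles`.
#'
#' @param path Path to the TSV.
#' @return Data.frame with an added `freq` column.
#' @export
read_reference_populations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "alt_alleles", "total_alleles")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("reference table missing column(s): ", paste(miss, collapse = ", "))
  }
  stopifnot(all(df$alt_alleles >= 0), all(df$alt_alleles <= df$total_alleles))
  df$freq <- df$alt_alleles / df$total_alleles
  df
}

#' Scenario-by-reference association grid
#'
#' For each reference population and each counting scenario, builds the 2x2
#' allele table and reports the Yates-corrected chi-square p-value and the
#' fixed-margins Monte-Carlo simulated p-value (plus the exact tail).
#'
#' @param cohort A cohort object.
#' @param table A variant table.
#' @param chrom,pos,ref,alt Variant coordinates.
#' @param refs Reference data.frame (see [read_reference_populations()]).
#' @param B Monte-Carlo replicates (default 1e6); `B = 0` skips simulation.
#' @param seed Integer seed; each grid cell uses an offset of it.
#' @return Data.frame: one row per (reference, scenario) with counts,
#'   frequencies, `chisq_stat`, `chisq_p`, `mc_p`, `exact_p`.
#' @export
run_association <- function(cohort, table, chrom, pos, ref, alt, refs,
                            B = 1e6, seed = 1) {
  if (nrow(refs) == 0) {
    return(data.frame(reference = character(0), scenario = character(0),
                      study_alt = integer(0), study_total = integer(0),
                      ref_alt = integer(0), ref_total = integer(0),
                      ref_freq = numeric(0), chisq_stat = numeric(0),
                      chisq_p = numeric(0), mc_p = numeric(0),
                      exact_p = numeric(0), stringsAsFactors = FALSE))
  }
  counts <- list(
    carrier = scenario_allele_counts(cohort, table, chrom, pos, ref, alt, "carrier"),
    case = scenario_allele_counts(cohort, table, chrom, pos, ref, alt, "case")
  )
  rows <- list()
  cell <- 0L
  for (r in seq_len(nrow(refs))) {
    for (sc in c("carrier", "case")) {
      cell <- cell + 1L
      cn <- counts[[sc]]
      O <- allele_table(cn$alt_alleles, cn$total_alleles,
                        refs$alt_alleles[r], refs$total_alleles[r])
      ch <- yates_chisq_2x2(O)
      mp <- if (B > 0) mc_simulated_p(O, B = B, seed = seed + cell) else NA_real_
      ep <- exact_fixed_margins_p(O)
      rows[[cell]] <- data.frame(
        reference = refs$name[r], scenario = sc,
        study_alt = cn$alt_alleles, study_total = cn$total_alleles,
        ref_alt = refs$alt_alleles[r], ref_total = refs$total_alleles[r],
        ref_freq = refs$alt_alleles[r] / refs$total_alleles[r],
        chisq_stat = ch$stat, chisq_p = ch$p, mc_p = mp, exact_p = ep,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
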