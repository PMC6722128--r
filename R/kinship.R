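# Relatedness QC: centered-IBS kinship, pair classification, family
# assignment checks, and X-heterozygosity sex inference.
#
# The kinship estimator is the centered, frequency-standardised genotype
# cross-product (GRM-style): on this scale parent-offspring and full-sib
# pairs sit near 0.5, second-degree near 0.25 and unrelated pairs near 0.

#' Centered-IBS kinship matrix
#'
#' Computes `K[j,k] = mean_m (g_jm - 2 p_m)(g_km - 2 p_m) / (2 p_m (1 - p_m))`
#' over retained autosomal markers, pairwise-complete over non-missing calls.
#' Allele frequencies `p_m` are estimated in-cohort.
#'
#' @param table A variant table of background markers.
#' @param maf_floor Markers with estimated alt frequency below this (or above
#'   one minus this) are excluded; near-monomorphic markers carry no
#'   relatedness information and destabilise the standardisation.
#' @param min_markers Fewer retained markers than this is an error.
#' @param founders_only Optional character vector of sample ids (e.g.
#'   founders) used to estimate allele frequencies; default uses all samples.
#' @return A list of class `kinship_matrix` with elements `ids`, `K`
#'   (symmetric matrix) and `n_markers` (pairwise-complete counts matrix).
#' @export
centered_ibs_kinship <- function(table, maf_floor = 0.01, min_markers = 1000,
                                 founders_only = NULL) {
  G <- table$geno
  freq_src <- if (is.null(founders_only)) G else {
    G[, intersect(founders_only, colnames(G)), drop = FALSE]
  }
  p <- rowMeans(freq_src, na.rm = TRUE) / 2
  keep <- !is.na(p) & p >= maf_floor & p <= 1 - maf_floor
  if (sum(keep) < min_markers) {
    stop(sprintf("only %d markers retained after MAF filtering (minimum %d)",
                 sum(keep), min_markers))
  }
  G <- G[keep, , drop = FALSE]
  p <- p[keep]
  Z <- (G - 2 * p) / sqrt(2 * p * (1 - p))
  obs <- !is.na(Z)
  Z0 <- Z
  Z0[!obs] <- 0
  M <- crossprod(obs)           # pairwise-complete marker counts
  K <- crossprod(Z0) / M
  structure(list(ids = colnames(G), K = K, n_markers = M),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("<kinship_matrix> %d samples, median %d markers/pair\n",
              length(x$ids), stats::median(x$n_markers[upper.tri(x$n_markers)])))
  invisible(x)
}

#' Classify a relatedness estimate into a degree band
#'
#' Default bands on the coefficient-of-relationship scale:
#' \eqn{\ge 0.8} duplicate/monozygotic, \eqn{[0.35, 0.8)} first degree,
#' \eqn{[0.15, 0.35)} second degree, below 0.15 unrelated.
#'
#' @param k Numeric vector of relatedness estimates.
#' @param thresholds Numeric vector `c(duplicate, first, second)` of lower
#'   band boundaries.
#' @return Character vector: `duplicate_mz`, `first_degree`, `second_degree`
#'   or `unrelated`.
#' @export
classify_pair <- function(k, thresholds = c(duplicate = 0.8, first = 0.35,
                                            second = 0.15)) {
  ifelse(k >= thresholds[["duplicate"]], "duplicate_mz",
  ifelse(k >= thresholds[["first"]], "first_degree",
  ifelse(k >= thresholds[["second"]], "second_degree", "unrelated")))
}

#' Check family assignments against the kinship matrix
#'
#' Flags genotyped members that look misassigned:
#' * `unrelated_to_family` — maximum kinship with own-family members is below
#'   the unrelated threshold;
#' * `better_family_match` — mean kinship with some other family exceeds the
#'   own-family mean by `margin`, naming that family;
#' * `role_implausible` — a labelled parent-child pair with kinship below the
#'   first-degree band.
#'
#' @param cohort A cohort object.
#' @param kin A `kinship_matrix` covering all genotyped members.
#' @param unrelated_threshold Below this, a pair is treated as unrelated.
#' @param first_degree_threshold Parent-child pairs below this are flagged.
#' @param margin Required excess of the competing family's mean kinship.
#' @return A data.frame with columns `kind`, `member_id`, `family_id`,
#'   `detail`.
#' @export
verify_family_assignment <- function(cohort, kin,
                                     unrelated_threshold = 0.15,
                                     first_degree_threshold = 0.35,
                                     margin = 0.2) {
  m <- cohort$members[cohort$members$has_genotype, , drop = FALSE]
  absent <- setdiff(m$member_id, kin$ids)
  if (length(absent) > 0) {
    stop("kinship matrix does not cover: ", paste(absent, collapse = ", "))
  }
  K <- kin$K
  findings <- list()
  note <- function(kind, id, fam, detail) {
    findings[[length(findings) + 1]] <<- data.frame(
      kind = kind, member_id = id, family_id = fam, detail = detail,
      stringsAsFactors = FALSE
    )
  }
  fam_of <- stats::setNames(m$family_id, m$member_id)
  fams <- unique(m$family_id)
  for (i in seq_len(nrow(m))) {
    id <- m$member_id[i]; fam <- m$family_id[i]
    own <- setdiff(m$member_id[m$family_id == fam], id)
    if (length(own) == 0) next
    own_k <- K[id, own]
    if (max(own_k) < unrelated_threshold) {
      note("unrelated_to_family", id, fam,
           sprintf("max within-family kinship %.3f", max(own_k)))
    }
    own_mean <- mean(own_k)
    for (other in setdiff(fams, fam)) {
      oth <- m$member_id[m$family_id == other]
      oth_mean <- mean(K[id, oth])
      if (oth_mean > own_mean + margin) {
        note("better_family_match", id, fam,
             sprintf("mean kinship %.3f with family %s vs %.3f with own",
                     oth_mean, other, own_mean))
      }
    }
  }
  # labelled parent-child pairs
  for (i in seq_len(nrow(m))) {
    id <- m$member_id[i]
    for (p in stats::na.omit(c(m$father_id[i], m$mother_id[i]))) {
      if (p %in% kin$ids && K[id, p] < first_degree_threshold) {
        note("role_implausible", id, fam_of[[id]],
             sprintf("kinship with labelled parent %s is %.3f", p, K[id, p]))
      }
    }
  }
  if (length(findings) == 0) {
    return(data.frame(kind = character(0), member_id = character(0),
                      family_id = character(0), detail = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

#' Infer genetic sex from X-chromosome heterozygosity
#'
#' Males are hemizygous on the non-pseudoautosomal X, so their called
#' heterozygosity there is near zero; females show ordinary diploid
#' heterozygosity. Depth-based approaches need alignments; a dosage matrix
#' carries heterozygosity only.
#'
#' @param table A variant table containing X-chromosome markers.
#' @param x_chrom_label Chromosome label of the X (default `"X"`).
#' @param par_regions List of `c(start, end)` base-pair intervals to exclude
#'   (pseudoautosomal regions). Default none.
#' @param male_max,female_min Heterozygosity-rate thresholds; rates in
#'   between (or marker counts below `min_markers`) give `ambiguous`.
#' @param min_markers Minimum non-missing X calls per sample.
#' @return A data.frame with columns `sample_id`, `x_het_rate`, `n_markers`,
#'   `inferred`.
#' @export
infer_sex <- function(table, x_chrom_label = "X", par_regions = list(),
                      male_max = 0.05, female_min = 0.20, min_markers = 200) {
  on_x <- table$variants$chrom == x_chrom_label
  if (length(par_regions) > 0) {
    in_par <- rep(FALSE, nrow(table$variants))
    for (iv in par_regions) {
      in_par <- in_par | (on_x & table$variants$pos >= iv[1] &
                          table$variants$pos <= iv[2])
    }
    on_x <- on_x & !in_par
  }
  if (!any(on_x)) stop("no X-chromosome markers found (label '", x_chrom_label, "')")
  X <- table$geno[on_x, , drop = FALSE]
  n_obs <- colSums(!is.na(X))
  n_het <- colSums(X == 1, na.rm = TRUE)
  rate <- ifelse(n_obs > 0, n_het / n_obs, NA_real_)
  inferred <- ifelse(n_obs < min_markers | is.na(rate), "ambiguous",
              ifelse(rate < male_max, "male",
              ifelse(rate > female_min, "female", "ambiguous")))
  data.frame(sample_id = colnames(X), x_het_rate = rate, n_markers = n_obs,
             inferred = inferred, row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a kinship matrix as square tab-delimited text
#' @param kin A `kinship_matrix`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_kinship <- function(kin, path) {
  df <- as.data.frame(kin$K)
  utils::write.table(cbind(id = kin$ids, df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
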