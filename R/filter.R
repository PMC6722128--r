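# Candidate risk-variant selection: per-family affected-only retention among
# siblings, cross-family matching, functional class filtering, and
# parental-origin assessment.
#
# The retention quantifier is ANY affected sibling (not all): a variant
# carried by one of two affected siblings and by no unaffected sibling is
# retained. Parents are excluded from the sibling-level step; members with a
# diagnosis other than the index disease constrain neither side.

#' Variants private to affected siblings within one family
#'
#' Retains variants where at least one genotyped affected sibling carries the
#' alternate allele and no genotyped unaffected sibling does. Unaffected
#' siblings with missing calls are recorded; under `missing_policy =
#' "strict"` such variants are dropped, under `"lenient"` (default) they are
#' kept with the missing ids flagged.
#'
#' @param fam A family data.frame (e.g. [family_members()]).
#' @param table A variant table covering the family's genotyped members.
#' @param missing_policy `"lenient"` or `"strict"`.
#' @return A data.frame with one row per retained variant: variant key
#'   columns, `family_id`, comma-separated `affected_carriers` and
#'   `missing_unaffected`.
#' @export
family_private_variants <- function(fam, table, missing_policy = c("lenient", "strict")) {
  missing_policy <- match.arg(missing_policy)
  sibs <- unlist(sibling_sets(fam))
  pheno <- stats::setNames(fam$phenotype, fam$member_id)
  geno_ids <- intersect(fam$member_id[fam$has_genotype], table$sample_ids)
  aff <- intersect(sibs[pheno[sibs] == "affected"], geno_ids)
  unaff <- intersect(sibs[pheno[sibs] == "unaffected"], geno_ids)
  if (length(aff) == 0) {
    stop("family ", fam$family_id[1], " has no genotyped affected siblings")
  }
  A <- table$geno[, aff, drop = FALSE]
  aff_carries <- rowSums(A >= 1, na.rm = TRUE) > 0
  if (length(unaff) > 0) {
    U <- table$geno[, unaff, drop = FALSE]
    unaff_carries <- rowSums(U >= 1, na.rm = TRUE) > 0
    unaff_missing <- rowSums(is.na(U)) > 0
  } else {
    unaff_carries <- rep(FALSE, nrow(table$variants))
    unaff_missing <- rep(FALSE, nrow(table$variants))
  }
  keep <- aff_carries & !unaff_carries
  if (missing_policy == "strict") keep <- keep & !unaff_missing
  idx <- which(keep)
  out <- table$variants[idx, , drop = FALSE]
  out$family_id <- rep(fam$family_id[1], length(idx))
  out$affected_carriers <- vapply(idx, function(i) {
    d <- table$geno[i, aff]
    paste(aff[!is.na(d) & d >= 1], collapse = ",")
  }, character(1))
  out$missing_unaffected <- vapply(idx, function(i) {
    if (length(unaff) == 0) return("")
    d <- table$geno[i, unaff]
    paste(unaff[is.na(d)], collapse = ",")
  }, character(1))
  rownames(out) <- NULL
  out
}

#' Match family-private hits across families
#'
#' Groups identical variants — exact (chrom, pos, ref, alt) key, no fuzzy
#' indel matching — and keeps those seen in at least `min_families` families.
#'
#' @param hits A data.frame of per-family hits (rows from
#'   [family_private_variants()], possibly several families bound together).
#' @param min_families Minimum number of distinct families (default 2).
#' @return A data.frame with one row per candidate variant: key columns,
#'   `n_families` and comma-separated `families`.
#' @export
cross_family_match <- function(hits, min_families = 2) {
  if (nrow(hits) == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      rsid = character(0), n_families = integer(0),
                      families = character(0), stringsAsFactors = FALSE))
  }
  key <- paste(hits$chrom, hits$pos, hits$ref, hits$alt, sep = ":")
  groups <- split(seq_len(nrow(hits)), key)
  rows <- lapply(groups, function(ix) {
    fams <- sort(unique(hits$family_id[ix]))
    cbind(hits[ix[1], c("chrom", "pos", "ref", "alt", "rsid"), drop = FALSE],
          data.frame(n_families = length(fams),
                     families = paste(fams, collapse = ","),
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_families >= min_families, , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter candidates by functional class
#'
#' @param candidates Candidate data.frame from [cross_family_match()].
#' @param annotations Annotation data.frame from [read_annotations()] (or of
#'   the same shape).
#' @param keep_classes Character vector of retained classes. The default is
#'   the frameshift-only focus; `lof_classes()` and
#'   `c(lof_classes(), "nonsynonymous")` are the usual broader presets.
#' @return The candidates annotated with `gene`, `func_class`,
#'   `protein_change` and restricted to `keep_classes`. Unannotated
#'   candidates get class `other` (kept only if `other` is in
#'   `keep_classes`).
#' @export
filter_functional <- function(candidates, annotations,
                              keep_classes = c("frameshift_ins", "frameshift_del")) {
  if (nrow(candidates) == 0) {
    candidates$gene <- character(0)
    candidates$func_class <- character(0)
    candidates$protein_change <- character(0)
    return(candidates)
  }
  akey <- paste(annotations$chrom, annotations$pos, annotations$ref,
                annotations$alt, sep = ":")
  ckey <- paste(candidates$chrom, candidates$pos, candidates$ref,
                candidates$alt, sep = ":")
  ix <- match(ckey, akey)
  candidates$gene <- ifelse(is.na(ix), NA_character_, annotations$gene[ix])
  candidates$func_class <- ifelse(is.na(ix), "other", annotations$func_class[ix])
  candidates$protein_change <- ifelse(is.na(ix), NA_character_,
                                      annotations$protein_change[ix])
  out <- candidates[candidates$func_class %in% keep_classes, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assess parental origin of a candidate variant within a family
#'
#' `inherited` if at least one genotyped parent of a carrier child carries
#' the variant; `putative_de_novo` if both parents are genotyped with
#' non-missing, non-carrier calls; `undetermined` when any parent is
#' ungenotyped or missing (a variant recurring across independent families
#' may still be presumed inherited — that judgement stays with the analyst).
#'
#' @param fam A family data.frame.
#' @param table A variant table.
#' @param chrom,pos,ref,alt Variant coordinates.
#' @return One of `"inherited"`, `"putative_de_novo"`, `"undetermined"`.
#' @export
assess_parental_origin <- function(fam, table, chrom, pos, ref, alt) {
  i <- variant_index(table, chrom, pos, ref, alt)
  dos <- table$geno[i, ]
  kids <- fam[!is.na(fam$father_id) | !is.na(fam$mother_id), , drop = FALSE]
  carrier_kids <- kids[kids$member_id %in% table$sample_ids &
                       !is.na(dos[kids$member_id]) &
                       dos[kids$member_id] >= 1, , drop = FALSE]
  if (nrow(carrier_kids) == 0) return("undetermined")
  parents <- unique(c(carrier_kids$father_id, carrier_kids$mother_id))
  parents <- parents[!is.na(parents)]
  par_dos <- rep(NA_integer_, length(parents))
  names(par_dos) <- parents
  genotyped <- intersect(parents, table$sample_ids)
  # a parent absent from the genotype matrix counts as ungenotyped
  has_geno <- stats::setNames(fam$has_genotype, fam$member_id)
  genotyped <- genotyped[vapply(genotyped, function(p) {
    !(p %in% names(has_geno)) || isTRUE(has_geno[[p]])
  }, logical(1))]
  par_dos[genotyped] <- dos[genotyped]
  if (any(!is.na(par_dos) & par_dos >= 1)) return("inherited")
  if (length(parents) == 2 && all(!is.na(par_dos)) && all(par_dos == 0)) {
    return("putative_de_novo")
  }
  "undetermined"
}

#' Run the full candidate selection over a cohort
#'
#' Applies [family_private_variants()] to every family with at least one
#' genotyped affected and one genotyped unaffected sibling, matches hits
#' across families, filters by functional class, and assesses parental
#' origin per contributing family.
#'
#' @param cohort A cohort object.
#' @param table A variant table.
#' @param annotations Annotation data.frame.
#' @param min_families Minimum families per candidate (default 2).
#' @param keep_classes Functional classes to keep.
#' @param missing_policy Passed to [family_private_variants()].
#' @return Candidate data.frame with per-family origin calls in the
#'   `origin` column (`family=call` pairs, comma-separated).
#' @export
select_candidates <- function(cohort, table, annotations, min_families = 2,
                              keep_classes = c("frameshift_ins", "frameshift_del"),
                              missing_policy = "lenient") {
  hit_list <- list()
  for (fid in family_ids(cohort)) {
    fam <- family_members(cohort, fid)
    sibs <- unlist(sibling_sets(fam))
    pheno <- stats::setNames(fam$phenotype, fam$member_id)
    geno_ids <- intersect(fam$member_id[fam$has_genotype], table$sample_ids)
    n_aff <- length(intersect(sibs[pheno[sibs] == "affected"], geno_ids))
    n_un <- length(intersect(sibs[pheno[sibs] == "unaffected"], geno_ids))
    if (n_aff >= 1 && n_un >= 1) {
      hit_list[[fid]] <- family_private_variants(fam, table, missing_policy)
    }
  }
  hits <- if (length(hit_list) > 0) do.call(rbind, hit_list) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), rsid = character(0),
               family_id = character(0), affected_carriers = character(0),
               missing_unaffected = character(0), stringsAsFactors = FALSE)
  cand <- cross_family_match(hits, min_families)
  cand <- filter_functional(cand, annotations, keep_classes)
  if (nrow(cand) > 0) {
    cand$origin <- vapply(seq_len(nrow(cand)), function(i) {
      fams <- strsplit(cand$families[i], ",", fixed = TRUE)[[1]]
      calls <- vapply(fams, function(fid) {
        assess_parental_origin(family_members(cohort, fid), table,
                               cand$chrom[i], cand$pos[i],
                               cand$ref[i], cand$alt[i])
      }, character(1))
      paste(sprintf("%s=%s", fams, calls), collapse = ",")
    }, character(1))
  } else {
    cand$origin <- character(0)
  }
  cand
}
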