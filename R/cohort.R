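# Pedigree / phenotype data model and PED file I/O.
#
# A cohort is a data.frame of members wrapped in a light S3 class. Phenotypes
# use a four-way vocabulary: affected sib-pair designs need a class for
# relatives with a psychiatric diagnosis other than the index disease, which
# must constrain neither side of the affected/unaffected logic downstream.

PHENOTYPE_LEVELS <- c("affected", "unaffected", "other_diagnosis", "unknown")
SEX_LEVELS <- c("male", "female", "unknown")

#' Default PED phenotype coding
#'
#' Standard PED uses 2 = affected, 1 = unaffected, 0/-9 = missing. This
#' dialect reserves -9 for an "other psychiatric diagnosis" class so that
#' files stay readable by standard tools while keeping individuals with a
#' different diagnosis out of both the affected and the unaffected constraint
#' sets.
#'
#' @return Named character vector mapping PED codes to phenotype classes.
#' @export
ped_phenotype_coding <- function() {
  c("2" = "affected", "1" = "unaffected", "0" = "unknown", "-9" = "other_diagnosis")
}

new_cohort <- function(members) {
  stopifnot(is.data.frame(members))
  rownames(members) <- NULL
  structure(list(members = members), class = "fam_cohort")
}

#' @export
print.fam_cohort <- function(x, ...) {
  m <- x$members
  cat(sprintf("<fam_cohort> %d members in %d families (%d genotyped)\n",
              nrow(m), length(unique(m$family_id)), sum(m$has_genotype)))
  tab <- table(m$phenotype)
  cat("  phenotypes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Member ids with DNA available
#'
#' @param cohort A cohort object.
#' @return Character vector of member ids with `has_genotype = TRUE`, in
#'   pedigree order.
#' @export
sample_order <- function(cohort) {
  cohort$members$member_id[cohort$members$has_genotype]
}

#' Mark which cohort members have genotype data
#'
#' PED files carry no DNA-availability column; availability is established
#' when a genotype source (e.g. a VCF) is linked. Members not named are
#' marked ungenotyped.
#'
#' @param cohort A cohort object.
#' @param ids Character vector of member ids with genotypes.
#' @return The cohort with `has_genotype` updated.
#' @export
set_genotyped <- function(cohort, ids) {
  unknown <- setdiff(ids, cohort$members$member_id)
  if (length(unknown) > 0) {
    stop("ids not in cohort: ", paste(unknown, collapse = ", "))
  }
  cohort$members$has_genotype <- cohort$members$member_id %in% ids
  cohort
}

#' Extract one family from a cohort
#'
#' @param cohort A cohort object.
#' @param family_id Family identifier.
#' @return A data.frame of the family's members.
#' @export
family_members <- function(cohort, family_id) {
  m <- cohort$members[cohort$members$family_id == family_id, , drop = FALSE]
  if (nrow(m) == 0) stop("no such family: ", family_id)
  rownames(m) <- NULL
  m
}

#' Family identifiers in a cohort
#' @param cohort A cohort object.
#' @return Character vector of family ids in order of first appearance.
#' @export
family_ids <- function(cohort) unique(cohort$members$family_id)

founders <- function(fam) {
  fam[is.na(fam$father_id) & is.na(fam$mother_id), , drop = FALSE]
}

#' Full siblings of a family: members sharing both listed parents
#'
#' Half-siblings (sharing one parent) do not form a sibling set here;
#' affected-sib-pair designs are nuclear families.
#'
#' @param fam A family data.frame (rows of cohort members).
#' @return List of character vectors of member ids, one per sibship.
#' @export
sibling_sets <- function(fam) {
  kids <- fam[!is.na(fam$father_id) & !is.na(fam$mother_id), , drop = FALSE]
  if (nrow(kids) == 0) return(list())
  key <- paste(kids$father_id, kids$mother_id, sep = "\r")
  unname(split(kids$member_id, key))
}

#' Read a PED/FAM pedigree file
#'
#' Whitespace-delimited, 6+ columns (family, individual, father, mother, sex,
#' phenotype), `#` comment lines ignored. Parent codes `0` (or `.`) mean
#' "no parent listed". Sex codes: 1 = male, 2 = female, other = unknown.
#'
#' @param path Path to the PED file.
#' @param phenotype_coding Named vector mapping phenotype codes to the classes
#'   `affected`, `unaffected`, `other_diagnosis`, `unknown`. Defaults to
#'   [ped_phenotype_coding()].
#' @param lenient If `TRUE` (default), unrecognised phenotype codes map to
#'   `unknown` and parents referenced but absent from the file are
#'   auto-created as ungenotyped founders of unknown sex and phenotype.
#'   If `FALSE`, both situations are errors.
#' @return A cohort object.
#' @export
read_ped <- function(path, phenotype_coding = ped_phenotype_coding(), lenient = TRUE) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(new_cohort(empty_members()))
  }
  fields <- strsplit(lines, "[ \t]+")
  ncol_min <- min(vapply(fields, length, integer(1)))
  if (ncol_min < 6) stop("PED file must have at least 6 columns")
  get <- function(i) vapply(fields, `[[`, character(1), i)
  fam <- get(1); ind <- get(2); fa <- get(3); mo <- get(4)
  sex_code <- get(5); phe_code <- get(6)

  dup <- ind[duplicated(ind)]
  if (length(dup) > 0) {
    stop("duplicate individual id(s): ", paste(unique(dup), collapse = ", "))
  }

  phe <- unname(phenotype_coding[phe_code])
  bad <- is.na(phe)
  if (any(bad)) {
    if (!lenient) {
      stop("unparseable phenotype code(s): ",
           paste(unique(phe_code[bad]), collapse = ", "))
    }
    phe[bad] <- "unknown"
  }
  sex <- ifelse(sex_code == "1", "male", ifelse(sex_code == "2", "female", "unknown"))
  none <- function(x) ifelse(x %in% c("0", "."), NA_character_, x)
  fa <- none(fa); mo <- none(mo)

  members <- data.frame(
    family_id = fam, member_id = ind, father_id = fa, mother_id = mo,
    sex = sex, phenotype = phe, has_genotype = TRUE,
    stringsAsFactors = FALSE
  )

  # parents referenced but not present: auto-create ungenotyped founders
  refs <- unique(stats::na.omit(c(fa, mo)))
  missing_par <- setdiff(refs, ind)
  if (length(missing_par) > 0) {
    if (!lenient) {
      stop("parent id(s) reference missing member(s): ",
           paste(missing_par, collapse = ", "))
    }
    par_fam <- vapply(missing_par, function(p) {
      members$family_id[which(members$father_id == p | members$mother_id == p)[1]]
    }, character(1))
    par_sex <- vapply(missing_par, function(p) {
      if (p %in% members$father_id) "male" else if (p %in% members$mother_id) "female" else "unknown"
    }, character(1))
    add <- data.frame(
      family_id = par_fam, member_id = missing_par,
      father_id = NA_character_, mother_id = NA_character_,
      sex = par_sex, phenotype = "unknown", has_genotype = FALSE,
      stringsAsFactors = FALSE
    )
    members <- rbind(members, add)
  }
  new_cohort(members)
}

empty_members <- function() {
  data.frame(
    family_id = character(0), member_id = character(0),
    father_id = character(0), mother_id = character(0),
    sex = character(0), phenotype = character(0),
    has_genotype = logical(0), stringsAsFactors = FALSE
  )
}

#' Write a cohort as a 6-column PED file
#'
#' Phenotypes are encoded 2 = affected, 1 = unaffected, 0 = unknown,
#' -9 = other diagnosis; the dialect is recorded in a header comment.
#'
#' @param cohort A cohort object.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_ped <- function(cohort, path) {
  m <- cohort$members
  code <- c(affected = "2", unaffected = "1", unknown = "0", other_diagnosis = "-9")
  sexc <- c(male = "1", female = "2", unknown = "0")
  hdr <- "# PED dialect: phenotype 2=affected 1=unaffected 0=unknown -9=other_diagnosis"
  lines <- hdr
  if (nrow(m) > 0) {
    lines <- c(lines, paste(
      m$family_id, m$member_id,
      ifelse(is.na(m$father_id), "0", m$father_id),
      ifelse(is.na(m$mother_id), "0", m$mother_id),
      sexc[m$sex], code[m$phenotype], sep = "\t"
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Structural validation of one family's pedigree
#'
#' Returns findings rather than raising: parental sex inconsistencies,
#' cycles (a member being its own ancestor), and advisory notes where the
#' sibship does not match an affected-sib-pair design (at least two affected
#' and one unaffected sibling).
#'
#' @param fam A family data.frame (e.g. from [family_members()]).
#' @return A data.frame with columns `kind`, `member_id`, `detail`. Zero rows
#'   means no findings.
#' @export
validate_pedigree <- function(fam) {
  findings <- list()
  note <- function(kind, id, detail) {
    findings[[length(findings) + 1]] <<- data.frame(
      kind = kind, member_id = id, detail = detail, stringsAsFactors = FALSE
    )
  }
  sex_of <- stats::setNames(fam$sex, fam$member_id)
  for (i in seq_len(nrow(fam))) {
    fa <- fam$father_id[i]; mo <- fam$mother_id[i]
    if (!is.na(fa) && fa %in% names(sex_of) && sex_of[[fa]] == "female") {
      note("parent-sex-mismatch", fam$member_id[i],
           sprintf("father %s is recorded female", fa))
    }
    if (!is.na(mo) && mo %in% names(sex_of) && sex_of[[mo]] == "male") {
      note("parent-sex-mismatch", fam$member_id[i],
           sprintf("mother %s is recorded male", mo))
    }
    if (!is.na(fa) && fa %in% names(sex_of) && sex_of[[fa]] == "unknown") {
      note("parent-sex-unknown", fam$member_id[i],
           sprintf("father %s has unknown sex", fa))
    }
  }
  # cycle detection: walk up from each member
  parent_map <- stats::setNames(
    lapply(seq_len(nrow(fam)), function(i) {
      stats::na.omit(c(fam$father_id[i], fam$mother_id[i]))
    }),
    fam$member_id
  )
  for (id in fam$member_id) {
    seen <- character(0)
    frontier <- id
    repeat {
      up <- unique(unlist(parent_map[intersect(frontier, names(parent_map))]))
      up <- up[!is.na(up)]
      if (length(up) == 0) break
      if (id %in% up) {
        note("cycle", id, "member is its own ancestor")
        break
      }
      up <- setdiff(up, seen)
      if (length(up) == 0) break
      seen <- c(seen, up)
      frontier <- up
    }
  }
  # advisory: study design expects >=2 affected and >=1 unaffected siblings
  sibs <- sibling_sets(fam)
  if (length(sibs) > 0) {
    pheno <- stats::setNames(fam$phenotype, fam$member_id)
    best_aff <- max(vapply(sibs, function(s) sum(pheno[s] == "affected"), integer(1)))
    best_unaff <- max(vapply(sibs, function(s) sum(pheno[s] == "unaffected"), integer(1)))
    if (best_aff < 2) {
      note("design-advisory", NA_character_,
           sprintf("largest sibship has %d affected sibling(s), design expects >=2", best_aff))
    }
    if (best_unaff < 1) {
      note("design-advisory", NA_character_,
           "no sibship has an unaffected sibling, design expects >=1")
    }
  }
  if (length(findings) == 0) {
    return(data.frame(kind = character(0), member_id = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}
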