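# Variant / genotype / annotation data model.
#
# Genotypes are stored as alternate-allele dosages (0, 1, 2) with NA for
# missing calls. Missingness is a first-class state and never collapses to
# dosage 0: the candidate filter and segregation semantics differ for
# "DNA absent" versus "non-carrier".

FUNC_CLASSES <- c("frameshift_ins", "frameshift_del", "stopgain", "stoploss",
                  "nonsynonymous", "synonymous", "splicing", "other")

#' Loss-of-function functional classes
#' @return Character vector of the functional classes treated as LoF.
#' @export
lof_classes <- function() {
  c("frameshift_ins", "frameshift_del", "stopgain", "stoploss", "splicing")
}

new_variant_table <- function(variants, geno, sample_ids) {
  stopifnot(is.data.frame(variants), is.matrix(geno),
            nrow(geno) == nrow(variants), ncol(geno) == length(sample_ids))
  colnames(geno) <- sample_ids
  rownames(variants) <- NULL
  structure(
    list(variants = variants, geno = geno, sample_ids = sample_ids),
    class = "variant_table"
  )
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table> %d variants x %d samples (%.1f%% missing calls)\n",
              nrow(x$variants), length(x$sample_ids),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' Locate a variant row in a variant table
#'
#' @param table A variant table.
#' @param chrom,pos,ref,alt Variant coordinates (1-based VCF convention,
#'   anchor-base indel representation).
#' @return Integer row index.
#' @export
variant_index <- function(table, chrom, pos, ref, alt) {
  i <- which(table$variants$chrom == chrom & table$variants$pos == pos &
             table$variants$ref == ref & table$variants$alt == alt)
  if (length(i) == 0) {
    stop(sprintf("variant %s:%d %s>%s not found", chrom, pos, ref, alt))
  }
  i[1]
}

#' Read a multi-sample VCF into a dosage table
#'
#' Multiallelic sites are split into one biallelic record per alternate
#' allele; per-sample dosage of each record counts that allele only, so
#' splitting conserves total alternate counts. Phased and unphased GT are
#' treated alike; any missing allele in a call (`./.` or half-calls) makes
#' the dosage missing.
#'
#' @param path Path to a VCF 4.x file (plain or bgzipped), GT field present.
#' @param cohort Optional cohort: sample columns are checked against members
#'   with `has_genotype = TRUE` and the table is indexed by member id.
#' @return A variant table.
#' @export
read_vcf <- function(path, cohort = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt_raw <- v@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2) stop("VCF has no genotype columns")
  samples <- colnames(gt_raw)[-1]
  fmt <- gt_raw[, 1]
  gt_only <- all(fmt == "GT")
  gt_field <- function(row_i) {
    if (gt_only) return(gt_raw[row_i, -1])
    keys <- strsplit(fmt[row_i], ":", fixed = TRUE)[[1]]
    gi <- match("GT", keys)
    if (is.na(gi)) stop("GT field absent at VCF record ", row_i)
    vapply(gt_raw[row_i, -1], function(cell) {
      if (is.na(cell)) return(NA_character_)
      strsplit(cell, ":", fixed = TRUE)[[1]][gi]
    }, character(1))
  }

  # fast path lookup for the common diploid biallelic GT codes
  gt_codes <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
                "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  var_rows <- list()
  geno_rows <- list()
  n <- nrow(fix)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    gts <- gt_field(i)
    simple <- length(alts) == 1 && all(is.na(gts) | gts %in% c(names(gt_codes), "./.", ".|.", "."))
    alleles <- if (simple) NULL else strsplit(gts, "[/|]")
    for (k in seq_along(alts)) {
      dos <- if (simple) {
        unname(gt_codes[gts])
      } else vapply(alleles, function(a) {
        if (length(a) == 0 || anyNA(a) || any(a == ".")) return(NA_integer_)
        sum(a == as.character(k))
      }, integer(1))
      rsid <- fix[i, "ID"]
      var_rows[[length(var_rows) + 1]] <- c(
        fix[i, "CHROM"], fix[i, "POS"], fix[i, "REF"], alts[k],
        if (is.na(rsid) || rsid == ".") NA_character_ else rsid
      )
      geno_rows[[length(geno_rows) + 1]] <- dos
    }
  }
  vm <- do.call(rbind, var_rows)
  variants <- data.frame(chrom = vm[, 1], pos = as.integer(vm[, 2]),
                         ref = vm[, 3], alt = vm[, 4], rsid = vm[, 5],
                         stringsAsFactors = FALSE)
  geno <- do.call(rbind, geno_rows)
  colnames(geno) <- samples

  if (!is.null(cohort)) {
    want <- sample_order(cohort)
    absent <- setdiff(want, samples)
    if (length(absent) > 0) {
      stop("genotyped cohort member(s) absent from VCF: ",
           paste(absent, collapse = ", "))
    }
    extra <- setdiff(samples, want)
    if (length(extra) > 0) {
      warning("VCF sample(s) not in cohort: ", paste(extra, collapse = ", "))
    }
    geno <- geno[, want, drop = FALSE]
    samples <- want
  }
  new_variant_table(variants, geno, samples)
}

#' Write a dosage table as a plain-text VCF 4.2 file
#'
#' Dosage 0/1/2 is emitted as `0/0`, `0/1`, `1/1`; missing as `./.`.
#'
#' @param table A variant table.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_vcf <- function(table, path) {
  v <- table$variants
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", table$sample_ids), collapse = "\t")
  )
  body <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    dos <- table$geno[i, ]
    gt <- ifelse(is.na(dos), "./.", gt_code[dos + 1])
    body[i] <- paste(c(
      v$chrom[i], v$pos[i],
      if (is.na(v$rsid[i])) "." else v$rsid[i],
      v$ref[i], v$alt[i], ".", "PASS", ".", "GT", gt
    ), collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a tab-delimited functional annotation table
#'
#' ANNOVAR-style: one row per variant keyed by (chrom, pos, ref, alt), with
#' gene, functional class and protein change columns. Class strings are
#' normalised to a closed vocabulary; unknown strings map to `other` and are
#' counted in the `unknown_classes` attribute.
#'
#' @param path Path to the table.
#' @param columns Named list mapping the roles `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `class`, `protein` to column names in the file.
#' @return A data.frame of annotation records with attribute
#'   `unknown_classes` (count of unrecognised class strings).
#' @export
read_annotations <- function(path,
                             columns = list(chrom = "chrom", pos = "pos",
                                            ref = "ref", alt = "alt",
                                            gene = "gene", class = "func_class",
                                            protein = "protein_change")) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- unlist(columns[c("chrom", "pos", "ref", "alt", "gene", "class")])
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("annotation table missing column(s): ", paste(miss, collapse = ", "))
  }
  cls <- normalize_func_class(raw[[columns$class]])
  prot <- if (!is.null(columns$protein) && columns$protein %in% names(raw)) {
    p <- raw[[columns$protein]]
    ifelse(is.na(p) | p == "" | p == ".", NA_character_, p)
  } else NA_character_
  out <- data.frame(
    chrom = as.character(raw[[columns$chrom]]),
    pos = as.integer(raw[[columns$pos]]),
    ref = as.character(raw[[columns$ref]]),
    alt = as.character(raw[[columns$alt]]),
    gene = as.character(raw[[columns$gene]]),
    func_class = cls$class,
    protein_change = prot,
    stringsAsFactors = FALSE
  )
  attr(out, "unknown_classes") <- cls$unknown
  out
}

normalize_func_class <- function(x) {
  key <- gsub("[ _]+", " ", tolower(trimws(x)))
  map <- c(
    "frameshift insertion" = "frameshift_ins",
    "frameshift ins" = "frameshift_ins",
    "insertion" = "frameshift_ins",
    "frameshift deletion" = "frameshift_del",
    "frameshift del" = "frameshift_del",
    "deletion" = "frameshift_del",
    "stopgain" = "stopgain",
    "stop gain" = "stopgain",
    "stoploss" = "stoploss",
    "stop loss" = "stoploss",
    "nonsynonymous snv" = "nonsynonymous",
    "nonsynonymous" = "nonsynonymous",
    "missense" = "nonsynonymous",
    "synonymous snv" = "synonymous",
    "synonymous" = "synonymous",
    "splicing" = "splicing",
    "splice" = "splicing",
    "other" = "other"
  )
  cls <- unname(map[key])
  unknown <- sum(is.na(cls))
  cls[is.na(cls)] <- "other"
  list(class = cls, unknown = unknown)
}

#' Sample ids carrying a variant
#'
#' @param table A variant table.
#' @param chrom,pos,ref,alt Variant coordinates.
#' @return Character vector of sample ids with dosage >= 1; missing calls are
#'   excluded.
#' @export
carrier_ids <- function(table, chrom, pos, ref, alt) {
  i <- variant_index(table, chrom, pos, ref, alt)
  dos <- table$geno[i, ]
  names(dos)[!is.na(dos) & dos >= 1]
}
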