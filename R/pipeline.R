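# End-to-end orchestration: relatedness QC -> candidate filter ->
# association grid -> segregation test, with all stage tables written as
# TSV and a machine-readable summary. QC findings are warnings by default
# (misassigned subjects are reported for manual review, not auto-dropped);
# `qc_strict = TRUE` drops flagged individuals before filtering.

#' Pipeline configuration
#'
#' @param vcf,ped,annotations,refs Input file paths (multi-sample VCF, PED
#'   pedigree, annotation TSV, reference-population TSV).
#' @param min_families Minimum families per candidate variant.
#' @param keep_classes Functional classes retained by the filter.
#' @param B Monte-Carlo replicates for the association simulation.
#' @param n_sims Gene-dropping replicates for the segregation simulation.
#' @param q Founder alternate-allele frequency for the segregation test;
#'   `NULL` uses the first reference population's frequency.
#' @param seed Integer seed propagated to every stochastic stage.
#' @param output_dir Directory for stage outputs.
#' @param qc_strict Drop individuals flagged by the kinship QC.
#' @param maf_floor,min_markers Passed to [centered_ibs_kinship()].
#' @return A config list of class `run_config`.
#' @export
run_config <- function(vcf, ped, annotations, refs,
                       min_families = 2,
                       keep_classes = c("frameshift_ins", "frameshift_del"),
                       B = 1e5, n_sims = 1e5, q = NULL, seed = 1,
                       output_dir = tempfile("famseg_run_"),
                       qc_strict = FALSE,
                       maf_floor = 0.01, min_markers = 1000) {
  structure(as.list(environment()), class = "run_config")
}

write_stage <- function(df, dir, name) {
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages: read inputs; centered-IBS kinship and X-heterozygosity sex QC;
#' affected-only cross-family candidate filtering; scenario-based
#' association against each reference population (Yates chi-square,
#' fixed-margins Monte-Carlo, exact tail); segregation test for each
#' candidate's contributing families. All stage tables land in
#' `cfg$output_dir`; a failure leaves partial outputs plus a `FAILED`
#' marker naming the stage.
#'
#' @param cfg A [run_config()].
#' @return A run report list: `qc` (findings, sex calls), `candidates`,
#'   `association`, `segregation`, `paths`.
#' @export
run_pipeline <- function(cfg) {
  for (p in c(cfg$vcf, cfg$ped, cfg$annotations, cfg$refs)) {
    if (!file.exists(p)) stop("input file does not exist: ", p)
  }
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "read_inputs"
  report <- list(paths = list(output_dir = cfg$output_dir))
  on_fail <- function(e) {
    writeLines(sprintf("FAILED at stage %s: %s", stage, conditionMessage(e)),
               file.path(cfg$output_dir, "FAILED"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    cohort <- read_ped(cfg$ped)
    table <- read_vcf(cfg$vcf, cohort = NULL)
    cohort <- set_genotyped(cohort, intersect(cohort$members$member_id,
                                              table$sample_ids))
    table <- read_vcf(cfg$vcf, cohort = cohort)
    anno <- read_annotations(cfg$annotations)
    refs <- read_reference_populations(cfg$refs)

    stage <- "relatedness_qc"
    autosomal <- table$variants$chrom != "X"
    bg <- new_variant_table(table$variants[autosomal, , drop = FALSE],
                            table$geno[autosomal, , drop = FALSE],
                            table$sample_ids)
    kin <- centered_ibs_kinship(bg, min_markers = cfg$min_markers,
                                maf_floor = cfg$maf_floor)
    qc_findings <- verify_family_assignment(cohort, kin)
    sex_calls <- tryCatch(infer_sex(table), error = function(e) NULL)
    write_kinship(kin, file.path(cfg$output_dir, "kinship.tsv"))
    write_stage(qc_findings, cfg$output_dir, "qc_findings.tsv")
    if (!is.null(sex_calls)) write_stage(sex_calls, cfg$output_dir, "sex_calls.tsv")
    if (nrow(qc_findings) > 0) {
      if (cfg$qc_strict) {
        drop_ids <- unique(qc_findings$member_id)
        keep <- setdiff(table$sample_ids, drop_ids)
        cohort$members$has_genotype <- cohort$members$has_genotype &
          !(cohort$members$member_id %in% drop_ids)
        table <- new_variant_table(table$variants,
                                   table$geno[, keep, drop = FALSE], keep)
        message("qc_strict: dropped ", length(drop_ids), " flagged individual(s)")
      } else {
        warning(nrow(qc_findings), " kinship QC finding(s); see qc_findings.tsv")
      }
    }

    stage <- "candidate_filter"
    candidates <- select_candidates(cohort, table, anno,
                                    min_families = cfg$min_families,
                                    keep_classes = cfg$keep_classes)
    write_stage(candidates, cfg$output_dir, "candidates.tsv")

    stage <- "association"
    assoc <- list()
    for (i in seq_len(nrow(candidates))) {
      res <- run_association(cohort, table, candidates$chrom[i],
                             candidates$pos[i], candidates$ref[i],
                             candidates$alt[i], refs, B = cfg$B,
                             seed = cfg$seed + i)
      res$variant <- variant_key(candidates[i, ])
      assoc[[i]] <- res
    }
    assoc <- if (length(assoc) > 0) do.call(rbind, assoc) else
      data.frame()
    write_stage(assoc, cfg$output_dir, "association.tsv")

    stage <- "segregation"
    seg_rows <- list()
    for (i in seq_len(nrow(candidates))) {
      fams <- strsplit(candidates$families[i], ",", fixed = TRUE)[[1]]
      q <- if (is.null(cfg$q)) refs$freq[1] else cfg$q
      seg <- run_segregation(cohort, q = q, families = fams,
                             n_sims = cfg$n_sims, seed = cfg$seed + 1000 + i)
      seg_rows[[i]] <- data.frame(
        variant = variant_key(candidates[i, ]),
        family_id = c(fams, "joint", "simulated"),
        p = c(unname(seg$per_family), seg$joint,
              if (is.null(seg$sim_p)) NA_real_ else seg$sim_p),
        q = q, n_sims = c(rep(NA, length(fams) + 1),
                          if (is.null(seg$n_sims)) NA else seg$n_sims),
        stringsAsFactors = FALSE
      )
    }
    seg <- if (length(seg_rows) > 0) do.call(rbind, seg_rows) else data.frame()
    write_stage(seg, cfg$output_dir, "segregation.tsv")

    stage <- "summary"
    summary_lines <- c(
      sprintf("seed\t%d", cfg$seed),
      sprintf("n_families\t%d", length(family_ids(cohort))),
      sprintf("n_samples\t%d", length(table$sample_ids)),
      sprintf("n_variants\t%d", nrow(table$variants)),
      sprintf("n_qc_findings\t%d", nrow(qc_findings)),
      sprintf("n_candidates\t%d", nrow(candidates))
    )
    writeLines(summary_lines, file.path(cfg$output_dir, "summary.tsv"))

    report$qc <- list(findings = qc_findings, sex_calls = sex_calls)
    report$candidates <- candidates
    report$association <- assoc
    report$segregation <- seg
    report
  }, error = on_fail)
}
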