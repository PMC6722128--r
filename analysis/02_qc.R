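#!/usr/bin/env Rscript
# Relatedness and sex QC of the simulated cohort: centered-IBS kinship over
# the autosomal background panel, family assignment checks, and
# X-heterozygosity sex inference.
library(famseg)

cohort <- read_ped("results/cohort/cohort.ped")
table <- read_vcf("results/cohort/genotypes.vcf")
cohort <- set_genotyped(cohort, intersect(cohort$members$member_id,
                                          table$sample_ids))

aut <- table$variants$chrom != "X"
bg <- famseg:::new_variant_table(table$variants[aut, ], table$geno[aut, ],
                                 table$sample_ids)
kin <- centered_ibs_kinship(bg)
findings <- verify_family_assignment(cohort, kin)
sex <- infer_sex(table)

dir.create("results/qc", recursive = TRUE, showWarnings = FALSE)
write_kinship(kin, "results/qc/kinship.tsv")
write.table(findings, "results/qc/findings.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(sex, "results/qc/sex_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("kinship over %d samples; %d family-assignment finding(s)",
                length(kin$ids), nrow(findings)))
message(sprintf("sex calls: %d male, %d female, %d ambiguous",
                sum(sex$inferred == "male"), sum(sex$inferred == "female"),
                sum(sex$inferred == "ambiguous")))
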