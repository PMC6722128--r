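#!/usr/bin/env Rscript
# Candidate risk-variant selection: variants carried by at least one
# affected sibling and no unaffected sibling within a family, matched
# across families (>=2), restricted to frameshift indels, with
# parental-origin assessment.
library(famseg)

cohort <- read_ped("results/cohort/cohort.ped")
table <- read_vcf("results/cohort/genotypes.vcf")
cohort <- set_genotyped(cohort, intersect(cohort$members$member_id,
                                          table$sample_ids))
anno <- read_annotations("results/cohort/annotations.tsv")

cand <- select_candidates(cohort, table, anno, min_families = 2)
write.table(cand, "results/candidates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("%d candidate variant(s):", nrow(cand)))
for (i in seq_len(nrow(cand))) {
  message(sprintf("  %s:%d %s>%s  gene=%s class=%s families=%s origin=%s",
                  cand$chrom[i], cand$pos[i], cand$ref[i], cand$alt[i],
                  cand$gene[i], cand$func_class[i], cand$families[i],
                  cand$origin[i]))
}
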