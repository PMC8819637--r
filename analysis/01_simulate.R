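#!/usr/bin/env Rscript
# Generate the synthetic raw inputs the rest of the workflow consumes:
# a time-and-motion observation log, an enrolment/visit log and an itemized
# expenditure ledger, emulating the study conditions (603 initiators, ~1280
# person-months, 50 observations, audited category totals).

library(prepcost)

cfg <- generator_config(seed = 20181101)
paths <- write_synthetic_fixtures(cfg, "results/synthetic")

visits <- gen_enrolment(cfg)
s <- enrolment_summary(visits)
cat(sprintf("Simulated %d initiators: %d person-months (median %d, IQR %d-%d)\n",
            reference_enrolment()$n_initiators, s$total_person_months,
            s$median_months, s$iqr_months[1], s$iqr_months[2]))
cat("Person-months by arm:\n")
print(s$by_arm)
cat("Wrote:", paste(unlist(paths), collapse = ", "), "\n")
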