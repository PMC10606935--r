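#!/usr/bin/env Rscript
# Simulate the study cohort: 30 healthy and 30 diseased subjects, one
# ~12 s walk each, recorded by 8 insole force sensors at 20 Hz, and
# write one CSV per subject plus a manifest under results/cohort/.

library(gaitropy)

spec <- cohort_spec(rng_seed = 7)
print(spec)

cohort <- generate_cohort(spec)
manifest <- write_cohort(cohort, "results/cohort", seed = spec$rng_seed)

cat(sprintf("\nWrote %d recordings to results/cohort/ (%s)\n",
            nrow(manifest), paste(table(manifest$label), collapse = " / ")))
cat("First subject:\n")
print(cohort[[1]])
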