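#!/usr/bin/env Rscript
# Regenerates the bundled toy contact-parameter table
# (inst/extdata/contact_params_toy.json) from the package's synthetic
# reference generator. The table is deliberately labelled toy/synthetic:
# it makes the pipeline runnable out of the box, but real analyses should
# re-estimate from a curated collection of high-resolution structures.
suppressMessages(library(wfcm))

ref <- make_reference_set(600, seed = 20240601 %% 2^31)
tab <- estimate_parameters(ref)
tab$metadata$provenance <-
  "synthetic toy reference set (wfcm::make_reference_set(600, seed=20240601)); not publication grade"
out <- file.path("inst", "extdata", "contact_params_toy.json")
write_param_table(tab, out)
cat("wrote", out, ":", length(tab$entries), "entries,",
    file.size(out), "bytes\n")
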