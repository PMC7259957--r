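#!/usr/bin/env Rscript

# Stage 3: luminal-calcium dose-inhibition of channel open probability.
#
# Simulates mean-P_o datasets across 8 luminal calcium concentrations
# (0.07-600 uM) from gating records whose true P_o follows the inhibitory
# Hill relation, fits the Hill equation by nonlinear least squares, and
# writes the dataset and fit (results/po_dataset.tsv,
# results/hill_fit.json).

suppressPackageStartupMessages(library(ercal))

seed <- 20260923L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

d <- simulate_po_dataset(seed = seed)
write.table(format(d$data, digits = 6), file.path(out_dir, "po_dataset.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

fit <- fit_hill(d$data)
print(fit)
message(sprintf("  (generator truth: P_max 0.65, K_inh 260 uM, H_inh 2.3)"))

jsonlite::write_json(list(p_max = fit$p_max, k_inh_uM = fit$k_inh,
                          h_inh = fit$h_inh, rss = fit$rss,
                          se = as.list(stats::setNames(fit$se,
                            c("p_max", "k_inh", "h_inh")[seq_along(fit$se)])),
                          seed = seed),
                     file.path(out_dir, "hill_fit.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("fit -> results/hill_fit.json")
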