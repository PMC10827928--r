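#!/usr/bin/env Rscript
# Step 1 -- simulate every input the downstream analyses consume.
#
# Produces, with known ground truth:
#   * a supplement-scale cross-disease study (anchor differential table,
#     multi-study report set for the comparison disease, six curated
#     reference sets, an identifier universe),
#   * a desk-scale expression matrix with two planted co-expression modules
#     and a trait driven by the first module,
#   * DAB-stain images for simulated cases and controls with planted
#     positive-pixel fractions.
# Everything is written as plain text (TSV/JSON) or PNG under results/sim/.

suppressMessages(library(crossproteo))
seed <- 20240
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("-- supplement-scale cross-disease study --")
study <- simulate_cross_disease_study(seed = seed)
write_diff_table(study$table_a, file.path(out, "epilepsy_hippocampus.tsv"))
readr::write_tsv(study$reports_b, file.path(out, "ad_study_reports.tsv"), progress = FALSE)
for (nm in names(study$reference_sets)) {
  readr::write_tsv(study$reference_sets[[nm]],
                   file.path(out, paste0("refset_", nm, ".tsv")), progress = FALSE)
}
writeLines(study$universe, file.path(out, "universe_ids.txt"))
jsonlite::write_json(study$answer_key$summary, file.path(out, "answer_key_summary.json"),
                     auto_unbox = TRUE)
readr::write_tsv(study$answer_key$records, file.path(out, "answer_key_records.tsv"),
                 progress = FALSE)
message(sprintf("anchor table: %d proteins; comparison reports: %d proteins; universe: %d",
                nrow(study$table_a), length(unique(study$reports_b$uniprot)),
                length(study$universe)))

message("-- planted co-expression fixture --")
gx <- gen_expression(n_proteins = 60, n_samples = 50, module_sizes = c(30, 30),
                     within_module_cor = 0.8, trait_cor = 0.9, seed = seed)
readr::write_tsv(tibble::as_tibble(gx$matrix, rownames = "protein"),
                 file.path(out, "abundance_matrix.tsv"), progress = FALSE)
readr::write_tsv(tibble::tibble(sample_id = names(gx$trait), value = gx$trait),
                 file.path(out, "trait.tsv"), progress = FALSE)
readr::write_tsv(gx$answer_key, file.path(out, "module_answer_key.tsv"), progress = FALSE)
message(sprintf("expression matrix: %d proteins x %d samples, modules %s",
                nrow(gx$matrix), ncol(gx$matrix), "30+30"))

message("-- stained sections (cases vs controls) --")
# planted per-case positive fractions emulate a ~1.7-fold case/control ratio
set.seed(seed)
groups <- list(control = pmax(stats::rnorm(10, 1.0, 0.4), 0.05) / 100,
               case = pmax(stats::rnorm(12, 1.7, 0.6), 0.05) / 100)
truth <- list()
for (grp in names(groups)) {
  for (i in seq_along(groups[[grp]])) {
    id <- sprintf("%s_%02d", grp, i)
    g <- gen_stain_image(120, 120, groups[[grp]][i], seed = seed + 100 * (grp == "case") + i,
                         out_png = file.path(out, paste0(id, ".png")))
    truth[[id]] <- g$answer_key$percent_positive
  }
}
jsonlite::write_json(truth, file.path(out, "stain_answer_key.json"),
                     auto_unbox = TRUE, digits = NA)
message(sprintf("wrote %d stained sections", length(truth)))
message("done: inputs under ", out)
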