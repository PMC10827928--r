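#!/usr/bin/env Rscript
# Step 2 -- cross-disease concordance classification.
#
# Reads the simulated differential table and multi-study report set from
# step 1 through the package's file readers, computes per-protein
# consistency calls, matches the two datasets by dual identifiers,
# classifies every anchor protein (same / opposite / inconsistent /
# anchor-only), annotates against the six reference sets, and checks the
# result against the generator's answer key.

suppressMessages(library(crossproteo))
sim <- "results/sim"
out <- "results"

tbl_a <- read_diff_table(file.path(sim, "epilepsy_hippocampus.tsv"),
                         list(uniprot = "uniprot", gene = "gene", log2fc = "log2fc"),
                         label = "epilepsy_hippocampus")
reports <- readr::read_tsv(file.path(sim, "ad_study_reports.tsv"),
                           show_col_types = FALSE, progress = FALSE)
calls <- call_table(reports)

ref_files <- list.files(sim, pattern = "^refset_", full.names = TRUE)
ref_sets <- lapply(ref_files, function(f) {
  read_reference_set(f, list(uniprot = "uniprot", gene = "gene"),
                     name = sub("^refset_(.*)\\.tsv$", "\\1", basename(f)))
})
names(ref_sets) <- vapply(ref_sets, attr, "", "name")

rec <- annotate_sets(match_tables(tbl_a, calls), ref_sets)
sm <- summarize_concordance(rec)

message(sprintf(
  "%d/%d (%d%%) anchor proteins matched; %d (%d%%) same direction (%d down, %d up), %d opposite, %d inconsistent",
  sm$n_matched, sm$n_a, sm$pct_matched, sm$n_same, sm$pct_same_of_matched,
  sm$n_same_down, sm$n_same_up, sm$n_opposite, sm$n_inconsistent_b))
message("reference-set overlaps: ",
        paste(names(sm$overlap_counts), unlist(sm$overlap_counts),
              sep = "=", collapse = ", "))

truth <- jsonlite::read_json(file.path(sim, "answer_key_summary.json"))
stopifnot(sm$n_matched == truth$n_matched, sm$n_same == truth$n_same,
          sm$n_opposite == truth$n_opposite,
          sm$n_inconsistent_b == truth$n_inconsistent_b)
message("summary agrees with the planted answer key")

readr::write_tsv(rec, file.path(out, "concordance_records.tsv"), progress = FALSE)
jsonlite::write_json(sm, file.path(out, "concordance_summary.json"), auto_unbox = TRUE)
message("wrote results/concordance_records.tsv and results/concordance_summary.json")
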