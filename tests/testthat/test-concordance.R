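# calls derived from a single-study table: each direction is one unanimous report
calls_from_table <- function(tbl) {
  tibble::tibble(uniprot = tbl$uniprot, gene = tbl$gene,
                 call = ifelse(tbl$direction == "up", "increased", "decreased"),
                 score = ifelse(tbl$direction == "up", 1L, -1L))
}

test_that("planted overlap and direction concordance are recovered exactly", {
  g <- gen_disease_tables(1000, 100, 100, 50, 0.5, seed = 7)
  rec <- match_tables(g$table_a, calls_from_table(g$table_b))
  sm <- summarize_concordance(rec)
  expect_equal(sm$n_matched, 50)
  expect_equal(sm$n_same, 25)
  expect_equal(sm$n_opposite, 25)
  expect_equal(sm$n_a_only, 50)
  # categories agree with the planted key, record by record
  truth <- g$answer_key[g$answer_key$in_a, ]
  merged <- dplyr::inner_join(rec, truth, by = c("uniprot", "gene"))
  expect_equal(nrow(merged), 100)
  expect_identical(merged$category.x, merged$category.y)
})

test_that("generators are deterministic: same seed, same tables, same files", {
  g1 <- gen_disease_tables(500, 60, 60, 30, 0.4, seed = 7)
  g2 <- gen_disease_tables(500, 60, 60, 30, 0.4, seed = 7)
  expect_identical(g1, g2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  gen_disease_tables(500, 60, 60, 30, 0.4, seed = 7, out_dir = d1)
  gen_disease_tables(500, 60, 60, 30, 0.4, seed = 7, out_dir = d2)
  for (f in c("table_a.tsv", "table_b.tsv", "answer_key.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("empty intersection and parameter violations are handled", {
  g <- gen_disease_tables(500, 40, 40, 0, 0.5, seed = 3)
  sm <- summarize_concordance(match_tables(g$table_a, calls_from_table(g$table_b)))
  expect_equal(sm$n_matched, 0)
  expect_equal(sm$n_same, 0)
  expect_equal(sm$n_opposite, 0)
  expect_error(gen_disease_tables(100, 80, 80, 90, 0.5, seed = 1),
               class = "crossproteo_param_error")
  expect_error(gen_disease_tables(100, 80, 80, 50, 1.5, seed = 1),
               class = "crossproteo_param_error")
})

test_that("a hand-enumerated 5-protein toy hits all five categories", {
  a <- tibble::tibble(
    uniprot = c("P1", "P2", "P3", "P4", "P5"),
    gene = c("A", "B", "C", "D", "E"),
    log2fc = c(1, -1, 1, -1, 1),
    direction = c("up", "down", "up", "down", "up"),
    significant = TRUE)
  b_calls <- tibble::tibble(
    uniprot = c("P1", "P2", "P3", "P4"),
    gene = c("A", "B", "C", "D"),
    call = c("increased", "decreased", "decreased", "inconsistent"),
    score = c(3L, -2L, -4L, NA_integer_))
  rec <- match_tables(a, b_calls)
  expect_identical(rec$category,
                   c("same_up", "same_down", "opposite", "inconsistent_b", "a_only"))
  sm <- summarize_concordance(rec)
  expect_equal(sm$n_matched, 4)
  expect_equal(sm$n_same_up, 1); expect_equal(sm$n_same_down, 1)
  expect_equal(sm$n_opposite, 1); expect_equal(sm$n_inconsistent_b, 1)
  expect_equal(sm$n_a_only, 1)
})

test_that("a table matched against its own calls is all same-direction", {
  g <- gen_disease_tables(300, 50, 50, 20, 0.5, seed = 11)
  rec <- match_tables(g$table_a, calls_from_table(g$table_a))
  expect_true(all(rec$category %in% c("same_up", "same_down")))
  expect_equal(summarize_concordance(rec)$n_matched, 50)
})

test_that("summary invariants hold over 100 random generator configurations", {
  set.seed(2024)
  for (i in 1:100) {
    n_u <- sample(50:500, 1)
    n_a <- sample(5:min(60, n_u %/% 2), 1)
    n_b <- sample(5:min(60, n_u %/% 2), 1)
    n_ov <- sample(0:min(n_a, n_b), 1)
    frac <- stats::runif(1)
    g <- gen_disease_tables(n_u, n_a, n_b, n_ov, frac, seed = i)
    rec <- match_tables(g$table_a, calls_from_table(g$table_b))
    sm <- summarize_concordance(rec)
    expect_equal(sm$n_matched, sm$n_same + sm$n_opposite + sm$n_inconsistent_b)
    expect_equal(sm$n_same, sm$n_same_up + sm$n_same_down)
    expect_equal(sm$n_a_only, n_a - sm$n_matched)
    expect_equal(sm$n_matched, n_ov)
    expect_equal(sm$n_same, round(frac * n_ov))
  }
})

test_that("flipping table-A directions swaps same and opposite but preserves matching", {
  g <- gen_disease_tables(400, 60, 60, 30, 0.6, seed = 13)
  flip <- g$table_a
  flip$direction <- ifelse(flip$direction == "up", "down", "up")
  flip$log2fc <- -flip$log2fc
  s1 <- summarize_concordance(match_tables(g$table_a, calls_from_table(g$table_b)))
  s2 <- summarize_concordance(match_tables(flip, calls_from_table(g$table_b)))
  expect_equal(s2$n_matched, s1$n_matched)
  expect_equal(s2$n_same, s1$n_opposite)
  expect_equal(s2$n_opposite, s1$n_same)
})

test_that("annotation flags reference-set membership with exact overlap counts", {
  g <- gen_disease_tables(500, 40, 40, 20, 0.5, seed = 21)
  rec <- match_tables(g$table_a, calls_from_table(g$table_b))
  all_a <- g$table_a[, c("uniprot", "gene")]
  disjoint <- tibble::tibble(uniprot = sprintf("X%03d", 1:10),
                             gene = sprintf("ZZ%03d", 1:10))
  planted9 <- all_a[1:9, ]
  ann <- annotate_sets(rec, list(all = all_a, none = disjoint, nine = planted9))
  expect_true(all(ann$in_all))
  expect_false(any(ann$in_none))
  counts <- attr(ann, "overlap_counts")
  expect_equal(unname(counts["all"]), 40L)
  expect_equal(unname(counts["none"]), 0L)
  expect_equal(unname(counts["nine"]), 9L)
})
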