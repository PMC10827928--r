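#' Match two differential tables and classify directional concordance
#'
#' Every record of the anchor table `a` is matched against the consistency
#' calls of the comparison dataset using dual-identifier matching (accession
#' first, then gene symbol; see [keys_match()]) and classified:
#'
#' * `same_up` / `same_down` — significantly altered in the same direction
#'   in both diseases;
#' * `opposite` — altered in opposite directions;
#' * `inconsistent_b` — matched, but the comparison evidence is internally
#'   inconsistent so no direction can be assigned;
#' * `a_only` — no match in the comparison dataset.
#'
#' Several anchor records may match the same comparison protein; each
#' receives that protein's call (set semantics).
#'
#' @param a Anchor differential table (tibble with `uniprot`, `gene`,
#'   `direction`).
#' @param b_calls Per-protein consistency calls for the comparison dataset,
#'   as returned by [call_table()] (columns `uniprot`, `gene`, `call`,
#'   `score`).
#' @return A tibble with one row per anchor record: key columns, `dir_a`,
#'   `call_b`, `score_b`, `category`.
#' @export
match_tables <- function(a, b_calls) {
  stopifnot(all(c("uniprot", "gene", "direction") %in% names(a)),
            all(c("uniprot", "gene", "call") %in% names(b_calls)))
  idx <- match_key_indices(a, b_calls)
  call_b <- ifelse(is.na(idx), NA_character_, b_calls$call[idx])
  score_b <- if ("score" %in% names(b_calls)) {
    ifelse(is.na(idx), NA_integer_, b_calls$score[idx])
  } else NA_integer_
  category <- dplyr::case_when(
    is.na(call_b) ~ "a_only",
    call_b == "inconsistent" ~ "inconsistent_b",
    a$direction == "up" & call_b == "increased" ~ "same_up",
    a$direction == "down" & call_b == "decreased" ~ "same_down",
    TRUE ~ "opposite"
  )
  tibble::tibble(
    uniprot = a$uniprot, gene = a$gene,
    dir_a = a$direction, call_b = call_b, score_b = score_b,
    category = category
  )
}

#' Annotate concordance records against reference protein sets
#'
#' Adds one logical column `in_<name>` per reference set, flagging records
#' whose key matches any member of the set (dual-identifier matching).
#'
#' @param records Output of [match_tables()].
#' @param reference_sets A named list of key tibbles (columns `uniprot`,
#'   `gene`), e.g. from [read_reference_set()]; names default to each set's
#'   `name` attribute.
#' @return `records` with annotation columns appended; per-set overlap
#'   counts are stored in the `overlap_counts` attribute.
#' @export
annotate_sets <- function(records, reference_sets) {
  nms <- names(reference_sets)
  if (is.null(nms)) nms <- rep("", length(reference_sets))
  counts <- integer(0)
  for (i in seq_along(reference_sets)) {
    set <- reference_sets[[i]]
    nm <- if (nzchar(nms[i])) nms[i] else attr(set, "name")
    if (is.null(nm) || !nzchar(nm)) nm <- paste0("set", i)
    hit <- !is.na(match_key_indices(records, set))
    records[[paste0("in_", nm)]] <- hit
    counts[nm] <- sum(hit)
  }
  attr(records, "overlap_counts") <- counts
  records
}

#' Summarize a concordance classification
#'
#' Category counts always partition the matched records, and reported
#' percentages use the printed-table convention (round half-up to integer
#' percent): fraction matched = matched / n anchor records; fraction
#' same-direction = same / matched.
#'
#' @param records Output of [match_tables()] (optionally annotated).
#' @return A list with counts `n_a`, `n_matched`, `n_same`, `n_same_up`,
#'   `n_same_down`, `n_opposite`, `n_inconsistent_b`, `n_a_only`, integer
#'   percentages `pct_matched`, `pct_same_of_matched`, and any per-set
#'   `overlap_counts` carried on `records`.
#' @export
summarize_concordance <- function(records) {
  cat_n <- function(x) sum(records$category == x)
  n_a <- nrow(records)
  n_same_up <- cat_n("same_up"); n_same_down <- cat_n("same_down")
  n_same <- n_same_up + n_same_down
  n_opp <- cat_n("opposite"); n_inc <- cat_n("inconsistent_b")
  n_matched <- n_same + n_opp + n_inc
  out <- list(
    n_a = n_a, n_matched = n_matched,
    n_same = n_same, n_same_up = n_same_up, n_same_down = n_same_down,
    n_opposite = n_opp, n_inconsistent_b = n_inc,
    n_a_only = n_a - n_matched,
    pct_matched = percent_int(n_matched, n_a),
    pct_same_of_matched = percent_int(n_same, n_matched)
  )
  oc <- attr(records, "overlap_counts")
  if (!is.null(oc)) out$overlap_counts <- as.list(oc)
  out
}
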