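#' Directional-consistency call from per-study signed reports
#'
#' Given the signed reports for one protein (one `+1` per prior study that
#' found it significantly increased, one `-1` per study that found it
#' decreased), computes the consistency classification and its signed score.
#' Let `M` be the majority-direction count and `m` the minority count:
#'
#' * `m == 0`: the protein is consistently altered; call follows the
#'   unanimous direction with score `+M` (increased) or `-M` (decreased).
#' * `m == 1` and `M > 5`: a single discordant report is tolerated for
#'   strongly replicated proteins; call follows the majority with score
#'   `+/-M`.
#' * otherwise (including ties): the evidence is inconsistent; no score.
#'
#' The score magnitude counts majority-direction reports only, so its sign
#' always encodes the call.
#'
#' @param reports Numeric vector of `+1`/`-1` study reports (non-empty).
#' @return A list with elements `call` (`"increased"`, `"decreased"` or
#'   `"inconsistent"`) and `score` (signed integer, `NA` iff inconsistent).
#' @examples
#' score_reports(c(1, 1, 1))            # increased, +3
#' score_reports(c(1, 1, 1, 1, 1, 1, 1, -1))  # increased, +7
#' score_reports(c(1, -1))              # inconsistent
#' @export
score_reports <- function(reports) {
  if (length(reports) == 0) abort_param("report vector is empty")
  if (!all(reports %in% c(-1, 1))) {
    abort_validation("reports must be +1 or -1")
  }
  n_up <- sum(reports == 1)
  n_down <- sum(reports == -1)
  M <- max(n_up, n_down)
  m <- min(n_up, n_down)
  if (m == 0 || (m == 1 && M > 5)) {
    if (n_up > n_down) list(call = "increased", score = M)
    else list(call = "decreased", score = -M)
  } else {
    list(call = "inconsistent", score = NA_integer_)
  }
}

#' Consistency calls for a whole report set
#'
#' Applies [score_reports()] to every protein of a long-format report table
#' and logs the summary counts.
#'
#' @param reports A tibble with columns `uniprot`, `gene`, `sign` (one row
#'   per study report), e.g. from [gen_study_reports()].
#' @return A tibble with one row per protein: `uniprot`, `gene`, `n_reports`,
#'   `call`, `score`.
#' @export
call_table <- function(reports) {
  stopifnot(all(c("uniprot", "gene", "sign") %in% names(reports)))
  out <- reports |>
    dplyr::group_by(.data$uniprot, .data$gene) |>
    dplyr::summarise(
      n_reports = dplyr::n(),
      res = list(tryCatch(
        score_reports(.data$sign),
        error = function(e) {
          rlang::abort(sprintf("protein %s/%s: %s", .data$uniprot[1],
                               .data$gene[1], conditionMessage(e)),
                       parent = e)
        }
      )),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      call = purrr::map_chr(.data$res, "call"),
      score = purrr::map_int(.data$res, ~ as.integer(.x$score))
    ) |>
    dplyr::select(-"res")
  counts <- table(factor(out$call, levels = c("increased", "decreased", "inconsistent")))
  message(sprintf("consistency calls: %d increased, %d decreased, %d inconsistent",
                  counts[["increased"]], counts[["decreased"]], counts[["inconsistent"]]))
  out
}
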