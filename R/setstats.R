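#' Hypergeometric upper-tail probability
#'
#' Probability of observing `k` or more query hits in a term of size `K`
#' when `n` items are drawn without replacement from a universe of size `N`:
#' the one-sided (enrichment) Fisher's exact p-value for the corresponding
#' 2x2 table. Computed with the numerically stable log-space routine
#' underlying [stats::phyper()].
#'
#' @param k Observed overlap (hits).
#' @param K Term / set size in the universe.
#' @param n Query size.
#' @param N Universe size.
#' @return Upper-tail probability in (0, 1]; exactly 1 when `k == 0`.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  ok <- k >= 0 & K >= 0 & n >= 0 & K <= N & n <= N & k <= pmin(K, n) &
    k >= pmax(0, K + n - N)
  if (!all(ok)) {
    abort_param("impossible 2x2 table: need 0 <= k <= min(K, n), K,n <= N, k >= K+n-N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Set-overlap enrichment test
#'
#' One-sided Fisher's exact test (hypergeometric upper tail) for the overlap
#' of two sets within an explicit universe. Elements outside the universe
#' are dropped with a warning. The odds ratio comes from the 2x2 table,
#' with a Haldane 0.5 continuity correction applied only when some cell
#' is zero.
#'
#' @param set_a,set_b Character vectors (or key tibbles, which are collapsed
#'   to their non-empty accession else gene identifier).
#' @param universe Character vector defining the background; must be
#'   non-empty.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return A list: `n_universe`, `n_set_a`, `n_set_b`, `n_overlap`,
#'   `odds_ratio`, `p`.
#' @export
overlap_test <- function(set_a, set_b, universe, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  as_ids <- function(x) {
    if (is.data.frame(x)) x <- ifelse(nzchar(x$uniprot), x$uniprot, x$gene)
    unique(as.character(x))
  }
  universe <- as_ids(universe)
  if (length(universe) == 0) abort_param("universe is empty")
  a <- as_ids(set_a); b <- as_ids(set_b)
  drop_a <- setdiff(a, universe); drop_b <- setdiff(b, universe)
  if (length(drop_a) || length(drop_b)) {
    warning(sprintf("%d set_a and %d set_b element(s) outside the universe were dropped",
                    length(drop_a), length(drop_b)))
    a <- intersect(a, universe); b <- intersect(b, universe)
  }
  N <- length(universe)
  k <- length(intersect(a, b))
  tab <- c(k, length(a) - k, length(b) - k, N - length(a) - length(b) + k)
  h <- if (any(tab == 0)) 0.5 else 0
  odds <- ((tab[1] + h) * (tab[4] + h)) / ((tab[2] + h) * (tab[3] + h))
  p <- if (alternative == "greater") {
    hypergeom_upper(k, length(b), length(a), N)
  } else {
    stats::fisher.test(matrix(tab, 2), alternative = "two.sided")$p.value
  }
  list(n_universe = N, n_set_a = length(a), n_set_b = length(b),
       n_overlap = k, odds_ratio = odds, p = p)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values, preserving input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort_validation("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Over-representation analysis against an annotation collection
#'
#' For each annotation term with at least one query hit, tests enrichment of
#' the query set with the hypergeometric upper tail, then adjusts across all
#' tested terms with Benjamini-Hochberg. Annotations are assumed
#' pre-propagated; terms are restricted to the universe before testing.
#'
#' @param query Character vector of query identifiers (must intersect the
#'   universe).
#' @param annotation Named list mapping term name to a character vector of
#'   member identifiers, e.g. from [read_annotation()].
#' @param universe Background identifier vector.
#' @param q_cutoff Report only terms with q below this value (default 0.05;
#'   `Inf` disables filtering).
#' @param min_hits Minimum query hits `k` for a term to be reported
#'   (filtering happens after BH adjustment, so `m` is unchanged).
#' @param top_n Optionally keep only the first `top_n` terms after sorting
#'   by q then descending fold enrichment.
#' @return A tibble: `term`, `k`, `K`, `n`, `N`, `fold_enrichment`, `p`, `q`.
#' @export
run_ora <- function(query, annotation, universe, q_cutoff = 0.05,
                    min_hits = 1, top_n = NULL) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) abort_param("universe is empty")
  query <- intersect(unique(as.character(query)), universe)
  if (length(query) == 0) abort_param("query outside background")
  n <- length(query); N <- length(universe)
  rows <- purrr::imap(annotation, function(members, term) {
    members <- intersect(unique(as.character(members)), universe)
    k <- length(intersect(query, members))
    if (k == 0) return(NULL)
    K <- length(members)
    tibble::tibble(term = term, k = k, K = K, n = n, N = N,
                   fold_enrichment = (k / n) / (K / N),
                   p = hypergeom_upper(k, K, n, N))
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0) return(res)
  res$q <- bh_adjust(res$p)
  res <- res[res$q < q_cutoff & res$k >= min_hits, ]
  res <- res[order(res$q, -res$fold_enrichment), ]
  if (!is.null(top_n)) res <- utils::head(res, top_n)
  res
}

#' Read an annotation collection (GMT or two-column TSV)
#'
#' GMT: one term per line, `term<TAB>description<TAB>member...`. Two-column
#' TSV: header `term`, `id` (or any two columns, first = term, second =
#' member identifier).
#'
#' @param path Input file; `.gmt` extension selects the GMT parser.
#' @return Named list of character vectors.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort_param(sprintf("file not found: %s", path))
  if (tolower(tools::file_ext(path)) == "gmt") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    stats::setNames(lapply(parts, function(x) unique(x[-(1:2)])),
                    vapply(parts, `[`, "", 1))
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (ncol(df) < 2) abort_param("two-column annotation file expected")
    split(as.character(df[[2]]), as.character(df[[1]]))
  }
}

#' Scan candidate universe sizes for an overlap p-value
#'
#' When the background used for a published Fisher overlap p-value is not
#' stated, this utility reports the upper-tail p obtained under each
#' candidate universe size, so the reproducing background can be identified
#' rather than asserted.
#'
#' @param k,K,n Overlap, set size, query size (as in [hypergeom_upper()]).
#' @param candidates Integer vector of universe sizes to try.
#' @return A tibble: `N`, `p`.
#' @export
scan_universe <- function(k, K, n, candidates) {
  tibble::tibble(
    N = as.integer(candidates),
    p = vapply(candidates, function(N) hypergeom_upper(k, K, n, N), 0)
  )
}
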