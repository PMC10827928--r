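# Supplement-scale synthetic scenario: a full cross-disease comparison
# with planted structure, for end-to-end pipeline exercise at the scale of
# a real epilepsy-vs-AD study. All tables are synthetic; the planted
# parameters (defaults below) define the simulated study conditions.

plant_report_vector <- function(call, n, exception) {
  if (call == "inconsistent") {
    n <- max(n, 2L)
    m <- n %/% 2L
    sample(c(rep(1, n - m), rep(-1, m)))
  } else {
    sgn <- if (call == "increased") 1 else -1
    s <- rep(sgn, n)
    if (exception && n >= 7) s[n] <- -sgn
    sample(s)
  }
}

#' Simulate a full cross-disease proteomic comparison study
#'
#' Generates, with known ground truth, every input of the concordance
#' pipeline at the scale of a hippocampal epilepsy-versus-advanced-AD
#' comparison: an anchor differential table (disease A), a multi-study
#' signed-report set for the comparison disease (B), six curated reference
#' protein sets with planted overlaps, and an identifier universe for
#' enrichment testing. Defaults plant the published study conditions:
#' 777 anchor proteins of which 689 match a 4743-protein comparison table
#' (251 down + 89 up concordant, 86 + 130 opposite, 133 matching
#' inconsistent evidence), reference overlaps 9 (causative genes, of a
#' 45-gene set), 55/125 (pTau interactors; 42 down + 13 up in A), 161/511
#' (total-tau interactors; 116 down + 45 up), 40/300 (plaque-enriched),
#' 41/192 (CAA-enriched) and 13/54 (NFT-enriched), inside a 5311-protein
#' universe.
#'
#' A small fraction of matched pairs are constructed to match only via
#' gene symbol (the B-side accession differs) and a few anchor records
#' carry an accession but no gene symbol, so the dual-identifier rule is
#' exercised.
#'
#' @param seed Integer RNG seed.
#' @param counts Named list of planted category counts: `n_a`, `same_down`,
#'   `same_up`, `opp_down`, `opp_up`, `inconsistent`, `n_b`, `n_universe`.
#' @param ref_sets Named list of reference-set plans, each
#'   `list(size =, hits_down =, hits_up =)` (hits are drawn from anchor
#'   proteins with the given direction; `hits_same_down`/`hits_same_up`
#'   restrict draws to concordant categories).
#' @param gene_match_frac Fraction of matched pairs forced to match via
#'   gene symbol only.
#' @param acc_only_frac Fraction of anchor records lacking a gene symbol.
#' @return A list: `table_a`, `reports_b` (long report tibble for
#'   [call_table()]), `reference_sets`, `universe` (accession vector),
#'   `answer_key` (planted category per anchor record plus expected
#'   summary and overlap counts), `params`.
#' @export
simulate_cross_disease_study <- function(
    seed,
    counts = list(n_a = 777, same_down = 251, same_up = 89,
                  opp_down = 86, opp_up = 130, inconsistent = 133,
                  n_b = 4743, n_universe = 5311),
    ref_sets = list(
      causative_genes = list(size = 45, hits_same_down = 8, hits_same_up = 1),
      ptau_interactors = list(size = 125, hits_down = 42, hits_up = 13),
      total_tau_interactors = list(size = 511, hits_down = 116, hits_up = 45),
      plaque_enriched = list(size = 300, hits_down = 25, hits_up = 15),
      caa_enriched = list(size = 192, hits_down = 26, hits_up = 15),
      nft_enriched = list(size = 54, hits_down = 8, hits_up = 5)),
    gene_match_frac = 0.05, acc_only_frac = 0.02) {
  n_matched <- with(counts, same_down + same_up + opp_down + opp_up + inconsistent)
  n_a_only <- counts$n_a - n_matched
  n_b_only <- counts$n_b - n_matched
  n_extra <- counts$n_universe - counts$n_a - n_b_only
  if (n_a_only < 0 || n_b_only < 0 || n_extra < 0) {
    abort_param("inconsistent planted counts: categories exceed table or universe sizes")
  }
  local_seed(seed, {
    idx_matched <- seq_len(n_matched)
    idx_a_only <- n_matched + seq_len(n_a_only)
    idx_b_only <- counts$n_a + seq_len(n_b_only)
    idx_extra <- counts$n_a + n_b_only + seq_len(n_extra)

    category <- sample(rep(c("same_down", "same_up", "opposite_down", "opposite_up",
                             "inconsistent_b"),
                           times = with(counts, c(same_down, same_up, opp_down,
                                                  opp_up, inconsistent))))
    dir_a_matched <- dplyr::case_when(
      category %in% c("same_down", "opposite_down") ~ "down",
      category %in% c("same_up", "opposite_up") ~ "up",
      TRUE ~ sample(c("up", "down"), n_matched, replace = TRUE))
    call_b_matched <- dplyr::case_when(
      category == "same_down" ~ "decreased",
      category == "same_up" ~ "increased",
      category == "opposite_down" ~ "increased",
      category == "opposite_up" ~ "decreased",
      TRUE ~ "inconsistent")

    keys_a <- make_keys(c(idx_matched, idx_a_only))
    dir_a <- c(dir_a_matched, sample(c("up", "down"), n_a_only, replace = TRUE))
    # a few anchor records carry no gene symbol (accession-only matching)
    acc_only <- stats::runif(counts$n_a) < acc_only_frac
    keys_a$gene[acc_only] <- ""
    table_a <- tibble::tibble(
      uniprot = keys_a$uniprot, gene = keys_a$gene,
      log2fc = rand_log2fc(dir_a), direction = dir_a, significant = TRUE)

    # comparison-side keys: a fraction matches via gene symbol only,
    # but never for anchor records that lost their gene symbol
    keys_b_matched <- make_keys(idx_matched)
    gene_match <- stats::runif(n_matched) < gene_match_frac & !acc_only[idx_matched]
    keys_b_matched$uniprot[gene_match] <- sprintf("Q%05d", idx_matched[gene_match])
    keys_b <- dplyr::bind_rows(keys_b_matched, make_keys(idx_b_only))
    call_b <- c(call_b_matched,
                sample(c("increased", "decreased", "inconsistent"), n_b_only,
                       replace = TRUE, prob = c(0.45, 0.45, 0.10)))
    n_rep <- sample(1:12, counts$n_b, replace = TRUE)
    exception <- stats::runif(counts$n_b) < 0.3
    signs <- lapply(seq_len(counts$n_b), function(i) {
      plant_report_vector(call_b[i], n_rep[i], exception[i])
    })
    n_rep_eff <- lengths(signs)
    reports_b <- tibble::tibble(
      uniprot = rep(keys_b$uniprot, n_rep_eff),
      gene = rep(keys_b$gene, n_rep_eff),
      study = unlist(lapply(n_rep_eff, seq_len)),
      sign = unlist(signs))

    # reference sets: hits drawn from anchor records, fillers from the
    # non-anchor part of the universe
    a_cat <- c(category, rep("a_only", n_a_only))
    pool_down <- which(dir_a == "down")
    pool_up <- which(dir_a == "up")
    pool_same_down <- which(a_cat == "same_down")
    pool_same_up <- which(a_cat == "same_up")
    filler_pool <- c(idx_b_only, idx_extra)
    reference_sets <- list()
    planted_overlap <- integer(0)
    for (nm in names(ref_sets)) {
      plan <- ref_sets[[nm]]
      hit_rows <- c(
        if (!is.null(plan$hits_same_down)) sample(pool_same_down, plan$hits_same_down),
        if (!is.null(plan$hits_same_up)) sample(pool_same_up, plan$hits_same_up),
        if (!is.null(plan$hits_down)) sample(pool_down, plan$hits_down),
        if (!is.null(plan$hits_up)) sample(pool_up, plan$hits_up))
      n_fill <- plan$size - length(hit_rows)
      if (n_fill < 0) abort_param(sprintf("reference set '%s': more hits than members", nm))
      fill_idx <- sample(filler_pool, n_fill)
      set <- dplyr::bind_rows(
        tibble::tibble(uniprot = table_a$uniprot[hit_rows],
                       gene = table_a$gene[hit_rows]),
        make_keys(fill_idx))
      attr(set, "name") <- nm
      reference_sets[[nm]] <- set
      planted_overlap[nm] <- length(hit_rows)
    }

    universe <- sprintf("P%05d", seq_len(counts$n_universe))
    answer_key <- list(
      records = tibble::tibble(
        uniprot = table_a$uniprot, gene = table_a$gene, dir_a = dir_a,
        category = sub("^opposite_(up|down)$", "opposite", a_cat)),
      summary = list(
        n_a = counts$n_a, n_matched = n_matched,
        n_same = counts$same_down + counts$same_up,
        n_same_down = counts$same_down, n_same_up = counts$same_up,
        n_opposite = counts$opp_down + counts$opp_up,
        n_inconsistent_b = counts$inconsistent, n_a_only = n_a_only),
      overlap_counts = as.list(planted_overlap))
    list(table_a = table_a, reports_b = reports_b,
         reference_sets = reference_sets, universe = universe,
         answer_key = answer_key,
         params = list(seed = seed, counts = counts, ref_sets = ref_sets))
  })
}
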