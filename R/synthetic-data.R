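# Synthetic-data generators. Every generator is a pure function of
# (parameters, seed) and emits an answer key sufficient to assert the
# downstream stage output exactly.

make_keys <- function(idx) {
  tibble::tibble(uniprot = sprintf("P%05d", idx),
                 gene = sprintf("G%05d", idx))
}

rand_log2fc <- function(direction) {
  ifelse(direction == "up", 1, -1) * stats::runif(length(direction), 0.3, 2.0)
}

#' Generate a pair of differential tables with planted concordance
#'
#' Builds two disease tables over a shared protein universe: exactly
#' `n_overlap` proteins appear in both, and among those,
#' `round(frac_same_direction * n_overlap)` have the same direction in both
#' tables (the rest are opposite). Effect sizes are drawn as
#' `sign * Uniform(0.3, 2)` log2 fold-changes.
#'
#' @param n_universe Size of the simulated protein universe.
#' @param n_a,n_b Table sizes.
#' @param n_overlap Planted shared proteins (`<= min(n_a, n_b)`).
#' @param frac_same_direction Fraction of shared proteins concordant in
#'   direction, in `[0, 1]`.
#' @param seed Integer RNG seed (generator is deterministic given it).
#' @param out_dir If given, writes `table_a.tsv`, `table_b.tsv` and
#'   `answer_key.json` there.
#' @return A list: `table_a`, `table_b` (canonical diff-table tibbles),
#'   `answer_key` (tibble with planted membership, directions and
#'   concordance category per universe protein involved).
#' @export
gen_disease_tables <- function(n_universe, n_a, n_b, n_overlap,
                               frac_same_direction, seed, out_dir = NULL) {
  if (!(n_overlap <= min(n_a, n_b) && min(n_a, n_b) <= n_universe &&
        n_a + n_b - n_overlap <= n_universe)) {
    abort_param("need n_overlap <= min(n_a, n_b) and n_a + n_b - n_overlap <= n_universe")
  }
  if (frac_same_direction < 0 || frac_same_direction > 1) {
    abort_param("frac_same_direction must be in [0, 1]")
  }
  local_seed(seed, {
    idx <- sample.int(n_universe, n_a + n_b - n_overlap)
    shared <- idx[seq_len(n_overlap)]
    a_only <- idx[n_overlap + seq_len(n_a - n_overlap)]
    b_only <- idx[(n_a) + seq_len(n_b - n_overlap)]
    n_same <- round(frac_same_direction * n_overlap)
    same_flag <- rep(FALSE, n_overlap)
    if (n_overlap > 0) same_flag[sample.int(n_overlap, n_same)] <- TRUE

    dir_a_shared <- sample(c("up", "down"), n_overlap, replace = TRUE)
    dir_b_shared <- ifelse(same_flag, dir_a_shared,
                           ifelse(dir_a_shared == "up", "down", "up"))
    dir_a_only <- sample(c("up", "down"), length(a_only), replace = TRUE)
    dir_b_only <- sample(c("up", "down"), length(b_only), replace = TRUE)

    mk_tbl <- function(idx, dirs) {
      k <- make_keys(idx)
      tibble::tibble(uniprot = k$uniprot, gene = k$gene,
                     log2fc = rand_log2fc(dirs), direction = dirs,
                     significant = TRUE)
    }
    table_a <- mk_tbl(c(shared, a_only), c(dir_a_shared, dir_a_only))
    table_b <- mk_tbl(c(shared, b_only), c(dir_b_shared, dir_b_only))

    key_all <- make_keys(c(shared, a_only, b_only))
    answer_key <- tibble::tibble(
      uniprot = key_all$uniprot, gene = key_all$gene,
      in_a = c(rep(TRUE, n_overlap + length(a_only)), rep(FALSE, length(b_only))),
      in_b = c(rep(TRUE, n_overlap), rep(FALSE, length(a_only)), rep(TRUE, length(b_only))),
      dir_a = c(dir_a_shared, dir_a_only, rep(NA_character_, length(b_only))),
      dir_b = c(dir_b_shared, rep(NA_character_, length(a_only)), dir_b_only),
      category = c(
        ifelse(same_flag, ifelse(dir_a_shared == "up", "same_up", "same_down"),
               "opposite"),
        rep("a_only", length(a_only)), rep("b_only", length(b_only)))
    )
    out <- list(table_a = table_a, table_b = table_b, answer_key = answer_key)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_diff_table(table_a, file.path(out_dir, "table_a.tsv"))
      write_diff_table(table_b, file.path(out_dir, "table_b.tsv"))
      jsonlite::write_json(answer_key, file.path(out_dir, "answer_key.json"),
                           dataframe = "rows")
    }
    out
  })
}

#' Generate multi-study signed report vectors with known consistency class
#'
#' Emulates per-study evidence vectors: each protein gets `+1`/`-1` reports
#' from a planted class. Consistent proteins are unanimous, except that
#' (when the report count allows a majority above 5) some carry one
#' tolerated discordant report; inconsistent proteins are built to violate
#' the consistency rule (tie, minority >= 2, or minority = 1 with majority
#' <= 5).
#'
#' @param n_proteins Number of proteins.
#' @param report_count_range Integer range (within 1-50) for per-protein
#'   report counts.
#' @param inconsistency_rate Fraction of proteins planted inconsistent.
#' @param seed Integer RNG seed.
#' @param exception_rate Among consistent proteins with enough reports,
#'   probability of carrying one tolerated discordant report.
#' @return A list: `reports` (long tibble `uniprot`, `gene`, `study`,
#'   `sign`), `answer_key` (tibble `uniprot`, `gene`, `call`, `score`).
#' @export
gen_study_reports <- function(n_proteins, report_count_range = c(1, 12),
                              inconsistency_rate = 0.2, seed,
                              exception_rate = 0.3) {
  if (report_count_range[1] < 1 || report_count_range[2] > 50 ||
      report_count_range[1] > report_count_range[2]) {
    abort_param("report_count_range must lie within [1, 50]")
  }
  if (inconsistency_rate < 0 || inconsistency_rate > 1) {
    abort_param("inconsistency_rate must be in [0, 1]")
  }
  local_seed(seed, {
    keys <- make_keys(seq_len(n_proteins))
    n_rep <- sample(seq(report_count_range[1], report_count_range[2]),
                    n_proteins, replace = TRUE)
    planted <- ifelse(stats::runif(n_proteins) < inconsistency_rate,
                      "inconsistent",
                      sample(c("increased", "decreased"), n_proteins, replace = TRUE))
    # inconsistency needs at least two reports
    n_rep[planted == "inconsistent" & n_rep < 2] <- 2L

    signs <- vector("list", n_proteins)
    score <- integer(n_proteins)
    for (i in seq_len(n_proteins)) {
      n <- n_rep[i]
      if (planted[i] == "inconsistent") {
        m <- n %/% 2                       # floor(n/2): tie or minority >= 2
        s <- c(rep(1, n - m), rep(-1, m))  # (or minority 1 with majority <= 5)
        score[i] <- NA_integer_
      } else {
        sgn <- if (planted[i] == "increased") 1 else -1
        flip <- n >= 7 && stats::runif(1) < exception_rate
        s <- rep(sgn, n)
        if (flip) s[n] <- -sgn
        score[i] <- sgn * (n - as.integer(flip))
      }
      signs[[i]] <- sample(s)
    }
    reports <- tibble::tibble(
      uniprot = rep(keys$uniprot, n_rep), gene = rep(keys$gene, n_rep),
      study = unlist(lapply(n_rep, seq_len)), sign = unlist(signs))
    answer_key <- tibble::tibble(uniprot = keys$uniprot, gene = keys$gene,
                                 call = planted, score = score)
    list(reports = reports, answer_key = answer_key)
  })
}

#' Generate an abundance matrix with planted co-expression modules
#'
#' Each planted module is driven by a shared latent profile: member
#' profiles are `sqrt(w) * latent + sqrt(1-w) * noise_sd * N(0,1)` with
#' `w = within_module_cor`, so for `noise_sd = 1` the expected pairwise
#' correlation inside a module is `w` (and exactly 1 in the noiseless
#' limit). Proteins beyond the planted modules are independent noise. The
#' trait is `trait_cor * latent[trait_module] + sqrt(1-trait_cor^2) * N(0,1)`.
#'
#' @param n_proteins Total proteins (rows).
#' @param n_samples Samples (columns; >= 4).
#' @param module_sizes Integer vector of planted module sizes
#'   (`sum <= n_proteins`).
#' @param within_module_cor Target within-module correlation in `[-1, 1]`.
#' @param trait_module Index of the module whose latent drives the trait.
#' @param trait_cor Planted module-trait correlation in `[-1, 1]`.
#' @param noise_sd Residual noise scale (0 = noiseless members).
#' @param seed Integer RNG seed.
#' @return A list: `matrix` (proteins x samples, named), `trait` (length
#'   `n_samples`), `answer_key` (tibble `protein`, `module`; 0 =
#'   background).
#' @export
gen_expression <- function(n_proteins, n_samples, module_sizes,
                           within_module_cor = 0.8, trait_module = 1,
                           trait_cor = 0.9, noise_sd = 1, seed) {
  if (n_samples < 4) abort_param("n_samples must be >= 4 (correlation p-values undefined below)")
  if (sum(module_sizes) > n_proteins) abort_param("sum(module_sizes) must be <= n_proteins")
  if (abs(within_module_cor) > 1 || abs(trait_cor) > 1) {
    abort_param("correlations must lie in [-1, 1]")
  }
  if (trait_module < 1 || trait_module > length(module_sizes)) {
    abort_param("trait_module out of range")
  }
  local_seed(seed, {
    w <- within_module_cor
    latents <- matrix(stats::rnorm(length(module_sizes) * n_samples),
                      length(module_sizes), n_samples)
    labels <- rep(0L, n_proteins)
    m <- matrix(stats::rnorm(n_proteins * n_samples, sd = 1), n_proteins, n_samples)
    row <- 1L
    for (j in seq_along(module_sizes)) {
      rows <- row:(row + module_sizes[j] - 1L)
      eps <- matrix(stats::rnorm(length(rows) * n_samples), length(rows), n_samples)
      m[rows, ] <- sqrt(w) * matrix(latents[j, ], length(rows), n_samples, byrow = TRUE) +
        sqrt(1 - w) * noise_sd * eps
      labels[rows] <- j
      row <- row + module_sizes[j]
    }
    trait <- trait_cor * latents[trait_module, ] +
      sqrt(1 - trait_cor^2) * stats::rnorm(n_samples)
    rownames(m) <- sprintf("PROT%04d", seq_len(n_proteins))
    colnames(m) <- sprintf("S%02d", seq_len(n_samples))
    names(trait) <- colnames(m)
    list(matrix = m, trait = trait,
         answer_key = tibble::tibble(protein = rownames(m), module = labels))
  })
}

#' Generate a flat-color stain image with a known positive-pixel fraction
#'
#' Paints exactly `round(positive_fraction * n_roi)` ROI pixels in the
#' positive (DAB-brown-like) color over a negative (hematoxylin-blue-like)
#' background, optionally with bounded RGB jitter (truncated at +/- 6 so
#' pixel classification under the default [ppc_config()] is unchanged).
#'
#' @param width,height Image size in pixels.
#' @param positive_fraction Fraction of ROI pixels painted positive, in
#'   `[0, 1]`.
#' @param roi_mask Logical height x width mask (default: whole image).
#' @param positive_color,negative_color RGB triples in 0-255 (must differ).
#' @param jitter_sd Gaussian RGB jitter SD (0 = flat color).
#' @param seed Integer RNG seed.
#' @param out_png,out_mask Optional paths; PNG files are written if given.
#' @return A list: `image` (height x width x 3 array, 0-255), `roi_mask`,
#'   `answer_key` (list with `n_roi`, `n_positive`, `percent_positive`).
#' @export
gen_stain_image <- function(width, height, positive_fraction, roi_mask = NULL,
                            positive_color = c(120, 70, 20),
                            negative_color = c(70, 70, 190),
                            jitter_sd = 0, seed,
                            out_png = NULL, out_mask = NULL) {
  if (positive_fraction < 0 || positive_fraction > 1) {
    abort_param("positive_fraction must be in [0, 1]")
  }
  if (all(positive_color == negative_color)) abort_param("colors must be distinct")
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, height, width)
  if (!any(roi_mask)) abort_param("ROI is empty")
  stopifnot(all(dim(roi_mask) == c(height, width)))
  local_seed(seed, {
    img <- array(rep(negative_color, each = height * width), c(height, width, 3))
    roi_idx <- which(roi_mask)
    n_pos <- round(positive_fraction * length(roi_idx))
    pos_idx <- if (n_pos > 0) sample(roi_idx, n_pos) else integer(0)
    npix <- height * width
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[pos_idx] <- positive_color[ch]
      if (jitter_sd > 0) {
        jit <- pmax(pmin(stats::rnorm(npix, sd = jitter_sd), 6), -6)
        plane <- pmax(pmin(plane + jit, 255), 0)
      }
      img[, , ch] <- plane
    }
    key <- list(n_roi = length(roi_idx), n_positive = n_pos,
                percent_positive = 100 * n_pos / length(roi_idx))
    if (!is.null(out_png)) png::writePNG(img / 255, out_png)
    if (!is.null(out_mask)) png::writePNG(matrix(as.numeric(roi_mask), height, width), out_mask)
    list(image = img, roi_mask = roi_mask, answer_key = key)
  })
}
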