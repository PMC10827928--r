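# Weighted co-expression network analysis: soft thresholding, adjacency,
# topological overlap, module detection, eigenproteins, trait correlation.

# Pearson correlation across rows of a proteins x samples matrix,
# pairwise-complete to tolerate scattered missing values.
row_cor <- function(m) {
  stats::cor(t(m), use = "pairwise.complete.obs")
}

filter_matrix <- function(m, max_missing = 0.3) {
  miss <- rowMeans(is.na(m))
  drop_miss <- miss > max_missing
  v <- apply(m, 1, stats::var, na.rm = TRUE)
  drop_const <- is.na(v) | v == 0
  drop <- drop_miss | drop_const
  if (any(drop)) {
    warning(sprintf("dropping %d protein(s): %d with >%d%% missing, %d constant",
                    sum(drop), sum(drop_miss), round(100 * max_missing),
                    sum(drop_const & !drop_miss)))
  }
  m[!drop, , drop = FALSE]
}

scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) n_bins <- max(2L, length(k) %/% 2L)
  # equal-width binning of connectivity; fit log10 p(k) ~ log10 k
  bin <- cut(k, breaks = n_bins, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- tapply(k, bin, length) / length(k)
  keep <- !is.na(dk) & !is.na(pk) & pk > 0
  if (sum(keep) < 3) return(list(r2 = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  list(r2 = r2, slope = unname(slope))
}

#' Soft-threshold power selection by scale-free topology fit
#'
#' For each candidate power, builds the weighted adjacency, computes each
#' protein's connectivity `k_i = sum_j a_ij` (j != i), bins `k` into
#' equal-occupancy bins, and regresses `log10 p(k)` on `log10 k`. The
#' reported fit index is `-sign(slope) * R^2`, so a scale-free (decreasing)
#' degree distribution scores positively. The chosen power is the smallest
#' with fit index >= `r2_target`; if none reaches the target, the maximizing
#' power is returned with a warning.
#'
#' @param m Proteins x samples abundance matrix.
#' @param powers Candidate integer powers (default 1:20).
#' @param r2_target Scale-free fit target (default 0.8).
#' @param signed Use the signed adjacency transform (default unsigned).
#' @return A list with `scan` (tibble: `power`, `r2`, `slope`,
#'   `mean_connectivity`) and `power` (the chosen value).
#' @export
pick_soft_threshold <- function(m, powers = 1:20, r2_target = 0.8, signed = FALSE) {
  m <- filter_matrix(m)
  if (nrow(m) < 20 || ncol(m) < 4) {
    abort_param("need at least 20 proteins and 4 samples after filtering")
  }
  cm <- row_cor(m)
  rows <- lapply(powers, function(b) {
    a <- adjacency_from_cor(cm, b, signed)
    k <- rowSums(a) - 1
    f <- scale_free_fit(k)
    tibble::tibble(power = b,
                   r2 = if (is.na(f$r2)) NA_real_ else -sign(f$slope) * f$r2,
                   slope = f$slope, mean_connectivity = mean(k))
  })
  scan <- dplyr::bind_rows(rows)
  ok <- which(!is.na(scan$r2) & scan$r2 >= r2_target)
  if (length(ok)) {
    power <- scan$power[ok[1]]
  } else {
    power <- scan$power[which.max(scan$r2)]
    warning(sprintf(
      "no candidate power reached scale-free fit %.2f; using power %d (fit %.2f)",
      r2_target, power, max(scan$r2, na.rm = TRUE)))
  }
  list(scan = scan, power = power)
}

adjacency_from_cor <- function(cm, power, signed = FALSE) {
  a <- if (signed) ((1 + cm) / 2)^power else abs(cm)^power
  a[is.na(a)] <- 0
  diag(a) <- 1
  a
}

#' Weighted network adjacency
#'
#' Unsigned: `a_ij = |cor(i,j)|^power`; signed: `a_ij = ((1+cor)/2)^power`.
#' Diagonal is 1.
#'
#' @inheritParams pick_soft_threshold
#' @param power Soft-threshold power (>= 1).
#' @return Symmetric adjacency matrix with entries in `[0, 1]`.
#' @export
wgcna_adjacency <- function(m, power, signed = FALSE) {
  if (power < 1) abort_param("power must be >= 1")
  adjacency_from_cor(row_cor(m), power, signed)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, where the sum runs over `u` distinct from both `i` and `j` and
#' `k_i = sum_{u != i} a_iu`; the diagonal is 1. Use `1 - tom(a)` as the
#' clustering dissimilarity.
#'
#' @param a Symmetric adjacency with entries in `[0, 1]` and unit diagonal.
#' @return Symmetric TOM similarity matrix in `[0, 1]`.
#' @export
tom <- function(a) {
  if (!isSymmetric(unname(a), tol = 1e-8)) {
    abort_validation("adjacency must be symmetric")
  }
  diag(a) <- 1
  k <- rowSums(a) - 1
  # (A^2)_ij counts u = i and u = j once each as a_ij; remove both
  cross <- a %*% a - 2 * a
  num <- cross + a
  den <- outer(k, k, pmin) + 1 - a
  t_mat <- num / den
  diag(t_mat) <- 1
  t_mat <- (t_mat + t(t_mat)) / 2
  dimnames(t_mat) <- dimnames(a)
  t_mat
}

#' Module eigenproteins
#'
#' For each module, the first right singular vector of the row-standardized
#' member submatrix (the module's first principal component across samples),
#' sign-anchored so it correlates positively with the module's mean
#' standardized profile. Unassigned proteins (label 0) are skipped.
#'
#' @param m Proteins x samples matrix.
#' @param labels Integer module label per row of `m` (0 = unassigned).
#' @return Modules x samples matrix with rownames `ME<label>`.
#' @export
eigenproteins <- function(m, labels) {
  stopifnot(nrow(m) == length(labels))
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) == 0) abort_param("no modules (all labels are 0)")
  out <- matrix(NA_real_, length(mods), ncol(m),
                dimnames = list(paste0("ME", mods), colnames(m)))
  for (i in seq_along(mods)) {
    sub <- m[labels == mods[i], , drop = FALSE]
    z <- t(scale(t(sub)))
    z[is.na(z)] <- 0
    v <- svd(z, nu = 0, nv = 1)$v[, 1]
    anchor <- colMeans(z)
    if (sum(v * anchor) < 0) v <- -v
    out[i, ] <- v
  }
  out
}

#' Detect co-expression modules from a TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on the dissimilarity, cut at a
#' fixed fraction (0.995) of the tree height; clusters smaller than
#' `min_module_size` are unassigned (label 0). Modules whose eigenproteins
#' correlate above `1 - merge_cut_height` are then merged iteratively.
#' Labels are renumbered by descending module size, so module 1 is always
#' the largest.
#'
#' @param diss Square TOM dissimilarity matrix (`1 - tom(a)`).
#' @param m Proteins x samples matrix (needed for eigenprotein merging),
#'   rows aligned with `diss`.
#' @param min_module_size Smallest retained module (default 20).
#' @param merge_cut_height Eigenprotein dissimilarity below which modules
#'   merge (default 0.15, i.e. correlation > 0.85 merges).
#' @param cut_fraction Fraction of the maximum dendrogram height at which
#'   the tree is cut (default 0.995).
#' @return A list: `labels` (integer per protein), `eigenproteins`,
#'   `module_sizes` (named by label), `tree` (the hclust object).
#' @export
detect_modules <- function(diss, m, min_module_size = 20,
                           merge_cut_height = 0.15, cut_fraction = 0.995) {
  stopifnot(nrow(diss) == ncol(diss), nrow(diss) == nrow(m))
  if (nrow(diss) < min_module_size) {
    warning("fewer proteins than min_module_size; all unassigned")
    return(list(labels = rep(0L, nrow(diss)), eigenproteins = NULL,
                module_sizes = integer(0), tree = NULL))
  }
  tree <- stats::hclust(stats::as.dist(diss), method = "average")
  labels <- stats::cutree(tree, h = cut_fraction * max(tree$height))
  sizes <- table(labels)
  labels[labels %in% as.integer(names(sizes)[sizes < min_module_size])] <- 0L
  if (all(labels == 0L)) {
    warning("no cluster reached min_module_size; all unassigned")
    return(list(labels = rep(0L, nrow(diss)), eigenproteins = NULL,
                module_sizes = integer(0), tree = tree))
  }
  # iterative eigenprotein merging
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2) break
    me <- eigenproteins(m, labels)
    cc <- stats::cor(t(me))
    diag(cc) <- -Inf
    top <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (max(cc) <= 1 - merge_cut_height) break
    labels[labels == mods[top[2]]] <- mods[top[1]]
  }
  # renumber by descending size
  mods <- sort(unique(labels[labels > 0]))
  sizes <- vapply(mods, function(x) sum(labels == x), 0L)
  new_id <- integer(max(mods))
  new_id[mods[order(-sizes, mods)]] <- seq_along(mods)
  labels <- ifelse(labels > 0, new_id[labels], 0L)
  me <- eigenproteins(m, labels)
  list(labels = as.integer(labels), eigenproteins = me,
       module_sizes = stats::setNames(
         vapply(seq_along(mods), function(x) sum(labels == x), 0L),
         seq_along(mods)),
       tree = tree)
}

#' Correlate profiles with a trait
#'
#' Pearson correlation of each row profile (protein or eigenprotein) with a
#' per-sample trait, with the two-sided Student-t p-value
#' (`t = r * sqrt((n-2) / (1-r^2))` on `n-2` degrees of freedom).
#'
#' @param profiles Entities x samples matrix (or a single numeric profile).
#' @param trait Numeric vector, one value per sample; must not be constant.
#' @return A tibble: `entity`, `r`, `p`, `r2`, `n`. Constant profiles give
#'   `NA` with a warning.
#' @export
trait_correlate <- function(profiles, trait) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
  n <- ncol(profiles)
  if (n < 4) abort_param("need at least 4 samples")
  if (length(trait) != n) abort_param("trait length must equal the number of samples")
  if (stats::var(trait, na.rm = TRUE) == 0) abort_param("trait is constant")
  r <- suppressWarnings(as.vector(stats::cor(t(profiles), trait,
                                             use = "pairwise.complete.obs")))
  const <- apply(profiles, 1, function(x) stats::var(x, na.rm = TRUE) == 0)
  if (any(const)) warning(sprintf("%d constant profile(s): correlation undefined", sum(const)))
  r[const] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p <- pmin(p, 1)
  ent <- rownames(profiles)
  if (is.null(ent)) ent <- as.character(seq_len(nrow(profiles)))
  tibble::tibble(entity = ent, r = r, p = p, r2 = r^2, n = n)
}

#' Full co-expression analysis
#'
#' Convenience wrapper: filter the matrix, pick (or accept) the soft power,
#' build the unsigned/signed adjacency and TOM, detect and merge modules,
#' and correlate eigenproteins (and optionally every protein) with a trait.
#'
#' @inheritParams pick_soft_threshold
#' @param trait Per-sample trait vector, or `NULL` to skip correlation.
#' @param power Soft power; `NULL` selects it via [pick_soft_threshold()].
#' @param min_module_size,merge_cut_height Passed to [detect_modules()].
#' @param protein_trait Also report per-protein trait correlations.
#' @return A list: `power`, `scan` (if scanned), `labels`, `module_sizes`,
#'   `eigenproteins`, `module_trait` and (optionally) `protein_trait`
#'   tibbles, and `proteins` (rownames kept after filtering).
#' @export
run_wgcna <- function(m, trait = NULL, power = NULL, signed = FALSE,
                      r2_target = 0.8, min_module_size = 20,
                      merge_cut_height = 0.15, protein_trait = FALSE) {
  m <- filter_matrix(m)
  scan <- NULL
  if (is.null(power)) {
    st <- pick_soft_threshold(m, r2_target = r2_target, signed = signed)
    power <- st$power
    scan <- st$scan
  }
  a <- wgcna_adjacency(m, power, signed)
  d <- 1 - tom(a)
  mod <- detect_modules(d, m, min_module_size, merge_cut_height)
  out <- list(power = power, scan = scan, labels = mod$labels,
              module_sizes = mod$module_sizes,
              eigenproteins = mod$eigenproteins,
              proteins = rownames(m))
  if (!is.null(trait)) {
    out$module_trait <- trait_correlate(mod$eigenproteins, trait)
    if (protein_trait) out$protein_trait <- trait_correlate(m, trait)
  }
  out
}
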