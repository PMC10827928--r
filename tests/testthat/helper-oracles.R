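# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths.

# Hypergeometric upper tail by direct log-space enumeration.
oracle_hyper_upper <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Literal transcription of the consistency rule.
oracle_consistency <- function(signs) {
  n_up <- sum(signs == 1); n_down <- sum(signs == -1)
  M <- max(n_up, n_down); m <- min(n_up, n_down)
  if (m == 0) {
    if (n_up > 0) list(call = "increased", score = M) else list(call = "decreased", score = -M)
  } else if (m == 1 && M > 5) {
    if (n_up > n_down) list(call = "increased", score = M) else list(call = "decreased", score = -M)
  } else {
    list(call = "inconsistent", score = NA_integer_)
  }
}

# Straight-from-definition scalar HSI pixel classifier.
oracle_classify <- function(r, g, b, cfg) {
  tot <- r + g + b
  inten <- tot / 3
  sat <- if (tot > 0) 1 - 3 * min(r, g, b) / tot else 0
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  if (den == 0) return("negative")
  hue <- acos(min(max(0.5 * ((r - g) + (r - b)) / den, -1), 1)) / (2 * pi)
  if (b > g) hue <- 1 - hue
  d <- abs(hue - cfg$hue_center); d <- min(d, 1 - d)
  if (d > cfg$hue_width || sat < cfg$saturation_min) return("negative")
  if (inten >= cfg$i_sp_lo && inten < cfg$i_sp_hi) "strong"
  else if (inten >= cfg$i_sp_hi && inten < cfg$i_p_hi) "medium"
  else if (inten >= cfg$i_p_hi && inten < cfg$i_wp_hi) "weak"
  else "negative"
}

# Chance-corrected partition agreement (independent check for module
# recovery), via mclust.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Planted-module recovery on one synthetic expression fixture; returns the
# ARI against truth and whether the trait-driving module has the top |r|.
recover_modules <- function(seed, module_sizes = c(30, 30), n_samples = 50,
                            within_module_cor = 0.8, trait_cor = 0.9,
                            power = 4) {
  gx <- gen_expression(sum(module_sizes), n_samples, module_sizes,
                       within_module_cor = within_module_cor,
                       trait_cor = trait_cor, seed = seed)
  a <- wgcna_adjacency(gx$matrix, power)
  mod <- detect_modules(1 - tom(a), gx$matrix)
  mt <- trait_correlate(mod$eigenproteins, gx$trait)
  # the detected module holding most of the planted trait-driving proteins
  planted <- gx$answer_key$module == 1
  det <- mod$labels[planted]
  det <- det[det > 0]
  top_det <- if (length(det)) as.integer(names(which.max(table(det)))) else NA_integer_
  top_r <- mt$entity[which.max(abs(mt$r))]
  list(ari = ari(mod$labels, gx$answer_key$module),
       trait_top = identical(top_r, paste0("ME", top_det)))
}
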