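test_that("adjacency follows the unsigned/signed transforms", {
  cm <- matrix(c(1, 0.5, -0.5,
                 0.5, 1, 0.25,
                 -0.5, 0.25, 1), 3, 3)
  a <- crossproteo:::adjacency_from_cor(cm, 4, signed = FALSE)
  expect_equal(a[1, 2], 0.5^4)
  expect_equal(a[1, 3], 0.5^4)        # sign-blind
  expect_equal(diag(a), rep(1, 3))
  a1 <- crossproteo:::adjacency_from_cor(cm, 1, signed = FALSE)
  expect_equal(a1[2, 3], 0.25)        # identity power
  s <- crossproteo:::adjacency_from_cor(cm, 4, signed = TRUE)
  expect_equal(s[1, 3], ((1 - 0.5) / 2)^4)
})

test_that("tom reproduces the 3-node hand oracle and stays in [0,1]", {
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  t3 <- tom(a)
  expect_equal(t3[1, 2], 0.5)         # (0.25 + 0.5) / (1 + 1 - 0.5)
  expect_equal(diag(t3), rep(1, 3))
  # no edges: off-diagonal overlap 0
  t0 <- tom(diag(4))
  expect_equal(t0[lower.tri(t0)], rep(0, 6))
  # property: random adjacencies give symmetric TOM with entries in [0,1]
  set.seed(5)
  for (i in 1:20) {
    n <- sample(5:25, 1)
    r <- matrix(stats::runif(n * n), n)
    a <- (r + t(r)) / 2; diag(a) <- 1
    tm <- tom(a)
    expect_true(isSymmetric(tm, tol = 1e-12))
    expect_true(all(tm >= -1e-12 & tm <= 1 + 1e-12))
  }
  expect_error(tom(matrix(c(1, 0.2, 0.8, 1), 2)), class = "crossproteo_validation_error")
})

test_that("eigenproteins behave as first principal components", {
  set.seed(8)
  m <- matrix(rnorm(5 * 12), 5, 12)
  # single-protein module: eigenprotein is that profile (standardized)
  me <- eigenproteins(m, c(1, 0, 0, 0, 0))
  expect_equal(abs(cor(me[1, ], m[1, ])), 1, tolerance = 1e-10)
  # module of copies of one profile: eigenprotein correlates 1 with it
  base <- rnorm(12)
  dup <- rbind(base, base + 0.001 * rnorm(12), base - 0.001 * rnorm(12))
  me2 <- eigenproteins(dup, c(1, 1, 1))
  expect_gt(cor(me2[1, ], base), 0.999)
  # PCA optimality: eigenprotein explains >= variance of any single member
  mod <- matrix(rnorm(8 * 20), 8, 20)
  me3 <- eigenproteins(mod, rep(1, 8))
  z <- t(scale(t(mod)))
  var_expl <- function(v) sum(stats::cor(t(z), v)^2)
  for (i in 1:8) expect_gte(var_expl(me3[1, ]) + 1e-9, var_expl(z[i, ]))
  # sign anchor: positive correlation with the module mean profile
  expect_gte(cor(me3[1, ], colMeans(z)), 0)
})

test_that("trait_correlate matches cor.test and handles exact/null profiles", {
  set.seed(9)
  m <- matrix(rnorm(4 * 10), 4, 10, dimnames = list(paste0("p", 1:4), NULL))
  trait <- rnorm(10)
  tc <- trait_correlate(m, trait)
  for (i in 1:4) {
    ct <- stats::cor.test(m[i, ], trait)
    expect_equal(tc$r[i], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(tc$p[i], ct$p.value, tolerance = 1e-12)
    expect_equal(tc$r2[i], tc$r[i]^2)
  }
  # trait equal to a profile
  self <- trait_correlate(trait, trait)
  expect_equal(self$r, 1)
  expect_lt(self$p, 1e-12)
  # orthogonal profile: r = 0, t = 0, p = 1
  prof <- rnorm(10)
  prof <- prof - trait * sum(prof * trait) / sum(trait^2)
  prof <- prof - mean(prof) + trait * 0  # recenter, then re-orthogonalize
  prof <- prof - trait * sum((prof - mean(prof)) * (trait - mean(trait))) /
    sum((trait - mean(trait))^2)
  orth <- trait_correlate(prof, trait)
  expect_equal(orth$r, 0, tolerance = 1e-8)
  expect_equal(orth$p, 1, tolerance = 1e-6)
  expect_warning(trait_correlate(rbind(rep(1, 10), m[1, ]), trait), "constant")
  expect_error(trait_correlate(m[, 1:3], trait[1:3]), class = "crossproteo_param_error")
})

test_that("planted modules and the trait-driving module are recovered", {
  for (seed in c(11, 12, 13)) {
    r <- recover_modules(seed)
    expect_gt(r$ari, 0.9)
    expect_true(r$trait_top)
  }
})

test_that("noiseless planted modules have within-module correlation exactly 1", {
  gx <- gen_expression(20, 10, c(10, 10), within_module_cor = 1, noise_sd = 0, seed = 2)
  cm <- stats::cor(t(gx$matrix[1:10, ]))
  expect_equal(unname(cm), matrix(1, 10, 10), tolerance = 1e-12)
})

test_that("the pipeline is invariant to joint sample permutation and row order", {
  gx <- gen_expression(60, 30, c(30, 30), seed = 4)
  perm <- sample(30)
  a1 <- wgcna_adjacency(gx$matrix, 4)
  mod1 <- detect_modules(1 - tom(a1), gx$matrix)
  mt1 <- trait_correlate(mod1$eigenproteins, gx$trait)
  m2 <- gx$matrix[, perm]
  a2 <- wgcna_adjacency(m2, 4)
  mod2 <- detect_modules(1 - tom(a2), m2)
  mt2 <- trait_correlate(mod2$eigenproteins, gx$trait[perm])
  expect_equal(mt1$r, mt2$r, tolerance = 1e-9)
  # protein row order does not change the partition
  ord <- sample(60)
  a3 <- wgcna_adjacency(gx$matrix[ord, ], 4)
  mod3 <- detect_modules(1 - tom(a3), gx$matrix[ord, ])
  expect_gt(ari(mod1$labels[ord], mod3$labels), 0.999)
})

test_that("soft-threshold scan is deterministic and flags non-scale-free input", {
  # a hierarchy of module sizes with moderate within-module correlation
  # gives a heavy-tailed connectivity distribution (scale-free-ish)
  gx <- gen_expression(200, 40, c(40, 20, 10, 5), within_module_cor = 0.5, seed = 6)
  s1 <- pick_soft_threshold(gx$matrix, powers = 1:12)
  s2 <- pick_soft_threshold(gx$matrix, powers = 1:12)
  expect_identical(s1, s2)
  expect_true(any(s1$scan$r2 >= 0.8, na.rm = TRUE))
  # i.i.d. noise: warning path, no candidate reaches the target
  noise <- matrix(rnorm(50 * 20), 50, 20,
                  dimnames = list(paste0("p", 1:50), NULL))
  expect_warning(pick_soft_threshold(noise, powers = 1:6), "no candidate power")
  expect_error(pick_soft_threshold(gx$matrix[1:5, ]), class = "crossproteo_param_error")
})

test_that("detect_modules renumbers by size and sends small clusters to module 0", {
  gx <- gen_expression(70, 40, c(40, 25), within_module_cor = 0.9, seed = 14)
  a <- wgcna_adjacency(gx$matrix, 4)
  mod <- detect_modules(1 - tom(a), gx$matrix, min_module_size = 20)
  sizes <- mod$module_sizes
  expect_true(all(diff(as.integer(sizes)) <= 0))  # module 1 is the largest
  expect_true(all(sizes >= 20))
  # pure-noise matrix: most proteins unassigned
  noise <- matrix(rnorm(60 * 25), 60, 25, dimnames = list(paste0("n", 1:60), NULL))
  an <- wgcna_adjacency(noise, 4)
  modn <- suppressWarnings(detect_modules(1 - tom(an), noise, min_module_size = 20))
  expect_gt(mean(modn$labels == 0), 0.5)
})

test_that("run_wgcna wires the stages together", {
  gx <- gen_expression(80, 40, c(30, 30), seed = 3)
  res <- run_wgcna(gx$matrix, gx$trait, power = 4, protein_trait = TRUE)
  expect_equal(length(res$labels), 80)
  expect_equal(nrow(res$module_trait), nrow(res$eigenproteins))
  expect_equal(nrow(res$protein_trait), 80)
})
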