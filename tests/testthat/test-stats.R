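test_that("single-gradient group model equals the squared pooled two-sample t", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 24; p <- 6
    arr <- array(rnorm(n * p), dim = c(n, p, 1))
    covs <- data.frame(
      group = rep(c("case", "control"), each = n / 2),
      age = 30, sex = "F", site = "s1"  # constants drop out of the design
    )
    eff <- fit_mglm(arr, covs)
    for (j in seq_len(p)) {
      tt <- stats::t.test(arr[1:(n / 2), j, 1], arr[(n / 2 + 1):n, j, 1],
                          var.equal = TRUE)
      expect_equal(eff$T2[j], unname(tt$statistic)^2, tolerance = 1e-10)
      expect_equal(eff$p[j], tt$p.value, tolerance = 1e-10)
    }
  }
})

test_that("Hotelling T2 maps monotonically to p at a fixed design", {
  set.seed(5)
  arr <- array(rnorm(30 * 20 * 3), dim = c(30, 20, 3))
  covs <- data.frame(group = rep(c("case", "control"), each = 15),
                     age = runif(30, 20, 40),
                     sex = sample(c("M", "F"), 30, replace = TRUE),
                     site = rep(c("a", "b", "c"), 10))
  eff <- fit_mglm(arr, covs)
  expect_true(all(eff$T2 >= 0))
  expect_equal(order(eff$T2), order(-eff$p))
  expect_equal(eff$F, eff$T2 * (30 - 6 - 3 + 1) / ((30 - 6) * 3),
               tolerance = 1e-12)
})

test_that("group model is invariant to subject order and dropped site level", {
  set.seed(7)
  n <- 24
  arr <- array(rnorm(n * 8 * 3), dim = c(n, 8, 3))
  covs <- data.frame(group = rep(c("case", "control"), each = n / 2),
                     age = runif(n, 10, 40),
                     sex = sample(c("M", "F"), n, replace = TRUE),
                     site = rep(c("a", "b", "c"), n / 3))
  eff <- fit_mglm(arr, covs)
  perm <- sample(n)
  eff_perm <- fit_mglm(arr[perm, , , drop = FALSE], covs[perm, ])
  expect_equal(eff_perm$p, eff$p, tolerance = 1e-10)
  eff_site <- fit_mglm(arr, covs, drop_site_level = "b")
  expect_equal(eff_site$p, eff$p, tolerance = 1e-10)
})

test_that("group model rejects degenerate inputs", {
  set.seed(8)
  arr <- array(rnorm(10 * 4 * 3), dim = c(10, 4, 3))
  covs <- data.frame(group = rep(c("case", "control"), each = 5),
                     age = runif(10, 10, 40), sex = rep(c("M", "F"), 5),
                     site = "s1")
  # aliased column: age duplicated through motion identical to age
  covs2 <- covs; covs2$motion <- covs2$age
  expect_error(fit_mglm(arr, covs2, include_motion = TRUE), "aliased")
  # constant response -> singular residual covariance
  arr2 <- arr; arr2[, 2, ] <- 1
  expect_error(fit_mglm(arr2, covs), "singular|constant")
  # too few residual df for a 3-variate response
  idx <- c(1:3, 6:8)
  expect_error(fit_mglm(arr[idx, , , drop = FALSE], covs[idx, ]), "df")
})

test_that("fdr_bh matches the brute-force step-up oracle", {
  expect_equal(fdr_bh(0.03)$q, 0.03)
  p4 <- c(0.01, 0.02, 0.03, 0.04)
  r4 <- fdr_bh(p4, alpha = 0.05)
  expect_equal(r4$q, bh_oracle(p4))
  expect_true(all(r4$significant))
  for (seed in 1:50) {
    set.seed(seed)
    p <- runif(sample(1:40, 1))
    expect_equal(fdr_bh(p)$q, bh_oracle(p))
  }
  expect_error(fdr_bh(c(0.5, 0)), "0, 1")
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("spin permutations are identity under no rotation and preserve multisets", {
  s <- tiny_scheme()
  perm_id <- conngrad:::spin_permutation_indices(s, diag(3))
  expect_equal(perm_id, seq_len(nrow(s)))
  set.seed(11)
  for (i in 1:5) {
    rot <- conngrad:::random_rotation()
    expect_equal(det(rot), 1, tolerance = 1e-12)
    expect_equal(crossprod(rot), diag(3), tolerance = 1e-12)
    perm <- conngrad:::spin_permutation_indices(s, rot)
    expect_equal(sort(perm), seq_len(nrow(s)))  # a true permutation
    # within-hemisphere: value multisets preserved per hemisphere
    for (h in c("L", "R")) {
      idx <- which(s$hemisphere == h)
      expect_setequal(perm[idx], idx)
    }
  }
})

test_that("spin test p-values behave at the identity and are reproducible", {
  s <- tiny_scheme()
  smooth_map <- s$z + 0.5 * s$y
  other <- s$y * s$z - s$x^2
  sp <- spin_test(smooth_map, smooth_map, s, n_perm = 99, seed = 3)
  expect_equal(sp$observed_r, 1)
  expect_equal(sp$p, (1 + sum(abs(sp$null_r) >= 1)) / 100)
  expect_gte(sp$p, 1 / 100)
  sp2 <- spin_test(smooth_map, other, s, n_perm = 99, seed = 3)
  sp3 <- spin_test(smooth_map, other, s, n_perm = 99, seed = 3)
  expect_identical(sp2, sp3)
  expect_error(spin_test(rep(1, nrow(s)), other, s), "constant")
  expect_error(spin_test(smooth_map, other, s, n_perm = 0), "n_perm")
})

test_that("effect stratification reproduces direct arithmetic and the global mean", {
  s4 <- micro_scheme()
  eff <- data.frame(parcel_id = 0:3, T2 = c(1, 2, 3, 4),
                    F = 1:4, p = rep(0.01, 4), q = c(0.01, 0.2, 0.01, 0.2),
                    significant = c(TRUE, FALSE, TRUE, FALSE))
  class(eff) <- c("effect_map", "data.frame")
  tab <- stratify_effects(eff, s4, by = "community")
  a_row <- tab[tab$label == "a", ]
  expect_equal(a_row$mean_T2, 2)          # parcels 0 and 2
  expect_equal(a_row$sd_T2, sd(c(1, 3)))
  expect_equal(a_row$n_parcels, 2)
  expect_equal(a_row$n_significant, 2)
  # weighted mean over strata reproduces the global mean
  expect_equal(sum(tab$mean_T2 * tab$n_parcels) / sum(tab$n_parcels),
               mean(eff$T2))
  # permutation invariance up to row order
  perm <- c(3, 1, 4, 2)
  eff_p <- eff[perm, ]; eff_p$parcel_id <- 0:3
  s_p <- s4[perm, ]; s_p$parcel_id <- 0:3
  s_p$homologue <- match(s4$homologue[perm] , perm) - 1L
  class(s_p) <- c("parcellation", "data.frame")
  tab_p <- stratify_effects(eff_p, s_p, by = "community")
  expect_equal(tab_p[order(tab_p$label), -1], tab[order(tab$label), -1],
               ignore_attr = TRUE)
  summ <- summarize_template(eff)
  expect_equal(summ$mean_T2, 2.5)
  expect_equal(summ$sd_T2, sd(1:4))
  expect_equal(summ$n_significant, 2)
})

test_that("classification utility is at chance for null features and perfect for separable ones", {
  set.seed(21)
  n <- 40
  covs <- data.frame(group = rep(c("case", "control"), each = n / 2),
                     age = runif(n, 20, 40),
                     sex = sample(c("M", "F"), n, replace = TRUE),
                     site = rep(c("a", "b"), n / 2))
  labels <- covs$group
  null_feats <- matrix(rnorm(n * 30), n)
  res_null <- evaluate_template_utility(null_feats, covs, labels,
                                        task = "classify", n_repeats = 5,
                                        seed = 1)
  half_width <- 1.96 * sqrt(0.25 / n)
  expect_gt(res_null$mean, 0.5 - half_width - 0.1)
  expect_lt(res_null$mean, 0.5 + half_width + 0.1)
  # perfectly separable features
  sep <- cbind(ifelse(labels == "case", 5, -5) + rnorm(n, sd = 0.01),
               matrix(rnorm(n * 5), n))
  res_sep <- evaluate_template_utility(sep, covs, labels, task = "classify",
                                       n_repeats = 3, seed = 1)
  expect_equal(res_sep$mean, 1)
  # determinism
  res_again <- evaluate_template_utility(sep, covs, labels, task = "classify",
                                         n_repeats = 3, seed = 1)
  expect_identical(res_sep, res_again)
  expect_error(evaluate_template_utility(sep, covs, rep("case", n),
                                         task = "classify"), "2 classes")
})

test_that("ridge prediction recovers a linear signal and reports correlation and error", {
  set.seed(22)
  n <- 50
  covs <- data.frame(group = "control", age = runif(n, 20, 40),
                     sex = sample(c("M", "F"), n, replace = TRUE),
                     site = "s1")
  x <- matrix(rnorm(n * 10), n)
  y <- x %*% rnorm(10) + rnorm(n, sd = 0.1)
  res <- evaluate_template_utility(x, covs, y, task = "predict",
                                   n_repeats = 3, seed = 2,
                                   ridge_lambda = 0.1)
  expect_setequal(res$metric, c("correlation", "mae"))
  expect_gt(res$mean[res$metric == "correlation"], 0.8)
  expect_lt(res$mean[res$metric == "mae"], stats::sd(y))
})
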