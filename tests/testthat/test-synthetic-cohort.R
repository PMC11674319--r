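test_that("parcellation geometry: hemispheres, unit centroids, homologue involution", {
  s <- make_parcellation(8, n_communities = 2, n_hierarchy = 2, seed = 1)
  expect_equal(sum(s$hemisphere == "L"), 4)
  expect_equal(sum(s$hemisphere == "R"), 4)
  expect_equal(sqrt(s$x^2 + s$y^2 + s$z^2), rep(1, 8), tolerance = 1e-12)
  # involution crossing hemispheres
  expect_equal(s$homologue[s$homologue + 1L], s$parcel_id)
  expect_true(all(s$hemisphere[s$homologue + 1L] != s$hemisphere))
  # homologous parcels are mirror images
  expect_equal(s$x[s$homologue + 1L], -s$x, tolerance = 1e-12)
  expect_equal(s$y[s$homologue + 1L], s$y, tolerance = 1e-12)

  big <- make_parcellation(200, n_communities = 7, n_hierarchy = 4, seed = 0)
  expect_equal(nrow(big), 200)
  expect_equal(length(unique(big$community)), 7)
  expect_equal(length(unique(big$hierarchy)), 4)
  expect_true("frontoparietal" %in% big$community)
})

test_that("parcellation rejects invalid sizes and is deterministic", {
  expect_error(make_parcellation(9), "even")
  expect_error(make_parcellation(6), "even")
  expect_error(make_parcellation(20, n_communities = 11), "n_communities")
  expect_identical(make_parcellation(40, 4, 2, seed = 3),
                   make_parcellation(40, 4, 2, seed = 3))
})

test_that("ground truth has zero-mean unit-sd smooth latent axes and valid effects", {
  s <- tiny_scheme()
  gt <- make_ground_truth(s, n_affected = 6, effect_size = 1.5, seed = 2)
  expect_equal(unname(colMeans(gt$latent_coords)), rep(0, 3),
               tolerance = 1e-12)
  expect_equal(unname(apply(gt$latent_coords, 2, sd)), rep(1, 3),
               tolerance = 1e-12)
  expect_true(all(gt$affected_parcels %in% s$parcel_id))
  # apex rule: affected parcels are the top of the first latent axis
  expect_setequal(gt$affected_parcels,
                  s$parcel_id[order(-gt$latent_coords[, 1])[1:6]])
  expect_error(make_ground_truth(s, effect_size = -1), "effect_size")
})

test_that("every simulated FC matrix is a valid correlation matrix", {
  s <- tiny_scheme()
  coh <- small_fc_cohort(s, 3, 3, seed = 5, effect_size = 1)
  for (rec in coh$subjects) {
    m <- unclass(rec$fc)
    expect_equal(m, t(m), tolerance = 1e-12)
    expect_equal(diag(m), rep(1, nrow(m)), tolerance = 1e-12)
    expect_gt(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  }
})

test_that("FC converges to the analytic factor-model correlation as noise vanishes", {
  s <- tiny_scheme()
  gt <- make_ground_truth(s, n_affected = 0, effect_size = 0, site_sd = 0,
                          seed = 4)
  # analytic correlation of x = A f + e: cov = AA' + sigma^2 I
  a <- conngrad:::base_loadings(gt)
  sigma <- 0.05
  analytic <- stats::cov2cor(tcrossprod(a) + diag(sigma^2, nrow(a)))
  devs <- vapply(c(2000, 20000), function(len) {
    coh <- simulate_fc_cohort(s, 2, 2, n_sites = 1, series_length = len,
                              noise_sd = sigma, truth = gt,
                              subject_jitter_sd = 0)
    max(abs(unclass(coh$subjects[[1]]$fc) - analytic))
  }, 0)
  expect_lt(devs[2], devs[1])       # deviation shrinks with series length
  expect_lt(devs[2], 0.05)
})

test_that("planted loading shift moves the case group's first gradient at affected parcels", {
  s <- make_parcellation(60, 4, 2, seed = 7)
  gt <- make_ground_truth(s, n_affected = 8, effect_size = 1.0, seed = 7)
  coh <- simulate_fc_cohort(s, 10, 10, truth = gt)
  grads <- lapply(coh$subjects, function(r) embed_functional(fisher_z(r$fc)))
  tmpl <- embed_functional(group_average_fc(
    lapply(coh$subjects, function(r) fisher_z(r$fc))))
  al <- align_cohort(grads, tmpl)
  g1 <- t(vapply(al, function(g) g$components[, 1], numeric(60)))
  aff <- gt$affected_parcels + 1L
  case <- vapply(coh$subjects, function(r) r$group == "case", TRUE)
  diff_aff <- mean(g1[case, aff]) - mean(g1[!case, aff])
  diff_un <- mean(g1[case, -aff]) - mean(g1[!case, -aff])
  # planted direction: cases shifted outward along the (positive) apex of G1
  expect_gt(diff_aff, 0)
  expect_gt(abs(diff_aff), abs(diff_un))
})

test_that("SC cohorts are symmetric, non-negative, zero-diagonal and distance-sparse", {
  s <- tiny_scheme()
  gt <- make_ground_truth(s, n_affected = 5, effect_size = 1, seed = 11)
  coh <- simulate_sc_cohort(s, 3, 3, truth = gt)
  d <- conngrad:::great_circle_dist(conngrad:::centroid_matrix(s))
  for (rec in coh$subjects) {
    m <- unclass(rec$sc)
    expect_equal(m, t(m), tolerance = 1e-12)
    expect_true(all(m >= 0))
    expect_equal(diag(m), rep(0, nrow(m)))
  }
  # distance dependence: near edges present more often than far edges
  pres <- Reduce(`+`, lapply(coh$subjects, function(r) unclass(r$sc) > 0))
  ut <- upper.tri(d)
  near <- d[ut] < stats::median(d[ut])
  expect_gt(mean(pres[ut][near]), mean(pres[ut][!near]))
  expect_error(simulate_sc_cohort(s, 3, 3, density_scale = -1, truth = gt),
               "density_scale")
})

test_that("large decay scale removes the distance dependence of edge density", {
  s <- tiny_scheme()
  d <- conngrad:::great_circle_dist(conngrad:::centroid_matrix(s))
  ut <- upper.tri(d)
  bins <- cut(d[ut], breaks = stats::quantile(d[ut], seq(0, 1, 0.25)),
              include.lowest = TRUE)
  counts <- numeric(nlevels(bins))
  total <- 0
  for (seed in 1:20) {
    gt <- make_ground_truth(s, n_affected = 0, effect_size = 0, seed = seed)
    # decay scale far above the maximum inter-centroid distance (pi)
    coh <- simulate_sc_cohort(s, 2, 2, density_scale = 2000, truth = gt)
    pres <- unclass(coh$subjects[[1]]$sc)[ut] > 0
    counts <- counts + tapply(pres, bins, sum)
    total <- total + tapply(rep(TRUE, sum(ut)), bins, sum)
  }
  chi <- suppressWarnings(
    stats::chisq.test(cbind(counts, total - counts),
                      simulate.p.value = TRUE, B = 5000)
  )
  expect_gt(chi$p.value, 0.01)
})

test_that("reference cohort is control-only and less dispersed than the study cohort", {
  s <- tiny_scheme()
  gt <- make_ground_truth(s, n_affected = 0, effect_size = 0, seed = 9)
  study <- simulate_fc_cohort(s, 2, 12, truth = gt)
  ref <- simulate_reference_cohort(s, n_subjects = 12, quality_factor = 4,
                                   truth = gt)
  expect_true(all(vapply(ref$subjects, function(r) r$group, "") == "control"))
  dispersion <- function(subjects) {
    ms <- lapply(subjects, function(r) unclass(r$fc))
    avg <- Reduce(`+`, ms) / length(ms)
    mean(vapply(ms, function(m) norm(m - avg, "F"), 0))
  }
  ctrl <- Filter(function(r) r$group == "control", study$subjects)
  expect_lt(dispersion(ref$subjects), dispersion(ctrl))
  expect_error(simulate_reference_cohort(s, 10, quality_factor = 1,
                                         truth = gt), "quality_factor")
})

test_that("all generators are reproducible from (parameters, seed)", {
  s <- tiny_scheme()
  gt <- make_ground_truth(s, n_affected = 4, effect_size = 1, seed = 21)
  f1 <- simulate_fc_cohort(s, 2, 2, truth = gt, series_length = 50)
  f2 <- simulate_fc_cohort(s, 2, 2, truth = gt, series_length = 50)
  expect_identical(f1, f2)
  s1 <- simulate_sc_cohort(s, 2, 2, truth = gt)
  s2 <- simulate_sc_cohort(s, 2, 2, truth = gt)
  expect_identical(s1, s2)
  r1 <- simulate_reference_cohort(s, 3, truth = gt)
  r2 <- simulate_reference_cohort(s, 3, truth = gt)
  expect_identical(r1, r2)
})

test_that("cohort generators validate their arguments", {
  s <- tiny_scheme()
  gt <- make_ground_truth(s, seed = 1)
  expect_error(simulate_fc_cohort(s, 1, 5, truth = gt), "2 subjects")
  expect_error(simulate_fc_cohort(s, 5, 5, series_length = 3, truth = gt),
               "series_length")
  expect_error(simulate_fc_cohort(s, 5, 5, noise_sd = 0, truth = gt),
               "noise_sd")
  bad <- gt
  bad$affected_parcels <- c(0L, 999L)
  expect_error(simulate_fc_cohort(s, 5, 5, truth = bad), "affected")
})
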