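#' Define the latent ground truth for a synthetic cohort
#'
#' The generative model behind every synthetic cohort is a low-dimensional
#' latent factor model: each parcel carries a 3-vector of latent gradient
#' coordinates, built from smooth low-order spherical-harmonic-like functions
#' of its centroid (z, y, and y*z, each standardised to zero mean and unit SD
#' across parcels), so that the planted gradients are spatially smooth axes.
#' A diagnosed-group effect is a shift of the affected parcels' loadings
#' along the first latent axis; site effects are small additive offsets on
#' the loadings.
#'
#' Affected parcels default to the apex of the first latent axis (the
#' `n_affected` parcels with the largest first-axis coordinate, shifted
#' further outward in cases) — emulating pathology concentrated at one end
#' of the principal connectivity hierarchy, the spatial pattern most
#' disease-gradient studies report. A `"random"` rule is available for
#' diffuse effects.
#'
#' @param scheme a [make_parcellation()] scheme.
#' @param n_affected number of parcels carrying the group effect.
#' @param effect_size shift magnitude in latent-coordinate SD units (>= 0).
#' @param affected_rule "axis1_apex" (default, deterministic) or "random".
#' @param n_sites number of acquisition sites in the study cohort.
#' @param site_sd SD of the per-site additive loading offsets, in the same
#'   units as the loadings (small relative to `effect_size` by default).
#' @param seed integer seed; all cohort generators derive their randomness
#'   from it.
#' @return A `ground_truth` list with `latent_coords` (parcels x 3, zero-mean
#'   unit-SD columns), `affected_parcels` (0-based ids), `effect_size`,
#'   `site_effects` (n_sites x 3), and `seed`.
#' @export
make_ground_truth <- function(scheme, n_affected = 10L, effect_size = 1.0,
                              n_sites = 3L, site_sd = 0.05, seed = 1L,
                              affected_rule = c("axis1_apex", "random")) {
  affected_rule <- match.arg(affected_rule)
  validate_parcellation(scheme)
  if (effect_size < 0) stop_invalid("effect_size must be >= 0")
  if (n_affected < 0 || n_affected > nrow(scheme)) {
    stop_invalid("n_affected must be in [0, n_parcels]")
  }
  xyz <- centroid_matrix(scheme)
  raw <- cbind(xyz[, "z"], xyz[, "y"], xyz[, "y"] * xyz[, "z"])
  latent <- apply(raw, 2, function(v) (v - mean(v)) / sd(v))
  colnames(latent) <- paste0("L", 1:3)

  drawn <- with_seed(child_seed(seed, 2L), {
    list(
      affected = switch(affected_rule,
        axis1_apex = sort(scheme$parcel_id[order(-latent[, 1])[seq_len(n_affected)]]),
        random = sort(sample(scheme$parcel_id, n_affected))),
      site_eff = matrix(rnorm(n_sites * 3, sd = site_sd), nrow = n_sites,
                        dimnames = list(paste0("site_", seq_len(n_sites)), NULL))
    )
  })

  structure(
    list(
      latent_coords = latent,
      affected_parcels = drawn$affected,
      effect_size = effect_size,
      site_effects = drawn$site_eff,
      seed = as.integer(seed)
    ),
    class = "ground_truth"
  )
}

# Loading strengths per latent axis: decreasing so the embedding's gradient
# order is stable (G1 tracks the first latent axis).
.latent_strengths <- c(1.0, 0.8, 0.6)

base_loadings <- function(truth) {
  truth$latent_coords %*% diag(.latent_strengths)
}

subject_covariates <- function(n_case, n_control, n_sites, seed,
                               site_names = NULL) {
  n <- n_case + n_control
  if (is.null(site_names)) site_names <- paste0("site_", seq_len(n_sites))
  with_seed(child_seed(seed, 3L), {
    data.frame(
      subject_id = sprintf("sub-%03d", seq_len(n)),
      group = rep(c("case", "control"), c(n_case, n_control)),
      age = round(runif(n, 8, 40), 1),
      sex = sample(c("M", "F"), n, replace = TRUE),
      # round-robin within group keeps sites balanced across groups
      site = c(site_names[(seq_len(n_case) - 1L) %% n_sites + 1L],
               site_names[(seq_len(n_control) - 1L) %% n_sites + 1L]),
      motion = round(rlnorm(n, meanlog = -2, sdlog = 0.4), 4),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a multi-site two-group functional connectivity cohort
#'
#' Each subject's parcel time series follows the latent factor model
#' `X = A F + E`, where the loading matrix `A` is the smooth latent gradient
#' geometry of `truth` (plus per-subject jitter and the subject's site
#' offset), `F` is a 3 x T standard normal factor series, and `E` is i.i.d.
#' noise with SD `noise_sd`. Case subjects have the first-axis loadings of
#' the affected parcels shifted by `effect_size` latent SD units, so the
#' group effect propagates through connectivity, embedding, and alignment
#' rather than being painted onto gradients post hoc. The returned functional
#' connectivity is the Pearson correlation of the series, which is a valid
#' correlation matrix by construction.
#'
#' @param scheme parcellation scheme.
#' @param n_case,n_control group sizes (each >= 2).
#' @param n_sites number of study sites (must not exceed the sites in
#'   `truth$site_effects`).
#' @param series_length number of timepoints T (> 3 latent factors).
#' @param noise_sd SD of the additive observation noise (> 0). The default 2
#'   with unit-scale loadings yields realistic resting-state correlation
#'   magnitudes (typical off-diagonal |r| around 0.1-0.3).
#' @param truth a [make_ground_truth()] object; carries the seed.
#' @param subject_jitter_sd SD of per-subject loading jitter (individual
#'   variability around the group geometry). The default 0.7, sized against
#'   unit-scale loadings, reflects the substantial inter-individual
#'   variability of resting-state connectivity.
#' @param return_series keep the raw time series on each record.
#' @return list with `subjects` (list of subject records, each with `fc` a
#'   functional `connectivity_matrix` in state `raw_r` plus covariates) and
#'   `truth` (unchanged).
#' @export
simulate_fc_cohort <- function(scheme, n_case = 30L, n_control = 30L,
                               n_sites = 3L, series_length = 200L,
                               noise_sd = 2.0, truth,
                               subject_jitter_sd = 0.7,
                               return_series = FALSE) {
  validate_parcellation(scheme)
  if (n_case < 2 || n_control < 2) {
    stop_invalid("need at least 2 subjects per group")
  }
  if (series_length <= ncol(truth$latent_coords)) {
    stop_invalid("series_length must exceed the number of latent factors")
  }
  if (noise_sd <= 0) stop_invalid("noise_sd must be > 0")
  if (n_sites > nrow(truth$site_effects)) {
    stop_invalid("truth defines %d site effects but n_sites = %d",
                 nrow(truth$site_effects), n_sites)
  }
  if (!all(truth$affected_parcels %in% scheme$parcel_id)) {
    stop_invalid("affected parcels outside the parcellation")
  }

  p <- nrow(scheme)
  A0 <- base_loadings(truth)
  cov_tab <- subject_covariates(n_case, n_control, n_sites, truth$seed)
  affected_rows <- truth$affected_parcels + 1L

  subjects <- lapply(seq_len(nrow(cov_tab)), function(s) {
    rec <- as.list(cov_tab[s, ])
    site_idx <- match(rec$site, rownames(truth$site_effects))
    with_seed(child_seed(truth$seed, 4L, s), {
      A <- A0 +
        matrix(rnorm(p * 3, sd = subject_jitter_sd), p, 3) +
        matrix(truth$site_effects[site_idx, ], p, 3, byrow = TRUE)
      if (rec$group == "case" && length(affected_rows)) {
        A[affected_rows, 1] <- A[affected_rows, 1] + truth$effect_size
      }
      f <- matrix(rnorm(3 * series_length), 3, series_length)
      x <- A %*% f + matrix(rnorm(p * series_length, sd = noise_sd),
                            p, series_length)
      rec$fc <- build_fc(x)
      if (return_series) rec$series <- x
      rec
    })
  })
  list(subjects = subjects, truth = truth)
}

# Calibrate the exponential distance-decay scale so the expected edge
# density over all parcel pairs hits `target`.
calibrate_density_scale <- function(scheme, target = 0.15) {
  d <- great_circle_dist(centroid_matrix(scheme))
  dv <- d[upper.tri(d)]
  uniroot(function(l) mean(exp(-dv / l)) - target,
          interval = c(1e-3, 100), tol = 1e-8)$root
}

#' Simulate a two-group structural connectivity cohort
#'
#' Streamline-count-like matrices with distance-dependent sparsity: each
#' subject draws edge (i, j) with probability `exp(-d_ij / density_scale)`
#' (`d_ij` the great-circle centroid distance), and gives present edges a
#' log-normal weight whose log-mean decreases with distance plus a latent
#' similarity term so the structural connectome shares the cohort's gradient
#' geometry. Case subjects have every edge incident to an affected parcel
#' multiplied by `exp(effect_size * effect_delta)`. Matrices are symmetric,
#' non-negative, with zero diagonal.
#'
#' @inheritParams simulate_fc_cohort
#' @param density_scale exponential decay scale (radians) of edge
#'   probability; `NULL` (default) calibrates it so the expected edge density
#'   is about 0.15, comparable to tractography-derived matrices.
#' @param effect_delta log-scale multiplier per unit effect size applied to
#'   case-group edges incident to affected parcels.
#' @return list with `subjects` (each with `sc` a structural
#'   `connectivity_matrix` in state `raw_count`) and `truth`.
#' @export
simulate_sc_cohort <- function(scheme, n_case = 30L, n_control = 30L,
                               density_scale = NULL, truth,
                               n_sites = 3L, effect_delta = 0.2) {
  validate_parcellation(scheme)
  if (n_case < 2 || n_control < 2) {
    stop_invalid("need at least 2 subjects per group")
  }
  if (!is.null(density_scale) && density_scale <= 0) {
    stop_invalid("density_scale must be > 0")
  }
  if (is.null(density_scale)) {
    density_scale <- calibrate_density_scale(scheme)
  }
  p <- nrow(scheme)
  d <- great_circle_dist(centroid_matrix(scheme))
  p_edge <- exp(-d / density_scale)
  # latent similarity raises the log-weight of edges joining parcels that are
  # close along the planted gradients
  lat <- base_loadings(truth)
  sim <- tcrossprod(lat) / ncol(lat)
  log_mu <- 2 - d + 0.5 * sim
  ut <- upper.tri(d)
  cov_tab <- subject_covariates(n_case, n_control, n_sites, truth$seed + 7L)
  affected_rows <- truth$affected_parcels + 1L
  case_scale <- exp(truth$effect_size * effect_delta)

  subjects <- lapply(seq_len(nrow(cov_tab)), function(s) {
    rec <- as.list(cov_tab[s, ])
    with_seed(child_seed(truth$seed, 5L, s), {
      m <- matrix(0, p, p)
      present <- runif(sum(ut)) < p_edge[ut]
      w <- exp(log_mu[ut] + rnorm(sum(ut), sd = 0.5)) * present
      m[ut] <- w
      m <- m + t(m)
      if (rec$group == "case" && length(affected_rows)) {
        m[affected_rows, ] <- m[affected_rows, ] * case_scale
        m[, affected_rows] <- m[, affected_rows] * case_scale
        # incident edges scaled once, not twice
        m[affected_rows, affected_rows] <-
          m[affected_rows, affected_rows] / case_scale
      }
      rec$sc <- connectivity_matrix(m, "structural", "raw_count")
      rec
    })
  })
  list(subjects = subjects, truth = truth)
}

#' Simulate an independent high-quality reference cohort
#'
#' A control-only cohort sharing the latent gradient geometry of the study
#' cohort but acquired at higher quality: the series length is multiplied
#' and the noise SD divided by `quality_factor` (> 1), with no group effect
#' and no study-site offsets. The subject loading jitter is also divided by
#' `quality_factor`: a large normative cohort (young healthy adults, single
#' protocol) is more homogeneous than a multi-site clinical study, so its
#' subject-to-subject connectivity dispersion is strictly lower. This
#' emulates aligning a clinical study to a template from a high-quality
#' reference dataset.
#'
#' @inheritParams simulate_fc_cohort
#' @param n_subjects reference cohort size.
#' @param quality_factor quality multiplier, strictly > 1.
#' @param series_length,noise_sd the *study-cohort* acquisition parameters;
#'   the reference cohort uses `series_length * quality_factor` timepoints
#'   and `noise_sd / quality_factor` noise.
#' @return list with `subjects` and `truth`.
#' @export
simulate_reference_cohort <- function(scheme, n_subjects = 100L,
                                      quality_factor = 4, truth,
                                      series_length = 200L, noise_sd = 2.0,
                                      subject_jitter_sd = 0.7) {
  validate_parcellation(scheme)
  if (quality_factor <= 1) stop_invalid("quality_factor must be > 1")
  if (n_subjects < 2) stop_invalid("need at least 2 reference subjects")
  p <- nrow(scheme)
  A0 <- base_loadings(truth)
  t_ref <- round(series_length * quality_factor)
  sd_ref <- noise_sd / quality_factor
  jitter_ref <- subject_jitter_sd / quality_factor
  cov_tab <- with_seed(child_seed(truth$seed, 6L), {
    data.frame(
      subject_id = sprintf("ref-%03d", seq_len(n_subjects)),
      group = "control",
      age = round(runif(n_subjects, 22, 36), 1),
      sex = sample(c("M", "F"), n_subjects, replace = TRUE),
      site = "reference",
      motion = round(rlnorm(n_subjects, meanlog = -2.5, sdlog = 0.3), 4),
      stringsAsFactors = FALSE
    )
  })
  subjects <- lapply(seq_len(n_subjects), function(s) {
    rec <- as.list(cov_tab[s, ])
    with_seed(child_seed(truth$seed, 7L, s), {
      A <- A0 + matrix(rnorm(p * 3, sd = jitter_ref), p, 3)
      f <- matrix(rnorm(3 * t_ref), 3, t_ref)
      x <- A %*% f + matrix(rnorm(p * t_ref, sd = sd_ref), p, t_ref)
      rec$fc <- build_fc(x)
      rec
    })
  })
  list(subjects = subjects, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "ground truth: %d parcels, %d affected, effect size %.2f, %d sites, seed %d\n",
    nrow(x$latent_coords), length(x$affected_parcels), x$effect_size,
    nrow(x$site_effects), x$seed
  ))
  invisible(x)
}
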