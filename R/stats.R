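# Between-group inference on aligned gradients and spatial null models.

# Design matrix for the group model: intercept + group (case = 1) + age +
# sex (M = 1) + site one-hot with the first level dropped. `drop_site_level`
# selects which site level is the reference (inference must not depend on
# it). Motion is appended when requested.
build_design <- function(covariates, drop_site_level = NULL,
                         include_motion = FALSE) {
  required <- c("group", "age", "sex", "site")
  missing_cols <- setdiff(required, names(covariates))
  if (length(missing_cols)) {
    stop_invalid("covariates missing column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  n <- nrow(covariates)
  x <- cbind(intercept = rep(1, n),
             group = as.numeric(covariates$group == "case"))
  # constant nuisance columns carry no information and would only alias the
  # intercept; drop them so reduced designs (e.g. single-site cohorts) work
  if (length(unique(covariates$age)) > 1) {
    x <- cbind(x, age = as.numeric(covariates$age))
  }
  if (length(unique(covariates$sex)) > 1) {
    x <- cbind(x, sex = as.numeric(covariates$sex == "M"))
  }
  sites <- unique(as.character(covariates$site))
  if (is.null(drop_site_level)) drop_site_level <- sites[1]
  for (s in setdiff(sites, drop_site_level)) {
    x <- cbind(x, as.numeric(covariates$site == s))
    colnames(x)[ncol(x)] <- paste0("site_", s)
  }
  if (include_motion) {
    if (is.null(covariates$motion)) stop_invalid("covariates lack 'motion'")
    x <- cbind(x, motion = as.numeric(covariates$motion))
  }
  x
}

as_gradient_array <- function(aligned) {
  if (is.array(aligned) && length(dim(aligned)) == 3) return(aligned)
  mats <- lapply(aligned, function(g) {
    if (inherits(g, "gradient_set")) g$components else as.matrix(g)
  })
  p <- nrow(mats[[1]]); k <- ncol(mats[[1]])
  arr <- array(0, dim = c(length(mats), p, k))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  arr
}

#' Parcel-wise multivariate group model with Hotelling's T-squared
#'
#' Fits, at every parcel, the multivariate linear model
#' `Y = intercept + group + age + sex + site` where Y holds the subject's
#' aligned gradient values (G1..Gk, k = 3 by default) at that parcel, and
#' tests the group contrast jointly across gradients with Hotelling's
#' T-squared: `T2 = (c'B)' S^-1 (c'B) / (c'(X'X)^-1 c)` with `S` the residual
#' covariance on `nu = n - rank(X)` degrees of freedom. The statistic is
#' mapped to `F = T2 (nu - q + 1) / (nu q)` with `(q, nu - q + 1)` degrees of
#' freedom, and parcel-wise p-values are FDR-adjusted by [fdr_bh()].
#'
#' @param aligned subjects x parcels x k array, or a list of aligned
#'   [gradient_set()] objects (one per subject, same order as `covariates`).
#' @param covariates data frame with columns `group` ("case"/"control"),
#'   `age`, `sex` ("M"/"F"), `site`, and optionally `motion`.
#' @param alpha_fdr significance threshold on the adjusted values.
#' @param include_motion add framewise-displacement-style motion as a
#'   nuisance covariate.
#' @param drop_site_level reference site level dropped from the one-hot
#'   encoding (the test is invariant to this choice).
#' @return an `effect_map` data frame: `parcel_id`, `T2`, `F`, `p`, `q`,
#'   `significant`.
#' @export
fit_mglm <- function(aligned, covariates, alpha_fdr = 0.05,
                     include_motion = FALSE, drop_site_level = NULL) {
  arr <- as_gradient_array(aligned)
  n <- dim(arr)[1]; p <- dim(arr)[2]; q <- dim(arr)[3]
  if (nrow(covariates) != n) {
    stop_invalid("covariates rows (%d) != subjects (%d)", nrow(covariates), n)
  }
  groups <- table(covariates$group)
  if (length(groups) < 2 || any(groups < 2)) {
    stop_invalid("need at least 2 subjects per group")
  }
  x <- build_design(covariates, drop_site_level, include_motion)
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    aliased <- colnames(x)[qr_x$pivot[(qr_x$rank + 1):ncol(x)]]
    stop_invalid("design matrix rank-deficient; aliased column(s): %s",
                 paste(aliased, collapse = ", "))
  }
  nu <- n - qr_x$rank
  if (nu < q) stop_invalid("residual df (%d) < response dimension (%d)", nu, q)

  xtx_inv <- chol2inv(qr.R(qr_x))
  g_idx <- which(colnames(x) == "group")
  c_xx_c <- xtx_inv[g_idx, g_idx]

  t2 <- numeric(p)
  for (j in seq_len(p)) {
    y <- arr[, j, , drop = TRUE]
    if (q == 1) y <- matrix(y, ncol = 1)
    b <- xtx_inv %*% crossprod(x, y)
    e <- y - x %*% b
    s <- crossprod(e) / nu
    if (rcond(s) < 1e-12) {
      stop_invalid("singular residual covariance at parcel %d (constant response?)",
                   j - 1L)
    }
    cb <- b[g_idx, ]
    t2[j] <- drop(crossprod(cb, solve(s, cb))) / c_xx_c
  }
  f <- t2 * (nu - q + 1) / (nu * q)
  pval <- pf(f, q, nu - q + 1, lower.tail = FALSE)
  adj <- fdr_bh(pval, alpha_fdr)
  out <- data.frame(parcel_id = seq_len(p) - 1L, T2 = t2, F = f, p = pval,
                    q = adj$q, significant = adj$significant)
  class(out) <- c("effect_map", "data.frame")
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment (monotonicity-enforced) with a significance flag
#' at the requested level.
#'
#' @param p p-values in (0, 1].
#' @param alpha FDR level (default 0.05).
#' @return list with `q` (adjusted values) and `significant` (`q < alpha`).
#' @export
fdr_bh <- function(p, alpha = 0.05) {
  if (!length(p)) stop_invalid("empty p-value vector")
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) {
    stop_invalid("p-values must lie in (0, 1]")
  }
  q <- p.adjust(p, method = "BH")
  list(q = q, significant = q < alpha)
}

random_rotation <- function() {
  a <- matrix(rnorm(9), 3, 3)
  qrd <- qr(a)
  q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

spin_permutation_indices <- function(scheme, rot) {
  xyz <- centroid_matrix(scheme)
  mirror <- diag(c(-1, 1, 1))
  perm <- integer(nrow(scheme))
  for (h in c("L", "R")) {
    idx <- which(scheme$hemisphere == h)
    q <- if (h == "L") rot else mirror %*% rot %*% mirror
    rotated <- xyz[idx, , drop = FALSE] %*% t(q)
    # squared Euclidean distance is monotone in the central angle
    d2 <- outer(rowSums(rotated^2), rowSums(xyz[idx, ]^2), `+`) -
      2 * tcrossprod(rotated, xyz[idx, , drop = FALSE])
    perm[idx] <- idx[.greedy_assign(d2)]
  }
  perm
}

#' Spin permutation test for the correlation of two parcel maps
#'
#' Tests the spatial correlation of two parcel-wise maps against a null that
#' preserves spatial autocorrelation: each permutation draws a uniform random
#' 3D rotation, applies it to the left-hemisphere centroids and its
#' sagittal-mirror conjugate to the right, and reassigns each parcel the
#' value of the nearest source parcel under the rotation, with uniqueness
#' enforced (greedy one-to-one matching), so the null maps are true
#' within-hemisphere permutations of `map_a`. The two-sided p-value uses the
#' add-one estimator `p = (1 + #{|null r| >= |observed r|}) / (n_perm + 1)`.
#'
#' @param map_a,map_b numeric parcel vectors (non-constant), in scheme order.
#' @param scheme parcellation scheme with unit-sphere centroids.
#' @param n_perm number of rotations (default 1000).
#' @param seed integer seed.
#' @return a `spin_null` list: `observed_r`, `null_r`, `p`, `n_perm`.
#' @export
spin_test <- function(map_a, map_b, scheme, n_perm = 1000L, seed = 1L) {
  validate_parcellation(scheme)
  if (n_perm < 1) stop_invalid("n_perm must be >= 1")
  if (length(map_a) != nrow(scheme) || length(map_b) != nrow(scheme)) {
    stop_invalid("maps must have one value per parcel")
  }
  if (sd(map_a) == 0 || sd(map_b) == 0) {
    stop_invalid("correlation undefined for a constant map")
  }
  observed <- cor(map_a, map_b)
  null_r <- with_seed(child_seed(seed, 8L), {
    vapply(seq_len(n_perm), function(b) {
      perm <- spin_permutation_indices(scheme, random_rotation())
      cor(map_a[perm], map_b)
    }, 0)
  })
  p <- (1 + sum(abs(null_r) >= abs(observed))) / (n_perm + 1)
  structure(list(observed_r = observed, null_r = null_r, p = p,
                 n_perm = as.integer(n_perm)),
            class = "spin_null")
}

#' @export
print.spin_null <- function(x, ...) {
  cat(sprintf("spin test: r = %.3f, p = %.4g (%d rotations)\n",
              x$observed_r, x$p, x$n_perm))
  invisible(x)
}

#' Stratify an effect map by community or hierarchy labels
#'
#' @param effects an `effect_map` from [fit_mglm()].
#' @param scheme parcellation scheme labelling every parcel.
#' @param by "community" or "hierarchy".
#' @return data frame with one row per label: `label`, `mean_T2`, `sd_T2`,
#'   `n_parcels`, `n_significant`.
#' @export
stratify_effects <- function(effects, scheme, by = c("community", "hierarchy")) {
  by <- match.arg(by)
  if (nrow(effects) != nrow(scheme)) {
    stop_invalid("effect map and parcellation differ in length")
  }
  labels <- scheme[[by]]
  if (anyNA(labels)) stop_invalid("unlabeled parcel(s) present")
  out <- do.call(rbind, lapply(unique(labels), function(l) {
    sel <- labels == l
    data.frame(label = l,
               mean_T2 = mean(effects$T2[sel]),
               sd_T2 = if (sum(sel) > 1) sd(effects$T2[sel]) else 0,
               n_parcels = sum(sel),
               n_significant = sum(effects$significant[sel]))
  }))
  rownames(out) <- NULL
  out
}

#' Whole-map summary of an effect map
#'
#' @param effects an `effect_map`.
#' @return list with `mean_T2`, `sd_T2`, `n_significant`.
#' @export
summarize_template <- function(effects) {
  if (!nrow(effects)) stop_invalid("empty effect map")
  list(mean_T2 = mean(effects$T2),
       sd_T2 = if (nrow(effects) > 1) sd(effects$T2) else 0,
       n_significant = sum(effects$significant))
}

#' Flatten aligned gradient sets into a subject-by-feature matrix
#'
#' Concatenates G1, G2, ..., Gk per subject (e.g. 600 features for 200
#' parcels and 3 gradients).
#'
#' @param aligned list of aligned [gradient_set()] objects or a
#'   subjects x parcels x k array.
#' @return subjects x (parcels * k) matrix.
#' @export
gradient_features <- function(aligned) {
  arr <- as_gradient_array(aligned)
  n <- dim(arr)[1]
  matrix(arr, nrow = n)
}

stratified_folds <- function(labels, n_folds) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' Cross-validated template utility: classification and prediction
#'
#' Quantifies how useful a set of aligned gradients is for clinical tasks:
#' classification of case vs control with a linear maximum-margin classifier
#' (support vector machine), or prediction of a continuous score with
#' L2-penalised (ridge) linear regression. Gradient features are concatenated
#' with age, sex, and one-hot site covariates; performance is evaluated by
#' stratified k-fold cross-validation repeated `n_repeats` times with
#' repeat-specific fold draws.
#'
#' @param aligned_features subjects x features matrix (see
#'   [gradient_features()]).
#' @param covariates covariate data frame (age, sex, site appended as
#'   features).
#' @param labels_or_scores two-level factor/character for `task = "classify"`
#'   or a numeric score for `task = "predict"`.
#' @param task "classify" or "predict".
#' @param n_folds folds per repeat (default 5).
#' @param n_repeats repetitions with re-drawn folds (default 100).
#' @param seed integer seed.
#' @param ridge_lambda fixed ridge penalty for the prediction task.
#' @return data frame with one row per metric (`accuracy`, or `correlation`
#'   and `mae`), columns `mean`, `sd`, `n_repeats`.
#' @export
evaluate_template_utility <- function(aligned_features, covariates,
                                      labels_or_scores,
                                      task = c("classify", "predict"),
                                      n_folds = 5L, n_repeats = 100L,
                                      seed = 1L, ridge_lambda = 1.0) {
  task <- match.arg(task)
  feats <- as.matrix(aligned_features)
  if (any(!is.finite(feats))) stop_invalid("features contain non-finite values")
  n <- nrow(feats)
  if (n < n_folds) stop_invalid("fewer subjects (%d) than folds (%d)", n, n_folds)
  x <- cbind(feats, build_design(covariates)[, -1, drop = FALSE])

  if (task == "classify") {
    y <- factor(labels_or_scores)
    if (nlevels(y) != 2) stop_invalid("classification requires exactly 2 classes")
    if (min(table(y)) < n_folds) {
      stop_invalid("each class needs at least n_folds subjects")
    }
    per_repeat <- with_seed(child_seed(seed, 9L), {
      vapply(seq_len(n_repeats), function(r) {
        folds <- stratified_folds(y, n_folds)
        pred <- factor(rep(levels(y)[1], n), levels = levels(y))
        for (f in seq_len(n_folds)) {
          tr <- folds != f
          fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "linear",
                            cost = 1, scale = FALSE)
          pred[!tr] <- predict(fit, x[!tr, , drop = FALSE])
        }
        mean(pred == y)
      }, 0)
    })
    out <- data.frame(metric = "accuracy", mean = mean(per_repeat),
                      sd = sd(per_repeat), n_repeats = n_repeats)
  } else {
    y <- as.numeric(labels_or_scores)
    if (sd(y) == 0) stop_invalid("prediction target is constant")
    res <- with_seed(child_seed(seed, 9L), {
      vapply(seq_len(n_repeats), function(r) {
        folds <- rep_len(seq_len(n_folds), n)[sample(n)]
        pred <- numeric(n)
        for (f in seq_len(n_folds)) {
          tr <- folds != f
          fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], alpha = 0,
                                lambda = ridge_lambda, standardize = TRUE)
          pred[!tr] <- predict(fit, x[!tr, , drop = FALSE])[, 1]
        }
        c(cor(pred, y), mean(abs(pred - y)))
      }, c(0, 0))
    })
    out <- data.frame(metric = c("correlation", "mae"),
                      mean = c(mean(res[1, ]), mean(res[2, ])),
                      sd = c(sd(res[1, ]), sd(res[2, ])),
                      n_repeats = n_repeats)
  }
  rownames(out) <- NULL
  out
}
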