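# Shared fixtures: everything is generated in code at test time.

tiny_scheme <- function(n = 40, seed = 1) {
  make_parcellation(n, n_communities = 4, n_hierarchy = 2, seed = seed)
}

# a hand-held 4-parcel parcellation with homologue map 0<->2, 1<->3
micro_scheme <- function() {
  s <- data.frame(
    parcel_id = 0:3,
    hemisphere = c("L", "L", "R", "R"),
    x = c(-0.6, -0.8, 0.6, 0.8),
    y = c(0.8, 0.0, 0.8, 0.0),
    z = c(0.0, 0.6, 0.0, 0.6),
    community = c("a", "b", "a", "b"),
    hierarchy = c("h1", "h2", "h1", "h2"),
    homologue = c(2L, 3L, 0L, 1L),
    stringsAsFactors = FALSE
  )
  class(s) <- c("parcellation", "data.frame")
  validate_parcellation(s)
  s
}

# dense random symmetric non-negative affinity (connected by construction)
random_affinity <- function(p, seed) {
  set.seed(seed)
  w <- matrix(runif(p * p, 0.05, 1), p, p)
  w <- (w + t(w)) / 2
  diag(w) <- 1
  w
}

random_orthogonal <- function(k, seed) {
  set.seed(seed)
  qrd <- qr(matrix(rnorm(k * k), k, k))
  qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))), k)
}

# small two-group FC cohort with sensible defaults for fast tests
small_fc_cohort <- function(scheme, n_case = 5, n_control = 5, seed = 1,
                            effect_size = 0, ...) {
  truth <- make_ground_truth(scheme, n_affected = 5,
                             effect_size = effect_size, seed = seed)
  simulate_fc_cohort(scheme, n_case, n_control, truth = truth,
                     series_length = 100, ...)
}

subject_covariate_table <- function(subjects) {
  do.call(rbind, lapply(subjects, function(s) {
    data.frame(subject_id = s$subject_id, group = s$group, age = s$age,
               sex = s$sex, site = s$site, motion = s$motion,
               stringsAsFactors = FALSE)
  }))
}

# dense-oracle diffusion map via the *non-symmetric* Markov operator:
# an independent eigendecomposition route for cross-checking
oracle_diffusion_map <- function(w, k = 3, alpha = 0.5) {
  d <- rowSums(w)
  w1 <- w / outer(d^alpha, d^alpha)
  d1 <- rowSums(w1)
  p_op <- w1 / d1
  e <- eigen(p_op)
  lam <- Re(e$values)
  ord <- order(lam, decreasing = TRUE)
  lam <- lam[ord]
  v <- Re(e$vectors[, ord, drop = FALSE])
  psi <- v * sqrt(d1)
  psi <- sweep(psi, 2, sqrt(colSums(psi^2)), "/")
  phi <- psi / psi[, 1]
  idx <- seq_len(k) + 1L
  comps <- phi[, idx, drop = FALSE] *
    matrix(lam[idx] / (1 - lam[idx]), nrow(w), k, byrow = TRUE)
  for (j in seq_len(k)) {
    i <- which.max(abs(comps[, j]))
    if (comps[i, j] < 0) comps[, j] <- -comps[, j]
  }
  list(components = comps, eigenvalues = lam[idx])
}

# brute-force Benjamini-Hochberg step-up, written independently of fdr_bh
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  q[o] <- p[o] * (n / seq_len(n))
  # enforce monotonicity from the largest rank downwards
  for (i in (n - 1):1) {
    if (n == 1) break
    q[o[i]] <- min(q[o[i]], q[o[i + 1]])
  }
  pmin(q, 1)
}

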