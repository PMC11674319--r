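#' Gradient set container
#'
#' Holds the low-dimensional connectome gradients G1..Gk for one connectome:
#' the parcels x k component matrix, the associated non-trivial eigenvalues,
#' and the fraction of embedding information each gradient carries.
#'
#' @param components parcels x k numeric matrix.
#' @param eigenvalues k non-increasing, non-negative eigenvalues.
#' @param variance_explained k ratios in \[0, 1\].
#' @param extra optional named list of additional metadata (e.g. the
#'   per-hemisphere eigenvalues of a structural embedding).
#' @return a `gradient_set` list.
#' @export
gradient_set <- function(components, eigenvalues, variance_explained,
                         extra = list()) {
  components <- as.matrix(components)
  k <- ncol(components)
  if (length(eigenvalues) != k || length(variance_explained) != k) {
    stop_invalid("eigenvalues / variance_explained must have length k = %d", k)
  }
  if (is.unsorted(rev(eigenvalues), strictly = FALSE)) {
    stop_invalid("eigenvalues must be non-increasing")
  }
  colnames(components) <- paste0("G", seq_len(k))
  structure(
    c(list(components = components, eigenvalues = eigenvalues,
           variance_explained = variance_explained), extra),
    class = "gradient_set"
  )
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf("gradient_set: %d parcels x %d gradients; variance explained %s\n",
              nrow(x$components), ncol(x$components),
              paste(sprintf("%.1f%%", 100 * x$variance_explained),
                    collapse = ", ")))
  invisible(x)
}

#' Row-wise sparsification of a connectivity matrix
#'
#' Keeps, for every row, the `ceil(density * (p - 1))` largest off-diagonal
#' values and zeroes the rest; the diagonal is excluded from the ranking and
#' set to 0. Ties are broken towards the lower column index so the result is
#' deterministic. The output may be asymmetric, as each row is thresholded
#' independently.
#'
#' @param m square numeric matrix (a `connectivity_matrix` is accepted).
#' @param density fraction of off-diagonal entries kept per row, in (0, 1].
#' @return plain numeric matrix of the same size.
#' @export
row_threshold <- function(m, density = 0.10) {
  if (!is_square(m)) stop_invalid("m must be square")
  if (density <= 0 || density > 1) stop_invalid("density must be in (0, 1]")
  v <- unclass(m)
  p <- nrow(v)
  k <- ceiling(density * (p - 1))
  out <- matrix(0, p, p)
  for (i in seq_len(p)) {
    vals <- v[i, ]
    vals[i] <- -Inf
    keep <- order(-vals, seq_len(p))[seq_len(k)]
    out[i, keep] <- v[i, keep]
  }
  diag(out) <- 0
  out
}

row_cosine <- function(m, what = "affinity input") {
  v <- unclass(m)
  norms <- sqrt(rowSums(v^2))
  zero <- which(norms == 0)
  if (length(zero)) {
    stop_invalid("%s has all-zero row(s): %s", what,
                 paste(head(zero, 5), collapse = ", "))
  }
  cs <- tcrossprod(v / norms)
  clip((cs + t(cs)) / 2, -1, 1)
}

#' Normalized-angle affinity matrix
#'
#' Converts row-wise cosine similarity into `1 - acos(cos_sim) / pi`, an
#' affinity in \[0, 1\] where 1 means identical connection patterns and 0
#' means opposite patterns — avoiding the negative similarities a raw cosine
#' kernel produces.
#'
#' @param m sparse (row-thresholded) or dense connectivity matrix with no
#'   all-zero rows.
#' @return an `affinity_matrix` (matrix with a `kernel` attribute), symmetric
#'   with unit diagonal.
#' @export
normalized_angle_affinity <- function(m) {
  a <- 1 - acos(row_cosine(m)) / pi
  diag(a) <- 1
  structure(a, kernel = "normalized_angle",
            class = c("affinity_matrix", "matrix", "array"))
}

#' Cosine similarity affinity matrix
#'
#' Row-wise cosine similarity with negative values floored at 0, since the
#' diffusion operator requires non-negative affinities.
#'
#' @inheritParams normalized_angle_affinity
#' @return an `affinity_matrix` with unit diagonal.
#' @export
cosine_affinity <- function(m) {
  a <- pmax(row_cosine(m), 0)
  diag(a) <- 1
  structure(a, kernel = "cosine",
            class = c("affinity_matrix", "matrix", "array"))
}

# Connected components of the positive-entry graph (simple BFS; avoids a
# graph-library dependency for a 10-line check).
affinity_components <- function(a) {
  p <- nrow(a)
  comp <- integer(p)
  cur <- 0L
  for (s in seq_len(p)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      nb <- which(a[i, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Diffusion map embedding
#'
#' Estimates connectome gradients as the leading non-trivial eigenvectors of
#' the diffusion operator built from an affinity matrix. The affinity `W` is
#' density-normalised by `W_ij / (d_i^alpha d_j^alpha)` (alpha = 0.5,
#' anisotropic diffusion), row-normalised to a Markov transition operator,
#' and eigendecomposed through its symmetric conjugate. The trivial constant
#' eigenvector (eigenvalue 1) is dropped; component i is eigenvector i+1
#' scaled by `lambda / (1 - lambda)` (the automatic diffusion-time
#' convention). Each component's sign is fixed so its largest-magnitude
#' element is positive, making embeddings reproducible despite eigenvector
#' sign ambiguity. Variance explained is each retained eigenvalue over the
#' sum of all positive non-trivial eigenvalues.
#'
#' @param a symmetric non-negative affinity matrix describing a connected
#'   graph.
#' @param k number of gradients to retain (default 3).
#' @param alpha density-normalisation exponent in \[0, 1\]; 0.5 by default.
#' @return a [gradient_set()].
#' @export
diffusion_map <- function(a, k = 3L, alpha = 0.5) {
  if (!is_square(a)) stop_invalid("affinity must be square")
  p <- nrow(a)
  if (k >= p) stop_invalid("k must be < number of parcels")
  w <- unclass(a)
  if (min(w) < 0) stop_invalid("affinity must be non-negative")
  check_symmetric(w, 1e-10, "affinity")
  comp <- affinity_components(w)
  if (max(comp) > 1) {
    sizes <- table(comp)
    stop_invalid("affinity graph is disconnected (%d components of sizes %s)",
                 max(comp), paste(sizes, collapse = ", "))
  }

  d <- rowSums(w)
  w1 <- w / outer(d^alpha, d^alpha)
  d1 <- rowSums(w1)
  m <- w1 / outer(sqrt(d1), sqrt(d1))
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  lam <- e$values
  # map conjugate-space eigenvectors back to Markov-operator eigenvectors;
  # row-dividing by the trivial eigenvector makes the constant mode all-ones
  phi <- e$vectors / e$vectors[, 1]

  lam_nt <- lam[-1]
  idx <- seq_len(k) + 1L
  comps <- phi[, idx, drop = FALSE] *
    matrix(lam[idx] / (1 - lam[idx]), p, k, byrow = TRUE)
  comps <- fix_signs(comps)
  pos_sum <- sum(lam_nt[lam_nt > 0])
  gradient_set(
    components = comps,
    eigenvalues = lam[idx],
    variance_explained = lam[idx] / pos_sum,
    extra = list(all_eigenvalues = lam, alpha = alpha)
  )
}

# Deterministic sign convention: the largest-|x| element of each column is
# made positive (idempotent).
fix_signs <- function(comps) {
  for (j in seq_len(ncol(comps))) {
    i <- which.max(abs(comps[, j]))
    if (comps[i, j] < 0) comps[, j] <- -comps[, j]
  }
  comps
}

#' Functional connectome gradients
#'
#' The standard functional embedding path: row-threshold the Fisher-z
#' connectivity to the top `density` entries per row, build the affinity, and
#' run the diffusion map. The identical code path serves group-level and
#' subject-level matrices.
#'
#' @param fc functional `connectivity_matrix` in state `fisher_z` (group
#'   average or single subject).
#' @param density row-threshold density (default 0.10, i.e. top 10% per row).
#' @param kernel "normalized_angle" (default) or "cosine".
#' @param k,alpha passed to [diffusion_map()].
#' @return a [gradient_set()].
#' @export
embed_functional <- function(fc, density = 0.10,
                             kernel = c("normalized_angle", "cosine"),
                             k = 3L, alpha = 0.5) {
  cm_check(fc, "functional", "fisher_z", "fc")
  kernel <- match.arg(kernel)
  sp <- row_threshold(fc, density)
  aff <- switch(kernel,
                normalized_angle = normalized_angle_affinity(sp),
                cosine = cosine_affinity(sp))
  diffusion_map(aff, k = k, alpha = alpha)
}

#' Structural connectome gradients (hemisphere-separate)
#'
#' Structural gradients are estimated per hemisphere to respect
#' lateralisation: each intra-hemispheric block of the log-transformed
#' connectome is embedded independently (no thresholding — the structural
#' connectome is already sparse), then the right-hemisphere gradients are
#' aligned onto the left via Procrustes rotation over homologous parcels and
#' the two are concatenated into a whole-brain gradient set. If the scheme
#' has no complete homologue map, hemispheres are matched by eigenvalue
#' order with a warning.
#'
#' @param sc structural `connectivity_matrix` in state `log`.
#' @param scheme parcellation scheme.
#' @param kernel,k,alpha as in [embed_functional()].
#' @return a [gradient_set()] whose `eigenvalues`/`variance_explained` are
#'   the left hemisphere's, with both hemispheres' spectra in
#'   `$hemisphere_eigenvalues`.
#' @export
embed_structural <- function(sc, scheme,
                             kernel = c("normalized_angle", "cosine"),
                             k = 3L, alpha = 0.5) {
  cm_check(sc, "structural", "log", "sc")
  kernel <- match.arg(kernel)
  validate_parcellation(scheme)
  if (nrow(sc) != nrow(scheme)) {
    stop_invalid("matrix size does not match parcellation")
  }
  aff_fun <- switch(kernel,
                    normalized_angle = normalized_angle_affinity,
                    cosine = cosine_affinity)
  idx_l <- which(scheme$hemisphere == "L")
  idx_r <- which(scheme$hemisphere == "R")
  g <- lapply(list(L = idx_l, R = idx_r), function(idx) {
    diffusion_map(aff_fun(unclass(sc)[idx, idx, drop = FALSE]),
                  k = k, alpha = alpha)
  })

  comps_r <- g$R$components
  if (!anyNA(scheme$homologue)) {
    # rows of the right block reordered to homologue order of the left block,
    # then rotated onto the left components
    match_r <- match(scheme$homologue[idx_l] + 1L, idx_r)
    pr <- procrustes_rotate(comps_r[match_r, , drop = FALSE],
                            g$L$components)
    comps_r <- comps_r %*% pr$rotation
  } else {
    warning("no homologue map; matching hemispheres by eigenvalue order",
            call. = FALSE)
  }
  comps <- matrix(0, nrow(scheme), k)
  comps[idx_l, ] <- g$L$components
  comps[idx_r, ] <- comps_r
  gradient_set(
    components = fix_signs(comps),
    eigenvalues = g$L$eigenvalues,
    variance_explained = g$L$variance_explained,
    extra = list(hemisphere_eigenvalues = list(L = g$L$eigenvalues,
                                               R = g$R$eigenvalues),
                 hemisphere_variance_explained =
                   list(L = g$L$variance_explained,
                        R = g$R$variance_explained))
  )
}
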