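#' Build a synthetic spherical parcellation scheme
#'
#' Places `n_parcels / 2` parcel centroids quasi-uniformly on each unit
#' hemisphere (a spherical Fibonacci lattice restricted to one half-shell,
#' mirrored across the sagittal plane), assigns spatially contiguous
#' community patches and latitude-band hierarchy levels, and records the
#' mirror-image homologous parcel of every parcel. The geometry emulates a
#' standard cortical parcellation (e.g. a 200-parcel atlas with 7 functional
#' communities and 4 hierarchy levels) well enough to drive spherical
#' rotation null models and hemisphere-aware embeddings.
#'
#' @param n_parcels even integer >= 8, total number of parcels.
#' @param n_communities number of community labels (spatial patches per
#'   hemisphere, mirrored). With the default 7 the canonical community names
#'   (visual, somatomotor, dorsal/ventral attention, limbic, frontoparietal,
#'   default mode) are used.
#' @param n_hierarchy number of cortical hierarchy levels (latitude bands).
#'   With the default 4 the canonical names (idiotypic, unimodal, heteromodal
#'   association, paralimbic) are used.
#' @param seed integer seed controlling the community clustering
#'   initialisation; the lattice itself is deterministic.
#' @return A `parcellation` data frame with columns `parcel_id` (0-based),
#'   `hemisphere` ("L"/"R"), `x`, `y`, `z` (unit centroid), `community`,
#'   `hierarchy`, and `homologue` (0-based id of the contralateral homologue).
#' @examples
#' scheme <- make_parcellation(40, n_communities = 4, n_hierarchy = 2, seed = 1)
#' table(scheme$hemisphere)
#' @export
make_parcellation <- function(n_parcels, n_communities = 7L, n_hierarchy = 4L,
                              seed = 1L) {
  if (n_parcels < 8 || n_parcels %% 2 != 0) {
    stop_invalid("n_parcels must be an even integer >= 8, got %s", n_parcels)
  }
  n_half <- n_parcels / 2
  if (n_communities < 1 || n_communities > n_half) {
    stop_invalid("n_communities must be in [1, n_parcels/2], got %s",
                 n_communities)
  }
  if (n_hierarchy < 1 || n_hierarchy > n_half) {
    stop_invalid("n_hierarchy must be in [1, n_parcels/2], got %s", n_hierarchy)
  }

  # Fibonacci-style lattice on the right half-shell (x > 0): full polar range,
  # azimuth folded into (-pi/2, pi/2) by the golden angle.
  i <- seq_len(n_half) - 0.5
  zc <- 1 - 2 * i / n_half
  golden <- pi * (3 - sqrt(5))
  az <- ((i * golden) %% pi) - pi / 2
  r <- sqrt(pmax(0, 1 - zc^2))
  right <- cbind(x = r * cos(az), y = r * sin(az), z = zc)
  left <- right
  left[, "x"] <- -left[, "x"]

  xyz <- rbind(left, right)
  hemisphere <- rep(c("L", "R"), each = n_half)
  # Mirror pairing: left parcel k <-> right parcel k.
  homologue <- as.integer(c(seq_len(n_half) + n_half, seq_len(n_half)) - 1L)

  # Contiguous community patches: k-means Voronoi cells on the right
  # hemisphere, mirrored to the left; clusters relabelled by order of first
  # occurrence so labels are reproducible.
  km <- with_seed(child_seed(seed, 1L), {
    kmeans(right, centers = n_communities, nstart = 10, iter.max = 50)
  })
  cl <- km$cluster
  cl <- match(cl, unique(cl))
  community_names <- if (n_communities == 7) {
    c("visual", "somatomotor", "dorsal_attention", "ventral_attention",
      "limbic", "frontoparietal", "default_mode")
  } else {
    paste0("community_", seq_len(n_communities))
  }
  community <- community_names[c(cl, cl)]

  # Hierarchy: equal-count latitude bands (inferior -> superior), mirrored.
  band <- cut(rank(zc, ties.method = "first"),
              breaks = seq(0, n_half, length.out = n_hierarchy + 1),
              labels = FALSE, include.lowest = TRUE)
  hierarchy_names <- if (n_hierarchy == 4) {
    c("idiotypic", "unimodal", "heteromodal_association", "paralimbic")
  } else {
    paste0("level_", seq_len(n_hierarchy))
  }
  hierarchy <- hierarchy_names[c(band, band)]

  scheme <- data.frame(
    parcel_id = seq_len(n_parcels) - 1L,
    hemisphere = hemisphere,
    x = xyz[, "x"], y = xyz[, "y"], z = xyz[, "z"],
    community = community,
    hierarchy = hierarchy,
    homologue = homologue,
    stringsAsFactors = FALSE
  )
  class(scheme) <- c("parcellation", "data.frame")
  validate_parcellation(scheme)
  scheme
}

#' Validate a parcellation scheme
#'
#' Checks the structural invariants of a [make_parcellation()]-style table:
#' unit-norm centroids, a two-hemisphere partition, and (where defined) a
#' homologue map that is an involution crossing hemispheres.
#'
#' @param scheme a `parcellation` data frame.
#' @param tol tolerance on centroid unit norms.
#' @return the scheme, invisibly; errors describe the violated invariant.
#' @export
validate_parcellation <- function(scheme, tol = 1e-9) {
  required <- c("parcel_id", "hemisphere", "x", "y", "z", "community",
                "hierarchy", "homologue")
  missing_cols <- setdiff(required, names(scheme))
  if (length(missing_cols)) {
    stop_invalid("parcellation is missing columns: %s",
                 paste(missing_cols, collapse = ", "))
  }
  if (!all(scheme$parcel_id == seq_len(nrow(scheme)) - 1L)) {
    stop_invalid("parcel_id must be 0-based and consecutive")
  }
  norms <- sqrt(scheme$x^2 + scheme$y^2 + scheme$z^2)
  bad <- which(abs(norms - 1) > tol)
  if (length(bad)) {
    stop_invalid("centroids are not unit vectors (first offender: parcel %d)",
                 scheme$parcel_id[bad[1]])
  }
  if (!all(scheme$hemisphere %in% c("L", "R"))) {
    stop_invalid("hemisphere labels must be 'L' or 'R'")
  }
  h <- scheme$homologue
  defined <- !is.na(h)
  if (any(defined)) {
    idx <- h[defined] + 1L
    if (any(idx < 1 | idx > nrow(scheme))) {
      stop_invalid("homologue ids outside the parcel range")
    }
    back <- scheme$homologue[idx]
    if (any(is.na(back)) || any(back != scheme$parcel_id[defined])) {
      stop_invalid("homologue map is not an involution")
    }
    if (any(scheme$hemisphere[idx] == scheme$hemisphere[defined])) {
      stop_invalid("homologue map must cross hemispheres")
    }
  }
  invisible(scheme)
}

centroid_matrix <- function(scheme) {
  as.matrix(scheme[, c("x", "y", "z")])
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf(
    "parcellation: %d parcels (%d L / %d R), %d communities, %d hierarchy levels\n",
    nrow(x), sum(x$hemisphere == "L"), sum(x$hemisphere == "R"),
    length(unique(x$community)), length(unique(x$hierarchy))
  ))
  invisible(x)
}
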