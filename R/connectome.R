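#' Connectivity matrix container
#'
#' A square parcel-by-parcel matrix tagged with its modality and transform
#' state, so downstream operations can enforce their contracts (e.g. the
#' Fisher transform only applies to raw functional correlations).
#'
#' @param values square numeric matrix.
#' @param modality "functional" or "structural".
#' @param transform_state one of "raw_r", "fisher_z" (functional) or
#'   "raw_count", "log" (structural).
#' @return a `connectivity_matrix` (a matrix with `modality` and
#'   `transform_state` attributes).
#' @export
connectivity_matrix <- function(values,
                                modality = c("functional", "structural"),
                                transform_state = c("raw_r", "fisher_z",
                                                    "raw_count", "log")) {
  modality <- match.arg(modality)
  transform_state <- match.arg(transform_state)
  if (!is_square(values)) stop_invalid("connectivity values must be square")
  if (any(!is.finite(values))) {
    stop_invalid("connectivity values contain non-finite entries")
  }
  valid_states <- list(functional = c("raw_r", "fisher_z"),
                       structural = c("raw_count", "log"))
  if (!transform_state %in% valid_states[[modality]]) {
    stop_invalid("transform_state '%s' is invalid for %s connectivity",
                 transform_state, modality)
  }
  if (modality == "structural" && min(values) < 0) {
    stop_invalid("structural connectivity must be non-negative")
  }
  structure(values, modality = modality, transform_state = transform_state,
            class = c("connectivity_matrix", "matrix", "array"))
}

cm_modality <- function(m) attr(m, "modality")
cm_state <- function(m) attr(m, "transform_state")

cm_check <- function(m, modality = NULL, state = NULL, what = "input") {
  if (!inherits(m, "connectivity_matrix")) {
    stop_invalid("%s must be a connectivity_matrix", what)
  }
  if (!is.null(modality) && cm_modality(m) != modality) {
    stop_invalid("%s must be %s connectivity, got %s",
                 what, modality, cm_modality(m))
  }
  if (!is.null(state) && cm_state(m) != state) {
    stop_invalid("%s must be in state '%s', got '%s'",
                 what, state, cm_state(m))
  }
  invisible(m)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity_matrix: %d x %d, %s (%s)\n",
              nrow(x), ncol(x), cm_modality(x), cm_state(x)))
  invisible(x)
}

#' Functional connectivity from parcel time series
#'
#' Pearson correlation between every pair of parcel time series.
#'
#' @param time_series parcels x timepoints numeric matrix (>= 3 timepoints,
#'   no constant rows).
#' @return functional `connectivity_matrix` in state `raw_r` (symmetric, unit
#'   diagonal).
#' @export
build_fc <- function(time_series) {
  if (!is.matrix(time_series) || ncol(time_series) < 3) {
    stop_invalid("time_series must be a parcels x T matrix with T >= 3")
  }
  sds <- apply(time_series, 1, sd)
  flat <- which(sds == 0)
  if (length(flat)) {
    stop_invalid("constant time series for parcel row(s): %s",
                 paste(head(flat, 5), collapse = ", "))
  }
  r <- cor(t(time_series))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  connectivity_matrix(r, "functional", "raw_r")
}

#' Fisher r-to-z transform of a correlation matrix
#'
#' Applies `atanh` to the off-diagonal correlations. The diagonal is set to 0
#' (atanh(1) diverges; self-similarity is ignored by the affinity kernels
#' downstream, but a defined value keeps the matrix total). Off-diagonal
#' correlations at exactly +/-1 — possible with short series — are clipped to
#' +/-(1 - 1e-7) with a warning.
#'
#' @param fc functional `connectivity_matrix` in state `raw_r`.
#' @return functional `connectivity_matrix` in state `fisher_z`.
#' @export
fisher_z <- function(fc) {
  cm_check(fc, "functional", "raw_r", "fc")
  v <- unclass(fc)
  off <- row(v) != col(v)
  saturated <- off & abs(v) >= 1
  if (any(saturated)) {
    warning(sprintf("%d off-diagonal |r| >= 1 entries clipped before atanh",
                    sum(saturated)), call. = FALSE)
    v[saturated] <- sign(v[saturated]) * (1 - 1e-7)
  }
  z <- atanh(v)
  diag(z) <- 0
  connectivity_matrix(z, "functional", "fisher_z")
}

#' Group-average functional connectivity
#'
#' Elementwise mean of subject-level Fisher-z matrices; the standard
#' group-representative functional connectome.
#'
#' @param z_matrices non-empty list of functional `connectivity_matrix`
#'   objects in state `fisher_z`, all the same size.
#' @return functional `connectivity_matrix` in state `fisher_z`.
#' @export
group_average_fc <- function(z_matrices) {
  if (!length(z_matrices)) stop_invalid("need at least one matrix")
  for (m in z_matrices) cm_check(m, "functional", "fisher_z", "every matrix")
  p <- nrow(z_matrices[[1]])
  if (!all(vapply(z_matrices, nrow, 0L) == p)) {
    stop_invalid("matrices have mixed shapes")
  }
  avg <- Reduce(`+`, lapply(z_matrices, unclass)) / length(z_matrices)
  connectivity_matrix(avg, "functional", "fisher_z")
}

#' Log-transform structural connectivity
#'
#' Maps streamline counts by `log(1 + x)`, reducing the heavy right tail of
#' connection strengths while preserving zeros and ordering.
#'
#' @param sc structural `connectivity_matrix` in state `raw_count`.
#' @return structural `connectivity_matrix` in state `log`.
#' @export
log_transform_sc <- function(sc) {
  cm_check(sc, "structural", "raw_count", "sc")
  connectivity_matrix(log1p(unclass(sc)), "structural", "log")
}

#' Distance-dependent group consensus structural connectome
#'
#' Builds a group-representative structural connectome that preserves the
#' subject-typical edge-length distribution. Candidate edges (present in at
#' least one subject) are binned by inter-centroid great-circle distance into
#' `n_bins` equal-count bins, intra- and inter-hemispheric edges binned
#' separately. Within each bin the K edges most frequently present across
#' subjects are retained, where K is the rounded mean per-subject count of
#' present edges in that bin; ties are broken by higher mean nonzero weight,
#' then by lower parcel-index pair, so the result is fully deterministic.
#' Retained edges get the mean of their nonzero subject weights; everything
#' else is zero.
#'
#' @param sc_list list of >= 2 structural `connectivity_matrix` objects in
#'   state `raw_count`.
#' @param scheme parcellation scheme supplying centroids and hemispheres.
#' @param n_bins number of distance bins per hemisphere class (default 10).
#' @return structural `connectivity_matrix` in state `raw_count`, symmetric.
#' @export
distance_consensus_group_sc <- function(sc_list, scheme, n_bins = 10L) {
  if (length(sc_list) < 2) stop_invalid("need at least 2 subjects")
  if (n_bins < 1) stop_invalid("n_bins must be >= 1")
  validate_parcellation(scheme)
  p <- nrow(scheme)
  for (m in sc_list) {
    cm_check(m, "structural", "raw_count", "every matrix")
    if (nrow(m) != p) stop_invalid("matrix size does not match parcellation")
  }
  n_sub <- length(sc_list)
  d <- great_circle_dist(centroid_matrix(scheme))
  ut <- which(upper.tri(d), arr.ind = TRUE)
  edge_i <- ut[, 1]; edge_j <- ut[, 2]
  edge_d <- d[ut]
  inter <- scheme$hemisphere[edge_i] != scheme$hemisphere[edge_j]

  pres <- matrix(0, nrow(ut), n_sub)
  wsum <- numeric(nrow(ut))
  for (s in seq_len(n_sub)) {
    w <- unclass(sc_list[[s]])[ut]
    pres[, s] <- w > 0
    wsum <- wsum + w
  }
  n_pres <- rowSums(pres)
  mean_w <- ifelse(n_pres > 0, wsum / n_pres, 0)

  out <- matrix(0, p, p)
  for (class_inter in c(FALSE, TRUE)) {
    sel <- which(inter == class_inter & n_pres > 0)
    if (!length(sel)) next
    # equal-count distance bins over candidate edges
    br <- quantile(edge_d[sel], probs = seq(0, 1, length.out = n_bins + 1))
    br <- unique(br)
    bins <- cut(edge_d[sel], breaks = br, labels = FALSE,
                include.lowest = TRUE)
    for (b in sort(unique(bins))) {
      cand <- sel[bins == b]
      # mean per-subject present-edge count in this bin
      k <- round(sum(n_pres[cand]) / n_sub)
      if (k < 1) {
        message(sprintf("consensus: bin %d (%s-hemispheric) retains no edges",
                        b, if (class_inter) "inter" else "intra"))
        next
      }
      k <- min(k, length(cand))
      ord <- order(-n_pres[cand], -mean_w[cand], edge_i[cand], edge_j[cand])
      keep <- cand[ord[seq_len(k)]]
      out[cbind(edge_i[keep], edge_j[keep])] <- mean_w[keep]
    }
  }
  out <- out + t(out)
  connectivity_matrix(out, "structural", "raw_count")
}

#' Flip a connectivity matrix across hemispheres
#'
#' Permutes rows and columns by the homologue map, swapping each parcel with
#' its contralateral homologue — used to pool lateralised pathology (e.g.
#' mapping left-focus patients onto the right hemisphere) before group
#' analysis.
#'
#' @param m `connectivity_matrix`.
#' @param scheme parcellation with a complete homologue involution.
#' @return `connectivity_matrix` of the same modality and state.
#' @export
flip_hemispheres <- function(m, scheme) {
  cm_check(m, what = "m")
  validate_parcellation(scheme)
  if (anyNA(scheme$homologue)) {
    stop_invalid("homologue map incomplete; unmapped parcels: %s",
                 paste(scheme$parcel_id[is.na(scheme$homologue)],
                       collapse = ", "))
  }
  if (nrow(m) != nrow(scheme)) {
    stop_invalid("matrix size does not match parcellation")
  }
  perm <- scheme$homologue + 1L
  connectivity_matrix(unclass(m)[perm, perm], cm_modality(m), cm_state(m))
}
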