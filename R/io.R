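# Plain-text (TSV) readers and writers for every pipeline artifact.
# All numeric output uses 17 significant digits so write -> read round-trips
# reproduce doubles bit-exactly.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a square matrix as TSV
#'
#' The file carries a one-line header of 0-based parcel ids; the reader
#' validates squareness and rejects non-finite entries, naming the offending
#' cell.
#'
#' @param m numeric matrix (a `connectivity_matrix` is accepted; its tags are
#'   not serialised).
#' @param path file path.
#' @return `read_matrix` returns a plain numeric matrix.
#' @export
write_matrix <- function(m, path) {
  v <- unclass(m)
  lines <- c(paste(paste0("p", seq_len(ncol(v)) - 1L), collapse = "\t"),
             apply(v, 1, function(row) paste(fmt_num(row), collapse = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(tab)
  if (!is.numeric(m)) stop_invalid("%s: non-numeric entries", path)
  if (nrow(m) != ncol(m)) {
    stop_invalid("%s: matrix is %d x %d, expected square", path,
                 nrow(m), ncol(m))
  }
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_invalid("%s: non-finite entry at row %d, column %d", path,
                 bad[1, 1], bad[1, 2])
  }
  dimnames(m) <- NULL
  m
}

#' Write / read a parcellation table
#'
#' TSV schema: parcel_id, hemisphere, x, y, z, community, hierarchy,
#' homologue. The reader re-validates all scheme invariants (unit centroids,
#' homologue involution).
#'
#' @param scheme a `parcellation`.
#' @param path file path.
#' @return `read_parcellation` returns a validated `parcellation`.
#' @export
write_parcellation <- function(scheme, path) {
  out <- scheme
  for (col in c("x", "y", "z")) out[[col]] <- fmt_num(out[[col]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  tab$homologue <- as.integer(tab$homologue)
  class(tab) <- c("parcellation", "data.frame")
  validate_parcellation(tab)
  tab
}

#' Write / read a subject covariate table
#'
#' TSV schema: subject_id, group, age, sex, site, motion. The reader errors
#' on any missing required column, naming it.
#'
#' @param covariates data frame of subject covariates.
#' @param path file path.
#' @return `read_covariates` returns the covariate data frame.
#' @export
write_covariates <- function(covariates, path) {
  write.table(covariates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "age", "sex", "site")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop_invalid("%s: missing column(s): %s", path,
                 paste(missing_cols, collapse = ", "))
  }
  tab
}

#' Write / read a gradient set
#'
#' Components go to `<path>` as TSV (parcel_id, G1..Gk); eigenvalues and
#' variance-explained ratios go to a TSV sidecar `<path>.eigenvalues.tsv`.
#' The pair round-trips bit-exactly.
#'
#' @param g a [gradient_set()].
#' @param path TSV path; the sidecar is `paste0(path, ".eigenvalues.tsv")`.
#' @return `read_gradients` returns a `gradient_set`.
#' @export
write_gradients <- function(g, path) {
  comps <- g$components
  lines <- c(paste(c("parcel_id", colnames(comps)), collapse = "\t"),
             vapply(seq_len(nrow(comps)), function(i) {
               paste(c(i - 1L, fmt_num(comps[i, ])), collapse = "\t")
             }, ""))
  writeLines(lines, path)
  side <- data.frame(eigenvalue = fmt_num(g$eigenvalues),
                     variance_explained = fmt_num(g$variance_explained))
  write.table(side, paste0(path, ".eigenvalues.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gradients
#' @export
read_gradients <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t")
  side <- read.table(paste0(path, ".eigenvalues.tsv"), header = TRUE,
                     sep = "\t")
  gradient_set(as.matrix(tab[, -1, drop = FALSE]),
               eigenvalues = side$eigenvalue,
               variance_explained = side$variance_explained)
}

#' Write an effect map as TSV
#'
#' @param effects an `effect_map` from [fit_mglm()].
#' @param path file path.
#' @export
write_effect_map <- function(effects, path) {
  out <- as.data.frame(effects)
  for (col in c("T2", "F", "p", "q")) out[[col]] <- fmt_num(out[[col]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cohort to a directory
#'
#' One matrix file per subject per modality (`<subject_id>_fc.tsv` /
#' `<subject_id>_sc.tsv`), a covariate table, the parcellation, and a
#' ground-truth TSV of affected parcels.
#'
#' @param cohort list with `subjects` and `truth` as returned by the
#'   simulators.
#' @param scheme parcellation scheme.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, scheme, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cov_rows <- lapply(cohort$subjects, function(s) {
    data.frame(subject_id = s$subject_id, group = s$group, age = s$age,
               sex = s$sex, site = s$site, motion = s$motion)
  })
  write_covariates(do.call(rbind, cov_rows), file.path(dir, "covariates.tsv"))
  write_parcellation(scheme, file.path(dir, "parcellation.tsv"))
  for (s in cohort$subjects) {
    if (!is.null(s$fc)) {
      write_matrix(s$fc, file.path(dir, paste0(s$subject_id, "_fc.tsv")))
    }
    if (!is.null(s$sc)) {
      write_matrix(s$sc, file.path(dir, paste0(s$subject_id, "_sc.tsv")))
    }
  }
  truth <- cohort$truth
  gt <- data.frame(
    field = c("effect_size", "seed",
              rep("affected_parcel", length(truth$affected_parcels))),
    value = c(truth$effect_size, truth$seed, truth$affected_parcels)
  )
  write.table(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @param modality which matrices to load.
#' @return list with `subjects` (records with covariates and the requested
#'   `connectivity_matrix`) and `scheme`.
#' @export
read_cohort <- function(dir, modality = c("functional", "structural")) {
  modality <- match.arg(modality)
  covs <- read_covariates(file.path(dir, "covariates.tsv"))
  scheme <- read_parcellation(file.path(dir, "parcellation.tsv"))
  suffix <- if (modality == "functional") "_fc.tsv" else "_sc.tsv"
  subjects <- lapply(seq_len(nrow(covs)), function(i) {
    rec <- as.list(covs[i, ])
    path <- file.path(dir, paste0(rec$subject_id, suffix))
    m <- read_matrix(path)
    if (nrow(m) != nrow(scheme)) {
      stop_invalid("%s: %d parcels, parcellation has %d", path, nrow(m),
                   nrow(scheme))
    }
    if (modality == "functional") {
      rec$fc <- connectivity_matrix(m, "functional", "raw_r")
    } else {
      rec$sc <- connectivity_matrix(m, "structural", "raw_count")
    }
    rec
  })
  list(subjects = subjects, scheme = scheme)
}
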