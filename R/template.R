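#' Procrustes rotation of one gradient set onto another
#'
#' Finds the orthogonal k x k matrix R minimising
#' `||source %*% R - target||_F` (closed form from the singular value
#' decomposition of `t(source) %*% target`). No centering and no scaling are
#' applied, and reflections are allowed (full orthogonal group), so gradient
#' magnitudes — which the group statistics compare — are preserved exactly:
#' `||aligned||_F == ||source||_F`.
#'
#' @param source,target parcels x k numeric matrices of equal shape.
#' @return list with `aligned` (`source %*% rotation`) and `rotation`
#'   (orthogonal k x k matrix).
#' @export
procrustes_rotate <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (!all(dim(source) == dim(target))) {
    stop_invalid("source and target must have identical shapes")
  }
  if (ncol(source) > nrow(source)) {
    stop_invalid("k must not exceed the number of parcels")
  }
  s <- crossprod(source, target)
  sv <- svd(s)
  if (min(sv$d) < 1e-12 * max(sv$d, 1e-300)) {
    warning("rank-deficient cross-product; Procrustes solution is not unique",
            call. = FALSE)
  }
  r <- sv$u %*% t(sv$v)
  list(aligned = source %*% r, rotation = r)
}

#' Template strategy specification
#'
#' The six group-level template construction strategies: (1) cases +
#' controls of the study cohort; (2) study controls only; (3) study cases
#' only; (4) the independent reference cohort; (5) strategy 1 rotated onto
#' strategy 4; (6) strategy 2 rotated onto strategy 4.
#'
#' @param strategy integer 1-6.
#' @return a `template_spec` list with the strategy number, the study-subject
#'   selection, whether a reference cohort is required, and a description.
#' @export
template_spec <- function(strategy) {
  if (!strategy %in% 1:6) stop_invalid("strategy must be an integer in 1..6")
  info <- list(
    list(sel = "cases+controls", ref = FALSE, desc = "case + control (study)"),
    list(sel = "controls_only",  ref = FALSE, desc = "control (study)"),
    list(sel = "cases_only",     ref = FALSE, desc = "case (study)"),
    list(sel = "reference",      ref = TRUE,  desc = "reference"),
    list(sel = "cases+controls", ref = TRUE,
         desc = "case + control (study) -> reference"),
    list(sel = "controls_only",  ref = TRUE,
         desc = "control (study) -> reference")
  )[[strategy]]
  structure(list(strategy = as.integer(strategy), study_selection = info$sel,
                 needs_reference = info$ref, description = info$desc),
            class = "template_spec")
}

select_subjects <- function(subjects, selection) {
  groups <- vapply(subjects, function(s) s$group, "")
  keep <- switch(selection,
                 "cases+controls" = rep(TRUE, length(subjects)),
                 "controls_only" = groups == "control",
                 "cases_only" = groups == "case",
                 "reference" = rep(TRUE, length(subjects)))
  subjects[keep]
}

group_gradients <- function(subjects, scheme, modality, params) {
  if (!length(subjects)) stop_invalid("empty subject selection")
  if (modality == "functional") {
    zs <- lapply(subjects, function(s) fisher_z(s$fc))
    embed_functional(group_average_fc(zs), density = params$density,
                     kernel = params$kernel, k = params$k,
                     alpha = params$alpha)
  } else {
    scs <- lapply(subjects, function(s) s$sc)
    grp <- if (length(scs) >= 2) {
      distance_consensus_group_sc(scs, scheme, n_bins = params$n_bins)
    } else {
      scs[[1]]
    }
    embed_structural(log_transform_sc(grp), scheme, kernel = params$kernel,
                     k = params$k, alpha = params$alpha)
  }
}

default_embed_params <- function(params = list()) {
  defaults <- list(density = 0.10, kernel = "normalized_angle", k = 3L,
                   alpha = 0.5, n_bins = 10L)
  defaults[names(params)] <- params
  defaults
}

#' Build a group-level template gradient set
#'
#' Applies one of the six template strategies: strategies 1-3 embed a group
#' connectome of the selected study subjects; strategy 4 embeds the
#' reference cohort; strategies 5 and 6 compute the strategy-1/-2 template
#' and Procrustes-rotate it onto the strategy-4 template, combining the
#' study group's own connectivity geometry with the reference cohort's axes.
#'
#' @param study list of study subject records (from the simulators or read
#'   from disk).
#' @param reference list of reference subject records, required for
#'   strategies 4-6.
#' @param spec a [template_spec()] or a strategy number 1-6.
#' @param scheme parcellation scheme (needed for structural modality).
#' @param modality "functional" or "structural".
#' @param params optional list overriding embedding parameters
#'   (`density`, `kernel`, `k`, `alpha`, `n_bins`).
#' @return a [gradient_set()] with the spec attached as attribute
#'   `template_spec`.
#' @export
build_template <- function(study, reference = NULL, spec, scheme = NULL,
                           modality = c("functional", "structural"),
                           params = list()) {
  if (is.numeric(spec)) spec <- template_spec(spec)
  modality <- match.arg(modality)
  params <- default_embed_params(params)
  if (spec$needs_reference && is.null(reference)) {
    stop_invalid("strategy %d requires a reference cohort", spec$strategy)
  }

  g <- if (spec$strategy == 4) {
    group_gradients(reference, scheme, modality, params)
  } else {
    sel <- select_subjects(study, spec$study_selection)
    if (!length(sel)) {
      stop_invalid("strategy %d selection '%s' matched no subjects",
                   spec$strategy, spec$study_selection)
    }
    base <- group_gradients(sel, scheme, modality, params)
    if (spec$strategy %in% c(5, 6)) {
      ref_t <- group_gradients(reference, scheme, modality, params)
      rotated <- procrustes_rotate(base$components, ref_t$components)$aligned
      colnames(rotated) <- colnames(base$components)
      base$components <- rotated
    }
    base
  }
  attr(g, "template_spec") <- spec
  g
}

#' Align individual gradient sets to a template
#'
#' Independently Procrustes-rotates every subject's gradients onto the
#' template; subject i's alignment never depends on the other subjects.
#'
#' @param subjects list of [gradient_set()] objects (or bare matrices).
#' @param template target [gradient_set()].
#' @return list of aligned `gradient_set` objects in the input order.
#' @export
align_cohort <- function(subjects, template) {
  tmpl <- if (inherits(template, "gradient_set")) template$components
          else as.matrix(template)
  lapply(seq_along(subjects), function(i) {
    g <- subjects[[i]]
    comps <- if (inherits(g, "gradient_set")) g$components else as.matrix(g)
    if (!all(dim(comps) == dim(tmpl))) {
      stop_invalid("subject %d gradients (%d x %d) do not match the template (%d x %d)",
                   i, nrow(comps), ncol(comps), nrow(tmpl), ncol(tmpl))
    }
    aligned <- procrustes_rotate(comps, tmpl)$aligned
    colnames(aligned) <- colnames(comps)
    if (inherits(g, "gradient_set")) {
      g$components <- aligned
      g
    } else {
      aligned
    }
  })
}

#' Per-gradient spatial correlation between two gradient sets
#'
#' @param a,b [gradient_set()] objects or parcels x k matrices of equal
#'   shape.
#' @return named numeric vector of Pearson correlations, one per gradient.
#' @export
template_similarity <- function(a, b) {
  ma <- if (inherits(a, "gradient_set")) a$components else as.matrix(a)
  mb <- if (inherits(b, "gradient_set")) b$components else as.matrix(b)
  if (!all(dim(ma) == dim(mb))) stop_invalid("shapes must match")
  const <- apply(ma, 2, sd) == 0 | apply(mb, 2, sd) == 0
  if (any(const)) {
    stop_invalid("correlation undefined for constant gradient column(s): %s",
                 paste(which(const), collapse = ", "))
  }
  r <- vapply(seq_len(ncol(ma)), function(j) cor(ma[, j], mb[, j]), 0)
  names(r) <- paste0("G", seq_len(ncol(ma)))
  r
}
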