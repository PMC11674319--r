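#' Default experiment configuration
#'
#' All tunables of the end-to-end experiment with their defaults: the main
#' analysis uses the normalized-angle kernel, 10% row density, three
#' gradients, alpha = 0.5 diffusion normalisation, 1000 spin rotations, and
#' an FDR level of 0.05. Simulation defaults describe a 100-parcel,
#' three-site, 30 + 30 cohort with a 100-subject quality-factor-4 reference
#' cohort and a planted first-gradient effect in 10 parcels.
#'
#' @param ... named overrides of any default.
#' @return a `run_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    # parcellation
    n_parcels = 100L, n_communities = 7L, n_hierarchy = 4L,
    # study cohort
    n_case = 30L, n_control = 30L, n_sites = 3L,
    series_length = 200L, noise_sd = 2.0, subject_jitter_sd = 0.7,
    n_affected = 10L, effect_size = 1.0, site_sd = 0.05,
    # reference cohort
    n_reference = 100L, quality_factor = 4,
    # structural generator (NULL: calibrated to ~15% edge density)
    sc_density_scale = NULL,
    # embedding
    modality = "functional", kernel = "normalized_angle",
    density = 0.10, k = 3L, alpha = 0.5, n_bins = 10L,
    # inference
    strategies = 1:6, alpha_fdr = 0.05, n_perm = 1000L,
    # template utility (off by default: expensive)
    evaluate_utility = FALSE, n_folds = 5L, n_repeats = 100L,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop_invalid("unknown config field(s): %s", paste(unknown, collapse = ", "))
  }
  for (nm in names(overrides)) cfg[nm] <- list(overrides[[nm]])
  validate_config(cfg)
  structure(cfg, class = c("run_config", "list"))
}

validate_config <- function(cfg) {
  if (!cfg$kernel %in% c("normalized_angle", "cosine")) {
    stop_invalid("unknown kernel '%s'", cfg$kernel)
  }
  if (!cfg$modality %in% c("functional", "structural")) {
    stop_invalid("unknown modality '%s'", cfg$modality)
  }
  if (!all(cfg$strategies %in% 1:6)) {
    stop_invalid("strategies must be a subset of 1..6")
  }
  if (cfg$density <= 0 || cfg$density > 1) {
    stop_invalid("density must be in (0, 1]")
  }
  invisible(cfg)
}

#' Read a YAML experiment configuration
#'
#' Unknown keys are rejected; missing keys take their [default_config()]
#' values.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_invalid("no such config file: %s", path)
  do.call(default_config, yaml::read_yaml(path))
}

simulate_cohorts <- function(cfg, scheme) {
  truth <- make_ground_truth(scheme, n_affected = cfg$n_affected,
                             effect_size = cfg$effect_size,
                             n_sites = cfg$n_sites, site_sd = cfg$site_sd,
                             seed = cfg$seed)
  if (cfg$modality == "functional") {
    study <- simulate_fc_cohort(scheme, cfg$n_case, cfg$n_control,
                                n_sites = cfg$n_sites,
                                series_length = cfg$series_length,
                                noise_sd = cfg$noise_sd, truth = truth,
                                subject_jitter_sd = cfg$subject_jitter_sd)
    reference <- simulate_reference_cohort(
      scheme, n_subjects = cfg$n_reference,
      quality_factor = cfg$quality_factor, truth = truth,
      series_length = cfg$series_length, noise_sd = cfg$noise_sd,
      subject_jitter_sd = cfg$subject_jitter_sd
    )
  } else {
    study <- simulate_sc_cohort(scheme, cfg$n_case, cfg$n_control,
                                density_scale = cfg$sc_density_scale,
                                truth = truth, n_sites = cfg$n_sites)
    # structural reference: an independent control-only draw of the same
    # latent geometry (no group effect enters control subjects)
    truth_ref <- make_ground_truth(scheme, n_affected = 0L, effect_size = 0,
                                   n_sites = 1L, site_sd = 0,
                                   seed = child_seed(cfg$seed, 10L))
    ref_all <- simulate_sc_cohort(scheme, n_case = 2L,
                                  n_control = cfg$n_reference,
                                  density_scale = cfg$sc_density_scale,
                                  truth = truth_ref, n_sites = 1L)
    reference <- list(
      subjects = select_subjects(ref_all$subjects, "controls_only"),
      truth = truth_ref
    )
  }
  list(study = study, reference = reference, truth = truth)
}

subject_gradients <- function(subjects, scheme, cfg) {
  lapply(subjects, function(s) {
    if (cfg$modality == "functional") {
      embed_functional(fisher_z(s$fc), density = cfg$density,
                       kernel = cfg$kernel, k = cfg$k, alpha = cfg$alpha)
    } else {
      embed_structural(log_transform_sc(s$sc), scheme, kernel = cfg$kernel,
                       k = cfg$k, alpha = cfg$alpha)
    }
  })
}

#' Run the full template-comparison experiment
#'
#' End-to-end pipeline: simulate the study and reference cohorts, embed
#' every subject, build each requested group-level template strategy, align
#' all study subjects to each template, fit the parcel-wise multivariate
#' group model, and summarise effects overall and stratified by community
#' and hierarchy. The whole run is a pure function of the configuration
#' (including its seed); rerunning reproduces outputs bit-exactly.
#'
#' @param config a [default_config()]-style `run_config`.
#' @param out_dir optional directory; when given, templates, aligned
#'   gradients, effect maps, summary tables, and a manifest with file
#'   checksums are written there.
#' @return list with `scheme`, `truth`, `templates`, `aligned`, `effects`,
#'   `summary` (one row per strategy), `stratified`, and — when
#'   `evaluate_utility` is set — per-strategy classification `utility`.
#' @export
run_experiment <- function(config = default_config(), out_dir = NULL) {
  cfg <- validate_config(config)
  scheme <- make_parcellation(cfg$n_parcels, cfg$n_communities,
                              cfg$n_hierarchy, seed = cfg$seed)
  sim <- simulate_cohorts(cfg, scheme)
  covs <- do.call(rbind, lapply(sim$study$subjects, function(s) {
    data.frame(subject_id = s$subject_id, group = s$group, age = s$age,
               sex = s$sex, site = s$site, motion = s$motion)
  }))
  subj_grads <- subject_gradients(sim$study$subjects, scheme, cfg)
  params <- list(density = cfg$density, kernel = cfg$kernel, k = cfg$k,
                 alpha = cfg$alpha, n_bins = cfg$n_bins)

  templates <- list(); aligned <- list(); effects <- list()
  summary_rows <- list(); stratified <- list(); utility <- list()
  for (s in cfg$strategies) {
    key <- paste0("strategy_", s)
    tmpl <- build_template(sim$study$subjects, sim$reference$subjects,
                           spec = s, scheme = scheme,
                           modality = cfg$modality, params = params)
    al <- align_cohort(subj_grads, tmpl)
    eff <- fit_mglm(al, covs, alpha_fdr = cfg$alpha_fdr)
    summ <- summarize_template(eff)
    templates[[key]] <- tmpl
    aligned[[key]] <- al
    effects[[key]] <- eff
    summary_rows[[key]] <- data.frame(
      strategy = s, description = attr(tmpl, "template_spec")$description,
      mean_T2 = summ$mean_T2, sd_T2 = summ$sd_T2,
      n_significant = summ$n_significant
    )
    stratified[[key]] <- list(
      community = stratify_effects(eff, scheme, "community"),
      hierarchy = stratify_effects(eff, scheme, "hierarchy")
    )
    if (isTRUE(cfg$evaluate_utility)) {
      utility[[key]] <- evaluate_template_utility(
        gradient_features(al), covs, covs$group, task = "classify",
        n_folds = cfg$n_folds, n_repeats = cfg$n_repeats, seed = cfg$seed
      )
    }
  }
  summary_tab <- do.call(rbind, summary_rows)
  rownames(summary_tab) <- NULL

  result <- list(scheme = scheme, truth = sim$truth, config = cfg,
                 templates = templates, aligned = aligned, effects = effects,
                 summary = summary_tab, stratified = stratified,
                 utility = if (length(utility)) utility else NULL)
  if (!is.null(out_dir)) write_experiment(result, out_dir)
  result
}

write_experiment <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_parcellation(result$scheme, file.path(out_dir, "parcellation.tsv"))
  write.table(result$summary, file.path(out_dir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (key in names(result$templates)) {
    write_gradients(result$templates[[key]],
                    file.path(out_dir, paste0(key, "_template.tsv")))
    write_effect_map(result$effects[[key]],
                     file.path(out_dir, paste0(key, "_effects.tsv")))
    for (by in c("community", "hierarchy")) {
      write.table(result$stratified[[key]][[by]],
                  file.path(out_dir, sprintf("%s_%s.tsv", key, by)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  cfg <- result$config
  yaml::write_yaml(cfg[setdiff(names(cfg), character(0))],
                   file.path(out_dir, "config.yaml"))
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "manifest.tsv"))
  sums <- tools::md5sum(files)
  manifest <- data.frame(file = basename(names(sums)), md5 = unname(sums))
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
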