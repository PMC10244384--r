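#' Build a pipeline run configuration
#'
#' Collects input paths (or a synthetic-data spec when paths are NULL), stage
#' toggles and all stage parameters. A single global seed is expanded into
#' fixed per-stage streams, so disabling one stage never shifts the
#' randomness of another.
#'
#' @param output_dir Directory for all outputs (created if needed).
#' @param panel_path,exposure_path,contact_path Input tables; when
#'   `panel_path` is NULL, a synthetic panel is generated from `sim`.
#' @param blood_path,tumor_path Bulk repertoire tables; when NULL and the
#'   enrichment stage is enabled, synthetic repertoires are generated.
#' @param stages Character subset of
#'   `c("distance", "cluster", "contacts", "classifier", "enrich")`.
#' @param sim `panel_spec` used when no panel is supplied.
#' @param exposure_threshold Exposed-fraction gate; default 0.30.
#' @param hotspot_threshold_s Half-life boundary for the hotspot search (s);
#'   default 10.
#' @param label_threshold_s Half-life boundary for high/low labels (s);
#'   default 60.
#' @param min_clade_size Smallest admissible hotspot clade; default 5.
#' @param permutations Replicates for both permutation nulls; default 1000.
#' @param classifier_residues Residue set of the trained classifier; default
#'   R, N, D, G, I, L, F.
#' @param tumor_high_bias,depth Synthetic repertoire parameters.
#' @param seed Global integer seed.
#' @return Object of class `run_config` (a validated list).
#' @export
run_config <- function(output_dir,
                       panel_path = NULL, exposure_path = NULL,
                       contact_path = NULL,
                       blood_path = NULL, tumor_path = NULL,
                       stages = c("distance", "cluster", "contacts",
                                  "classifier", "enrich"),
                       sim = panel_spec(n_tcrs = 60, seed = 1L,
                                        couple_exposure = TRUE),
                       exposure_threshold = 0.30,
                       hotspot_threshold_s = 10, label_threshold_s = 60,
                       min_clade_size = 5, permutations = 1000,
                       classifier_residues = c("R", "N", "D", "G", "I", "L", "F"),
                       tumor_high_bias = 3, depth = 10000L, seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(exposure_threshold > 0, exposure_threshold < 1,
            hotspot_threshold_s > 0, label_threshold_s > 0,
            min_clade_size >= 1, permutations >= 1, depth > 0)
  structure(list(output_dir = output_dir, panel_path = panel_path,
                 exposure_path = exposure_path, contact_path = contact_path,
                 blood_path = blood_path, tumor_path = tumor_path,
                 stages = stages, sim = sim,
                 exposure_threshold = exposure_threshold,
                 hotspot_threshold_s = hotspot_threshold_s,
                 label_threshold_s = label_threshold_s,
                 min_clade_size = min_clade_size,
                 permutations = permutations,
                 classifier_residues = classifier_residues,
                 tumor_high_bias = tumor_high_bias, depth = depth,
                 seed = as.integer(seed)),
            class = "run_config")
}

# fixed per-stage seed streams derived from the global seed
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 1L, cluster = 2L, contacts = 3L, classifier = 4L,
               enrich = 5L)
  (seed + 10007L * offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full inference pipeline
#'
#' Executes the enabled stages in dependency order: panel (input or
#' synthetic) -> 4-mer distances -> UPGMA tree, hotspot and permutation
#' control; panel + exposures -> classifier training, evaluation and
#' cross-validation; predicted labels + repertoires -> high-avidity
#' enrichment test. Contact-model fitting runs from the contact table. All
#' outputs are tab-separated (newick for the tree) under
#' `config$output_dir`, with a JSON run manifest recording package version,
#' seed, parameters and the stages executed.
#'
#' @param config `run_config`.
#' @return Invisible list of in-memory stage results (`panel`, `tree`,
#'   `hotspot`, `contact_model`, `classifier`, `evaluation`,
#'   `cross_validation`, `enrichment`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  res <- list()
  manifest <- list(package = "tcravidity",
                   version = as.character(utils::packageVersion("tcravidity")),
                   seed = config$seed, stages = list(),
                   parameters = config[c("exposure_threshold",
                                         "hotspot_threshold_s",
                                         "label_threshold_s",
                                         "min_clade_size", "permutations",
                                         "tumor_high_bias", "depth")])

  # --- panel ---------------------------------------------------------------
  if (!is.null(config$panel_path)) {
    panel <- read_clonotype_table(config$panel_path)
    exposures <- if (!is.null(config$exposure_path))
      read_exposure_table(config$exposure_path) else NULL
  } else {
    sim <- config$sim
    sim$seed <- stage_seed(config$seed, "simulate")
    gen <- generate_panel(sim)
    panel <- gen$panel
    exposures <- gen$exposures
    write_clonotype_table(panel, out("panel.tsv"))
    write_exposure_table(exposures, out("exposures.tsv"))
    manifest$stages$simulate <- list(n_tcrs = nrow(panel))
  }
  if (!"label" %in% names(panel) && "halflife_s" %in% names(panel))
    panel$label <- avidity_labels(panel$halflife_s, config$label_threshold_s)
  res$panel <- panel

  # --- distances + clustering ---------------------------------------------
  need_tree <- "cluster" %in% config$stages
  if ("distance" %in% config$stages || need_tree) {
    d <- distance_matrix(panel)
    write_distance_matrix(d, out("distance_matrix.tsv"), long = TRUE)
    res$distance <- d
    manifest$stages$distance <- list(n = nrow(d))
  }
  if (need_tree) {
    tree <- upgma(res$distance)
    write_tree_newick(tree, out("tree.nwk"))
    hl <- setNames(panel$halflife_s, panel$tcr_id)
    hot <- cluster_enrichment_null(tree, hl,
                                   threshold = config$hotspot_threshold_s,
                                   min_size = config$min_clade_size,
                                   b = config$permutations,
                                   seed = stage_seed(config$seed, "cluster"))
    write.table(data.frame(tcr_id = hot$members), out("hotspot_members.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(statistic = c("clade_high_fraction",
                                         "inside_fraction",
                                         "outside_low_fraction", "p_value"),
                           value = c(hot$clade_high_fraction,
                                     hot$inside_fraction,
                                     hot$outside_low_fraction, hot$p_value)),
                out("hotspot_report.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    res$tree <- tree
    res$hotspot <- hot
    manifest$stages$cluster <- list(hotspot_size = length(hot$members),
                                    p_value = hot$p_value)
  }

  # --- contact model -------------------------------------------------------
  if ("contacts" %in% config$stages) {
    contacts <- if (!is.null(config$contact_path)) {
      read_contact_table(config$contact_path)
    } else {
      generate_contacts(contact_spec(10, noise_sd = 0,
                                     seed = stage_seed(config$seed, "contacts")))
    }
    write_contact_table(contacts, out("contact_table.tsv"))
    cm <- fit_contact_model(contacts)
    write.table(data.frame(parameter = c("k", "gamma", "delta", "r_squared"),
                           value = c(cm$k, cm$gamma, cm$delta,
                                     cm$diagnostics$r_squared)),
                out("contact_model.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    res$contact_model <- cm
    manifest$stages$contacts <- list(n = cm$diagnostics$n)
  }

  # --- classifier ----------------------------------------------------------
  if ("classifier" %in% config$stages) {
    if (is.null(exposures)) stop("classifier stage needs exposure profiles")
    fdef <- feature_definition(config$classifier_residues,
                               encoding = "exposed_presence",
                               exposure_threshold = config$exposure_threshold)
    X <- feature_matrix(panel, exposures, fdef)
    y <- panel$label
    model <- fit_logistic(X, y, fdef = fdef)
    write_avidity_model(model, out("avidity_model.tsv"))
    pred <- predict_avidity(model, X)
    ev <- evaluate_classifier(pred$p, y, model$threshold)
    cv_seed <- stage_seed(config$seed, "classifier")
    cv <- list(
      leave20out_random = cross_validate(X, y, "leave20out_random",
                                         seed = cv_seed),
      leave20out_stratified = cross_validate(X, y, "leave20out_stratified",
                                             seed = cv_seed + 1L),
      leave_one_epitope_out = cross_validate(X, y, "leave_one_epitope_out",
                                             epitopes = panel$pmhc))
    write.table(data.frame(
      metric = c("auc", "sensitivity", "specificity", "accuracy",
                 paste0("cv_", names(cv))),
      value = c(ev$auc, ev$sensitivity, ev$specificity, ev$accuracy,
                vapply(cv, `[[`, numeric(1), "success"))),
      out("classifier_metrics.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    panel$predicted_label <- pred$label
    write_clonotype_table(panel, out("panel_predicted.tsv"))
    res$classifier <- model
    res$evaluation <- ev
    res$cross_validation <- cv
    res$panel <- panel
    manifest$stages$classifier <- list(auc = ev$auc)
  }

  # --- repertoire enrichment ----------------------------------------------
  if ("enrich" %in% config$stages) {
    reference <- data.frame(
      cdr3b = panel$cdr3b,
      label = if ("predicted_label" %in% names(panel)) panel$predicted_label
              else panel$label)
    en_seed <- stage_seed(config$seed, "enrich")
    if (!is.null(config$blood_path) && !is.null(config$tumor_path)) {
      blood <- read_repertoire_table(config$blood_path)
      tumor <- read_repertoire_table(config$tumor_path)
    } else {
      reps <- generate_repertoires(panel, config$tumor_high_bias,
                                   config$depth, seed = en_seed)
      blood <- reps$blood[, c("cdr3b", "count")]
      tumor <- reps$tumor[, c("cdr3b", "count")]
    }
    lab_blood <- label_repertoire(reference, blood)
    lab_tumor <- label_repertoire(reference, tumor)
    enr <- ha_enrichment_test(lab_tumor, lab_blood, b = config$permutations,
                              seed = en_seed + 1L)
    write.table(data.frame(
      statistic = c("n_tumor", "m_blood", "pct_ha_tumor", "pct_ha_blood",
                    "difference", "p_value"),
      value = c(enr$n, enr$m, enr$pct_ha_tumor, enr$pct_ha_blood,
                enr$observed, enr$p_value)),
      out("ha_enrichment.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    res$enrichment <- enr
    manifest$stages$enrich <- list(p_value = enr$p_value)
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
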