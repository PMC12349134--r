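# End-to-end orchestration: simulate (optional) -> curate -> split ->
# select/train -> rank -> loadings -> threshold -> profile -> overlap ->
# predict state. Stage outputs are files, so any stage can be re-run in
# isolation; a manifest records config, seeds, version and checksums.

write_tsv_matrix <- function(m, path, rowname_col = "id") {
  df <- data.table::data.table(.id = rownames(m) %||% as.character(seq_len(nrow(m))))
  data.table::setnames(df, ".id", rowname_col)
  df <- cbind(df, data.table::as.data.table(as.matrix(m)))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' @param output_dir Run directory (created if absent).
#' @param generator A [generator_config()] for synthetic input, or `NULL` to
#'   read an existing table from `values_path` / `meta_path`.
#' @param values_path,meta_path Input table paths when `generator` is `NULL`.
#' @param curation A [curation_config()].
#' @param split_fractions Train/validation/test proportions.
#' @param architectures List of candidate [cvae_config()]s.
#' @param n_replicates Seeded trainings per candidate.
#' @param percentile Cross-component retention percentile.
#' @param elbow_override Optional manual elbow cut.
#' @param n_ses_components How many SES-centric components (by socioeconomic
#'   mean weight strength among the leading ranked components) feed the state
#'   prediction; default 4.
#' @param n_folds,ridge State-prediction settings.
#' @param seed Master seed; every stage seed is derived from it.
#' @return A `run_config` list.
#' @export
run_config <- function(output_dir,
                       generator = generator_config(),
                       values_path = NULL, meta_path = NULL,
                       curation = curation_config(),
                       split_fractions = c(0.8, 0.1, 0.1),
                       architectures = list(cvae_config(latent_dim = 20,
                                                        hidden_dim = 64,
                                                        frontend_dim = 50)),
                       n_replicates = 3,
                       percentile = 0.95,
                       elbow_override = NULL,
                       n_ses_components = 4,
                       n_folds = 10,
                       ridge = 1,
                       seed = 1L) {
  if (is.null(generator) && (is.null(values_path) || is.null(meta_path))) {
    fail("either a generator config or input table paths are required")
  }
  structure(list(
    output_dir = output_dir, generator = generator,
    values_path = values_path, meta_path = meta_path,
    curation = curation, split_fractions = split_fractions,
    architectures = architectures, n_replicates = n_replicates,
    percentile = percentile, elbow_override = elbow_override,
    n_ses_components = n_ses_components,
    n_folds = n_folds, ridge = ridge, seed = as.integer(seed)
  ), class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    fail("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full stratification-discovery pipeline
#'
#' Executes every stage on one configuration, writing each stage's outputs
#' under the run directory together with a manifest (serialized configuration,
#' seeds, package version, stage file checksums). Deterministic given the
#' configuration: identical configs give identical manifests and outputs.
#'
#' @param config A [run_config()].
#' @return The run directory path, invisibly; stage results are attached as
#'   the `results` attribute.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)
  res <- list()

  if (!is.null(config$generator)) {
    sim <- run_stage("simulate", {
      gen <- config$generator
      gen$seed <- derive_seed(config$seed, 1L)
      generate_phenome(gen)
    })
    write_phenome(sim$table, out("phenome_raw.tsv"), out("phenome_meta.tsv"))
    jsonlite::write_json(
      list(ses_variable_index = sim$truth$ses_variable_index,
           ses_factors = sim$truth$ses_factors,
           planted = sim$truth$planted,
           state_offsets = sim$truth$state_offsets),
      out("ground_truth.json"), auto_unbox = TRUE, digits = 10)
    raw <- sim$table
    res$truth <- sim$truth
  } else {
    raw <- run_stage("read-input", {
      if (!file.exists(config$values_path)) {
        fail("input path not found: %s", config$values_path)
      }
      read_phenome(config$values_path, config$meta_path)
    })
  }

  cur <- run_stage("curate", curate(raw, config$curation))
  write_phenome(cur$table, out("phenome_curated.tsv"), out("phenome_curated_meta.tsv"))
  jsonlite::write_json(
    list(dropped_events = cur$report$dropped_events,
         dropped_missingness = cur$report$dropped_missingness,
         dropped_near_constant = cur$report$dropped_near_constant,
         encoded = cur$report$encoded,
         winsorized_counts = as.list(cur$report$winsorized_counts),
         retained_events = cur$report$retained_events),
    out("curation_report.json"), auto_unbox = TRUE, digits = 10)
  res$curation <- cur

  split <- run_stage("split", stratified_split(
    cur$table, fractions = config$split_fractions,
    seed = derive_seed(config$seed, 2L)))
  data.table::fwrite(
    data.table::data.table(participant_id = cur$table$participant_ids,
                           split = as.character(split)),
    out("split.tsv"), sep = "\t", quote = FALSE)
  res$split <- split

  sel <- run_stage("select", select_architecture(
    config$architectures, cur$table, split,
    n_replicates = config$n_replicates,
    base_seed = derive_seed(config$seed, 3L)))
  data.table::fwrite(as.data.frame(sel), out("model_selection.tsv"),
                     sep = "\t", quote = FALSE)
  model <- attr(sel, "winner_model")
  res$selection <- sel
  res$model <- model

  pca <- run_stage("pca-baseline", fit_pca_baseline(
    cur$table, split, n_components = model$config$latent_dim,
    seed = derive_seed(config$seed, 4L)))
  res$pca <- pca
  res$mse <- c(cvae = mse_test(model, cur$table, split),
               pca = mse_test(pca, cur$table, split))

  ranking <- run_stage("rank", {
    r <- ablation_rank(model, cur$table, split)
    if (!is.null(config$elbow_override)) {
      r$elbow_cut <- find_elbow(r, override = config$elbow_override)
    }
    r
  })
  data.table::fwrite(
    data.table::data.table(rank = seq_along(ranking$order),
                           component = ranking$order,
                           ablation_mse = ranking$ablation_mse[ranking$order]),
    out("component_ranking.tsv"), sep = "\t", quote = FALSE)
  res$ranking <- ranking

  loadings <- run_stage("loadings", {
    test_idx <- which(split == "test")
    scores <- compute_scores(model, cur$table, subset = test_idx)
    compute_loadings(scores, cur$table)
  })
  write_tsv_matrix(loadings$r, out("loadings.tsv"), "variable")
  res$loadings <- loadings

  mask <- run_stage("threshold", threshold_95(loadings, config$percentile))
  write_tsv_matrix(mask * 1L, out("threshold_mask.tsv"), "variable")
  res$mask <- mask

  profile <- run_stage("profile", category_profile(
    loadings, mask, cur$table$meta,
    components = component_letters(ranking),
    categories = unique(cur$table$meta$category)))
  data.table::fwrite(profile, out("category_profile.tsv"), sep = "\t", quote = FALSE)
  res$profile <- profile

  ses_components <- run_stage("ses-components", {
    letters_map <- component_letters(ranking)
    ses_mean <- vapply(letters_map, function(k) {
      rows <- which(cur$table$meta$category == "Socioeconomic" & mask[, k])
      if (!length(rows)) 0 else mean(loadings$weight_strength[rows, k])
    }, numeric(1))
    n_pick <- min(config$n_ses_components, length(letters_map))
    letters_map[order(-ses_mean)[seq_len(n_pick)]]
  })
  res$ses_components <- ses_components

  overlap <- run_stage("overlap", ses_overlap(mask, cur$table$meta, ses_components))
  jsonlite::write_json(
    list(sets = overlap$sets, intersections = overlap$intersections,
         unique = overlap$unique),
    out("ses_overlap.json"), auto_unbox = TRUE)
  res$overlap <- overlap

  prediction <- run_stage("predict-state", {
    scores <- ses_component_scores(cur$table, loadings, mask, ses_components)
    predict_state(scores, cur$table$state, n_folds = config$n_folds,
                  seed = derive_seed(config$seed, 5L), ridge = config$ridge)
  })
  write_tsv_matrix(as.matrix(prediction$confusion)[, , drop = FALSE],
                   out("state_confusion.tsv"), "true_state")
  write_tsv_matrix(prediction$coefficients, out("state_coefficients.tsv"), "state")
  data.table::fwrite(most_influential_component(prediction),
                     out("state_top_component.tsv"), sep = "\t", quote = FALSE)
  res$prediction <- prediction

  manifest <- list(
    package_version = as.character(utils::packageVersion("phenostrat")),
    seed = config$seed,
    stage_seeds = list(simulate = derive_seed(config$seed, 1L),
                       split = derive_seed(config$seed, 2L),
                       select = derive_seed(config$seed, 3L),
                       pca = derive_seed(config$seed, 4L),
                       predict_state = derive_seed(config$seed, 5L)),
    split_fractions = config$split_fractions,
    n_replicates = config$n_replicates,
    percentile = config$percentile,
    n_folds = config$n_folds,
    ridge = config$ridge,
    files = as.list(tools::md5sum(sort(list.files(config$output_dir,
                                                  full.names = TRUE,
                                                  pattern = "\\.(tsv|json)$"))))
  )
  names(manifest$files) <- basename(names(manifest$files))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)

  invisible(structure(config$output_dir, results = res))
}
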