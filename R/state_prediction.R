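# Validation of socioeconomic multidimensionality: predict state of residence
# from socioeconomic-only component scores with one-vs-rest ridge logistic
# regression under stratified k-fold cross-validation.

#' Socioeconomic-only component scores
#'
#' For each chosen component, the participant score is the dot product of the
#' participant's curated socioeconomic variable values with the component's
#' socioeconomic loadings. By default only loadings retained by the
#' cross-component threshold mask contribute (masked-out entries contribute
#' 0); `masked = FALSE` uses all socioeconomic loadings.
#'
#' @param table The curated [phenome_table()].
#' @param loadings A [compute_loadings()] result.
#' @param mask A [threshold_95()] mask.
#' @param components Component indices (named vector labels are carried to the
#'   score columns).
#' @param meta Variable metadata aligned with the loading rows; defaults to
#'   `table$meta`.
#' @param category Category defining the measure set; default
#'   `"Socioeconomic"`.
#' @param masked Use only threshold-retained loadings (default `TRUE`).
#' @return Participants x components score matrix (`ses_scores`).
#' @export
ses_component_scores <- function(table, loadings, mask, components,
                                 meta = table$meta, category = "Socioeconomic",
                                 masked = TRUE) {
  stopifnot(inherits(table, "phenome_table"), inherits(loadings, "loading_matrix"))
  in_cat <- meta$category == category
  if (!any(in_cat)) fail("no variables in category '%s'", category)
  labels <- names(components) %||% sprintf("comp_%03d", components)
  S <- matrix(0, nrow(table$values), length(components),
              dimnames = list(table$participant_ids, labels))
  for (i in seq_along(components)) {
    k <- components[i]
    use <- in_cat & (if (masked) mask[, k] else TRUE)
    if (!any(use)) {
      fail("no %s variables retained in component %d", category, k)
    }
    S[, i] <- table$values[, use, drop = FALSE] %*% loadings$r[use, k]
  }
  structure(S, masked = masked, components = components, class = c("ses_scores", "matrix"))
}

make_stratified_folds <- function(labels, n_folds, seed) {
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (s in levels(labels)) {
      idx <- sample(which(labels == s))
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' Predict state of residence from SES component scores
#'
#' Stratified k-fold cross-validation; in each fold one binary ridge-penalised
#' logistic classifier per state (one-vs-rest, via `glmnet` with `alpha = 0`
#' and a single fixed penalty) is trained on the remaining folds, and each
#' held-out participant is assigned the state whose classifier gives the
#' highest probability. Out-of-fold predictions are pooled into a row-wise
#' percentage confusion matrix; coefficients are averaged over folds.
#'
#' @param scores A [ses_component_scores()] matrix (or any numeric feature
#'   matrix).
#' @param state_labels Per-participant state factor.
#' @param n_folds Number of cross-validation folds; default 10. Every state
#'   must have at least `n_folds` members.
#' @param seed Seed for the fold assignment.
#' @param ridge Total ridge penalty strength; the glmnet lambda is
#'   `ridge / n_train`. Default 1 (a unit ridge penalty).
#' @return A `state_prediction_result`: list with `confusion` (percent, rows
#'   = true states summing to 100), `per_state_accuracy`, `overall_accuracy`
#'   (percent), `coefficients` (state x component fold means),
#'   `chance_level` (percent), `above_chance` (per state), `predicted`
#'   (pooled out-of-fold labels), `densities` (per state per component,
#'   evaluated kernel density curves), and settings.
#' @export
predict_state <- function(scores, state_labels, n_folds = 10, seed = 1L,
                          ridge = 1) {
  scores <- as.matrix(scores)
  state_labels <- droplevels(as.factor(state_labels))
  if (nrow(scores) != length(state_labels)) fail("scores and labels misaligned")
  n_folds <- assert_count(n_folds, "n_folds", 2L)
  counts <- table(state_labels)
  small <- names(counts)[counts < n_folds]
  if (length(small)) {
    fail("state(s) with fewer members than folds: %s",
         paste(small, collapse = ", "))
  }
  states <- levels(state_labels)
  folds <- make_stratified_folds(state_labels, n_folds, seed)
  prob <- matrix(NA_real_, nrow(scores), length(states),
                 dimnames = list(NULL, states))
  coef_sum <- matrix(0, length(states), ncol(scores),
                     dimnames = list(states, colnames(scores)))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    te <- !tr
    n_train <- sum(tr)
    for (s in states) {
      y <- as.integer(state_labels[tr] == s)
      fit <- glmnet::glmnet(scores[tr, , drop = FALSE], y,
                            family = "binomial", alpha = 0,
                            lambda = ridge / n_train,
                            standardize = FALSE)
      prob[te, s] <- as.vector(stats::predict(
        fit, scores[te, , drop = FALSE], type = "response"))
      coef_sum[s, ] <- coef_sum[s, ] +
        as.vector(stats::coef(fit))[-1]  # drop intercept
    }
  }
  predicted <- factor(states[max.col(prob, ties.method = "first")],
                      levels = states)
  confusion <- 100 * prop.table(table(true = state_labels, predicted = predicted),
                                margin = 1)
  per_state_accuracy <- diag(as.matrix(confusion))
  overall_accuracy <- 100 * mean(predicted == state_labels)
  chance_level <- 100 / length(states)
  densities <- lapply(states, function(s) {
    lapply(seq_len(ncol(scores)), function(j) {
      d <- stats::density(scores[state_labels == s, j])
      data.frame(x = d$x, y = d$y)
    })
  })
  names(densities) <- states
  structure(list(
    confusion = confusion,
    per_state_accuracy = per_state_accuracy,
    overall_accuracy = overall_accuracy,
    coefficients = coef_sum / n_folds,
    chance_level = chance_level,
    above_chance = per_state_accuracy > chance_level,
    predicted = predicted,
    densities = densities,
    n_folds = n_folds, seed = seed, ridge = ridge
  ), class = "state_prediction_result")
}

#' @exportS3Method base::print
print.state_prediction_result <- function(x, ...) {
  cat(sprintf(
    "<state_prediction_result> %d states, %d-fold CV\n  overall accuracy %.2f%% (chance %.2f%%); %d state(s) above chance\n",
    nrow(x$confusion), x$n_folds, x$overall_accuracy, x$chance_level,
    sum(x$above_chance)))
  invisible(x)
}

#' Most influential component per state
#'
#' For each state, the component whose fold-averaged one-vs-rest coefficient
#' has the largest magnitude; ties go to the earlier component. States whose
#' coefficients are all zero are flagged as degenerate.
#'
#' @param result A [predict_state()] result.
#' @return Data frame with `state`, `component` (column label), `coefficient`,
#'   `degenerate`.
#' @export
most_influential_component <- function(result) {
  co <- result$coefficients
  idx <- max.col(abs(co), ties.method = "first")
  data.frame(
    state = rownames(co),
    component = colnames(co)[idx],
    coefficient = co[cbind(seq_len(nrow(co)), idx)],
    degenerate = rowSums(abs(co)) == 0,
    stringsAsFactors = FALSE
  )
}

#' Permutation null band for the overall prediction accuracy
#'
#' Re-runs the cross-validated prediction with the state labels permuted,
#' giving the null distribution of the overall accuracy under no
#' geography-phenome association.
#'
#' @param scores,state_labels,n_folds,ridge As in [predict_state()].
#' @param n_permutations Number of label permutations; default 20.
#' @param seed Seed for permutations and folds.
#' @return Numeric vector of null overall accuracies (percent).
#' @export
permutation_null_accuracy <- function(scores, state_labels, n_folds = 10,
                                      n_permutations = 20, seed = 1L,
                                      ridge = 1) {
  vapply(seq_len(n_permutations), function(b) {
    perm <- withr::with_seed(derive_seed(seed, b), sample(seq_along(state_labels)))
    res <- predict_state(scores, state_labels[perm], n_folds = n_folds,
                         seed = derive_seed(seed, 10000L + b), ridge = ridge)
    res$overall_accuracy
  }, numeric(1))
}
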