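# Component-level analysis of the trained embedding: participant scores,
# phenotype loadings / weight strengths, ablation ranking with elbow cut,
# and cross-component percentile thresholding.

#' Participant component scores
#'
#' Passes participants through the encoder and returns the posterior means
#' (default) or one seeded posterior sample per participant.
#'
#' @param model A trained [cvae_model()].
#' @param table The curated [phenome_table()].
#' @param subset Row indices (or a logical vector) of the participants to
#'   score; defaults to all.
#' @param mode `"posterior_mean"` (deterministic) or `"sample"`.
#' @param seed Seed for `"sample"` mode.
#' @return A participants x K score matrix with `provenance` attribute.
#' @export
compute_scores <- function(model, table, subset = NULL,
                           mode = c("posterior_mean", "sample"), seed = 1L) {
  stopifnot(inherits(model, "cvae_model"), inherits(table, "phenome_table"))
  mode <- match.arg(mode)
  idx <- subset %||% seq_len(nrow(table$values))
  if (is.logical(idx)) idx <- which(idx)
  if (!length(idx)) fail("empty participant subset")
  X <- table$values[idx, , drop = FALSE]
  Y <- frontend_project(model$frontend, X)
  C <- onehot_sites(if (is.null(model$site_levels)) NULL else table$site[idx],
                    model$site_levels)
  fw <- cvae_forward(model$params, Y, C, model$config$activation, eps = NULL)
  scores <- fw$mu
  if (mode == "sample") {
    eps <- withr::with_seed(seed, matrix(
      stats::rnorm(length(idx) * model$config$latent_dim),
      length(idx), model$config$latent_dim))
    scores <- fw$mu + eps * exp(0.5 * fw$lv)
  }
  rownames(scores) <- table$participant_ids[idx]
  colnames(scores) <- sprintf("comp_%03d", seq_len(ncol(scores)))
  structure(scores, provenance = list(mode = mode, subset = idx, seed = seed))
}

#' Phenotype loadings per component
#'
#' Pearson correlation of each curated variable with each component's scores
#' over the given participants; the loading magnitudes are the weight
#' strengths. A zero-variance variable receives loading 0 and is flagged
#' rather than raising, so downstream thresholding remains total.
#'
#' @param scores A score matrix from [compute_scores()].
#' @param table The curated [phenome_table()], aligned with `scores` via the
#'   score matrix's participant subset.
#' @param subset Participant rows over which to correlate; defaults to the
#'   rows the scores were computed on.
#' @return A `loading_matrix`: list with `r` (variables x K correlations),
#'   `weight_strength` (`|r|`), `flagged` (zero-variance variable names), and
#'   the subset used.
#' @export
compute_loadings <- function(scores, table, subset = NULL) {
  stopifnot(inherits(table, "phenome_table"))
  idx <- subset %||% attr(scores, "provenance")$subset %||%
    seq_len(nrow(table$values))
  if (is.logical(idx)) idx <- which(idx)
  if (length(idx) < 3) fail("at least 3 participants required for loadings")
  if (nrow(scores) != length(idx)) fail("scores and subset are misaligned")
  X <- table$values[idx, , drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  flagged <- table$meta$name[sds == 0]
  r <- matrix(0, ncol(X), ncol(scores),
              dimnames = list(table$meta$name, colnames(scores)))
  ok <- sds > 0
  if (any(ok)) {
    r[ok, ] <- stats::cor(X[, ok, drop = FALSE], scores)
  }
  if (length(flagged)) {
    warning(sprintf("%d zero-variance variable(s) assigned loading 0",
                    length(flagged)), call. = FALSE)
  }
  structure(list(r = r, weight_strength = abs(r), flagged = flagged,
                 subset = idx),
            class = "loading_matrix")
}

#' @exportS3Method base::print
print.loading_matrix <- function(x, ...) {
  cat(sprintf("<loading_matrix> %d variables x %d components (over %d participants)\n",
              nrow(x$r), ncol(x$r), length(x$subset)))
  invisible(x)
}

#' Rank components by single-component ablation
#'
#' For each component k, zeroes every latent score coordinate except k,
#' decodes with the site condition intact, and measures the test-split
#' reconstruction error. Components are ranked ascending by this
#' single-component MSE: the top-ranked components are those whose scores
#' alone degrade reconstruction the least.
#'
#' @param model A trained [cvae_model()].
#' @param table The curated [phenome_table()].
#' @param split A [stratified_split()] assignment.
#' @param subset Which split to evaluate on; default `"test"`.
#' @return A `component_ranking`: list with `order` (permutation of 1..K,
#'   best first), `ablation_mse` (per component, original indexing),
#'   `full_mse` (all components jointly), and `elbow_cut` from [find_elbow()].
#' @export
ablation_rank <- function(model, table, split, subset = "test") {
  stopifnot(inherits(model, "cvae_model"))
  idx <- which(split == subset)
  if (!length(idx)) fail("empty '%s' split", subset)
  X <- table$values[idx, , drop = FALSE]
  cc <- if (is.null(model$site_levels)) NULL else table$site[idx]
  scores <- compute_scores(model, table, subset = idx)
  K <- ncol(scores)
  ablation_mse <- vapply(seq_len(K), function(k) {
    Z <- matrix(0, nrow(scores), K)
    Z[, k] <- scores[, k]
    mean(rowSums((decode_scores(model, Z, cc) - X)^2))
  }, numeric(1))
  full_mse <- mean(rowSums((decode_scores(model, unclass(scores), cc) - X)^2))
  ord <- order(ablation_mse)
  ranking <- structure(list(order = ord, ablation_mse = ablation_mse,
                            full_mse = full_mse, elbow_cut = NA_integer_),
                       class = "component_ranking")
  ranking$elbow_cut <- if (K >= 3) find_elbow(ranking) else K
  ranking
}

#' @exportS3Method base::print
print.component_ranking <- function(x, ...) {
  cat(sprintf("<component_ranking> K=%d, elbow cut at %d\n",
              length(x$order), x$elbow_cut))
  cat("  top components:", paste(utils::head(x$order, 10), collapse = ", "), "\n")
  invisible(x)
}

#' Elbow cut of a sorted ablation curve
#'
#' Returns the rank index maximising the perpendicular distance of the sorted
#' single-component-MSE curve to the chord joining its endpoints. A manual
#' `override` takes precedence (the visual elbow call on real data is a
#' judgment; the override makes it explicit) and is logged via a message.
#' An exactly linear curve has degenerate geometry: the cut falls back to 1
#' with a warning.
#'
#' @param ranking A `component_ranking` (or a list with `order` and
#'   `ablation_mse`).
#' @param override Optional manual cut.
#' @return The number of leading ranked components to interpret.
#' @export
find_elbow <- function(ranking, override = NULL) {
  if (!is.null(override)) {
    message(sprintf("elbow override in effect: %d", override))
    return(assert_count(override, "override"))
  }
  y <- ranking$ablation_mse[ranking$order]
  K <- length(y)
  if (K < 3) fail("elbow detection requires at least 3 components")
  x <- seq_len(K)
  # perpendicular distance of each point to the chord (1, y1) -- (K, yK)
  dx <- K - 1
  dy <- y[K] - y[1]
  dist <- abs(dy * x - dx * y + dx * y[1] - dy * 1) / sqrt(dx^2 + dy^2)
  if (max(dist) < sqrt(.Machine$double.eps) * max(1, abs(y[1]))) {
    warning("ablation curve is exactly linear; degenerate elbow geometry, returning 1",
            call. = FALSE)
    return(1L)
  }
  which.max(dist)
}

#' Cross-component percentile thresholding
#'
#' For each variable, ranks all K components by weight strength and retains
#' the variable only in its top `ceil((1 - percentile) * K)` components
#' (5 of 100 at the default 95th percentile). Ties are broken toward the
#' lower component index, so the mask is deterministic.
#'
#' @param loadings A [compute_loadings()] result.
#' @param percentile Retention percentile; default 0.95.
#' @return A `threshold_mask`: logical variables x K matrix with
#'   `retain_count` attribute.
#' @export
threshold_95 <- function(loadings, percentile = 0.95) {
  stopifnot(inherits(loadings, "loading_matrix"))
  assert_proportion(percentile, "percentile", allow_zero = FALSE, allow_one = FALSE)
  ws <- loadings$weight_strength
  K <- ncol(ws)
  # round first: 1 - 0.95 is not exactly 0.05 in floating point, and a bare
  # ceiling would retain one component too many
  keep_n <- as.integer(ceiling(round((1 - percentile) * K, 9)))
  mask <- matrix(FALSE, nrow(ws), K, dimnames = dimnames(ws))
  for (v in seq_len(nrow(ws))) {
    top <- order(-ws[v, ], seq_len(K))[seq_len(keep_n)]
    mask[v, top] <- TRUE
  }
  structure(mask, retain_count = keep_n, percentile = percentile,
            class = c("threshold_mask", "matrix"))
}

#' Greedily match components to generative factors
#'
#' Evaluation helper for synthetic cohorts: matches each given component to a
#' distinct ground-truth factor by repeatedly taking the pair with the largest
#' absolute score correlation.
#'
#' @param scores Component score matrix (participants x components).
#' @param factor_scores Ground-truth factor score matrix for the same
#'   participants.
#' @param components Component column indices to match; defaults to all.
#' @return Data frame with `component`, `factor`, `abs_r` per matched pair.
#' @export
match_components <- function(scores, factor_scores, components = NULL) {
  components <- components %||% seq_len(ncol(scores))
  R <- abs(stats::cor(scores[, components, drop = FALSE], factor_scores))
  out <- data.frame(component = integer(), factor = integer(), abs_r = numeric())
  while (nrow(out) < min(dim(R)) && any(is.finite(R))) {
    best <- arrayInd(which.max(R), dim(R))
    out <- rbind(out, data.frame(component = components[best[1]],
                                 factor = best[2], abs_r = R[best]))
    R[best[1], ] <- -Inf
    R[, best[2]] <- -Inf
  }
  out
}
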