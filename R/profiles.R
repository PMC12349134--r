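# Characterisation of components: category-level weight strength profiles,
# socioeconomic-measure overlap across components, and per-component
# phenotype listings.

#' Letter labels for ranked components
#'
#' The leading ranked components are conventionally labelled A, B, C, ... in
#' ablation order. Returns a named integer vector mapping letters to latent
#' component indices.
#'
#' @param ranking A [ablation_rank()] result.
#' @param n How many leading components to label; defaults to the elbow cut.
#' @return Named integer vector, e.g. `c(A = 17, B = 3, ...)`.
#' @export
component_letters <- function(ranking, n = NULL) {
  n <- n %||% ranking$elbow_cut
  n <- min(n, length(ranking$order), length(LETTERS))
  stats::setNames(ranking$order[seq_len(n)], LETTERS[seq_len(n)])
}

#' Category-level profile of components
#'
#' For every component and predefined category: the mean weight strength over
#' the variables of that category retained in the component (by the
#' cross-component threshold mask), the retained count, and the retained
#' proportion of the category (percent). Categories with no retained variable
#' in a component get mean 0 and proportion 0.
#'
#' @param loadings A [compute_loadings()] result.
#' @param mask A [threshold_95()] mask.
#' @param meta Variable metadata (`name`, `category`) aligned with the loading
#'   rows.
#' @param components Component indices to profile; defaults to all.
#' @param categories Closed category list used for validation.
#' @return Data frame with columns `component`, `category`,
#'   `mean_weight_strength`, `retained_count`, `retained_proportion`.
#' @export
category_profile <- function(loadings, mask, meta, components = NULL,
                             categories = phenome_categories) {
  stopifnot(inherits(loadings, "loading_matrix"))
  if (!all(dim(mask) == dim(loadings$r))) fail("mask and loadings are misaligned")
  if (nrow(meta) != nrow(loadings$r)) fail("metadata and loadings are misaligned")
  bad <- setdiff(unique(meta$category), categories)
  if (length(bad)) fail("unknown categories: %s", paste(bad, collapse = ", "))
  components <- components %||% seq_len(ncol(mask))
  cats <- sort(unique(meta$category))
  cat_size <- table(factor(meta$category, levels = cats))
  out <- expand.grid(component = components, category = cats,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$mean_weight_strength <- 0
  out$retained_count <- 0L
  out$retained_proportion <- 0
  for (i in seq_len(nrow(out))) {
    k <- out$component[i]
    rows <- which(meta$category == out$category[i] & mask[, k])
    if (length(rows)) {
      out$mean_weight_strength[i] <- mean(loadings$weight_strength[rows, k])
      out$retained_count[i] <- length(rows)
      out$retained_proportion[i] <-
        100 * length(rows) / as.integer(cat_size[[out$category[i]]])
    }
  }
  out
}

#' Socioeconomic-measure overlap across components
#'
#' Set algebra over the retained socioeconomic variables of the named
#' components: the retained set per component, the intersection cardinality of
#' every non-empty subset of components, and the variables unique to each
#' component (retained there and in none of the others).
#'
#' @param mask A [threshold_95()] mask.
#' @param meta Variable metadata aligned with the mask rows.
#' @param components Component indices (>= 2) to compare.
#' @param category Category defining the measure universe; default
#'   `"Socioeconomic"`.
#' @return An `overlap_report`: list with `sets` (per component), `universe`,
#'   `intersections` (named by `&`-joined component labels), and `unique`.
#' @export
ses_overlap <- function(mask, meta, components, category = "Socioeconomic") {
  if (length(components) < 2) fail("at least 2 components required")
  if (any(components < 1 | components > ncol(mask))) {
    fail("component id out of range 1..%d", ncol(mask))
  }
  if (!any(meta$category == category)) {
    fail("no variables in category '%s'", category)
  }
  in_cat <- meta$category == category
  labels <- names(components) %||% as.character(components)
  sets <- lapply(seq_along(components), function(i) {
    meta$name[in_cat & mask[, components[i]]]
  })
  names(sets) <- labels
  m <- length(sets)
  intersections <- list()
  for (size in seq_len(m)) {
    for (combo in utils::combn(m, size, simplify = FALSE)) {
      key <- paste(labels[combo], collapse = "&")
      intersections[[key]] <- length(Reduce(intersect, sets[combo]))
    }
  }
  uniques <- lapply(seq_len(m), function(i) {
    setdiff(sets[[i]], unlist(sets[-i], use.names = FALSE))
  })
  names(uniques) <- labels
  structure(list(sets = sets, universe = meta$name[in_cat],
                 intersections = intersections, unique = uniques),
            class = "overlap_report")
}

#' @exportS3Method base::print
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> %d components over a %d-measure universe\n",
              length(x$sets), length(x$universe)))
  for (nm in names(x$sets)) {
    cat(sprintf("  %s: %d retained, %d unique\n", nm, length(x$sets[[nm]]),
                length(x$unique[[nm]])))
  }
  invisible(x)
}

#' Ranked phenotype listing for one component
#'
#' The phenotypes retained in a component by the threshold mask, sorted by
#' weight strength descending (ties by variable name, deterministically),
#' annotated with category — the data behind a Manhattan-style plot.
#'
#' @param loadings A [compute_loadings()] result.
#' @param mask A [threshold_95()] mask.
#' @param component Component index.
#' @param meta Variable metadata aligned with the loading rows.
#' @return Data frame with `variable`, `category`, `loading`,
#'   `weight_strength`, sorted.
#' @export
top_phenotype_table <- function(loadings, mask, component, meta) {
  stopifnot(inherits(loadings, "loading_matrix"))
  if (component < 1 || component > ncol(mask)) {
    fail("component id out of range 1..%d", ncol(mask))
  }
  rows <- which(mask[, component])
  out <- data.frame(
    variable = meta$name[rows],
    category = meta$category[rows],
    loading = loadings$r[rows, component],
    weight_strength = loadings$weight_strength[rows, component],
    stringsAsFactors = FALSE
  )
  out[order(-out$weight_strength, out$variable), , drop = FALSE]
}
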