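#' Site-stratified train/validation/test split
#'
#' Partitions participants into train/validation/test folds while preserving
#' the per-site proportions (within one participant per site, by largest
#' remainder apportionment). Seeded and reproducible.
#'
#' @param table A [phenome_table()] (only its row count is used when
#'   `site_labels` is given explicitly).
#' @param site_labels Per-participant site factor; defaults to `table$site`.
#' @param fractions Length-3 numeric vector of train/validation/test
#'   proportions summing to 1; default `c(0.8, 0.1, 0.1)`.
#' @param seed Integer seed.
#' @return A `split_assignment`: a factor of length n with levels
#'   `train`, `val`, `test`, plus the fractions and seed as attributes.
#' @export
stratified_split <- function(table, site_labels = NULL,
                             fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  n <- if (inherits(table, "phenome_table")) nrow(table$values) else as.integer(table)
  site_labels <- site_labels %||%
    (if (inherits(table, "phenome_table")) table$site else NULL)
  if (is.null(site_labels)) fail("site labels are required for a stratified split")
  site_labels <- as.factor(site_labels)
  if (length(site_labels) != n) fail("site labels length != participants")
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    fail("`fractions` must be 3 non-negative proportions summing to 1")
  }
  counts <- table(site_labels)
  small <- names(counts)[counts < 3]
  if (length(small)) {
    fail("sites with fewer participants than splits: %s",
         paste(small, collapse = ", "))
  }
  assignment <- factor(rep("train", n), levels = c("train", "val", "test"))
  withr::with_seed(seed, {
    for (s in levels(site_labels)) {
      idx <- which(site_labels == s)
      ns <- length(idx)
      # largest-remainder apportionment of ns over the three folds
      raw <- fractions * ns
      base <- floor(raw)
      rem <- ns - sum(base)
      if (rem > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      }
      shuffled <- sample(idx)
      assignment[shuffled] <- rep(c("train", "val", "test"), times = base)
    }
  })
  structure(assignment, fractions = fractions, seed = seed,
            class = c("split_assignment", "factor"))
}
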