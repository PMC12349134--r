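#' Replicated architecture selection
#'
#' Trains each candidate architecture `n_replicates` times with different
#' seeded weight initialisations and reports the mean and standard deviation
#' of the test-split reconstruction error; the winner is the candidate with
#' the lowest mean. Replicates that diverge are recorded, excluded with a
#' warning, and a candidate with fewer than 80% successful replicates is
#' disqualified from winning.
#'
#' @param candidates List of [cvae_config()] objects.
#' @param table A curated [phenome_table()].
#' @param split A [stratified_split()] assignment.
#' @param n_replicates Seeded trainings per candidate; default 25.
#' @param base_seed Base seed from which per-replicate seeds are derived.
#' @return A `model_selection_table` data frame (one row per architecture:
#'   dimensions, mean/sd test MSE, replicate counts, `winner` flag) with the
#'   per-replicate MSE matrix and the winning trained model as attributes.
#' @export
select_architecture <- function(candidates, table, split, n_replicates = 25,
                                base_seed = 1L) {
  if (!length(candidates)) fail("at least one candidate architecture required")
  stopifnot(all(vapply(candidates, inherits, logical(1), "cvae_config")))
  n_replicates <- assert_count(n_replicates, "n_replicates")

  mse <- matrix(NA_real_, length(candidates), n_replicates)
  best_models <- vector("list", length(candidates))
  best_mse <- rep(Inf, length(candidates))
  for (a in seq_along(candidates)) {
    for (r in seq_len(n_replicates)) {
      cfg <- candidates[[a]]
      cfg$seed <- derive_seed(base_seed, a * 1000L + r)
      fit <- tryCatch(train_cvae(table, split, cfg), error = function(e) e)
      if (inherits(fit, "error")) {
        warning(sprintf("architecture %d replicate %d failed: %s",
                        a, r, conditionMessage(fit)), call. = FALSE)
        next
      }
      mse[a, r] <- mse_test(fit, table, split)
      if (mse[a, r] < best_mse[a]) {
        best_mse[a] <- mse[a, r]
        best_models[[a]] <- fit
      }
    }
  }
  n_ok <- rowSums(!is.na(mse))
  qualified <- n_ok >= 0.8 * n_replicates
  mean_mse <- rowMeans(mse, na.rm = TRUE)
  sd_mse <- apply(mse, 1, stats::sd, na.rm = TRUE)
  mean_for_rank <- ifelse(qualified, mean_mse, Inf)
  if (all(!is.finite(mean_for_rank))) fail("no candidate qualified")
  winner <- which.min(mean_for_rank)

  out <- data.frame(
    architecture = seq_along(candidates),
    frontend_dim = vapply(candidates, function(c) c$frontend_dim %||% NA_integer_,
                          numeric(1)),
    hidden_dim = vapply(candidates, function(c) c$hidden_dim, numeric(1)),
    latent_dim = vapply(candidates, function(c) c$latent_dim, numeric(1)),
    mean_mse = mean_mse,
    sd_mse = sd_mse,
    n_replicates = n_ok,
    qualified = qualified,
    winner = seq_along(candidates) == winner
  )
  structure(out, class = c("model_selection_table", "data.frame"),
            replicate_mse = mse, winner_model = best_models[[winner]])
}
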