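# Shared fixtures, built in code at test time.

# A small clean cohort configuration: continuous only, no planted violations,
# single fully covered event. Individual tests override fields as needed.
clean_config <- function(...) {
  defaults <- list(
    n_participants = 500, n_variables = 40, n_factors = 3,
    factor_variances = c(9, 4, 1), frac_discrete = 0, frac_nonlinear = 0,
    noise_sd = 1, n_sites = 4, site_effect_sd = 0.5,
    missing_rate = 0, outlier_rate = 0, n_states = 4, state_ses_shift = 1,
    frac_near_constant = 0, frac_high_missing = 0,
    events = c(baseline = 1), event_shares = 1, seed = 1L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(generator_config, args)
}

# Hand-built phenome table from an explicit matrix (continuous by default).
toy_table <- function(values, dtype = "continuous", category = "Behavior",
                      event = "baseline", site = NULL, state = NULL) {
  values <- as.matrix(values)
  p <- ncol(values)
  meta <- data.frame(
    name = colnames(values) %||% sprintf("v%02d", seq_len(p)),
    category = rep_len(category, p),
    dtype = rep_len(dtype, p),
    event = rep_len(event, p),
    stringsAsFactors = FALSE
  )
  colnames(values) <- meta$name
  phenome_table(values, meta, site = site, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exactly linear model: data X = Z %*% diag(scale) %*% Q with Q having
# orthonormal rows; encoder recovers Z, decoder maps it back. Used to check
# ablation arithmetic against the closed form.
linear_toy_model <- function(scale, Q) {
  K <- length(scale); d <- ncol(Q)
  cfg <- cvae_config(latent_dim = K, hidden_dim = K, frontend_dim = NULL,
                     conditioned = FALSE, activation = "linear")
  params <- list(
    W1 = diag(d), b1 = rep(0, d),
    Wmu = t(Q) %*% diag(1 / scale, K), bmu = rep(0, K),
    Wlv = matrix(0, d, K), blv = rep(0, K),
    W4 = diag(K), b4 = rep(0, K),
    W5 = diag(scale, K) %*% Q, b5 = rep(0, d)
  )
  cvae_model(params, cfg)
}

# Quick trained model on a small nonlinear cohort, memoised across test files.
.trained_cache <- new.env(parent = emptyenv())
small_trained_fixture <- function() {
  if (!is.null(.trained_cache$fit)) return(.trained_cache$fit)
  cfg <- clean_config(n_participants = 600, n_variables = 60,
                      frac_discrete = 0.15, frac_nonlinear = 0.3,
                      missing_rate = 0.03, outlier_rate = 0.002,
                      frac_near_constant = 0.02, seed = 42L)
  sim <- generate_phenome(cfg)
  cur <- curate(sim$table)
  split <- stratified_split(cur$table, seed = 11L)
  model <- train_cvae(cur$table, split,
                      cvae_config(latent_dim = 6, hidden_dim = 32,
                                  frontend_dim = 25, max_epochs = 80,
                                  patience = 15, seed = 5L))
  .trained_cache$fit <- list(sim = sim, curated = cur$table,
                             report = cur$report, split = split, model = model)
  .trained_cache$fit
}
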