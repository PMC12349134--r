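#' Configure the synthetic phenome generator
#'
#' Defines the statistical features of a simulated deeply-phenotyped cohort:
#' a low-rank latent factor structure with heterogeneous factor variances,
#' additive data-collection-site (batch) offsets, a squashing nonlinearity on a
#' subset of factor-to-phenotype links, discrete variables obtained by
#' thresholding continuous latents, completely-at-random missingness,
#' heavy-tailed outliers, collection events with unequal participant coverage,
#' and state-of-residence labels whose socioeconomic factor means are shifted
#' per state. Defaults describe a 2,000 x 300 desk-scale cohort spread over
#' 21 sites and 17 states, mirroring a large US child-development study.
#'
#' @param n_participants,n_variables,n_factors Cohort dimensions; the factor
#'   count must be below the variable count.
#' @param factor_variances Positive, non-increasing variances of the latent
#'   factors; length `n_factors`.
#' @param frac_discrete Fraction of variables converted to discrete levels by
#'   quantile-thresholding their continuous latent.
#' @param frac_nonlinear Fraction of variables whose factor link passes through
#'   an odd squashing function (`a * tanh(u / a)` with `a` the linear
#'   predictor's standard deviation).
#' @param noise_sd Standard deviation of additive Gaussian measurement noise.
#' @param n_sites Number of data-collection sites; participants are assigned
#'   uniformly.
#' @param site_effect_sd Standard deviation of the additive per-site,
#'   per-variable batch offsets.
#' @param missing_rate Completely-at-random missingness rate applied to all
#'   entries.
#' @param outlier_rate,outlier_scale Rate of entries (continuous variables
#'   only) multiplied by `outlier_scale` (> 1) to create heavy tails.
#' @param n_states,state_ses_shift Number of states of residence and the
#'   standard deviation of the per-state mean shift added to the
#'   socioeconomic-linked factor scores (the first `min(2, n_factors)`
#'   factors). `state_ses_shift = 0` removes all geographic signal.
#' @param frac_near_constant Fraction of variables planted as near-constant
#'   (one dominant level), exercising the near-zero-variance filter.
#' @param frac_high_missing Fraction of variables planted with heavy extra
#'   missingness, exercising the population-fraction pruning rule.
#' @param events Named vector of participant coverage per collection event;
#'   participants outside an event's coverage have all of that event's
#'   variables missing en bloc.
#' @param event_shares Fraction of variables assigned to each event.
#' @param category_assignment Optional character vector (length `n_variables`)
#'   assigning each variable a category from [phenome_categories]; by default
#'   categories are drawn with the `"Socioeconomic"` category oversampled to
#'   12% so socioeconomic analyses are well populated at desk scale.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#'
#' @return A `generator_config` list, validated.
#' @export
generator_config <- function(n_participants = 2000,
                             n_variables = 300,
                             n_factors = 5,
                             factor_variances = c(25, 16, 9, 4, 1),
                             frac_discrete = 0.2,
                             frac_nonlinear = 0.25,
                             noise_sd = 1,
                             n_sites = 21,
                             site_effect_sd = 0.5,
                             missing_rate = 0.05,
                             outlier_rate = 0.002,
                             outlier_scale = 8,
                             n_states = 17,
                             state_ses_shift = 2,
                             frac_near_constant = 0.02,
                             frac_high_missing = 0.02,
                             events = c(baseline = 1, screener = 0.995,
                                        six_month = 0.98, one_year = 0.96,
                                        two_year = 0.55),
                             event_shares = c(0.50, 0.05, 0.15, 0.20, 0.10),
                             category_assignment = NULL,
                             seed = 1L) {
  config <- list(
    n_participants = assert_count(n_participants, "n_participants", 2L),
    n_variables = assert_count(n_variables, "n_variables", 2L),
    n_factors = assert_count(n_factors, "n_factors", 1L),
    factor_variances = factor_variances,
    frac_discrete = assert_proportion(frac_discrete, "frac_discrete"),
    frac_nonlinear = assert_proportion(frac_nonlinear, "frac_nonlinear"),
    noise_sd = noise_sd,
    n_sites = assert_count(n_sites, "n_sites", 1L),
    site_effect_sd = site_effect_sd,
    missing_rate = assert_proportion(missing_rate, "missing_rate"),
    outlier_rate = assert_proportion(outlier_rate, "outlier_rate"),
    outlier_scale = outlier_scale,
    n_states = assert_count(n_states, "n_states", 1L),
    state_ses_shift = state_ses_shift,
    frac_near_constant = assert_proportion(frac_near_constant, "frac_near_constant"),
    frac_high_missing = assert_proportion(frac_high_missing, "frac_high_missing"),
    events = events,
    event_shares = event_shares,
    category_assignment = category_assignment,
    seed = as.integer(seed)
  )
  if (config$n_factors >= config$n_variables) {
    fail("n_factors (%d) must be < n_variables (%d)",
         config$n_factors, config$n_variables)
  }
  v <- config$factor_variances
  if (length(v) != config$n_factors || any(!is.finite(v)) || any(v <= 0) ||
      any(diff(v) > 0)) {
    fail("factor_variances must be %d strictly positive, non-increasing values",
         config$n_factors)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) fail("noise_sd must be >= 0")
  if (!is.numeric(site_effect_sd) || site_effect_sd < 0) {
    fail("site_effect_sd must be >= 0")
  }
  if (config$outlier_rate > 0 && outlier_scale <= 1) {
    fail("outlier_scale must be > 1")
  }
  if (state_ses_shift < 0) fail("state_ses_shift must be >= 0")
  if (is.null(names(events)) || any(events <= 0) || any(events > 1)) {
    fail("`events` must be a named vector of coverages in (0, 1]")
  }
  if (length(event_shares) != length(events) ||
      abs(sum(event_shares) - 1) > 1e-8) {
    fail("`event_shares` must align with `events` and sum to 1")
  }
  if (!is.null(category_assignment)) {
    if (length(category_assignment) != config$n_variables) {
      fail("category_assignment must have one entry per variable")
    }
    bad <- setdiff(unique(category_assignment), phenome_categories)
    if (length(bad)) fail("unknown categories: %s", paste(bad, collapse = ", "))
  }
  structure(config, class = "generator_config")
}

#' Null-geography variant of a generator configuration
#'
#' Returns the same configuration with `state_ses_shift` set to zero: state
#' labels become independent of the socioeconomic factor scores, providing the
#' negative control for the state-prediction analysis.
#'
#' @param config A [generator_config()].
#' @return The configuration with `state_ses_shift = 0`, all else unchanged.
#' @export
null_state_variant <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  config$state_ses_shift <- 0
  config
}

#' Generate a synthetic phenome table with planted ground truth
#'
#' Simulates `value = squash(loadings %*% factors) + site offset + noise`,
#' converts a configured fraction of variables to discrete levels, plants
#' near-constant and heavily missing variables, injects multiplicative
#' outliers, applies event-block and completely-at-random missingness, and
#' draws state labels whose socioeconomic factor means differ by state.
#'
#' @param config A [generator_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{table}{A [phenome_table()] with site and state labels.}
#'     \item{truth}{Planted ground truth: `factor_loadings` (variables x
#'       factors, unit row norms), `factor_scores` (participants x factors,
#'       state shifts included), `site_labels`, `site_offsets`,
#'       `state_labels`, `state_offsets`, `ses_factors`,
#'       `ses_variable_index`, and a `planted` bookkeeping list (near-constant
#'       variables, high-missing variables, nonlinear variables, discrete
#'       variables, low-coverage events, outlier cell count).}
#'   }
#' @export
generate_phenome <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_participants
  p <- config$n_variables
  k <- config$n_factors
  withr::with_seed(config$seed, {
    # latent structure: unit row-norm loadings keep per-variable signal O(1)
    L <- matrix(stats::rnorm(p * k), p, k)
    L <- L / sqrt(rowSums(L^2))
    FS <- sapply(seq_len(k), function(j) {
      stats::rnorm(n, sd = sqrt(config$factor_variances[j]))
    })
    FS <- matrix(FS, n, k)

    # geography: per-state mean shifts on the SES-linked factors
    ses_factors <- seq_len(min(2L, k))
    state <- factor(sample(rep_len(sprintf("state_%02d", seq_len(config$n_states)), n)))
    state_offsets <- matrix(
      stats::rnorm(config$n_states * length(ses_factors),
                   sd = config$state_ses_shift),
      config$n_states, length(ses_factors),
      dimnames = list(levels(state)[seq_len(config$n_states)], NULL)
    )
    FS[, ses_factors] <- FS[, ses_factors] +
      state_offsets[as.integer(state), , drop = FALSE]

    eta <- FS %*% t(L)

    # odd squashing nonlinearity on a subset of variable links
    n_nl <- round(config$frac_nonlinear * p)
    nonlinear_vars <- sort(sample.int(p, n_nl))
    if (n_nl > 0) {
      # per-variable linear-predictor SD sets the squashing scale
      a <- sqrt(as.vector(L[nonlinear_vars, , drop = FALSE]^2 %*%
                            config$factor_variances))
      a <- pmax(a, 1e-8)
      eta[, nonlinear_vars] <- t(a * tanh(t(eta[, nonlinear_vars, drop = FALSE]) / a))
    }

    # additive site (batch) structure
    site <- factor(sample(rep_len(sprintf("site_%02d", seq_len(config$n_sites)), n)))
    site_offsets <- matrix(
      stats::rnorm(config$n_sites * p, sd = config$site_effect_sd),
      config$n_sites, p,
      dimnames = list(levels(site)[seq_len(config$n_sites)], NULL)
    )
    X <- eta + site_offsets[as.integer(site), , drop = FALSE] +
      matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)

    # planted filter violations
    n_nc <- round(config$frac_near_constant * p)
    n_hm <- round(config$frac_high_missing * p)
    special <- sample.int(p, n_nc + n_hm)
    near_constant_vars <- sort(special[seq_len(n_nc)])
    high_missing_vars <- sort(special[n_nc + seq_len(n_hm)])
    if (n_nc > 0) {
      for (v in near_constant_vars) {
        X[, v] <- ifelse(stats::runif(n) < 0.002, 1, 0)
      }
    }

    # discrete variables: quantile-thresholded continuous latents, 2-4 levels
    dtype <- rep("continuous", p)
    eligible <- setdiff(seq_len(p), near_constant_vars)
    n_disc <- round(config$frac_discrete * p)
    discrete_vars <- sort(sample(eligible, min(n_disc, length(eligible))))
    levels_per <- rep_len(2:4, length(discrete_vars))
    for (i in seq_along(discrete_vars)) {
      v <- discrete_vars[i]
      nl <- levels_per[i]
      cuts <- stats::quantile(X[, v], probs = seq_len(nl - 1) / nl)
      X[, v] <- findInterval(X[, v], cuts)
      dtype[v] <- "discrete"
    }
    dtype[near_constant_vars] <- "discrete"

    # heavy-tailed outliers on continuous entries
    cont <- which(dtype == "continuous")
    n_out <- 0L
    if (config$outlier_rate > 0 && length(cont)) {
      cells <- which(matrix(stats::runif(n * length(cont)) < config$outlier_rate,
                            n, length(cont)), arr.ind = TRUE)
      n_out <- nrow(cells)
      if (n_out > 0) {
        idx <- cbind(cells[, 1], cont[cells[, 2]])
        X[idx] <- X[idx] * config$outlier_scale
      }
    }

    # collection events: block missingness for participants outside coverage
    event_names <- names(config$events)
    pool <- rep(event_names, times = round(config$event_shares * p))
    pool <- rep_len(c(pool, rep(event_names[1], p)), max(p, length(pool)))[seq_len(p)]
    event_of <- sample(pool)
    for (e in event_names) {
      cov_e <- config$events[[e]]
      if (cov_e < 1) {
        out_participants <- sample.int(n, round((1 - cov_e) * n))
        X[out_participants, event_of == e] <- NA
      }
    }

    # planted heavy missingness, then completely-at-random missingness
    for (v in high_missing_vars) {
      X[stats::runif(n) < 0.25, v] <- NA
    }
    if (config$missing_rate > 0) {
      X[matrix(stats::runif(n * p) < config$missing_rate, n, p)] <- NA
    }

    categories <- config$category_assignment
    if (is.null(categories)) {
      weights <- rep((1 - 0.12) / (length(phenome_categories) - 1),
                     length(phenome_categories))
      weights[phenome_categories == "Socioeconomic"] <- 0.12
      categories <- sample(phenome_categories, p, replace = TRUE, prob = weights)
      categories[sample.int(p, 1)] <- "Socioeconomic"  # guarantee presence
    }

    meta <- data.frame(
      name = sprintf("var_%04d", seq_len(p)),
      category = categories,
      dtype = dtype,
      event = event_of,
      stringsAsFactors = FALSE
    )
    dimnames(X) <- NULL
    table <- phenome_table(X, meta,
                           participant_ids = sprintf("P%05d", seq_len(n)),
                           site = site, state = state)
    truth <- list(
      factor_loadings = L,
      factor_scores = FS,
      site_labels = site,
      site_offsets = site_offsets,
      state_labels = state,
      state_offsets = state_offsets,
      ses_factors = ses_factors,
      ses_variable_index = which(categories == "Socioeconomic"),
      planted = list(
        near_constant = near_constant_vars,
        high_missing = high_missing_vars,
        nonlinear = nonlinear_vars,
        discrete = discrete_vars,
        low_coverage_events = event_names[config$events < 0.95],
        n_outlier_cells = n_out
      )
    )
    list(table = table, truth = truth)
  })
}
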