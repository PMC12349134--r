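# Site-conditioned variational autoencoder on tabular phenome data.
#
# Architecture: optional PCA front-end projection; two-layer encoder
# [x; c] -> hidden -> (mu, log sigma^2); reparameterised z; two-layer decoder
# [z; c] -> hidden -> linear output in front-end space. ReLU hidden
# activations (a linear variant is provided for the probabilistic-PCA limit),
# Adam optimiser, early stopping on the validation objective.

#' Configure a conditional variational autoencoder
#'
#' @param latent_dim Latent dimensionality K (the number of components).
#' @param hidden_dim Width of the encoder/decoder hidden layers.
#' @param frontend_dim PCA projection size applied before the encoder
#'   (`NULL` = ingest curated variables directly). Must be >= `latent_dim`.
#' @param conditioned Whether to condition encoder and decoder on the
#'   data-collection site (one-of-n vector appended to the encoder input and
#'   to the latent code before decoding).
#' @param beta Weight of the KL term in the objective; default 1 (the plain
#'   evidence lower bound).
#' @param activation `"relu"` (default) or `"linear"` hidden activations.
#' @param learning_rate,batch_size,max_epochs Adam optimiser settings.
#' @param patience Early-stopping patience: training stops after this many
#'   epochs without validation improvement, restoring the best-validation
#'   parameters.
#' @param seed Integer seed controlling weight initialisation, minibatch
#'   shuffling and reparameterisation noise; identical seeds give identical
#'   trained models.
#' @return A `cvae_config` list.
#' @export
cvae_config <- function(latent_dim = 100, hidden_dim = 150, frontend_dim = NULL,
                        conditioned = TRUE, beta = 1,
                        activation = c("relu", "linear"),
                        learning_rate = 1e-3, batch_size = 128,
                        max_epochs = 200, patience = 10, seed = 1L) {
  activation <- match.arg(activation)
  latent_dim <- assert_count(latent_dim, "latent_dim")
  hidden_dim <- assert_count(hidden_dim, "hidden_dim")
  if (!is.null(frontend_dim)) {
    frontend_dim <- assert_count(frontend_dim, "frontend_dim")
    if (latent_dim > frontend_dim) fail("latent_dim must be <= frontend_dim")
  }
  if (beta < 0) fail("beta must be >= 0")
  structure(list(
    latent_dim = latent_dim, hidden_dim = hidden_dim,
    frontend_dim = frontend_dim, conditioned = isTRUE(conditioned),
    beta = beta, activation = activation,
    learning_rate = learning_rate, batch_size = assert_count(batch_size, "batch_size"),
    max_epochs = assert_count(max_epochs, "max_epochs"),
    patience = assert_count(patience, "patience"),
    seed = as.integer(seed)
  ), class = "cvae_config")
}

#' Construct a CVAE model object from explicit parameters
#'
#' Low-level constructor, used by [train_cvae()] and by tests that need a
#' model with hand-specified weights (e.g. an exactly linear decoder).
#'
#' @param params Named list of weight matrices `W1, b1, Wmu, bmu, Wlv, blv,
#'   W4, b4, W5, b5` (encoder hidden, posterior heads, decoder hidden,
#'   decoder output).
#' @param config A [cvae_config()].
#' @param frontend `NULL`, or `list(center, rotation)` of the PCA front-end.
#' @param site_levels Character vector of site labels seen in training
#'   (`NULL` for an unconditioned model).
#' @param history Optional training history data frame.
#' @return An object of class `cvae_model`.
#' @export
cvae_model <- function(params, config, frontend = NULL, site_levels = NULL,
                       history = NULL) {
  structure(list(params = params, config = config, frontend = frontend,
                 site_levels = site_levels, history = history),
            class = "cvae_model")
}

#' @exportS3Method base::print
print.cvae_model <- function(x, ...) {
  cat(sprintf(
    "<cvae_model> frontend=%s hidden=%d latent=%d %s beta=%.3g\n",
    if (is.null(x$config$frontend_dim)) "none" else x$config$frontend_dim,
    x$config$hidden_dim, x$config$latent_dim,
    if (is.null(x$site_levels)) "unconditioned"
    else sprintf("conditioned on %d sites", length(x$site_levels)),
    x$config$beta
  ))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs; best validation loss %.4f\n",
                nrow(x$history), min(x$history$val_loss)))
  }
  invisible(x)
}

act_fun <- function(x, activation) {
  if (activation == "relu") pmax(x, 0) else x
}
act_mask <- function(pre, activation) {
  if (activation == "relu") (pre > 0) * 1 else 1
}

onehot_sites <- function(site, site_levels) {
  if (is.null(site_levels)) return(NULL)
  site <- as.character(site)
  unseen <- setdiff(unique(site), site_levels)
  if (length(unseen)) {
    fail("site label(s) unseen in training: %s", paste(unseen, collapse = ", "))
  }
  C <- matrix(0, length(site), length(site_levels))
  C[cbind(seq_along(site), match(site, site_levels))] <- 1
  C
}

# Forward pass in model-input space. eps = NULL takes z = mu.
cvae_forward <- function(params, X, C, activation, eps = NULL) {
  XC <- if (is.null(C)) X else cbind(X, C)
  H1pre <- sweep(XC %*% params$W1, 2, params$b1, `+`)
  H1 <- act_fun(H1pre, activation)
  mu <- sweep(H1 %*% params$Wmu, 2, params$bmu, `+`)
  lv <- sweep(H1 %*% params$Wlv, 2, params$blv, `+`)
  lv <- pmin(pmax(lv, -15), 15)  # numerical guard on log-variance
  Z <- if (is.null(eps)) mu else mu + eps * exp(0.5 * lv)
  ZC <- if (is.null(C)) Z else cbind(Z, C)
  H2pre <- sweep(ZC %*% params$W4, 2, params$b4, `+`)
  H2 <- act_fun(H2pre, activation)
  Xhat <- sweep(H2 %*% params$W5, 2, params$b5, `+`)
  list(XC = XC, H1pre = H1pre, H1 = H1, mu = mu, lv = lv, Z = Z, ZC = ZC,
       H2pre = H2pre, H2 = H2, Xhat = Xhat, eps = eps)
}

kl_diag_gaussian <- function(mu, lv) {
  0.5 * rowSums(exp(lv) + mu^2 - 1 - lv)
}

#' Evidence lower bound terms for a batch
#'
#' Computes the negative ELBO as optimised during training: a squared-error
#' reconstruction term (Gaussian log-likelihood up to constants, summed over
#' model-input dimensions) plus `beta` times the closed-form KL divergence of
#' the diagonal Gaussian posterior from the standard Gaussian prior; both
#' averaged over the batch.
#'
#' @param x_batch Numeric matrix of inputs in the model's input space (the
#'   front-end space when a front-end is used).
#' @param c_batch Site labels for the batch (`NULL` for an unconditioned
#'   model).
#' @param model A [cvae_model()].
#' @param beta KL weight; defaults to the model's configured value.
#' @param sample Draw the latent code stochastically (`TRUE`) or use the
#'   posterior mean (default, deterministic).
#' @return A list `(total, reconstruction, kl)`; all finite.
#' @export
elbo_loss <- function(x_batch, c_batch = NULL, model, beta = NULL,
                      sample = FALSE) {
  beta <- beta %||% model$config$beta
  x_batch <- as.matrix(x_batch)
  C <- onehot_sites(c_batch, model$site_levels)
  eps <- if (sample) {
    matrix(stats::rnorm(nrow(x_batch) * model$config$latent_dim),
           nrow(x_batch), model$config$latent_dim)
  } else NULL
  fw <- cvae_forward(model$params, x_batch, C, model$config$activation, eps)
  recon <- mean(rowSums((fw$Xhat - x_batch)^2))
  kl <- mean(kl_diag_gaussian(fw$mu, fw$lv))
  if (!is.finite(recon) || !is.finite(kl)) {
    fail("non-finite ELBO terms (reconstruction=%s, kl=%s)",
         format(recon), format(kl))
  }
  list(total = recon + beta * kl, reconstruction = recon, kl = kl)
}

cvae_init_params <- function(d, h, K, m, activation) {
  gain <- if (activation == "relu") 2 else 1
  rmat <- function(a, b) matrix(stats::rnorm(a * b, sd = sqrt(gain / a)), a, b)
  list(
    W1 = rmat(d + m, h), b1 = rep(0, h),
    Wmu = rmat(h, K) * 0.1, bmu = rep(0, K),
    Wlv = rmat(h, K) * 0.1, blv = rep(-1, K),
    W4 = rmat(K + m, h), b4 = rep(0, h),
    W5 = rmat(h, d), b5 = rep(0, d)
  )
}

cvae_backward <- function(params, fw, X, beta, activation, K) {
  B <- nrow(X)
  G5 <- 2 * (fw$Xhat - X) / B
  dW5 <- crossprod(fw$H2, G5); db5 <- colSums(G5)
  GH2 <- (G5 %*% t(params$W5)) * act_mask(fw$H2pre, activation)
  dW4 <- crossprod(fw$ZC, GH2); db4 <- colSums(GH2)
  GZ <- (GH2 %*% t(params$W4))[, seq_len(K), drop = FALSE]
  dmu <- GZ + beta * fw$mu / B
  sig <- exp(0.5 * fw$lv)
  GLV <- GZ * fw$eps * 0.5 * sig + beta * 0.5 * (exp(fw$lv) - 1) / B
  dWmu <- crossprod(fw$H1, dmu); dbmu <- colSums(dmu)
  dWlv <- crossprod(fw$H1, GLV); dblv <- colSums(GLV)
  GH1 <- (dmu %*% t(params$Wmu) + GLV %*% t(params$Wlv)) *
    act_mask(fw$H1pre, activation)
  dW1 <- crossprod(fw$XC, GH1); db1 <- colSums(GH1)
  list(W1 = dW1, b1 = db1, Wmu = dWmu, bmu = dbmu, Wlv = dWlv, blv = dblv,
       W4 = dW4, b4 = db4, W5 = dW5, b5 = db5)
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

fit_frontend <- function(X_train, frontend_dim) {
  if (is.null(frontend_dim)) return(NULL)
  if (frontend_dim > min(dim(X_train))) {
    fail("frontend_dim (%d) exceeds the training data rank bound", frontend_dim)
  }
  center <- colMeans(X_train)
  sv <- svd(sweep(X_train, 2, center), nu = 0, nv = frontend_dim)
  list(center = center, rotation = sv$v)
}

frontend_project <- function(frontend, X) {
  if (is.null(frontend)) return(X)
  sweep(X, 2, frontend$center) %*% frontend$rotation
}

frontend_invert <- function(frontend, Y) {
  if (is.null(frontend)) return(Y)
  sweep(Y %*% t(frontend$rotation), 2, frontend$center, `+`)
}

#' Train a site-conditioned variational autoencoder
#'
#' Fits the PCA front-end on the training split only, trains encoder and
#' decoder by Adam on minibatches of the training split, and applies early
#' stopping on the validation objective (reconstruction + beta * KL, evaluated
#' at the posterior mean), restoring the best-validation parameters.
#'
#' @param table A curated [phenome_table()].
#' @param split A [stratified_split()] assignment.
#' @param config A [cvae_config()].
#' @param site_labels Per-participant site labels; defaults to `table$site`.
#'   Required when `config$conditioned` is `TRUE`.
#' @return A trained [cvae_model()] with training history.
#' @export
train_cvae <- function(table, split, config, site_labels = NULL) {
  stopifnot(inherits(table, "phenome_table"), inherits(config, "cvae_config"))
  X <- table$values
  if (anyNA(X)) fail("table contains missing values; curate it first")
  site_labels <- site_labels %||% table$site
  if (config$conditioned && is.null(site_labels)) {
    fail("conditioning requested but no site labels available")
  }
  train_idx <- which(split == "train")
  val_idx <- which(split == "val")
  if (!length(train_idx) || !length(val_idx)) fail("split lacks train or val rows")

  site_levels <- if (config$conditioned) levels(as.factor(site_labels)) else NULL
  m <- length(site_levels)
  K <- config$latent_dim
  h <- config$hidden_dim

  withr::with_seed(config$seed, {
    frontend <- fit_frontend(X[train_idx, , drop = FALSE], config$frontend_dim)
    Y <- frontend_project(frontend, X)
    d <- ncol(Y)
    if (K > d) fail("latent_dim (%d) exceeds model input dimension (%d)", K, d)
    C <- if (config$conditioned) onehot_sites(site_labels, site_levels) else NULL

    params <- cvae_init_params(d, h, K, m, config$activation)
    state <- list(m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0))
    Yval <- Y[val_idx, , drop = FALSE]
    Cval <- if (is.null(C)) NULL else C[val_idx, , drop = FALSE]

    val_loss_now <- function(pars) {
      fw <- cvae_forward(pars, Yval, Cval, config$activation, eps = NULL)
      mean(rowSums((fw$Xhat - Yval)^2)) +
        config$beta * mean(kl_diag_gaussian(fw$mu, fw$lv))
    }

    best <- list(loss = Inf, params = params, epoch = 0L)
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric())
    t_step <- 0L
    stall <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      order_idx <- sample(train_idx)
      batch_starts <- seq(1, length(order_idx), by = config$batch_size)
      epoch_losses <- numeric(length(batch_starts))
      for (bi in seq_along(batch_starts)) {
        rows <- order_idx[batch_starts[bi]:min(batch_starts[bi] +
                                                 config$batch_size - 1,
                                               length(order_idx))]
        Xb <- Y[rows, , drop = FALSE]
        Cb <- if (is.null(C)) NULL else C[rows, , drop = FALSE]
        eps <- matrix(stats::rnorm(length(rows) * K), length(rows), K)
        fw <- cvae_forward(params, Xb, Cb, config$activation, eps)
        recon <- mean(rowSums((fw$Xhat - Xb)^2))
        kl <- mean(kl_diag_gaussian(fw$mu, fw$lv))
        loss <- recon + config$beta * kl
        if (!is.finite(loss)) {
          fail("training diverged at epoch %d (non-finite loss); try a lower learning rate",
               epoch)
        }
        epoch_losses[bi] <- loss
        grads <- cvae_backward(params, fw, Xb, config$beta, config$activation, K)
        t_step <- t_step + 1L
        upd <- adam_step(params, grads, state, config$learning_rate, t_step)
        params <- upd$params; state <- upd$state
      }
      vl <- val_loss_now(params)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = mean(epoch_losses), val_loss = vl))
      if (vl < best$loss - 1e-9) {
        best <- list(loss = vl, params = params, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
    cvae_model(best$params, config, frontend = frontend,
               site_levels = site_levels, history = history)
  })
}

#' Reconstruct participants through the trained model
#'
#' Encodes to the posterior, takes the posterior mean (default) or a seeded
#' sample, decodes with the site condition, and inverts the front-end so the
#' reconstruction lives in the curated-variable space.
#'
#' @param model A trained [cvae_model()].
#' @param x Matrix of curated-variable rows to reconstruct.
#' @param c Site labels for `x` (required for conditioned models; labels
#'   unseen in training raise an error).
#' @param mode `"posterior_mean"` (deterministic) or `"sample"`.
#' @param seed Seed for `"sample"` mode.
#' @return The reconstructed matrix, same shape as `x`.
#' @export
reconstruct <- function(model, x, c = NULL, mode = c("posterior_mean", "sample"),
                        seed = 1L) {
  stopifnot(inherits(model, "cvae_model"))
  mode <- match.arg(mode)
  x <- as.matrix(x)
  Y <- frontend_project(model$frontend, x)
  C <- onehot_sites(c, model$site_levels)
  eps <- if (mode == "sample") {
    withr::with_seed(seed, matrix(stats::rnorm(nrow(Y) * model$config$latent_dim),
                                  nrow(Y), model$config$latent_dim))
  } else NULL
  fw <- cvae_forward(model$params, Y, C, model$config$activation, eps)
  frontend_invert(model$frontend, fw$Xhat)
}

# Decode explicit latent scores (with condition intact) back to the
# curated-variable space; used by the ablation ranking.
decode_scores <- function(model, Z, c = NULL) {
  C <- onehot_sites(c, model$site_levels)
  ZC <- if (is.null(C)) Z else cbind(Z, C)
  H2pre <- sweep(ZC %*% model$params$W4, 2, model$params$b4, `+`)
  H2 <- act_fun(H2pre, model$config$activation)
  Yhat <- sweep(H2 %*% model$params$W5, 2, model$params$b5, `+`)
  frontend_invert(model$frontend, Yhat)
}

#' Test-split reconstruction error
#'
#' Mean over test participants of the summed squared reconstruction error
#' across curated variables (the participant-summed convention, which makes
#' architectures with different front-end sizes and the PCA baseline directly
#' comparable).
#'
#' @param model A trained [cvae_model()] or [fit_pca_baseline()] model.
#' @param table The curated [phenome_table()].
#' @param split A [stratified_split()] assignment.
#' @param subset Which split to evaluate; default `"test"`.
#' @return A single number.
#' @export
mse_test <- function(model, table, split, subset = "test") {
  UseMethod("mse_test")
}

#' @export
mse_test.cvae_model <- function(model, table, split, subset = "test") {
  idx <- which(split == subset)
  if (!length(idx)) fail("empty '%s' split", subset)
  X <- table$values[idx, , drop = FALSE]
  cc <- if (is.null(model$site_levels)) NULL else table$site[idx]
  Xhat <- reconstruct(model, X, cc)
  mean(rowSums((Xhat - X)^2))
}
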