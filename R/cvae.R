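# Conditional variational autoencoder for platform-effect removal.
#
# The measuring platform (scRNA-seq vs ST) is the condition: a scalar input
# feature appended to both the encoder and decoder inputs (0 = scRNA-seq,
# 10 = ST). Encoder and decoder are single-hidden-layer feed-forward maps with
# tanh activations, a diagonal-Gaussian posterior, a standard-normal prior and
# a unit-variance Gaussian decoder (reconstruction term = squared error).
# Optimization is plain minibatch Adam written in matrix algebra.

#' Per-gene min-max scaling to [0, 10]
#'
#' `x' = 10 (x - min_g) / (max_g - min_g)` per gene. Scaling factors are
#' fitted per condition (scRNA-seq and ST data are rescaled separately).
#' Degenerate genes (max = min) scale to 0 and inverse-scale back to min.
#'
#' @param m genes x samples matrix.
#' @param factors optional previously fitted factors (list with `min`, `max`).
#' @return list with `scaled` (genes x samples) and `factors`.
#' @export
minmax_scale <- function(m, factors = NULL) {
  if (is.null(factors)) {
    factors <- list(min = apply(m, 1, min), max = apply(m, 1, max))
  } else if (!identical(names(factors$min), rownames(m))) {
    stop("scaling factors do not match the gene panel")
  }
  rng <- factors$max - factors$min
  rng[rng == 0] <- Inf  # degenerate genes map to 0
  scaled <- 10 * (m - factors$min) / rng
  list(scaled = scaled, factors = factors)
}

#' Invert per-gene min-max scaling
#' @param scaled genes x samples matrix on the 0-10 scale.
#' @param factors factors from [minmax_scale()].
#' @return matrix on the original scale.
#' @export
minmax_unscale <- function(scaled, factors) {
  rng <- factors$max - factors$min
  factors$min + scaled * rng / 10
}

#' KL divergence of a diagonal Gaussian from N(0, I)
#'
#' `0.5 * sum(sigma^2 + mu^2 - 1 - log sigma^2)` per row.
#'
#' @param mu,logvar matrices (samples x latent) of posterior means and
#'   log-variances.
#' @return numeric vector, one KL value per row.
#' @export
gaussian_kl <- function(mu, logvar) {
  0.5 * rowSums(exp(logvar) + mu^2 - 1 - logvar)
}

#' CVAE training configuration
#'
#' @param latent_dim latent width; the pipeline sets this to 3 K for K cell
#'   types.
#' @param lr initial Adam learning rate (default 0.003).
#' @param epochs maximum epochs (default 1000; training normally stops much
#'   earlier on the validation loss).
#' @param batch_size minibatch size.
#' @param val_frac fraction of pseudo-spots held out for validation.
#' @param patience_decay epochs without validation improvement before the
#'   learning rate is halved.
#' @param patience_stop epochs without validation improvement before early
#'   stopping.
#' @param seed integer seed controlling initialization, shuffling and the
#'   reparameterization noise.
#' @return list of class `cvae_config`.
#' @export
cvae_config <- function(latent_dim, lr = 0.003, epochs = 1000,
                        batch_size = 128, val_frac = 0.2,
                        patience_decay = 5, patience_stop = 10, seed = 1) {
  stopifnot(latent_dim >= 1, lr > 0, epochs >= 1)
  structure(list(latent_dim = as.integer(latent_dim), lr = lr,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 val_frac = val_frac, patience_decay = patience_decay,
                 patience_stop = patience_stop, seed = as.integer(seed)),
            class = "cvae_config")
}

.glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

.cvae_init <- function(n_genes, hidden, latent) {
  list(W1 = .glorot(n_genes + 1, hidden), b1 = numeric(hidden),
       Wm = .glorot(hidden, latent),     bm = numeric(latent),
       Wv = .glorot(hidden, latent),     bv = numeric(latent),
       W4 = .glorot(latent + 1, hidden), b4 = numeric(hidden),
       W5 = .glorot(hidden, n_genes),    b5 = numeric(n_genes))
}

# Forward pass. x: samples x genes, cond: scalar or vector of condition codes.
# If eps is NULL the posterior mean is used (deterministic).
.cvae_forward <- function(w, x, cond, eps = NULL) {
  n <- nrow(x)
  cvec <- rep_len(cond, n)
  Xin <- cbind(x, cvec)
  H <- tanh(sweep(Xin %*% w$W1, 2, w$b1, "+"))
  mu <- sweep(H %*% w$Wm, 2, w$bm, "+")
  logv <- sweep(H %*% w$Wv, 2, w$bv, "+")
  z <- if (is.null(eps)) mu else mu + exp(0.5 * logv) * eps
  Zin <- cbind(z, cvec)
  H2 <- tanh(sweep(Zin %*% w$W4, 2, w$b4, "+"))
  xhat <- sweep(H2 %*% w$W5, 2, w$b5, "+")
  list(Xin = Xin, H = H, mu = mu, logv = logv, z = z, Zin = Zin,
       H2 = H2, xhat = xhat)
}

#' CVAE loss (negative ELBO)
#'
#' KL of the encoding posterior from the standard-normal prior plus the
#' Gaussian reconstruction error, averaged over samples. Minimized during
#' training.
#'
#' @param model a trained or initialized CVAE (list with `weights`).
#' @param x samples x genes scaled matrix.
#' @param cond condition code(s), 0 (scRNA-seq) or 10 (ST).
#' @param eps optional reparameterization noise (samples x latent); posterior
#'   mean is used when NULL.
#' @return list with `total`, `kl` and `recon` (means over samples).
#' @export
cvae_loss <- function(model, x, cond, eps = NULL) {
  f <- .cvae_forward(model$weights, x, cond, eps)
  if (!all(is.finite(f$xhat))) stop("non-finite activations in CVAE forward pass")
  recon <- 0.5 * sum((x - f$xhat)^2) / nrow(x)
  kl <- mean(gaussian_kl(f$mu, f$logv))
  list(total = recon + kl, kl = kl, recon = recon)
}

# Backward pass for one minibatch; returns gradients of the mean loss.
.cvae_backward <- function(w, x, f, eps) {
  n <- nrow(x)
  L <- ncol(f$mu)
  dxhat <- (f$xhat - x) / n
  dW5 <- crossprod(f$H2, dxhat); db5 <- colSums(dxhat)
  dH2 <- (dxhat %*% t(w$W5)) * (1 - f$H2^2)
  dW4 <- crossprod(f$Zin, dH2); db4 <- colSums(dH2)
  dz <- (dH2 %*% t(w$W4))[, seq_len(L), drop = FALSE]
  dmu <- dz + f$mu / n
  dlogv <- dz * (0.5 * exp(0.5 * f$logv) * eps) + 0.5 * (exp(f$logv) - 1) / n
  dH <- (dmu %*% t(w$Wm) + dlogv %*% t(w$Wv)) * (1 - f$H^2)
  dWm <- crossprod(f$H, dmu); dbm <- colSums(dmu)
  dWv <- crossprod(f$H, dlogv); dbv <- colSums(dlogv)
  dW1 <- crossprod(f$Xin, dH); db1 <- colSums(dH)
  list(W1 = dW1, b1 = db1, Wm = dWm, bm = dbm, Wv = dWv, bv = dbv,
       W4 = dW4, b4 = db4, W5 = dW5, b5 = db5)
}

#' Train the conditional variational autoencoder
#'
#' Training rows are the pseudo-spots (80%, condition 0), the reference cells
#' (condition 0) and the real ST spots (condition 10); the remaining 20% of
#' pseudo-spots form the validation set. Adam with the configured initial
#' learning rate; the rate is halved after `patience_decay` epochs without
#' validation-loss improvement and training stops after `patience_stop`
#' epochs without improvement (weights revert to the best epoch).
#'
#' @param st_scaled genes x spots ST matrix scaled with the ST-condition
#'   factors.
#' @param ref_scaled genes x cells reference matrix scaled with the
#'   scRNA-seq-condition factors.
#' @param pseudo_scaled pseudo-spots x genes matrix scaled with the
#'   scRNA-seq-condition factors (may be NULL to train without pseudo-spots;
#'   validation then holds out reference cells instead).
#' @param config a [cvae_config()].
#' @return object of class `trained_cvae` with the learned weights, layer
#'   sizes, condition codes and the loss history.
#' @export
train_cvae <- function(st_scaled, ref_scaled, pseudo_scaled, config) {
  G <- nrow(st_scaled)
  if (nrow(ref_scaled) != G) stop("gene-panel mismatch between ST and reference")
  if (!is.null(pseudo_scaled) && ncol(pseudo_scaled) != G)
    stop("gene-panel mismatch between ST and pseudo-spots")
  latent <- config$latent_dim
  hidden <- floor(sqrt(G * latent))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  if (!is.null(pseudo_scaled)) {
    sp <- split_pseudospots(nrow(pseudo_scaled), config$val_frac, config$seed)
    x_val <- pseudo_scaled[sp$val, , drop = FALSE]
    x_extra <- pseudo_scaled[sp$train, , drop = FALSE]
  } else {
    sp <- split_pseudospots(ncol(ref_scaled), config$val_frac, config$seed)
    x_val <- t(ref_scaled[, sp$val, drop = FALSE])
    x_extra <- NULL
    ref_scaled <- ref_scaled[, sp$train, drop = FALSE]
  }
  x_train <- rbind(x_extra, t(ref_scaled), t(st_scaled))
  cond_train <- c(rep(0, nrow(x_train) - ncol(st_scaled)), rep(10, ncol(st_scaled)))
  if (nrow(x_val) == 0) stop("empty validation set")

  w <- .cvae_init(G, hidden, latent)
  m1 <- lapply(w, function(p) p * 0); m2 <- m1
  lr <- config$lr; beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8; t_step <- 0
  n <- nrow(x_train)
  best <- list(loss = Inf, w = w, epoch = 0)
  since_best <- 0
  history <- numeric(0)

  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1, n)]
      xb <- x_train[idx, , drop = FALSE]
      cb <- cond_train[idx]
      eps <- matrix(rnorm(length(idx) * latent), length(idx), latent)
      f <- .cvae_forward(w, xb, cb, eps)
      if (!all(is.finite(f$xhat))) stop("non-finite activations during CVAE training")
      g <- .cvae_backward(w, xb, f, eps)
      t_step <- t_step + 1
      for (p in names(w)) {
        m1[[p]] <- beta1 * m1[[p]] + (1 - beta1) * g[[p]]
        m2[[p]] <- beta2 * m2[[p]] + (1 - beta2) * g[[p]]^2
        mhat <- m1[[p]] / (1 - beta1^t_step)
        vhat <- m2[[p]] / (1 - beta2^t_step)
        w[[p]] <- w[[p]] - lr * mhat / (sqrt(vhat) + adam_eps)
      }
    }
    vl <- cvae_loss(list(weights = w), x_val, 0)$total
    history <- c(history, vl)
    if (vl < best$loss - 1e-8) {
      best <- list(loss = vl, w = w, epoch = epoch)
      since_best <- 0
    } else {
      since_best <- since_best + 1
      if (since_best %% config$patience_decay == 0) lr <- lr / 2
      if (since_best >= config$patience_stop) break
    }
  }

  best$w <- lapply(best$w, unname)
  structure(list(weights = best$w, n_genes = G, hidden = hidden,
                 latent_dim = latent, cond_codes = c(sc = 0, st = 10),
                 gene_ids = rownames(st_scaled), config = config,
                 val_loss = best$loss, history = history,
                 best_epoch = best$epoch),
            class = "trained_cvae")
}

#' @export
print.trained_cvae <- function(x, ...) {
  cat("Trained CVAE:", x$n_genes, "genes ->", x$hidden, "hidden ->",
      x$latent_dim, "latent; best validation loss",
      format(x$val_loss, digits = 5), "at epoch", x$best_epoch, "\n")
  invisible(x)
}

#' Transform ST data into the scRNA-seq space
#'
#' Encodes each spot under the ST condition (posterior mean) and decodes it
#' under the scRNA-seq condition, clips to the 0-10 training range,
#' inverse-scales with the scRNA-seq factors, multiplies by 10,000, rounds to
#' the nearest integer and clamps at zero, yielding a non-negative integer
#' count matrix in the reference space.
#'
#' @param trained a `trained_cvae`.
#' @param st_scaled genes x spots matrix scaled with the ST-condition factors.
#' @param sc_factors the scRNA-seq-condition scaling factors.
#' @return genes x spots non-negative integer matrix.
#' @export
transform_st <- function(trained, st_scaled, sc_factors) {
  dec <- .cvae_translate(trained, st_scaled,
                         cond_in = trained$cond_codes["st"],
                         cond_out = trained$cond_codes["sc"])
  expr <- minmax_unscale(dec, sc_factors)
  out <- pmax(round(expr * 1e4), 0)
  storage.mode(out) <- "double"
  out
}

#' Denoise the reference through the scRNA-seq-condition autoencoder
#'
#' Encode and decode with condition 0 and inverse-scale with the scRNA-seq
#' factors. Stays continuous (no rescaling to counts): the output feeds the
#' signature averaging.
#'
#' @inheritParams transform_st
#' @param ref_scaled genes x cells matrix scaled with the scRNA-seq factors.
#' @return genes x cells non-negative real matrix.
#' @export
denoise_reference <- function(trained, ref_scaled, sc_factors) {
  dec <- .cvae_translate(trained, ref_scaled,
                         cond_in = trained$cond_codes["sc"],
                         cond_out = trained$cond_codes["sc"])
  pmax(minmax_unscale(dec, sc_factors), 0)
}

# Encode with cond_in (posterior mean), decode with cond_out; returns the
# decoded genes x samples matrix clipped to the 0-10 training range.
.cvae_translate <- function(trained, x_scaled, cond_in, cond_out) {
  w <- trained$weights
  x <- t(x_scaled)
  f <- .cvae_forward(w, x, cond_in)          # z = posterior mean
  Zin <- cbind(f$mu, rep_len(cond_out, nrow(x)))
  H2 <- tanh(sweep(Zin %*% w$W4, 2, w$b4, "+"))
  xhat <- sweep(H2 %*% w$W5, 2, w$b5, "+")
  out <- t(pmin(pmax(xhat, 0), 10))
  dimnames(out) <- dimnames(x_scaled)
  out
}

#' Save / load a trained CVAE as a plain-text directory
#'
#' Weights are written as CSV matrices and the configuration, gene panel and
#' scaling factors as JSON, so a model directory is portable text.
#'
#' @param trained a `trained_cvae`.
#' @param dir directory to create.
#' @param factors optional list of scaling-factor sets to store alongside.
#' @return `dir`, invisibly.
#' @export
save_cvae <- function(trained, dir, factors = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in names(trained$weights))
    write.csv(trained$weights[[p]], file.path(dir, paste0(p, ".csv")),
              row.names = FALSE)
  meta <- trained[setdiff(names(trained), "weights")]
  meta$config <- unclass(meta$config)
  meta$cond_codes <- as.list(meta$cond_codes)  # keep names through JSON
  if (!is.null(factors)) meta$factors <- factors
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_cvae
#' @export
load_cvae <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  weights <- list()
  for (p in c("W1", "b1", "Wm", "bm", "Wv", "bv", "W4", "b4", "W5", "b5")) {
    m <- as.matrix(read.csv(file.path(dir, paste0(p, ".csv"))))
    dimnames(m) <- NULL
    weights[[p]] <- if (startsWith(p, "b")) drop(m) else m
  }
  obj <- c(list(weights = weights), meta)
  obj$cond_codes <- unlist(obj$cond_codes)
  obj$config <- do.call(cvae_config, obj$config[names(obj$config) %in%
    names(formals(cvae_config))])
  class(obj) <- "trained_cvae"
  obj
}
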