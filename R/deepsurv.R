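## Native feed-forward Cox partial-likelihood network ("Deepsurv"): a
## multi-layer perceptron outputting a scalar log-risk, trained by
## minimizing the negative log Cox partial likelihood with batch-wise risk
## sets, batch normalization, dropout, L2 regularization, and early stopping.

#' Deepsurv training configuration
#'
#' Defaults follow the standard clinical-dataset configuration: 512 epochs
#' with early stopping, batch size 32 with batch normalization, momentum
#' 0.85 (SGD), learning rate 0.01 with inverse-time decay 0.001, L2
#' regularization coefficient 15, and dropout 0.1. The regularization
#' coefficient applies to the sum-form objective
#' \eqn{\sum_{events} NPLL + (\lambda/2)\|W\|^2}, so its effective per-event
#' weight is \eqn{\lambda / D} with `D` the number of training events.
#'
#' @param layers Number of hidden layers (0 = linear Cox-limit model).
#' @param nodes Nodes per hidden layer.
#' @param activation `"relu"` or `"selu"`.
#' @param optimizer `"adam"` or `"sgd"` (with momentum).
#' @param epochs Maximum epochs.
#' @param batch_size Mini-batch size; batches without events are skipped.
#' @param batch_norm Batch normalization on hidden layers.
#' @param momentum SGD momentum.
#' @param learning_rate Initial learning rate.
#' @param lr_decay Inverse-time decay: `lr_t = lr / (1 + decay * epoch)`.
#' @param l2_reg L2 coefficient on the weights (not biases or
#'   batch-norm parameters).
#' @param dropout Hidden-layer dropout probability in `[0, 1)`.
#' @param val_fraction Fraction of the training data held out for early
#'   stopping (0 disables early stopping).
#' @param patience Early-stopping patience in epochs.
#' @param seed Integer seed (initialization, batching, dropout).
#' @return Object of class `deepsurv_config`.
#' @export
deepsurv_config <- function(layers = 1L, nodes = 8L,
                            activation = c("relu", "selu"),
                            optimizer = c("adam", "sgd"),
                            epochs = 512L, batch_size = 32L,
                            batch_norm = TRUE, momentum = 0.85,
                            learning_rate = 0.01, lr_decay = 0.001,
                            l2_reg = 15, dropout = 0.1,
                            val_fraction = 0.1, patience = 16L, seed = 1L) {
  activation <- match.arg(activation)
  optimizer <- match.arg(optimizer)
  if (learning_rate <= 0 || lr_decay < 0 || momentum < 0) {
    stop("rates must be positive (decay/momentum nonnegative)")
  }
  if (dropout < 0 || dropout >= 1) stop("`dropout` must be in [0, 1)")
  if (l2_reg < 0) stop("`l2_reg` must be nonnegative")
  structure(
    list(layers = as.integer(layers), nodes = as.integer(nodes),
         activation = activation, optimizer = optimizer,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         batch_norm = isTRUE(batch_norm), momentum = momentum,
         learning_rate = learning_rate, lr_decay = lr_decay,
         l2_reg = l2_reg, dropout = dropout,
         val_fraction = val_fraction, patience = as.integer(patience),
         seed = as.integer(seed)),
    class = "deepsurv_config"
  )
}

#' Negative log Cox partial likelihood of a score vector
#'
#' Sum-form over events with Breslow tie handling:
#' \eqn{-\sum_{i: event} [s_i - \log \sum_{j: t_j \ge t_i} e^{s_j}]}.
#' Used both as the network training loss (computed within each batch's risk
#' sets) and as the validation criterion; with batch size >= n it equals the
#' full-cohort negative log partial likelihood.
#'
#' @param scores Numeric log-risk scores.
#' @param time,event Survival outcome.
#' @return List with `loss` and `grad` (d loss / d scores).
#' @export
cox_npll <- function(scores, time, event) {
  n <- length(scores)
  if (sum(event) == 0) return(list(loss = 0, grad = rep(0, n)))
  ord <- order(time)
  s <- scores[ord]; tt <- time[ord]; ev <- event[ord]
  es <- exp(s - max(s))
  rc <- rev(cumsum(rev(es)))            # sum over {j: t_j >= t_i} in sorted order
  ut <- unique(tt)
  first <- match(ut, tt)                # first index at each unique time
  denom_u <- rc[first]                  # shared Breslow denominator per time
  d_u <- vapply(ut, function(u) sum(ev[tt == u]), numeric(1))
  loss <- -(sum(s[ev == 1]) - max(scores) * sum(ev)) +
    sum(d_u[d_u > 0] * log(denom_u[d_u > 0]))
  ## grad: -delta_j + e^{s_j} * A(t_j), A(t) = sum_{u <= t} d_u / denom_u
  a_u <- cumsum(d_u / denom_u)
  A <- a_u[match(tt, ut)]
  g <- -ev + es * A
  grad <- numeric(n)
  grad[ord] <- g
  list(loss = loss, grad = grad)
}

selu_lambda <- 1.0507009873554805
selu_alpha <- 1.6732632423543772

act_fwd <- function(z, activation) {
  if (activation == "relu") pmax(z, 0)
  else selu_lambda * ifelse(z > 0, z, selu_alpha * (exp(z) - 1))
}

act_bwd <- function(z, activation) {
  if (activation == "relu") (z > 0) * 1
  else selu_lambda * ifelse(z > 0, 1, selu_alpha * exp(z))
}

init_deepsurv_params <- function(p, cfg) {
  sizes <- c(p, rep(cfg$nodes, cfg$layers), 1L)
  params <- list(W = list(), b = list(), gamma = list(), beta = list(),
                 run_mean = list(), run_var = list())
  for (l in seq_len(length(sizes) - 1L)) {
    fan_in <- sizes[l]
    sd0 <- if (cfg$activation == "relu") sqrt(2 / fan_in) else sqrt(1 / fan_in)
    params$W[[l]] <- matrix(rnorm(fan_in * sizes[l + 1L], 0, sd0),
                            fan_in, sizes[l + 1L])
    params$b[[l]] <- rep(0, sizes[l + 1L])
    if (l < length(sizes) - 1L && cfg$batch_norm) {
      params$gamma[[l]] <- rep(1, sizes[l + 1L])
      params$beta[[l]] <- rep(0, sizes[l + 1L])
      params$run_mean[[l]] <- rep(0, sizes[l + 1L])
      params$run_var[[l]] <- rep(1, sizes[l + 1L])
    }
  }
  params
}

## Forward pass. training = TRUE uses batch statistics and dropout and
## returns the caches needed for backprop.
deepsurv_forward <- function(params, X, cfg, training = FALSE) {
  L <- cfg$layers
  eps <- 1e-5
  cache <- list(A = list(), Z = list(), Xhat = list(), ivs = list(),
                mask = list(), mu = list())
  a <- X
  for (l in seq_len(L)) {
    z <- sweep(a %*% params$W[[l]], 2, params$b[[l]], `+`)
    if (cfg$batch_norm) {
      if (training && nrow(z) > 1L) {
        mu <- colMeans(z)
        va <- colMeans(sweep(z, 2, mu)^2)
        params$run_mean[[l]] <- 0.9 * params$run_mean[[l]] + 0.1 * mu
        params$run_var[[l]] <- 0.9 * params$run_var[[l]] + 0.1 * va
      } else {
        mu <- params$run_mean[[l]]
        va <- params$run_var[[l]]
      }
      ivs <- 1 / sqrt(va + eps)
      xhat <- sweep(sweep(z, 2, mu), 2, ivs, `*`)
      zb <- sweep(sweep(xhat, 2, params$gamma[[l]], `*`), 2, params$beta[[l]], `+`)
      cache$Xhat[[l]] <- xhat; cache$ivs[[l]] <- ivs; cache$mu[[l]] <- mu
    } else {
      zb <- z
    }
    h <- act_fwd(zb, cfg$activation)
    if (training && cfg$dropout > 0) {
      mask <- matrix(runif(length(h)) >= cfg$dropout, nrow(h), ncol(h)) /
        (1 - cfg$dropout)
      h <- h * mask
      cache$mask[[l]] <- mask
    }
    cache$A[[l]] <- a       # input to layer l
    cache$Z[[l]] <- zb      # pre-activation (post-BN)
    a <- h
  }
  s <- as.numeric(sweep(a %*% params$W[[L + 1L]], 2, params$b[[L + 1L]], `+`))
  cache$A[[L + 1L]] <- a
  list(scores = s, cache = cache, params = params)
}

## Backward pass: gradient of (loss wrt scores = dscores) through the net.
deepsurv_backward <- function(params, cache, dscores, cfg) {
  L <- cfg$layers
  g <- list(W = list(), b = list(), gamma = list(), beta = list())
  delta <- matrix(dscores, ncol = 1)
  g$W[[L + 1L]] <- t(cache$A[[L + 1L]]) %*% delta
  g$b[[L + 1L]] <- colSums(delta)
  da <- delta %*% t(params$W[[L + 1L]])
  for (l in rev(seq_len(L))) {
    if (cfg$dropout > 0 && !is.null(cache$mask[[l]])) {
      da <- da * cache$mask[[l]]
    }
    dzb <- da * act_bwd(cache$Z[[l]], cfg$activation)
    if (cfg$batch_norm) {
      xhat <- cache$Xhat[[l]]
      ivs <- cache$ivs[[l]]
      g$gamma[[l]] <- colSums(dzb * xhat)
      g$beta[[l]] <- colSums(dzb)
      dxhat <- sweep(dzb, 2, params$gamma[[l]], `*`)
      N <- nrow(dxhat)
      dz <- sweep(
        dxhat - matrix(colMeans(dxhat), N, ncol(dxhat), byrow = TRUE) -
          xhat * matrix(colMeans(dxhat * xhat), N, ncol(dxhat), byrow = TRUE),
        2, ivs, `*`
      )
    } else {
      dz <- dzb
    }
    g$W[[l]] <- t(cache$A[[l]]) %*% dz
    g$b[[l]] <- colSums(dz)
    da <- dz %*% t(params$W[[l]])
  }
  g
}

make_optimizer_state <- function(params, cfg) {
  zero_like <- function(lst) lapply(lst, function(x) x * 0)
  list(m = list(W = zero_like(params$W), b = zero_like(params$b),
                gamma = zero_like(params$gamma), beta = zero_like(params$beta)),
       v = list(W = zero_like(params$W), b = zero_like(params$b),
                gamma = zero_like(params$gamma), beta = zero_like(params$beta)),
       t = 0)
}

apply_update <- function(params, grads, state, cfg, lr) {
  groups <- c("W", "b", "gamma", "beta")
  state$t <- state$t + 1
  for (gr in groups) {
    for (l in seq_along(params[[gr]])) {
      if (l > length(grads[[gr]]) || is.null(grads[[gr]][[l]])) next
      gmat <- grads[[gr]][[l]]
      if (cfg$optimizer == "adam") {
        b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
        state$m[[gr]][[l]] <- b1 * state$m[[gr]][[l]] + (1 - b1) * gmat
        state$v[[gr]][[l]] <- b2 * state$v[[gr]][[l]] + (1 - b2) * gmat^2
        mhat <- state$m[[gr]][[l]] / (1 - b1^state$t)
        vhat <- state$v[[gr]][[l]] / (1 - b2^state$t)
        params[[gr]][[l]] <- params[[gr]][[l]] - lr * mhat / (sqrt(vhat) + eps)
      } else {
        state$m[[gr]][[l]] <- cfg$momentum * state$m[[gr]][[l]] - lr * gmat
        params[[gr]][[l]] <- params[[gr]][[l]] + state$m[[gr]][[l]]
      }
    }
  }
  list(params = params, state = state)
}

#' Fit the Cox partial-likelihood neural network
#'
#' Trains a feed-forward network outputting a scalar log-risk by minimizing
#' the negative log Cox partial likelihood with risk sets formed within each
#' mini-batch (full-batch mode, `batch_size >= n`, makes the loss exactly the
#' full-cohort partial likelihood, recovering Cox regression in the 0-layer
#' linear limit). Early stopping monitors the partial likelihood of a held-out
#' split. Survival curves use the Breslow baseline on the final scores.
#'
#' @param x Numeric (one-hot encoded) design matrix.
#' @param time,event Survival outcome.
#' @param config A [deepsurv_config()].
#' @return Object of class `c("deepsurv_fit", "survival_fit")` with elements
#'   `params`, `config`, `history` (per-epoch train/validation loss),
#'   `skipped_batches`, and `baseline`.
#' @export
fit_deepsurv <- function(x, time, event, config = deepsurv_config()) {
  stopifnot(inherits(config, "deepsurv_config"))
  x <- as.matrix(x)
  n <- nrow(x)
  cfg <- config
  with_seed(cfg$seed, {
    params <- init_deepsurv_params(ncol(x), cfg)

    ## validation split for early stopping
    idx <- sample(n)
    n_val <- floor(cfg$val_fraction * n)
    use_es <- n_val >= 5 && sum(event[idx[seq_len(n_val)]]) >= 1
    val_idx <- if (use_es) idx[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(idx, val_idx)
    Xtr <- x[tr_idx, , drop = FALSE]
    ttr <- time[tr_idx]; etr <- event[tr_idx]
    d_total <- max(sum(etr), 1)

    state <- make_optimizer_state(params, cfg)
    best <- list(params = params, loss = Inf, epoch = 0L)
    wait <- 0L
    skipped <- 0L
    history <- data.frame(epoch = integer(0), train = numeric(0),
                          val = numeric(0))

    for (epoch in seq_len(cfg$epochs)) {
      lr <- cfg$learning_rate / (1 + cfg$lr_decay * (epoch - 1))
      perm <- sample(length(tr_idx))
      batches <- split(perm, ceiling(seq_along(perm) / cfg$batch_size))
      ep_loss <- 0; ep_events <- 0
      for (bi in batches) {
        if (sum(etr[bi]) == 0) { skipped <- skipped + 1L; next }
        fw <- deepsurv_forward(params, Xtr[bi, , drop = FALSE], cfg,
                               training = TRUE)
        params <- fw$params          # running BN stats updated
        nl <- cox_npll(fw$scores, ttr[bi], etr[bi])
        if (!is.finite(nl$loss)) {
          stop("NaN/Inf Deepsurv loss at epoch ", epoch,
               "; consider lowering the learning rate")
        }
        grads <- deepsurv_backward(params, fw$cache, nl$grad / d_total, cfg)
        if (cfg$l2_reg > 0) {
          for (l in seq_along(grads$W)) {
            grads$W[[l]] <- grads$W[[l]] + (cfg$l2_reg / d_total) * params$W[[l]]
          }
        }
        up <- apply_update(params, grads, state, cfg, lr)
        params <- up$params; state <- up$state
        ep_loss <- ep_loss + nl$loss
        ep_events <- ep_events + sum(etr[bi])
      }

      val_loss <- NA_real_
      if (use_es) {
        sv <- deepsurv_forward(params, x[val_idx, , drop = FALSE], cfg,
                               training = FALSE)$scores
        val_loss <- cox_npll(sv, time[val_idx], event[val_idx])$loss /
          max(sum(event[val_idx]), 1)
        if (val_loss < best$loss - 1e-8) {
          best <- list(params = params, loss = val_loss, epoch = epoch)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= cfg$patience) {
            history <- rbind(history, data.frame(
              epoch = epoch, train = ep_loss / max(ep_events, 1), val = val_loss))
            break
          }
        }
      }
      history <- rbind(history, data.frame(
        epoch = epoch, train = ep_loss / max(ep_events, 1), val = val_loss))
    }

    final <- if (use_es && is.finite(best$loss)) best$params else params
    s_all <- deepsurv_forward(final, x, cfg, training = FALSE)$scores
    structure(
      list(params = final, config = cfg,
           history = history, skipped_batches = skipped,
           cols = colnames(x),
           baseline = breslow_baseline(time, event, s_all)),
      class = c("deepsurv_fit", "survival_fit")
    )
  })
}

#' @export
predict_risk.deepsurv_fit <- function(object, newdata, ...) {
  nd <- as.matrix(newdata)[, object$cols, drop = FALSE]
  deepsurv_forward(object$params, nd, object$config, training = FALSE)$scores
}
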