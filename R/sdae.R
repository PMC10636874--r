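#' Stacked denoising autoencoder configuration
#'
#' @param widths Integer vector of layer widths, input width first, strictly
#'   positive and non-increasing toward the bottleneck (last entry). The
#'   first width must equal the feature (PPMI) column count at training time.
#' @param corruption Fraction of input entries independently masked to zero
#'   during training, in \[0, 1).
#' @param epochs Training epochs per greedy stage.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param seed Integer seed; together with the config and data it fully
#'   determines the trained parameters.
#' @param fine_tune After greedy layer-wise pretraining, fine-tune the whole
#'   unrolled stack end-to-end.
#' @param scale_input Min-max scale each input column to \[0, 1\] before
#'   training (guards against sigmoid saturation on large PPMI values).
#' @return An object of class `sdae_config`.
#' @export
sdae_config <- function(widths, corruption = 0.2, epochs = 100,
                        learning_rate = 1e-3, batch_size = 32, seed = 1,
                        fine_tune = FALSE, scale_input = FALSE) {
  widths <- as.integer(widths)
  if (length(widths) < 2) stop("need at least an input and one hidden width")
  if (any(widths <= 0)) stop("layer widths must be strictly positive")
  if (any(diff(widths) > 0))
    stop("layer widths must be non-increasing toward the bottleneck")
  if (corruption < 0 || corruption >= 1) stop("corruption must be in [0, 1)")
  if (epochs < 1 || batch_size < 1 || learning_rate <= 0)
    stop("epochs, batch_size must be >= 1 and learning_rate > 0")
  structure(list(widths = widths, corruption = corruption, epochs = epochs,
                 learning_rate = learning_rate, batch_size = batch_size,
                 seed = as.integer(seed), fine_tune = fine_tune,
                 scale_input = scale_input),
            class = "sdae_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Masking corruption for denoising training
#'
#' Independently zeroes each entry with the given probability; the same seed
#' produces the same mask.
#'
#' @param x Numeric matrix (rows = examples).
#' @param fraction Probability an entry is set to 0, in \[0, 1).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Matrix of the same shape.
#' @export
corrupt <- function(x, fraction, seed = NULL) {
  if (fraction < 0 || fraction >= 1) stop("corruption fraction must be in [0, 1)")
  x <- as.matrix(x)
  if (fraction == 0) return(x)
  if (!is.null(seed)) set.seed(seed)
  mask <- matrix(stats::runif(length(x)) >= fraction, nrow(x), ncol(x))
  x * mask
}

glorot_init <- function(fan_in, fan_out) {
  s <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -s, s), fan_in, fan_out)
}

adam_new <- function(shapes) {
  lapply(shapes, function(sh) list(m = array(0, sh), v = array(0, sh)))
}

adam_step <- function(par, grad, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(par = par - lr * mhat / (sqrt(vhat) + eps), state = st)
}

# one denoising-autoencoder stage: sigmoid encoder, linear decoder,
# squared reconstruction loss of the clean input from the corrupted input
train_dae_stage <- function(H, d_out, cfg, stage) {
  n <- nrow(H); d_in <- ncol(H)
  W1 <- glorot_init(d_in, d_out); b1 <- numeric(d_out)
  W2 <- glorot_init(d_out, d_in); b2 <- numeric(d_in)
  opt <- adam_new(list(c(d_in, d_out), d_out, c(d_out, d_in), d_in))
  t_step <- 0L
  trace <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = cfg$batch_size)
    ep_loss <- 0
    for (s in starts) {
      rows <- ord[s:min(s + cfg$batch_size - 1, n)]
      Xb <- H[rows, , drop = FALSE]
      Xc <- if (cfg$corruption > 0) corrupt(Xb, cfg$corruption) else Xb
      Y <- sigmoid(sweep(Xc %*% W1, 2, b1, "+"))
      Z <- sweep(Y %*% W2, 2, b2, "+")
      R <- Z - Xb
      loss <- mean(R^2)
      if (!is.finite(loss))
        stop("non-finite training loss at stage ", stage, ", epoch ", epoch)
      ep_loss <- ep_loss + loss * length(rows)
      dZ <- 2 * R / length(R)
      gW2 <- crossprod(Y, dZ); gb2 <- colSums(dZ)
      dY <- (dZ %*% t(W2)) * Y * (1 - Y)
      gW1 <- crossprod(Xc, dY); gb1 <- colSums(dY)
      t_step <- t_step + 1L
      up <- adam_step(W1, gW1, opt[[1]], cfg$learning_rate, t_step)
      W1 <- up$par; opt[[1]] <- up$state
      up <- adam_step(b1, gb1, opt[[2]], cfg$learning_rate, t_step)
      b1 <- up$par; opt[[2]] <- up$state
      up <- adam_step(W2, gW2, opt[[3]], cfg$learning_rate, t_step)
      W2 <- up$par; opt[[3]] <- up$state
      up <- adam_step(b2, gb2, opt[[4]], cfg$learning_rate, t_step)
      b2 <- up$par; opt[[4]] <- up$state
    }
    trace[epoch] <- ep_loss / n
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, trace = trace)
}

#' Train a stacked denoising autoencoder on a PPMI matrix
#'
#' Greedy layer-wise training: stage k learns a denoising autoencoder that
#' reconstructs the clean stage input from its corrupted version through a
#' sigmoid hidden layer of the next configured width with a linear decoder
#' and squared loss; the stage's hidden representation of the clean input
#' feeds the next stage. Optionally fine-tunes the unrolled encoder/decoder
#' stack end-to-end afterwards.
#'
#' @param X Feature matrix (rows = nodes), e.g. a [ppmi()] matrix. Column
#'   count must equal `cfg$widths[1]`.
#' @param cfg An [sdae_config()].
#' @return An object of class `sdae_state`: per-layer parameter list, per-stage
#'   loss traces, the config, and input-scaling parameters if used.
#' @export
train_sdae <- function(X, cfg) {
  stopifnot(inherits(cfg, "sdae_config"))
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("training features must be finite")
  if (ncol(X) != cfg$widths[1])
    stop("input width ", ncol(X), " does not match configured first width ",
         cfg$widths[1])
  scaling <- NULL
  if (cfg$scale_input) {
    lo <- apply(X, 2, min); hi <- apply(X, 2, max)
    rng <- ifelse(hi > lo, hi - lo, 1)
    X <- sweep(sweep(X, 2, lo), 2, rng, "/")
    scaling <- list(lo = lo, rng = rng)
  }
  set.seed(cfg$seed)
  H <- X
  layers <- list()
  traces <- list()
  for (k in seq_along(cfg$widths)[-1]) {
    st <- train_dae_stage(H, cfg$widths[k], cfg, stage = k - 1L)
    layers[[k - 1L]] <- st[c("W1", "b1", "W2", "b2")]
    traces[[k - 1L]] <- st$trace
    H <- sigmoid(sweep(H %*% st$W1, 2, st$b1, "+"))
  }
  state <- structure(list(layers = layers, loss_trace = traces, config = cfg,
                          scaling = scaling, fine_tune_trace = NULL),
                     class = "sdae_state")
  if (cfg$fine_tune) state <- fine_tune_sdae(state, X)
  state
}

# end-to-end fine-tuning of the unrolled stack (encoders then decoders in
# reverse), squared reconstruction loss, corruption on the raw input only
fine_tune_sdae <- function(state, X) {
  cfg <- state$config
  L <- length(state$layers)
  n <- nrow(X)
  shapes <- unlist(lapply(state$layers, function(l)
    list(dim(l$W1), length(l$b1), dim(l$W2), length(l$b2))), recursive = FALSE)
  opt <- adam_new(shapes)
  t_step <- 0L
  trace <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = cfg$batch_size)
    ep_loss <- 0
    for (s in starts) {
      rows <- ord[s:min(s + cfg$batch_size - 1, n)]
      Xb <- X[rows, , drop = FALSE]
      Xc <- if (cfg$corruption > 0) corrupt(Xb, cfg$corruption) else Xb
      # forward: encoder stack (sigmoid), then decoder stack in reverse
      # (sigmoid between stages, linear at the final output)
      acts <- vector("list", 2 * L + 1)
      acts[[1]] <- Xc
      for (k in seq_len(L)) {
        l <- state$layers[[k]]
        acts[[k + 1]] <- sigmoid(sweep(acts[[k]] %*% l$W1, 2, l$b1, "+"))
      }
      for (k in seq(L, 1)) {
        l <- state$layers[[k]]
        pre <- sweep(acts[[2 * L - k + 1]] %*% l$W2, 2, l$b2, "+")
        acts[[2 * L - k + 2]] <- if (k == 1) pre else sigmoid(pre)
      }
      Z <- acts[[2 * L + 1]]
      R <- Z - Xb
      loss <- mean(R^2)
      if (!is.finite(loss))
        stop("non-finite training loss at stage fine-tune, epoch ", epoch)
      ep_loss <- ep_loss + loss * length(rows)
      # backward
      delta <- 2 * R / length(R)
      grads <- vector("list", L)
      for (k in seq_len(L)) {   # decoders, output side first (layer 1 decoder)
        a_in <- acts[[2 * L - k + 1]]
        if (k > 1) delta <- delta * acts[[2 * L - k + 2]] *
            (1 - acts[[2 * L - k + 2]])
        grads[[k]] <- c(grads[[k]],
                        list(gW2 = crossprod(a_in, delta), gb2 = colSums(delta)))
        delta <- delta %*% t(state$layers[[k]]$W2)
      }
      for (k in seq(L, 1)) {    # encoders, deepest first
        a_out <- acts[[k + 1]]
        delta <- delta * a_out * (1 - a_out)
        grads[[k]] <- c(grads[[k]],
                        list(gW1 = crossprod(acts[[k]], delta),
                             gb1 = colSums(delta)))
        delta <- delta %*% t(state$layers[[k]]$W1)
      }
      t_step <- t_step + 1L
      for (k in seq_len(L)) {
        base <- (k - 1) * 4
        l <- state$layers[[k]]
        up <- adam_step(l$W1, grads[[k]]$gW1, opt[[base + 1]], cfg$learning_rate, t_step)
        l$W1 <- up$par; opt[[base + 1]] <- up$state
        up <- adam_step(l$b1, grads[[k]]$gb1, opt[[base + 2]], cfg$learning_rate, t_step)
        l$b1 <- up$par; opt[[base + 2]] <- up$state
        up <- adam_step(l$W2, grads[[k]]$gW2, opt[[base + 3]], cfg$learning_rate, t_step)
        l$W2 <- up$par; opt[[base + 3]] <- up$state
        up <- adam_step(l$b2, grads[[k]]$gb2, opt[[base + 4]], cfg$learning_rate, t_step)
        l$b2 <- up$par; opt[[base + 4]] <- up$state
        state$layers[[k]] <- l
      }
    }
    trace[epoch] <- ep_loss / n
  }
  state$fine_tune_trace <- trace
  state
}

#' @export
print.sdae_state <- function(x, ...) {
  cat("sdae_state: widths", paste(x$config$widths, collapse = "-"), "\n")
  for (k in seq_along(x$loss_trace)) {
    tr <- x$loss_trace[[k]]
    cat("  stage", k, ": loss", signif(tr[1], 4), "->",
        signif(tr[length(tr)], 4), "\n")
  }
  invisible(x)
}

#' Encode rows through the trained SDAE bottleneck
#'
#' Applies the encoder stack only (no decoders); the output width is the last
#' configured width. The map is row-wise, so permuting input rows permutes
#' output rows identically.
#'
#' @param state An `sdae_state` from [train_sdae()].
#' @param X Matrix whose column count equals the trained input width.
#' @return Embedding matrix with one row per input row and bottleneck width
#'   columns; rownames carried over.
#' @export
encode <- function(state, X) {
  stopifnot(inherits(state, "sdae_state"))
  X <- as.matrix(X)
  if (ncol(X) != state$config$widths[1])
    stop("input width ", ncol(X), " does not match trained width ",
         state$config$widths[1])
  if (!is.null(state$scaling))
    X <- sweep(sweep(X, 2, state$scaling$lo), 2, state$scaling$rng, "/")
  H <- X
  for (l in state$layers)
    H <- sigmoid(sweep(H %*% l$W1, 2, l$b1, "+"))
  H
}
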