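# Dual-branch cross-attention lifting network, implemented directly on BLAS
# matrix primitives with hand-derived backpropagation: two token streams
# (coordinate tokens from the 133 keypoints, bone tokens from the 132 bone
# features) are fused by cross-attention layers, the fused joint tokens pass
# through a self-attention encoder, and a linear head regresses root-relative
# 3D coordinates. All batched activations are stored as (B*T) x d matrices
# with sample-major row blocks.

#' Lifting model configuration
#'
#' Defaults follow the published full-scale profile: a 6-layer, 8-head
#' self-attention encoder with hidden width 256 and 4 cross-attention fusion
#' layers. See \code{\link{desk_profile}} for the reduced profile used by the
#' package's CPU-scale experiments.
#'
#' @param hidden hidden width (divisible by \code{heads}).
#' @param depth self-attention encoder layers.
#' @param heads attention heads.
#' @param cross_layers dual-branch cross-attention fusion layers.
#' @param dropout dropout rate on residual branches during training.
#' @param ffn_mult feed-forward expansion factor.
#' @param multi_hypothesis also train an auxiliary regression head on the
#'   pre-encoder fused tokens, giving a second pose hypothesis.
#' @return object of class \code{lift_config}.
#' @export
lift_config <- function(hidden = 256, depth = 6, heads = 8, cross_layers = 4,
                        dropout = 0.1, ffn_mult = 4, multi_hypothesis = FALSE) {
  stopifnot(hidden %% heads == 0, depth >= 1, cross_layers >= 1,
            dropout >= 0, dropout < 1)
  structure(list(hidden = hidden, depth = depth, heads = heads,
                 cross_layers = cross_layers, dropout = dropout,
                 ffn_mult = ffn_mult, multi_hypothesis = multi_hypothesis),
            class = "lift_config")
}

#' Desk-scale model profile
#'
#' The reduced configuration used for single-CPU experiments and tests:
#' hidden 16, 2 heads, 1 cross-attention fusion layer, 1 encoder layer,
#' feed-forward expansion 2, no dropout. All architectural elements of the
#' full profile are preserved at reduced width.
#'
#' @return a \code{lift_config}.
#' @export
desk_profile <- function() {
  lift_config(hidden = 16, depth = 1, heads = 2, cross_layers = 1,
              dropout = 0, ffn_mult = 2)
}

#' Training configuration
#'
#' Defaults follow the published training recipe: AdamW, 210 epochs, batch
#' size 64, initial learning rate 1e-3, cosine-annealed with multiplicative
#' 0.1 drops at epochs 170 and 200, and train-time augmentation (random
#' in-plane rotation within 15 degrees, 2D scaling in 0.8-1.2, left/right
#' flipping). See \code{\link{desk_training}} for the CPU-scale profile.
#'
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr initial learning rate.
#' @param lr_drop_epochs epochs at which the rate is additionally multiplied
#'   by 0.1 (use \code{integer(0)} to disable).
#' @param cosine use cosine annealing as the base schedule.
#' @param seed integer seed controlling initialization, shuffling and
#'   augmentation.
#' @param weights a \code{\link{loss_weights}}.
#' @param augment apply train-time augmentation.
#' @param weight_decay AdamW decoupled weight decay.
#' @return object of class \code{train_config}.
#' @export
train_config <- function(epochs = 210, batch_size = 64, lr = 1e-3,
                         lr_drop_epochs = c(170, 200), cosine = TRUE,
                         seed = 1, weights = loss_weights(), augment = TRUE,
                         weight_decay = 0.01) {
  stopifnot(epochs >= 1, lr > 0,
            length(lr_drop_epochs) == 0 || epochs > max(lr_drop_epochs))
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, lr_drop_epochs = lr_drop_epochs, cosine = cosine,
                 seed = as.integer(seed), weights = weights, augment = augment,
                 weight_decay = weight_decay), class = "train_config")
}

#' Desk-scale training profile
#'
#' Short-schedule training used for the CPU-scale synthetic experiments:
#' 4 epochs, batch 64, initial rate 5e-3 cosine-annealed, no step drops.
#'
#' @param ... overrides passed to \code{\link{train_config}}.
#' @return a \code{train_config}.
#' @export
desk_training <- function(...) {
  args <- list(epochs = 4, batch_size = 64, lr = 5e-3,
               lr_drop_epochs = integer(0), cosine = TRUE)
  args[names(list(...))] <- list(...)
  do.call(train_config, args)
}

# ---- parameter containers ------------------------------------------------

rmat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
ln_params <- function(d) list(g = rep(1, d), b = rep(0, d))
att_params <- function(d) list(Wq = rmat(d, d), bq = numeric(d),
                               Wk = rmat(d, d), bk = numeric(d),
                               Wv = rmat(d, d), bv = numeric(d),
                               Wo = rmat(d, d), bo = numeric(d))
ffn_params <- function(d, f) list(W1 = rmat(d, f), b1 = numeric(f),
                                  W2 = rmat(f, d), b2 = numeric(d))

#' Initialize lifting-network parameters
#'
#' @param cfg a \code{lift_config}.
#' @param seed integer seed for the Gaussian initialization.
#' @return nested parameter list (embeddings, cross layers, encoder layers,
#'   output head), leaves are numeric matrices/vectors.
#' @export
init_lift_params <- function(cfg, seed = 1) {
  d <- cfg$hidden; f <- cfg$ffn_mult * d
  with_rng(seed, {
    p <- list(
      embed = list(Wp = rmat(2, d), bp = numeric(d), pos_j = rmat(133, d),
                   Wb = rmat(3, d), bb = numeric(d), pos_b = rmat(132, d)),
      cross = lapply(seq_len(cfg$cross_layers), function(i)
        list(lnj = ln_params(d), lnb = ln_params(d),
             att_jb = att_params(d), att_bj = att_params(d),
             lnj2 = ln_params(d), ffn_j = ffn_params(d, f),
             lnb2 = ln_params(d), ffn_b = ffn_params(d, f))),
      enc = lapply(seq_len(cfg$depth), function(i)
        list(ln1 = ln_params(d), att = att_params(d),
             ln2 = ln_params(d), ffn = ffn_params(d, f))),
      head = list(ln = ln_params(d), Wh = rmat(d, 3), bh = numeric(3)))
    if (cfg$multi_hypothesis)
      p$head2 <- list(ln = ln_params(d), Wh = rmat(d, 3), bh = numeric(3))
    p
  })
}

#' Analytic parameter count
#'
#' Number of trainable scalars as a closed-form function of the model
#' configuration; asserted against the instantiated parameters in the test
#' suite.
#'
#' @param cfg a \code{lift_config}.
#' @return integer.
#' @export
count_lift_params <- function(cfg) {
  d <- cfg$hidden; f <- cfg$ffn_mult * d
  embed <- (2 * d + d) + 133 * d + (3 * d + d) + 132 * d
  att <- 4 * (d * d + d)
  ffn <- d * f + f + f * d + d
  ln <- 2 * d
  cross <- cfg$cross_layers * (4 * ln + 2 * att + 2 * ffn)
  enc <- cfg$depth * (2 * ln + att + ffn)
  head <- ln + d * 3 + 3
  n <- embed + cross + enc + head
  if (cfg$multi_hypothesis) n <- n + head
  as.integer(n)
}

# ---- layer primitives (forward + backward) -------------------------------

lin_fwd <- function(X, W, b) X %*% W + rep(b, each = nrow(X))

ln_fwd <- function(X, p) .ln_fwd(X, p$g, p$b)

ln_bwd <- function(dY, cache, p) {
  r <- .ln_bwd(dY, cache$xh, cache$inv, p$g)
  list(dX = r$dX, grad = list(g = drop(r$g), b = drop(r$b)))
}

# pure-R layer-norm reference used to cross-check the compiled kernel
ln_fwd_ref <- function(X, p) {
  n <- nrow(X); d <- ncol(X)
  mu <- .rowMeans(X, n, d)
  xc <- X - mu
  inv <- 1 / sqrt(.rowMeans(xc * xc, n, d) + 1e-5)
  xh <- xc * inv
  list(Y = xh * rep(p$g, each = n) + rep(p$b, each = n),
       xh = xh, inv = inv)
}

ffn_fwd <- function(X, p) {
  n <- nrow(X)
  A <- X %*% p$W1 + rep(p$b1, each = n)
  H <- pmax(A, 0)
  list(Y = H %*% p$W2 + rep(p$b2, each = n), X = X, H = H)
}

ffn_bwd <- function(dY, cache, p) {
  dH <- dY %*% t(p$W2)
  dH[cache$H <= 0] <- 0
  list(dX = dH %*% t(p$W1),
       grad = list(W1 = crossprod(cache$X, dH), b1 = colSums(dH),
                   W2 = crossprod(cache$H, dY), b2 = colSums(dY)))
}

att_fwd <- function(Xq, Xkv, p, B, Tq, Tk, h) {
  Q <- lin_fwd(Xq, p$Wq, p$bq)
  K <- lin_fwd(Xkv, p$Wk, p$bk)
  V <- lin_fwd(Xkv, p$Wv, p$bv)
  core <- .att_core_fwd(Q, K, V, B, Tq, Tk, h)
  list(Y = lin_fwd(core$O, p$Wo, p$bo),
       Q = Q, K = K, V = V, O = core$O, A = core$A, Xq = Xq, Xkv = Xkv)
}

att_bwd <- function(dY, cache, p, B, Tq, Tk, h) {
  dO <- tcrossprod(dY, p$Wo)
  core <- .att_core_bwd(dO, cache$A, cache$Q, cache$K, cache$V, B, Tq, Tk, h)
  list(dXq = tcrossprod(core$dQ, p$Wq),
       dXkv = tcrossprod(core$dK, p$Wk) + tcrossprod(core$dV, p$Wv),
       grad = list(Wq = crossprod(cache$Xq, core$dQ), bq = .colSums(core$dQ, nrow(core$dQ), ncol(core$dQ)),
                   Wk = crossprod(cache$Xkv, core$dK), bk = .colSums(core$dK, nrow(core$dK), ncol(core$dK)),
                   Wv = crossprod(cache$Xkv, core$dV), bv = .colSums(core$dV, nrow(core$dV), ncol(core$dV)),
                   Wo = crossprod(cache$O, dY), bo = .colSums(dY, nrow(dY), ncol(dY))))
}

# pure-R reference implementation of the attention core, used to
# cross-check the compiled kernels in the test suite. A is stored as a
# Tq x (h*Tk) x B cube with head blocks side by side, matching the kernel.
att_core_fwd_ref <- function(Q, K, V, B, Tq, Tk, h) {
  d <- ncol(Q); dh <- d / h; scal <- 1 / sqrt(dh)
  O <- matrix(0, B * Tq, d)
  A <- array(0, c(Tq, Tk * h, B))
  for (b in seq_len(B)) {
    rq <- ((b - 1) * Tq + 1):(b * Tq)
    rk <- ((b - 1) * Tk + 1):(b * Tk)
    for (hh in seq_len(h)) {
      cs <- ((hh - 1) * dh + 1):(hh * dh)
      S <- (Q[rq, cs, drop = FALSE] %*% t(K[rk, cs, drop = FALSE])) * scal
      E <- exp(S - apply(S, 1, max))
      Ab <- E / rowSums(E)
      O[rq, cs] <- Ab %*% V[rk, cs, drop = FALSE]
      A[, ((hh - 1) * Tk + 1):(hh * Tk), b] <- Ab
    }
  }
  list(O = O, A = A)
}

drop_fwd <- function(X, rate, train) {
  if (!train || rate <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix(stats::runif(length(X)) >= rate, nrow(X), ncol(X)) / (1 - rate)
  list(Y = X * mask, mask = mask)
}

drop_bwd <- function(dY, mask) if (is.null(mask)) dY else dY * mask

# ---- full forward / backward --------------------------------------------

lift_forward_core <- function(params, Xj_in, Xb_in, cfg, B, train = FALSE) {
  Tj <- 133L; Tb <- 132L
  cache <- list(Xj_in = Xj_in, Xb_in = Xb_in, B = B)
  Xj <- lin_fwd(Xj_in, params$embed$Wp, params$embed$bp) +
    params$embed$pos_j[rep(seq_len(Tj), B), ]
  Xb <- lin_fwd(Xb_in, params$embed$Wb, params$embed$bb) +
    params$embed$pos_b[rep(seq_len(Tb), B), ]
  cache$cross <- vector("list", cfg$cross_layers)
  for (l in seq_len(cfg$cross_layers)) {
    p <- params$cross[[l]]
    cj <- ln_fwd(Xj, p$lnj); cb <- ln_fwd(Xb, p$lnb)
    ajb <- att_fwd(cj$Y, cb$Y, p$att_jb, B, Tj, Tb, cfg$heads)
    abj <- att_fwd(cb$Y, cj$Y, p$att_bj, B, Tb, Tj, cfg$heads)
    djb <- drop_fwd(ajb$Y, cfg$dropout, train)
    dbj <- drop_fwd(abj$Y, cfg$dropout, train)
    Xj <- Xj + djb$Y
    Xb <- Xb + dbj$Y
    cj2 <- ln_fwd(Xj, p$lnj2); cb2 <- ln_fwd(Xb, p$lnb2)
    fj <- ffn_fwd(cj2$Y, p$ffn_j); fb <- ffn_fwd(cb2$Y, p$ffn_b)
    dfj <- drop_fwd(fj$Y, cfg$dropout, train)
    dfb <- drop_fwd(fb$Y, cfg$dropout, train)
    Xj <- Xj + dfj$Y
    Xb <- Xb + dfb$Y
    cache$cross[[l]] <- list(cj = cj, cb = cb, ajb = ajb, abj = abj,
                             cj2 = cj2, cb2 = cb2, fj = fj, fb = fb,
                             djb = djb$mask, dbj = dbj$mask,
                             dfj = dfj$mask, dfb = dfb$mask)
  }
  cache$Xj_fused <- Xj
  cache$enc <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    p <- params$enc[[l]]
    c1 <- ln_fwd(Xj, p$ln1)
    a <- att_fwd(c1$Y, c1$Y, p$att, B, Tj, Tj, cfg$heads)
    da <- drop_fwd(a$Y, cfg$dropout, train)
    Xj <- Xj + da$Y
    c2 <- ln_fwd(Xj, p$ln2)
    fo <- ffn_fwd(c2$Y, p$ffn)
    df <- drop_fwd(fo$Y, cfg$dropout, train)
    Xj <- Xj + df$Y
    cache$enc[[l]] <- list(c1 = c1, a = a, c2 = c2, fo = fo,
                           da = da$mask, df = df$mask)
  }
  hf <- ln_fwd(Xj, params$head$ln)
  Y <- lin_fwd(hf$Y, params$head$Wh, params$head$bh)
  cache$hf <- hf
  out <- list(Y = Y, cache = cache)
  if (cfg$multi_hypothesis) {
    h2 <- ln_fwd(cache$Xj_fused, params$head2$ln)
    out$Y2 <- lin_fwd(h2$Y, params$head2$Wh, params$head2$bh)
    cache$h2 <- h2
    out$cache <- cache
  }
  out
}

lift_backward_core <- function(dY, fw, params, cfg, dY2 = NULL) {
  cache <- fw$cache
  B <- cache$B; Tj <- 133L; Tb <- 132L
  g <- list()
  hb <- ln_bwd(dY %*% t(params$head$Wh), cache$hf, params$head$ln)
  g$head <- list(ln = hb$grad, Wh = crossprod(cache$hf$Y, dY), bh = colSums(dY))
  dXj <- hb$dX
  dXj_fused_extra <- NULL
  if (!is.null(dY2)) {
    h2b <- ln_bwd(dY2 %*% t(params$head2$Wh), cache$h2, params$head2$ln)
    g$head2 <- list(ln = h2b$grad, Wh = crossprod(cache$h2$Y, dY2),
                    bh = colSums(dY2))
    dXj_fused_extra <- h2b$dX
  }
  g$enc <- vector("list", cfg$depth)
  for (l in rev(seq_len(cfg$depth))) {
    p <- params$enc[[l]]; cc <- cache$enc[[l]]
    dfo <- drop_bwd(dXj, cc$df)
    fb <- ffn_bwd(dfo, cc$fo, p$ffn)
    l2 <- ln_bwd(fb$dX, cc$c2, p$ln2)
    dXj <- dXj + l2$dX
    dA <- drop_bwd(dXj, cc$da)
    ab <- att_bwd(dA, cc$a, p$att, B, Tj, Tj, cfg$heads)
    l1 <- ln_bwd(ab$dXq + ab$dXkv, cc$c1, p$ln1)
    dXj <- dXj + l1$dX
    g$enc[[l]] <- list(ln1 = l1$grad, att = ab$grad, ln2 = l2$grad,
                       ffn = fb$grad)
  }
  if (!is.null(dXj_fused_extra)) dXj <- dXj + dXj_fused_extra
  dXb <- matrix(0, B * Tb, cfg$hidden)
  g$cross <- vector("list", cfg$cross_layers)
  for (l in rev(seq_len(cfg$cross_layers))) {
    p <- params$cross[[l]]; cc <- cache$cross[[l]]
    dfj <- drop_bwd(dXj, cc$dfj)
    fjb <- ffn_bwd(dfj, cc$fj, p$ffn_j)
    lj2 <- ln_bwd(fjb$dX, cc$cj2, p$lnj2)
    dXj <- dXj + lj2$dX
    dfb <- drop_bwd(dXb, cc$dfb)
    fbb <- ffn_bwd(dfb, cc$fb, p$ffn_b)
    lb2 <- ln_bwd(fbb$dX, cc$cb2, p$lnb2)
    dXb <- dXb + lb2$dX
    djb <- drop_bwd(dXj, cc$djb)
    jb <- att_bwd(djb, cc$ajb, p$att_jb, B, Tj, Tb, cfg$heads)
    dbj <- drop_bwd(dXb, cc$dbj)
    bj <- att_bwd(dbj, cc$abj, p$att_bj, B, Tb, Tj, cfg$heads)
    lj <- ln_bwd(jb$dXq + bj$dXkv, cc$cj, p$lnj)
    lb <- ln_bwd(jb$dXkv + bj$dXq, cc$cb, p$lnb)
    dXj <- dXj + lj$dX
    dXb <- dXb + lb$dX
    g$cross[[l]] <- list(lnj = lj$grad, lnb = lb$grad, att_jb = jb$grad,
                         att_bj = bj$grad, lnj2 = lj2$grad, ffn_j = fjb$grad,
                         lnb2 = lb2$grad, ffn_b = fbb$grad)
  }
  g$embed <- list(
    Wp = crossprod(cache$Xj_in, dXj), bp = colSums(dXj),
    pos_j = rowsum(dXj, rep(seq_len(Tj), B)),
    Wb = crossprod(cache$Xb_in, dXb), bb = colSums(dXb),
    pos_b = rowsum(dXb, rep(seq_len(Tb), B)))
  g
}

# ---- parameter-tree utilities and AdamW ----------------------------------

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    nm <- names(a)
    names(out) <- nm
    for (i in seq_along(a)) {
      bi <- if (is.null(nm) || nm[i] == "") b[[i]] else b[[nm[i]]]
      out[[i]] <- tree_map2(f, a[[i]], bi)
    }
    out
  } else f(a, b)
}

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map(f, a[[i]])
    out
  } else f(a)
}

tree_flatten <- function(a) {
  if (is.list(a)) unlist(lapply(a, tree_flatten), use.names = FALSE)
  else as.numeric(a)
}

adamw_init <- function(params) list(m = tree_map(function(x) x * 0, params),
                                    v = tree_map(function(x) x * 0, params),
                                    t = 0L)

adamw_step <- function(params, grads, state, lr, wd = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  c1 <- 1 / (1 - beta1^state$t)
  c2 <- 1 / (1 - beta2^state$t)
  upd <- tree_map2(function(m, v) (m * c1) / (sqrt(v * c2) + eps),
                   state$m, state$v)
  params <- tree_map2(function(p, u) p - lr * u - lr * wd * p, params, upd)
  list(params = params, state = state)
}

# learning rate at epoch e (1-based)
lr_at_epoch <- function(tcfg, e) {
  lr <- tcfg$lr
  if (tcfg$cosine && tcfg$epochs > 1)
    lr <- lr * 0.5 * (1 + cos(pi * (e - 1) / tcfg$epochs))
  lr * 0.1^sum(e >= tcfg$lr_drop_epochs)
}
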