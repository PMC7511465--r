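#' @useDynLib mvseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Compact 2D U-Net engine. Batches are column-major (H, W, C, B) arrays,
# weights (k, k, Cin, Cout). All forward/backward kernels live in src/;
# this file wires them into the encoder-decoder topology, the loss, and Adam.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Numerically stable binary cross-entropy on logits; returns mean loss and
# the gradient with respect to the logits.
bce_with_logits <- function(logits, target, with_grad = TRUE) {
  n <- length(logits)
  loss <- sum(pmax(logits, 0) - logits * target + log1p(exp(-abs(logits)))) / n
  if (!with_grad) return(list(loss = loss))
  list(loss = loss, dlogits = (sigmoid(logits) - target) / n)
}

unet_channels <- function(depth, base_filters) base_filters * 2^(seq_len(depth + 1) - 1)

# He-normal initialization, deterministic given cfg$seed.
unet_init <- function(cfg) {
  stopifnot(cfg$depth >= 1, cfg$base_filters >= 1)
  ch <- unet_channels(cfg$depth, cfg$base_filters)
  w <- list()
  mk <- function(k, cin, cout) {
    array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
          c(k, k, cin, cout))
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$seed)
  cin <- 1L
  for (l in seq_len(cfg$depth)) {
    w[[paste0("enc", l, "_c1_w")]] <- mk(3, cin, ch[l])
    w[[paste0("enc", l, "_c1_b")]] <- numeric(ch[l])
    w[[paste0("enc", l, "_c2_w")]] <- mk(3, ch[l], ch[l])
    w[[paste0("enc", l, "_c2_b")]] <- numeric(ch[l])
    cin <- ch[l]
  }
  bot <- ch[cfg$depth + 1]
  w[["bot_c1_w"]] <- mk(3, cin, bot); w[["bot_c1_b"]] <- numeric(bot)
  w[["bot_c2_w"]] <- mk(3, bot, bot); w[["bot_c2_b"]] <- numeric(bot)
  above <- bot
  for (l in rev(seq_len(cfg$depth))) {
    w[[paste0("dec", l, "_up_w")]] <- mk(3, above, ch[l])
    w[[paste0("dec", l, "_up_b")]] <- numeric(ch[l])
    w[[paste0("dec", l, "_c1_w")]] <- mk(3, 2 * ch[l], ch[l])
    w[[paste0("dec", l, "_c1_b")]] <- numeric(ch[l])
    w[[paste0("dec", l, "_c2_w")]] <- mk(3, ch[l], ch[l])
    w[[paste0("dec", l, "_c2_b")]] <- numeric(ch[l])
    above <- ch[l]
  }
  w[["head_w"]] <- mk(1, ch[1], 1L)
  w[["head_b"]] <- numeric(1)
  w
}

# Forward pass; when training = TRUE a cache of every conv input and output
# (for the ReLU mask) plus pooling argmax indices is kept for the backward pass.
unet_forward <- function(w, x, depth, training = FALSE) {
  cache <- if (training) list(inputs = list(), outputs = list(), pool = list()) else NULL
  conv_block <- function(x, name) {
    for (tag in c("_c1", "_c2")) {
      key <- paste0(name, tag)
      if (training) cache$inputs[[key]] <<- x
      x <- relu(cpp_conv2d_fwd(x, w[[paste0(key, "_w")]], w[[paste0(key, "_b")]]))
      if (training) cache$outputs[[key]] <<- x
    }
    x
  }
  skips <- list()
  for (l in seq_len(depth)) {
    x <- conv_block(x, paste0("enc", l))
    skips[[l]] <- x
    p <- cpp_maxpool2_fwd(x)
    if (training) cache$pool[[l]] <- list(idx = p$idx, xdim = dim(x))
    x <- p$y
  }
  x <- conv_block(x, "bot")
  for (l in rev(seq_len(depth))) {
    x <- cpp_upsample2_fwd(x)
    key <- paste0("dec", l, "_up")
    if (training) cache$inputs[[key]] <- x
    x <- relu(cpp_conv2d_fwd(x, w[[paste0(key, "_w")]], w[[paste0(key, "_b")]]))
    if (training) cache$outputs[[key]] <- x
    x <- concat_ch(x, skips[[l]])
    x <- conv_block(x, paste0("dec", l))
  }
  if (training) cache$inputs[["head"]] <- x
  logits <- cpp_conv2d_fwd(x, w[["head_w"]], w[["head_b"]])
  list(logits = logits, cache = cache)
}

# Backward pass: returns gradient list with the same names/shapes as weights.
unet_backward <- function(w, cache, dlogits, depth) {
  g <- list()
  conv_bwd <- function(key, dy) {
    dy <- dy * (cache$outputs[[key]] > 0)   # ReLU mask
    r <- cpp_conv2d_bwd(cache$inputs[[key]], w[[paste0(key, "_w")]], dy)
    g[[paste0(key, "_w")]] <<- r$dw
    g[[paste0(key, "_b")]] <<- r$db
    r$dx
  }
  r <- cpp_conv2d_bwd(cache$inputs[["head"]], w[["head_w"]], dlogits)
  g[["head_w"]] <- r$dw; g[["head_b"]] <- r$db
  dx <- r$dx
  dskip <- list()
  for (l in seq_len(depth)) {
    dx <- conv_bwd(paste0("dec", l, "_c2"), dx)
    dx <- conv_bwd(paste0("dec", l, "_c1"), dx)
    nch <- dim(dx)[3] / 2
    dskip[[l]] <- dx[, , nch + seq_len(nch), , drop = FALSE]
    dx <- dx[, , seq_len(nch), , drop = FALSE]
    dx <- conv_bwd(paste0("dec", l, "_up"), dx)
    dx <- cpp_upsample2_bwd(dx)
  }
  dx <- conv_bwd("bot_c2", dx)
  dx <- conv_bwd("bot_c1", dx)
  for (l in rev(seq_len(depth))) {
    p <- cache$pool[[l]]
    dx <- cpp_maxpool2_bwd(p$idx, dx, p$xdim)
    dx <- dx + dskip[[l]]
    dx <- conv_bwd(paste0("enc", l, "_c2"), dx)
    dx <- conv_bwd(paste0("enc", l, "_c1"), dx)
  }
  g
}

adam_init <- function(w) {
  list(m = lapply(w, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p))),
       v = lapply(w, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p))),
       t = 0L)
}

adam_step <- function(w, g, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(w)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    w[[nm]] <- w[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(w = w, state = state)
}
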