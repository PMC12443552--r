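# Internal layer primitives for the 3D encoder-decoder.
#
# Feature maps are numeric arrays dim (d1,d2,d3,C).  Each encoder level is
# conv(k3,same) -> instance norm -> ReLU -> strided conv(k2,s2) -> ReLU,
# channels doubling per level; the decoder mirrors with transposed-conv
# upsampling and ends in a linear k3 output head.  Fusion happens between
# encoder and decoder at the bottleneck.  Backprop is written out layer by
# layer; the convolution GEMMs live in src/nnops.cpp.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

.relu <- function(x) cpp_relu_fwd(x)

.reluBwd <- function(dy, xPre) cpp_relu_bwd(dy, xPre)

.INORM_EPS <- 1e-5

# instance norm over the spatial axes of each channel; returns cache for bwd
.inormFwd <- function(x, g, b) {
  d <- .dims4(x)
  out <- cpp_inorm_fwd(x, d, g, b, .INORM_EPS)
  list(y = out$y, xhat = out$xhat, inv = out$inv, dims = d)
}

.inormBwd <- function(dy, cache, g) {
  out <- cpp_inorm_bwd(dy, cache$xhat, cache$inv, g, cache$dims)
  list(dx = out$dx, dg = out$dg, db = out$db)
}

.heInit <- function(nrowW, ncolW, fanIn) {
  matrix(rnorm(nrowW * ncolW, sd = sqrt(2 / fanIn)), nrowW, ncolW)
}

.encChannels <- function(cfg) cfg@baseChannels * 2^(seq_len(cfg@levels) - 1)
.latentChannels <- function(cfg) cfg@baseChannels * 2^cfg@levels

# one encoder's parameters as a flat named list of arrays
.initEncoderParams <- function(cin, cfg) {
  ch <- .encChannels(cfg); L <- cfg@levels
  p <- list()
  for (l in seq_len(L)) {
    ci <- if (l == 1) cin else ch[l]
    p[[sprintf("conv%d.w", l)]] <- .heInit(27 * ci, ch[l], 27 * ci)
    p[[sprintf("conv%d.b", l)]] <- numeric(ch[l])
    if (cfg@norm == "instance") {
      p[[sprintf("in%d.g", l)]] <- rep(1, ch[l])
      p[[sprintf("in%d.b", l)]] <- numeric(ch[l])
    }
    cn <- if (l == L) .latentChannels(cfg) else ch[l + 1]
    p[[sprintf("down%d.w", l)]] <- .heInit(8 * ch[l], cn, 8 * ch[l])
    p[[sprintf("down%d.b", l)]] <- numeric(cn)
  }
  p
}

.initDecoderParams <- function(cfg) {
  ch <- .encChannels(cfg); L <- cfg@levels
  p <- list()
  for (l in rev(seq_len(L))) {
    ci <- if (l == L) .latentChannels(cfg) else ch[l + 1]
    p[[sprintf("up%d.w", l)]] <- .heInit(ci, 8 * ch[l], 8 * ci)
    p[[sprintf("up%d.b", l)]] <- numeric(ch[l])
    if (l > 1) {
      p[[sprintf("dconv%d.w", l)]] <- .heInit(27 * ch[l], ch[l], 27 * ch[l])
      p[[sprintf("dconv%d.b", l)]] <- numeric(ch[l])
      if (cfg@norm == "instance") {
        p[[sprintf("din%d.g", l)]] <- rep(1, ch[l])
        p[[sprintf("din%d.b", l)]] <- numeric(ch[l])
      }
    }
  }
  # linear 1x1 output head over the first-stage channels
  p[["out.w"]] <- .heInit(ch[1], 1, ch[1])
  p[["out.b"]] <- numeric(1)
  p
}

.dims4 <- function(x) {
  d <- dim(x)
  as.integer(d)
}

.encFwd <- function(p, x, cfg, keepCache = FALSE) {
  L <- cfg@levels
  cache <- if (keepCache) list() else NULL
  h <- x
  for (l in seq_len(L)) {
    cin <- h
    h <- cpp_conv3_fwd(cin, .dims4(cin), p[[sprintf("conv%d.w", l)]],
                       p[[sprintf("conv%d.b", l)]])
    if (cfg@norm == "instance") {
      nf <- .inormFwd(h, p[[sprintf("in%d.g", l)]], p[[sprintf("in%d.b", l)]])
      if (keepCache) cache[[sprintf("in%d", l)]] <- nf[c("xhat", "inv", "dims")]
      h <- nf$y
    }
    hPre <- h
    h <- .relu(h)
    din <- h
    h <- cpp_down2_fwd(din, .dims4(din), p[[sprintf("down%d.w", l)]],
                       p[[sprintf("down%d.b", l)]])
    dPre <- h
    h <- .relu(h)
    if (keepCache) {
      cache[[sprintf("conv%d.x", l)]] <- cin
      cache[[sprintf("relu%d.pre", l)]] <- hPre
      cache[[sprintf("down%d.x", l)]] <- din
      cache[[sprintf("downrelu%d.pre", l)]] <- dPre
    }
  }
  list(latent = h, cache = cache)
}

.encBwd <- function(p, cache, dLatent, cfg) {
  L <- cfg@levels
  g <- list()
  dh <- dLatent
  for (l in rev(seq_len(L))) {
    dh <- .reluBwd(dh, cache[[sprintf("downrelu%d.pre", l)]])
    din <- cache[[sprintf("down%d.x", l)]]
    bw <- cpp_down2_bwd(din, .dims4(din), p[[sprintf("down%d.w", l)]], dh)
    g[[sprintf("down%d.w", l)]] <- bw$dw
    g[[sprintf("down%d.b", l)]] <- bw$db
    dh <- .reluBwd(bw$dx, cache[[sprintf("relu%d.pre", l)]])
    if (cfg@norm == "instance") {
      nb <- .inormBwd(dh, cache[[sprintf("in%d", l)]],
                      p[[sprintf("in%d.g", l)]])
      g[[sprintf("in%d.g", l)]] <- nb$dg
      g[[sprintf("in%d.b", l)]] <- nb$db
      dh <- nb$dx
    }
    cin <- cache[[sprintf("conv%d.x", l)]]
    # the first conv consumes raw image data; its input gradient is unused
    cb <- cpp_conv3_bwd(cin, .dims4(cin), p[[sprintf("conv%d.w", l)]], dh,
                        need_dx = (l > 1L))
    g[[sprintf("conv%d.w", l)]] <- cb$dw
    g[[sprintf("conv%d.b", l)]] <- cb$db
    dh <- cb$dx
  }
  list(grads = g, dx = dh)
}

.decFwd <- function(p, z, cfg, keepCache = FALSE) {
  L <- cfg@levels
  cache <- if (keepCache) list() else NULL
  h <- z
  for (l in rev(seq_len(L))) {
    uin <- h
    h <- cpp_up2_fwd(uin, .dims4(uin), p[[sprintf("up%d.w", l)]],
                     p[[sprintf("up%d.b", l)]])
    if (keepCache) cache[[sprintf("up%d.x", l)]] <- uin
    if (l > 1) {
      cin <- h
      h <- cpp_conv3_fwd(cin, .dims4(cin), p[[sprintf("dconv%d.w", l)]],
                         p[[sprintf("dconv%d.b", l)]])
      if (cfg@norm == "instance") {
        nf <- .inormFwd(h, p[[sprintf("din%d.g", l)]],
                        p[[sprintf("din%d.b", l)]])
        if (keepCache)
          cache[[sprintf("din%d", l)]] <- nf[c("xhat", "inv", "dims")]
        h <- nf$y
      }
      hPre <- h
      h <- .relu(h)
      if (keepCache) {
        cache[[sprintf("dconv%d.x", l)]] <- cin
        cache[[sprintf("drelu%d.pre", l)]] <- hPre
      }
    } else {
      hPre <- h
      h <- .relu(h)
      oin <- h
      d <- dim(oin)
      y <- matrix(oin, prod(d[1:3]), d[4]) %*% p[["out.w"]] + p[["out.b"]]
      h <- array(y, c(d[1:3], 1L))
      if (keepCache) {
        cache[["urelu1.pre"]] <- hPre
        cache[["out.x"]] <- oin
      }
    }
  }
  list(y = h, cache = cache)
}

.decBwd <- function(p, cache, dy, cfg) {
  L <- cfg@levels
  g <- list()
  oin <- cache[["out.x"]]
  dox <- dim(oin)
  Xm <- matrix(oin, prod(dox[1:3]), dox[4])
  dyv <- matrix(dy, prod(dox[1:3]), 1L)
  g[["out.w"]] <- crossprod(Xm, dyv)
  g[["out.b"]] <- sum(dyv)
  dh <- array(dyv %*% t(p[["out.w"]]), dox)
  dh <- .reluBwd(dh, cache[["urelu1.pre"]])
  for (l in seq_len(L)) {
    if (l > 1) {
      dh <- .reluBwd(dh, cache[[sprintf("drelu%d.pre", l)]])
      if (cfg@norm == "instance") {
        nb <- .inormBwd(dh, cache[[sprintf("din%d", l)]],
                        p[[sprintf("din%d.g", l)]])
        g[[sprintf("din%d.g", l)]] <- nb$dg
        g[[sprintf("din%d.b", l)]] <- nb$db
        dh <- nb$dx
      }
      cin <- cache[[sprintf("dconv%d.x", l)]]
      cb <- cpp_conv3_bwd(cin, .dims4(cin), p[[sprintf("dconv%d.w", l)]], dh)
      g[[sprintf("dconv%d.w", l)]] <- cb$dw
      g[[sprintf("dconv%d.b", l)]] <- cb$db
      dh <- cb$dx
    }
    uin <- cache[[sprintf("up%d.x", l)]]
    ub <- cpp_up2_bwd(uin, .dims4(uin), p[[sprintf("up%d.w", l)]], dh)
    g[[sprintf("up%d.w", l)]] <- ub$dw
    g[[sprintf("up%d.b", l)]] <- ub$db
    dh <- ub$dx
  }
  list(grads = g, dx = dh)
}

# ---------------------------------------------------------------------------
# Adam (one state entry per parameter tensor; sparsely updated parameters
# keep their own step counter so bias correction stays exact)

.adamInit <- function() new.env(parent = emptyenv())

.adamStep <- function(state, key, param, grad, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  s <- state[[key]]
  if (is.null(s)) s <- list(m = param * 0, v = param * 0, t = 0L)
  s$t <- s$t + 1L
  s$m <- beta1 * s$m + (1 - beta1) * grad
  s$v <- beta2 * s$v + (1 - beta2) * grad * grad
  mh <- s$m / (1 - beta1^s$t)
  vh <- s$v / (1 - beta2^s$t)
  state[[key]] <- s
  param - lr * mh / (sqrt(vh) + eps)
}

.applyAdam <- function(state, prefix, params, grads, lr) {
  for (nm in names(grads)) {
    params[[nm]] <- .adamStep(state, paste0(prefix, ".", nm),
                              params[[nm]], grads[[nm]], lr)
  }
  params
}

# gradient accumulation helper
.addGrads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else
    a[[nm]] + b[[nm]]
  a
}
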