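# The full ASYM network: front-end projection, cross-modal interactive
# Bi-Mamba stage with shared state-transition dynamics, bidirectional
# cross-modal attention, dual-path fusion (temporal feature pyramid +
# sigmoid-gated dynamic fusion), and the Mamba-based enhancement head with
# a linear classifier.
#
# The forward pass returns a cache sufficient for an exact hand-derived
# backward pass; gradients accumulate into a named environment so that
# aliased (shared) parameters receive contributions from every path that
# touches them.

cfg_dt_rank <- function(cfg, width) {
  if (!is.null(cfg$dt_rank)) cfg$dt_rank else max(1L, width %/% 16L)
}

has_audio <- function(cfg) cfg$modality %in% c("both", "audio")
has_video <- function(cfg) cfg$modality %in% c("both", "video")
is_bimodal <- function(cfg) identical(cfg$modality, "both")

#' Instantiate an ASYM model
#'
#' @param cfg Configuration from [load_config()].
#' @param f_audio Number of audio feature channels (e.g. 25 eGeMAPS
#'   descriptors). Ignored when `modality = "video"`.
#' @param f_video Number of visual feature channels (e.g. 136 facial
#'   landmark coordinates). Ignored when `modality = "audio"`.
#' @param seed Integer seed for parameter initialization; defaults to
#'   `cfg$seed`.
#' @return An object of class `asym_model`.
#' @export
asym_model <- function(cfg, f_audio = NULL, f_video = NULL, seed = NULL) {
  if (!inherits(cfg, "asym_config")) cfg <- do.call(load_config, list(overrides = cfg))
  if (is.null(seed)) seed <- cfg$seed
  set.seed(seed)
  D <- cfg$d_model
  if (cfg$fusion == "concat" && !is_bimodal(cfg)) {
    stop("plain-concatenation fusion requires both modalities")
  }
  P <- new_store()
  S <- new.env(parent = emptyenv())   # BN running statistics
  blocks <- list()

  if (has_audio(cfg)) {
    stopifnot(!is.null(f_audio))
    p_set(P, "front.audio.W", glorot(f_audio, D))
    p_set(P, "front.audio.b", numeric(D))
  }
  if (has_video(cfg)) {
    stopifnot(!is.null(f_video))
    p_set(P, "front.video.W", glorot(f_video, D))
    p_set(P, "front.video.b", numeric(D))
  }

  bcfg <- bimamba_config(D, cfg$state_dim, cfg$conv_kernel,
                         static_ssm = cfg$static_ssm,
                         dt_rank = cfg_dt_rank(cfg, D),
                         bidirectional = cfg$bidirectional)
  for (i in seq_len(cfg$n_blocks)) {
    shared <- if (is_bimodal(cfg)) sprintf("co.sh%d", i) else NULL
    if (has_audio(cfg)) {
      blocks[[sprintf("co.a.b%d", i)]] <-
        bimamba_init(bcfg, store = P, prefix = sprintf("co.a.b%d", i),
                     shared_prefix = shared)
    }
    if (has_video(cfg)) {
      blocks[[sprintf("co.v.b%d", i)]] <-
        bimamba_init(bcfg, store = P, prefix = sprintf("co.v.b%d", i),
                     shared_prefix = shared)
    }
  }

  use_cma <- cfg$cma && is_bimodal(cfg)
  if (use_cma) {
    da <- cfg$d_attn
    p_set(P, "att.Wq", glorot(D, da)); p_set(P, "att.bq", numeric(da))
    p_set(P, "att.Wk", glorot(D, da)); p_set(P, "att.bk", numeric(da))
    p_set(P, "att.Wv", glorot(D, da)); p_set(P, "att.bv", numeric(da))
    p_set(P, "att.Wo", glorot(da, D)); p_set(P, "att.bo", numeric(D))
    for (m in c("audio", "video")) {
      if (cfg$merge == "concat_project") {
        p_set(P, sprintf("mrg.%s.W", m), glorot(2L * D, D))
        p_set(P, sprintf("mrg.%s.b", m), numeric(D))
      }
      p_set(P, sprintf("mrg.%s.ln.g", m), rep(1, D))
      p_set(P, sprintf("mrg.%s.ln.b", m), numeric(D))
    }
  }

  use_fpn <- cfg$fusion %in% c("dual", "fpn_only") || !is_bimodal(cfg)
  use_gd <- cfg$fusion %in% c("dual", "gd_only") && is_bimodal(cfg)
  if (use_fpn) {
    mods <- c(if (has_audio(cfg)) "audio", if (has_video(cfg)) "video")
    for (m in mods) {
      for (l in 1:3) {
        p_set(P, sprintf("fpn.%s.l%d.convw", m, l),
              matrix(stats::runif(D * cfg$fpn_kernel, -1, 1) / sqrt(cfg$fpn_kernel),
                     D, cfg$fpn_kernel))
        p_set(P, sprintf("fpn.%s.l%d.convb", m, l), numeric(D))
      }
      p_set(P, sprintf("fpn.%s.l1.bn.g", m), rep(1, D))
      p_set(P, sprintf("fpn.%s.l1.bn.b", m), numeric(D))
    }
    c_lvl <- if (is_bimodal(cfg)) 2L * D else D
    p_set(P, "fpn.lvl.W", glorot(c_lvl, cfg$d_level))
    p_set(P, "fpn.lvl.b", numeric(cfg$d_level))
    p_set(P, "fpn.out.W", glorot(3L * cfg$d_level, D))
    p_set(P, "fpn.out.b", numeric(D))
  }
  if (use_gd) {
    p_set(P, "gate.W", glorot(2L * D, D))
    p_set(P, "gate.b", numeric(D))
  }

  c_fuse <- if (!is_bimodal(cfg)) 2L * D
            else switch(cfg$fusion, dual = 2L * D, fpn_only = D,
                        gd_only = D, concat = 2L * D)
  p_set(P, "fuse.W", glorot(c_fuse, cfg$d_head))
  p_set(P, "fuse.b", numeric(cfg$d_head))

  if (cfg$enhance) {
    dh <- cfg$d_head
    for (cc in c("c1", "c2")) {
      p_set(P, sprintf("res.%s.w", cc), matrix(stats::runif(dh * 3L, -1, 1) / sqrt(3), dh, 3L))
      p_set(P, sprintf("res.%s.b", cc), numeric(dh))
    }
    for (bb in c("bn1", "bn2")) {
      p_set(P, sprintf("res.%s.g", bb), rep(1, dh))
      p_set(P, sprintf("res.%s.b", bb), numeric(dh))
    }
    hcfg <- bimamba_config(dh, cfg$state_dim, cfg$conv_kernel,
                           static_ssm = cfg$static_ssm,
                           dt_rank = cfg_dt_rank(cfg, dh),
                           bidirectional = cfg$bidirectional)
    for (i in seq_len(cfg$n_blocks)) {
      blocks[[sprintf("hd.b%d", i)]] <-
        bimamba_init(hcfg, store = P, prefix = sprintf("hd.b%d", i))
    }
  }
  p_set(P, "cls.w", stats::rnorm(cfg$d_head, sd = 1 / sqrt(cfg$d_head)))
  p_set(P, "cls.b", 0)

  structure(list(cfg = cfg, P = P, S = S, blocks = blocks,
                 f_audio = f_audio, f_video = f_video, seed = seed,
                 use_cma = use_cma, use_fpn = use_fpn, use_gd = use_gd),
            class = "asym_model")
}

#' @export
print.asym_model <- function(x, ...) {
  np <- asym_num_params(x)
  cat(sprintf("<asym_model> profile=%s modality=%s fusion=%s D=%d params=%s\n",
              x$cfg$profile, x$cfg$modality, x$cfg$fusion, x$cfg$d_model,
              format(np, big.mark = ",")))
  invisible(x)
}

#' Total trainable parameter count of a model
#' @param model An `asym_model`.
#' @return Integer number of trainable scalars (shared tensors counted once).
#' @export
asym_num_params <- function(model) {
  sum(vapply(ls(model$P), function(n) length(p_get(model$P, n)), integer(1L)))
}

#' Per-submodule parameter census
#' @param model An `asym_model`.
#' @return Named integer vector: parameters per top-level submodule.
#' @export
asym_param_census <- function(model) {
  nms <- ls(model$P)
  grp <- sub("\\..*$", "", nms)
  counts <- vapply(nms, function(n) length(p_get(model$P, n)), integer(1L))
  tapply(counts, grp, sum)
}

# Nearest / linear resampling of an L x D sequence to L_ref rows (used both
# for pyramid upsampling and for aligning unequal-length streams).
resample_f <- function(X, L_ref, mode = "nearest") {
  if (mode == "nearest") {
    c(upsample_f(X, L_ref), list(mode = "nearest"))
  } else {
    L <- nrow(X)
    pos <- (seq_len(L_ref) - 0.5) * L / L_ref + 0.5
    i0 <- pmin(pmax(floor(pos), 1L), L)
    i1 <- pmin(i0 + 1L, L)
    w <- pmin(pmax(pos - i0, 0), 1)
    Y <- X[i0, , drop = FALSE] * (1 - w) + X[i1, , drop = FALSE] * w
    list(out = Y, i0 = i0, i1 = i1, w = w, L_in = L, mode = "linear")
  }
}

resample_b <- function(dY, cache) {
  if (cache$mode == "nearest") return(upsample_b(dY, cache))
  dX <- matrix(0, cache$L_in, ncol(dY))
  for (t in seq_len(nrow(dY))) {
    dX[cache$i0[t], ] <- dX[cache$i0[t], ] + dY[t, ] * (1 - cache$w[t])
    dX[cache$i1[t], ] <- dX[cache$i1[t], ] + dY[t, ] * cache$w[t]
  }
  dX
}

# ---- pyramid ---------------------------------------------------------------

# Level 1: conv(k, stride 1, same padding) -> BN -> dropout.
# Levels 2-3: conv(k, same) -> max-pool(2, 2). A level whose input has a
# single time step is omitted with a warning and replaced downstream by
# zeros at the reference length.
fpn_pyramid_f <- function(X, P, S, m, cfg, training) {
  key <- function(l, s) sprintf("fpn.%s.l%d.%s", m, l, s)
  c1 <- dwconv_f(X, p_get(P, key(1L, "convw")), p_get(P, key(1L, "convb")), "same")
  b1 <- bn_f(c1$out, p_get(P, key(1L, "bn.g")), p_get(P, key(1L, "bn.b")),
             S, sprintf("fpn.%s.l1.bn", m), training)
  d1 <- dropout_f(b1$out, cfg$dropout, training)
  lvls <- list(d1$out)
  caches <- list(list(c1 = c1, b1 = b1, d1 = d1))
  for (l in 2:3) {
    prev <- lvls[[l - 1L]]
    if (is.null(prev) || nrow(prev) < 2L) {
      warning(sprintf("pyramid level %d omitted: input length %s < 2", l,
                      if (is.null(prev)) "0" else nrow(prev)))
      lvls[l] <- list(NULL)
      caches[[l]] <- list(skipped = TRUE)
      next
    }
    cv <- dwconv_f(prev, p_get(P, key(l, "convw")), p_get(P, key(l, "convb")), "same")
    mp <- maxpool2_f(cv$out)
    lvls[[l]] <- mp$out
    caches[[l]] <- list(cv = cv, mp = mp)
  }
  list(levels = lvls, caches = caches)
}

fpn_pyramid_b <- function(dlvls, pyr, P, m, G) {
  key <- function(l, s) sprintf("fpn.%s.l%d.%s", m, l, s)
  dprev <- NULL
  for (l in 3:2) {
    cc <- pyr$caches[[l]]
    if (isTRUE(cc$skipped)) next
    dl <- dlvls[[l]]
    if (!is.null(dprev)) dl <- dl + 0  # levels feed forward only via pooling
    dcv <- maxpool2_b(dl, cc$mp)
    cb <- dwconv_b(dcv, cc$cv, p_get(P, key(l, "convw")))
    g_add(G, key(l, "convw"), cb$dw); g_add(G, key(l, "convb"), cb$db)
    dlvls[[l - 1L]] <- dlvls[[l - 1L]] + cb$dX
  }
  cc <- pyr$caches[[1L]]
  dd <- dropout_b(dlvls[[1L]], cc$d1)
  bb <- bn_b(dd, cc$b1, p_get(P, key(1L, "bn.g")))
  g_add(G, key(1L, "bn.g"), bb$dg); g_add(G, key(1L, "bn.b"), bb$db)
  cb <- dwconv_b(bb$dX, cc$c1, p_get(P, key(1L, "convw")))
  g_add(G, key(1L, "convw"), cb$dw); g_add(G, key(1L, "convb"), cb$db)
  cb$dX
}

# ---- full forward ----------------------------------------------------------

asym_forward_cache <- function(model, audio = NULL, video = NULL,
                               training = FALSE) {
  cfg <- model$cfg; P <- model$P; S <- model$S
  cache <- list()

  run_modality <- function(x, m) {
    fr <- lin_f(x, p_get(P, sprintf("front.%s.W", m)),
                p_get(P, sprintf("front.%s.b", m)))
    h <- fr$out
    bl <- list()
    pfx <- if (m == "audio") "co.a" else "co.v"
    for (i in seq_len(cfg$n_blocks)) {
      bf <- bimamba_f(model$blocks[[sprintf("%s.b%d", pfx, i)]], h, training)
      h <- bf$out
      bl[[i]] <- bf$cache
    }
    list(out = h, fr = fr, bl = bl)
  }

  A <- V <- NULL
  if (has_audio(cfg)) {
    check_finite_seq(audio, "audio input")
    cache$ca <- run_modality(audio, "audio"); A <- cache$ca$out
  }
  if (has_video(cfg)) {
    check_finite_seq(video, "video input")
    cache$cv <- run_modality(video, "video"); V <- cache$cv$out
  }

  attn_maps <- NULL
  if (model$use_cma) {
    proj <- function(X, w, b) lin_f(X, p_get(P, paste0("att.", w)),
                                    p_get(P, paste0("att.", b)))
    cache$qa <- proj(A, "Wq", "bq"); cache$ka <- proj(A, "Wk", "bk")
    cache$va <- proj(A, "Wv", "bv")
    cache$qv <- proj(V, "Wq", "bq"); cache$kv <- proj(V, "Wk", "bk")
    cache$vv <- proj(V, "Wv", "bv")
    cache$m_av <- mha_f(cache$qa$out, cache$kv$out, cache$vv$out, cfg$n_heads)
    cache$m_va <- mha_f(cache$qv$out, cache$ka$out, cache$va$out, cfg$n_heads)
    cache$oa <- lin_f(cache$m_av$out, p_get(P, "att.Wo"), p_get(P, "att.bo"))
    cache$ov <- lin_f(cache$m_va$out, p_get(P, "att.Wo"), p_get(P, "att.bo"))
    mrg <- function(ctx, al, m) {
      if (cfg$merge == "concat_project") {
        lp <- lin_f(cbind(ctx, al), p_get(P, sprintf("mrg.%s.W", m)),
                    p_get(P, sprintf("mrg.%s.b", m)))
        ln <- ln_f(lp$out, p_get(P, sprintf("mrg.%s.ln.g", m)),
                   p_get(P, sprintf("mrg.%s.ln.b", m)))
        list(out = ln$out, lp = lp, ln = ln)
      } else {
        ln <- ln_f(ctx + al, p_get(P, sprintf("mrg.%s.ln.g", m)),
                   p_get(P, sprintf("mrg.%s.ln.b", m)))
        list(out = ln$out, ln = ln)
      }
    }
    cache$ma <- mrg(A, cache$oa$out, "audio"); A <- cache$ma$out
    cache$mv <- mrg(V, cache$ov$out, "video"); V <- cache$mv$out
    attn_maps <- list(audio_to_video = cache$m_av$P,
                      video_to_audio = cache$m_va$P)
  }

  # align stream lengths to the fusion reference length
  if (is_bimodal(cfg)) {
    L_ref <- min(nrow(A), nrow(V))
    if (nrow(A) != L_ref) {
      cache$rsA <- resample_f(A, L_ref, cfg$upsample); A <- cache$rsA$out
    }
    if (nrow(V) != L_ref) {
      cache$rsV <- resample_f(V, L_ref, cfg$upsample); V <- cache$rsV$out
    }
  } else {
    L_ref <- nrow(if (has_audio(cfg)) A else V)
  }
  cache$L_ref <- L_ref
  D <- cfg$d_model

  paths <- list()
  if (model$use_fpn) {
    if (is_bimodal(cfg)) {
      cache$pyrA <- fpn_pyramid_f(A, P, S, "audio", cfg, training)
      cache$pyrV <- fpn_pyramid_f(V, P, S, "video", cfg, training)
      lv_in <- lapply(1:3, function(l) {
        la <- cache$pyrA$levels[[l]]; lv <- cache$pyrV$levels[[l]]
        if (is.null(la) || is.null(lv)) NULL else cbind(la, lv)
      })
    } else {
      X1 <- if (has_audio(cfg)) A else V
      m1 <- if (has_audio(cfg)) "audio" else "video"
      cache$pyrA <- fpn_pyramid_f(X1, P, S, m1, cfg, training)
      lv_in <- cache$pyrA$levels
    }
    cache$lvl <- vector("list", 3L)
    ups <- vector("list", 3L)
    parts <- vector("list", 3L)
    for (l in 1:3) {
      if (is.null(lv_in[[l]])) { parts[[l]] <- matrix(0, L_ref, cfg$d_level); next }
      lf <- lin_f(lv_in[[l]], p_get(P, "fpn.lvl.W"), p_get(P, "fpn.lvl.b"))
      cache$lvl[[l]] <- lf
      if (nrow(lf$out) != L_ref) {
        ups[[l]] <- resample_f(lf$out, L_ref, cfg$upsample)
        parts[[l]] <- ups[[l]]$out
      } else {
        parts[[l]] <- lf$out
      }
    }
    cache$ups <- ups
    cache$fpn_cat <- do.call(cbind, parts)
    cache$fo <- lin_f(cache$fpn_cat, p_get(P, "fpn.out.W"), p_get(P, "fpn.out.b"))
    paths$fpn <- cache$fo$out
  }
  if (model$use_gd) {
    if (cfg$gate_granularity == "channel") {
      pooled <- c(colMeans(A), colMeans(V))
      z <- drop(pooled %*% p_get(P, "gate.W")) + p_get(P, "gate.b")
      gam <- sigmoid(z)
      gm <- matrix(gam, L_ref, D, byrow = TRUE)
    } else {
      Zin <- cbind(A, V)
      z <- sweep(Zin %*% p_get(P, "gate.W"), 2L, p_get(P, "gate.b"), "+")
      gam <- sigmoid(z)
      gm <- gam
      cache$gZin <- Zin
    }
    cache$gate <- list(gam = gam, gm = gm, z = z, A = A, V = V)
    paths$gd <- gm * A + (1 - gm) * V
  }
  if (cfg$fusion == "concat" && is_bimodal(cfg)) paths$plain <- cbind(A, V)
  if (!is_bimodal(cfg)) paths$plain <- if (has_audio(cfg)) A else V
  if (length(paths) == 0L) stop("no fusion path enabled")

  cache$path_names <- names(paths)
  Ffuse <- do.call(cbind, unname(paths))
  cache$fu <- lin_f(Ffuse, p_get(P, "fuse.W"), p_get(P, "fuse.b"))
  H <- cache$fu$out
  cache$A_al <- A; cache$V_al <- V

  if (cfg$enhance) {
    rc1 <- dwconv_f(H, p_get(P, "res.c1.w"), p_get(P, "res.c1.b"), "same")
    rb1 <- bn_f(rc1$out, p_get(P, "res.bn1.g"), p_get(P, "res.bn1.b"), S,
                "res.bn1", training)
    rr1 <- relu_f(rb1$out)
    rc2 <- dwconv_f(rr1$out, p_get(P, "res.c2.w"), p_get(P, "res.c2.b"), "same")
    rb2 <- bn_f(rc2$out, p_get(P, "res.bn2.g"), p_get(P, "res.bn2.b"), S,
                "res.bn2", training)
    rr2 <- relu_f(rb2$out + H)
    cache$res <- list(rc1 = rc1, rb1 = rb1, rr1 = rr1, rc2 = rc2, rb2 = rb2,
                      rr2 = rr2)
    H <- rr2$out
    cache$hd <- list()
    for (i in seq_len(cfg$n_blocks)) {
      bf <- bimamba_f(model$blocks[[sprintf("hd.b%d", i)]], H, training)
      cache$hd[[i]] <- bf$cache
      H <- bf$out
    }
  }
  cache$H <- H

  pooled <- switch(cfg$pool,
                   mean = colMeans(H),
                   max = apply(H, 2L, max),
                   last = H[nrow(H), ])
  if (cfg$pool == "max") cache$maxidx <- apply(H, 2L, which.max)
  cache$pooled <- pooled
  logit <- sum(pooled * p_get(P, "cls.w")) + p_get(P, "cls.b")
  prob <- sigmoid(logit)
  list(logit = logit, prob = prob, label = as.integer(prob >= 0.5),
       attn = attn_maps, cache = cache)
}

asym_backward <- function(model, cache, dlogit, G) {
  cfg <- model$cfg; P <- model$P
  Th <- nrow(cache$H)
  dpooled <- dlogit * p_get(P, "cls.w")
  g_add(G, "cls.w", dlogit * cache$pooled)
  g_add(G, "cls.b", dlogit)
  dH <- switch(cfg$pool,
    mean = matrix(rep(dpooled / Th, each = Th), Th, length(dpooled)),
    max = { M <- matrix(0, Th, length(dpooled))
            M[cbind(cache$maxidx, seq_along(dpooled))] <- dpooled; M },
    last = { M <- matrix(0, Th, length(dpooled))
             M[Th, ] <- dpooled; M })

  if (cfg$enhance) {
    for (i in rev(seq_len(cfg$n_blocks))) {
      dH <- bimamba_b(model$blocks[[sprintf("hd.b%d", i)]], cache$hd[[i]], dH, G)
    }
    rs <- cache$res
    drr2 <- relu_b(dH, rs$rr2)
    dskip <- drr2                               # identity skip
    bb2 <- bn_b(drr2, rs$rb2, p_get(P, "res.bn2.g"))
    g_add(G, "res.bn2.g", bb2$dg); g_add(G, "res.bn2.b", bb2$db)
    cb2 <- dwconv_b(bb2$dX, rs$rc2, p_get(P, "res.c2.w"))
    g_add(G, "res.c2.w", cb2$dw); g_add(G, "res.c2.b", cb2$db)
    drr1 <- relu_b(cb2$dX, rs$rr1)
    bb1 <- bn_b(drr1, rs$rb1, p_get(P, "res.bn1.g"))
    g_add(G, "res.bn1.g", bb1$dg); g_add(G, "res.bn1.b", bb1$db)
    cb1 <- dwconv_b(bb1$dX, rs$rc1, p_get(P, "res.c1.w"))
    g_add(G, "res.c1.w", cb1$dw); g_add(G, "res.c1.b", cb1$db)
    dH <- cb1$dX + dskip
  }

  fb <- lin_b(dH, cache$fu, p_get(P, "fuse.W"))
  g_add(G, "fuse.W", fb$dW); g_add(G, "fuse.b", fb$db)
  dF <- fb$dX
  D <- cfg$d_model; L_ref <- cache$L_ref
  dA <- matrix(0, L_ref, D); dV <- matrix(0, L_ref, D)
  col0 <- 0L
  for (pn in cache$path_names) {
    w <- switch(pn, fpn = D, gd = D,
                plain = if (is_bimodal(cfg)) 2L * D else D)
    dP_ <- dF[, col0 + seq_len(w), drop = FALSE]; col0 <- col0 + w
    if (pn == "fpn") {
      fob <- lin_b(dP_, cache$fo, p_get(P, "fpn.out.W"))
      g_add(G, "fpn.out.W", fob$dW); g_add(G, "fpn.out.b", fob$db)
      dcat <- fob$dX
      dl_audio <- vector("list", 3L); dl_video <- vector("list", 3L)
      for (l in 1:3) {
        dpart <- dcat[, (l - 1L) * cfg$d_level + seq_len(cfg$d_level), drop = FALSE]
        if (is.null(cache$lvl[[l]])) next
        if (!is.null(cache$ups[[l]])) dpart <- resample_b(dpart, cache$ups[[l]])
        lvb <- lin_b(dpart, cache$lvl[[l]], p_get(P, "fpn.lvl.W"))
        g_add(G, "fpn.lvl.W", lvb$dW); g_add(G, "fpn.lvl.b", lvb$db)
        if (is_bimodal(cfg)) {
          dl_audio[[l]] <- lvb$dX[, seq_len(D), drop = FALSE]
          dl_video[[l]] <- lvb$dX[, D + seq_len(D), drop = FALSE]
        } else {
          dl_audio[[l]] <- lvb$dX
        }
      }
      zero_like <- function(tpl) lapply(tpl, function(x)
        if (is.null(x)) NULL else matrix(0, nrow(x), ncol(x)))
      fill0 <- function(dl, tpl) {
        for (l in 1:3) if (is.null(dl[[l]]) && !is.null(tpl[[l]]))
          dl[[l]] <- matrix(0, nrow(tpl[[l]]), ncol(tpl[[l]]))
        dl
      }
      dl_audio <- fill0(dl_audio, cache$pyrA$levels)
      m1 <- if (has_audio(cfg)) "audio" else "video"
      dxa <- fpn_pyramid_b(dl_audio, cache$pyrA, P, m1, G)
      if (is_bimodal(cfg)) {
        dl_video <- fill0(dl_video, cache$pyrV$levels)
        dxv <- fpn_pyramid_b(dl_video, cache$pyrV, P, "video", G)
        dA <- dA + dxa; dV <- dV + dxv
      } else if (has_audio(cfg)) dA <- dA + dxa else dV <- dV + dxa
    } else if (pn == "gd") {
      gt <- cache$gate
      dA <- dA + dP_ * gt$gm
      dV <- dV + dP_ * (1 - gt$gm)
      dgm <- dP_ * (gt$A - gt$V)
      if (cfg$gate_granularity == "channel") {
        dgam <- colSums(dgm)
        dz <- dgam * gt$gam * (1 - gt$gam)
        pooled <- c(colMeans(gt$A), colMeans(gt$V))
        g_add(G, "gate.W", outer(pooled, dz))
        g_add(G, "gate.b", dz)
        dpool <- drop(p_get(P, "gate.W") %*% dz)
        dA <- dA + matrix(rep(dpool[seq_len(D)] / L_ref, each = L_ref), L_ref, D)
        dV <- dV + matrix(rep(dpool[D + seq_len(D)] / L_ref, each = L_ref), L_ref, D)
      } else {
        dz <- dgm * gt$gam * (1 - gt$gam)
        g_add(G, "gate.W", crossprod(cache$gZin, dz))
        g_add(G, "gate.b", colSums(dz))
        dZin <- dz %*% t(p_get(P, "gate.W"))
        dA <- dA + dZin[, seq_len(D), drop = FALSE]
        dV <- dV + dZin[, D + seq_len(D), drop = FALSE]
      }
    } else {  # plain
      if (is_bimodal(cfg)) {
        dA <- dA + dP_[, seq_len(D), drop = FALSE]
        dV <- dV + dP_[, D + seq_len(D), drop = FALSE]
      } else if (has_audio(cfg)) dA <- dA + dP_ else dV <- dV + dP_
    }
  }

  if (!is.null(cache$rsA)) dA <- resample_b(dA, cache$rsA)
  if (!is.null(cache$rsV)) dV <- resample_b(dV, cache$rsV)

  if (model$use_cma) {
    unmrg <- function(dX, mc, m) {
      lnb <- ln_b(dX, mc$ln, p_get(P, sprintf("mrg.%s.ln.g", m)))
      g_add(G, sprintf("mrg.%s.ln.g", m), lnb$dg)
      g_add(G, sprintf("mrg.%s.ln.b", m), lnb$db)
      if (cfg$merge == "concat_project") {
        lb <- lin_b(lnb$dX, mc$lp, p_get(P, sprintf("mrg.%s.W", m)))
        g_add(G, sprintf("mrg.%s.W", m), lb$dW)
        g_add(G, sprintf("mrg.%s.b", m), lb$db)
        Dm <- ncol(lb$dX) %/% 2L
        list(dctx = lb$dX[, seq_len(Dm), drop = FALSE],
             dal = lb$dX[, Dm + seq_len(Dm), drop = FALSE])
      } else {
        list(dctx = lnb$dX, dal = lnb$dX)
      }
    }
    ua <- unmrg(dA, cache$ma, "audio")
    uv <- unmrg(dV, cache$mv, "video")
    dA <- ua$dctx; dV <- uv$dctx
    oab <- lin_b(ua$dal, cache$oa, p_get(P, "att.Wo"))
    ovb <- lin_b(uv$dal, cache$ov, p_get(P, "att.Wo"))
    g_add(G, "att.Wo", oab$dW + ovb$dW)
    g_add(G, "att.bo", oab$db + ovb$db)
    mb_av <- mha_b(oab$dX, cache$m_av)
    mb_va <- mha_b(ovb$dX, cache$m_va)
    accp <- function(dX, pc, w, b) {
      lb <- lin_b(dX, pc, p_get(P, paste0("att.", w)))
      g_add(G, paste0("att.", w), lb$dW)
      g_add(G, paste0("att.", b), lb$db)
      lb$dX
    }
    dA <- dA + accp(mb_av$dQ, cache$qa, "Wq", "bq") +
      accp(mb_va$dK, cache$ka, "Wk", "bk") +
      accp(mb_va$dV, cache$va, "Wv", "bv")
    dV <- dV + accp(mb_va$dQ, cache$qv, "Wq", "bq") +
      accp(mb_av$dK, cache$kv, "Wk", "bk") +
      accp(mb_av$dV, cache$vv, "Wv", "bv")
  }

  back_modality <- function(dX, cm, m) {
    pfx <- if (m == "audio") "co.a" else "co.v"
    for (i in rev(seq_len(cfg$n_blocks))) {
      dX <- bimamba_b(model$blocks[[sprintf("%s.b%d", pfx, i)]],
                      cm$bl[[i]], dX, G)
    }
    fb <- lin_b(dX, cm$fr, p_get(P, sprintf("front.%s.W", m)))
    g_add(G, sprintf("front.%s.W", m), fb$dW)
    g_add(G, sprintf("front.%s.b", m), fb$db)
    invisible(NULL)
  }
  if (has_audio(cfg)) back_modality(dA, cache$ca, "audio")
  if (has_video(cfg)) back_modality(dV, cache$cv, "video")
  invisible(G)
}

#' Run the model on one sample pair
#'
#' @param model An [asym_model()].
#' @param audio `T x F_a` audio feature matrix (or `NULL` for video-only
#'   models).
#' @param video `T x F_v` visual feature matrix (or `NULL`).
#' @param return_attention If `TRUE`, include the cross-modal attention
#'   maps (per head, per direction).
#' @return List with `logit`, `prob`, `label` and optionally `attn`.
#' @export
asym_predict <- function(model, audio = NULL, video = NULL,
                         return_attention = FALSE) {
  fw <- asym_forward_cache(model, audio, video, training = FALSE)
  out <- fw[c("logit", "prob", "label")]
  if (return_attention) out$attn <- fw$attn
  out
}
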