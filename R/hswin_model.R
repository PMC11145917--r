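#' Configuration of the hybrid 3D shifted-window transformer
#'
#' The segmentation network is a U-shaped 3D Swin transformer with an
#' optional dilated-convolution front end (the "hybrid" part): the front
#' end extracts multi-scale local features at full resolution, tokens are
#' formed by patch partition + linear embedding, a four-stage encoder with
#' block depths `depths` (patch merging between stages, channel width
#' doubling C, 2C, 4C, 8C) learns multi-scale context, the deepest stage
#' acts as the bottleneck, and a decoder with three patch-expanding stages
#' fuses the three encoder skips by concatenation + linear reduction before
#' a final expansion back to voxel resolution and a linear softmax head.
#'
#' @param embed_dim token embedding width C at stage 1.
#' @param token_patch voxels per token `(z, y, x)`.
#' @param window attention window `(z, y, x)` in tokens; clamped per stage
#'   to the token grid.
#' @param depths Swin blocks per encoder stage (length 4); the decoder
#'   mirrors stages 1-3.
#' @param heads attention heads per stage (default `max(1, dim / 16)`).
#' @param dilation_rates dilation factors of the parallel 3x3x3 front-end
#'   convolutions.
#' @param conv_channels channels per dilated branch.
#' @param fused_channels channels after the 1x1x1 fusion convolution.
#' @param mlp_ratio MLP hidden width as a multiple of the stage width.
#' @param dropout dropout probability on attention-proj and MLP outputs.
#' @param num_classes output classes (2: background / cell).
#' @param in_channels input image channels.
#' @param hybrid include the dilated convolution block (`FALSE` gives the
#'   ablated pure Swin variant).
#' @param seed weight-initialization seed.
#' @return an `hswin3d_config` list.
#' @export
hswin3d_config <- function(embed_dim = 32L, token_patch = c(2L, 2L, 2L),
                           window = c(4L, 4L, 4L), depths = c(2L, 2L, 6L, 2L),
                           heads = NULL, dilation_rates = c(1L, 2L, 3L),
                           conv_channels = 4L, fused_channels = 8L,
                           mlp_ratio = 4, dropout = 0, num_classes = 2L,
                           in_channels = 1L, hybrid = TRUE, seed = 1L) {
  cfg <- list(embed_dim = as.integer(embed_dim),
              token_patch = as.integer(token_patch),
              window = as.integer(window), depths = as.integer(depths),
              heads = if (is.null(heads)) NULL else as.integer(heads),
              dilation_rates = as.integer(dilation_rates),
              conv_channels = as.integer(conv_channels),
              fused_channels = as.integer(fused_channels),
              mlp_ratio = mlp_ratio, dropout = dropout,
              num_classes = as.integer(num_classes),
              in_channels = as.integer(in_channels),
              hybrid = isTRUE(hybrid), seed = as.integer(seed))
  if (length(cfg$depths) != 4L || any(cfg$depths < 1L))
    stop("depths must be 4 positive block counts")
  dims <- as.integer(cfg$embed_dim * 2^(0:3))
  if (is.null(cfg$heads)) cfg$heads <- pmax(1L, dims %/% 16L)
  if (length(cfg$heads) != 4L || any(dims %% cfg$heads != 0L))
    stop("heads must divide the stage widths ", paste(dims, collapse = ","))
  cfg$stage_dims <- dims
  structure(cfg, class = "hswin3d_config")
}

rn <- function(nr, nc = NULL, sd = 0.02) {
  if (is.null(nc)) stats::rnorm(nr, 0, sd) else
    matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
}

block_params <- function(D, H, hid, wc) {
  list(ln1_g = rep(1, D), ln1_b = rep(0, D),
       qkv_w = rn(D, 3 * D), qkv_b = rep(0, 3 * D),
       proj_w = rn(D, D), proj_b = rep(0, D),
       ln2_g = rep(1, D), ln2_b = rep(0, D),
       fc1_w = rn(D, hid), fc1_b = rep(0, hid),
       fc2_w = rn(hid, D), fc2_b = rep(0, D),
       relpos = matrix(0, n_relpos(wc), H))
}

#' Build a hybrid 3D Swin transformer model
#'
#' Initializes all weights (truncated-normal-scale Gaussian, seed taken
#' from the config) and returns the model handle. The handle is an
#' environment so index plans can be cached per input shape.
#'
#' @param cfg an [hswin3d_config()].
#' @return an object of class `hswin3d`.
#' @export
build_model <- function(cfg = hswin3d_config()) {
  stopifnot(inherits(cfg, "hswin3d_config"))
  dims <- cfg$stage_dims
  params <- list()
  add <- function(prefix, lst) {
    names(lst) <- paste0(prefix, ".", names(lst))
    params[names(lst)] <<- lst
  }
  with_seed(cfg$seed, {
    nd <- length(cfg$dilation_rates)
    cc <- cfg$conv_channels
    if (cfg$hybrid) {
      for (k in seq_len(nd)) {
        add(paste0("front.conv", k),
            list(w = rn(27 * cfg$in_channels, cc, sd = sqrt(2 / (27 * cfg$in_channels))),
                 b = rep(0, cc)))
      }
      add("front.fuse", list(w = rn(nd * cc, cfg$fused_channels,
                                    sd = sqrt(2 / (nd * cc))),
                             b = rep(0, cfg$fused_channels)))
    }
    feat <- if (cfg$hybrid) cfg$fused_channels else cfg$in_channels
    P8 <- prod(cfg$token_patch)
    add("embed", list(w = rn(P8 * feat, dims[1]), b = rep(0, dims[1]),
                      ln_g = rep(1, dims[1]), ln_b = rep(0, dims[1])))
    for (s in 1:4) {
      hid <- round(dims[s] * cfg$mlp_ratio)
      for (i in seq_len(cfg$depths[s]))
        add(sprintf("enc%d.b%d", s, i),
            block_params(dims[s], cfg$heads[s], hid, cfg$window))
      if (s < 4)
        add(sprintf("merge%d", s),
            list(ln_g = rep(1, 8 * dims[s]), ln_b = rep(0, 8 * dims[s]),
                 w = rn(8 * dims[s], 2 * dims[s]), b = rep(0, 2 * dims[s])))
    }
    for (s in 3:1) {
      add(sprintf("dec%d", s),
          list(expand_w = rn(2 * dims[s], 8 * dims[s]),
               expand_b = rep(0, 8 * dims[s]),
               fuse_w = rn(2 * dims[s], dims[s]), fuse_b = rep(0, dims[s])))
      hid <- round(dims[s] * cfg$mlp_ratio)
      for (i in seq_len(cfg$depths[s]))
        add(sprintf("dec%d.b%d", s, i),
            block_params(dims[s], cfg$heads[s], hid, cfg$window))
    }
    add("final", list(expand_w = rn(dims[1], prod(cfg$token_patch) * dims[1]),
                      expand_b = rep(0, prod(cfg$token_patch) * dims[1]),
                      ln_g = rep(1, dims[1]), ln_b = rep(0, dims[1])))
    add("head", list(w = rn(dims[1], cfg$num_classes),
                     b = rep(0, cfg$num_classes)))
  })
  model <- new.env(parent = emptyenv())
  model$cfg <- cfg
  model$params <- params
  model$cache <- new.env(parent = emptyenv())
  model$meta <- list(n_stages = 4L, n_skips = 3L, stage_dims = dims,
                     depths = cfg$depths, heads = cfg$heads)
  class(model) <- "hswin3d"
  model
}

#' @export
print.hswin3d <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<hswin3d> %s, C = %d, widths %s, depths %s, heads %s, %s parameters\n",
              if (x$cfg$hybrid) "hybrid (dilated conv front end)" else "ablated (no conv front end)",
              x$cfg$embed_dim, paste(x$meta$stage_dims, collapse = "/"),
              paste(x$cfg$depths, collapse = ","),
              paste(x$cfg$heads, collapse = ","),
              format(n_par, big.mark = ",")))
  invisible(x)
}

#' @export
summary.hswin3d <- function(object, ...) {
  print(object)
  cat(sprintf("  encoder stages: %d (patch merging between stages)\n",
              object$meta$n_stages))
  cat(sprintf("  decoder skip connections: %d\n", object$meta$n_skips))
  cat(sprintf("  token patch %s, window %s, MLP ratio %g\n",
              paste(object$cfg$token_patch, collapse = "x"),
              paste(object$cfg$window, collapse = "x"), object$cfg$mlp_ratio))
  invisible(object)
}

# ---- gather/scatter between resolutions -----------------------------------

# fine (B*Nf x F) -> coarse (B*Nc x P*F) using idx (Nc x P)
fine_to_coarse <- function(M, idx, B, Nf) {
  F_ <- ncol(M); Nc <- nrow(idx); P <- ncol(idx)
  iv <- as.vector(idx)
  out <- matrix(0, B * Nc, P * F_)
  for (b in seq_len(B)) {
    Mb <- M[(b - 1L) * Nf + iv, , drop = FALSE]
    dim(Mb) <- c(Nc, P * F_)
    out[(b - 1L) * Nc + seq_len(Nc), ] <- Mb
  }
  out
}

# coarse (B*Nc x P*F) -> fine (B*Nf x F)
coarse_to_fine <- function(M, idx, B, Nf) {
  Nc <- nrow(idx); P <- ncol(idx); F_ <- ncol(M) / P
  iv <- as.vector(idx)
  out <- matrix(0, B * Nf, F_)
  for (b in seq_len(B)) {
    Mb <- M[(b - 1L) * Nc + seq_len(Nc), , drop = FALSE]
    dim(Mb) <- c(Nc * P, F_)
    out[(b - 1L) * Nf + iv, ] <- Mb
  }
  out
}

# ---- window (de)stacking ---------------------------------------------------

to_cube <- function(M, perm, B, N, ws, nwin, dh, H) {
  C <- dh * H
  A <- array(0, c(ws, nwin * B, C))
  for (b in seq_len(B)) {
    Mb <- M[(b - 1L) * N + perm, , drop = FALSE]
    A[, (b - 1L) * nwin + seq_len(nwin), ] <- array(Mb, c(ws, nwin, C))
  }
  dim(A) <- c(ws, nwin * B, dh, H)
  A <- aperm(A, c(1, 3, 2, 4))
  dim(A) <- c(ws, dh, nwin * B * H)
  A
}

from_cube <- function(A, perm, B, N, ws, nwin, dh, H) {
  C <- dh * H
  dim(A) <- c(ws, dh, nwin * B, H)
  A <- aperm(A, c(1, 3, 2, 4))
  dim(A) <- c(ws * nwin * B, C)
  M <- matrix(0, B * N, C)
  for (b in seq_len(B)) {
    M[(b - 1L) * N + perm, ] <-
      A[(b - 1L) * nwin * ws + seq_len(nwin * ws), , drop = FALSE]
  }
  M
}

EMPTY_CUBE <- array(0, c(0, 0, 0))

# ---- Swin block ------------------------------------------------------------

run_block_fwd <- function(X, p, prefix, sp, B, H, shifted, train, dropout) {
  g <- function(nm) p[[paste0(prefix, ".", nm)]]
  C <- ncol(X); dh <- C %/% H
  N <- sp$N; ws <- sp$ws; nwin <- sp$nwin
  perm <- if (shifted) sp$perm_s else sp$perm0
  mask <- if (shifted) sp$mask else EMPTY_CUBE
  ln1 <- layernorm_fwd(X, g("ln1_g"), g("ln1_b"))
  qkv <- linear_fwd(ln1$Y, g("qkv_w"), g("qkv_b"))
  Qc <- to_cube(qkv[, 1:C, drop = FALSE], perm, B, N, ws, nwin, dh, H)
  Kc <- to_cube(qkv[, C + 1:C, drop = FALSE], perm, B, N, ws, nwin, dh, H)
  Vc <- to_cube(qkv[, 2 * C + 1:C, drop = FALSE], perm, B, N, ws, nwin, dh, H)
  bias <- array(g("relpos")[sp$relidx, , drop = FALSE], c(ws, ws, H))
  att <- attn_forward_cpp(Qc, Kc, Vc, 1 / sqrt(dh), bias, mask, nwin, B)
  A <- from_cube(att$out, perm, B, N, ws, nwin, dh, H)
  proj <- linear_fwd(A, g("proj_w"), g("proj_b"))
  dm1 <- NULL
  if (train && dropout > 0) {
    dm1 <- (matrix(stats::runif(length(proj)), nrow(proj)) >= dropout) / (1 - dropout)
    proj <- proj * dm1
  }
  X1 <- X + proj
  ln2 <- layernorm_fwd(X1, g("ln2_g"), g("ln2_b"))
  f1 <- linear_fwd(ln2$Y, g("fc1_w"), g("fc1_b"))
  gl <- gelu_fwd(f1)
  f2 <- linear_fwd(gl$Y, g("fc2_w"), g("fc2_b"))
  dm2 <- NULL
  if (train && dropout > 0) {
    dm2 <- (matrix(stats::runif(length(f2)), nrow(f2)) >= dropout) / (1 - dropout)
    f2 <- f2 * dm2
  }
  X2 <- X1 + f2
  cache <- NULL
  if (train)
    cache <- list(X = X, ln1 = ln1, Qc = Qc, Kc = Kc, Vc = Vc, P = att$P,
                  A = A, X1 = X1, ln2 = ln2, gl = gl, shifted = shifted,
                  dm1 = dm1, dm2 = dm2)
  list(X = X2, cache = cache)
}

run_block_bwd <- function(dX2, cache, p, prefix, sp, B, H, G) {
  g <- function(nm) p[[paste0(prefix, ".", nm)]]
  setg <- function(nm, val) assign(paste0(prefix, ".", nm), val, envir = G)
  C <- ncol(dX2); dh <- C %/% H
  N <- sp$N; ws <- sp$ws; nwin <- sp$nwin
  perm <- if (cache$shifted) sp$perm_s else sp$perm0
  df2 <- dX2
  if (!is.null(cache$dm2)) df2 <- df2 * cache$dm2
  lb2 <- linear_bwd(df2, cache$gl$Y, g("fc2_w"))
  setg("fc2_w", lb2$dW); setg("fc2_b", lb2$db)
  df1 <- gelu_bwd(lb2$dX, cache$gl)
  lb1 <- linear_bwd(df1, cache$ln2$Y, g("fc1_w"))
  setg("fc1_w", lb1$dW); setg("fc1_b", lb1$db)
  lnb2 <- layernorm_bwd(lb1$dX, cache$ln2, g("ln2_g"))
  setg("ln2_g", lnb2$dg); setg("ln2_b", lnb2$db)
  dX1 <- dX2 + lnb2$dX
  dproj <- dX1
  if (!is.null(cache$dm1)) dproj <- dproj * cache$dm1
  pb <- linear_bwd(dproj, cache$A, g("proj_w"))
  setg("proj_w", pb$dW); setg("proj_b", pb$db)
  dOut <- to_cube(pb$dX, perm, B, N, ws, nwin, dh, H)
  ab <- attn_backward_cpp(dOut, cache$Qc, cache$Kc, cache$Vc, cache$P,
                          1 / sqrt(dh), nwin, B, H)
  dqkv <- cbind(from_cube(ab$dQ, perm, B, N, ws, nwin, dh, H),
                from_cube(ab$dK, perm, B, N, ws, nwin, dh, H),
                from_cube(ab$dV, perm, B, N, ws, nwin, dh, H))
  qb <- linear_bwd(dqkv, cache$ln1$Y, g("qkv_w"))
  setg("qkv_w", qb$dW); setg("qkv_b", qb$db)
  drel <- matrix(0, nrow(g("relpos")), H)
  for (hh in seq_len(H)) {
    db_h <- as.vector(ab$dbias[, , hh])
    rs <- rowsum(db_h, sp$relidx)
    drel[as.integer(rownames(rs)), hh] <- rs
  }
  setg("relpos", drel)
  lnb1 <- layernorm_bwd(qb$dX, cache$ln1, g("ln1_g"))
  setg("ln1_g", lnb1$dg); setg("ln1_b", lnb1$db)
  dX1 + lnb1$dX
}

# ---- full forward / backward ----------------------------------------------

# xs: list of B numeric 3D arrays (already normalized), all the same shape
hswin_forward <- function(model, xs, train = FALSE) {
  cfg <- model$cfg
  p <- model$params
  B <- length(xs)
  dims <- dim(xs[[1]])
  for (x in xs) if (!identical(dim(x), dims)) stop("batch shapes differ")
  plan <- get_plan(model, dims)
  nvox <- plan$nvox
  R <- matrix(0, B * nvox, 1)
  for (b in seq_len(B)) R[(b - 1L) * nvox + seq_len(nvox), 1] <- as.vector(xs[[b]])
  cache <- if (train) list(B = B, dims = dims) else NULL

  if (cfg$hybrid) {
    nd <- length(cfg$dilation_rates)
    branches <- vector("list", nd)
    cols <- vector("list", nd)
    for (k in seq_len(nd)) {
      cp <- plan$conv[[k]]
      Xcol <- matrix(0, B * nvox, 27L)
      for (b in seq_len(B)) {
        ap <- array(0, cp$padded_dims)
        dl <- cp$dilation
        ap[dl + seq_len(dims[1]), dl + seq_len(dims[2]), dl + seq_len(dims[3])] <- xs[[b]]
        Xcol[(b - 1L) * nvox + seq_len(nvox), ] <-
          matrix(ap[as.vector(cp$idx)], nvox, 27L)
      }
      cols[[k]] <- Xcol
      branches[[k]] <- linear_fwd(Xcol, p[[paste0("front.conv", k, ".w")]],
                                  p[[paste0("front.conv", k, ".b")]])
    }
    Xcat <- do.call(cbind, branches)
    r1 <- relu_fwd(Xcat)
    fuse <- linear_fwd(r1$Y, p[["front.fuse.w"]], p[["front.fuse.b"]])
    r2 <- relu_fwd(fuse)
    V <- r2$Y
    if (train) cache$front <- list(cols = cols, r1 = r1, r1Y = r1$Y, r2 = r2)
  } else {
    V <- R
  }

  Xtok <- fine_to_coarse(V, plan$embed_idx, B, nvox)
  emb <- linear_fwd(Xtok, p[["embed.w"]], p[["embed.b"]])
  eln <- layernorm_fwd(emb, p[["embed.ln_g"]], p[["embed.ln_b"]])
  X <- eln$Y
  if (train) cache$embed <- list(Xtok = Xtok, eln = eln)

  skips <- vector("list", 3)
  if (train) cache$enc <- vector("list", 4)
  for (s in 1:4) {
    sp <- plan$stages[[s]]
    bl_caches <- vector("list", cfg$depths[s])
    for (i in seq_len(cfg$depths[s])) {
      shifted <- (i %% 2L == 0L) && sp$can_shift
      r <- run_block_fwd(X, p, sprintf("enc%d.b%d", s, i), sp, B,
                         cfg$heads[s], shifted, train, cfg$dropout)
      X <- r$X
      bl_caches[[i]] <- r$cache
    }
    if (s < 4) {
      skips[[s]] <- X
      Xcat <- fine_to_coarse(X, plan$merge_idx[[s]], B, sp$N)
      mln <- layernorm_fwd(Xcat, p[[sprintf("merge%d.ln_g", s)]],
                           p[[sprintf("merge%d.ln_b", s)]])
      Xm <- linear_fwd(mln$Y, p[[sprintf("merge%d.w", s)]],
                       p[[sprintf("merge%d.b", s)]])
      if (train) cache$enc[[s]] <- list(blocks = bl_caches, mln = mln)
      X <- Xm
    } else if (train) cache$enc[[s]] <- list(blocks = bl_caches)
  }

  if (train) cache$dec <- vector("list", 3)
  for (s in 3:1) {
    sp <- plan$stages[[s]]
    Nc <- plan$stages[[s + 1]]$N
    Yx <- linear_fwd(X, p[[sprintf("dec%d.expand_w", s)]],
                     p[[sprintf("dec%d.expand_b", s)]])
    Xup <- coarse_to_fine(Yx, plan$merge_idx[[s]], B, sp$N)
    Xcat <- cbind(Xup, skips[[s]])
    Xf <- linear_fwd(Xcat, p[[sprintf("dec%d.fuse_w", s)]],
                     p[[sprintf("dec%d.fuse_b", s)]])
    dcache <- list(X_in = X, Xcat = Xcat)
    X <- Xf
    bl_caches <- vector("list", cfg$depths[s])
    for (i in seq_len(cfg$depths[s])) {
      shifted <- (i %% 2L == 0L) && sp$can_shift
      r <- run_block_fwd(X, p, sprintf("dec%d.b%d", s, i), sp, B,
                         cfg$heads[s], shifted, train, cfg$dropout)
      X <- r$X
      bl_caches[[i]] <- r$cache
    }
    if (train) { dcache$blocks <- bl_caches; cache$dec[[s]] <- dcache }
  }

  Yf <- linear_fwd(X, p[["final.expand_w"]], p[["final.expand_b"]])
  Vout <- coarse_to_fine(Yf, plan$embed_idx, B, nvox)
  fln <- layernorm_fwd(Vout, p[["final.ln_g"]], p[["final.ln_b"]])
  logits <- linear_fwd(fln$Y, p[["head.w"]], p[["head.b"]])
  if (train) {
    cache$final <- list(X_in = X, fln = fln)
    cache$plan <- plan
  }
  list(logits = logits, cache = cache, plan = plan, B = B)
}

hswin_backward <- function(model, dlogits, cache) {
  cfg <- model$cfg
  p <- model$params
  B <- cache$B
  plan <- cache$plan
  nvox <- plan$nvox
  G <- new.env(parent = emptyenv())

  hb <- linear_bwd(dlogits, cache$final$fln$Y, p[["head.w"]])
  assign("head.w", hb$dW, envir = G); assign("head.b", hb$db, envir = G)
  flnb <- layernorm_bwd(hb$dX, cache$final$fln, p[["final.ln_g"]])
  assign("final.ln_g", flnb$dg, envir = G)
  assign("final.ln_b", flnb$db, envir = G)
  dYf <- fine_to_coarse(flnb$dX, plan$embed_idx, B, nvox)
  feb <- linear_bwd(dYf, cache$final$X_in, p[["final.expand_w"]])
  assign("final.expand_w", feb$dW, envir = G)
  assign("final.expand_b", feb$db, envir = G)
  dX <- feb$dX

  dskips <- vector("list", 3)
  for (s in 1:3) {
    sp <- plan$stages[[s]]
    for (i in rev(seq_len(cfg$depths[s])))
      dX <- run_block_bwd(dX, cache$dec[[s]]$blocks[[i]], p,
                          sprintf("dec%d.b%d", s, i), sp, B, cfg$heads[s], G)
    fb <- linear_bwd(dX, cache$dec[[s]]$Xcat, p[[sprintf("dec%d.fuse_w", s)]])
    assign(sprintf("dec%d.fuse_w", s), fb$dW, envir = G)
    assign(sprintf("dec%d.fuse_b", s), fb$db, envir = G)
    D <- cfg$stage_dims[s]
    dXup <- fb$dX[, seq_len(D), drop = FALSE]
    dskips[[s]] <- fb$dX[, D + seq_len(D), drop = FALSE]
    dYx <- fine_to_coarse(dXup, plan$merge_idx[[s]], B, sp$N)
    eb <- linear_bwd(dYx, cache$dec[[s]]$X_in, p[[sprintf("dec%d.expand_w", s)]])
    assign(sprintf("dec%d.expand_w", s), eb$dW, envir = G)
    assign(sprintf("dec%d.expand_b", s), eb$db, envir = G)
    dX <- eb$dX
  }

  for (s in 4:1) {
    sp <- plan$stages[[s]]
    if (s < 4) {
      mb <- linear_bwd(dX, cache$enc[[s]]$mln$Y, p[[sprintf("merge%d.w", s)]])
      assign(sprintf("merge%d.w", s), mb$dW, envir = G)
      assign(sprintf("merge%d.b", s), mb$db, envir = G)
      mlnb <- layernorm_bwd(mb$dX, cache$enc[[s]]$mln,
                            p[[sprintf("merge%d.ln_g", s)]])
      assign(sprintf("merge%d.ln_g", s), mlnb$dg, envir = G)
      assign(sprintf("merge%d.ln_b", s), mlnb$db, envir = G)
      dX <- coarse_to_fine(mlnb$dX, plan$merge_idx[[s]], B, sp$N)
      dX <- dX + dskips[[s]]
    }
    for (i in rev(seq_len(cfg$depths[s])))
      dX <- run_block_bwd(dX, cache$enc[[s]]$blocks[[i]], p,
                          sprintf("enc%d.b%d", s, i), sp, B, cfg$heads[s], G)
  }

  elnb <- layernorm_bwd(dX, cache$embed$eln, p[["embed.ln_g"]])
  assign("embed.ln_g", elnb$dg, envir = G)
  assign("embed.ln_b", elnb$db, envir = G)
  eb <- linear_bwd(elnb$dX, cache$embed$Xtok, p[["embed.w"]])
  assign("embed.w", eb$dW, envir = G); assign("embed.b", eb$db, envir = G)

  if (cfg$hybrid) {
    dV <- coarse_to_fine(eb$dX, plan$embed_idx, B, nvox)
    dfuse <- relu_bwd(dV, cache$front$r2)
    fb <- linear_bwd(dfuse, cache$front$r1Y, p[["front.fuse.w"]])
    assign("front.fuse.w", fb$dW, envir = G)
    assign("front.fuse.b", fb$db, envir = G)
    dcat <- relu_bwd(fb$dX, cache$front$r1)
    cc <- cfg$conv_channels
    for (k in seq_along(cfg$dilation_rates)) {
      dYk <- dcat[, (k - 1L) * cc + seq_len(cc), drop = FALSE]
      assign(paste0("front.conv", k, ".w"),
             crossprod(cache$front$cols[[k]], dYk), envir = G)
      assign(paste0("front.conv", k, ".b"), colSums(dYk), envir = G)
    }
  }
  as.list(G)
}

#' Voxel-wise class probabilities for one or more patches
#'
#' Each patch is min-max normalized to `[0, 1]` before the forward pass (so
#' raw intensity units do not matter); output probabilities sum to one per
#' voxel. In evaluation mode the pass is deterministic for fixed weights.
#'
#' @param object a trained or freshly built [build_model()] network.
#' @param patch a 3D array (or an [intensity_volume()], or a list of arrays
#'   forming a batch); spatial dims must satisfy the divisibility contract.
#' @param normalize min-max normalize per patch (default TRUE).
#' @param ... unused.
#' @return array `(z, y, x, class)` of probabilities (a list of them for a
#'   batch input).
#' @export
predict.hswin3d <- function(object, patch, normalize = TRUE, ...) {
  single <- !is.list(patch) || inherits(patch, "intensity_volume")
  xs <- if (inherits(patch, "intensity_volume")) list(patch$data)
        else if (is.list(patch)) lapply(patch, function(q)
          if (inherits(q, "intensity_volume")) q$data else q)
        else list(patch)
  if (normalize) xs <- lapply(xs, minmax_norm)
  logits <- fast_forward(object, xs)
  dims <- dim(xs[[1]])
  nvox <- prod(dims)
  out <- vector("list", length(xs))
  for (b in seq_along(xs)) {
    pr <- softmax_rows(logits[(b - 1L) * nvox + seq_len(nvox), , drop = FALSE])
    out[[b]] <- array(pr, c(dims, ncol(pr)))
  }
  if (single) out[[1]] else out
}

minmax_norm <- function(x) {
  lo <- min(x); hi <- max(x)
  (x - lo) / (hi - lo + 1e-8)
}
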