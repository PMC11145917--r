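# Precomputed index structures for one input shape: token-grid geometry,
# window partition permutations (regular and cyclically shifted, with the
# attention masks forbidding wrapped pairs), relative-position bias indices
# and patch grouping indices for embedding/merging/expanding. Plans are
# cached on the model keyed by the input shape.

# fine-grid indices grouped under a coarse grid: matrix (N_coarse x prod(factor)),
# entry [t, p] = 1-based fine linear index (z-fastest everywhere)
group_index <- function(grid_fine, factor) {
  gc <- grid_fine %/% factor
  if (any(gc * factor != grid_fine))
    stop("grid not divisible by grouping factor")
  Nc <- prod(gc)
  P <- prod(factor)
  pos <- as.matrix(expand.grid(pz = 0:(factor[1] - 1), py = 0:(factor[2] - 1),
                               px = 0:(factor[3] - 1)))
  tok <- as.matrix(expand.grid(cz = 0:(gc[1] - 1), cy = 0:(gc[2] - 1),
                               cx = 0:(gc[3] - 1)))
  idx <- matrix(0L, Nc, P)
  for (p in seq_len(P)) {
    fz <- tok[, 1] * factor[1] + pos[p, 1]
    fy <- tok[, 2] * factor[2] + pos[p, 2]
    fx <- tok[, 3] * factor[3] + pos[p, 3]
    idx[, p] <- 1L + fz + fy * grid_fine[1] + fx * grid_fine[1] * grid_fine[2]
  }
  idx
}

NEG_INF_MASK <- -1e9

# window partition for one stage: permutation into (position-in-window
# fastest, window next) stacked order, with optional cyclic shift + mask
window_plan <- function(grid, window_cfg) {
  eff <- pmin(window_cfg, grid)
  bad <- which(grid %% eff != 0)
  if (length(bad) > 0)
    stop("token grid (", paste(grid, collapse = "x"),
         ") not divisible by attention window on axis ",
         c("z", "y", "x")[bad[1]])
  nw <- grid %/% eff
  shift <- ifelse(grid > eff, eff %/% 2L, 0L)
  can_shift <- any(shift > 0)
  make_perm <- function(sh) {
    g <- expand.grid(iz = 0:(eff[1] - 1), iy = 0:(eff[2] - 1),
                     ix = 0:(eff[3] - 1), wz = 0:(nw[1] - 1),
                     wy = 0:(nw[2] - 1), wx = 0:(nw[3] - 1))
    pz <- (g$wz * eff[1] + g$iz + sh[1]) %% grid[1]
    py <- (g$wy * eff[2] + g$iy + sh[2]) %% grid[2]
    px <- (g$wx * eff[3] + g$ix + sh[3]) %% grid[3]
    cbind(perm = 1L + pz + py * grid[1] + px * grid[1] * grid[2],
          pz = pz, py = py, px = px)
  }
  ws <- prod(eff)
  nwin <- prod(nw)
  p0 <- make_perm(c(0L, 0L, 0L))
  plan <- list(grid = grid, eff = eff, ws = ws, nwin = nwin, shift = shift,
               perm0 = p0[, "perm"], can_shift = can_shift)
  if (can_shift) {
    ps <- make_perm(shift)
    plan$perm_s <- ps[, "perm"]
    # per-axis segment labels of the ORIGINAL coordinates: tokens may only
    # attend within their pre-shift contiguous segment
    seg <- function(coord, n, e, sh) {
      if (sh == 0) return(rep(0L, length(coord)))
      ifelse(coord < n - e, 0L, ifelse(coord < n - sh, 1L, 2L))
    }
    lab <- seg(ps[, "pz"], grid[1], eff[1], shift[1]) +
      3L * seg(ps[, "py"], grid[2], eff[2], shift[2]) +
      9L * seg(ps[, "px"], grid[3], eff[3], shift[3])
    mask <- array(0, c(ws, ws, nwin))
    for (w in seq_len(nwin)) {
      lw <- lab[(w - 1L) * ws + seq_len(ws)]
      mask[, , w] <- ifelse(outer(lw, lw, `==`), 0, NEG_INF_MASK)
    }
    plan$mask <- mask
  }
  plan
}

# relative-position bias index vector (length ws^2, column-major over the
# (query, key) matrix) into a table of prod(2*window_cfg - 1) rows
relpos_index <- function(eff, window_cfg) {
  pos <- as.matrix(expand.grid(iz = 0:(eff[1] - 1), iy = 0:(eff[2] - 1),
                               ix = 0:(eff[3] - 1)))
  s1 <- 2L * window_cfg[1] - 1L
  s2 <- 2L * window_cfg[2] - 1L
  oz <- outer(pos[, 1], pos[, 1], `-`)
  oy <- outer(pos[, 2], pos[, 2], `-`)
  ox <- outer(pos[, 3], pos[, 3], `-`)
  idx <- (oz + window_cfg[1] - 1L) +
    (oy + window_cfg[2] - 1L) * s1 +
    (ox + window_cfg[3] - 1L) * s1 * s2 + 1L
  as.vector(idx)
}

n_relpos <- function(window_cfg) prod(2L * window_cfg - 1L)

# full plan for one input spatial shape
build_plan <- function(cfg, dims) {
  tp <- cfg$token_patch
  bad <- which(dims %% (tp * 8L) != 0)
  if (length(bad) > 0)
    stop("input shape (", paste(dims, collapse = "x"),
         ") must be divisible by token_patch * 8 on axis ",
         c("z", "y", "x")[bad[1]])
  g1 <- dims %/% tp
  stages <- vector("list", 4)
  for (s in 1:4) {
    grid <- g1 %/% as.integer(2^(s - 1))
    wp <- window_plan(grid, cfg$window)
    wp$relidx <- relpos_index(wp$eff, cfg$window)
    wp$N <- prod(grid)
    stages[[s]] <- wp
  }
  merge_idx <- lapply(1:3, function(s)
    group_index(stages[[s]]$grid, c(2L, 2L, 2L)))
  list(dims = dims, nvox = prod(dims), g1 = g1,
       embed_idx = group_index(dims, tp),
       stages = stages, merge_idx = merge_idx)
}

# zero-padded im2col indices for a 3x3x3 kernel at one dilation
conv_plan <- function(dims, dilation) {
  pd <- dims + 2L * dilation
  offs <- as.matrix(expand.grid(kz = -1:1, ky = -1:1, kx = -1:1))
  vox <- as.matrix(expand.grid(z = 0:(dims[1] - 1), y = 0:(dims[2] - 1),
                               x = 0:(dims[3] - 1)))
  idx <- matrix(0L, nrow(vox), 27L)
  for (k in 1:27) {
    z <- vox[, 1] + dilation + offs[k, 1] * dilation
    y <- vox[, 2] + dilation + offs[k, 2] * dilation
    x <- vox[, 3] + dilation + offs[k, 3] * dilation
    idx[, k] <- 1L + z + y * pd[1] + x * pd[1] * pd[2]
  }
  list(padded_dims = pd, idx = idx, dilation = dilation)
}

get_plan <- function(model, dims) {
  key <- paste(dims, collapse = "x")
  if (is.null(model$cache[[key]])) {
    plan <- build_plan(model$cfg, dims)
    if (model$cfg$hybrid)
      plan$conv <- lapply(model$cfg$dilation_rates,
                          function(d) conv_plan(dims, as.integer(d)))
    model$cache[[key]] <- plan
  }
  model$cache[[key]]
}
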