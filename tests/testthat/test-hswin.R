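test_that("the encoder has four stages with doubling widths and three skips", {
  cfg <- hswin3d_config(embed_dim = 16L)
  m <- build_model(cfg)
  expect_identical(m$meta$n_stages, 4L)
  expect_identical(m$meta$n_skips, 3L)
  expect_identical(m$meta$stage_dims, 16L * c(1L, 2L, 4L, 8L))
  expect_identical(m$cfg$depths, c(2L, 2L, 6L, 2L))
  # one block-parameter set per configured depth, encoder and decoder
  for (s in 1:4)
    expect_true(sprintf("enc%d.b%d", s, cfg$depths[s]) ==
                  sprintf("enc%d.b%d", s, cfg$depths[s]) &&
                !is.null(m$params[[sprintf("enc%d.b%d.qkv_w", s, cfg$depths[s])]]))
  for (s in 1:3) {
    expect_false(is.null(m$params[[sprintf("dec%d.fuse_w", s)]]))
    expect_identical(dim(m$params[[sprintf("dec%d.fuse_w", s)]]),
                     c(2L * m$meta$stage_dims[s], m$meta$stage_dims[s]))
  }
  expect_error(hswin3d_config(depths = c(2L, 2L, 6L)), "4 positive")
})

test_that("forward output matches the input shape and softmax-normalizes", {
  m <- build_model(tiny_model_cfg())
  x <- array(runif(16^3), c(16L, 16L, 16L))
  pr <- predict(m, x)
  expect_identical(dim(pr), c(16L, 16L, 16L, 2L))
  expect_lt(max(abs(pr[, , , 1] + pr[, , , 2] - 1)), 1e-5)
  expect_true(all(pr >= 0 & pr <= 1))
  # deterministic in eval mode
  expect_identical(pr, predict(m, x))
  # zero-weight head: uniform 0.5/0.5 everywhere
  m$params[["head.w"]][] <- 0
  m$params[["head.b"]][] <- 0
  pr0 <- predict(m, x)
  expect_lt(max(abs(pr0 - 0.5)), 1e-6)
})

test_that("token-grid arithmetic puts a 32^3 input at a 2^3 bottleneck", {
  m <- build_model(hswin3d_config(embed_dim = 16L))
  plan <- fosmapr:::get_plan(m, c(32L, 32L, 32L))
  expect_identical(plan$g1, c(16L, 16L, 16L))
  expect_identical(plan$stages[[4]]$grid, c(2L, 2L, 2L))
  # divisibility violations name the offending axis
  expect_error(fosmapr:::get_plan(m, c(24L, 32L, 32L)), "axis z")
  expect_error(fosmapr:::get_plan(m, c(32L, 32L, 24L)), "axis x")
  expect_error(fosmapr:::get_plan(m, c(96L, 96L, 96L)), "window")
})

test_that("checkpoints round trip bitwise and reject mismatched configs", {
  m <- build_model(tiny_model_cfg())
  x <- array(runif(16^3), c(16L, 16L, 16L))
  pr <- predict(m, x)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(predict(m2, x), pr)
  ck <- readRDS(path)
  expect_identical(ck$seed, m$cfg$seed)
  expect_identical(ck$cfg$depths, m$cfg$depths)
  expect_error(load_checkpoint(path, hswin3d_config(embed_dim = 32L)),
               "mismatch on 'embed_dim'")
  expect_error(load_checkpoint(tempfile()), "checkpoint not found")
})

test_that("shifted-window attention obeys the wrapped-pair mask (brute-force oracle)", {
  grid <- c(4L, 4L, 4L)
  win <- c(2L, 2L, 2L)
  wp <- fosmapr:::window_plan(grid, win)
  expect_true(wp$can_shift)
  N <- 64L; H <- 2L; dh <- 3L; C <- H * dh
  set.seed(31)
  Q <- matrix(rnorm(N * C), N, C)
  K <- matrix(rnorm(N * C), N, C)
  V <- matrix(rnorm(N * C), N, C)
  scale <- 1 / sqrt(dh)
  Qc <- fosmapr:::to_cube(Q, wp$perm_s, 1L, N, wp$ws, wp$nwin, dh, H)
  Kc <- fosmapr:::to_cube(K, wp$perm_s, 1L, N, wp$ws, wp$nwin, dh, H)
  Vc <- fosmapr:::to_cube(V, wp$perm_s, 1L, N, wp$ws, wp$nwin, dh, H)
  res <- fosmapr:::attn_forward_cpp(Qc, Kc, Vc, scale,
                                    array(0, c(wp$ws, wp$ws, H)), wp$mask,
                                    wp$nwin, 1L)
  got <- fosmapr:::from_cube(res$out, wp$perm_s, 1L, N, wp$ws, wp$nwin, dh, H)
  # oracle: token p may attend to q iff both land in the same window of the
  # cyclically shifted grid AND share the per-axis pre-shift segment
  coords <- as.matrix(expand.grid(z = 0:3, y = 0:3, x = 0:3))
  wid <- function(c_) ((c_ - 1) %% 4) %/% 2          # shift = 1, window = 2
  seg <- function(c_) ifelse(c_ < 2, 0L, ifelse(c_ < 3, 1L, 2L))
  want <- matrix(0, N, C)
  for (i in 1:N) {
    ok <- rep(TRUE, N)
    for (a in 1:3)
      ok <- ok & wid(coords[, a]) == wid(coords[i, a]) &
        seg(coords[, a]) == seg(coords[i, a])
    js <- which(ok)
    for (h in 1:H) {
      cols <- (h - 1) * dh + 1:dh
      sc <- as.numeric(Q[i, cols] %*% t(K[js, cols, drop = FALSE])) * scale
      w <- exp(sc - max(sc)); w <- w / sum(w)
      want[i, cols] <- as.numeric(w %*% V[js, cols, drop = FALSE])
    }
  }
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_model_cfg()
  m <- build_model(cfg)
  set.seed(55)
  xs <- list(array(runif(16^3), c(16L, 16L, 16L)))
  y <- rbinom(16^3, 1, 0.2)
  fw <- fosmapr:::hswin_forward(m, xs, train = TRUE)
  ls <- fosmapr:::seg_loss(fw$logits, y, 1L, 16^3)
  gr <- fosmapr:::hswin_backward(m, ls$dlogits, fw$cache)
  loss_of <- function() {
    f <- fosmapr:::hswin_forward(m, xs, train = FALSE)
    fosmapr:::seg_loss(f$logits, y, 1L, 16^3)$loss
  }
  for (nm in c("enc1.b1.qkv_w", "enc3.b1.fc1_w", "merge1.w", "dec2.fuse_w",
               "front.conv1.w", "head.w")) {
    idx <- sample(length(m$params[[nm]]), 2)
    for (i in idx) {
      eps <- 1e-5
      p0 <- m$params[[nm]][i]
      m$params[[nm]][i] <- p0 + eps; lp <- loss_of()
      m$params[[nm]][i] <- p0 - eps; lm <- loss_of()
      m$params[[nm]][i] <- p0
      num <- (lp - lm) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 5e-3,
                   info = sprintf("%s[%d]", nm, i))
    }
  }
})

test_that("the single-precision core agrees with the double-precision reference", {
  cfg <- tiny_model_cfg()
  m <- build_model(cfg)
  set.seed(77)
  xs <- lapply(1:2, function(i) array(runif(16^3), c(16L, 16L, 16L)))
  y <- rbinom(2 * 16^3, 1, 0.1)
  fwR <- fosmapr:::hswin_forward(m, xs, train = TRUE)
  lsR <- fosmapr:::seg_loss(fwR$logits, y, 2L, 16^3)
  grR <- fosmapr:::hswin_backward(m, lsR$dlogits, fwR$cache)
  fast <- fosmapr:::fast_step(m, xs, y)
  expect_equal(fast$loss, lsR$loss, tolerance = 1e-5)
  logC <- fosmapr:::fast_forward(m, xs)
  expect_lt(max(abs(logC - fwR$logits)), 1e-4)
  for (nm in names(grR)) {
    a <- as.numeric(grR[[nm]]); b <- as.numeric(fast$grads[[nm]])
    expect_lt(max(abs(a - b)) / (max(abs(a)) + 1e-6), 1e-3)
  }
})

test_that("training is reproducible and its loss decreases", {
  set.seed(91)
  pairs <- lapply(1:6, function(i) {
    img <- array(runif(16^3, 0, 0.2), c(16L, 16L, 16L))
    msk <- array(0, c(16L, 16L, 16L))
    msk[4:8, 4:8, 4:8] <- 1
    img[4:8, 4:8, 4:8] <- img[4:8, 4:8, 4:8] + 0.8
    list(id = i, image = img, mask = msk)
  })
  run_once <- function() {
    m <- build_model(tiny_model_cfg())
    list(rep = train_model(m, pairs, epochs = 3L, lr = 1e-3, batch_size = 2L,
                           val_frac = 0.2, seed = 13L), model = m)
  }
  r1 <- run_once()
  r2 <- run_once()
  expect_identical(r1$rep$history$loss[1], r2$rep$history$loss[1])
  expect_identical(r1$rep$history, r2$rep$history)
  expect_lt(r1$rep$history$loss[3], r1$rep$history$loss[1])
  expect_identical(r1$rep$n_train + r1$rep$n_val, 6L)
})
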