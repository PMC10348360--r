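test_that("input embedding concatenates the two token channels", {
  cfg <- tiny_cfg()
  P <- init_encoder_params(cfg)
  va <- atom_vocab(); vn <- nmr_vocab()
  tp <- list(atom_ids = c(va$id[["<G>"]], va$id[["C"]], va$id[["C"]]),
             nmr_ids = c(vn$id[["<G>"]], vn$id[["ppm15"]], vn$id[["ppm15"]]))
  z0 <- embed_inputs(tp, P, cfg)
  expect_equal(ncol(z0), cfg$d_model)
  # identical (atom, nmr) pairs -> identical rows (no positional encoding)
  expect_equal(z0[2, ], z0[3, ])
  # changing only the NMR token changes only the second half
  tp2 <- tp; tp2$nmr_ids[3] <- vn$id[["ppm40"]]
  z1 <- embed_inputs(tp2, P, cfg)
  half <- cfg$d_model / 2
  expect_equal(z1[3, seq_len(half)], z0[3, seq_len(half)])
  expect_false(all(z1[3, -seq_len(half)] == z0[3, -seq_len(half)]))
})

test_that("the distance encoder is equivariant, maskable and identity-initialisable", {
  cfg <- tiny_cfg()
  P <- init_encoder_params(cfg)
  feat <- tiny_feats()[[4]]
  Draw <- feat$channels$Draw
  np1 <- nrow(Draw)
  pm <- rep(1, np1)
  D <- distance_encoder(Draw, pm, P, cfg)
  expect_true(all(D[1, ] == 0) && all(D[, 1] == 0))

  # permuting atoms permutes D consistently
  perm <- c(1L, 1L + sample(np1 - 1L))
  Dp <- distance_encoder(Draw[perm, perm], pm, P, cfg)
  expect_equal(Dp, D[perm, perm], tolerance = 1e-10)

  # positions masked out are exactly zero
  pm2 <- pm; pm2[np1] <- 0
  D2 <- distance_encoder(Draw, pm2, P, cfg)
  expect_true(all(D2[np1, ] == 0) && all(D2[, np1] == 0))
  expect_error(distance_encoder(Draw, rep(0, np1), P, cfg), "padded")

  # identity initialisation reproduces Draw
  Pid <- distance_encoder_identity(P, cfg)
  Did <- distance_encoder(Draw, pm, Pid, cfg)
  expect_equal(Did, Draw, tolerance = 1e-12)
})

test_that("modified attention reduces to plain softmax attention when unbiased", {
  cfg1 <- encoder_config(n_layers = 1L, d_model = 16L, n_heads = 1L,
                         lambda_b = 0, init_seed = 5L)
  P1 <- init_encoder_params(cfg1)
  set.seed(2)
  z <- matrix(rnorm(4 * 16), 4, 16)
  ch <- list(M = matrix(1, 4, 4), Bnorm = matrix(0, 4, 4),
             Draw = matrix(0, 4, 4), pad_mask = rep(1, 4), ablation = "none")
  out <- modified_attention(z, ch, P1, cfg1, layer = 1L, D = matrix(0, 4, 4))

  # five-line brute-force attention oracle
  Q <- z %*% P1$l1_Wq + matrix(P1$l1_bq, 4, 16, byrow = TRUE)
  K <- z %*% P1$l1_Wk + matrix(P1$l1_bk, 4, 16, byrow = TRUE)
  S <- Q %*% t(K) / sqrt(16)
  A <- exp(S - apply(S, 1, max)); A <- A / rowSums(A)
  expect_lt(max(abs(out$attn[[1]] - A)), 1e-6)
  expect_equal(rowSums(A), rep(1, 4), tolerance = 1e-12)

  # element-wise gating: a zeroed pair kills the score when lambda = 0, D = 0
  chz <- ch; chz$M[2, 3] <- chz$M[3, 2] <- 0
  outz <- modified_attention(z, chz, P1, cfg1, layer = 1L, D = matrix(0, 4, 4))
  expect_equal(outz$attn[[1]][2, 3], 0)

  # the full bias algebra against a dense-loop oracle, multi-head
  cfg2 <- encoder_config(n_layers = 1L, d_model = 16L, n_heads = 2L,
                         lambda_b = 0.2, init_seed = 6L)
  P2 <- init_encoder_params(cfg2)
  M <- matrix(c(1, 1, 0, 1, 1, 1, 0, 1, 1), 3, 3)
  Bn <- matrix(c(0, .5, 0, .5, 0, 1, 0, 1, 0), 3, 3)
  Dm <- matrix(rnorm(9, sd = 0.1), 3, 3)
  z3 <- matrix(rnorm(3 * 16), 3, 16)
  ch3 <- list(M = M, Bnorm = Bn, Draw = Dm, pad_mask = rep(1, 3), ablation = "none")
  out3 <- modified_attention(z3, ch3, P2, cfg2, layer = 1L, D = Dm)
  for (h in 1:2) {
    idx <- ((h - 1) * 8 + 1):(h * 8)
    Qh <- (z3 %*% P2$l1_Wq + matrix(P2$l1_bq, 3, 16, byrow = TRUE))[, idx]
    Kh <- (z3 %*% P2$l1_Wk + matrix(P2$l1_bk, 3, 16, byrow = TRUE))[, idx]
    S <- Qh %*% t(Kh) / sqrt(8)
    A <- exp(S - apply(S, 1, max)); A <- A / rowSums(A)
    A3d <- A * M + 0.2 * Bn + Dm
    expect_lt(max(abs(out3$attn[[h]] - A3d)), 1e-6)
  }
})

test_that("increasing lambda strictly increases A2d at bonded positions", {
  feat <- tiny_feats()[[1]]
  z <- matrix(rnorm(4 * 32, sd = 0.5), 4, 32)
  res <- lapply(c(0.2, 0.5), function(lam) {
    cfg <- encoder_config(n_layers = 1L, d_model = 32L, n_heads = 2L,
                          lambda_b = lam, init_seed = 4L)
    P <- init_encoder_params(cfg)
    modified_attention(z, feat$channels, P, cfg, layer = 1L,
                       D = matrix(0, 4, 4))$attn[[1]]
  })
  bonded <- which(feat$channels$Bnorm > 0, arr.ind = TRUE)
  expect_true(all(res[[2]][bonded] > res[[1]][bonded]))
})

test_that("the encoder is permutation-equivariant with an invariant global node", {
  cfg <- tiny_cfg()
  P <- init_encoder_params(cfg)
  feat <- tiny_feats()[[2]]
  st <- encode(feat$tp, feat$channels, P, cfg)
  expect_equal(dim(st$r), c(feat$mol$n_atoms + 1L, cfg$d_model))

  set.seed(8)
  for (rep in 1:3) {
    perm <- c(1L, 1L + sample(feat$mol$n_atoms))
    tpp <- feat$tp
    tpp$atom_ids <- feat$tp$atom_ids[perm]
    tpp$nmr_ids <- feat$tp$nmr_ids[perm]
    chp <- feat$channels
    for (nm in c("B", "Bnorm", "M", "Draw")) chp[[nm]] <- feat$channels[[nm]][perm, perm]
    stp <- encode(tpp, chp, P, cfg)
    expect_lt(max(abs(stp$r - st$r[perm, ])), 1e-5)
    expect_lt(max(abs(stp$r[1, ] - st$r[1, ])), 1e-5)
  }

  # eval-mode forward passes are identical (dropout off)
  st2 <- encode(feat$tp, feat$channels, P, cfg)
  expect_identical(st$r, st2$r)
})

test_that("checkpoints round-trip through the versioned archive", {
  cfg <- tiny_cfg()
  ck <- list(params = init_encoder_params(cfg), heads = init_ssl_heads(cfg),
             cfg = cfg, ssl_opts = ssl_options(), ablation = "none")
  path <- tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, ck$params)
  saveRDS(list(a = 1), path)
  expect_error(load_checkpoint(path), "format")
})
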