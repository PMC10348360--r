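test_that("metrics match reference implementations on random toys", {
  skip_if_not_installed("pROC")
  set.seed(3)
  for (rep in 1:100) {
    y <- rnorm(20)
    p <- y + rnorm(20)
    expect_equal(rmse(y, p), sqrt(mean((y - p)^2)), tolerance = 1e-12)
    expect_equal(r_squared(y, p), 1 - sum((y - p)^2) / sum((y - mean(y))^2),
                 tolerance = 1e-12)
    lab <- rbinom(20, 1, 0.5)
    if (length(unique(lab)) < 2) next
    sc <- runif(20)
    ref <- suppressMessages(as.numeric(pROC::auc(lab, sc, direction = "<")))
    expect_equal(roc_auc(lab, sc), ref, tolerance = 1e-9)
  }
  expect_error(roc_auc(rep(1, 5), runif(5)), "single class")
})

test_that("scaffold split partitions with no scaffold spanning two splits", {
  pt <- generate_fixtures(100, seed = 6L)
  sp <- scaffold_split(pt, split_spec(seed = 2L))
  idx <- sort(c(sp$train, sp$valid, sp$test))
  expect_identical(idx, seq_len(100L))
  expect_length(intersect(sp$train, sp$valid), 0L)
  expect_length(intersect(sp$train, sp$test), 0L)
  keys <- vapply(pt$records$smiles, function(s)
    molbert:::murcko_scaffold_key(parse_smiles(s, canonicalize = FALSE)), "")
  for (k in unique(keys)) {
    grp <- which(keys == k)
    inside <- c(all(grp %in% sp$train), all(grp %in% sp$valid), all(grp %in% sp$test))
    expect_equal(sum(inside), 1L, info = k)
  }

  # ten molecules with ten distinct scaffolds -> 8 / 1 / 1
  ten <- data.frame(smiles = c("C1CCCCC1", "C1CCCC1", "C1CCC1", "C1CCNCC1",
                               "C1CCOC1", "c1ccccc1", "c1ccncc1", "c1ccoc1",
                               "c1ccsc1", "c1ccc2ccccc2c1"))
  sp10 <- scaffold_split(ten, split_spec())
  expect_equal(lengths(sp10), c(train = 8L, valid = 1L, test = 1L))

  # all one scaffold -> random fallback with a warning
  one <- data.frame(smiles = c("c1ccccc1", "Cc1ccccc1", "CCc1ccccc1"))
  expect_warning(spf <- scaffold_split(one, split_spec(seed = 1L)), "fallback|random")
  expect_equal(sort(unlist(spf)), 1:3, ignore_attr = TRUE)
})

test_that("pre-training reduces the loss deterministically", {
  cfg <- tiny_cfg(seed = 3L)
  smis <- generate_fixtures(8, seed = 12L)$records$smiles
  feats <- featurize_molecules(smis, cfg, seed = 2L)
  ck <- pretrain(smis, cfg, epochs = 3L, seed = 5L, feats = feats)
  expect_false(ck$diverged)
  expect_lt(tail(ck$history$L_total, 1), ck$history$L_total[1])
  expect_equal(names(ck$history),
               c("epoch", "L_A", "L_N", "L_B", "L_3D",
                 "sigma1", "sigma2", "sigma3", "sigma4", "L_total"))
  # bit-identical trajectory under the same seed
  ck2 <- pretrain(smis, cfg, epochs = 3L, seed = 5L, feats = feats)
  expect_identical(ck$history, ck2$history)
  expect_identical(ck$params, ck2$params)
  # a different seed gives a different trajectory
  ck3 <- pretrain(smis, cfg, epochs = 3L, seed = 6L, feats = feats)
  expect_false(identical(ck$history$L_total, ck3$history$L_total))
})

test_that("adam with zero learning rate leaves parameters bit-stable", {
  cfg <- tiny_cfg(seed = 4L)
  smis <- c("CCO", "CCC")
  feats <- featurize_molecules(smis, cfg, seed = 2L)
  p0 <- init_encoder_params(cfg)
  ck <- pretrain(smis, cfg, epochs = 2L, lr = 0, seed = 5L, feats = feats)
  expect_identical(ck$params, p0)
})

test_that("fine-tuning trains a head and predicts through the full pipeline", {
  cfg <- tiny_cfg(seed = 9L)
  pt <- generate_fixtures(40, seed = 13L)
  feats <- featurize_molecules(pt$records$smiles, cfg, seed = 3L)
  ck <- list(params = init_encoder_params(cfg), heads = init_ssl_heads(cfg),
             cfg = cfg, ssl_opts = ssl_options(), ablation = "none")
  res <- finetune(ck, pt, spec = split_spec(seed = 4L),
                  ft = finetune_config(epochs = 2L), seed = 7L, n_runs = 2L,
                  feats = feats)
  expect_equal(nrow(res$metrics), 2L)
  expect_true(all(c("rmse", "r2") %in% names(res$metrics)))
  expect_equal(nrow(res$summary), 2L)
  expect_true(all(is.finite(res$metrics$rmse)))

  # prediction: failures are flagged, the batch continues
  expect_warning(pr <- predict_molecules(res$model, c("CCO", "zz_bad", "CCN")),
                 "failed")
  expect_true(is.na(pr[2]))
  expect_true(all(is.finite(pr[c(1, 3)])))
})

test_that("binary fine-tuning yields probabilities and single-class splits error", {
  cfg <- tiny_cfg(seed = 10L)
  pt <- generate_fixtures(60, seed = 14L)
  # a separable binary label: contains any heteroatom
  has_het <- vapply(pt$records$smiles, function(s) {
    m <- parse_smiles(s, canonicalize = FALSE)
    as.numeric(any(m$atoms$element != "C"))
  }, 0)
  ptb <- list(records = data.frame(smiles = pt$records$smiles, cls = has_het),
              task_types = c(cls = "binary"))
  class(ptb) <- "property_table"
  feats <- featurize_molecules(ptb$records$smiles, cfg, seed = 3L)
  ck <- list(params = init_encoder_params(cfg), heads = init_ssl_heads(cfg),
             cfg = cfg, ssl_opts = ssl_options(), ablation = "none")
  res <- finetune(ck, ptb, spec = split_spec(method = "random", seed = 5L),
                  ft = finetune_config(epochs = 2L, pretrain_reg_weight = 0),
                  seed = 7L, feats = feats)
  expect_true(all(c("roc_auc") %in% names(res$metrics)))
  pr <- predict_molecules(res$model, c("CCO", "CCC"))
  expect_true(all(pr >= 0 & pr <= 1))

  ptc <- ptb; ptc$records$cls <- 1
  expect_error(
    suppressWarnings(finetune(ck, ptc, spec = split_spec(method = "random", seed = 5L),
                              feats = feats)),
    "single-class")
})
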