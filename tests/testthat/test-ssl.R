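test_that("reconstruction losses obey the cross-entropy closed forms", {
  cfg <- tiny_cfg()
  H <- init_ssl_heads(cfg)
  feat <- tiny_feats()[[4]]
  P <- init_encoder_params(cfg)
  st <- encode(feat$tp, feat$channels, P, cfg)
  cp <- corrupt_pair(feat$tp, seed = 5L)

  # uniform logits (zeroed head) -> log V for both vocabularies
  H0 <- H
  for (nm in c("atom_W1", "atom_b1", "atom_W2", "atom_b2",
               "nmr_W1", "nmr_b1", "nmr_W2", "nmr_b2")) H0[[nm]][] <- 0
  expect_equal(atom_recon_loss(st$r, cp$atom$plan, H0),
               log(length(atom_vocab()$tokens)), tolerance = 1e-12)
  expect_equal(nmr_recon_loss(st$r, cp$nmr$plan, H0),
               log(length(nmr_vocab()$tokens)), tolerance = 1e-12)

  # hand-rolled cross-entropy oracle on the same toy inputs
  pos <- cp$atom$plan$selected
  hidden <- pmax(st$r[pos, , drop = FALSE] %*% H$atom_W1 +
                 matrix(H$atom_b1, length(pos), ncol(H$atom_W1), byrow = TRUE), 0)
  logits <- hidden %*% H$atom_W2 +
    matrix(H$atom_b2, length(pos), ncol(H$atom_W2), byrow = TRUE)
  p <- exp(logits - apply(logits, 1, max)); p <- p / rowSums(p)
  ce <- -mean(log(p[cbind(seq_along(pos), cp$atom$plan$originals)]))
  expect_equal(atom_recon_loss(st$r, cp$atom$plan, H), ce, tolerance = 1e-7)

  # scoring only the <M> positions is also available
  expect_no_error(atom_recon_loss(st$r, cp$atom$plan, H, scored_actions = "mask_only"))
})

test_that("bond energy loss matches the symmetrised MSE oracle", {
  cfg <- tiny_cfg()
  H <- init_ssl_heads(cfg)
  P <- init_encoder_params(cfg)
  feat <- tiny_feats()[[4]]  # has three different bond types
  st <- encode(feat$tp, feat$channels, P, cfg)
  bonds <- feat$bonds
  Bn <- feat$channels$Bnorm

  mlp <- function(x) {
    h <- pmax(x %*% H$bond_W1 + matrix(H$bond_b1, nrow(x), ncol(H$bond_W1), byrow = TRUE), 0)
    h %*% H$bond_W2 + matrix(H$bond_b2, nrow(x), 1, byrow = TRUE)
  }
  q <- y <- numeric(nrow(bonds))
  for (r in seq_len(nrow(bonds))) {
    i <- bonds$i[r] + 1L; j <- bonds$j[r] + 1L
    q[r] <- (mlp(cbind(st$r[i, , drop = FALSE], st$r[j, , drop = FALSE])) +
             mlp(cbind(st$r[j, , drop = FALSE], st$r[i, , drop = FALSE]))) / 2
    y[r] <- Bn[i, j]
  }
  expect_equal(bond_energy_loss(st$r, Bn, bonds, H), mean((y - q)^2),
               tolerance = 1e-7)

  # constant predictor (zeroed weights, bias = mean target) -> variance
  H0 <- H; H0$bond_W1[] <- 0; H0$bond_W2[] <- 0; H0$bond_b1[] <- 0
  H0$bond_b2[] <- mean(y)
  expect_equal(bond_energy_loss(st$r, Bn, bonds, H0),
               mean((y - mean(y))^2), tolerance = 1e-12)

  # single atom: no bonds -> 0 with a warning
  single <- featurize_molecules("C", cfg, seed = 1L)[[1]]
  sts <- encode(single$tp, single$channels, P, cfg)
  expect_warning(l0 <- bond_energy_loss(sts$r, single$channels$Bnorm,
                                        single$bonds, H), "no bonds")
  expect_equal(l0, 0)
})

test_that("3D loss is zero at the true geometry and matches the brute-force oracle", {
  # with d_model = 3 and an identity projection, r' equals the coordinates
  m <- embed_conformer(parse_smiles("CC(N)=O"), 2L)
  gt <- geometry_targets(m)
  H3 <- list(coord_Wr = diag(3))
  r_true <- rbind(0, m$coords)
  expect_equal(l3d(r_true, gt, H3), 0, tolerance = 1e-12)

  # rigid motion of r' leaves the loss unchanged
  th <- 1.1
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  r_mov <- rbind(0, m$coords %*% R + matrix(c(5, -2, 1), m$n_atoms, 3, byrow = TRUE))
  expect_equal(l3d(r_mov, gt, H3), 0, tolerance = 1e-10)

  # distances are translation-invariant predictions
  rp <- matrix(rnorm(12), 4, 3)
  gt4 <- list(dist_pairs = cbind(t(combn(4, 2)), 0), angle_triples = matrix(0, 0, 4),
              torsion_quads = matrix(0, 0, 5), signed = FALSE)
  p1 <- geom_predictions(rp, gt4)
  p2 <- geom_predictions(rp + matrix(c(1, 2, 3), 4, 3, byrow = TRUE), gt4)
  expect_equal(p1$d, p2$d, tolerance = 1e-12)

  # brute-force oracle on a 4-atom toy with random projection
  cfg <- tiny_cfg()
  H <- init_ssl_heads(cfg)
  P <- init_encoder_params(cfg)
  chain <- embed_conformer(parse_smiles("CCCO"), 3L)
  gtc <- geometry_targets(chain)
  feat <- featurize_molecules(list(chain), cfg)[[1]]
  st <- encode(feat$tp, feat$channels, P, cfg)
  rp2 <- project_coords(st$r, H)
  pr <- geom_predictions(rp2, gtc)
  ref <- mean((pr$d - gtc$dist_pairs[, 3])^2) +
    mean((pr$theta - gtc$angle_triples[, 4])^2) +
    mean((pr$phi - gtc$torsion_quads[, 5])^2)
  expect_equal(l3d(st$r, gtc, H), ref, tolerance = 1e-7)

  # two-atom molecule: only the distance family contributes
  two <- featurize_molecules("CO", cfg, seed = 1L)[[1]]
  st2 <- encode(two$tp, two$channels, P, cfg)
  gt2 <- two$geometry
  expect_equal(nrow(gt2$angle_triples), 0L)
  rp3 <- project_coords(st2$r, H)
  dd <- molbert:::geom_distances(rp3, gt2$dist_pairs[, 1:2, drop = FALSE])
  expect_equal(l3d(st2$r, gt2, H), mean((dd - gt2$dist_pairs[, 3])^2),
               tolerance = 1e-10)
})

test_that("the uncertainty-weighted total behaves as the formula dictates", {
  L <- c(1.3, 0.7, 0.2, 2.1)
  # all sigmas 1: the log terms vanish and the total is the plain sum
  expect_equal(total_loss(L)$total, sum(L), tolerance = 1e-12)
  # doubling one component with sigma = 1 adds exactly that component
  L2 <- L; L2[1] <- 2 * L[1]
  expect_equal(total_loss(L2)$total - total_loss(L)$total, L[1], tolerance = 1e-12)

  # the implemented gradient vanishes at sigma_k^2 = 2 L_k
  ns <- asNamespace("molbert")
  tape <- ns$ad_tape()
  ls <- ns$ad_param(tape, matrix(0.5 * log(2 * L), 1))
  comps <- lapply(L, function(v) ns$ad_const(tape, matrix(v, 1, 1)))
  tot <- ns$total_loss_node(tape, ls, comps[[1]], comps[[2]], comps[[3]], comps[[4]])
  ns$ad_backward(tape, tot)
  expect_lt(max(abs(ls$grad)), 1e-6)
})
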