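test_that("tokenization prepends the global node and honours chiral tokens", {
  va <- atom_vocab()
  ids <- tokenize(parse_smiles("CCO"), vocab = va)
  expect_equal(va$tokens[ids], c("<G>", "C", "C", "O"))

  m1 <- parse_smiles("C[C@H](N)C(=O)O")
  m2 <- parse_smiles("C[C@@H](N)C(=O)O")
  t1 <- tokenize(m1, use_chiral_tokens = TRUE, va)
  t2 <- tokenize(m2, use_chiral_tokens = TRUE, va)
  expect_false(identical(t1, t2))
  expect_identical(tokenize(m1, FALSE, va), tokenize(m2, FALSE, va))

  # element outside the vocabulary -> <UNK> with a warning
  mx <- parse_smiles("CC")
  mx$atoms$element[2] <- "Se"
  expect_warning(tu <- tokenize(mx, vocab = va), "UNK")
  expect_equal(va$tokens[tu[3]], "<UNK>")
})

test_that("surrogate NMR shifts depend only on the radius-1 environment", {
  s <- surrogate_nmr(parse_smiles("CC"))
  expect_equal(s[1], s[2])
  s2 <- surrogate_nmr(parse_smiles("CC=O"))
  expect_false(s2[1] == s2[2])  # alkane vs carbonyl carbon

  # every environment in the fixture set has a non-default table entry
  tab <- read.csv(system.file("extdata", "nmr_environments.csv",
                              package = "molbert"), stringsAsFactors = FALSE)
  pt <- generate_fixtures(80, seed = 5L, include_chiral_pairs = TRUE)
  for (smi in pt$records$smiles) {
    m <- parse_smiles(smi, canonicalize = FALSE)
    bo <- molbert:::mol_bond_orders(m)
    for (a in seq_len(m$n_atoms)) {
      env <- molbert:::atom_environment(m, a, bo)
      expect_true(any(tab$element == m$atoms$element[a] & tab$environment == env),
                  info = paste(smi, env))
    }
  }

  # user override replaces values exactly
  m <- parse_smiles("CCO")
  ov <- data.frame(smiles = m$smiles, atom_index = 1L, value = 123.4)
  expect_equal(surrogate_nmr(m, ov)[2], 123.4)
})

test_that("NMR discretization bins, clamps and flags non-finite shifts", {
  vn <- nmr_vocab(bin_width = 1.0)
  expect_equal(vn$tokens[discretize_nmr(12.3, vn)], "ppm12")
  ids <- discretize_nmr(c(0.4, 0.6), vn)
  expect_equal(ids[1], ids[2])
  expect_equal(vn$tokens[ids[1]], "ppm0")
  expect_equal(vn$tokens[discretize_nmr(1e6, vn)], "ppm299")
  expect_equal(vn$tokens[discretize_nmr(-1e6, vn)], "ppm-50")
  expect_equal(vn$tokens[discretize_nmr(NaN, vn)], "<UNK>")
})

test_that("surrogate bond energies come from the packaged table", {
  tab <- read.csv(system.file("extdata", "bde_table.csv", package = "molbert"),
                  stringsAsFactors = FALSE)
  B <- surrogate_bde(parse_smiles("CC"))
  cc <- tab$bde_kj_mol[tab$elem_a == "C" & tab$elem_b == "C" & tab$order == 1]
  expect_equal(B[2, 3], cc)
  expect_equal(sum(B != 0), 2L)
  expect_true(isSymmetric(B))
  expect_true(all(diag(B) == 0))
  expect_true(all(B[1, ] == 0))

  m <- parse_smiles("CCO")
  ov <- data.frame(smiles = m$smiles, i = 0L, j = 1L, value = 999)
  Bo <- surrogate_bde(m, ov)
  expect_equal(Bo[2, 3], 999)
  expect_equal(Bo[3, 2], 999)
})

test_that("normalize_b min-maxes over bonded entries only", {
  B <- matrix(0, 4, 4)
  B[2, 3] <- B[3, 2] <- 300; B[3, 4] <- B[4, 3] <- 400; B[2, 4] <- B[4, 2] <- 500
  Bn <- normalize_b(B)
  expect_equal(Bn[2, 3], 0)
  expect_equal(Bn[3, 4], 0.5)
  expect_equal(Bn[2, 4], 1)
  expect_true(all(Bn >= 0 & Bn <= 1))

  # degenerate range: single bond type everywhere -> all bonded entries 1
  B1 <- surrogate_bde(parse_smiles("CCCC"))
  expect_message(Bn1 <- normalize_b(B1), "degenerate")
  expect_true(all(Bn1[B1 != 0] == 1))
  expect_error(normalize_b(matrix(0, 3, 3)), "non-zero")
})

test_that("binarize produces the adjacency mask with global connectivity", {
  B <- surrogate_bde(parse_smiles("CCO"))
  M <- binarize(B)
  expect_true(all(M %in% c(0, 1)))
  expect_true(isSymmetric(M))
  expect_true(all(diag(M) == 1))
  expect_true(all(M[1, ] == 1) && all(M[, 1] == 1))
  expect_equal(M[2, 3], 1); expect_equal(M[3, 4], 1)
  expect_equal(M[2, 4], 0)  # C and O not bonded in CCO

  # disconnected fragments: no cross-fragment 1s outside global row/col/diag
  Md <- binarize(surrogate_bde(parse_smiles("CC.CC")))
  expect_equal(Md[2:3, 4:5], matrix(0, 2, 2))

  # min-max sends the weakest bond to 0, so binarize(Bnorm) keeps a subset
  # of binarize(B)'s bonds (equality only in the degenerate all-equal case)
  Bn <- normalize_b(B)
  expect_true(all(binarize(Bn)[-1, -1] <= M[-1, -1]))
  expect_equal(sum(binarize(Bn)[-1, -1] < M[-1, -1]), 2L)  # the one C-C bond
})

test_that("distance matrix is exact, isometry-invariant and globally zeroed", {
  m <- parse_smiles("CC")
  m$coords <- rbind(c(0, 0, 0), c(0, 0, 1.5))
  D <- distance_matrix(m)
  expect_equal(D[2, 3], 1.5)
  expect_true(all(D[1, ] == 0) && all(D[, 1] == 0))
  expect_true(isSymmetric(D))

  # unit square: diagonals sqrt(2)
  sq <- parse_smiles("C1CCC1")
  sq$coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  Dsq <- distance_matrix(sq)
  expect_equal(Dsq[2, 4], sqrt(2))
  expect_equal(Dsq[3, 5], sqrt(2))

  # rigid motion leaves Draw unchanged
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  sq2 <- sq
  sq2$coords <- sq$coords %*% R + matrix(c(3, -1, 2), 4, 3, byrow = TRUE)
  expect_lt(max(abs(distance_matrix(sq2) - Dsq)), 1e-9)

  expect_error(distance_matrix(parse_smiles("CC")), "coordinates")
})

test_that("geometry targets match closed forms and the brute-force oracle", {
  tri <- parse_smiles("CCC")
  tri$coords <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))
  gt <- geometry_targets(tri)
  expect_equal(gt$angle_triples[1, "theta"], pi / 2, tolerance = 1e-12,
               ignore_attr = TRUE)

  chain <- parse_smiles("CCCC")
  chain$coords <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  gt4 <- geometry_targets(chain)
  expect_equal(gt4$torsion_quads[1, "phi"], pi, tolerance = 1e-12,
               ignore_attr = TRUE)

  # collinear triple -> exactly pi
  lin <- parse_smiles("CCC")
  lin$coords <- rbind(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0))
  expect_equal(geometry_targets(lin)$angle_triples[1, "theta"], pi,
               ignore_attr = TRUE)

  # 50 random embedded fixtures vs an independent vector-algebra oracle
  pt <- generate_fixtures(50, seed = 31L)
  worst <- 0
  for (k in seq_len(50)) {
    m <- embed_conformer(parse_smiles(pt$records$smiles[k], canonicalize = FALSE),
                         seed = k)
    gt <- geometry_targets(m)
    X <- m$coords
    for (r in seq_len(nrow(gt$angle_triples))) {
      tr <- gt$angle_triples[r, ]
      worst <- max(worst, abs(tr["theta"] -
        oracle_angle(X[tr["i"], ], X[tr["j"], ], X[tr["k"], ])))
    }
    for (r in seq_len(nrow(gt$torsion_quads))) {
      tq <- gt$torsion_quads[r, ]
      worst <- max(worst, abs(tq["phi"] -
        oracle_torsion(X[tq["i"], ], X[tq["j"], ], X[tq["k"], ], X[tq["l"], ])))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("enantiomer pairs share Draw and unsigned torsions, differing only in chiral tokens", {
  m1 <- embed_conformer(parse_smiles("C[C@H](N)C(=O)O"), seed = 3L)
  m2 <- embed_conformer(parse_smiles("C[C@@H](N)C(=O)O"), seed = 3L)
  expect_equal(distance_matrix(m1), distance_matrix(m2), tolerance = 1e-12)
  g1 <- geometry_targets(m1); g2 <- geometry_targets(m2)
  expect_equal(g1$torsion_quads[, "phi"], g2$torsion_quads[, "phi"],
               tolerance = 1e-12)
  # signed torsions expose the handedness the unsigned form hides
  s1 <- geometry_targets(m1, signed_torsions = TRUE)$torsion_quads[, "phi"]
  s2 <- geometry_targets(m2, signed_torsions = TRUE)$torsion_quads[, "phi"]
  expect_equal(s1, -s2, tolerance = 1e-12)
  expect_gt(max(abs(s1 - s2)), 0.1)
})
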