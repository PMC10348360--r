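## The four self-supervised pre-training losses and their uncertainty-
## weighted combination:
##
##   L = L_A/sigma1^2 + L_N/sigma2^2 + L_B/sigma3^2 + L_3D/sigma4^2
##       + log sigma1 + log sigma2 + log sigma3 + log sigma4
##
## L_A / L_N: mean cross-entropy reconstructing corrupted atom / NMR tokens;
## L_B: mean squared error predicting normalised bond energies from the two
## endpoint representations; L_3D: mean squared error on interatomic
## distances, bond angles and torsions recomputed from coordinates projected
## out of the token representations.  Component losses are averaged within
## each family so the total is molecule-size invariant; sigmas are learned
## as log(sigma) to stay positive.

#' Initialise the SSL head parameters
#'
#' Two-layer reconstruction heads for atoms and NMR bins, a two-layer bond
#' energy head over concatenated endpoint representations, the 3-column
#' coordinate projection, and the four log-sigma task weights (initialised
#' at 0, i.e. sigma = 1).
#'
#' @param cfg an [encoder_config()].
#' @param vocab_atoms,vocab_nmr vocabularies sizing the output layers.
#' @param seed init seed.
#' @return named list of parameter matrices.
#' @export
init_ssl_heads <- function(cfg, vocab_atoms = atom_vocab(),
                           vocab_nmr = nmr_vocab(), seed = 2L) {
  d <- cfg$d_model
  with_local_seed(seed, list(
    atom_W1 = rmat(d, d, 0.05), atom_b1 = matrix(0, 1, d),
    atom_W2 = rmat(d, length(vocab_atoms$tokens), 0.05),
    atom_b2 = matrix(0, 1, length(vocab_atoms$tokens)),
    nmr_W1 = rmat(d, d, 0.05), nmr_b1 = matrix(0, 1, d),
    nmr_W2 = rmat(d, length(vocab_nmr$tokens), 0.05),
    nmr_b2 = matrix(0, 1, length(vocab_nmr$tokens)),
    bond_W1 = rmat(2L * d, d, 0.05), bond_b1 = matrix(0, 1, d),
    bond_W2 = rmat(d, 1L, 0.05), bond_b2 = matrix(0, 1, 1),
    coord_Wr = rmat(d, 3L, 0.05),
    log_sigma = matrix(0, 1, 4)
  ))
}

mlp2_node <- function(tape, r, W1, b1, W2, b2) {
  ad_add_rowvec(ad_mm(ad_relu(ad_add_rowvec(ad_mm(r, W1), b1)), W2), b2)
}

## positions scored by the reconstruction losses
scored_positions <- function(plan, scored_actions = "all") {
  if (identical(scored_actions, "all")) plan$selected
  else plan$selected[plan$action == "mask"]
}

loss_recon_node <- function(tape, Hn, prefix, r, plan, scored_actions = "all") {
  pos <- scored_positions(plan, scored_actions)
  if (!length(pos)) {
    warning("reconstruction loss: no scored positions; loss defined as 0")
    return(ad_const(tape, matrix(0, 1, 1)))
  }
  labels <- plan$originals[match(pos, plan$selected)]
  logits <- mlp2_node(tape, ad_rows(r, pos),
                      Hn[[paste0(prefix, "_W1")]], Hn[[paste0(prefix, "_b1")]],
                      Hn[[paste0(prefix, "_W2")]], Hn[[paste0(prefix, "_b2")]])
  ad_cross_entropy(logits, labels)
}

#' Atom-token reconstruction loss L_A
#'
#' Mean cross-entropy over the corrupted positions (all corruption actions
#' by default, including "keep"; set `scored_actions = "mask_only"` to score
#' only the `<M>` positions).
#'
#' @param r (n+1) x d_model representations from [encode()].
#' @param plan the `corruption_plan` of the atom sequence.
#' @param heads SSL head parameters ([init_ssl_heads()]).
#' @param scored_actions `"all"` or `"mask_only"`.
#' @return non-negative scalar.
#' @export
atom_recon_loss <- function(r, plan, heads, scored_actions = "all") {
  tape <- ad_tape()
  Hn <- ad_wrap_params(tape, heads)
  loss_recon_node(tape, Hn, "atom", ad_const(tape, r), plan, scored_actions)$val[1, 1]
}

#' NMR-token reconstruction loss L_N
#' @inheritParams atom_recon_loss
#' @export
nmr_recon_loss <- function(r, plan, heads, scored_actions = "all") {
  tape <- ad_tape()
  Hn <- ad_wrap_params(tape, heads)
  loss_recon_node(tape, Hn, "nmr", ad_const(tape, r), plan, scored_actions)$val[1, 1]
}

loss_bond_node <- function(tape, Hn, r, Bnorm, bonds, aggregate = "mean") {
  if (!nrow(bonds)) {
    warning("bond_energy_loss: no bonds; loss defined as 0")
    return(ad_const(tape, matrix(0, 1, 1)))
  }
  i <- bonds$i + 1L; j <- bonds$j + 1L   # shift past the global node
  y <- Bnorm[cbind(i, j)]
  ri <- ad_rows(r, i); rj <- ad_rows(r, j)
  qf <- mlp2_node(tape, ad_cbind(ri, rj), Hn$bond_W1, Hn$bond_b1, Hn$bond_W2, Hn$bond_b2)
  qr <- mlp2_node(tape, ad_cbind(rj, ri), Hn$bond_W1, Hn$bond_b1, Hn$bond_W2, Hn$bond_b2)
  q <- ad_scale(ad_add(qf, qr), 0.5)
  se <- ad_square(ad_add_const(q, -matrix(y, ncol = 1L)))
  if (identical(aggregate, "mean")) ad_mean(se) else ad_sum(se)
}

#' Bond-energy regression loss L_B
#'
#' Predicts the normalised bond energy of each bonded pair from the two
#' endpoint representations through a two-layer head; the unordered pair is
#' counted once, with the two concatenation orders averaged so the
#' prediction is symmetric.  Averaged over bonds by default
#' (`aggregate = "sum"` gives the raw sum).
#'
#' @param r (n+1) x d_model representations.
#' @param Bnorm normalised bond-energy matrix (targets).
#' @param bonds bond table of the molecule (atom indices, 1-based).
#' @param heads SSL head parameters.
#' @param aggregate `"mean"` (default) or `"sum"`.
#' @return non-negative scalar.
#' @export
bond_energy_loss <- function(r, Bnorm, bonds, heads, aggregate = "mean") {
  tape <- ad_tape()
  Hn <- ad_wrap_params(tape, heads)
  loss_bond_node(tape, Hn, ad_const(tape, r), Bnorm, bonds, aggregate)$val[1, 1]
}

#' Project token representations to 3D coordinates
#'
#' `r' = r W_r`, global node excluded: one predicted coordinate triple per
#' heavy atom.
#'
#' @param r (n+1) x d_model representations.
#' @param heads SSL head parameters.
#' @return n x 3 matrix.
#' @export
project_coords <- function(r, heads) {
  r[-1L, , drop = FALSE] %*% heads$coord_Wr
}

#' Geometry predictions from projected coordinates
#'
#' Computes predicted distances, bond angles and torsions from `r'` with the
#' same geometry kernels used to build the targets, so the two sides agree
#' by construction.
#'
#' @param rprime n x 3 projected coordinates.
#' @param gt a `geometry_targets` giving the index lists.
#' @return list with `d`, `theta`, `phi` numeric vectors.
#' @export
geom_predictions <- function(rprime, gt) {
  list(
    d = if (nrow(gt$dist_pairs)) geom_distances(rprime, gt$dist_pairs[, 1:2, drop = FALSE]) else numeric(0),
    theta = if (nrow(gt$angle_triples)) geom_angles(rprime, gt$angle_triples[, 1:3, drop = FALSE]) else numeric(0),
    phi = if (nrow(gt$torsion_quads)) geom_torsions(rprime, gt$torsion_quads[, 1:4, drop = FALSE],
                                                    signed = isTRUE(gt$signed)) else numeric(0)
  )
}

## node-level geometric quantities from a coordinate node (n x 3)
geom_dist_node <- function(tape, rp, pairs) {
  dd <- ad_sub(ad_rows(rp, pairs[, 1]), ad_rows(rp, pairs[, 2]))
  ad_sqrt(ad_rowsums(ad_square(dd)))
}

geom_angle_node <- function(tape, rp, triples) {
  u <- ad_sub(ad_rows(rp, triples[, 1]), ad_rows(rp, triples[, 2]))
  v <- ad_sub(ad_rows(rp, triples[, 3]), ad_rows(rp, triples[, 2]))
  cr <- ad_cross3(u, v)
  ad_atan2(ad_sqrt(ad_rowsums(ad_square(cr))), ad_rowsums(ad_mul(u, v)))
}

geom_torsion_node <- function(tape, rp, quads) {
  b1 <- ad_sub(ad_rows(rp, quads[, 2]), ad_rows(rp, quads[, 1]))
  b2 <- ad_sub(ad_rows(rp, quads[, 3]), ad_rows(rp, quads[, 2]))
  b3 <- ad_sub(ad_rows(rp, quads[, 4]), ad_rows(rp, quads[, 3]))
  na_ <- ad_cross3(b1, b2)
  nb_ <- ad_cross3(b2, b3)
  den <- ad_mul(ad_sqrt(ad_rowsums(ad_square(na_))), ad_sqrt(ad_rowsums(ad_square(nb_))))
  ad_acos(ad_div(ad_rowsums(ad_mul(na_, nb_)), den))
}

loss_3d_node <- function(tape, Hn, r, gt, aggregate = "mean") {
  rp <- ad_mm(ad_rows(r, 2:nrow(r$val)), Hn$coord_Wr)
  agg <- if (identical(aggregate, "mean")) ad_mean else ad_sum
  total <- NULL
  addterm <- function(total, term) if (is.null(total)) term else ad_add(total, term)
  if (nrow(gt$dist_pairs)) {
    dhat <- geom_dist_node(tape, rp, gt$dist_pairs[, 1:2, drop = FALSE])
    total <- addterm(total, agg(ad_square(ad_add_const(dhat, -matrix(gt$dist_pairs[, 3], ncol = 1L)))))
  }
  if (nrow(gt$angle_triples)) {
    th <- geom_angle_node(tape, rp, gt$angle_triples[, 1:3, drop = FALSE])
    total <- addterm(total, agg(ad_square(ad_add_const(th, -matrix(gt$angle_triples[, 4], ncol = 1L)))))
  }
  if (nrow(gt$torsion_quads)) {
    ph <- geom_torsion_node(tape, rp, gt$torsion_quads[, 1:4, drop = FALSE])
    total <- addterm(total, agg(ad_square(ad_add_const(ph, -matrix(gt$torsion_quads[, 5], ncol = 1L)))))
  }
  if (is.null(total)) ad_const(tape, matrix(0, 1, 1)) else total
}

#' 3D reconstruction loss L_3D
#'
#' Mean squared error per quantity family (distances in squared Angstrom,
#' angles and torsions in squared radians), summed across the families.
#' Families without entries (fewer than three or four atoms) contribute 0.
#'
#' @param r (n+1) x d_model representations.
#' @param gt a `geometry_targets`.
#' @param heads SSL head parameters (the coordinate projection).
#' @param aggregate `"mean"` (default) or `"sum"` within each family.
#' @return non-negative scalar.
#' @export
l3d <- function(r, gt, heads, aggregate = "mean") {
  tape <- ad_tape()
  Hn <- ad_wrap_params(tape, heads)
  loss_3d_node(tape, Hn, ad_const(tape, r), gt, aggregate)$val[1, 1]
}

total_loss_node <- function(tape, log_sigma, L_A, L_N, L_B, L_3D) {
  comps <- list(L_A, L_N, L_B, L_3D)
  total <- NULL
  for (k in 1:4) {
    s <- ad_cols(log_sigma, k)
    w <- ad_exp(ad_scale(s, -2))
    term <- ad_add(ad_mul(w, comps[[k]]), s)
    total <- if (is.null(total)) term else ad_add(total, term)
  }
  total
}

#' Uncertainty-weighted total pre-training loss
#'
#' `L = sum_k L_k / sigma_k^2 + sum_k log sigma_k` with learnable sigmas
#' (passed as log sigma).  At sigma = 1 the total is the plain sum of the
#' components; for fixed components the minimiser over sigma satisfies
#' `sigma_k^2 = 2 L_k`.
#'
#' @param losses numeric vector (L_A, L_N, L_B, L_3D).
#' @param log_sigma numeric vector of the four log sigmas (default all 0).
#' @return list with `total` and the `weights` (1/sigma_k^2) applied.
#' @export
total_loss <- function(losses, log_sigma = rep(0, 4)) {
  stopifnot(length(losses) == 4L, length(log_sigma) == 4L)
  w <- exp(-2 * log_sigma)
  list(total = sum(w * losses) + sum(log_sigma), weights = w)
}

## full SSL objective on a tape (used by pretrain and as the fine-tuning
## regulariser); feat is one molecule's cached featurisation
ssl_objective_node <- function(tape, Pn, Hn, feat, cfg, opts, step_seed,
                               training = TRUE) {
  cp <- corrupt_pair(feat$tp, opts$select_rate, opts$split, step_seed)
  fw <- encode_forward(tape, Pn, cp$atom$ids, cp$nmr$ids, feat$channels, cfg,
                       training = training, dseed = derive_seed(step_seed, 77L))
  r <- fw$r
  ablation <- feat$channels$ablation %||% "none"
  zero <- function() ad_const(tape, matrix(0, 1, 1))
  L_A <- loss_recon_node(tape, Hn, "atom", r, cp$atom$plan, opts$scored_actions)
  L_N <- if (identical(ablation, "nochem")) zero()
         else loss_recon_node(tape, Hn, "nmr", r, cp$nmr$plan, opts$scored_actions)
  L_B <- if (identical(ablation, "nochem")) zero()
         else loss_bond_node(tape, Hn, r, feat$channels$Bnorm, feat$bonds, opts$aggregate)
  L_3D <- if (identical(ablation, "no3d")) zero()
          else loss_3d_node(tape, Hn, r, feat$geometry, opts$aggregate)
  total <- total_loss_node(tape, Hn$log_sigma, L_A, L_N, L_B, L_3D)
  list(total = total, parts = c(L_A = L_A$val[1, 1], L_N = L_N$val[1, 1],
                                L_B = L_B$val[1, 1], L_3D = L_3D$val[1, 1]),
       plan = cp, r = r)
}

#' Default SSL options
#'
#' @param select_rate fraction of positions corrupted per sequence
#'   (default 0.2).
#' @param split (mask, random, keep) probabilities within the selection
#'   (default c(0.8, 0.1, 0.1)).
#' @param scored_actions which corrupted positions the reconstruction
#'   losses score (`"all"` or `"mask_only"`).
#' @param aggregate `"mean"` or `"sum"` within each loss family.
#' @export
ssl_options <- function(select_rate = 0.2, split = c(0.8, 0.1, 0.1),
                        scored_actions = "all", aggregate = "mean") {
  list(select_rate = select_rate, split = split,
       scored_actions = scored_actions, aggregate = aggregate)
}
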