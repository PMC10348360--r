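## The molecular transformer encoder: paired token embeddings, a learned
## distance-fraction channel D, and a stack of modified self-attention
## layers in which the raw attention matrix A is gated by the adjacency
## mask M, biased by the normalised bond-energy matrix Bnorm (weight
## lambda), and shifted additively by D:
##
##   A    = softmax(Q K' / sqrt(d_k))
##   A2d  = A (*) M + lambda * Bnorm
##   A3d  = A2d + D
##   out  = A3d V
##
## There are no positional encodings: token order carries no information, so
## atom representations are permutation-equivariant and the global-node
## representation permutation-invariant, which the tests assert.

#' Encoder configuration
#'
#' @param n_layers number of transformer layers (default 6).
#' @param d_model token representation width (default 512; must be even and
#'   divisible by `n_heads`).
#' @param n_heads attention heads (default 8; `n_heads = 1` recovers the
#'   single-head algebra exactly).
#' @param lambda_b balance weight on the bond-energy bias (default 0.2).
#' @param dropout dropout rate (default 0.1).
#' @param ffn_mult feed-forward width multiplier (default 4).
#' @param max_atoms upper bound on heavy atoms per molecule (default 64).
#' @param dist_centers Gaussian basis centres (Angstrom) for the distance
#'   encoder; the raw distance itself is always the first basis feature.
#' @param init_seed seed for parameter initialisation.
#' @param use_chiral_tokens give stereocentres distinct atom tokens.
#' @return an `encoder_config` list.
#' @export
encoder_config <- function(n_layers = 6L, d_model = 512L, n_heads = 8L,
                           lambda_b = 0.2, dropout = 0.1, ffn_mult = 4L,
                           max_atoms = 64L,
                           dist_centers = c(1, 2, 3, 4, 6, 8),
                           init_seed = 1L, use_chiral_tokens = FALSE) {
  stopifnot(d_model %% 2L == 0L, d_model %% n_heads == 0L, lambda_b >= 0,
            dropout >= 0, dropout < 1, n_layers >= 1L)
  cfg <- list(n_layers = as.integer(n_layers), d_model = as.integer(d_model),
              n_heads = as.integer(n_heads), d_k = as.integer(d_model / n_heads),
              lambda_b = lambda_b, dropout = dropout,
              ffn_mult = as.integer(ffn_mult), max_atoms = as.integer(max_atoms),
              dist_centers = dist_centers, dist_k = 2L + length(dist_centers),
              init_seed = as.integer(init_seed),
              use_chiral_tokens = isTRUE(use_chiral_tokens))
  class(cfg) <- "encoder_config"
  cfg
}

## seeded scaled-normal init
rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

transformer_layer_params <- function(d, ffn, sd) {
  list(Wq = rmat(d, d, sd), bq = matrix(0, 1, d),
       Wk = rmat(d, d, sd), bk = matrix(0, 1, d),
       Wv = rmat(d, d, sd), bv = matrix(0, 1, d),
       Wo = rmat(d, d, sd), bo = matrix(0, 1, d),
       ln1_g = matrix(1, 1, d), ln1_b = matrix(0, 1, d),
       W1 = rmat(d, ffn, sd), b1 = matrix(0, 1, ffn),
       W2 = rmat(ffn, d, sd), b2 = matrix(0, 1, d),
       ln2_g = matrix(1, 1, d), ln2_b = matrix(0, 1, d))
}

#' Initialise encoder parameters
#'
#' Seeded scaled-normal initialisation for the two embedding tables, the
#' distance encoder and all transformer layers.
#'
#' @param cfg an [encoder_config()].
#' @param vocab_atoms,vocab_nmr vocabularies sizing the embedding tables.
#' @return named list of parameter matrices.
#' @export
init_encoder_params <- function(cfg, vocab_atoms = atom_vocab(),
                                vocab_nmr = nmr_vocab()) {
  d <- cfg$d_model
  sd <- 0.05
  with_local_seed(cfg$init_seed, {
    P <- list(
      emb_atom = rmat(length(vocab_atoms$tokens), d / 2L, 0.02),
      emb_nmr = rmat(length(vocab_nmr$tokens), d / 2L, 0.02),
      dist_We = rmat(cfg$dist_k, d, sd),
      dist_wd = rmat(cfg$dist_k, 1L, sd),
      dist_va = rmat(d, 1L, sd),
      dist_vb = rmat(d, 1L, sd)
    )
    dl <- transformer_layer_params(d, cfg$ffn_mult * d, sd)
    names(dl) <- paste0("dist_", names(dl))
    P <- c(P, dl)
    for (l in seq_len(cfg$n_layers)) {
      ll <- transformer_layer_params(d, cfg$ffn_mult * d, sd)
      names(ll) <- paste0("l", l, "_", names(ll))
      P <- c(P, ll)
    }
    P
  })
}

## distance basis features for every ordered pair, rows in column-major
## (n+1)^2 order so a length-(n+1)^2 vector reshapes back to the matrix
dist_basis <- function(Draw, centers) {
  v <- as.vector(Draw)
  out <- cbind(v, exp(-v), sapply(centers, function(c0) exp(-(v - c0)^2 / 2)))
  dimnames(out) <- NULL
  out
}

## dropout as a constant scale mask drawn from a derived seed
drop_mask <- function(dims, p, seed) {
  keep <- with_local_seed(seed, stats::runif(prod(dims)) >= p)
  matrix(keep / (1 - p), dims[1L], dims[2L])
}

## one standard (unmodified) transformer encoder layer used inside the
## distance encoder
plain_layer_node <- function(tape, Pn, pre, h, mask_rows, cfg, training, dseed) {
  d <- cfg$d_model
  q <- ad_add_rowvec(ad_mm(h, Pn[[paste0(pre, "Wq")]]), Pn[[paste0(pre, "bq")]])
  k <- ad_add_rowvec(ad_mm(h, Pn[[paste0(pre, "Wk")]]), Pn[[paste0(pre, "bk")]])
  v <- ad_add_rowvec(ad_mm(h, Pn[[paste0(pre, "Wv")]]), Pn[[paste0(pre, "bv")]])
  msk <- outer(mask_rows, mask_rows)
  a <- ad_rowsoftmax(ad_scale(ad_mm(q, ad_t(k)), 1 / sqrt(d)), mask = msk)
  o <- ad_add_rowvec(ad_mm(ad_mm(a, v), Pn[[paste0(pre, "Wo")]]), Pn[[paste0(pre, "bo")]])
  if (training && cfg$dropout > 0)
    o <- ad_mul_const(o, drop_mask(dim(o$val), cfg$dropout, derive_seed(dseed, 91L)))
  h1 <- ad_layernorm(ad_add(h, o), Pn[[paste0(pre, "ln1_g")]], Pn[[paste0(pre, "ln1_b")]])
  f <- ad_add_rowvec(ad_mm(ad_relu(ad_add_rowvec(ad_mm(h1, Pn[[paste0(pre, "W1")]]),
                                                 Pn[[paste0(pre, "b1")]])),
                           Pn[[paste0(pre, "W2")]]), Pn[[paste0(pre, "b2")]])
  if (training && cfg$dropout > 0)
    f <- ad_mul_const(f, drop_mask(dim(f$val), cfg$dropout, derive_seed(dseed, 92L)))
  ad_layernorm(ad_add(h1, f), Pn[[paste0(pre, "ln2_g")]], Pn[[paste0(pre, "ln2_b")]])
}

## node-level distance encoder: Draw -> D
distance_encoder_node <- function(tape, Pn, Draw, pad_mask, cfg,
                                  training = FALSE, dseed = 0L) {
  np1 <- nrow(Draw)
  Phi <- dist_basis(Draw, cfg$dist_centers)
  valid <- pad_mask > 0
  ## token distance-profile embedding: masked mean over the basis-lifted
  ## profile entries (position-shared weights keep the map equivariant);
  ## PhiSum[i, ] = mean_j basis(d_ij); Phi rows are column-major (i fastest)
  PhiSum <- matrix(0, np1, ncol(Phi))
  PhiM <- array(Phi, c(np1, np1, ncol(Phi)))
  for (k in seq_len(ncol(Phi))) PhiSum[, k] <- rowMeans(PhiM[, valid, k, drop = FALSE])
  h <- ad_mm(ad_const(tape, PhiSum), Pn$dist_We)
  g <- plain_layer_node(tape, Pn, "dist_", h, pad_mask, cfg, training, dseed)
  Dpair <- ad_reshape(ad_mm(ad_const(tape, Phi), Pn$dist_wd), np1, np1)
  ui <- ad_mm(g, Pn$dist_va)
  vj <- ad_mm(g, Pn$dist_vb)
  ones_row <- ad_const(tape, matrix(1, 1L, np1))
  ones_col <- ad_const(tape, matrix(1, np1, 1L))
  D <- ad_add(Dpair, ad_add(ad_mm(ui, ones_row), ad_mm(ones_col, ad_t(vj))))
  gmask <- pad_mask
  gmask[1L] <- 0          # the global node carries no raw geometry
  ad_mul_const(D, outer(gmask, gmask))
}

#' Distance-fraction matrix D (value level)
#'
#' Learned transformation of the raw distance matrix: every pairwise
#' distance is lifted into a fixed basis (the raw distance plus Gaussian
#' bumps), each token's distance profile is pooled into an embedding and
#' passed through one standard transformer encoder layer, and the final
#' score for a pair combines the pair's basis features with both tokens'
#' encoded profiles.  All weights are shared across positions, so permuting
#' atoms permutes D's rows and columns consistently.  Padded positions and
#' the global node's row/column are exactly 0.  D is not required to be
#' symmetric.
#'
#' @param Draw raw distance matrix ((n+1) x (n+1), global node first).
#' @param pad_mask 0/1 validity vector of length n+1.
#' @param params encoder parameters ([init_encoder_params()]).
#' @param cfg an [encoder_config()].
#' @return (n+1) x (n+1) numeric matrix.
#' @export
distance_encoder <- function(Draw, pad_mask, params, cfg) {
  if (all(pad_mask == 0)) stop("distance_encoder: all positions padded")
  tape <- ad_tape()
  Pn <- ad_wrap_params(tape, params)
  distance_encoder_node(tape, Pn, Draw, pad_mask, cfg)$val
}

#' Parameters making the distance encoder the identity map
#'
#' Sets the pair projection to pick out the raw-distance basis feature and
#' silences the token-profile terms, so `distance_encoder()` returns `Draw`
#' itself (away from the global node's zeroed row/column).  Used to verify
#' the wiring of the channel.
#'
#' @param params parameter list to modify.
#' @param cfg the matching [encoder_config()].
#' @return modified parameter list.
#' @export
distance_encoder_identity <- function(params, cfg) {
  params$dist_wd <- matrix(c(1, rep(0, cfg$dist_k - 1L)), cfg$dist_k, 1L)
  params$dist_va <- matrix(0, cfg$d_model, 1L)
  params$dist_vb <- matrix(0, cfg$d_model, 1L)
  params
}

## node-level input embedding
embed_inputs_node <- function(tape, Pn, atom_ids, nmr_ids) {
  ad_cbind(ad_rows(Pn$emb_atom, atom_ids), ad_rows(Pn$emb_nmr, nmr_ids))
}

#' Embed the paired token sequences
#'
#' Atom and NMR embeddings (each `d_model / 2` wide) are concatenated per
#' position; there are no positional encodings.
#'
#' @param tp a `token_pair` (or a list with `atom_ids`, `nmr_ids`).
#' @param params,cfg encoder parameters and config.
#' @return (n+1) x d_model matrix z0.
#' @export
embed_inputs <- function(tp, params, cfg) {
  tape <- ad_tape()
  Pn <- ad_wrap_params(tape, params)
  embed_inputs_node(tape, Pn, tp$atom_ids, tp$nmr_ids)$val
}

## node-level modified attention layer; returns list(z = node, attn = list
## of per-head A3d value matrices)
modified_attention_node <- function(tape, Pn, pre, z, channels, D_node, cfg,
                                    training = FALSE, dseed = 0L) {
  d <- cfg$d_model; H <- cfg$n_heads; dk <- cfg$d_k
  pm <- channels$pad_mask
  msk <- outer(pm, pm)
  Q <- ad_add_rowvec(ad_mm(z, Pn[[paste0(pre, "Wq")]]), Pn[[paste0(pre, "bq")]])
  K <- ad_add_rowvec(ad_mm(z, Pn[[paste0(pre, "Wk")]]), Pn[[paste0(pre, "bk")]])
  V <- ad_add_rowvec(ad_mm(z, Pn[[paste0(pre, "Wv")]]), Pn[[paste0(pre, "bv")]])
  heads <- vector("list", H)
  attn <- vector("list", H)
  for (h in seq_len(H)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    Qh <- ad_cols(Q, idx); Kh <- ad_cols(K, idx); Vh <- ad_cols(V, idx)
    A <- ad_rowsoftmax(ad_scale(ad_mm(Qh, ad_t(Kh)), 1 / sqrt(dk)), mask = msk)
    A2d <- ad_add_const(ad_mul_const(A, channels$M), cfg$lambda_b * channels$Bnorm)
    A3d <- ad_add(A2d, D_node)
    attn[[h]] <- A3d$val
    heads[[h]] <- ad_mm(A3d, Vh)
  }
  cat_ <- heads[[1L]]
  if (H > 1L) for (h in 2:H) cat_ <- ad_cbind(cat_, heads[[h]])
  O <- ad_add_rowvec(ad_mm(cat_, Pn[[paste0(pre, "Wo")]]), Pn[[paste0(pre, "bo")]])
  if (training && cfg$dropout > 0)
    O <- ad_mul_const(O, drop_mask(dim(O$val), cfg$dropout, derive_seed(dseed, 1L)))
  z1 <- ad_layernorm(ad_add(z, O), Pn[[paste0(pre, "ln1_g")]], Pn[[paste0(pre, "ln1_b")]])
  f <- ad_add_rowvec(ad_mm(ad_relu(ad_add_rowvec(ad_mm(z1, Pn[[paste0(pre, "W1")]]),
                                                 Pn[[paste0(pre, "b1")]])),
                           Pn[[paste0(pre, "W2")]]), Pn[[paste0(pre, "b2")]])
  if (training && cfg$dropout > 0)
    f <- ad_mul_const(f, drop_mask(dim(f$val), cfg$dropout, derive_seed(dseed, 2L)))
  z2 <- ad_layernorm(ad_add(z1, f), Pn[[paste0(pre, "ln2_g")]], Pn[[paste0(pre, "ln2_b")]])
  list(z = z2, attn = attn)
}

#' One modified-attention layer (value level)
#'
#' Exposes the layer algebra for direct inspection: returns the updated
#' token representations and each head's A3d matrix.
#'
#' @param z (n+1) x d_model input representations.
#' @param channels a `pair_channels`.
#' @param params,cfg encoder parameters and config.
#' @param layer which layer's weights to apply (default 1).
#' @param D optional precomputed distance-fraction matrix; defaults to the
#'   learned channel (a zero matrix under the `"no3d"` ablation).
#' @return list with `z` ((n+1) x d_model) and `attn` (per-head A3d).
#' @export
modified_attention <- function(z, channels, params, cfg, layer = 1L, D = NULL) {
  tape <- ad_tape()
  Pn <- ad_wrap_params(tape, params)
  if (is.null(D)) {
    D_node <- if (identical(channels$ablation, "no3d"))
      ad_const(tape, matrix(0, nrow(z), nrow(z)))
    else distance_encoder_node(tape, Pn, channels$Draw, channels$pad_mask, cfg)
  } else D_node <- ad_const(tape, D)
  out <- modified_attention_node(tape, Pn, paste0("l", layer, "_"),
                                 ad_const(tape, z), channels, D_node, cfg)
  list(z = out$z$val, attn = out$attn)
}

## full forward pass on a tape; returns nodes for the losses
encode_forward <- function(tape, Pn, atom_ids, nmr_ids, channels, cfg,
                           training = FALSE, dseed = 0L) {
  z <- embed_inputs_node(tape, Pn, atom_ids, nmr_ids)
  D_node <- if (identical(channels$ablation, "no3d"))
    ad_const(tape, matrix(0, length(atom_ids), length(atom_ids)))
  else distance_encoder_node(tape, Pn, channels$Draw, channels$pad_mask, cfg,
                             training, derive_seed(dseed, 999L))
  attn <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    out <- modified_attention_node(tape, Pn, paste0("l", l, "_"), z, channels,
                                   D_node, cfg, training, derive_seed(dseed, l))
    z <- out$z
    attn[[l]] <- out$attn
  }
  list(r = z, attn = attn, D = D_node)
}

#' Encode a molecule's token pair into representations
#'
#' Runs the full encoder in evaluation mode (no dropout) and returns the
#' per-token representations together with every layer's per-head A3d
#' attention matrices.  Position 1 of `r` is the whole-molecule (global
#' node) representation.
#'
#' @param tp a `token_pair` (optionally corrupted ids).
#' @param channels a `pair_channels` for the same molecule.
#' @param params,cfg encoder parameters and config.
#' @return an `encoder_state`: `r` ((n+1) x d_model), `attn` (list of layers,
#'   each a list of per-head matrices), `D`, `channels`.
#' @export
encode <- function(tp, channels, params, cfg) {
  tape <- ad_tape()
  Pn <- ad_wrap_params(tape, params)
  fw <- encode_forward(tape, Pn, tp$atom_ids, tp$nmr_ids, channels, cfg)
  st <- list(r = fw$r$val, attn = fw$attn, D = fw$D$val, channels = channels)
  class(st) <- "encoder_state"
  st
}

#' Save / load a model checkpoint
#'
#' A checkpoint bundles the parameter tensors, the configuration, the
#' vocabularies and any training history under a versioned header.
#'
#' @param ckpt checkpoint list.
#' @param path file path.
#' @return `load_checkpoint` returns the checkpoint list.
#' @export
save_checkpoint <- function(ckpt, path) {
  ckpt$format <- "molbert-checkpoint-v1"
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!identical(ckpt$format, "molbert-checkpoint-v1"))
    stop("load_checkpoint: unrecognised checkpoint format")
  ckpt
}
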