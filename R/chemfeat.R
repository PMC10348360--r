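## Per-molecule feature channels: token sequences with the global node <G>,
## surrogate NMR shifts and bond dissociation energies, the normalised
## bond-energy matrix, the adjacency mask, the raw distance matrix and the
## 3D geometry targets (distances, bond angles, torsions).

.TOK_PAD <- "<PAD>"; .TOK_G <- "<G>"; .TOK_M <- "<M>"; .TOK_UNK <- "<UNK>"

.BASE_ELEMENTS <- c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I", "B")
.CHIRAL_ELEMENTS <- c("C", "N", "S", "P")

#' Atom token vocabulary
#'
#' Fixed, finite vocabulary: the four specials, one token per supported
#' element, and `@`/`@@` variants for elements that can be stereocentres.
#' The chiral variants are always present so embedding tables have a stable
#' size whether or not chiral tokens are in use.
#'
#' @return list with `tokens` (character) and `id` (named integer map).
#' @export
atom_vocab <- function() {
  tokens <- c(.TOK_PAD, .TOK_G, .TOK_M, .TOK_UNK, .BASE_ELEMENTS,
              paste0(rep(.CHIRAL_ELEMENTS, each = 2L), c("@", "@@")))
  list(tokens = tokens, id = stats::setNames(seq_along(tokens), tokens))
}

#' NMR token vocabulary
#'
#' Specials plus one token per shift bin of width `bin_width` ppm over
#' `range`.  The `<G>` slot of an NMR sequence holds the dedicated `<G>` id.
#'
#' @param bin_width bin width in ppm (default 1.0).
#' @param range ppm range covered; shifts outside are clamped to the edge
#'   bins (default c(-50, 300)).
#' @export
nmr_vocab <- function(bin_width = 1.0, range = c(-50, 300)) {
  stopifnot(bin_width > 0, range[2] > range[1])
  lo <- floor(range[1] / bin_width)
  hi <- ceiling(range[2] / bin_width) - 1L
  bins <- lo:hi
  tokens <- c(.TOK_PAD, .TOK_G, .TOK_M, .TOK_UNK, paste0("ppm", bins))
  list(tokens = tokens, id = stats::setNames(seq_along(tokens), tokens),
       bin_width = bin_width, range = range, bins = bins)
}

#' Tokenize a molecule's atoms
#'
#' One token per heavy atom in the order the atoms appear in the parsed
#' molecule, with `<G>` prepended at position 1.  With `use_chiral_tokens`,
#' stereocentres get distinct `@`/`@@` element variants.  Elements outside
#' the vocabulary map to `<UNK>` with a warning.
#'
#' @param m a `molecule`.
#' @param use_chiral_tokens distinguish stereocentres (default FALSE).
#' @param vocab an [atom_vocab()].
#' @return integer token ids, length `n_atoms + 1`.
#' @export
tokenize <- function(m, use_chiral_tokens = FALSE, vocab = atom_vocab()) {
  toks <- m$atoms$element
  if (use_chiral_tokens) {
    tag <- m$atoms$chiral
    toks <- ifelse(tag == "CCW", paste0(toks, "@"),
                   ifelse(tag == "CW", paste0(toks, "@@"), toks))
  }
  ids <- vocab$id[toks]
  if (anyNA(ids)) {
    warning(sprintf("tokenize: %d atom(s) outside vocabulary mapped to %s",
                    sum(is.na(ids)), .TOK_UNK))
    ids[is.na(ids)] <- vocab$id[[.TOK_UNK]]
  }
  unname(c(vocab$id[[.TOK_G]], ids))
}

## ---- surrogate chemistry tables ----

.chem_tables <- new.env(parent = emptyenv())

load_chem_table <- function(name) {
  if (is.null(.chem_tables[[name]])) {
    path <- system.file("extdata", name, package = "molbert")
    if (!nzchar(path)) path <- file.path("inst", "extdata", name)
    .chem_tables[[name]] <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .chem_tables[[name]]
}

## radius-1 environment key: element + sorted multiset of (neighbour, order)
atom_environment <- function(m, a, bo = mol_bond_orders(m)) {
  nbr <- which(bo[a, ] > 0)
  if (!length(nbr)) return(m$atoms$element[a])
  parts <- sort(paste0(m$atoms$element[nbr], ":", bo[a, nbr]))
  paste0(m$atoms$element[a], "|", paste(parts, collapse = ","))
}

#' Surrogate per-atom NMR shifts
#'
#' Deterministic stand-in for a trained shift predictor: each atom's
#' radius-1 environment (element plus the sorted multiset of neighbour
#' elements and bond orders) is looked up in the packaged table
#' `nmr_environments.csv`; unknown environments fall back to the element
#' default row.  Identical environments always receive identical shifts.
#'
#' @param m a `molecule`.
#' @param override optional data.frame (smiles, atom_index, value) with
#'   0-based atom indices; matching rows replace table values exactly.
#' @return numeric vector of shifts (ppm), one per heavy atom.
#' @export
surrogate_nmr <- function(m, override = NULL) {
  tab <- load_chem_table("nmr_environments.csv")
  bo <- mol_bond_orders(m)
  envs <- vapply(seq_len(m$n_atoms), function(a) atom_environment(m, a, bo), "")
  key <- paste0(tab$element, "\r", tab$environment)
  hit <- match(paste0(m$atoms$element, "\r", envs), key)
  miss <- is.na(hit)
  if (any(miss)) {
    defaults <- match(paste0(m$atoms$element[miss], "\r", "*"), key)
    hit[miss] <- defaults
  }
  shifts <- tab$shift_ppm[hit]
  shifts[is.na(shifts)] <- 0
  if (!is.null(override) && !is.null(m$smiles)) {
    rows <- override[override$smiles == m$smiles, , drop = FALSE]
    if (nrow(rows)) shifts[rows$atom_index + 1L] <- rows$value
  }
  shifts
}

#' Discretize NMR shifts into token ids
#'
#' Token id corresponds to `floor(shift / bin_width)` clamped to the
#' configured ppm range; non-finite shifts map to `<UNK>`.
#'
#' @param shifts numeric shifts (ppm).
#' @param vocab an [nmr_vocab()]; its bin width and range are used.
#' @return integer token ids (no `<G>` prepended).
#' @export
discretize_nmr <- function(shifts, vocab = nmr_vocab()) {
  bin <- floor(shifts / vocab$bin_width)
  bin <- pmin(pmax(bin, min(vocab$bins)), max(vocab$bins))
  ids <- vocab$id[paste0("ppm", bin)]
  ids[!is.finite(shifts)] <- vocab$id[[.TOK_UNK]]
  unname(ids)
}

#' Build the paired atom/NMR token sequences
#'
#' @param m a `molecule`.
#' @param use_chiral_tokens passed to [tokenize()].
#' @param vocab_atoms,vocab_nmr vocabularies.
#' @param nmr_override passed to [surrogate_nmr()].
#' @return a `token_pair`: `atom_ids` and `nmr_ids` (both length n+1 with
#'   `<G>` at position 1) plus the vocabularies.
#' @export
token_pair <- function(m, use_chiral_tokens = FALSE,
                       vocab_atoms = atom_vocab(), vocab_nmr = nmr_vocab(),
                       nmr_override = NULL) {
  atom_ids <- tokenize(m, use_chiral_tokens, vocab_atoms)
  shifts <- surrogate_nmr(m, nmr_override)
  nmr_ids <- c(vocab_nmr$id[[.TOK_G]], discretize_nmr(shifts, vocab_nmr))
  tp <- list(atom_ids = atom_ids, nmr_ids = unname(nmr_ids),
             vocab_atoms = vocab_atoms, vocab_nmr = vocab_nmr, shifts = shifts)
  class(tp) <- "token_pair"
  tp
}

#' Surrogate bond-energy matrix B
#'
#' Deterministic stand-in for a trained BDE predictor: each bonded pair gets
#' the packaged mean bond dissociation energy (kJ/mol) keyed by the two
#' elements and the bond order; non-bonded entries are 0, as are the global
#' node's row and column.  Unknown bond keys fall back to an order default
#' with a warning.
#'
#' @param m a `molecule`.
#' @param override optional data.frame (smiles, i, j, value) with 0-based
#'   atom indices; matching bonds get the given value exactly.
#' @return symmetric (n+1) x (n+1) matrix, kJ/mol; index 1 is `<G>`.
#' @export
surrogate_bde <- function(m, override = NULL) {
  tab <- load_chem_table("bde_table.csv")
  n <- m$n_atoms
  B <- matrix(0, n + 1L, n + 1L)
  defaults <- c(`1` = 300, `2` = 600, `3` = 850, `4` = 500)
  nmiss <- 0L
  for (r in seq_len(nrow(m$bonds))) {
    i <- m$bonds$i[r]; j <- m$bonds$j[r]; o <- m$bonds$order[r]
    es <- sort(c(m$atoms$element[i], m$atoms$element[j]))
    hit <- which(tab$elem_a == es[1] & tab$elem_b == es[2] & tab$order == o)
    val <- if (length(hit)) tab$bde_kj_mol[hit[1L]] else { nmiss <- nmiss + 1L; defaults[[as.character(o)]] }
    B[i + 1L, j + 1L] <- B[j + 1L, i + 1L] <- val
  }
  if (nmiss > 0L)
    warning(sprintf("surrogate_bde: %d bond key(s) not in table; order defaults used", nmiss))
  if (!is.null(override) && !is.null(m$smiles)) {
    rows <- override[override$smiles == m$smiles, , drop = FALSE]
    for (r in seq_len(nrow(rows)))
      B[rows$i[r] + 2L, rows$j[r] + 2L] <- B[rows$j[r] + 2L, rows$i[r] + 2L] <- rows$value[r]
  }
  B
}

#' Min-max normalise the bond-energy matrix
#'
#' `(B - Bmin) / (Bmax - Bmin)` taken over the bonded (non-zero) entries
#' only, so structural zeros do not corrupt the range; non-bonded entries
#' stay 0.  A degenerate range (all bonds equal) maps every bonded entry to
#' 1.
#'
#' @param B bond-energy matrix from [surrogate_bde()].
#' @return matrix of the same shape with bonded entries in [0, 1].
#' @export
normalize_b <- function(B) {
  nz <- B != 0
  if (!any(nz)) stop("normalize_b: B has no non-zero entries")
  v <- B[nz]
  bmin <- min(v); bmax <- max(v)
  out <- B
  if (bmax == bmin) {
    message("normalize_b: degenerate range (Bmax == Bmin); bonded entries set to 1")
    out[nz] <- 1
  } else {
    out[nz] <- (v - bmin) / (bmax - bmin)
  }
  out
}

#' Binarize the bond-energy matrix into the attention mask M
#'
#' `M[i, j] = 1` iff the pair is bonded, `i == j`, or either index is the
#' global node (position 1), which is connected to every token.
#'
#' @param B bond-energy matrix ((n+1) x (n+1), global node first).
#' @return 0/1 matrix of the same shape.
#' @export
binarize <- function(B) {
  M <- (B != 0) * 1
  diag(M) <- 1
  M[1L, ] <- 1
  M[, 1L] <- 1
  M
}

#' Raw interatomic distance matrix
#'
#' Euclidean distances in Angstrom over the heavy atoms, with the global
#' node's row and column set to 0.
#'
#' @param m a `molecule` with coordinates (see [embed_conformer()]).
#' @return symmetric (n+1) x (n+1) matrix with zero diagonal.
#' @export
distance_matrix <- function(m) {
  if (is.null(m$coords)) stop("distance_matrix: geometry error: no coordinates")
  D <- as.matrix(stats::dist(m$coords))
  out <- matrix(0, m$n_atoms + 1L, m$n_atoms + 1L)
  out[-1L, -1L] <- D
  out
}

## geometry kernels shared between target construction and the 3D
## reconstruction head (guaranteeing the two sides agree by construction)

geom_distances <- function(X, pairs) {
  sqrt(rowSums((X[pairs[, 1], , drop = FALSE] - X[pairs[, 2], , drop = FALSE])^2))
}

geom_angles <- function(X, triples) {
  u <- X[triples[, 1], , drop = FALSE] - X[triples[, 2], , drop = FALSE]
  v <- X[triples[, 3], , drop = FALSE] - X[triples[, 2], , drop = FALSE]
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  atan2(sqrt(rowSums(cr^2)), rowSums(u * v))
}

geom_torsions <- function(X, quads, signed = FALSE) {
  b1 <- X[quads[, 2], , drop = FALSE] - X[quads[, 1], , drop = FALSE]
  b2 <- X[quads[, 3], , drop = FALSE] - X[quads[, 2], , drop = FALSE]
  b3 <- X[quads[, 4], , drop = FALSE] - X[quads[, 3], , drop = FALSE]
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  na_ <- cr(b1, b2); nb_ <- cr(b2, b3)
  den <- sqrt(rowSums(na_^2)) * sqrt(rowSums(nb_^2))
  cosphi <- rowSums(na_ * nb_) / pmax(den, 1e-12)
  phi <- acos(pmin(pmax(cosphi, -1), 1))
  if (signed) {
    s <- sign(rowSums(cr(na_, nb_) * b2))
    phi <- phi * ifelse(s == 0, 1, s)
  }
  phi
}

#' Ground-truth 3D geometry targets
#'
#' Interatomic distances over all unordered heavy-atom pairs, bond angles
#' over bonded paths i-j-k (via `atan2(|u x v|, u . v)` about the central
#' atom), and torsion angles over bonded paths i-j-k-l (unsigned, via the
#' arc-cosine of the bond-plane normals; `signed = TRUE` attaches the sign
#' of the dihedral).  Collinear triples give exactly pi; torsions whose
#' normals degenerate (three collinear atoms) are skipped with a warning.
#'
#' @param m a `molecule` with coordinates.
#' @param signed_torsions use signed dihedrals (default FALSE, matching the
#'   mirror-invariant unsigned convention).
#' @return a `geometry_targets` list: `dist_pairs` (i, j, d), `angle_triples`
#'   (i, j, k, theta), `torsion_quads` (i, j, k, l, phi); indices are atom
#'   positions, global node excluded.
#' @export
geometry_targets <- function(m, signed_torsions = FALSE) {
  if (is.null(m$coords)) stop("geometry_targets: geometry error: no coordinates")
  X <- m$coords
  n <- m$n_atoms
  pairs <- if (n >= 2L) t(utils::combn(n, 2L)) else matrix(0L, 0L, 2L)
  dp <- if (nrow(pairs)) cbind(pairs, geom_distances(X, pairs)) else matrix(0, 0L, 3L)
  nb <- mol_neighbors(m)
  triples <- NULL
  for (j in seq_len(n)) if (length(nb[[j]]) >= 2L) {
    cmb <- utils::combn(sort(nb[[j]]), 2L)
    triples <- rbind(triples, cbind(cmb[1, ], j, cmb[2, ]))
  }
  at <- if (!is.null(triples)) cbind(triples, geom_angles(X, triples)) else matrix(0, 0L, 4L)
  quads <- NULL
  for (r in seq_len(nrow(m$bonds))) {
    jj <- m$bonds$i[r]; kk <- m$bonds$j[r]
    for (ii in setdiff(nb[[jj]], kk)) for (ll in setdiff(nb[[kk]], jj))
      if (ii != ll) quads <- rbind(quads, c(ii, jj, kk, ll))
  }
  if (!is.null(quads)) {
    b1 <- X[quads[, 2], , drop = FALSE] - X[quads[, 1], , drop = FALSE]
    b2 <- X[quads[, 3], , drop = FALSE] - X[quads[, 2], , drop = FALSE]
    b3 <- X[quads[, 4], , drop = FALSE] - X[quads[, 3], , drop = FALSE]
    cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                               a[, 3] * b[, 1] - a[, 1] * b[, 3],
                               a[, 1] * b[, 2] - a[, 2] * b[, 1])
    ok <- rowSums(cr(b1, b2)^2) > 1e-16 & rowSums(cr(b2, b3)^2) > 1e-16
    if (any(!ok)) {
      warning(sprintf("geometry_targets: %d degenerate torsion(s) skipped", sum(!ok)))
      quads <- quads[ok, , drop = FALSE]
    }
    tq <- cbind(quads, geom_torsions(X, quads, signed = signed_torsions))
  } else tq <- matrix(0, 0L, 5L)
  colnames(dp) <- c("i", "j", "d")
  colnames(at) <- c("i", "j", "k", "theta")
  colnames(tq) <- c("i", "j", "k", "l", "phi")
  gt <- list(dist_pairs = dp, angle_triples = at, torsion_quads = tq,
             signed = signed_torsions)
  class(gt) <- "geometry_targets"
  gt
}

#' Build all pairwise channels for a molecule
#'
#' Convenience wrapper assembling the `pair_channels` used by the encoder:
#' B, Bnorm, M, Draw, and an all-valid pad mask (single-molecule processing
#' is unpadded; the mask generalises to padded batches).
#'
#' @param m a `molecule` with coordinates.
#' @param bde_override,ablation see [surrogate_bde()] and the ablation
#'   switches (`"none"`, `"no3d"`, `"nochem"`).
#' @return a `pair_channels` list: B, Bnorm, M, Draw, pad_mask.
#' @export
build_channels <- function(m, bde_override = NULL, ablation = "none") {
  B <- surrogate_bde(m, bde_override)
  M <- binarize(B)
  Bn <- if (identical(ablation, "nochem")) M
        else if (!any(B != 0)) B            # single atom: nothing to normalise
        else normalize_b(B)
  Draw <- distance_matrix(m)
  ch <- list(B = B, Bnorm = Bn, M = M, Draw = Draw,
             pad_mask = rep(1, m$n_atoms + 1L), ablation = ablation)
  class(ch) <- "pair_channels"
  ch
}
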