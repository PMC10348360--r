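## Attention-based interpretability: extract a layer's A3d matrices, compare
## atoms by the similarity of their attention profiles, and export heatmaps.

#' Extract an attention map for a molecule
#'
#' Runs the encoder and returns the recorded A3d matrix of the requested
#' layer, either head-averaged or per head.  The atom-only submatrix
#' (global node dropped) is what the heatmap export plots.
#'
#' @param ckpt a [pretrain()] checkpoint (or any list with `params`, `heads`,
#'   `cfg`, `ablation`).
#' @param smiles a single SMILES string.
#' @param layer which encoder layer (default: the last).
#' @param reduce `"mean"` (head average, default) or `"per_head"`.
#' @param seed conformer seed.
#' @return an `attention_map`: `matrix` ((n+1) x (n+1), or a list per head),
#'   `atom_labels`, `layer`, `reduce`, `smiles`, `ablation`.
#' @export
attention_map <- function(ckpt, smiles, layer = NULL, reduce = "mean",
                          seed = 1L) {
  stopifnot(reduce %in% c("mean", "per_head"))
  feat <- featurize_molecules(smiles, ckpt$cfg, seed,
                              ckpt$ablation %||% "none")[[1L]]
  layer <- layer %||% ckpt$cfg$n_layers
  if (layer < 1L || layer > ckpt$cfg$n_layers)
    stop(sprintf("attention_map: layer %d out of range 1..%d", layer, ckpt$cfg$n_layers))
  st <- encode(feat$tp, feat$channels, ckpt$params, ckpt$cfg)
  heads <- st$attn[[layer]]
  mat <- if (identical(reduce, "mean")) Reduce(`+`, heads) / length(heads) else heads
  labels <- c("<G>", paste0(feat$mol$atoms$element, seq_len(feat$mol$n_atoms)))
  out <- list(matrix = mat, atom_labels = labels, layer = layer,
              reduce = reduce, smiles = feat$mol$smiles,
              ablation = ckpt$ablation %||% "none")
  class(out) <- "attention_map"
  out
}

#' Pairwise atom similarity from an attention map
#'
#' Cosine similarity between the atoms' attention-score row vectors
#' (global node excluded): symmetric with unit diagonal, invariant to
#' uniform rescaling of the attention matrix.  A zero-norm row's
#' similarities are defined as 0 (diagonal stays 1), with a message.
#' `method = "euclidean"` instead returns `1 / (1 + distance)`.
#'
#' @param map an [attention_map()] (head-mean) or a plain matrix.
#' @param method `"cosine"` (default) or `"euclidean"`.
#' @return n x n similarity matrix.
#' @export
atom_similarity <- function(map, method = "cosine") {
  A <- if (inherits(map, "attention_map")) map$matrix else map
  if (is.list(A)) stop("atom_similarity: reduce the map to head-mean first")
  if (inherits(map, "attention_map")) A <- A[-1L, -1L, drop = FALSE]
  n <- nrow(A)
  if (identical(method, "euclidean")) {
    S <- 1 / (1 + as.matrix(stats::dist(A)))
    diag(S) <- 1
    return(S)
  }
  nrm <- sqrt(rowSums(A^2))
  zero <- nrm == 0
  if (any(zero)) message(sprintf("atom_similarity: %d zero-norm row(s); similarity set to 0", sum(zero)))
  nrm[zero] <- 1
  S <- (A / nrm) %*% t(A / nrm)
  S[zero, ] <- 0; S[, zero] <- 0
  diag(S) <- 1
  S <- (S + t(S)) / 2
  S
}

#' Export an attention map as CSV and a heatmap image
#'
#' Writes the atom-only attention submatrix to `<path>.csv` (header row of
#' atom labels in canonical atom order) and renders a heatmap to
#' `<path>.png`.
#'
#' @param map an [attention_map()] with `reduce = "mean"`.
#' @param path output path prefix (no extension).
#' @return invisibly, the two file paths.
#' @export
export_heatmap <- function(map, path) {
  stopifnot(inherits(map, "attention_map"), !is.list(map$matrix))
  A <- map$matrix[-1L, -1L, drop = FALSE]
  labels <- map$atom_labels[-1L]
  dimnames(A) <- list(labels, labels)
  csv <- paste0(path, ".csv")
  png <- paste0(path, ".png")
  utils::write.csv(A, csv, row.names = TRUE)
  grDevices::png(png, width = 640, height = 640)
  on.exit(grDevices::dev.off())
  n <- nrow(A)
  graphics::image(seq_len(n), seq_len(n), t(A[n:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Greens", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "",
                  main = sprintf("%s (layer %d)", map$smiles, map$layer))
  graphics::axis(1, at = seq_len(n), labels = labels, las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(n), labels = rev(labels), las = 2, cex.axis = 0.7)
  invisible(c(csv = csv, png = png))
}

#' Read back an exported attention CSV
#' @param path the `.csv` written by [export_heatmap()].
#' @return numeric matrix with atom labels as dimnames.
#' @export
read_heatmap_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  as.matrix(df)
}
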