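## Masked-token corruption for self-supervised pre-training.
##
## A fraction of the non-global positions is selected; within the selection,
## tokens are replaced by <M>, by a random different valid token, or kept,
## BERT-style.  The plan records what was corrupted so the reconstruction
## losses know which positions to score.

#' Corrupt a token sequence
#'
#' Selects `ceiling(select_rate * n)` of the n non-global positions
#' uniformly without replacement (at least one position is always selected),
#' then applies the mask / random-replace / keep split within the selection.
#' The global node at position 1 is never corrupted.  Deterministic under
#' `seed`.
#'
#' @param ids integer token ids with `<G>` at position 1.
#' @param vocab the vocabulary the ids live in ([atom_vocab()] or
#'   [nmr_vocab()]); random replacements are drawn from its non-special
#'   tokens and never equal `<M>`, `<G>`, `<PAD>`, `<UNK>` or the original
#'   token.
#' @param select_rate fraction of positions to corrupt (default 0.2).
#' @param split probabilities of (mask, random_replace, keep) within the
#'   selection; must sum to 1 (default c(0.8, 0.1, 0.1)).
#' @param seed integer seed.
#' @return list with `ids` (corrupted sequence) and `plan` (a
#'   `corruption_plan`: selected positions, action per position, original
#'   ids, seed).
#' @export
corrupt <- function(ids, vocab, select_rate = 0.2, split = c(0.8, 0.1, 0.1),
                    seed = 1L) {
  stopifnot(length(ids) >= 2L, select_rate >= 0, select_rate <= 1,
            length(split) == 3L, all(split >= 0), abs(sum(split) - 1) < 1e-9)
  n <- length(ids) - 1L
  k <- max(1L, ceiling(select_rate * n))
  specials <- vocab$id[c(.TOK_PAD, .TOK_G, .TOK_M, .TOK_UNK)]
  pool <- setdiff(unname(vocab$id), unname(specials))
  with_local_seed(seed, {
    selected <- 1L + sort(sample.int(n, k))
    action <- sample(c("mask", "random", "keep"), k, replace = TRUE, prob = split)
    originals <- ids[selected]
    out <- ids
    for (q in seq_len(k)) {
      p <- selected[q]
      if (action[q] == "mask") {
        out[p] <- vocab$id[[.TOK_M]]
      } else if (action[q] == "random") {
        cand <- setdiff(pool, ids[p])
        out[p] <- if (length(cand)) cand[sample.int(length(cand), 1L)] else vocab$id[[.TOK_M]]
      }
    }
    plan <- list(selected = selected, action = action, originals = originals,
                 seed = seed)
    class(plan) <- "corruption_plan"
    list(ids = out, plan = plan)
  })
}

#' Corrupt both halves of a token pair independently
#'
#' The atom and NMR sequences are corrupted with independent seeds derived
#' from the master seed, so the two selections are independent.
#'
#' @param tp a `token_pair`.
#' @inheritParams corrupt
#' @return list with `atom` and `nmr`, each as returned by [corrupt()].
#' @export
corrupt_pair <- function(tp, select_rate = 0.2, split = c(0.8, 0.1, 0.1),
                         seed = 1L) {
  list(
    atom = corrupt(tp$atom_ids, tp$vocab_atoms, select_rate, split,
                   derive_seed(seed, 1L)),
    nmr = corrupt(tp$nmr_ids, tp$vocab_nmr, select_rate, split,
                  derive_seed(seed, 2L))
  )
}
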