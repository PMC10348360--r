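## Pre-training and fine-tuning loops, scaffold splitting and metrics.

## ---- metrics ----

#' Regression and classification metrics
#'
#' `rmse`, `r_squared` (coefficient of determination) and `roc_auc`
#' (rank-based Mann-Whitney estimate with tie correction).
#'
#' @param obs observed values / 0-1 labels.
#' @param pred predictions / scores.
#' @return scalar metric.
#' @export
rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

#' @rdname rmse
#' @export
r_squared <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)

#' @rdname rmse
#' @export
roc_auc <- function(obs, pred) {
  pos <- pred[obs == 1]; neg <- pred[obs == 0]
  if (!length(pos) || !length(neg))
    stop("roc_auc: metric error: a split contains a single class")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

## ---- scaffold split ----

## Bemis-Murcko-style scaffold: iteratively strip degree-1 atoms until only
## ring systems and linkers remain; acyclic molecules reduce to the empty
## scaffold and share one group
murcko_scaffold_key <- function(m) {
  keep <- rep(TRUE, m$n_atoms)
  bonds <- m$bonds
  repeat {
    deg <- integer(m$n_atoms)
    for (r in seq_len(nrow(bonds))) {
      if (keep[bonds$i[r]] && keep[bonds$j[r]]) {
        deg[bonds$i[r]] <- deg[bonds$i[r]] + 1L
        deg[bonds$j[r]] <- deg[bonds$j[r]] + 1L
      }
    }
    leaf <- keep & deg <= 1L
    if (!any(leaf) || !any(keep & !leaf)) { if (all(deg[keep] <= 1L)) keep[] <- FALSE; break }
    keep[leaf] <- FALSE
  }
  if (!any(keep)) return("")
  ## Weisfeiler-Lehman refinement over the retained subgraph
  idx <- which(keep)
  lab <- paste0(m$atoms$element[idx], ifelse(m$atoms$aromatic[idx], "a", ""))
  names(lab) <- idx
  sub <- bonds[keep[bonds$i] & keep[bonds$j], , drop = FALSE]
  for (it in 1:3) {
    newlab <- lab
    for (q in seq_along(idx)) {
      a <- idx[q]
      nb <- c(paste0(sub$order[sub$i == a], lab[as.character(sub$j[sub$i == a])]),
              paste0(sub$order[sub$j == a], lab[as.character(sub$i[sub$j == a])]))
      newlab[q] <- paste0(lab[q], "(", paste(sort(nb), collapse = ","), ")")
    }
    lab <- newlab
  }
  paste(sort(lab), collapse = ";")
}

#' Split specification
#' @param fractions train/valid/test fractions summing to 1 (default
#'   c(0.8, 0.1, 0.1)).
#' @param method `"scaffold"` or `"random"`.
#' @param seed seed for the random method (and the fallback).
#' @export
split_spec <- function(fractions = c(0.8, 0.1, 0.1), method = "scaffold", seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, length(fractions) == 3L,
            method %in% c("scaffold", "random"))
  list(fractions = fractions, method = method, seed = as.integer(seed))
}

#' Scaffold-based train/valid/test split
#'
#' Computes a Bemis-Murcko-style scaffold per molecule (ring systems plus
#' linkers, hashed by Weisfeiler-Lehman refinement so the key is independent
#' of atom order), groups molecules by scaffold, sorts the groups by size
#' (largest first, ties by key), and assigns whole groups greedily to fill
#' the train, then validation, then test quotas — no scaffold ever spans two
#' splits.  With fewer than three distinct scaffolds (or
#' `method = "random"`), a seeded random split is used instead (with a
#' warning in the fallback case).
#'
#' @param table a `property_table` (or data.frame with a `smiles` column).
#' @param spec a [split_spec()].
#' @return list of integer index vectors `train`, `valid`, `test`.
#' @export
scaffold_split <- function(table, spec = split_spec()) {
  df <- if (is.data.frame(table)) table else table$records
  n <- nrow(df)
  random_split <- function() with_local_seed(spec$seed, {
    ord <- sample.int(n)
    n_tr <- round(spec$fractions[1] * n)
    n_va <- round(spec$fractions[2] * n)
    list(train = sort(ord[seq_len(n_tr)]),
         valid = sort(ord[n_tr + seq_len(n_va)]),
         test = sort(ord[-(seq_len(n_tr + n_va))]))
  })
  if (identical(spec$method, "random")) return(random_split())
  keys <- vapply(df$smiles, function(s)
    murcko_scaffold_key(parse_smiles(s, canonicalize = FALSE)), "")
  groups <- split(seq_len(n), keys)
  if (length(groups) < 3L) {
    warning("scaffold_split: fewer than 3 distinct scaffolds; falling back to a random split")
    return(random_split())
  }
  ord <- order(-vapply(groups, length, 0L), names(groups))
  groups <- groups[ord]
  n_tr <- spec$fractions[1] * n
  n_va <- spec$fractions[2] * n
  out <- list(train = integer(0), valid = integer(0), test = integer(0))
  for (g in groups) {
    if (length(out$train) < n_tr) out$train <- c(out$train, g)
    else if (length(out$valid) < n_va) out$valid <- c(out$valid, g)
    else out$test <- c(out$test, g)
  }
  lapply(out, sort)
}

## ---- optimiser ----

adam_init <- function(params) {
  list(m = lapply(params, function(w) w * 0), v = lapply(params, function(w) w * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

## ---- featurisation cache ----

#' Featurize molecules for the encoder
#'
#' Parses (if needed), embeds a conformer (if absent), and builds the token
#' pair, channel matrices, geometry targets and bond table per molecule.
#' Under the `"nochem"` ablation the NMR sequence is replaced by a constant
#' token and Bnorm by the plain adjacency mask; under `"no3d"` the encoder
#' will zero the D channel and the 3D loss is dropped.
#'
#' @param mols list of `molecule` objects or character SMILES.
#' @param cfg an [encoder_config()].
#' @param seed seed stream for conformer embedding.
#' @param ablation `"none"`, `"no3d"`, `"nochem"`.
#' @param nmr_override,bde_override optional user tables (see
#'   [surrogate_nmr()], [surrogate_bde()]).
#' @return list of per-molecule feature lists.
#' @export
featurize_molecules <- function(mols, cfg, seed = 1L, ablation = "none",
                                nmr_override = NULL, bde_override = NULL) {
  va <- atom_vocab(); vn <- nmr_vocab()
  out <- vector("list", length(mols))
  for (k in seq_along(mols)) {
    m <- mols[[k]]
    if (is.character(m)) m <- parse_smiles(m)
    if (is.null(m$coords)) m <- embed_conformer(m, derive_seed(seed, k))
    tp <- token_pair(m, cfg$use_chiral_tokens, va, vn, nmr_override)
    if (identical(ablation, "nochem"))
      tp$nmr_ids <- c(vn$id[[.TOK_G]], rep(vn$id[["ppm0"]], m$n_atoms))
    ch <- build_channels(m, bde_override, ablation)
    out[[k]] <- list(mol = m, tp = tp, channels = ch,
                     geometry = geometry_targets(m), bonds = m$bonds)
  }
  out
}

## ---- pre-training ----

#' Pre-train the encoder with the four self-supervised tasks
#'
#' Full loop per molecule and epoch: corrupt both token sequences, run the
#' encoder, evaluate the four losses, combine them with the learned
#' uncertainty weights, and take an Adam step (gradients accumulated over
#' `batch_size` molecules).  Deterministic for a fixed seed.  Training
#' aborts on a non-finite loss, returning the last finite state.
#'
#' @param mols list of molecules or SMILES (conformers embedded as needed).
#' @param cfg an [encoder_config()].
#' @param ssl_opts an [ssl_options()].
#' @param epochs,batch_size,lr loop hyperparameters.
#' @param seed master seed for corruption, shuffling and dropout.
#' @param ablation channel ablation (see [featurize_molecules()]).
#' @param feats optional precomputed [featurize_molecules()] output.
#' @param log_path optional CSV path receiving the per-epoch loss breakdown.
#' @param verbose print per-epoch losses.
#' @return a checkpoint list: `params`, `heads`, `cfg`, `ssl_opts`,
#'   `ablation`, `history` (data.frame: epoch, L_A, L_N, L_B, L_3D,
#'   sigma1..4, L_total).
#' @export
pretrain <- function(mols, cfg = encoder_config(), ssl_opts = ssl_options(),
                     epochs = 30L, batch_size = 8L, lr = 1e-3, seed = 1L,
                     ablation = "none", feats = NULL, log_path = NULL,
                     verbose = FALSE) {
  stopifnot(length(mols) >= 2L || !is.null(feats))
  if (is.null(feats)) feats <- featurize_molecules(mols, cfg, derive_seed(seed, 0L), ablation)
  params <- init_encoder_params(cfg)
  heads <- init_ssl_heads(cfg, seed = derive_seed(cfg$init_seed, 13L))
  all_par <- c(params, heads)
  opt <- adam_init(all_par)
  warmup_steps <- max(1, round(0.1 * epochs * length(feats) / batch_size))
  history <- NULL
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- with_local_seed(derive_seed(seed, 1000L + ep), sample(length(feats)))
    acc <- NULL
    nb <- 0L
    ep_parts <- c(L_A = 0, L_N = 0, L_B = 0, L_3D = 0)
    ep_total <- 0
    for (k in ord) {
      step <- step + 1L
      tape <- ad_tape()
      Wn <- ad_wrap_params(tape, all_par)
      obj <- ssl_objective_node(tape, Wn, Wn, feats[[k]], cfg, ssl_opts,
                                derive_seed(seed, step), training = TRUE)
      if (!is.finite(obj$total$val[1, 1])) {
        warning(sprintf("pretrain: non-finite loss at step %d; aborting with last state", step))
        ckpt <- list(params = all_par[names(params)], heads = all_par[names(heads)],
                     cfg = cfg, ssl_opts = ssl_opts, ablation = ablation,
                     history = history, diverged = TRUE)
        return(ckpt)
      }
      ad_backward(tape, obj$total)
      g <- ad_collect_grads(Wn)
      acc <- if (is.null(acc)) g else mapply(`+`, acc, g, SIMPLIFY = FALSE)
      nb <- nb + 1L
      ep_parts <- ep_parts + obj$parts
      ep_total <- ep_total + obj$total$val[1, 1]
      if (nb == batch_size || k == ord[length(ord)]) {
        acc <- lapply(acc, function(x) x / nb)
        lr_t <- lr * min(1, opt$t / max(1, warmup_steps))  # linear warmup
        upd <- adam_step(all_par, acc, opt, lr_t)
        all_par <- upd$params
        opt <- upd$state
        acc <- NULL; nb <- 0L
      }
    }
    sig <- exp(all_par$log_sigma)
    row <- data.frame(epoch = ep, t(ep_parts / length(feats)),
                      sigma1 = sig[1], sigma2 = sig[2], sigma3 = sig[3],
                      sigma4 = sig[4], L_total = ep_total / length(feats))
    history <- rbind(history, row)
    if (verbose) message(sprintf("epoch %d: L_total %.4f", ep, row$L_total))
  }
  if (!is.null(log_path)) utils::write.csv(history, log_path, row.names = FALSE)
  list(params = all_par[names(params)], heads = all_par[names(heads)],
       cfg = cfg, ssl_opts = ssl_opts, ablation = ablation, history = history,
       diverged = FALSE)
}

#' Masked-token reconstruction accuracy
#'
#' Corrupts each molecule's atom sequence, encodes, and scores the argmax
#' prediction at the corrupted positions; also reports the majority-class
#' baseline (always predicting the most frequent true token).
#'
#' @param ckpt a [pretrain()] checkpoint.
#' @param feats featurized molecules ([featurize_molecules()]).
#' @param seed corruption seed.
#' @param reps independent corruption draws per molecule (default 5; more
#'   draws give a steadier estimate on small sets).
#' @return list with `accuracy`, `baseline`, `n`.
#' @export
masked_accuracy <- function(ckpt, feats, seed = 1L, reps = 5L) {
  correct <- 0L; total <- 0L; truth <- integer(0)
  for (k in seq_along(feats)) {
    feat <- feats[[k]]
    for (rep in seq_len(reps)) {
      cp <- corrupt_pair(feat$tp, ckpt$ssl_opts$select_rate, ckpt$ssl_opts$split,
                         derive_seed(seed, k * 1000L + rep))
      tape <- ad_tape()
      Wn <- ad_wrap_params(tape, c(ckpt$params, ckpt$heads))
      fw <- encode_forward(tape, Wn, cp$atom$ids, cp$nmr$ids, feat$channels, ckpt$cfg)
      pos <- cp$atom$plan$selected
      logits <- mlp2_node(tape, ad_rows(fw$r, pos), Wn$atom_W1, Wn$atom_b1,
                          Wn$atom_W2, Wn$atom_b2)$val
      pred <- max.col(logits)
      correct <- correct + sum(pred == cp$atom$plan$originals)
      total <- total + length(pos)
      truth <- c(truth, cp$atom$plan$originals)
    }
  }
  list(accuracy = correct / total,
       baseline = max(table(truth)) / length(truth), n = total)
}

## ---- fine-tuning ----

init_task_head <- function(d, hidden, seed) {
  with_local_seed(seed, list(
    head_W1 = rmat(d, hidden, 0.1), head_b1 = matrix(0, 1, hidden),
    head_W2 = rmat(hidden, 1L, 0.1), head_b2 = matrix(0, 1, 1)
  ))
}

#' Fine-tuning configuration
#' @param head_hidden hidden width of the two-layer prediction head
#'   (default 64; ReLU activation, dropout 0.1).
#' @param pretrain_reg_weight weight of the retained pre-training loss
#'   (default 0.1; 0 gives plain supervised fine-tuning).
#' @param epochs,batch_size,lr loop hyperparameters (Adam with linear warmup
#'   over the first tenth of the steps).
#' @param dropout head dropout rate.
#' @param select_by_valid keep the epoch with the best validation metric
#'   rather than the last (default TRUE; the validation split exists for
#'   exactly this).
#' @param freeze_encoder train the head only, leaving the encoder untouched
#'   (the random-features / representation-quality control).
#' @export
finetune_config <- function(head_hidden = 64L, pretrain_reg_weight = 0.1,
                            epochs = 8L, batch_size = 8L, lr = 1e-3,
                            dropout = 0.1, select_by_valid = TRUE,
                            freeze_encoder = FALSE) {
  list(head_hidden = as.integer(head_hidden),
       pretrain_reg_weight = pretrain_reg_weight, epochs = as.integer(epochs),
       batch_size = as.integer(batch_size), lr = lr, dropout = dropout,
       select_by_valid = isTRUE(select_by_valid),
       freeze_encoder = isTRUE(freeze_encoder))
}

## forward the prediction head on the global-node representation
task_pred_node <- function(tape, Wn, r, ft, training, dseed) {
  g <- ad_rows(r, 1L)
  h <- ad_relu(ad_add_rowvec(ad_mm(g, Wn$head_W1), Wn$head_b1))
  if (training && ft$dropout > 0)
    h <- ad_mul_const(h, drop_mask(dim(h$val), ft$dropout, dseed))
  ad_add_rowvec(ad_mm(h, Wn$head_W2), Wn$head_b2)
}

finetune_one <- function(ckpt, feats, y, task, ft, train_idx, seed,
                         valid_idx = integer(0)) {
  cfg <- ckpt$cfg
  head <- init_task_head(cfg$d_model, ft$head_hidden, derive_seed(seed, 5L))
  all_par <- c(ckpt$params, ckpt$heads, head)
  trainable <- if (ft$freeze_encoder) names(head) else names(all_par)
  opt <- adam_init(all_par)
  warmup_steps <- max(1, round(0.1 * ft$epochs * length(train_idx) / ft$batch_size))
  mu <- 0; sdv <- 1
  if (task == "regression") {
    mu <- mean(y[train_idx]); sdv <- stats::sd(y[train_idx])
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
  }
  valid_metric <- function(params) {
    mdl <- list(params = params, task = task, ft = ft, cfg = cfg, mu = mu, sd = sdv)
    pv <- model_predict_feats(mdl, feats[valid_idx])
    if (task == "regression") r_squared(y[valid_idx], pv)
    else tryCatch(roc_auc(y[valid_idx], pv), error = function(e) NA_real_)
  }
  use_valid <- ft$select_by_valid && length(valid_idx) >= 3L
  best <- list(score = -Inf, params = all_par)
  step <- 0L
  for (ep in seq_len(ft$epochs)) {
    ord <- with_local_seed(derive_seed(seed, 2000L + ep), sample(train_idx))
    acc <- NULL; nb <- 0L
    for (k in ord) {
      step <- step + 1L
      tape <- ad_tape()
      Wn <- ad_wrap_params(tape, all_par)
      sseed <- derive_seed(seed, step)
      fw <- encode_forward(tape, Wn, feats[[k]]$tp$atom_ids, feats[[k]]$tp$nmr_ids,
                           feats[[k]]$channels, cfg,
                           training = !ft$freeze_encoder,
                           dseed = derive_seed(sseed, 3L))
      pred <- task_pred_node(tape, Wn, fw$r, ft, TRUE, derive_seed(sseed, 4L))
      loss <- if (task == "regression") {
        ad_square(ad_add_const(pred, -matrix((y[k] - mu) / sdv, 1, 1)))
      } else {
        p <- ad_sigmoid(pred)
        ad_neg_bce(p, y[k])
      }
      if (ft$pretrain_reg_weight > 0 && !ft$freeze_encoder) {
        obj <- ssl_objective_node(tape, Wn, Wn, feats[[k]], cfg, ckpt$ssl_opts,
                                  derive_seed(sseed, 6L), training = TRUE)
        loss <- ad_add(loss, ad_scale(obj$total, ft$pretrain_reg_weight))
      }
      ad_backward(tape, loss)
      g <- ad_collect_grads(Wn)
      acc <- if (is.null(acc)) g else mapply(`+`, acc, g, SIMPLIFY = FALSE)
      nb <- nb + 1L
      if (nb == ft$batch_size || k == ord[length(ord)]) {
        acc <- lapply(acc, function(x) x / nb)
        frozen <- setdiff(names(acc), trainable)
        if (length(frozen)) acc[frozen] <- lapply(acc[frozen], function(x) x * 0)
        lr_t <- ft$lr * min(1, opt$t / max(1, warmup_steps))  # linear warmup
        upd <- adam_step(all_par, acc, opt, lr_t)
        all_par <- upd$params; opt <- upd$state
        acc <- NULL; nb <- 0L
      }
    }
    if (use_valid) {
      sc <- valid_metric(all_par)
      if (is.finite(sc) && sc > best$score) best <- list(score = sc, params = all_par)
    }
  }
  if (use_valid && is.finite(best$score)) all_par <- best$params
  list(params = all_par, task = task, ft = ft, cfg = cfg, mu = mu, sd = sdv,
       ssl_opts = ckpt$ssl_opts, ablation = ckpt$ablation,
       valid_score = if (use_valid) best$score else NA_real_)
}

model_predict_feats <- function(model, feats) {
  vapply(feats, function(feat) {
    tape <- ad_tape()
    Wn <- ad_wrap_params(tape, model$params)
    fw <- encode_forward(tape, Wn, feat$tp$atom_ids, feat$tp$nmr_ids,
                         feat$channels, model$cfg)
    raw <- task_pred_node(tape, Wn, fw$r, model$ft, FALSE, 0L)$val[1, 1]
    if (model$task == "regression") raw * model$sd + model$mu
    else 1 / (1 + exp(-raw))
  }, 0)
}

## binary cross-entropy on a probability node
ad_neg_bce <- function(p, y) {
  if (y >= 0.5) ad_scale(ad_log(p), -1) else ad_scale(ad_log(ad_add_const(ad_scale(p, -1), 1)), -1)
}

#' Fine-tune a pre-trained encoder on a property table
#'
#' Attaches a two-layer prediction head to the global-node representation
#' and minimises the task loss (squared error for regression, binary
#' cross-entropy for classification) plus `pretrain_reg_weight` times the
#' retained pre-training objective.  Reports RMSE and R-squared (regression)
#' or ROC-AUC (binary) on the held-out test split; `n_runs` independent
#' seeded runs give mean and standard deviation.
#'
#' @param ckpt a [pretrain()] checkpoint (or an untrained one built from
#'   [init_encoder_params()] for control experiments).
#' @param table a `property_table` with one labelled property.
#' @param property which property column to model (default: the first).
#' @param spec a [split_spec()].
#' @param ft a [finetune_config()].
#' @param seed master seed.
#' @param n_runs number of independent runs (default 1).
#' @param feats optional precomputed featurisation of the table's molecules.
#' @return list with `model` (last run), `metrics` (data.frame per run),
#'   `summary` (mean and sd per metric), `split`.
#' @export
finetune <- function(ckpt, table, property = NULL, spec = split_spec(),
                     ft = finetune_config(), seed = 1L, n_runs = 1L,
                     feats = NULL) {
  df <- table$records
  property <- property %||% names(table$task_types)[1L]
  task <- unname(table$task_types[[property]])
  y <- df[[property]]
  keep <- !is.na(y)
  df <- df[keep, , drop = FALSE]; y <- y[keep]
  if (is.null(feats))
    feats <- featurize_molecules(df$smiles, ckpt$cfg, derive_seed(seed, 999L),
                                 ckpt$ablation %||% "none")
  split <- scaffold_split(list(records = df), spec)
  if (task == "binary" &&
      (length(unique(y[split$test])) < 2L || length(unique(y[split$train])) < 2L))
    stop("finetune: metric error: single-class train or test split")
  metrics <- NULL
  model <- NULL
  for (run in seq_len(n_runs)) {
    rs <- derive_seed(seed, 31L * run)
    model <- finetune_one(ckpt, feats, y, task, ft, split$train, rs, split$valid)
    pred <- model_predict_feats(model, feats[split$test])
    row <- if (task == "regression")
      data.frame(run = run, rmse = rmse(y[split$test], pred),
                 r2 = r_squared(y[split$test], pred))
    else data.frame(run = run, roc_auc = roc_auc(y[split$test], pred))
    metrics <- rbind(metrics, row)
  }
  summ <- data.frame(metric = setdiff(names(metrics), "run"),
                     mean = vapply(setdiff(names(metrics), "run"), function(c0) mean(metrics[[c0]]), 0),
                     sd = vapply(setdiff(names(metrics), "run"), function(c0) stats::sd(metrics[[c0]]), 0))
  list(model = model, metrics = metrics, summary = summ, split = split,
       property = property, task = task)
}

#' Predict properties for new molecules
#'
#' Featurizes each SMILES (embedding a conformer) and applies the
#' fine-tuned model; unparseable or unembeddable molecules yield NA with a
#' warning while the rest of the batch proceeds.  Binary-task outputs are
#' probabilities in [0, 1].
#'
#' @param model the `model` component of a [finetune()] result.
#' @param smiles character vector.
#' @param seed conformer seed.
#' @return named numeric vector of predictions (NA on failure).
#' @export
predict_molecules <- function(model, smiles, seed = 1L) {
  out <- rep(NA_real_, length(smiles))
  names(out) <- smiles
  for (k in seq_along(smiles)) {
    feat <- tryCatch(
      featurize_molecules(smiles[k], model$cfg, derive_seed(seed, k),
                          model$ablation %||% "none")[[1L]],
      error = function(e) NULL)
    if (is.null(feat)) {
      warning(sprintf("predict_molecules: failed on %s", dQuote(smiles[k])))
      next
    }
    out[k] <- model_predict_feats(model, list(feat))
  }
  out
}
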