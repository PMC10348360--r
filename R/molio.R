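## Molecule input/output: conformer embedding, SDF and property-table I/O,
## and the synthetic fixture generator.

## covalent radii (Angstrom) for bond-length targets
.COV_RADII <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39,
                Se = 1.20, As = 1.19, Sn = 1.39)

## order-dependent contraction of the covalent-radius sum
.ORDER_SCALE <- c(`1` = 1.00, `2` = 0.87, `3` = 0.78, `4` = 0.93)

bond_length_target <- function(e1, e2, order) {
  r1 <- .COV_RADII[[e1]] %||% 0.9
  r2 <- .COV_RADII[[e2]] %||% 0.9
  (r1 + r2) * .ORDER_SCALE[[as.character(order)]]
}

## crude hybridisation from bond orders: sp if a triple bond or two doubles,
## sp2 if aromatic or one double, else sp3
atom_hybridization <- function(m) {
  bo <- mol_bond_orders(m)
  vapply(seq_len(m$n_atoms), function(a) {
    ords <- bo[a, bo[a, ] > 0]
    if (any(ords == 3) || sum(ords == 2) >= 2) "sp"
    else if (any(ords == 2) || any(ords == 4) || m$atoms$aromatic[a]) "sp2"
    else "sp3"
  }, "")
}

## graph (topological) distance matrix, Inf across fragments
graph_distances <- function(m) {
  n <- m$n_atoms
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  nb <- mol_neighbors(m)
  for (s in seq_len(n)) {
    q <- s; D[s, s] <- 0
    while (length(q)) {
      a <- q[1L]; q <- q[-1L]
      for (b in nb[[a]]) if (D[s, b] > D[s, a] + 1) { D[s, b] <- D[s, a] + 1; q <- c(q, b) }
    }
  }
  D
}

#' Embed a 3D conformer for a molecule
#'
#' Generates Cartesian coordinates by minimising a molecular-mechanics-style
#' penalty (bond lengths from covalent radii, hybridisation-dependent bond
#' angles, planarity of sp2 centres and aromatic bonds, soft non-bonded
#' repulsion, and signed-volume restraints at stereocentres) from a seeded
#' random start.  The same molecule and seed always give identical
#' coordinates.  Enantiomer pairs are embedded as exact mirror images: the
#' optimisation is always run with the handedness of the first stereocentre
#' normalised, and the result is reflected when the molecule's own tags call
#' for the opposite hand, so their interatomic distance multisets agree to
#' machine precision.
#'
#' @param m a `molecule` from [parse_smiles()].
#' @param seed integer seed controlling the random start.
#' @return the molecule with `coords` set (n_atoms x 3, Angstrom).
#' @export
embed_conformer <- function(m, seed = 1L) {
  stopifnot(inherits(m, "molecule"), m$n_atoms >= 1L)
  n <- m$n_atoms
  if (n == 1L) { m$coords <- matrix(0, 1L, 3L); return(m) }
  bonds <- m$bonds
  if (n == 2L && nrow(bonds) == 1L) {
    L <- bond_length_target(m$atoms$element[1], m$atoms$element[2], bonds$order[1])
    m$coords <- rbind(c(0, 0, 0), c(L, 0, 0))
    return(m)
  }
  ch <- chirality_signs(m)
  flip <- length(ch$signs) > 0L && ch$signs[1L] < 0L
  signs <- if (flip) -ch$signs else ch$signs
  hyb <- atom_hybridization(m)
  gd <- graph_distances(m)
  nb <- mol_neighbors(m)

  ## precomputed term tables
  blen <- cbind(bonds$i, bonds$j,
                mapply(function(i, j, o) bond_length_target(m$atoms$element[i], m$atoms$element[j], o),
                       bonds$i, bonds$j, bonds$order))
  ang <- NULL
  for (j in seq_len(n)) {
    nbs <- nb[[j]]
    if (length(nbs) >= 2L) {
      cmb <- utils::combn(sort(nbs), 2L)
      th0 <- switch(hyb[j], sp = pi, sp2 = 2 * pi / 3, 109.47 * pi / 180)
      ang <- rbind(ang, cbind(t(cmb)[, 1], j, t(cmb)[, 2], cos(th0)))
    }
  }
  sp2c <- which(hyb == "sp2" & vapply(nb, length, 0L) >= 3L)
  arotor <- NULL  # torsions across aromatic/double bonds kept planar
  for (r in seq_len(nrow(bonds))) {
    if (bonds$order[r] %in% c(2L, 4L)) {
      jj <- bonds$i[r]; kk <- bonds$j[r]
      for (ii in setdiff(nb[[jj]], kk)) for (ll in setdiff(nb[[kk]], jj))
        if (ii != ll) arotor <- rbind(arotor, c(ii, jj, kk, ll))
    }
  }
  far <- which(gd >= 3 & upper.tri(gd), arr.ind = TRUE)
  crossr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                 a[, 1] * b[, 2] - a[, 2] * b[, 1])

  ## penalty energy and its analytic gradient, evaluated together
  eval_obj <- function(x, want_grad = FALSE) {
    X <- matrix(x, n, 3L)
    G <- matrix(0, n, 3L)
    addg <- function(i, g) G[i, ] <<- G[i, ] + g
    e <- 0
    ## bond lengths
    dv <- X[blen[, 1], , drop = FALSE] - X[blen[, 2], , drop = FALSE]
    d <- pmax(sqrt(rowSums(dv^2)), 1e-9)
    e <- e + 10 * sum((d - blen[, 3])^2)
    if (want_grad) {
      co <- 20 * (d - blen[, 3]) / d
      for (r in seq_len(nrow(blen))) {
        addg(blen[r, 1], co[r] * dv[r, ])
        addg(blen[r, 2], -co[r] * dv[r, ])
      }
    }
    ## bond angles via cosine matching
    if (!is.null(ang)) {
      u <- X[ang[, 1], , drop = FALSE] - X[ang[, 2], , drop = FALSE]
      v <- X[ang[, 3], , drop = FALSE] - X[ang[, 2], , drop = FALSE]
      cu <- pmax(sqrt(rowSums(u^2)), 1e-9); cv <- pmax(sqrt(rowSums(v^2)), 1e-9)
      cs <- rowSums(u * v) / (cu * cv)
      e <- e + 3 * sum((cs - ang[, 4])^2)
      if (want_grad) {
        co <- 6 * (cs - ang[, 4])
        gu <- (v / (cu * cv) - cs * u / cu^2) * co
        gv <- (u / (cu * cv) - cs * v / cv^2) * co
        for (r in seq_len(nrow(ang))) {
          addg(ang[r, 1], gu[r, ])
          addg(ang[r, 3], gv[r, ])
          addg(ang[r, 2], -gu[r, ] - gv[r, ])
        }
      }
    }
    ## sp2 planarity (squared triple product at the centre)
    for (j in sp2c) {
      ns <- nb[[j]][1:3]
      u <- X[ns[1], ] - X[j, ]; v <- X[ns[2], ] - X[j, ]; w <- X[ns[3], ] - X[j, ]
      vw <- c(v[2] * w[3] - v[3] * w[2], v[3] * w[1] - v[1] * w[3], v[1] * w[2] - v[2] * w[1])
      vol <- sum(u * vw)
      e <- e + 3 * vol^2
      if (want_grad) {
        wu <- c(w[2] * u[3] - w[3] * u[2], w[3] * u[1] - w[1] * u[3], w[1] * u[2] - w[2] * u[1])
        uv <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
        co <- 6 * vol
        addg(ns[1], co * vw); addg(ns[2], co * wu); addg(ns[3], co * uv)
        addg(j, -co * (vw + wu + uv))
      }
    }
    ## planarity across double/aromatic bonds (triple product of bond vectors)
    if (!is.null(arotor)) {
      b1 <- X[arotor[, 2], , drop = FALSE] - X[arotor[, 1], , drop = FALSE]
      b2 <- X[arotor[, 3], , drop = FALSE] - X[arotor[, 2], , drop = FALSE]
      b3 <- X[arotor[, 4], , drop = FALSE] - X[arotor[, 3], , drop = FALSE]
      c23 <- crossr(b2, b3); c31 <- crossr(b3, b1); c12 <- crossr(b1, b2)
      vol <- rowSums(b1 * c23)
      e <- e + 1 * sum(vol^2)
      if (want_grad) {
        co <- 2 * vol
        for (r in seq_len(nrow(arotor))) {
          g1 <- co[r] * c23[r, ]; g2 <- co[r] * c31[r, ]; g3 <- co[r] * c12[r, ]
          addg(arotor[r, 1], -g1)
          addg(arotor[r, 2], g1 - g2)
          addg(arotor[r, 3], g2 - g3)
          addg(arotor[r, 4], g3)
        }
      }
    }
    ## soft non-bonded repulsion (graph distance >= 3)
    if (nrow(far)) {
      dv2 <- X[far[, 1], , drop = FALSE] - X[far[, 2], , drop = FALSE]
      d2 <- pmax(sqrt(rowSums(dv2^2)), 1e-9)
      pen <- pmax(0, 2.7 - d2)
      e <- e + 0.6 * sum(pen^2)
      if (want_grad) {
        act <- which(pen > 0)
        for (r in act) {
          co <- -1.2 * pen[r] / d2[r]
          addg(far[r, 1], co * dv2[r, ])
          addg(far[r, 2], -co * dv2[r, ])
        }
      }
    }
    ## stereocentre handedness (hinge on the signed volume)
    if (length(ch$centers)) {
      for (q in seq_along(ch$centers)) {
        c0 <- ch$centers[q]; ns <- ch$nbrs[[q]]
        u <- X[ns[1], ] - X[c0, ]; v <- X[ns[2], ] - X[c0, ]; w <- X[ns[3], ] - X[c0, ]
        vw <- c(v[2] * w[3] - v[3] * w[2], v[3] * w[1] - v[1] * w[3], v[1] * w[2] - v[2] * w[1])
        vol <- sum(u * vw)
        gap <- max(0, 1.0 - signs[q] * vol)
        e <- e + 5 * gap^2
        if (want_grad && gap > 0) {
          wu <- c(w[2] * u[3] - w[3] * u[2], w[3] * u[1] - w[1] * u[3], w[1] * u[2] - w[2] * u[1])
          uv <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
          co <- -10 * gap * signs[q]
          addg(ns[1], co * vw); addg(ns[2], co * wu); addg(ns[3], co * uv)
          addg(c0, -co * (vw + wu + uv))
        }
      }
    }
    if (want_grad) list(e = e, g = as.vector(G)) else e
  }
  obj <- function(x) eval_obj(x, FALSE)
  grd <- function(x) eval_obj(x, TRUE)$g

  ok <- FALSE
  X <- NULL
  for (attempt in 0:5) {
    x0 <- with_local_seed(derive_seed(seed, attempt),
                          stats::rnorm(3L * n, sd = 0.6 + 0.45 * n^(1 / 3)))
    fit <- stats::optim(x0, obj, grd, method = "BFGS",
                        control = list(maxit = 600, reltol = 1e-12))
    Xc <- matrix(fit$par, n, 3L)
    d <- sqrt(rowSums((Xc[bonds$i, , drop = FALSE] - Xc[bonds$j, , drop = FALSE])^2))
    allpair <- stats::dist(Xc)
    if (all(d > 0.5 & d < 3.0) && min(allpair) > 0.7) { ok <- TRUE; X <- Xc; break }
  }
  if (!ok) {
    warning(sprintf("embed_conformer: geometry optimisation failed for %s; molecule skipped",
                    m$smiles %||% "<molecule>"))
    stop(sprintf("geometry error: could not embed %s", m$smiles %||% "<molecule>"))
  }
  if (flip) X[, 3] <- -X[, 3]
  X <- X - matrix(colMeans(X), n, 3L, byrow = TRUE)
  m$coords <- X
  validate_molecule(m)
  m
}

#' Read molecules from an SDF file
#'
#' Coordinates present in the file are kept (overriding any later conformer
#' embedding); hydrogens are dropped so molecules follow the heavy-atom
#' convention.  Records that fail to convert are skipped with a warning.
#'
#' @param path SDF file (V2000).
#' @return list of `molecule` objects.
#' @export
read_sdf <- function(path) {
  stopifnot(file.exists(path))
  sdfs <- ChemmineR::read.SDFset(path)
  out <- list()
  nfail <- 0L
  for (k in seq_along(sdfs)) {
    mol <- tryCatch({
      sdf <- sdfs[[k]]
      ab <- ChemmineR::atomblock(sdf)
      bb <- ChemmineR::bondblock(sdf)
      elems <- gsub("_[0-9]+$", "", rownames(ab))
      heavy <- which(elems != "H")
      remap <- match(seq_along(elems), heavy)
      bonds <- data.frame(i = remap[bb[, 1]], j = remap[bb[, 2]], order = as.integer(bb[, 3]))
      bonds <- bonds[!is.na(bonds$i) & !is.na(bonds$j), , drop = FALSE]
      sw <- bonds$i > bonds$j
      tmp <- bonds$i[sw]; bonds$i[sw] <- bonds$j[sw]; bonds$j[sw] <- tmp
      bonds <- unique(bonds[order(bonds$i, bonds$j), , drop = FALSE])
      rownames(bonds) <- NULL
      smi <- tryCatch(sub("[\t\n ].*$", "",
                          ChemmineOB::convertFormat("SDF", "CAN", paste(c(ChemmineR::sdf2str(sdf), ""), collapse = "\n"))),
                      error = function(e) NA_character_)
      m <- list(atoms = data.frame(element = elems[heavy], charge = 0L, chiral = "none",
                                   aromatic = FALSE, nH = NA_integer_, stringsAsFactors = FALSE),
                bonds = bonds, coords = unname(ab[heavy, 1:3, drop = FALSE]),
                n_atoms = length(heavy), stereo_nbrs = NULL,
                smiles = smi, smiles_input = smi)
      class(m) <- "molecule"
      validate_molecule(m)
      m
    }, error = function(e) NULL)
    if (is.null(mol)) nfail <- nfail + 1L else out[[length(out) + 1L]] <- mol
  }
  if (nfail > 0L) warning(sprintf("read_sdf: %d record(s) skipped", nfail))
  out
}

#' Write molecules to an SDF (V2000) file
#' @param mols list of `molecule` objects (coordinates optional; zeros written
#'   when absent).
#' @param path output path.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in mols) {
    X <- m$coords %||% matrix(0, m$n_atoms, 3L)
    lines <- c(m$smiles %||% "molecule", "  molbert", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", m$n_atoms, nrow(m$bonds)))
    for (a in seq_len(m$n_atoms))
      lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                                X[a, 1], X[a, 2], X[a, 3], m$atoms$element[a]))
    for (r in seq_len(nrow(m$bonds)))
      lines <- c(lines, sprintf("%3d%3d%3d  0", m$bonds$i[r], m$bonds$j[r],
                                min(m$bonds$order[r], 4L)))
    lines <- c(lines, "M  END", "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a property table (CSV with a smiles column)
#'
#' The file must contain a column named `smiles` (case-insensitive); all
#' other columns are treated as property labels.  Columns whose non-missing
#' values are all in \{0, 1\} are typed as binary classification tasks,
#' everything else as regression.  Records whose SMILES fail to parse are
#' dropped with a warning reporting the count.
#'
#' @param path CSV file path.
#' @return a `property_table`: list with `records` (data.frame), `task_types`
#'   (named character vector).
#' @export
read_table <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  sc <- which(tolower(names(df)) == "smiles")
  if (!length(sc)) stop("read_table: format error: no 'smiles' column in ", path)
  names(df)[sc[1L]] <- "smiles"
  keep <- vapply(df$smiles, function(s)
    !inherits(tryCatch(parse_smiles(s, canonicalize = FALSE), error = identity), "error"),
    TRUE)
  if (any(!keep)) warning(sprintf("read_table: %d unparseable record(s) skipped", sum(!keep)))
  df <- df[keep, , drop = FALSE]
  props <- setdiff(names(df), "smiles")
  if (!length(props)) stop("read_table: no property columns")
  task_types <- vapply(props, function(p) {
    v <- df[[p]][!is.na(df[[p]])]
    if (length(v) && is.numeric(v) && all(v %in% c(0, 1))) "binary" else "regression"
  }, "")
  pt <- list(records = df, task_types = task_types)
  class(pt) <- "property_table"
  pt
}

#' @export
print.property_table <- function(x, ...) {
  cat(sprintf("<property_table> %d records, tasks: %s\n", nrow(x$records),
              paste(sprintf("%s (%s)", names(x$task_types), x$task_types), collapse = ", ")))
  invisible(x)
}

#' Write a property table to CSV
#' @param pt a `property_table`.
#' @param path output path.
#' @export
write_table <- function(pt, path) {
  utils::write.csv(pt$records, path, row.names = FALSE)
  invisible(path)
}

## ---- synthetic fixtures ----

## Deterministic part of the fixture label: a linear function of composition.
## y = 0.8 nC + 2.5 nO + 1.8 nN + 3.0 n(F,Cl,Br,I) + 0.5 n(aromatic atoms)
fixture_label <- function(m) {
  e <- m$atoms$element
  0.8 * sum(e == "C") + 2.5 * sum(e == "O") + 1.8 * sum(e == "N") +
    3.0 * sum(e %in% c("F", "Cl", "Br", "I")) + 0.5 * sum(m$atoms$aromatic)
}

## random alkyl tree SMILES with nc carbons
random_alkane <- function(nc) {
  if (nc == 1L) return("C")
  ## grow a random tree, then write it by DFS
  parent <- c(0L, vapply(2:nc, function(k) sample.int(k - 1L, 1L), 0L))
  kids <- split(seq_len(nc)[-1L], parent[-1L])
  wr <- function(a) {
    ks <- kids[[as.character(a)]]
    if (is.null(ks)) return("C")
    sub <- vapply(ks, wr, "")
    k <- length(sub)
    branches <- if (k > 1L) paste0("(", sub[-k], ")", collapse = "") else ""
    paste0("C", branches, sub[k])
  }
  wr(1L)
}

#' Generate synthetic molecule fixtures with a learnable label
#'
#' Emits `n` distinct valid SMILES drawn from parameterised templates
#' (alkanes, ethers, alcohols, amines, halides, benzene derivatives; 2-16
#' heavy atoms) with a regression label `y` computed by a documented
#' closed-form function of composition ([fixture_label()]) plus Gaussian
#' noise with sd `noise_sd`.  With `include_chiral_pairs`, @/@@ enantiomer
#' pairs are included.
#'
#' @param n number of molecules (>= 1).
#' @param seed integer seed; the same (n, seed) always gives the same table.
#' @param include_chiral_pairs include enantiomer pairs differing only in
#'   their stereo tag.
#' @param noise_sd standard deviation of the label noise (default 0.1).
#' @return a `property_table` with columns `smiles`, `y`.
#' @export
generate_fixtures <- function(n, seed = 1L, include_chiral_pairs = FALSE,
                              noise_sd = 0.1) {
  stopifnot(n >= 1L)
  with_local_seed(seed, {
    smis <- character(0)
    seen <- character(0)
    halides <- c("F", "Cl", "Br")
    hetero_caps <- c("O", "N", "OC", "NC", "O", "N")
    chiral_groups <- c("N", "O", "Cl", "CC", "CO", "C(=O)O")
    add <- function(s) {
      can <- tryCatch(canonical_smiles(s), error = function(e) NA_character_)
      if (is.na(can) || can %in% seen) return(FALSE)
      ok <- !inherits(tryCatch(parse_smiles(s, canonicalize = FALSE), error = identity), "error")
      if (!ok) return(FALSE)
      seen <<- c(seen, can)
      smis <<- c(smis, s)
      TRUE
    }
    if (include_chiral_pairs) {
      while (length(smis) < min(n, 6L) && length(smis) + 2L <= n + 1L) {
        gs <- sample(chiral_groups, 2L)
        base <- sprintf("C[C@H](%s)%s", gs[1L], gs[2L])
        mirr <- sprintf("C[C@@H](%s)%s", gs[1L], gs[2L])
        if (add(base)) add(mirr)
        if (length(smis) >= n) break
      }
    }
    guard <- 0L
    while (length(smis) < n && guard < 50L * n) {
      guard <- guard + 1L
      kind <- sample(c("alkane", "ether", "amine", "alcohol", "halide",
                       "benzene", "ring"), 1L,
                     prob = c(0.12, 0.12, 0.12, 0.12, 0.12, 0.2, 0.2))
      nc <- sample(2:10, 1L)
      s <- switch(kind,
        alkane = random_alkane(nc),
        ether = paste0(random_alkane(sample(1:4, 1L)), "O", random_alkane(sample(1:4, 1L))),
        amine = paste0(random_alkane(nc), "N"),
        alcohol = paste0(random_alkane(nc), "O"),
        halide = paste0(random_alkane(nc), sample(halides, 1L)),
        benzene = {
          nsub <- sample(0:2, 1L)
          core <- c("c1", "c", "c", "c", "c", "c1")
          if (nsub > 0) {
            subs <- sample(c("C", "CC", "O", "N", "Cl", "CCO", "C(C)C"), nsub, replace = TRUE)
            pos <- sample(6L, nsub)
            for (q in seq_len(nsub)) core[pos[q]] <- paste0(core[pos[q]], "(", subs[q], ")")
          }
          paste(core, collapse = "")
        },
        ring = {
          core <- sample(c("C1CCCCC1", "C1CCCC1", "C1CCC1", "C1CCNCC1",
                           "C1CCOC1", "C1CCOCC1", "C1CCNC1", "C1CNCCN1",
                           "C1COCCN1", "c1ccncc1", "c1ccoc1", "c1ccsc1",
                           "c1cncnc1", "c1ccc2ccccc2c1",
                           "c1ccc(cc1)C1CCCCC1", "c1ccc(cc1)c1ccccc1"), 1L)
          sub <- sample(c("", "C", "CC", "CCC", "CCCC", "OC", "NC"), 1L)
          paste0(sub, core)
        })
      m <- tryCatch(parse_smiles(s, canonicalize = FALSE), error = function(e) NULL)
      if (is.null(m) || m$n_atoms < 2L || m$n_atoms > 16L) next
      add(s)
    }
    if (length(smis) < n)
      stop("generate_fixtures: could not generate enough distinct molecules")
    smis <- smis[seq_len(n)]
    y <- vapply(smis, function(s) fixture_label(parse_smiles(s, canonicalize = FALSE)), 0) +
      stats::rnorm(n, sd = noise_sd)
    pt <- list(records = data.frame(smiles = unname(smis), y = unname(y),
                                    stringsAsFactors = FALSE),
               task_types = c(y = "regression"))
    class(pt) <- "property_table"
    pt
  })
}
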