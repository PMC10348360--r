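## SMILES parsing into a heavy-atom molecular graph.
##
## The tokenizer, the chirality handling and the conformer embedder all need
## the atom order and the stereo-neighbour order exactly as written in the
## SMILES string, so parsing is done in-package for the organic subset used
## here (B, C, N, O, F, P, S, Cl, Br, I; aromatic b,c,n,o,p,s; bracket atoms
## with charge, H count and @/@@ tags; branches, ring closures, dots).
## Canonical SMILES are obtained through Open Babel (ChemmineOB).

.ELEMENTS2 <- c("Cl", "Br")
.ELEMENTS1 <- c("B", "C", "N", "O", "F", "P", "S", "I")
.AROMATIC1 <- c("b", "c", "n", "o", "p", "s")

#' Parse a SMILES string into a molecule
#'
#' Builds a heavy-atom graph: implicit hydrogens are not materialised as
#' atoms.  Chiral tags (`@` / `@@`) are preserved per atom, along with the
#' neighbour order needed to interpret them.  The canonical SMILES (Open
#' Babel) is stored on the molecule.
#'
#' @param s SMILES string (non-empty).
#' @param canonicalize compute and store the canonical SMILES (default TRUE;
#'   turn off in tight loops where only the graph is needed).
#' @return An object of class `molecule` with components `atoms`
#'   (data.frame: element, charge, chiral, aromatic, nH), `bonds`
#'   (data.frame: i, j, order with i < j, 1-based), `coords` (NULL until
#'   [embed_conformer()] is called), `smiles`, `n_atoms`, and per-atom
#'   stereo neighbour bookkeeping used by the embedder.
#' @examples
#' m <- parse_smiles("CCO")
#' m$n_atoms        # 3
#' nrow(m$bonds)    # 2
#' @export
parse_smiles <- function(s, canonicalize = TRUE) {
  if (!is.character(s) || length(s) != 1L || !nzchar(s))
    stop("parse_smiles: input must be a single non-empty string")
  st <- tryCatch(smiles_scan(s), error = function(e)
    stop(sprintf("parse_smiles: cannot parse %s: %s", dQuote(s), conditionMessage(e)), call. = FALSE))
  m <- st
  m$smiles_input <- s
  m$smiles <- if (canonicalize) canonical_smiles(s) else s
  class(m) <- "molecule"
  validate_molecule(m)
  m
}

## core scanner: returns atoms/bonds plus stereo neighbour order
smiles_scan <- function(s) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  atoms <- list()
  bonds <- list()
  ## stereo bookkeeping: for each atom, the neighbour atom indices in SMILES
  ## order; an implicit H is recorded as 0 at the slot where it sits
  nbr_order <- list()
  prev_stack <- integer(0)   # branch stack
  prev <- 0L                 # atom index of the bonding predecessor
  pend_order <- 1L           # bond order queued by a bond symbol
  pend_arom <- FALSE
  ring_open <- list()        # ring-closure digit -> c(atom, order)
  i <- 1L
  add_atom <- function(elem, aromatic, chiral = "none", charge = 0L, nH = NA_integer_) {
    atoms[[length(atoms) + 1L]] <<- list(element = elem, aromatic = aromatic,
                                         chiral = chiral, charge = charge, nH = nH)
    idx <- length(atoms)
    nbr_order[[idx]] <<- integer(0)
    ## bracket-atom implicit H participates in the stereo neighbour order at
    ## the position it is written (right after the preceding atom)
    idx
  }
  add_bond <- function(a, b, order) {
    bonds[[length(bonds) + 1L]] <<- c(min(a, b), max(a, b), order)
    nbr_order[[a]] <<- c(nbr_order[[a]], b)
    nbr_order[[b]] <<- c(nbr_order[[b]], a)
  }
  connect <- function(idx) {
    if (prev > 0L) {
      ord <- pend_order
      if (pend_arom || (atoms[[prev]]$aromatic && atoms[[idx]]$aromatic && ord == 1L && !pend_explicit))
        ord <- 4L
      add_bond(prev, idx, ord)
    }
    prev <<- idx
    pend_order <<- 1L
    pend_arom <<- FALSE
    pend_explicit <<- FALSE
  }
  pend_explicit <- FALSE
  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (two %in% .ELEMENTS2) {
      idx <- add_atom(two, FALSE); connect(idx); i <- i + 2L
    } else if (ch %in% .ELEMENTS1) {
      idx <- add_atom(ch, FALSE); connect(idx); i <- i + 1L
    } else if (ch %in% .AROMATIC1) {
      idx <- add_atom(toupper(ch), TRUE); connect(idx); i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      ba <- parse_bracket_atom(body)
      idx <- add_atom(ba$element, ba$aromatic, ba$chiral, ba$charge, ba$nH)
      connect(idx)
      ## implicit H written inside the bracket occupies the next stereo slot
      if (!is.na(ba$nH) && ba$nH > 0L && ba$chiral != "none")
        nbr_order[[idx]] <- c(nbr_order[[idx]], 0L)
      i <- j + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pend_order <- switch(ch, "-" = 1L, "=" = 2L, "#" = 3L, ":" = 4L, "/" = 1L, "\\" = 1L)
      pend_arom <- identical(ch, ":")
      pend_explicit <- TRUE
      i <- i + 1L
    } else if (ch == "(") {
      prev_stack <- c(prev_stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(prev_stack)) stop("unbalanced parenthesis")
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n) stop("bad ring closure")
        key <- paste(chars[(i + 1L):(i + 2L)], collapse = ""); i <- i + 3L
      } else { key <- ch; i <- i + 1L }
      if (prev == 0L) stop("ring closure before any atom")
      if (is.null(ring_open[[key]])) {
        ring_open[[key]] <- c(prev, pend_order, as.integer(pend_explicit))
        ## reserve the stereo slot for the yet-unknown ring partner
        nbr_order[[prev]] <- c(nbr_order[[prev]], -as.integer(key) - 1000L)
        pend_order <- 1L; pend_explicit <- FALSE
      } else {
        op <- ring_open[[key]]; ring_open[[key]] <- NULL
        a <- op[1L]; ord <- max(op[2L], pend_order)
        if (atoms[[a]]$aromatic && atoms[[prev]]$aromatic && ord == 1L && !op[3L] && !pend_explicit)
          ord <- 4L
        bonds[[length(bonds) + 1L]] <- c(min(a, prev), max(a, prev), ord)
        ## fill the reserved slot on the opening atom
        slot <- which(nbr_order[[a]] == -as.integer(key) - 1000L)[1L]
        nbr_order[[a]][slot] <- prev
        nbr_order[[prev]] <- c(nbr_order[[prev]], a)
        pend_order <- 1L; pend_explicit <- FALSE
      }
    } else if (ch == ".") {
      prev <- 0L; i <- i + 1L
    } else {
      stop(sprintf("unexpected character '%s' at position %d", ch, i))
    }
  }
  if (length(ring_open)) stop("unmatched ring closure")
  if (!length(atoms)) stop("no atoms")
  at <- data.frame(
    element = vapply(atoms, function(a) a$element, ""),
    charge = vapply(atoms, function(a) as.integer(a$charge), 0L),
    chiral = vapply(atoms, function(a) a$chiral, ""),
    aromatic = vapply(atoms, function(a) a$aromatic, FALSE),
    nH = vapply(atoms, function(a) as.integer(a$nH), 0L),
    stringsAsFactors = FALSE
  )
  bd <- if (length(bonds)) {
    b <- do.call(rbind, bonds)
    b <- unique(as.data.frame(b))
    names(b) <- c("i", "j", "order")
    b[order(b$i, b$j), , drop = FALSE]
  } else data.frame(i = integer(0), j = integer(0), order = integer(0))
  rownames(bd) <- NULL
  list(atoms = at, bonds = bd, coords = NULL, n_atoms = nrow(at),
       stereo_nbrs = nbr_order)
}

parse_bracket_atom <- function(body) {
  rx <- "^([0-9]*)([A-Za-z][a-z]?)(@{1,2})?(H([0-9]*))?([+-][0-9]*)?$"
  mt <- regmatches(body, regexec(rx, body))[[1]]
  if (!length(mt)) stop(sprintf("bad bracket atom [%s]", body))
  sym <- mt[3]
  aromatic <- sym %in% .AROMATIC1
  elem <- if (aromatic) toupper(sym) else sym
  if (!elem %in% c(.ELEMENTS1, .ELEMENTS2, "Si", "Se", "As", "Sn", "H"))
    stop(sprintf("unsupported element '%s'", elem))
  chiral <- if (mt[4] == "@") "CCW" else if (mt[4] == "@@") "CW" else "none"
  nH <- if (nzchar(mt[5])) { if (nzchar(mt[6])) as.integer(mt[6]) else 1L } else 0L
  charge <- 0L
  if (nzchar(mt[7])) {
    sign <- if (substr(mt[7], 1, 1) == "+") 1L else -1L
    mag <- substr(mt[7], 2, nchar(mt[7]))
    charge <- sign * (if (nzchar(mag)) as.integer(mag) else 1L)
  }
  list(element = elem, aromatic = aromatic, chiral = chiral, nH = nH, charge = charge)
}

validate_molecule <- function(m) {
  stopifnot(m$n_atoms >= 1L)
  if (nrow(m$bonds)) {
    stopifnot(all(m$bonds$i >= 1L), all(m$bonds$j <= m$n_atoms), all(m$bonds$i < m$bonds$j))
    if (anyDuplicated(m$bonds[, c("i", "j")])) stop("duplicate bonds")
  }
  if (!is.null(m$coords)) {
    stopifnot(is.matrix(m$coords), nrow(m$coords) == m$n_atoms, ncol(m$coords) == 3L)
    if (nrow(m$bonds)) {
      d <- sqrt(rowSums((m$coords[m$bonds$i, , drop = FALSE] -
                         m$coords[m$bonds$j, , drop = FALSE])^2))
      if (any(d <= 0.5 | d >= 3.0))
        stop("bonded interatomic distances outside (0.5, 3.0) Angstrom")
    }
  }
  invisible(m)
}

#' Canonical SMILES via Open Babel
#' @param s a SMILES string
#' @return canonical SMILES string
#' @export
canonical_smiles <- function(s) {
  out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", s),
                  error = function(e) "")
  out <- sub("[\t\n ].*$", "", out)
  if (!nzchar(out)) stop(sprintf("canonicalization failed for %s", dQuote(s)))
  out
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d heavy atoms, %d bonds%s\n",
              x$smiles, x$n_atoms, nrow(x$bonds),
              if (is.null(x$coords)) "" else ", 3D coords"))
  invisible(x)
}

## neighbour lists from the bond table
mol_neighbors <- function(m) {
  nb <- vector("list", m$n_atoms)
  for (r in seq_len(nrow(m$bonds))) {
    i <- m$bonds$i[r]; j <- m$bonds$j[r]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

## bond-order lookup matrix (0 = not bonded)
mol_bond_orders <- function(m) {
  B <- matrix(0L, m$n_atoms, m$n_atoms)
  for (r in seq_len(nrow(m$bonds))) {
    i <- m$bonds$i[r]; j <- m$bonds$j[r]
    B[i, j] <- B[j, i] <- m$bonds$order[r]
  }
  B
}

## Desired sign of the signed volume det[n2-n1, n3-n1, c-n1]-style chirality
## test over the first three heavy neighbours of each stereocentre.
## Convention: for neighbour order (k1,k2,k3,k4) as written in the SMILES
## (implicit H occupying its written slot, 0), "@" (CCW) means k2,k3,k4 turn
## counter-clockwise when viewed from k1.  Removing the H from the 4-slot
## list to leave three heavy neighbours multiplies the parity by the sign of
## the permutation that moves H to the end.
chirality_signs <- function(m) {
  out <- integer(0)
  idx <- integer(0)
  nbrs <- list()
  for (a in seq_len(m$n_atoms)) {
    tag <- m$atoms$chiral[a]
    if (identical(tag, "none") || !nzchar(tag)) next
    ord <- m$stereo_nbrs[[a]]
    if (length(ord) < 3L) next
    s <- if (identical(tag, "CW")) 1L else -1L
    hpos <- which(ord == 0L)
    if (length(hpos)) {
      ## move H to the last slot; each adjacent transposition flips parity
      s <- s * (-1L)^(length(ord) - hpos[1L])
      ord <- ord[ord != 0L]
    }
    if (length(ord) < 3L) next
    idx <- c(idx, a)
    out <- c(out, s)
    nbrs[[length(nbrs) + 1L]] <- ord[1:3]
  }
  list(centers = idx, signs = out, nbrs = nbrs)
}
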