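# Shared small fixtures: a reduced encoder configuration and a handful of
# featurized molecules, built once per test run.

tiny_cfg <- function(seed = 7L, ...) {
  encoder_config(n_layers = 2L, d_model = 32L, n_heads = 2L, init_seed = seed, ...)
}

# lazily cached featurizations keyed by a label
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

tiny_feats <- function() cached("tiny_feats", {
  cfg <- tiny_cfg()
  featurize_molecules(c("CCO", "CC(=O)N", "c1ccccc1", "C[C@H](N)C(=O)O"),
                      cfg, seed = 4L)
})

# graph invariants used for isomorphism-level comparisons
graph_signature <- function(m) {
  bo <- paste(pmin(m$atoms$element[m$bonds$i], m$atoms$element[m$bonds$j]),
              pmax(m$atoms$element[m$bonds$i], m$atoms$element[m$bonds$j]),
              m$bonds$order)
  deg <- tabulate(c(m$bonds$i, m$bonds$j), m$n_atoms)
  list(n = m$n_atoms, elements = sort(m$atoms$element),
       degrees = sort(deg), bonds = sort(bo))
}

# independent scalar-loop oracle for angles and torsions (vector algebra
# written long-hand, no shared code with the package kernels)
oracle_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  cx <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
  atan2(sqrt(sum(cx^2)), sum(u * v))
}

oracle_torsion <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3], b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3], b2[1] * b3[2] - b2[2] * b3[1])
  acos(min(max(sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2)), -1), 1))
}
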