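# Shared test helpers: quick profile builders, random graphs, and
# independent definitional oracles used to cross-check the implementation.

profile_from_newick <- function(...) {
  read_profile(text = c(...))
}

quartet_profile_incompatible <- function() {
  profile_from_newick("((a,b),(c,d));", "((a,c),(b,d));")
}

# connected Erdos-Renyi graph as a plain list(vertices, edges)
random_connected_graph <- function(n, p = 0.4) {
  repeat {
    m <- matrix(stats::runif(n * n) < p, n, n)
    m[lower.tri(m, diag = TRUE)] <- FALSE
    idx <- which(m, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    vs <- sprintf("v%d", seq_len(n))
    edges <- cbind(vs[idx[, 1L]], vs[idx[, 2L]])
    comp <- supercut:::graph_components(vs, edges)
    if (max(comp) == 1L) return(list(vertices = vs, edges = edges))
  }
}

# definitional oracle: F is a minimal cut iff G - F is disconnected and no
# maximal proper subset of F disconnects G
oracle_is_minimal_cut <- function(g, f) {
  comps <- function(edges) max(supercut:::graph_components(g$vertices, edges))
  if (comps(supercut:::drop_edges(g$edges, f)) < 2L) return(FALSE)
  for (e in f) {
    if (comps(supercut:::drop_edges(g$edges, setdiff(f, e))) > 1L) return(FALSE)
  }
  TRUE
}

# definitional oracle: U is a minimal separator iff it is a minimal a-b
# separator for some nonadjacent pair a, b
oracle_is_minimal_separator <- function(g, u) {
  vs <- g$vertices
  keyd <- supercut:::edge_keys(g$edges)
  adjacent <- function(a, b) supercut:::edge_key(a, b) %in% keyd
  separates <- function(rem, a, b) {
    keep <- setdiff(vs, rem)
    sub <- g$edges[g$edges[, 1L] %in% keep & g$edges[, 2L] %in% keep, , drop = FALSE]
    comp <- supercut:::graph_components(keep, sub)
    comp[[a]] != comp[[b]]
  }
  outside <- setdiff(vs, u)
  for (a in outside) for (b in outside) {
    if (a >= b || adjacent(a, b)) next
    if (!separates(u, a, b)) next
    ok <- TRUE
    for (x in u) if (separates(setdiff(u, x), a, b)) { ok <- FALSE; break }
    if (ok) return(TRUE)
  }
  FALSE
}

# all minimal cuts by brute force over every edge subset (tiny graphs only)
oracle_all_minimal_cuts <- function(g) {
  keys <- supercut:::edge_keys(g$edges)
  out <- list()
  for (mask in seq_len(2^length(keys) - 1L)) {
    f <- keys[bitwAnd(mask, bitwShiftL(1L, seq_along(keys) - 1L)) != 0L]
    if (oracle_is_minimal_cut(g, f)) out[[length(out) + 1L]] <- sort(f)
  }
  sig <- vapply(out, paste, "", collapse = ";")
  out[!duplicated(sig)]
}

cut_signatures <- function(cuts) sort(vapply(cuts, paste, "", collapse = ";"))

random_recipe_profile <- function(seed, n_labels = 6L, n_trees = 2L,
                                  sizes = n_labels - 1L, contraction = 0.3,
                                  perturb = "none") {
  random_profile(profile_recipe(n_labels = n_labels, n_trees = n_trees,
                                subset_sizes = sizes,
                                contraction_prob = contraction,
                                perturb = perturb, seed = seed))
}
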