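# Display graph G(P) and edge label intersection graph LG(P) (the line graph
# of the display graph), together with the cut and separator machinery:
# minimality, legality, niceness, parallelism, and cut-induced splits.
#
# A cut is represented as a sorted character vector of edge keys "u--v"; a
# separator is a sorted character vector of ELIG vertex ids, which are the
# same edge keys.

#' Build the display graph of a profile
#'
#' The vertex set is the union of the tree vertex sets with equal-label
#' leaves identified; every edge keeps the index of the input tree it came
#' from.  An edge is internal iff both endpoints are internal vertices.
#'
#' @param profile a [ps_profile].
#' @return object of class `display_graph`: list with `vertices`, `edges`
#'   (two-column character matrix), `tree` (provenance index per edge),
#'   `leaves`, `keys` (canonical edge keys), and `components` (vertex
#'   membership; the deciders partition the profile when there are several).
#' @export
build_display_graph <- function(profile) {
  stopifnot(inherits(profile, "ps_profile"))
  edges <- matrix(character(0), 0L, 2L)
  tree_of <- integer(0)
  for (i in seq_along(profile$trees)) {
    tr <- profile$trees[[i]]
    if (nrow(tr$edges) > 0L) {
      edges <- rbind(edges, tr$edges)
      tree_of <- c(tree_of, rep(i, nrow(tr$edges)))
    }
  }
  vertices <- sort(unique(c(profile$labels,
                            unlist(lapply(profile$trees, `[[`, "vertices")))))
  keys <- edge_keys(edges)
  if (anyDuplicated(keys)) internal_error("duplicate display edge")
  structure(
    list(vertices = vertices, edges = edges, tree = tree_of,
         leaves = profile$labels, keys = keys,
         components = graph_components(vertices, edges)),
    class = "display_graph"
  )
}

#' @export
print.display_graph <- function(x, ...) {
  cat(sprintf("<display graph: %d vertices (%d leaves), %d edges, %d component(s)>\n",
              length(x$vertices), length(x$leaves), nrow(x$edges),
              max(x$components)))
  invisible(x)
}

# Accept a display graph, an elig, or a plain list(vertices, edges).
as_plain_graph <- function(g) {
  if (inherits(g, "display_graph")) return(list(vertices = g$vertices, edges = g$edges))
  if (inherits(g, "elig")) return(list(vertices = g$vertices, edges = g$edges))
  if (is.list(g) && !is.null(g$vertices) && !is.null(g$edges))
    return(list(vertices = g$vertices, edges = g$edges))
  domain_error("expected a graph (vertices + edges)")
}

display_internal_vertices <- function(display) {
  setdiff(display$vertices, display$leaves)
}

# keys of internal display edges (= internal edges of the input trees)
display_internal_edges <- function(display) {
  internal <- display_internal_vertices(display)
  keep <- display$edges[, 1L] %in% internal & display$edges[, 2L] %in% internal
  display$keys[keep]
}

# per-tree slice F_i of a cut (keys of tree i's edges in f)
cut_tree_slice <- function(display, f, i) {
  intersect(f, display$keys[display$tree == i])
}

#' Build the edge label intersection graph (line graph)
#'
#' Vertices are the edges of the display graph (by edge key); two vertices
#' are adjacent iff the corresponding display edges share an endpoint.
#'
#' @param display a `display_graph`.
#' @return object of class `elig`: `vertices`, `edges` (pairs of edge keys),
#'   `tree_edges` (per input tree, the keys belonging to it), and the
#'   originating `display` graph.
#' @export
build_elig <- function(display) {
  stopifnot(inherits(display, "display_graph"))
  keys <- display$keys
  pairs <- matrix(character(0), 0L, 2L)
  for (v in display$vertices) {
    inc <- keys[display$edges[, 1L] == v | display$edges[, 2L] == v]
    if (length(inc) >= 2L) {
      cmb <- utils::combn(sort(inc), 2L)
      pairs <- rbind(pairs, t(cmb))
    }
  }
  pairs <- unique(pairs)
  ntrees <- if (length(display$tree) > 0L) max(display$tree) else 0L
  tree_edges <- lapply(seq_len(ntrees), function(i) keys[display$tree == i])
  structure(
    list(vertices = keys, edges = pairs, tree_edges = tree_edges,
         display = display),
    class = "elig"
  )
}

#' @export
print.elig <- function(x, ...) {
  cat(sprintf("<edge label intersection graph: %d vertices, %d edges>\n",
              length(x$vertices), nrow(x$edges)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Minimal cuts

#' Is an edge set a minimal cut?
#'
#' `f` is a minimal cut of connected `g` iff `g - f` is disconnected and no
#' proper subset of `f` disconnects `g`; equivalently, `g - f` has exactly two
#' connected components and every edge of `f` joins the two.
#'
#' @param g a graph (display graph or `list(vertices, edges)`), connected.
#' @param f edge set: character vector of edge keys or a two-column matrix.
#' @return logical.
#' @export
is_minimal_cut <- function(g, f) {
  g <- as_plain_graph(g)
  f <- as_edge_keys(f)
  keys <- edge_keys(g$edges)
  if (!all(f %in% keys)) domain_error("cut contains edges not in the graph")
  comp <- graph_components(g$vertices, drop_edges(g$edges, f))
  if (max(comp) != 2L) return(FALSE)
  fe <- keys_to_edges(f)
  all(comp[fe[, 1L]] != comp[fe[, 2L]])
}

#' Enumerate all minimal cuts of a connected graph
#'
#' Minimal cuts are in bijection with vertex bipartitions `(S, V\\S)` whose
#' two sides both induce connected subgraphs; the cut is the boundary
#' `delta(S)`.  Enumeration walks all connected vertex sets containing a
#' fixed root and keeps those with a connected complement.  Exponential but
#' exact; guarded by `max_vertices`.
#'
#' @param g a connected graph.
#' @param max_vertices refuse graphs larger than this (default 18).
#' @return list of cuts (sorted edge-key vectors) in canonical order.
#' @export
enumerate_minimal_cuts <- function(g, max_vertices = 18L) {
  g <- as_plain_graph(g)
  n <- length(g$vertices)
  if (n > max_vertices)
    resource_error(sprintf(
      "graph has %d vertices; raise max_vertices (<= 25) to enumerate cuts", n))
  if (n > 25L) resource_error("cut enumeration supports at most 25 vertices")
  if (!graph_is_connected(g$vertices, g$edges))
    domain_error("cut enumeration requires a connected graph")
  if (n < 2L) return(list())
  vs <- g$vertices
  bit <- as.integer(2^(seq_len(n) - 1L))
  adjmask <- integer(n)
  ei <- match(g$edges[, 1L], vs)
  ej <- match(g$edges[, 2L], vs)
  for (k in seq_along(ei)) {
    adjmask[ei[k]] <- bitwOr(adjmask[ei[k]], bit[ej[k]])
    adjmask[ej[k]] <- bitwOr(adjmask[ej[k]], bit[ei[k]])
  }
  full <- if (n == 31L) -1L else as.integer(2^n - 1L)
  bits_of <- function(mask) which(bitwAnd(mask, bit) != 0L)
  connected_mask <- function(mask) {
    start <- bit[bits_of(mask)[1L]]
    visited <- start
    frontier <- start
    while (frontier != 0L) {
      nxt <- 0L
      for (v in bits_of(frontier)) nxt <- bitwOr(nxt, adjmask[v])
      nxt <- bitwAnd(nxt, bitwAnd(mask, bitwNot(visited)))
      visited <- bitwOr(visited, nxt)
      frontier <- nxt
    }
    visited == mask
  }
  sets <- new.env(parent = emptyenv())
  sets$out <- vector("list", 256L)
  sets$k <- 0L
  record <- function(S) {
    comp <- bitwAnd(full, bitwNot(S))
    if (comp == 0L) return()
    if (!connected_mask(comp)) return()
    sets$k <- sets$k + 1L
    if (sets$k > length(sets$out)) sets$out <- c(sets$out, vector("list", length(sets$out)))
    sets$out[[sets$k]] <- S
  }
  recurse <- function(S, nbr, forbidden) {
    record(S)
    cand <- bitwAnd(nbr, bitwAnd(bitwNot(S), bitwNot(forbidden)))
    for (v in bits_of(cand)) {
      recurse(bitwOr(S, bit[v]), bitwOr(nbr, adjmask[v]), forbidden)
      forbidden <- bitwOr(forbidden, bit[v])
    }
  }
  recurse(bit[1L], adjmask[1L], 0L)
  masks <- sets$out[seq_len(sets$k)]
  keys <- edge_keys(g$edges)
  in1 <- bit[ei]; in2 <- bit[ej]
  cuts <- lapply(masks, function(S) {
    cross <- xor(bitwAnd(S, in1) != 0L, bitwAnd(S, in2) != 0L)
    sort(keys[cross])
  })
  cuts <- cuts[order(vapply(cuts, paste, "", collapse = ";"))]
  cuts[!duplicated(vapply(cuts, paste, "", collapse = ";"))]
}

#' Classify a cut of the display graph as legal and/or nice
#'
#' A cut is legal when, for every input tree, the tree's edges in the cut are
#' incident on a common vertex; it is nice when it is legal and every
#' connected component of the display graph minus the cut has at least one
#' edge.
#'
#' @param display a `display_graph`.
#' @param f a cut (edge keys or matrix).
#' @return list with logicals `legal` and `nice`.
#' @export
classify_cut <- function(display, f) {
  stopifnot(inherits(display, "display_graph"))
  f <- as_edge_keys(f)
  if (!all(f %in% display$keys)) domain_error("cut contains edges not in the display graph")
  legal <- TRUE
  for (i in seq_len(max(display$tree, 0L))) {
    sl <- cut_tree_slice(display, f, i)
    if (length(sl) >= 2L) {
      ends <- keys_to_edges(sl)
      common <- Reduce(intersect, lapply(seq_len(nrow(ends)),
                                         function(r) ends[r, ]))
      if (length(common) == 0L) { legal <- FALSE; break }
    }
  }
  nice <- FALSE
  if (legal) {
    rest <- drop_edges(display$edges, f)
    comp <- graph_components(display$vertices, rest)
    with_edge <- unique(comp[rest[, 1L]])
    nice <- length(setdiff(unique(comp), with_edge)) == 0L
  }
  list(legal = legal, nice = nice)
}

#' Are two minimal cuts parallel?
#'
#' Minimal cuts `f1` and `f2` are parallel when at most one connected
#' component of `g - f1` contains edges of `f2` (edges shared between the two
#' cuts lie in neither component).  The relation is symmetric for minimal
#' cuts.
#'
#' @param g a connected graph.
#' @param f1,f2 minimal cuts.
#' @return logical.
#' @export
cuts_parallel <- function(g, f1, f2) {
  g <- as_plain_graph(g)
  f1 <- as_edge_keys(f1); f2 <- as_edge_keys(f2)
  if (!is_minimal_cut(g, f1) || !is_minimal_cut(g, f2))
    domain_error("parallelism is defined for minimal cuts only")
  comp <- graph_components(g$vertices, drop_edges(g$edges, f1))
  rest <- setdiff(f2, f1)
  if (length(rest) == 0L) return(TRUE)
  fe <- keys_to_edges(rest)
  touched <- unique(comp[fe[, 1L]])   # an edge not in f1 lies inside one side
  length(touched) <= 1L
}

# ---------------------------------------------------------------------------
# Minimal separators

#' Is a vertex set a minimal separator?
#'
#' `u` is a minimal separator of `g` iff `g - u` has at least two full
#' components (components in which every member of `u` has a neighbour).
#'
#' @param g a graph.
#' @param u character vector of vertex ids.
#' @return logical with attribute `"full_components"` (their count).
#' @export
is_minimal_separator <- function(g, u) {
  g <- as_plain_graph(g)
  u <- unique(as.character(u))
  if (!all(u %in% g$vertices)) domain_error("separator contains unknown vertices")
  if (length(u) == 0L || length(u) >= length(g$vertices))
    return(structure(FALSE, full_components = 0L))
  keep <- setdiff(g$vertices, u)
  sub <- g$edges[g$edges[, 1L] %in% keep & g$edges[, 2L] %in% keep, , drop = FALSE]
  comp <- graph_components(keep, sub)
  # neighbours of each u-member among kept vertices
  nfull <- 0L
  for (cid in seq_len(max(comp, 0L))) {
    members <- keep[comp == cid]
    ok <- TRUE
    for (x in u) {
      nb <- c(g$edges[g$edges[, 1L] == x, 2L], g$edges[g$edges[, 2L] == x, 1L])
      if (!any(nb %in% members)) { ok <- FALSE; break }
    }
    if (ok) nfull <- nfull + 1L
  }
  structure(nfull >= 2L, full_components = nfull)
}

#' Enumerate all minimal separators of a connected graph
#'
#' Close-separator closure: seed with `N(C)` for every component `C` of
#' `G - N[v]` over all vertices `v`, then repeatedly expand each discovered
#' separator `S` through `N(C)` for components `C` of `G - (S union N[x])`,
#' `x in S`, until no new separator appears.
#'
#' @param g a connected graph.
#' @param max_vertices guard on graph size (default 64).
#' @return list of separators (sorted vertex-id vectors) in canonical order.
#' @export
enumerate_minimal_separators <- function(g, max_vertices = 64L) {
  g <- as_plain_graph(g)
  n <- length(g$vertices)
  if (n > max_vertices)
    resource_error(sprintf("graph has %d vertices; raise max_vertices", n))
  adj <- adjacency_list(g$vertices, g$edges)
  neighbours_of_set <- function(set) {
    out <- unique(unlist(adj[set], use.names = FALSE))
    setdiff(out, set)
  }
  components_without <- function(removed) {
    keep <- setdiff(g$vertices, removed)
    if (length(keep) == 0L) return(list())
    sub <- g$edges[g$edges[, 1L] %in% keep & g$edges[, 2L] %in% keep, , drop = FALSE]
    comp <- graph_components(keep, sub)
    lapply(seq_len(max(comp)), function(cid) keep[comp == cid])
  }
  seen <- new.env(parent = emptyenv())
  queue <- list()
  add <- function(sep) {
    if (length(sep) == 0L) return()
    key <- paste(sort(sep), collapse = ";")
    if (!is.null(seen[[key]])) return()
    seen[[key]] <- TRUE
    queue[[length(queue) + 1L]] <<- sort(sep)
  }
  for (v in g$vertices) {
    for (C in components_without(c(v, adj[[v]]))) add(neighbours_of_set(C))
  }
  i <- 0L
  while (i < length(queue)) {
    i <- i + 1L
    S <- queue[[i]]
    for (x in S) {
      for (C in components_without(union(S, c(x, adj[[x]]))))
        add(neighbours_of_set(C))
    }
  }
  out <- queue
  out <- Filter(function(S) isTRUE(as.logical(is_minimal_separator(g, S))), out)
  out[order(vapply(out, paste, "", collapse = ";"))]
}

#' Are two minimal separators parallel?
#'
#' `u1` and `u2` are parallel when `g - u1` has at most one component
#' containing vertices of `u2`.
#'
#' @param g a graph.
#' @param u1,u2 minimal separators.
#' @return logical.
#' @export
separators_parallel <- function(g, u1, u2) {
  g <- as_plain_graph(g)
  u1 <- unique(as.character(u1)); u2 <- unique(as.character(u2))
  if (!isTRUE(as.logical(is_minimal_separator(g, u1))) ||
      !isTRUE(as.logical(is_minimal_separator(g, u2))))
    domain_error("parallelism is defined for minimal separators only")
  keep <- setdiff(g$vertices, u1)
  sub <- g$edges[g$edges[, 1L] %in% keep & g$edges[, 2L] %in% keep, , drop = FALSE]
  comp <- graph_components(keep, sub)
  rest <- intersect(u2, keep)
  length(unique(comp[rest])) <= 1L
}

#' Is a separator of the ELIG legal?
#'
#' Legal means: for every input tree, the members that are edges of that tree
#' form a clique in the tree's line graph, i.e. those tree edges share a
#' common endpoint.
#'
#' @param elig an `elig`.
#' @param u character vector of ELIG vertices (display edge keys).
#' @return logical.
#' @export
separator_is_legal <- function(elig, u) {
  stopifnot(inherits(elig, "elig"))
  u <- unique(as.character(u))
  if (!all(u %in% elig$vertices)) domain_error("separator contains unknown ELIG vertices")
  for (te in elig$tree_edges) {
    members <- intersect(u, te)
    if (length(members) >= 2L) {
      ends <- keys_to_edges(members)
      common <- Reduce(intersect, lapply(seq_len(nrow(ends)), function(r) ends[r, ]))
      if (length(common) == 0L) return(FALSE)
    }
  }
  TRUE
}

# ---------------------------------------------------------------------------
# Cut-induced splits

#' Split of the label set induced by a nice minimal cut
#'
#' Removing a nice minimal cut leaves exactly two components, each of which
#' contains at least one leaf; the induced split is the bipartition of the
#' leaves by component.
#'
#' @param display a `display_graph`.
#' @param f a nice minimal cut.
#' @return a split key.
#' @export
cut_to_split <- function(display, f) {
  stopifnot(inherits(display, "display_graph"))
  f <- as_edge_keys(f)
  if (!is_minimal_cut(display, f))
    domain_error("cut_to_split requires a minimal cut")
  cl <- classify_cut(display, f)
  if (!cl$nice) domain_error("cut_to_split requires a nice cut")
  comp <- graph_components(display$vertices, drop_edges(display$edges, f))
  a <- display$leaves[comp[display$leaves] == 1L]
  b <- display$leaves[comp[display$leaves] == 2L]
  split_key(a, b)
}
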