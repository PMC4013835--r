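# Chordality, clique trees, legal (LT1/LT2) and restricted triangulations,
# and the construction of a legal triangulation of the display graph directly
# from a certificate cut set, via the (X_F, Y_F) separator pairs and their
# interpolation families O_F.

as_igraph <- function(g) {
  g <- as_plain_graph(g)
  igraph::graph_from_data_frame(
    as.data.frame(g$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = g$vertices, stringsAsFactors = FALSE))
}

#' Chordality test by maximum cardinality search
#'
#' Runs maximum cardinality search and checks the resulting elimination
#' order; on failure a chordless cycle of length at least four is returned
#' as a witness.
#'
#' @param g a graph.
#' @return list with `chordal` (logical) and either `order` (a perfect
#'   elimination ordering, vertices eliminated first listed first) or
#'   `cycle` (vertex ids of a chordless cycle).
#' @export
is_chordal <- function(g) {
  g <- as_plain_graph(g)
  v <- g$vertices
  n <- length(v)
  if (n <= 3L) return(list(chordal = TRUE, order = v))
  adj <- adjacency_list(v, g$edges)
  weight <- stats::setNames(rep(0L, n), v)
  numbered <- character(0)
  order_mcs <- character(n)       # order_mcs[i] visited i-th (last eliminated first)
  for (i in seq_len(n)) {
    cand <- setdiff(v, numbered)
    x <- cand[which.max(weight[cand])]
    order_mcs[i] <- x
    numbered <- c(numbered, x)
    for (w in adj[[x]]) if (!(w %in% numbered)) weight[[w]] <- weight[[w]] + 1L
  }
  pos <- stats::setNames(seq_len(n), order_mcs)
  for (i in seq(n, 1L)) {
    x <- order_mcs[i]
    earlier <- adj[[x]][pos[adj[[x]]] < i]      # numbered before x
    if (length(earlier) <= 1L) next
    u <- earlier[which.max(pos[earlier])]       # latest-numbered earlier nbr
    others <- setdiff(earlier, u)
    missing <- others[!(others %in% adj[[u]])]
    if (length(missing) > 0L) {
      y <- missing[[1L]]
      # chordless cycle through x: shortest y-u path avoiding N[x] \ {y,u}
      avoid <- setdiff(c(x, adj[[x]]), c(y, u))
      keep <- setdiff(v, avoid)
      sub <- g$edges[g$edges[, 1L] %in% keep & g$edges[, 2L] %in% keep, , drop = FALSE]
      path <- shortest_path_plain(keep, sub, y, u)
      if (is.null(path)) internal_error("failed to extract a chordless cycle witness")
      return(list(chordal = FALSE, cycle = c(x, path)))
    }
  }
  list(chordal = TRUE, order = rev(order_mcs))
}

shortest_path_plain <- function(vertices, edges, from, to) {
  adj <- adjacency_list(vertices, edges)
  prev <- stats::setNames(rep(NA_character_, length(vertices)), vertices)
  seen <- from; queue <- from
  while (length(queue) > 0L) {
    x <- queue[[1L]]; queue <- queue[-1L]
    if (x == to) break
    for (w in adj[[x]]) {
      if (!(w %in% seen)) { seen <- c(seen, w); prev[[w]] <- x; queue <- c(queue, w) }
    }
  }
  if (!(to %in% seen)) return(NULL)
  path <- to
  while (path[[1L]] != from) path <- c(prev[[path[[1L]]]], path)
  path
}

#' Clique tree of a chordal graph
#'
#' Maximal cliques joined by a maximum-weight spanning tree on the clique
#' intersection sizes; the coherence property (each vertex's cliques induce a
#' subtree) is verified before return.  Intersections along tree edges are
#' the minimal separators of the graph.
#'
#' @param h a chordal graph.
#' @return list of class `clique_tree` with `cliques` (list of vertex-id
#'   vectors), `tree_edges` (two-column matrix of clique indices), and
#'   `separators` (intersections along the tree edges).
#' @export
clique_tree <- function(h) {
  hp <- as_plain_graph(h)
  chk <- is_chordal(hp)
  if (!chk$chordal) domain_error("clique_tree requires a chordal graph")
  ig <- as_igraph(hp)
  cl <- lapply(igraph::max_cliques(ig), function(x) sort(names(x)))
  cl <- cl[order(vapply(cl, paste, "", collapse = ","))]
  k <- length(cl)
  if (k == 1L) {
    out <- structure(list(cliques = cl,
                          tree_edges = matrix(integer(0), 0L, 2L),
                          separators = list()),
                     class = "clique_tree")
    return(out)
  }
  pairs <- utils::combn(k, 2L)
  wt <- apply(pairs, 2L, function(p) length(intersect(cl[[p[1L]]], cl[[p[2L]]])))
  keep <- wt > 0L
  cg <- igraph::graph_from_data_frame(
    data.frame(from = as.character(pairs[1L, keep]),
               to = as.character(pairs[2L, keep]),
               weight = -wt[keep]),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(k))))
  mst <- igraph::mst(cg)
  te <- igraph::as_edgelist(mst)
  te <- matrix(as.integer(te), ncol = 2L)
  seps <- lapply(seq_len(nrow(te)), function(r)
    sort(intersect(cl[[te[r, 1L]]], cl[[te[r, 2L]]])))
  # coherence: the cliques containing each vertex induce a subtree
  for (x in hp$vertices) {
    nodes <- which(vapply(cl, function(cc) x %in% cc, logical(1L)))
    sub <- te[te[, 1L] %in% nodes & te[, 2L] %in% nodes, , drop = FALSE]
    if (!graph_is_connected(as.character(nodes),
                            matrix(as.character(sub), ncol = 2L)))
      internal_error("clique tree violates coherence")
  }
  structure(list(cliques = cl, tree_edges = te, separators = seps),
            class = "clique_tree")
}

#' Saturate a graph on a family of vertex sets
#'
#' Makes each member set a clique; idempotent; never removes edges.
#'
#' @param g a graph.
#' @param families list of character vectors of vertex ids.
#' @return a plain graph `list(vertices, edges)`.
#' @export
saturate <- function(g, families) {
  g <- as_plain_graph(g)
  extra <- matrix(character(0), 0L, 2L)
  for (X in families) {
    X <- unique(as.character(X))
    if (!all(X %in% g$vertices)) domain_error("family member outside the vertex set")
    if (length(X) >= 2L) extra <- rbind(extra, t(utils::combn(sort(X), 2L)))
  }
  list(vertices = g$vertices, edges = dedupe_edges(rbind(g$edges, extra)))
}

#' Is a graph a legal triangulation of a display graph?
#'
#' Legal means: chordal; (LT1) no clique contains an internal display edge
#' together with any other display edge; (LT2) no fill-in edge has a leaf as
#' an endpoint.
#'
#' @param display a `display_graph`.
#' @param h a supergraph of the display graph on the same vertex set.
#' @return logical with attribute `"violation"` naming the failed condition
#'   when `FALSE`.
#' @export
is_legal_triangulation <- function(display, h) {
  hp <- as_plain_graph(h)
  if (!setequal(hp$vertices, display$vertices))
    domain_error("triangulation must keep the display vertex set")
  hk <- edge_keys(hp$edges)
  if (!all(display$keys %in% hk))
    domain_error("triangulation must contain every display edge")
  if (!is_chordal(hp)$chordal)
    return(structure(FALSE, violation = "not chordal"))
  fill <- setdiff(hk, display$keys)
  if (length(fill) > 0L) {
    fe <- keys_to_edges(fill)
    if (any(fe[, 1L] %in% display$leaves | fe[, 2L] %in% display$leaves))
      return(structure(FALSE, violation = "LT2: fill-in edge touches a leaf"))
  }
  internal_keys <- display_internal_edges(display)
  ig <- as_igraph(hp)
  for (cl in igraph::max_cliques(ig)) {
    members <- names(cl)
    de <- display$keys[display$edges[, 1L] %in% members &
                       display$edges[, 2L] %in% members]
    if (length(de) >= 2L && any(de %in% internal_keys))
      return(structure(FALSE, violation = "LT1: clique mixes an internal edge with another display edge"))
  }
  TRUE
}

#' Is a graph a restricted triangulation of the ELIG?
#'
#' Restricted means chordal with every fill-in edge valid: no fill-in edge
#' joins two edges of the same input tree.
#'
#' @param elig an `elig`.
#' @param h a supergraph of the ELIG on the same vertex set.
#' @return logical with attribute `"violation"` when `FALSE`.
#' @export
is_restricted_triangulation <- function(elig, h) {
  hp <- as_plain_graph(h)
  if (!setequal(hp$vertices, elig$vertices))
    domain_error("triangulation must keep the ELIG vertex set")
  ek <- row_keys(elig$edges)
  he <- canon_rows(hp$edges)
  hk <- row_keys(he)
  if (!all(ek %in% hk))
    domain_error("triangulation must contain every ELIG edge")
  if (!is_chordal(hp)$chordal)
    return(structure(FALSE, violation = "not chordal"))
  fill <- he[!(hk %in% ek), , drop = FALSE]
  for (r in seq_len(nrow(fill))) {
    for (te in elig$tree_edges) {
      if (fill[r, 1L] %in% te && fill[r, 2L] %in% te)
        return(structure(FALSE, violation = "invalid fill-in edge within one tree"))
    }
  }
  TRUE
}

# ---------------------------------------------------------------------------
# Certificate cuts -> legal triangulation

#' Separator pairs (X_F, Y_F) of an ordered certificate cut set
#'
#' For each cut `F` of a minimally complete, ordered set of pairwise parallel
#' legal minimal cuts, builds the vertex pair `(X_F, Y_F)` by the three
#' construction rules: (1a) an internal sole-slice edge not yet
#' differentiated contributes its two endpoints to the two sides (and is
#' recorded as differentiated by `F`); (1b) an internal sole-slice edge
#' already differentiated by an earlier cut `I` contributes its unique
#' endpoint in the component of the display graph minus `I` that meets `F`,
#' to both sides; (2) a non-internal sole-slice edge contributes its non-leaf
#' endpoint to both sides; (3) a multi-edge tree slice contributes its common
#' endpoint to both sides.  The interpolation family `O_F` is derived from
#' the differentiated pairs.
#'
#' @param display a `display_graph`.
#' @param cutset a `cutset` (order respected).
#' @return list of class `cut_separator_pairs`; one record per cut with
#'   `X`, `Y`, `O` (list), `pairs` (x_i/y_i matrix), `common` (z's), `A`, `B`
#'   (component vertex sets), `slices`, `sole` and `differentiates` (edge
#'   keys first differentiated by this cut).
#' @export
build_cut_separator_pairs <- function(display, cutset) {
  cuts <- cutset$cuts
  for (f in cuts) {
    if (!is_minimal_cut(display, f)) domain_error("precondition failed: minimal")
    if (!classify_cut(display, f)$legal) domain_error("precondition failed: legal")
  }
  if (!cutset_is_complete(display, cuts)) domain_error("precondition failed: complete")
  for (i in seq_along(cuts)) for (j in seq_len(i - 1L)) {
    if (!cuts_parallel(display, cuts[[i]], cuts[[j]]))
      domain_error("precondition failed: pairwise parallel")
  }
  for (i in seq_along(cuts)) {
    if (cutset_is_complete(display, cuts[-i]))
      domain_error("precondition failed: no proper subset complete")
  }
  internal_keys <- display_internal_edges(display)
  ntrees <- max(display$tree)
  diff_by <- list()   # edge key -> cut index that differentiates it
  comp_of <- lapply(cuts, function(f)
    graph_components(display$vertices, drop_edges(display$edges, f)))
  out <- vector("list", length(cuts))
  for (ci in seq_along(cuts)) {
    f <- cuts[[ci]]
    comp <- comp_of[[ci]]
    A <- sort(names(comp)[comp == 1L])
    B <- sort(names(comp)[comp == 2L])
    slices <- lapply(seq_len(ntrees), function(i) cut_tree_slice(display, f, i))
    sole <- unlist(slices[lengths(slices) == 1L], use.names = FALSE)
    X <- character(0); Y <- character(0)
    pairs <- matrix(character(0), 0L, 2L)
    commons <- character(0)
    for (e in sort(sole)) {
      uv <- keys_to_edges(e)[1L, ]
      if (e %in% internal_keys) {
        if (is.null(diff_by[[e]])) {
          xa <- uv[uv %in% A]; yb <- uv[uv %in% B]
          if (length(xa) != 1L || length(yb) != 1L)
            internal_error("cut member does not straddle the two components")
          pairs <- rbind(pairs, c(xa, yb))
          diff_by[[e]] <- ci
        } else {
          I <- cuts[[diff_by[[e]]]]
          icomp <- comp_of[[diff_by[[e]]]]
          rest <- setdiff(f, I)
          if (length(rest) == 0L) internal_error("distinct minimal cuts cannot nest")
          fe <- keys_to_edges(rest)
          qs <- unique(icomp[fe[, 1L]])
          if (length(qs) != 1L)
            internal_error("differentiating cut is not parallel to the current cut")
          qmembers <- names(icomp)[icomp == qs]
          vtx <- uv[uv %in% qmembers]
          if (length(vtx) != 1L)
            internal_error("edge must have a unique endpoint in the meeting component")
          commons <- c(commons, vtx)
        }
      } else {
        nonleaf <- uv[!(uv %in% display$leaves)]
        if (length(nonleaf) != 1L) internal_error("leaf edge with two leaf endpoints")
        commons <- c(commons, nonleaf)
      }
    }
    for (i in which(lengths(slices) > 1L)) {
      ends <- keys_to_edges(slices[[i]])
      common <- Reduce(intersect, lapply(seq_len(nrow(ends)), function(r) ends[r, ]))
      if (length(common) == 0L) internal_error("legal slice without a common endpoint")
      commons <- c(commons, common[[1L]])
    }
    commons <- unique(commons)
    m <- nrow(pairs)
    if (m < 1L)
      internal_error("every cut of a minimally complete set must differentiate an edge")
    X <- unique(c(pairs[, 1L], commons))
    Y <- unique(c(pairs[, 2L], commons))
    O <- lapply(seq_len(m), function(j)
      unique(c(pairs[seq_len(j), 1L], pairs[seq(j, m), 2L], commons)))
    out[[ci]] <- list(X = X, Y = Y, O = O, pairs = pairs, common = commons,
                      A = A, B = B, slices = slices, sole = sort(sole))
  }
  attr(out, "differentiated_by") <- diff_by
  structure(out, class = "cut_separator_pairs")
}

#' Legal triangulation of the display graph from a certificate cut set
#'
#' Saturates the display graph on the family consisting of each leaf's open
#' neighbourhood plus, for every cut, the pair `{X_F, Y_F}` and the
#' interpolation family `O_F`.  The cut set is first minimised to a
#' no-proper-subset-complete subset (canonical order).  The result is
#' verified to be a legal triangulation before it is returned.
#'
#' @param display a `display_graph`.
#' @param cutset a `cutset` (complete, pairwise parallel, legal, minimal).
#' @return list of class `legal_triangulation` with `graph` (the saturated
#'   graph), `fill_in` (edge keys), `families` (the saturation family list)
#'   and `pairs` (the [build_cut_separator_pairs] output).
#' @export
cuts_to_triangulation <- function(display, cutset) {
  cuts <- order_cuts(cutset$cuts)
  i <- 1L
  while (i <= length(cuts)) {
    if (length(cuts) > 1L && cutset_is_complete(display, cuts[-i])) {
      cuts <- cuts[-i]
    } else i <- i + 1L
  }
  cutset <- structure(list(cuts = cuts), class = "cutset")
  pairs <- build_cut_separator_pairs(display, cutset)
  fam <- list()
  for (l in display$leaves) {
    nb <- c(display$edges[display$edges[, 1L] == l, 2L],
            display$edges[display$edges[, 2L] == l, 1L])
    fam[[length(fam) + 1L]] <- unique(nb)
  }
  for (rec in pairs) {
    fam[[length(fam) + 1L]] <- rec$X
    fam[[length(fam) + 1L]] <- rec$Y
    for (o in rec$O) fam[[length(fam) + 1L]] <- o
  }
  h <- saturate(display, fam)
  ok <- is_legal_triangulation(display, h)
  if (!isTRUE(as.logical(ok)))
    internal_error(sprintf("cut-set triangulation failed verification (%s)",
                           attr(ok, "violation")))
  structure(list(graph = h,
                 fill_in = setdiff(edge_keys(h$edges), display$keys),
                 families = fam, pairs = pairs),
            class = "legal_triangulation")
}

#' @export
print.legal_triangulation <- function(x, ...) {
  cat(sprintf("<legal triangulation: %d vertices, %d edges (%d fill-in)>\n",
              length(x$graph$vertices), nrow(x$graph$edges), length(x$fill_in)))
  invisible(x)
}
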