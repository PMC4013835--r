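# Deciding agreement: a profile has an agreement supertree (AST) iff the
# display graph admits a complete set of pairwise parallel legal minimal cuts
# in which every cut contains at most one edge of each input tree.  The
# decider reuses the compatibility search with that extra candidate filter;
# the AST is built from the induced splits and verified by split-set
# equality against every input.  The cut function Psi and the edge-splitting
# surgery are shipped as verification utilities.

#' Find an agreement certificate cut set
#'
#' Same exact search as [find_complete_parallel_cutset], with candidate cuts
#' pre-filtered to those containing at most one edge of every input tree.
#'
#' @param profile a [ps_profile] whose display graph is connected.
#' @param guard a [supercut_guard].
#' @return a `cutset` or `NULL`.
#' @export
find_agreement_cutset <- function(profile, guard = supercut_guard()) {
  search_cutset(build_display_graph(profile), guard, per_tree_limit = TRUE)
}

#' Decide whether a profile has an agreement supertree
#'
#' On success the AST is built from the splits induced by the certificate
#' cuts and verified: its restriction to each input tree's labels must have
#' exactly that tree's split set.
#'
#' @param profile a [ps_profile].
#' @param guard a [supercut_guard].
#' @return list with `has_ast` (`TRUE`/`FALSE`/`NA`), `status`, and
#'   `certificate` (list with per-component `cutsets` and the `ast`).
#' @export
decide_agreement <- function(profile, guard = supercut_guard()) {
  display <- build_display_graph(profile)
  subs <- if (max(display$components) == 1L) list(profile)
          else split_profile_by_component(profile, display)
  cutsets <- list()
  trees <- list()
  for (sp in subs) {
    res <- tryCatch(search_cutset(build_display_graph(sp), guard,
                                  per_tree_limit = TRUE),
                    supercut_guard_exceeded = function(e) e)
    if (inherits(res, "condition"))
      return(list(has_ast = NA, status = "unknown", certificate = NULL))
    if (is.null(res))
      return(list(has_ast = FALSE, status = "no", certificate = NULL))
    sd <- build_display_graph(sp)
    sigma <- vapply(res$cuts, function(f) cut_to_split(sd, f), "")
    sigma <- unique(sigma[!vapply(sigma, split_is_trivial, logical(1L))])
    ast <- tree_from_splits(sigma, sp$labels)
    cutsets[[length(cutsets) + 1L]] <- res
    trees[[length(trees) + 1L]] <- ast
  }
  ast <- join_supertrees(trees, profile$labels)
  for (tr in profile$trees) {
    if (!displays_and_agrees(ast, tr)$agrees)
      internal_error("constructed supertree fails to agree with an input tree")
  }
  cert <- structure(list(cutsets = cutsets, ast = ast),
                    class = "ast_certificate")
  list(has_ast = TRUE, status = "yes", certificate = cert)
}

#' @export
print.ast_certificate <- function(x, ...) {
  cat("<agreement certificate>\n")
  for (cs in x$cutsets) print(cs)
  cat(" agreement supertree:", write_newick(x$ast), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Cut function of an AST

# vertices of the minimal subtree of `tree` connecting `labels`
steiner_vertices <- function(tree, labels) {
  if (length(labels) == 0L) return(character(0))
  if (length(labels) == 1L) return(labels)
  v <- tree$vertices; e <- tree$edges
  repeat {
    deg <- table(factor(c(e[, 1L], e[, 2L]), levels = v))
    drop <- v[deg <= 1L & !(v %in% labels)]
    if (length(drop) == 0L) break
    e <- e[!(e[, 1L] %in% drop | e[, 2L] %in% drop), , drop = FALSE]
    v <- setdiff(v, drop)
  }
  v[v %in% c(labels, unique(as.vector(e)))]
}

#' Cut function of an agreement supertree
#'
#' For each edge `e = {u, v}` of the AST, `Psi(e)` is the set of input-tree
#' edges `f` for which `e` is the agreement edge: the split of `f` has its
#' sides contained in the two label sides `L_u`, `L_v` of `e`.  Every
#' `Psi(e)` is a cut of the display graph; it is a minimal cut iff its
#' removal leaves exactly two components.
#'
#' @param ast a [pstree] that agrees with every tree of `profile`.
#' @param profile a [ps_profile].
#' @return object of class `cut_function`: list with `edges` (AST edge keys),
#'   `psi` (named list of display edge-key vectors), `sides` (per edge, the
#'   label sets `L_u`, `L_v`), `vsets` (per edge, the display-vertex sets
#'   `V_u`, `V_v`), and `minimal` (named logical).
#' @export
cut_function <- function(ast, profile) {
  for (tr in profile$trees) {
    if (!displays_and_agrees(ast, tr)$agrees)
      domain_error("the supertree does not agree with every input tree")
  }
  display <- build_display_graph(profile)
  esm <- edge_split_map(ast)
  adj <- adjacency_list(ast$vertices, ast$edges)
  tree_maps <- lapply(profile$trees, edge_split_map)
  psi <- list(); sides <- list(); vsets <- list()
  minimal <- logical(0)
  for (r in seq_len(nrow(ast$edges))) {
    u <- ast$edges[r, 1L]; v <- ast$edges[r, 2L]
    k <- edge_key(u, v)
    # labels on each side of e (side of v first computed like edge_split_map)
    seen <- v; queue <- v
    while (length(queue) > 0L) {
      x <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj[[x]]) {
        if (x == v && w == u) next
        if (!(w %in% seen)) { seen <- c(seen, w); queue <- c(queue, w) }
      }
    }
    lv_side <- intersect(ast$leaves, seen)
    lu_side <- setdiff(ast$leaves, lv_side)
    members <- character(0)
    for (i in seq_along(profile$trees)) {
      tm <- tree_maps[[i]]
      hits <- character(0)
      for (fk in names(tm)) {
        sd <- split_sides(tm[[fk]])
        if ((all(sd$a %in% lu_side) && all(sd$b %in% lv_side)) ||
            (all(sd$a %in% lv_side) && all(sd$b %in% lu_side)))
          hits <- c(hits, fk)
      }
      if (length(hits) > 1L)
        internal_error("more than one agreement edge for one input tree")
      members <- c(members, hits)
    }
    vu <- unique(unlist(lapply(profile$trees, function(tr)
      steiner_vertices(tr, intersect(tr$leaves, lu_side)))))
    vv <- unique(unlist(lapply(profile$trees, function(tr)
      steiner_vertices(tr, intersect(tr$leaves, lv_side)))))
    psi[[k]] <- sort(members)
    sides[[k]] <- list(u = sort(lu_side), v = sort(lv_side))
    vsets[[k]] <- list(u = sort(vu), v = sort(vv))
    comp <- graph_components(display$vertices,
                             drop_edges(display$edges, members))
    minimal[[k]] <- max(comp) == 2L
  }
  structure(list(edges = names(psi), psi = psi, sides = sides,
                 vsets = vsets, minimal = minimal),
            class = "cut_function")
}

#' Split an AST edge at one endpoint
#'
#' The surgery used to make cut-function values minimal: for AST edge
#' `e = {u, v}` whose `Psi(e)` is not a minimal cut, the far side `L_v` is
#' partitioned by the components of the display graph minus `Psi(e)`; the
#' subtree beyond `v` is deleted and, for each part, the minimal connecting
#' subtree is re-attached directly to `u`.  The result is again an AST.
#'
#' @param ast a [pstree] agreeing with every input tree.
#' @param e AST edge (edge key or vertex pair).
#' @param u endpoint of `e` at which to split (the kept side).
#' @param profile a [ps_profile].
#' @return a [pstree].
#' @export
split_edge_at <- function(ast, e, u, profile) {
  e <- as_edge_keys(e)
  uv <- keys_to_edges(e)[1L, ]
  if (!(u %in% uv)) domain_error("u must be an endpoint of e")
  v <- setdiff(uv, u)
  cf <- cut_function(ast, profile)
  if (!(e %in% cf$edges)) domain_error("e is not an edge of the supertree")
  if (cf$minimal[[e]])
    domain_error("splitting applies only to edges with a non-minimal cut-function value")
  display <- build_display_graph(profile)
  comp <- graph_components(display$vertices,
                           drop_edges(display$edges, cf$psi[[e]]))
  # label side beyond v in the ast
  adj <- adjacency_list(ast$vertices, ast$edges)
  seen <- v; queue <- v
  while (length(queue) > 0L) {
    x <- queue[[1L]]; queue <- queue[-1L]
    for (w in adj[[x]]) {
      if (x == v && w == u) next
      if (!(w %in% seen)) { seen <- c(seen, w); queue <- c(queue, w) }
    }
  }
  l_v <- intersect(ast$leaves, seen)
  parts <- split(l_v, comp[l_v])
  if (length(parts) <= 1L)
    domain_error("the far side is not split by the cut; swap the roles of u and v")
  s_v_vertices <- seen          # vertices of the subtree beyond v (incl. v)
  keep_vertices <- setdiff(ast$vertices, s_v_vertices)
  keep_edges <- ast$edges[ast$edges[, 1L] %in% keep_vertices &
                          ast$edges[, 2L] %in% keep_vertices, , drop = FALSE]
  sub_edges <- ast$edges[ast$edges[, 1L] %in% s_v_vertices &
                         ast$edges[, 2L] %in% s_v_vertices, , drop = FALSE]
  # distance from v inside the far subtree, to locate each part's root
  dist <- stats::setNames(rep(NA_integer_, length(s_v_vertices)), s_v_vertices)
  dist[[v]] <- 0L
  queue <- v
  sub_adj <- adjacency_list(s_v_vertices, sub_edges)
  while (length(queue) > 0L) {
    x <- queue[[1L]]; queue <- queue[-1L]
    for (w in sub_adj[[x]]) {
      if (is.na(dist[[w]])) { dist[[w]] <- dist[[x]] + 1L; queue <- c(queue, w) }
    }
  }
  new_edges <- keep_edges
  new_vertices <- keep_vertices
  for (part in parts) {
    sv <- steiner_vertices(
      pstree_skeleton(s_v_vertices, sub_edges, ast$leaves), part)
    pe <- sub_edges[sub_edges[, 1L] %in% sv & sub_edges[, 2L] %in% sv, , drop = FALSE]
    root <- sv[which.min(dist[sv])]
    new_edges <- rbind(new_edges, pe, c(u, root))
    new_vertices <- c(new_vertices, sv)
  }
  out <- suppress_degree2(new_vertices, new_edges, protect = ast$leaves)
  pstree(out$edges, ast$leaves, vertices = out$vertices, index = ast$index)
}

# a light un-validated tree-shaped holder for steiner_vertices
pstree_skeleton <- function(vertices, edges, leaves) {
  structure(list(vertices = vertices, edges = edges,
                 leaves = intersect(leaves, vertices), index = NA_integer_),
            class = "pstree")
}

#' Normalise an AST so all internal-edge cut-function values are minimal cuts
#'
#' Repeatedly applies [split_edge_at] to an internal edge with a largest
#' non-minimal cut-function value (canonical tie-break), preferring the
#' endpoint whose far side is split into more than one part; the loop
#' terminates with every internal-edge value a minimal cut.  Leaf-edge values
#' are not touched: the value of the leaf edge of label `l` is always the set
#' of display edges incident on `l`, so it is minimal exactly when `l` is not
#' a cut vertex of the display graph -- a property of the profile that no
#' supertree surgery can change.
#'
#' @param ast a [pstree] agreeing with every input tree.
#' @param profile a [ps_profile].
#' @param max_iter safety bound on the number of splitting steps.
#' @return a [pstree] (an AST with minimal internal-edge cut values).
#' @export
normalize_ast <- function(ast, profile, max_iter = 200L) {
  for (iter in seq_len(max_iter)) {
    cf <- cut_function(ast, profile)
    internal <- cf$edges[vapply(strsplit(cf$edges, EDGE_SEP, fixed = TRUE),
                                function(uv) !(uv[1L] %in% ast$leaves) &&
                                  !(uv[2L] %in% ast$leaves), logical(1L))]
    bad <- internal[!cf$minimal[internal]]
    if (length(bad) == 0L) return(ast)
    sizes <- lengths(cf$psi[bad])
    e <- sort(bad[sizes == max(sizes)])[1L]
    uv <- sort(keys_to_edges(e)[1L, ])
    ast <- tryCatch(
      split_edge_at(ast, e, uv[1L], profile),
      supercut_domain_error = function(err) split_edge_at(ast, e, uv[2L], profile))
  }
  internal_error("AST normalisation did not converge")
}

# ---------------------------------------------------------------------------
# Brute-force agreement oracle

#' Brute-force agreement-supertree oracle
#'
#' Enumerates every unrooted topology (multifurcating included) on the label
#' universe and tests whether one agrees with all input trees.
#'
#' @param profile a [ps_profile] with at most 6 labels in total.
#' @return logical.
#' @export
brute_force_ast <- function(profile) {
  if (length(profile$labels) > 6L)
    resource_error("brute-force agreement oracle supports at most 6 labels")
  for (cand in all_topologies(profile$labels)) {
    ok <- TRUE
    for (tr in profile$trees) {
      if (!displays_and_agrees(cand, tr)$agrees) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}
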