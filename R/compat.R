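# Deciding compatibility: a profile has a compatible supertree iff its
# display graph admits a complete set of pairwise parallel legal minimal
# cuts.  The decider realises the existential characterization as an exact
# backtracking search over the internal input-tree edges (most-constrained
# first), choosing for each a candidate cut in which it is the sole edge of
# its tree, and pruning on pairwise parallelism.  The supertree is assembled
# from the splits the certificate cuts induce.

#' Search guards for the exact deciders
#'
#' @param max_vertices largest display graph (vertex count) the cut
#'   enumeration will accept.
#' @param max_parallel_checks backtracking budget: number of pairwise
#'   parallelism tests before the decider reports "unknown".
#' @return a list of class `supercut_guard`.
#' @export
supercut_guard <- function(max_vertices = 18L, max_parallel_checks = 5e6) {
  structure(list(max_vertices = as.integer(max_vertices),
                 max_parallel_checks = max_parallel_checks),
            class = "supercut_guard")
}

guard_error <- function(msg) {
  stop(structure(
    class = c("supercut_guard_exceeded", "supercut_resource_error",
              "supercut_error", "error", "condition"),
    list(message = msg, call = NULL)))
}

#' Candidate cuts for an internal tree edge
#'
#' The candidates for internal edge `e` of input tree `T` are the legal
#' minimal cuts `F` whose slice `F` with the edges of `T` is exactly `{e}`
#' (leaf edges of `T` count: a cut containing `e` plus a leaf edge of `T` is
#' not a candidate).
#'
#' @param display a `display_graph`.
#' @param e an internal display edge (edge key or vertex pair).
#' @param all_cuts list of legal minimal cuts (e.g. the enumeration output,
#'   filtered by [classify_cut]).
#' @return sub-list of `all_cuts`.
#' @export
candidate_cuts_for_edge <- function(display, e, all_cuts) {
  e <- as_edge_keys(e)
  if (length(e) != 1L) domain_error("expected a single edge")
  if (!(e %in% display$keys)) domain_error("edge is not in the display graph")
  i <- display$tree[match(e, display$keys)]
  if (!(e %in% display_internal_edges(display)))
    domain_error("candidate cuts are defined for internal edges")
  Filter(function(f) identical(cut_tree_slice(display, f, i), e), all_cuts)
}

# is a cut list complete for the display graph?
cutset_is_complete <- function(display, cuts) {
  for (e in display_internal_edges(display)) {
    i <- display$tree[match(e, display$keys)]
    ok <- FALSE
    for (f in cuts) {
      if (identical(cut_tree_slice(display, f, i), e)) { ok <- TRUE; break }
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

cut_signature <- function(f) paste(f, collapse = ";")

# canonical ordering of a list of cuts (sorted edge lists, lexicographic)
order_cuts <- function(cuts) cuts[order(vapply(cuts, cut_signature, ""))]

# The shared exact search.  `per_tree_limit` = TRUE restricts candidates to
# cuts with at most one edge per input tree (the agreement variant).
search_cutset <- function(display, guard = supercut_guard(),
                          per_tree_limit = FALSE) {
  if (max(display$components) != 1L)
    domain_error("the display graph must be connected; partition the profile first")
  internal <- display_internal_edges(display)
  if (length(internal) == 0L)
    return(structure(list(cuts = list()), class = "cutset"))
  cuts <- enumerate_minimal_cuts(display, max_vertices = guard$max_vertices)
  legal <- Filter(function(f) classify_cut(display, f)$legal, cuts)
  if (per_tree_limit) {
    ntrees <- max(display$tree)
    legal <- Filter(function(f) {
      all(vapply(seq_len(ntrees),
                 function(i) length(cut_tree_slice(display, f, i)) <= 1L,
                 logical(1L)))
    }, legal)
  }
  if (length(legal) == 0L) return(NULL)
  cand_idx <- lapply(internal, function(e) {
    i <- display$tree[match(e, display$keys)]
    which(vapply(legal, function(f)
      identical(cut_tree_slice(display, f, i), e), logical(1L)))
  })
  if (any(lengths(cand_idx) == 0L)) return(NULL)
  ord <- order(lengths(cand_idx))
  cand_idx <- cand_idx[ord]

  # per-cut component membership of the display graph minus the cut
  memb <- lapply(legal, function(f)
    graph_components(display$vertices, drop_edges(display$edges, f)))
  ekey_ends <- keys_to_edges(display$keys)
  ends_of <- function(f) keys_to_edges(f)
  par_cache <- new.env(parent = emptyenv())
  checks <- 0L
  parallel_pair <- function(i, j) {
    if (i == j) return(TRUE)
    key <- paste(min(i, j), max(i, j))
    hit <- par_cache[[key]]
    if (!is.null(hit)) return(hit)
    checks <<- checks + 1L
    if (checks > guard$max_parallel_checks)
      guard_error("parallelism-check budget exceeded; result unknown")
    f1 <- legal[[i]]; f2 <- legal[[j]]
    rest <- setdiff(f2, f1)
    ok <- TRUE
    if (length(rest) > 0L) {
      fe <- keys_to_edges(rest)
      ok <- length(unique(memb[[i]][fe[, 1L]])) <= 1L
    }
    par_cache[[key]] <- ok
    ok
  }

  chosen <- integer(0)
  found <- NULL
  bt <- function(k) {
    if (!is.null(found)) return()
    if (k > length(cand_idx)) { found <<- unique(chosen); return() }
    for (ci in cand_idx[[k]]) {
      ok <- TRUE
      for (cj in unique(chosen)) {
        if (!parallel_pair(ci, cj)) { ok <- FALSE; break }
      }
      if (ok) {
        chosen <<- c(chosen, ci)
        bt(k + 1L)
        chosen <<- chosen[-length(chosen)]
        if (!is.null(found)) return()
      }
    }
  }
  bt(1L)
  if (is.null(found)) return(NULL)
  cuts_found <- order_cuts(legal[found])
  # minimise: greedily drop cuts whose removal keeps completeness
  i <- 1L
  while (i <= length(cuts_found)) {
    if (length(cuts_found) > 1L &&
        cutset_is_complete(display, cuts_found[-i])) {
      cuts_found <- cuts_found[-i]
    } else i <- i + 1L
  }
  # a minimally complete set of parallel legal minimal cuts is nice
  for (f in cuts_found) {
    if (!classify_cut(display, f)$nice)
      internal_error("minimised certificate contains a non-nice cut")
  }
  structure(list(cuts = cuts_found), class = "cutset")
}

#' @export
print.cutset <- function(x, ...) {
  cat(sprintf("<cut set: %d cuts>\n", length(x$cuts)))
  for (f in x$cuts) cat(" ", paste(f, collapse = "  "), "\n")
  invisible(x)
}

#' Find a complete set of pairwise parallel legal minimal cuts
#'
#' Exact backtracking search over the internal input-tree edges.  Returns a
#' minimally complete certificate (all member cuts are then nice), or `NULL`
#' when an exhaustive search proves none exists.  A guard overrun raises a
#' `supercut_guard_exceeded` condition, distinguishing "unknown" from "no".
#'
#' @param profile a [ps_profile] whose display graph is connected.
#' @param guard a [supercut_guard].
#' @return a `cutset` or `NULL`.
#' @export
find_complete_parallel_cutset <- function(profile, guard = supercut_guard()) {
  search_cutset(build_display_graph(profile), guard, per_tree_limit = FALSE)
}

#' Build the supertree induced by a certificate cut set
#'
#' Collects the non-trivial splits induced by the member cuts, adds the
#' trivial splits of the label universe, and constructs the corresponding
#' tree; the result is checked to display every input tree before it is
#' returned.
#'
#' @param profile a [ps_profile].
#' @param cutset a `cutset` (complete, pairwise parallel, nice, minimal).
#' @return a [pstree] on the full label universe.
#' @export
build_supertree_from_cuts <- function(profile, cutset) {
  display <- build_display_graph(profile)
  cuts <- cutset$cuts
  for (f in cuts) {
    if (!is_minimal_cut(display, f))
      domain_error("cut set member is not a minimal cut")
    if (!classify_cut(display, f)$nice)
      domain_error("cut set member is not a nice cut")
  }
  if (!cutset_is_complete(display, cuts))
    domain_error("cut set is not complete")
  for (i in seq_along(cuts)) {
    for (j in seq_len(i - 1L)) {
      if (!cuts_parallel(display, cuts[[i]], cuts[[j]]))
        domain_error("cut set members are not pairwise parallel")
    }
  }
  sigma <- vapply(cuts, function(f) cut_to_split(display, f), "")
  sigma <- unique(sigma[!vapply(sigma, split_is_trivial, logical(1L))])
  tree <- tree_from_splits(sigma, profile$labels)
  for (tr in profile$trees) {
    if (!displays_and_agrees(tree, tr)$displays)
      internal_error("constructed supertree fails to display an input tree")
  }
  tree
}

# split a profile into connected sub-profiles of its display graph
split_profile_by_component <- function(profile, display) {
  k <- max(display$components)
  groups <- vapply(profile$trees, function(tr)
    display$components[[tr$vertices[[1L]]]], integer(1L))
  lapply(seq_len(k), function(cid)
    ps_profile(profile$trees[groups == cid], relabel = FALSE))
}

# chain component supertrees into one tree on all labels: subdivide one edge
# of each non-degenerate component tree and connect the subdividers
join_supertrees <- function(trees, labels) {
  if (length(trees) == 1L) return(trees[[1L]])
  # namespace internal ids per component
  trees <- lapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    internal <- setdiff(tr$vertices, tr$leaves)
    if (length(internal) > 0L) {
      map <- stats::setNames(sprintf("c%d.%s", i, internal), internal)
      relab <- function(x) ifelse(x %in% names(map), map[x], x)
      tr$vertices <- unname(relab(tr$vertices))
      if (nrow(tr$edges) > 0L)
        tr$edges <- matrix(unname(relab(as.vector(tr$edges))), ncol = 2L)
    }
    tr
  })
  single <- vapply(trees, function(tr) length(tr$vertices) == 1L, logical(1L))
  multis <- trees[!single]
  singles <- trees[single]
  if (length(multis) == 0L)
    return(tree_from_splits(character(0), labels))
  edges <- matrix(character(0), 0L, 2L)
  joiners <- character(0)
  for (i in seq_along(multis)) {
    tr <- multis[[i]]
    j <- sprintf("j%d", i)
    joiners <- c(joiners, j)
    ek <- sort(edge_keys(tr$edges))[1L]
    uv <- keys_to_edges(ek)
    rest <- drop_edges(tr$edges, ek)
    edges <- rbind(edges, rest, c(uv[1L, 1L], j), c(j, uv[1L, 2L]))
  }
  if (length(joiners) > 1L) {
    for (i in seq_len(length(joiners) - 1L))
      edges <- rbind(edges, c(joiners[i], joiners[i + 1L]))
  }
  for (tr in singles) edges <- rbind(edges, c(joiners[1L], tr$vertices))
  out <- suppress_degree2(unique(c(labels, as.vector(edges))), edges,
                          protect = labels)
  pstree(out$edges, labels, vertices = out$vertices)
}

#' Decide whether a profile is compatible
#'
#' A disconnected display graph is handled by partitioning the profile into
#' the sub-profiles its components induce, deciding each, and chaining the
#' component supertrees (each input tree's restriction is unchanged, so
#' display is preserved).
#'
#' @param profile a [ps_profile].
#' @param guard a [supercut_guard].
#' @return list with `compatible` (`TRUE`/`FALSE`/`NA`), `status`
#'   (`"yes"`, `"no"`, `"unknown"`), and `certificate` (for a yes: list with
#'   the per-component `cutsets`, the induced `splits`, and the `supertree`).
#' @export
decide_compatibility <- function(profile, guard = supercut_guard()) {
  display <- build_display_graph(profile)
  subs <- if (max(display$components) == 1L) list(profile)
          else split_profile_by_component(profile, display)
  cutsets <- list()
  trees <- list()
  splits <- character(0)
  for (sp in subs) {
    res <- tryCatch(search_cutset(build_display_graph(sp), guard),
                    supercut_guard_exceeded = function(e) e)
    if (inherits(res, "condition"))
      return(list(compatible = NA, status = "unknown", certificate = NULL))
    if (is.null(res))
      return(list(compatible = FALSE, status = "no", certificate = NULL))
    cutsets[[length(cutsets) + 1L]] <- res
    st <- build_supertree_from_cuts(sp, res)
    trees[[length(trees) + 1L]] <- st
    splits <- c(splits, tree_splits(st)$internal)
  }
  supertree <- join_supertrees(trees, profile$labels)
  for (tr in profile$trees) {
    if (!displays_and_agrees(supertree, tr)$displays)
      internal_error("combined supertree fails to display an input tree")
  }
  cert <- structure(list(cutsets = cutsets, splits = sort(unique(splits)),
                         supertree = supertree),
                    class = "compat_certificate")
  list(compatible = TRUE, status = "yes", certificate = cert)
}

#' @export
print.compat_certificate <- function(x, ...) {
  cat("<compatibility certificate>\n")
  for (cs in x$cutsets) print(cs)
  cat(" splits:", paste(x$splits, collapse = "  "), "\n")
  cat(" supertree:", write_newick(x$supertree), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Brute-force oracle

.supercut_cache <- new.env(parent = emptyenv())

#' All unrooted binary tree topologies on a label set
#'
#' Generated by sequential leaf insertion into every edge; `(2n-5)!!` trees
#' for `n >= 3`.
#'
#' @param labels character vector (at most 8 labels).
#' @return list of [pstree] objects.
#' @export
all_binary_topologies <- function(labels) {
  labels <- sort(unique(as.character(labels)))
  n <- length(labels)
  if (n > 8L) resource_error("binary topology enumeration supports at most 8 labels")
  key <- paste("bin", paste(labels, collapse = ","))
  hit <- .supercut_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- if (n == 1L) {
    list(pstree(matrix(character(0), 0L, 2L), labels, vertices = labels))
  } else if (n == 2L) {
    list(pstree(matrix(labels, 1L, 2L), labels))
  } else {
    trees <- list(cbind(rep("b1", 3L), labels[1:3]))
    if (n > 3L) {
      for (k in 4:n) {
        nxt <- list()
        w <- sprintf("b%d", k - 2L)
        for (e in trees) {
          for (r in seq_len(nrow(e))) {
            e2 <- rbind(e[-r, , drop = FALSE],
                        c(e[r, 1L], w), c(w, e[r, 2L]), c(w, labels[k]))
            nxt[[length(nxt) + 1L]] <- e2
          }
        }
        trees <- nxt
      }
    }
    lapply(trees, function(e) pstree(e, labels))
  }
  .supercut_cache[[key]] <- out
  out
}

#' Contract a set of internal edges of a tree
#'
#' @param tree a [pstree].
#' @param keys edge keys of internal edges to contract.
#' @return a [pstree] with the edges contracted (endpoints merged).
#' @export
contract_edges <- function(tree, keys) {
  keys <- as_edge_keys(keys)
  if (length(keys) == 0L) return(tree)
  tk <- edge_keys(tree$edges)
  if (!all(keys %in% tk)) domain_error("contraction edges must be tree edges")
  # union-find over vertices
  parent <- stats::setNames(tree$vertices, tree$vertices)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (k in keys) {
    uv <- keys_to_edges(k)
    if (uv[1L, 1L] %in% tree$leaves || uv[1L, 2L] %in% tree$leaves)
      domain_error("only internal edges can be contracted")
    a <- find(uv[1L, 1L]); b <- find(uv[1L, 2L])
    if (a != b) parent[[b]] <- a
  }
  rep_of <- vapply(tree$vertices, find, "")
  e <- tree$edges
  e <- cbind(unname(rep_of[e[, 1L]]), unname(rep_of[e[, 2L]]))
  e <- e[e[, 1L] != e[, 2L], , drop = FALSE]
  pstree(e, tree$leaves, vertices = unique(unname(rep_of)), index = tree$index)
}

#' All unrooted tree topologies (multifurcating included) on a label set
#'
#' Generated as edge-contraction classes of the binary topologies,
#' de-duplicated by their internal split sets.
#'
#' @param labels character vector (at most 7 labels).
#' @return list of [pstree] objects.
#' @export
all_topologies <- function(labels) {
  labels <- sort(unique(as.character(labels)))
  if (length(labels) > 7L)
    resource_error("full topology enumeration supports at most 7 labels")
  key <- paste("all", paste(labels, collapse = ","))
  hit <- .supercut_cache[[key]]
  if (!is.null(hit)) return(hit)
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (bt in all_binary_topologies(labels)) {
    ik <- names(tree_splits(bt)$by_edge)
    internal <- ik[vapply(strsplit(ik, EDGE_SEP, fixed = TRUE), function(uv)
      !(uv[1L] %in% labels) && !(uv[2L] %in% labels), logical(1L))]
    subsets <- if (length(internal) == 0L) list(character(0)) else {
      unlist(lapply(0:length(internal), function(m)
        utils::combn(internal, m, simplify = FALSE)), recursive = FALSE)
    }
    for (s in subsets) {
      tr <- contract_edges(bt, s)
      sig <- paste0("sig:", paste(sort(tree_splits(tr)$internal), collapse = " "))
      if (is.null(seen[[sig]])) {
        seen[[sig]] <- TRUE
        out[[length(out) + 1L]] <- tr
      }
    }
  }
  .supercut_cache[[key]] <- out
  out
}

#' Brute-force compatibility oracle
#'
#' Enumerates all unrooted binary topologies on the label universe and tests
#' whether one displays every input tree.  A compatible supertree exists iff
#' a binary one does, because display is closed under refinement.
#'
#' @param profile a [ps_profile] with at most 7 labels in total.
#' @return logical.
#' @export
brute_force_compatible <- function(profile) {
  if (length(profile$labels) > 7L)
    resource_error("brute-force compatibility oracle supports at most 7 labels")
  for (cand in all_binary_topologies(profile$labels)) {
    ok <- TRUE
    for (tr in profile$trees) {
      if (!displays_and_agrees(cand, tr)$displays) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}
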