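# Unrooted leaf-labelled phylogenetic trees ("pstree"): a light edge-list
# representation in which leaf vertex ids ARE the labels and internal vertex
# ids are free strings (namespaced per input tree, e.g. "t2.1").  Branch
# lengths and internal node labels carry no meaning anywhere in the package:
# all objects are unweighted topologies.

#' Construct an unrooted phylogenetic tree
#'
#' Builds a `pstree` from an explicit edge list.  Leaf vertices are identified
#' with their labels; internal vertices may use any ids disjoint from the
#' labels.  Degenerate forms with one leaf (an isolated labelled vertex) or
#' two leaves (a single edge) are permitted.
#'
#' @param edges two-column character matrix of vertex-id pairs (may have zero
#'   rows for a single-leaf tree).
#' @param leaves character vector of leaf labels (the degree-one vertices).
#' @param vertices optional character vector of all vertex ids; inferred from
#'   `edges` and `leaves` when omitted.
#' @param index integer index of the input tree this tree came from (used to
#'   namespace internal vertices inside profiles); `NA` when free-standing.
#' @param validate check the tree invariants (connected, acyclic, no
#'   degree-two vertices, labelled leaves).
#' @return an object of class `pstree` with fields `vertices`, `edges`,
#'   `leaves`, `index`.
#' @export
pstree <- function(edges, leaves, vertices = NULL, index = NA_integer_,
                   validate = TRUE) {
  if (is.null(dim(edges))) edges <- matrix(as.character(edges), ncol = 2L)
  storage.mode(edges) <- "character"
  vertices <- vertices %||% unique(c(leaves, as.vector(t(edges))))
  obj <- structure(
    list(vertices = vertices, edges = edges, leaves = sort(unique(leaves)),
         index = as.integer(index)),
    class = "pstree"
  )
  if (validate) validate_pstree(obj)
  obj
}

validate_pstree <- function(tree) {
  v <- tree$vertices; e <- tree$edges; lv <- tree$leaves
  if (anyDuplicated(v)) domain_error("duplicate vertex ids in tree")
  if (anyDuplicated(lv)) domain_error("duplicate leaf labels in tree")
  if (any(grepl(EDGE_SEP, v, fixed = TRUE)) || any(grepl("|", v, fixed = TRUE)) ||
      any(grepl(",", v, fixed = TRUE)))
    domain_error("vertex ids may not contain '--', '|' or ','")
  if (!all(lv %in% v)) domain_error("leaf labels must be vertices")
  if (nrow(e) != length(v) - 1L) domain_error("tree must be acyclic and connected")
  if (!all(as.vector(e) %in% v)) domain_error("edge endpoint is not a vertex")
  if (!graph_is_connected(v, e)) domain_error("tree is not connected")
  deg <- table(factor(c(e[, 1L], e[, 2L]), levels = v))
  if (length(v) == 1L) {
    if (!identical(sort(lv), sort(v))) domain_error("an isolated vertex must be a labelled leaf")
    return(invisible(tree))
  }
  deg1 <- v[deg == 1L]
  if (!setequal(deg1, lv)) domain_error("degree-one vertices and leaf labels must coincide")
  if (any(deg == 2L)) domain_error("tree has a degree-two vertex")
  if (any(deg[!(v %in% lv)] < 3L)) domain_error("internal vertex of degree < 3")
  invisible(tree)
}

#' @export
print.pstree <- function(x, ...) {
  cat(sprintf("<pstree: %d leaves, %d internal vertices>\n",
              length(x$leaves), length(x$vertices) - length(x$leaves)))
  cat(" ", write_newick(x), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Newick I/O

#' Parse a Newick string into an unrooted tree
#'
#' Branch lengths and internal node labels are parsed and discarded; only the
#' topology and the leaf labels are semantic.  A degree-two root arising from
#' a rooted representation is suppressed, so the result never has degree-two
#' vertices.  Internal vertex ids are namespaced as `"t<tree_index>.<n>"`.
#'
#' @param text a single well-formed Newick statement ending in `";"`.
#' @param tree_index integer used to namespace internal vertex ids.
#' @return a [pstree].
#' @export
parse_newick <- function(text, tree_index = 1L) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  pos <- 1L
  n <- length(chars)
  peek <- function() if (pos <= n) chars[[pos]] else NA_character_
  skip_ws <- function() while (pos <= n && grepl("[[:space:]]", chars[[pos]])) pos <<- pos + 1L
  expect <- function(ch) {
    skip_ws()
    if (!identical(peek(), ch)) parse_error(sprintf("expected '%s'", ch), pos)
    pos <<- pos + 1L
  }
  read_name <- function() {
    skip_ws()
    start <- pos
    while (pos <= n && !chars[[pos]] %in% c("(", ")", ",", ":", ";") &&
           !grepl("[[:space:]]", chars[[pos]])) pos <<- pos + 1L
    paste(chars[seq(start, length.out = pos - start)], collapse = "")
  }
  skip_length <- function() {
    skip_ws()
    if (identical(peek(), ":")) {
      pos <<- pos + 1L
      num <- read_name()
      if (!nzchar(num)) parse_error("expected branch length after ':'", pos)
    }
  }
  parse_subtree <- function() {
    skip_ws()
    if (identical(peek(), "(")) {
      pos <<- pos + 1L
      children <- list(parse_subtree())
      skip_ws()
      while (identical(peek(), ",")) {
        pos <<- pos + 1L
        children[[length(children) + 1L]] <- parse_subtree()
      }
      expect(")")
      read_name()   # internal label, discarded
      skip_length()
      list(leaf = NULL, children = children)
    } else {
      nm <- read_name()
      if (!nzchar(nm)) parse_error("expected a leaf label", pos)
      skip_length()
      list(leaf = nm, children = NULL)
    }
  }
  root <- parse_subtree()
  expect(";")
  skip_ws()
  if (pos <= n) parse_error("trailing characters after ';'", pos)

  # flatten the rooted parse into an edge list
  counter <- 0L
  leaves <- character(0)
  edges <- matrix(character(0), 0L, 2L)
  new_internal <- function() {
    counter <<- counter + 1L
    sprintf("t%d.%d", tree_index, counter)
  }
  build <- function(node) {
    if (!is.null(node$leaf)) {
      if (node$leaf %in% leaves)
        domain_error(sprintf("duplicate leaf label '%s'", node$leaf))
      leaves <<- c(leaves, node$leaf)
      return(node$leaf)
    }
    id <- new_internal()
    for (ch in node$children) {
      cid <- build(ch)
      edges <<- rbind(edges, c(id, cid))
    }
    id
  }
  build(root)
  vertices <- unique(c(leaves, as.vector(t(edges))))

  # drop degree-<=1 internal vertices (single-child root chains), then
  # suppress all remaining degree-two internal vertices
  repeat {
    if (nrow(edges) == 0L) break
    deg <- table(factor(c(edges[, 1L], edges[, 2L]), levels = vertices))
    drop <- vertices[deg <= 1L & !(vertices %in% leaves)]
    if (length(drop) == 0L) break
    edges <- edges[!(edges[, 1L] %in% drop | edges[, 2L] %in% drop), , drop = FALSE]
    vertices <- setdiff(vertices, drop)
  }
  g <- suppress_degree2(vertices, edges, protect = leaves)
  pstree(g$edges, leaves, vertices = g$vertices, index = tree_index)
}

#' Write a tree as a canonical Newick string
#'
#' The output is deterministic: the tree is written from the internal vertex
#' adjacent to the lexicographically smallest leaf, and sibling subtrees are
#' ordered by their smallest descendant label.  `parse_newick(write_newick(t))`
#' has the same split set as `t`.
#'
#' @param tree a [pstree].
#' @return a Newick string ending in `";"`.
#' @export
write_newick <- function(tree) {
  v <- tree$vertices; e <- tree$edges; lv <- tree$leaves
  if (length(v) == 1L) return(paste0(v, ";"))
  if (length(v) == 2L) return(sprintf("(%s,%s);", sort(lv)[1L], sort(lv)[2L]))
  adj <- adjacency_list(v, e)
  render <- function(node, parent) {
    if (node %in% lv) return(list(str = node, min = node))
    subs <- lapply(setdiff(adj[[node]], parent), render, parent = node)
    subs <- subs[order(vapply(subs, `[[`, "", "min"))]
    list(str = paste0("(", paste(vapply(subs, `[[`, "", "str"), collapse = ","), ")"),
         min = subs[[1L]]$min)
  }
  r0 <- sort(lv)[1L]
  root <- setdiff(adj[[r0]], character(0))[1L]
  subs <- lapply(adj[[root]], render, parent = root)
  subs <- subs[order(vapply(subs, `[[`, "", "min"))]
  paste0("(", paste(vapply(subs, `[[`, "", "str"), collapse = ","), ");")
}

# ---------------------------------------------------------------------------
# Splits

# Internal: named vector, edge key -> split key, for every edge.
edge_split_map <- function(tree) {
  e <- tree$edges; lv <- tree$leaves
  if (nrow(e) == 0L) return(stats::setNames(character(0), character(0)))
  adj <- adjacency_list(tree$vertices, e)
  keys <- edge_keys(e)
  out <- character(nrow(e))
  for (i in seq_len(nrow(e))) {
    u <- e[i, 1L]; v <- e[i, 2L]
    # leaves on v's side of edge (u,v)
    seen <- v; queue <- v
    while (length(queue) > 0L) {
      x <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj[[x]]) {
        if (w == u && x == v) next
        if (!(w %in% seen)) { seen <- c(seen, w); queue <- c(queue, w) }
      }
    }
    side <- intersect(lv, seen)
    out[i] <- split_key(side, setdiff(lv, side))
  }
  stats::setNames(out, keys)
}

#' Splits of a tree
#'
#' One split per edge, partitioned into the non-trivial splits of the internal
#' edges and the trivial splits of the leaf edges.
#'
#' @param tree a [pstree].
#' @return list with character vectors `internal` and `trivial` of canonical
#'   split keys (see [split_key]), and `by_edge`, a vector mapping each edge
#'   key to its split key.
#' @export
tree_splits <- function(tree) {
  m <- edge_split_map(tree)
  lv <- tree$leaves
  internal_edge <- function(k) {
    uv <- strsplit(k, EDGE_SEP, fixed = TRUE)[[1L]]
    !(uv[1L] %in% lv) && !(uv[2L] %in% lv)
  }
  is_int <- vapply(names(m), internal_edge, logical(1L))
  list(internal = sort(unname(m[is_int])),
       trivial = sort(unname(m[!is_int])),
       by_edge = m)
}

# ---------------------------------------------------------------------------
# Restriction

#' Restrict a tree to a label subset
#'
#' Returns the minimal subtree connecting the labels in `labels`, with all
#' degree-two vertices suppressed.  Surviving vertices keep their ids.
#'
#' @param tree a [pstree].
#' @param labels non-empty subset of the tree's leaf labels.
#' @return a [pstree] on exactly `labels`.
#' @export
restrict_tree <- function(tree, labels) {
  labels <- unique(as.character(labels))
  if (length(labels) < 1L) domain_error("restriction label set must be non-empty")
  if (!all(labels %in% tree$leaves))
    domain_error("restriction labels must be a subset of the tree's labels")
  if (length(labels) == 1L)
    return(pstree(matrix(character(0), 0L, 2L), labels, vertices = labels,
                  index = tree$index))
  v <- tree$vertices; e <- tree$edges
  repeat {
    deg <- table(factor(c(e[, 1L], e[, 2L]), levels = v))
    drop <- v[deg <= 1L & !(v %in% labels)]
    if (length(drop) == 0L) break
    e <- e[!(e[, 1L] %in% drop | e[, 2L] %in% drop), , drop = FALSE]
    v <- setdiff(v, drop)
  }
  # drop pruned-away leaves that are still isolated (degree 0)
  v <- v[v %in% c(labels, unique(as.vector(e)))]
  g <- suppress_degree2(v, e, protect = labels)
  pstree(g$edges, labels, vertices = g$vertices, index = tree$index)
}

# ---------------------------------------------------------------------------
# Display / agreement between a supertree and an input tree

#' Does a supertree display / agree with a tree?
#'
#' `S` displays `t` when the splits of `t` are a subset of the splits of `S`
#' restricted to the labels of `t`; they agree when the two split sets are
#' equal.  Agreement implies display.
#'
#' @param supertree a [pstree] whose labels contain those of `t`.
#' @param t a [pstree].
#' @return list with logicals `displays` and `agrees`.
#' @export
displays_and_agrees <- function(supertree, t) {
  if (!all(t$leaves %in% supertree$leaves))
    domain_error("supertree labels must contain the tree's labels")
  r <- restrict_tree(supertree, t$leaves)
  s1 <- tree_splits(t)$internal
  s2 <- tree_splits(r)$internal
  list(displays = all(s1 %in% s2), agrees = setequal(s1, s2))
}

# ---------------------------------------------------------------------------
# ape interoperability

#' Convert a pstree to an ape "phylo" object
#'
#' @param x a [pstree].
#' @param ... unused.
#' @return an unrooted `ape::phylo`.
#' @importFrom ape as.phylo
#' @export
as.phylo.pstree <- function(x, ...) {
  if (length(x$vertices) < 2L)
    domain_error("cannot convert a single-vertex tree to phylo")
  ape::read.tree(text = write_newick(x))
}
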