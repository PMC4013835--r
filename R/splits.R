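# Splits (unordered bipartitions of a label set) in a canonical string form:
# "a,b|c,d,e" with each side sorted and the lexicographically smaller side
# first.  Split keys are the currency of compatibility throughout.

#' Canonical key for a split
#'
#' @param side_a,side_b disjoint non-empty character vectors of labels.
#' @return the canonical `"x,y|z,w"` key.
#' @export
split_key <- function(side_a, side_b) {
  side_a <- sort(unique(as.character(side_a)))
  side_b <- sort(unique(as.character(side_b)))
  if (length(side_a) == 0L || length(side_b) == 0L)
    domain_error("both sides of a split must be non-empty")
  if (length(intersect(side_a, side_b)) > 0L)
    domain_error("split sides must be disjoint")
  sa <- paste(side_a, collapse = ",")
  sb <- paste(side_b, collapse = ",")
  if (sa <= sb) paste(sa, sb, sep = "|") else paste(sb, sa, sep = "|")
}

#' Sides of a split key
#' @param key a split key from [split_key].
#' @return list with character vectors `a` and `b`.
#' @export
split_sides <- function(key) {
  halves <- strsplit(key, "|", fixed = TRUE)[[1L]]
  if (length(halves) != 2L) domain_error(sprintf("malformed split key: %s", key))
  list(a = strsplit(halves[1L], ",", fixed = TRUE)[[1L]],
       b = strsplit(halves[2L], ",", fixed = TRUE)[[1L]])
}

#' Is a split trivial (one side a singleton)?
#' @param key a split key.
#' @export
split_is_trivial <- function(key) {
  s <- split_sides(key)
  length(s$a) == 1L || length(s$b) == 1L
}

#' Pairwise compatibility of two splits
#'
#' Splits `A1|A2` and `B1|B2` over the same label universe are compatible iff
#' at least one of the four side intersections is empty, i.e. some tree
#' displays both.
#'
#' @param s1,s2 split keys.
#' @return logical.
#' @export
splits_compatible <- function(s1, s2) {
  x <- split_sides(s1); y <- split_sides(s2)
  length(intersect(x$a, y$a)) == 0L || length(intersect(x$a, y$b)) == 0L ||
    length(intersect(x$b, y$a)) == 0L || length(intersect(x$b, y$b)) == 0L
}

#' Build the tree displaying a pairwise-compatible split set
#'
#' Implements the splits-equivalence construction by iterative refinement of a
#' star ("tree popping"): each non-trivial split, taken in canonical order,
#' refines one vertex of the current tree.  The result is the unique tree
#' whose internal splits are exactly the given non-trivial splits; processing
#' order cannot affect it.
#'
#' @param splits character vector of split keys; every split must bipartition
#'   exactly `labels`.  Trivial splits are implicitly included and ignored.
#' @param labels the label universe.
#' @return a [pstree].  If two input splits are incompatible, an error of
#'   class `supercut_incompatible` is raised carrying the offending `pair`.
#' @export
tree_from_splits <- function(splits, labels) {
  labels <- sort(unique(as.character(labels)))
  splits <- unique(as.character(splits))
  for (s in splits) {
    sd <- split_sides(s)
    if (!setequal(c(sd$a, sd$b), labels))
      domain_error(sprintf("split %s is not over the given label universe", s))
  }
  splits <- splits[!vapply(splits, split_is_trivial, logical(1L))]
  splits <- sort(splits)
  if (length(splits) > 1L) {
    for (i in seq_len(length(splits) - 1L)) {
      for (j in seq(i + 1L, length(splits))) {
        if (!splits_compatible(splits[i], splits[j])) {
          stop(structure(
            class = c("supercut_incompatible", "supercut_error", "error", "condition"),
            list(message = sprintf("incompatible splits: %s vs %s",
                                   splits[i], splits[j]),
                 call = sys.call(-1), pair = c(splits[i], splits[j]))))
        }
      }
    }
  }
  if (length(labels) == 1L)
    return(pstree(matrix(character(0), 0L, 2L), labels, vertices = labels))
  if (length(labels) == 2L)
    return(pstree(matrix(labels, 1L, 2L), labels))

  # start from a star and refine
  counter <- 1L
  centre <- "s1"
  vertices <- c(labels, centre)
  edges <- cbind(rep(centre, length(labels)), labels)
  adj_of <- function() adjacency_list(vertices, edges)

  leafset_beyond <- function(adj, from, towards) {
    seen <- towards; queue <- towards
    while (length(queue) > 0L) {
      x <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj[[x]]) {
        if (x == towards && w == from) next
        if (!(w %in% seen)) { seen <- c(seen, w); queue <- c(queue, w) }
      }
    }
    intersect(labels, seen)
  }

  for (s in splits) {
    sd <- split_sides(s)
    adj <- adj_of()
    placed <- FALSE
    for (v in setdiff(vertices, labels)) {
      nb <- adj[[v]]
      pure_a <- logical(length(nb)); pure_b <- logical(length(nb)); ok <- TRUE
      for (k in seq_along(nb)) {
        ls <- leafset_beyond(adj, v, nb[[k]])
        pure_a[k] <- all(ls %in% sd$a)
        pure_b[k] <- all(ls %in% sd$b)
        if (!pure_a[k] && !pure_b[k]) { ok <- FALSE; break }
      }
      if (!ok || !any(pure_a) || !any(pure_b)) next
      # refine v: move the B-side neighbours onto a new vertex unless the
      # split is already realised by a single B-side (or A-side) edge
      if (sum(pure_b & !pure_a) == 1L && sum(pure_a) == length(nb) - 1L ||
          sum(pure_a & !pure_b) == 1L && sum(pure_b) == length(nb) - 1L) {
        # the split is an existing edge of the tree
        placed <- TRUE
        break
      }
      counter <- counter + 1L
      nv <- sprintf("s%d", counter)
      move <- nb[pure_b]
      keep_keys <- edge_key(rep(v, length(move)), move)
      edges <- edges[!(edge_keys(edges) %in% keep_keys), , drop = FALSE]
      edges <- rbind(edges, cbind(rep(nv, length(move)), move), c(v, nv))
      vertices <- c(vertices, nv)
      placed <- TRUE
      break
    }
    if (!placed)
      internal_error(sprintf("failed to place split %s despite pairwise compatibility", s))
  }
  out <- pstree(edges, labels, vertices = vertices)
  if (!setequal(tree_splits(out)$internal, splits))
    internal_error("constructed tree does not realise the requested split set")
  out
}
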