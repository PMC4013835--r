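# Independent certificate verification.  Construction uses the package's own
# graph code; verification re-checks every predicate definitionally on top
# of igraph components, so that a bug in one path cannot hide in the other.

ig_components <- function(vertices, edges) {
  ig <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE), directed = FALSE,
    vertices = data.frame(name = vertices, stringsAsFactors = FALSE))
  m <- igraph::components(ig)$membership
  stats::setNames(as.integer(m), names(m))
}

verify_minimal_cut <- function(display, f) {
  comp0 <- ig_components(display$vertices, display$edges)
  comp <- ig_components(display$vertices, drop_edges(display$edges, f))
  if (max(comp) <= max(comp0)) return(FALSE)        # not even a cut
  for (e in f) {       # no maximal proper subset may disconnect
    sub <- setdiff(f, e)
    compx <- ig_components(display$vertices, drop_edges(display$edges, sub))
    if (max(compx) > max(comp0)) return(FALSE)
  }
  TRUE
}

verify_parallel <- function(display, f1, f2) {
  one_way <- function(a, b) {
    comp <- ig_components(display$vertices, drop_edges(display$edges, a))
    rest <- setdiff(b, a)
    if (length(rest) == 0L) return(TRUE)
    fe <- keys_to_edges(rest)
    # an edge entirely inside a component counts for that component
    inside <- unique(comp[fe[, 1L]][comp[fe[, 1L]] == comp[fe[, 2L]]])
    length(inside) <= 1L
  }
  one_way(f1, f2) && one_way(f2, f1)
}

#' Verify a certificate cut set against a profile
#'
#' Re-checks, on an independent code path, that every cut is a legal minimal
#' cut of the display graph, that the cuts are nice, pairwise parallel, and
#' complete, that (for agreement certificates) no cut has two edges of one
#' input tree, and that the certificate supertree displays (or agrees with)
#' every input tree.
#'
#' @param profile a [ps_profile].
#' @param cuts list of cuts (edge-key vectors), a `cutset`, or the path of a
#'   certificate JSON file written by [write_certificate].
#' @param supertree optional [pstree] (or Newick string) to check against the
#'   inputs.
#' @param criterion `"compatibility"` or `"agreement"`.
#' @return `TRUE`, or `FALSE` with attribute `"failures"` describing every
#'   failed check.
#' @export
verify_certificate <- function(profile, cuts, supertree = NULL,
                               criterion = c("compatibility", "agreement")) {
  criterion <- match.arg(criterion)
  if (is.character(cuts) && length(cuts) == 1L && file.exists(cuts)) {
    cert <- read_certificate(cuts)
    if (is.null(supertree)) supertree <- cert$supertree
    criterion <- cert$criterion %||% criterion
    cuts <- cert$cuts
  }
  if (inherits(cuts, "cutset")) cuts <- cuts$cuts
  cuts <- lapply(cuts, as_edge_keys)
  if (is.character(supertree)) supertree <- parse_newick(supertree, 0L)
  fails <- character(0)
  note <- function(msg) fails <<- c(fails, msg)
  display <- build_display_graph(profile)
  ntrees <- length(profile$trees)
  comp0 <- ig_components(display$vertices, display$edges)
  groups <- integer(length(cuts))
  for (i in seq_along(cuts)) {
    f <- cuts[[i]]
    if (!all(f %in% display$keys)) {
      note(sprintf("cut %d contains non-display edges", i)); next
    }
    groups[i] <- comp0[[keys_to_edges(f[1L])[1L, 1L]]]
    if (any(comp0[unique(as.vector(keys_to_edges(f)))] != groups[i]))
      note(sprintf("cut %d spans several display components", i))
  }
  if (length(fails) == 0L) {
    for (cid in unique(comp0)) {
      vs <- names(comp0)[comp0 == cid]
      sub <- list(vertices = vs,
                  edges = display$edges[display$edges[, 1L] %in% vs, , drop = FALSE])
      subkeys <- edge_keys(sub$edges)
      subdisp <- display
      subdisp$vertices <- vs
      subdisp$edges <- sub$edges
      subdisp$keys <- subkeys
      subdisp$tree <- display$tree[display$keys %in% subkeys]
      subdisp$leaves <- intersect(display$leaves, vs)
      local_cuts <- cuts[groups == cid]
      for (i in seq_along(local_cuts)) {
        f <- local_cuts[[i]]
        if (!verify_minimal_cut(subdisp, f)) note("a cut is not a minimal cut")
        cl <- classify_cut(subdisp, f)
        if (!cl$legal) note("a cut is not legal")
        if (!cl$nice) note("a cut is not nice")
        if (criterion == "agreement") {
          for (t in seq_len(ntrees)) {
            if (length(cut_tree_slice(display, f, t)) > 1L)
              note("a cut has two edges of one input tree")
          }
        }
      }
      if (length(local_cuts) >= 2L) {
        for (i in seq_along(local_cuts)) for (j in seq_len(i - 1L)) {
          if (!verify_parallel(subdisp, local_cuts[[i]], local_cuts[[j]]))
            note("two cuts are not parallel")
        }
      }
    }
    for (e in display_internal_edges(display)) {
      t <- display$tree[match(e, display$keys)]
      covered <- any(vapply(cuts, function(f)
        identical(cut_tree_slice(display, f, t), e), logical(1L)))
      if (!covered) note(sprintf("internal edge %s is not solely covered", e))
    }
  }
  if (!is.null(supertree)) {
    if (!setequal(supertree$leaves, profile$labels))
      note("supertree labels differ from the label universe")
    else {
      for (tr in profile$trees) {
        da <- displays_and_agrees(supertree, tr)
        if (criterion == "agreement" && !da$agrees)
          note("supertree does not agree with an input tree")
        if (criterion == "compatibility" && !da$displays)
          note("supertree does not display an input tree")
      }
    }
  }
  if (length(fails) == 0L) TRUE else structure(FALSE, failures = unique(fails))
}

#' Write a certificate as JSON
#'
#' Schema: `criterion`; `cuts`, a list of cuts, each a list of edges, each
#' edge a pair of vertex ids (leaf vertices appear as their labels, internal
#' vertices as their namespaced ids); `supertree`, a Newick string.
#'
#' @param cuts a `cutset`, a list of cuts, or a decider certificate (the
#'   `certificate` element of [decide_compatibility] / [decide_agreement]).
#' @param path output file.
#' @param criterion recorded in the file.
#' @export
write_certificate <- function(cuts, path,
                              criterion = c("compatibility", "agreement")) {
  criterion <- match.arg(criterion)
  supertree <- NULL
  if (inherits(cuts, "compat_certificate")) {
    supertree <- cuts$supertree
    cuts <- unlist(lapply(cuts$cutsets, `[[`, "cuts"), recursive = FALSE)
  } else if (inherits(cuts, "ast_certificate")) {
    supertree <- cuts$ast
    cuts <- unlist(lapply(cuts$cutsets, `[[`, "cuts"), recursive = FALSE)
  } else if (inherits(cuts, "cutset")) {
    cuts <- cuts$cuts
  }
  payload <- list(
    criterion = criterion,
    cuts = lapply(cuts, function(f) {
      m <- keys_to_edges(as_edge_keys(f))
      lapply(seq_len(nrow(m)), function(r) c(m[r, 1L], m[r, 2L]))
    })
  )
  if (!is.null(supertree)) payload$supertree <- write_newick(supertree)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a certificate JSON file
#' @param path file written by [write_certificate].
#' @return list with `criterion`, `cuts` (list of edge-key vectors) and
#'   `supertree` (Newick string or `NULL`).
#' @export
read_certificate <- function(path) {
  obj <- jsonlite::read_json(path)
  cuts <- lapply(obj$cuts, function(f)
    sort(vapply(f, function(p) edge_key(p[[1L]], p[[2L]]), "")))
  list(criterion = obj$criterion %||% "compatibility",
       cuts = cuts, supertree = obj$supertree %||% NULL)
}
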