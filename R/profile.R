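# Profiles: ordered collections of unrooted trees with possibly overlapping
# label sets.  Internal vertex ids of distinct trees are kept disjoint by
# namespacing them "t<i>.<n>"; leaves with equal labels are identified when
# the display graph is built.

#' Construct a profile of trees
#'
#' @param trees list of [pstree] objects.
#' @param relabel rename the internal vertices of tree `i` to `"t<i>.<n>"`
#'   (in canonical id order).  With `relabel = FALSE` the existing ids are
#'   kept and must already be disjoint across trees.
#' @return object of class `ps_profile`: list with `trees` and `labels`
#'   (the label universe).
#' @export
ps_profile <- function(trees, relabel = TRUE) {
  stopifnot(is.list(trees), length(trees) >= 1L)
  trees <- lapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    if (!inherits(tr, "pstree")) domain_error("profile members must be pstree objects")
    tr$index <- i
    if (relabel) {
      internal <- sort(setdiff(tr$vertices, tr$leaves))
      if (length(internal) > 0L) {
        map <- stats::setNames(sprintf("t%d.%d", i, seq_along(internal)), internal)
        relab <- function(x) ifelse(x %in% names(map), map[x], x)
        tr$vertices <- unname(relab(tr$vertices))
        if (nrow(tr$edges) > 0L) {
          tr$edges <- matrix(unname(relab(as.vector(tr$edges))), ncol = 2L)
        }
      }
    }
    tr
  })
  internals <- lapply(trees, function(tr) setdiff(tr$vertices, tr$leaves))
  all_int <- unlist(internals)
  if (anyDuplicated(all_int))
    domain_error("internal vertex ids of distinct trees must be disjoint")
  labels <- sort(unique(unlist(lapply(trees, `[[`, "leaves"))))
  if (any(all_int %in% labels))
    domain_error("internal vertex ids may not collide with leaf labels")
  structure(list(trees = trees, labels = labels), class = "ps_profile")
}

#' @export
print.ps_profile <- function(x, ...) {
  cat(sprintf("<profile: %d trees, %d labels (%s)>\n", length(x$trees),
              length(x$labels), paste(x$labels, collapse = " ")))
  for (tr in x$trees) cat(" ", write_newick(tr), "\n")
  invisible(x)
}

#' Read a profile from Newick text
#'
#' One Newick statement per line; blank lines and `#` comments are ignored.
#'
#' @param path file path, or `NULL` when `text` is given.
#' @param text optional character vector of lines (overrides `path`).
#' @return a [ps_profile].
#' @export
read_profile <- function(path = NULL, text = NULL) {
  lines <- text %||% readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) domain_error("no trees found in input")
  trees <- lapply(seq_along(lines), function(i) parse_newick(lines[[i]], i))
  ps_profile(trees, relabel = FALSE)
}

#' Write a profile as Newick lines
#' @param profile a [ps_profile].
#' @param path output file; when `NULL` the lines are returned.
#' @export
write_profile <- function(profile, path = NULL) {
  lines <- vapply(profile$trees, write_newick, "")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
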