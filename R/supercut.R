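# Front end: a single classed entry point over the deciders, in the style of
# a model-fitting function, with print / summary / plot methods.

#' Decide supertree compatibility or agreement for a profile
#'
#' The main entry point.  Builds the display graph of the profile, searches
#' for a certificate (a complete set of pairwise parallel legal minimal cuts;
#' for agreement, additionally with at most one edge per input tree in each
#' cut), and on success constructs the supertree from the splits the cuts
#' induce.
#'
#' @param x a [ps_profile], a character vector of Newick strings, or the path
#'   of a Newick file (one tree per line, `#` comments ignored).
#' @param criterion `"compatibility"` (does some supertree display every
#'   input?) or `"agreement"` (does some supertree restrict to exactly every
#'   input?).
#' @param guard a [supercut_guard].
#' @return object of class `supercut`: list with `criterion`, `status`
#'   (`"yes"`, `"no"`, `"unknown"`), `decision` (logical or `NA`),
#'   `certificate`, `supertree` (a [pstree] or `NULL`), `profile`, `call`.
#' @examples
#' fit <- supercut(fig1_profile())
#' fit
#' summary(fit)
#' @export
supercut <- function(x, criterion = c("compatibility", "agreement"),
                     guard = supercut_guard()) {
  criterion <- match.arg(criterion)
  profile <- as_ps_profile(x)
  res <- if (criterion == "compatibility") decide_compatibility(profile, guard)
         else decide_agreement(profile, guard)
  decision <- if (criterion == "compatibility") res$compatible else res$has_ast
  supertree <- if (isTRUE(decision)) {
    if (criterion == "compatibility") res$certificate$supertree
    else res$certificate$ast
  } else NULL
  structure(list(criterion = criterion, status = res$status,
                 decision = decision, certificate = res$certificate,
                 supertree = supertree, profile = profile,
                 call = match.call()),
            class = "supercut")
}

as_ps_profile <- function(x) {
  if (inherits(x, "ps_profile")) return(x)
  if (is.character(x)) {
    if (length(x) == 1L && file.exists(x)) return(read_profile(x))
    return(read_profile(text = x))
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1L), "pstree")))
    return(ps_profile(x))
  domain_error("cannot interpret input as a profile")
}

#' @export
print.supercut <- function(x, ...) {
  what <- if (x$criterion == "compatibility") "a compatible supertree"
          else "an agreement supertree"
  verdict <- switch(x$status,
                    yes = sprintf("the profile HAS %s", what),
                    no = sprintf("the profile has NO %s", sub("^an? ", "", what)),
                    unknown = "search budget exhausted: result UNKNOWN")
  cat(sprintf("supercut: %d trees on %d labels -- %s\n",
              length(x$profile$trees), length(x$profile$labels), verdict))
  if (!is.null(x$supertree))
    cat("  supertree:", write_newick(x$supertree), "\n")
  invisible(x)
}

#' @export
summary.supercut <- function(object, ...) {
  structure(list(fit = object), class = "summary.supercut")
}

#' @export
print.summary.supercut <- function(x, ...) {
  fit <- x$fit
  print(fit)
  if (!is.null(fit$certificate)) {
    cutsets <- fit$certificate$cutsets
    k <- 0L
    for (cs in cutsets) {
      for (f in cs$cuts) {
        k <- k + 1L
        cat(sprintf("  cut %d: %s\n", k, paste(f, collapse = "  ")))
      }
    }
    if (!is.null(fit$supertree)) {
      sp <- tree_splits(fit$supertree)$internal
      cat("  internal splits:", paste(sp, collapse = "  "), "\n")
      for (tr in fit$profile$trees) {
        da <- displays_and_agrees(fit$supertree, tr)
        cat(sprintf("  input %s: displayed=%s agrees=%s\n",
                    write_newick(tr), da$displays, da$agrees))
      }
    }
  }
  invisible(x)
}

#' Plot the supertree of a supercut fit
#'
#' @param x a `supercut` object with status `"yes"`.
#' @param ... passed to `ape::plot.phylo`.
#' @export
plot.supercut <- function(x, ...) {
  if (is.null(x$supertree)) {
    message("no supertree to plot (status: ", x$status, ")")
    return(invisible(x))
  }
  ape::plot.phylo(as.phylo.pstree(x$supertree), type = "unrooted", ...)
  invisible(x)
}
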