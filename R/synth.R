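# Fixtures for the two worked-example profiles and seeded random profile
# generators covering compatible, agreeing and incompatible regimes.
#
# Both fixture constructors self-verify against every printed cut and split
# before returning; a mismatch is a hard error, never silently patched.

# cuts written with explicit display-graph vertex ids
fixture_cut <- function(...) {
  pairs <- list(...)
  sort(vapply(pairs, function(p) edge_key(p[1L], p[2L]), ""))
}

#' The two-tree compatible example profile
#'
#' First tree: internal path 1-2-3 with leaves a, b, c at 1, f at 2, d, e at
#' 3.  Second tree: internal path 4-5-6-7 with a, b at 4, c at 5, d at 6 and
#' f, g at 7.  The constructor verifies that the four reference cuts
#' `{{1,2},{5,6}}`, `{{2,3},{6,7},{5,6}}`, `{{4,5},{1,2},{1,c}}`,
#' `{{6,7},{2,f}}` are nice, minimal, legal and pairwise parallel, that the
#' set is complete, and that the induced splits are `abc|defg`, `abcfg|de`,
#' `ab|cdefg`, `abcde|fg`.
#'
#' @return a [ps_profile] with attribute `"cuts"` (the four reference cuts,
#'   as a `cutset`).
#' @export
fig1_profile <- function() {
  t1 <- pstree(rbind(c("1", "a"), c("1", "b"), c("1", "c"), c("1", "2"),
                     c("2", "f"), c("2", "3"), c("3", "d"), c("3", "e")),
               leaves = c("a", "b", "c", "d", "e", "f"))
  t2 <- pstree(rbind(c("4", "a"), c("4", "b"), c("4", "5"), c("5", "c"),
                     c("5", "6"), c("6", "d"), c("6", "7"), c("7", "f"),
                     c("7", "g")),
               leaves = c("a", "b", "c", "d", "f", "g"))
  profile <- ps_profile(list(t1, t2), relabel = FALSE)
  display <- build_display_graph(profile)
  cuts <- list(
    fixture_cut(c("1", "2"), c("5", "6")),
    fixture_cut(c("2", "3"), c("6", "7"), c("5", "6")),
    fixture_cut(c("4", "5"), c("1", "2"), c("1", "c")),
    fixture_cut(c("6", "7"), c("2", "f"))
  )
  expected_splits <- c(
    split_key(c("a", "b", "c"), c("d", "e", "f", "g")),
    split_key(c("a", "b", "c", "f", "g"), c("d", "e")),
    split_key(c("a", "b"), c("c", "d", "e", "f", "g")),
    split_key(c("a", "b", "c", "d", "e"), c("f", "g"))
  )
  for (i in seq_along(cuts)) {
    if (!is_minimal_cut(display, cuts[[i]]))
      fixture_error("reference cut is not minimal; re-transcribe the fixture")
    cl <- classify_cut(display, cuts[[i]])
    if (!cl$legal || !cl$nice)
      fixture_error("reference cut is not nice; re-transcribe the fixture")
    if (cut_to_split(display, cuts[[i]]) != expected_splits[[i]])
      fixture_error("reference cut induces the wrong split; re-transcribe the fixture")
  }
  for (i in seq_along(cuts)) for (j in seq_len(i - 1L)) {
    if (!cuts_parallel(display, cuts[[i]], cuts[[j]]))
      fixture_error("reference cuts are not pairwise parallel")
  }
  if (!cutset_is_complete(display, cuts))
    fixture_error("reference cut set is not complete")
  attr(profile, "cuts") <- structure(list(cuts = cuts), class = "cutset")
  profile
}

#' The two-tree agreeing example profile (synthetic reconstruction)
#'
#' The topology of this example is a synthetic reconstruction (the reference
#' object is only available as a drawing), constrained by its printed
#' certificate: first tree as in [fig1_profile]; second tree with
#' internal path 4-5-6 carrying a, b, c at 4, g at 5 and d, f at 6.  The
#' constructor verifies that the three reference cuts `{{1,2},{4,5}}`,
#' `{{1,2},{5,6}}`, `{{2,3},{6,d}}` form a complete set of pairwise parallel
#' legal minimal cuts with at most one edge per input tree each, and that the
#' profile has an agreement supertree.
#'
#' @return a [ps_profile] with attribute `"cuts"`.
#' @export
fig2_profile <- function() {
  t1 <- pstree(rbind(c("1", "a"), c("1", "b"), c("1", "c"), c("1", "2"),
                     c("2", "f"), c("2", "3"), c("3", "d"), c("3", "e")),
               leaves = c("a", "b", "c", "d", "e", "f"))
  t2 <- pstree(rbind(c("4", "a"), c("4", "b"), c("4", "c"), c("4", "5"),
                     c("5", "g"), c("5", "6"), c("6", "d"), c("6", "f")),
               leaves = c("a", "b", "c", "d", "f", "g"))
  profile <- ps_profile(list(t1, t2), relabel = FALSE)
  display <- build_display_graph(profile)
  cuts <- list(
    fixture_cut(c("1", "2"), c("4", "5")),
    fixture_cut(c("1", "2"), c("5", "6")),
    fixture_cut(c("2", "3"), c("6", "d"))
  )
  ntrees <- length(profile$trees)
  for (f in cuts) {
    if (!is_minimal_cut(display, f))
      fixture_error("reference cut is not minimal; re-transcribe the fixture")
    cl <- classify_cut(display, f)
    if (!cl$legal || !cl$nice)
      fixture_error("reference cut is not nice; re-transcribe the fixture")
    for (i in seq_len(ntrees)) {
      if (length(cut_tree_slice(display, f, i)) > 1L)
        fixture_error("reference cut has two edges of one tree")
    }
  }
  for (i in seq_along(cuts)) for (j in seq_len(i - 1L)) {
    if (!cuts_parallel(display, cuts[[i]], cuts[[j]]))
      fixture_error("reference cuts are not pairwise parallel")
  }
  if (!cutset_is_complete(display, cuts))
    fixture_error("reference cut set is not complete")
  dec <- decide_agreement(profile)
  if (!isTRUE(dec$has_ast))
    fixture_error("reconstructed profile has no agreement supertree")
  attr(profile, "cuts") <- structure(list(cuts = cuts), class = "cutset")
  profile
}

#' Incompatible fixture profiles
#'
#' The classic incompatible quartet pair `ab|cd` vs `ac|bd`, plus a
#' five-label trio of quartets (`ab|cd`, `ab|ce`, `ad|be`) that is pairwise
#' compatible but jointly incompatible.  Each profile is verified
#' incompatible by the brute-force oracle at construction.
#'
#' @return list of two [ps_profile] objects.
#' @export
incompatible_fixture <- function() {
  quartet <- function(a, b, c, d, idx) {
    parse_newick(sprintf("((%s,%s),(%s,%s));", a, b, c, d), idx)
  }
  p1 <- ps_profile(list(quartet("a", "b", "c", "d", 1L),
                        quartet("a", "c", "b", "d", 2L)), relabel = FALSE)
  p2 <- ps_profile(list(quartet("a", "b", "c", "d", 1L),
                        quartet("a", "b", "c", "e", 2L),
                        quartet("a", "d", "b", "e", 3L)), relabel = FALSE)
  for (p in list(p1, p2)) {
    if (brute_force_compatible(p))
      fixture_error("incompatible fixture is actually compatible")
  }
  list(p1, p2)
}

# ---------------------------------------------------------------------------
# Seeded random profiles

#' Recipe for a random profile
#'
#' @param n_labels number of labels of the generating supertree.
#' @param n_trees number of input trees.
#' @param subset_sizes label-subset size per input tree (recycled); each must
#'   be at least 1.
#' @param contraction_prob probability of contracting each internal edge of a
#'   restricted input tree (contraction yields compatible but possibly
#'   non-agreeing inputs).
#' @param perturb `"none"`, or `"swap"` to exchange two leaf labels in one
#'   input tree (producing likely-incompatible profiles).
#' @param seed integer seed; identical recipes give byte-identical profiles.
#' @return a list of class `profile_recipe`.
#' @export
profile_recipe <- function(n_labels, n_trees, subset_sizes = n_labels,
                           contraction_prob = 0, perturb = c("none", "swap"),
                           seed = 1L) {
  perturb <- match.arg(perturb)
  if (any(subset_sizes < 1L)) domain_error("subset sizes must be at least 1")
  if (any(subset_sizes > n_labels)) domain_error("subset sizes exceed n_labels")
  structure(list(n_labels = as.integer(n_labels), n_trees = as.integer(n_trees),
                 subset_sizes = as.integer(subset_sizes),
                 contraction_prob = contraction_prob, perturb = perturb,
                 seed = as.integer(seed)),
            class = "profile_recipe")
}

# uniform-ish random binary tree by sequential attachment at a random edge
random_binary_tree <- function(labels) {
  n <- length(labels)
  if (n == 1L) return(pstree(matrix(character(0), 0L, 2L), labels, vertices = labels))
  if (n == 2L) return(pstree(matrix(labels, 1L, 2L), labels))
  edges <- cbind(rep("b1", 3L), labels[1:3])
  if (n > 3L) {
    for (k in 4:n) {
      r <- sample.int(nrow(edges), 1L)
      w <- sprintf("b%d", k - 2L)
      edges <- rbind(edges[-r, , drop = FALSE],
                     c(edges[r, 1L], w), c(w, edges[r, 2L]), c(w, labels[k]))
    }
  }
  pstree(edges, labels)
}

label_pool <- function(n) {
  if (n <= 26L) letters[seq_len(n)] else sprintf("l%02d", seq_len(n))
}

#' Generate a seeded random profile
#'
#' Draws a random binary supertree `S`; each input tree is the restriction of
#' `S` to a random label subset, with each internal edge then contracted
#' independently with the recipe's probability.  With perturbation mode
#' `"swap"`, two leaf labels of one input tree are exchanged afterwards.  The
#' generating supertree is returned as ground truth when no perturbation was
#' applied.  All randomness flows through the recipe seed; the caller's
#' random state is left untouched.
#'
#' @param recipe a [profile_recipe].
#' @return list with `profile` (a [ps_profile]) and `truth` (a [pstree] or
#'   `NULL`).
#' @export
random_profile <- function(recipe) {
  stopifnot(inherits(recipe, "profile_recipe"))
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(recipe$seed)
  labels <- label_pool(recipe$n_labels)
  truth <- random_binary_tree(labels)
  sizes <- rep_len(recipe$subset_sizes, recipe$n_trees)
  trees <- vector("list", recipe$n_trees)
  for (i in seq_len(recipe$n_trees)) {
    sub <- sort(sample(labels, sizes[[i]]))
    tr <- restrict_tree(truth, sub)
    if (recipe$contraction_prob > 0) {
      sp <- tree_splits(tr)
      ik <- names(sp$by_edge)[sp$by_edge %in% sp$internal]
      todo <- ik[stats::runif(length(ik)) < recipe$contraction_prob]
      if (length(todo) > 0L) tr <- contract_edges(tr, todo)
    }
    trees[[i]] <- tr
  }
  if (recipe$perturb == "swap") {
    vict <- sample.int(recipe$n_trees, 1L)
    tr <- trees[[vict]]
    if (length(tr$leaves) >= 2L) {
      pairx <- sample(tr$leaves, 2L)
      swap <- function(x) ifelse(x == pairx[1L], pairx[2L],
                                 ifelse(x == pairx[2L], pairx[1L], x))
      tr$vertices <- unname(swap(tr$vertices))
      if (nrow(tr$edges) > 0L)
        tr$edges <- matrix(unname(swap(as.vector(tr$edges))), ncol = 2L)
      trees[[vict]] <- pstree(tr$edges, tr$leaves, vertices = tr$vertices)
    }
  }
  profile <- ps_profile(trees, relabel = TRUE)
  list(profile = profile,
       truth = if (recipe$perturb == "none") truth else NULL)
}
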