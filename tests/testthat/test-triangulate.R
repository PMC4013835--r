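# Chordality, clique trees, saturation, legal/restricted triangulations and
# the certificate-to-triangulation construction.

test_that("is_chordal matches the igraph oracle and produces witnesses", {
  tree_g <- list(vertices = letters[1:5],
                 edges = rbind(c("a", "b"), c("b", "c"), c("b", "d"), c("d", "e")))
  expect_true(is_chordal(tree_g)$chordal)
  sq <- list(vertices = c("p", "q", "r", "s"),
             edges = rbind(c("p", "q"), c("q", "r"), c("r", "s"), c("p", "s")))
  r <- is_chordal(sq)
  expect_false(r$chordal)
  expect_setequal(r$cycle, c("p", "q", "r", "s"))
  set.seed(97)
  for (i in 1:25) {
    g <- random_connected_graph(sample(5:9, 1L), stats::runif(1, 0.3, 0.7))
    mine <- is_chordal(g)
    ig <- supercut:::as_igraph(g)
    expect_identical(mine$chordal, igraph::is_chordal(ig)$chordal)
    if (!mine$chordal) {
      # the witness is a genuine chordless cycle of length >= 4
      cyc <- mine$cycle
      expect_gte(length(cyc), 4L)
      keys <- supercut:::edge_keys(g$edges)
      for (k in seq_along(cyc)) {
        a <- cyc[k]; b <- cyc[if (k == length(cyc)) 1L else k + 1L]
        expect_true(supercut:::edge_key(a, b) %in% keys)
      }
      chords <- utils::combn(cyc, 2L, function(p) supercut:::edge_key(p[1L], p[2L]))
      ring <- vapply(seq_along(cyc), function(k)
        supercut:::edge_key(cyc[k], cyc[if (k == length(cyc)) 1L else k + 1L]), "")
      expect_length(intersect(setdiff(chords, ring), keys), 0L)
    }
  }
})

test_that("clique trees are coherent and their edge intersections are minimal separators", {
  tree_g <- list(vertices = letters[1:5],
                 edges = rbind(c("a", "b"), c("b", "c"), c("b", "d"), c("d", "e")))
  ct <- clique_tree(tree_g)
  expect_length(ct$cliques, 4L)        # the cliques of a tree are its edges
  expect_true(all(lengths(ct$cliques) == 2L))
  k4 <- list(vertices = letters[1:4],
             edges = t(utils::combn(letters[1:4], 2L)))
  expect_length(clique_tree(k4)$cliques, 1L)
  expect_error(clique_tree(list(vertices = c("p", "q", "r", "s"),
                                edges = rbind(c("p", "q"), c("q", "r"),
                                              c("r", "s"), c("p", "s")))),
               class = "supercut_domain_error")
  set.seed(101)
  for (i in 1:10) {
    g <- random_connected_graph(7L, 0.45)
    seps <- enumerate_minimal_separators(g)
    if (length(seps) == 0L) next
    # saturate a maximal pairwise-parallel subfamily -> minimal triangulation
    fam <- list()
    for (s in seps) {
      if (all(vapply(fam, function(x) separators_parallel(g, s, x), logical(1L))))
        fam[[length(fam) + 1L]] <- s
    }
    h <- saturate(g, fam)
    expect_true(is_chordal(h)$chordal)
    fill <- setdiff(supercut:::edge_keys(h$edges), supercut:::edge_keys(g$edges))
    for (e in fill) {
      h2 <- list(vertices = h$vertices,
                 edges = supercut:::drop_edges(h$edges, e))
      expect_false(is_chordal(h2)$chordal)
    }
    # clique-tree edge intersections of the saturation are minimal separators
    ct <- clique_tree(h)
    for (s in ct$separators) {
      if (length(s) > 0L)
        expect_true(as.logical(is_minimal_separator(h, s)))
    }
  }
})

test_that("saturate is idempotent, monotone and clique-forming", {
  g <- list(vertices = letters[1:4], edges = rbind(c("a", "b"), c("c", "d")))
  expect_identical(saturate(g, list()), supercut:::as_plain_graph(saturate(g, list())))
  expect_equal(nrow(saturate(g, list(letters[1:4]))$edges), 6L)
  h <- saturate(g, list(c("a", "c")))
  expect_identical(supercut:::edge_keys(saturate(h, list(c("a", "c")))$edges),
                   supercut:::edge_keys(h$edges))
  expect_true(all(supercut:::edge_keys(g$edges) %in%
                  supercut:::edge_keys(h$edges)))
  expect_error(saturate(g, list(c("a", "z"))), class = "supercut_domain_error")
})

test_that("legal triangulation checks LT1 and LT2", {
  single <- ps_profile(list(parse_newick("((a,b),c,(d,e));", 1L)), relabel = FALSE)
  d <- build_display_graph(single)
  expect_true(isTRUE(is_legal_triangulation(d, d)))   # a tree is trivially legal
  # a chordal supergraph whose fill-in touches a leaf violates LT2
  with_leaf_fill <- list(vertices = d$vertices,
                         edges = rbind(d$edges, c("a", "t1.1")))
  expect_true(is_chordal(with_leaf_fill)$chordal)
  r <- is_legal_triangulation(d, with_leaf_fill)
  expect_false(as.logical(r))
  expect_match(attr(r, "violation"), "LT2")
  # a chordal supergraph joining two display edges in one clique with an
  # internal edge violates LT1
  p2 <- ps_profile(list(parse_newick("((a,b),c,(d,e));", 1L)), relabel = FALSE)
  d2 <- build_display_graph(p2)
  h2 <- list(vertices = d2$vertices,
             edges = rbind(d2$edges, c("t1.2", "t1.3")))
  expect_true(is_chordal(h2)$chordal)
  r2 <- is_legal_triangulation(d2, h2)
  expect_false(as.logical(r2))
  expect_match(attr(r2, "violation"), "LT1")
})

test_that("a maximal parallel family containing a certificate saturates to a restricted triangulation", {
  fig1 <- fig1_profile()
  d <- build_display_graph(fig1)
  el <- build_elig(d)
  # for a compatible profile, any maximal pairwise-parallel separator family
  # containing a complete legal certificate is all-legal, and its saturation
  # is a restricted (minimal) triangulation of the ELIG
  fam <- find_complete_parallel_cutset(fig1)$cuts
  for (s in enumerate_minimal_separators(el)) {
    if (all(vapply(fam, function(x) separators_parallel(el, s, x), logical(1L))))
      fam[[length(fam) + 1L]] <- s
  }
  for (s in fam) expect_true(separator_is_legal(el, s))
  h <- saturate(el, fam)
  expect_true(isTRUE(is_restricted_triangulation(el, h)))
  # an invalid fill-in (two disjoint edges of one tree) is rejected
  bad <- list(vertices = el$vertices, edges = rbind(el$edges, c("1--a", "3--d")))
  rb <- is_restricted_triangulation(el, bad)
  expect_false(as.logical(rb))
})

test_that("separator pairs differentiate every internal edge with the expected shapes", {
  fig1 <- fig1_profile()
  d <- build_display_graph(fig1)
  cs <- supercut:::order_cuts(attr(fig1, "cuts")$cuts)
  pairs <- build_cut_separator_pairs(d, structure(list(cuts = cs), class = "cutset"))
  diffd <- attr(pairs, "differentiated_by")
  expect_setequal(names(diffd), supercut:::display_internal_edges(d))
  # canonical order: {1-2,1-c,4-5} first, then {1-2,5-6} which differentiates
  # both of its sole-slice internal edges
  expect_identical(cs[[2L]], c("1--2", "5--6"))
  rec <- pairs[[2L]]
  expect_equal(nrow(rec$pairs), 2L)
  expect_length(rec$common, 0L)
  # a multi-edge slice contributes its common endpoint to both sides
  rec3 <- pairs[[1L]]                    # {1-2, 1-c, 4-5}: T1 slice shares vertex 1
  expect_true("1" %in% intersect(rec3$X, rec3$Y))
  # X/Y members are endpoints of cut edges
  for (idx in seq_along(pairs)) {
    ends <- unique(as.vector(supercut:::keys_to_edges(cs[[idx]])))
    expect_true(all(c(pairs[[idx]]$X, pairs[[idx]]$Y) %in% ends))
  }
  expect_error(build_cut_separator_pairs(
    d, structure(list(cuts = cs[1:2]), class = "cutset")),
    class = "supercut_domain_error")
})

test_that("certificate cuts always produce verified legal triangulations", {
  fig1 <- fig1_profile()
  d1 <- build_display_graph(fig1)
  tri <- cuts_to_triangulation(d1, attr(fig1, "cuts"))
  expect_true(isTRUE(is_legal_triangulation(d1, tri$graph)))
  expect_true(is_chordal(tri$graph)$chordal)
  # fill-in never touches leaves
  fe <- supercut:::keys_to_edges(tri$fill_in)
  expect_false(any(fe %in% d1$leaves))
  # single-tree profile with its own certificate
  single <- ps_profile(list(parse_newick("((a,b),c,(d,(e,f)));", 1L)), relabel = FALSE)
  ds <- build_display_graph(single)
  tris <- cuts_to_triangulation(ds, find_complete_parallel_cutset(single))
  expect_true(isTRUE(is_legal_triangulation(ds, tris$graph)))
  set.seed(103)
  for (i in 1:15) {
    rp <- random_recipe_profile(1500L + i, contraction = 0.3)
    dd <- build_display_graph(rp$profile)
    if (max(dd$components) > 1L) next
    cset <- find_complete_parallel_cutset(rp$profile)
    expect_false(is.null(cset))
    tr <- cuts_to_triangulation(dd, cset)
    expect_true(is_chordal(tr$graph)$chordal)
    expect_true(isTRUE(is_legal_triangulation(dd, tr$graph)))
    # the subgraph induced by each F_union is itself chordal with no
    # illegal clique (spot check)
    for (rec in tr$pairs) {
      fu <- union(rec$X, rec$Y)
      sub <- tr$graph$edges[tr$graph$edges[, 1L] %in% fu &
                            tr$graph$edges[, 2L] %in% fu, , drop = FALSE]
      expect_true(is_chordal(list(vertices = fu, edges = sub))$chordal)
    }
  }
})
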