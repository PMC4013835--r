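# Display graph, ELIG, minimal cuts, minimal separators, parallelism, and
# cut-induced splits, cross-checked against definitional brute-force oracles.

test_that("display graph merges leaves by label and keeps edge provenance", {
  p <- profile_from_newick("((a,b),(c,d));", "((a,b),(c,d));")
  d <- build_display_graph(p)
  expect_length(d$vertices, 8L)        # 4 shared leaves + 2x2 internals
  expect_equal(nrow(d$edges), 10L)
  expect_setequal(unique(d$tree), c(1L, 2L))

  fig1 <- build_display_graph(fig1_profile())
  for (k in c("1--2", "2--3", "4--5", "5--6", "6--7", "1--c", "2--f"))
    expect_true(k %in% fig1$keys)

  disjoint <- profile_from_newick("((a,b),(c,d));", "((w,x),(y,z));")
  expect_equal(max(build_display_graph(disjoint)$components), 2L)
})

test_that("the ELIG is the line graph of the display graph", {
  p <- profile_from_newick("(a,b,c);")
  el <- build_elig(build_display_graph(p))
  expect_length(el$vertices, 3L)
  expect_equal(nrow(el$edges), 3L)     # line graph of a 3-edge star = triangle
  set.seed(13)
  for (i in 1:5) {
    rp <- random_recipe_profile(100L + i)
    d <- build_display_graph(rp$profile)
    el <- build_elig(d)
    expect_length(el$vertices, nrow(d$edges))
    # adjacency iff shared endpoint, by definition re-derived here
    for (r in seq_len(nrow(el$edges))) {
      uv <- supercut:::keys_to_edges(el$edges[r, 1L])[1L, ]
      pq <- supercut:::keys_to_edges(el$edges[r, 2L])[1L, ]
      expect_true(length(intersect(uv, pq)) >= 1L)
    }
  }
})

test_that("edge components of the display graph match ELIG components after removal", {
  # path correspondence: after removing an arbitrary edge set F, two edges
  # lie in one component of the display graph iff they are connected in the
  # ELIG minus F
  set.seed(17)
  for (i in 1:10) {
    rp <- random_recipe_profile(200L + i)
    d <- build_display_graph(rp$profile)
    if (max(d$components) > 1L) next
    el <- build_elig(d)
    f <- sample(d$keys, sample.int(min(4L, length(d$keys)), 1L))
    comp_d <- supercut:::graph_components(d$vertices,
                                          supercut:::drop_edges(d$edges, f))
    rest <- setdiff(d$keys, f)
    keep_el <- el$edges[el$edges[, 1L] %in% rest & el$edges[, 2L] %in% rest, , drop = FALSE]
    comp_el <- supercut:::graph_components(rest, keep_el)
    grp_d <- vapply(rest, function(k) {
      uv <- supercut:::keys_to_edges(k)[1L, ]
      comp_d[[uv[1L]]]
    }, integer(1L))
    # equal partitions of the surviving edges
    expect_equal(length(unique(grp_d)), length(unique(comp_el)))
    expect_true(all(tapply(comp_el[rest], grp_d, function(x) length(unique(x))) == 1L))
  }
})

test_that("is_minimal_cut matches its definitional characterisation", {
  fig1 <- build_display_graph(fig1_profile())
  expect_true(is_minimal_cut(fig1, c("1--2", "5--6")))
  path <- list(vertices = c("x", "y", "z"), edges = rbind(c("x", "y"), c("y", "z")))
  expect_true(is_minimal_cut(path, "x--y"))
  expect_false(is_minimal_cut(path, c("x--y", "y--z")))
  expect_error(is_minimal_cut(path, "x--z"), class = "supercut_domain_error")
  set.seed(23)
  for (i in 1:5) {
    g <- random_connected_graph(8L)
    keys <- supercut:::edge_keys(g$edges)
    for (m in 1:3) {
      for (rep in 1:30) {
        f <- sort(sample(keys, m))
        expect_identical(is_minimal_cut(g, f), oracle_is_minimal_cut(g, f))
      }
    }
  }
})

test_that("enumerate_minimal_cuts is exhaustive and duplicate-free", {
  tri <- list(vertices = c("x", "y", "z"),
              edges = rbind(c("x", "y"), c("y", "z"), c("x", "z")))
  expect_length(enumerate_minimal_cuts(tri), 3L)
  path <- list(vertices = c("x", "y", "z"), edges = rbind(c("x", "y"), c("y", "z")))
  expect_length(enumerate_minimal_cuts(path), 2L)
  fig1 <- build_display_graph(fig1_profile())
  found <- cut_signatures(enumerate_minimal_cuts(fig1))
  for (f in attr(fig1_profile(), "cuts")$cuts)
    expect_true(paste(f, collapse = ";") %in% found)
  set.seed(29)
  for (i in 1:4) {
    g <- random_connected_graph(6L, 0.45)
    if (nrow(g$edges) > 9L) next
    expect_identical(cut_signatures(enumerate_minimal_cuts(g)),
                     cut_signatures(oracle_all_minimal_cuts(g)))
  }
  big <- random_connected_graph(20L)
  expect_error(enumerate_minimal_cuts(big, max_vertices = 18L),
               class = "supercut_resource_error")
})

test_that("classify_cut identifies legal and nice cuts", {
  fig1 <- fig1_profile()
  d <- build_display_graph(fig1)
  f3 <- c("1--2", "1--c", "4--5")
  expect_equal(classify_cut(d, f3), list(legal = TRUE, nice = TRUE))
  # two non-incident edges of one tree
  expect_false(classify_cut(d, c("1--a", "3--d"))$legal)
  # a minimal cut isolating a leaf: legal but not nice
  inc_e <- d$keys[d$edges[, 1L] == "e" | d$edges[, 2L] == "e"]
  expect_true(is_minimal_cut(d, inc_e))
  cl <- classify_cut(d, inc_e)
  expect_true(cl$legal)
  expect_false(cl$nice)
})

test_that("cut parallelism matches the definition and is symmetric", {
  d <- build_display_graph(fig1_profile())
  f1 <- c("1--2", "5--6"); f2 <- c("2--3", "5--6", "6--7")
  expect_true(cuts_parallel(d, f1, f2))
  expect_true(cuts_parallel(d, f1, f1))
  sq <- list(vertices = c("p", "q", "r", "s"),
             edges = rbind(c("p", "q"), c("q", "r"), c("r", "s"), c("p", "s")))
  expect_false(cuts_parallel(sq, c("p--q", "r--s"), c("q--r", "p--s")))
  expect_error(cuts_parallel(d, c("1--2"), f1), class = "supercut_domain_error")
  set.seed(31)
  for (i in 1:5) {
    rp <- random_recipe_profile(300L + i)
    dd <- build_display_graph(rp$profile)
    if (max(dd$components) > 1L) next
    cuts <- enumerate_minimal_cuts(dd)
    idx <- sample.int(length(cuts), min(6L, length(cuts)))
    for (a in idx) for (b in idx) {
      expect_identical(cuts_parallel(dd, cuts[[a]], cuts[[b]]),
                       cuts_parallel(dd, cuts[[b]], cuts[[a]]))
    }
  }
})

test_that("is_minimal_separator matches the pairwise definitional oracle", {
  el <- build_elig(build_display_graph(fig1_profile()))
  r <- is_minimal_separator(el, c("1--2", "5--6"))
  expect_true(as.logical(r))
  expect_gte(attr(r, "full_components"), 2L)
  set.seed(37)
  for (i in 1:4) {
    g <- random_connected_graph(7L)
    for (rep in 1:40) {
      u <- sample(g$vertices, sample.int(4L, 1L))
      expect_identical(as.logical(is_minimal_separator(g, u)),
                       oracle_is_minimal_separator(g, u))
    }
  }
})

test_that("enumerate_minimal_separators agrees with brute force on small graphs", {
  set.seed(41)
  for (i in 1:4) {
    g <- random_connected_graph(7L)
    found <- cut_signatures(enumerate_minimal_separators(g))
    all_u <- list()
    vs <- g$vertices
    for (mask in seq_len(2^length(vs) - 1L)) {
      u <- vs[bitwAnd(mask, bitwShiftL(1L, seq_along(vs) - 1L)) != 0L]
      if (length(u) >= length(vs) - 1L) next
      if (oracle_is_minimal_separator(g, u)) all_u[[length(all_u) + 1L]] <- sort(u)
    }
    expect_identical(found, cut_signatures(all_u))
  }
})

test_that("minimal separators of the ELIG leave exactly two full components", {
  # the line graph of a connected display graph admits no three-component
  # minimal separators
  set.seed(43)
  for (i in 1:6) {
    rp <- random_recipe_profile(400L + i, n_labels = 5L, sizes = c(4L, 4L))
    d <- build_display_graph(rp$profile)
    if (max(d$components) > 1L) next
    el <- build_elig(d)
    for (u in enumerate_minimal_separators(el)) {
      keep <- setdiff(el$vertices, u)
      sub <- el$edges[el$edges[, 1L] %in% keep & el$edges[, 2L] %in% keep, , drop = FALSE]
      expect_equal(max(supercut:::graph_components(keep, sub)), 2L)
      # no separator swallows a vertex's whole incidence set
      for (v in d$vertices) {
        inc <- d$keys[d$edges[, 1L] == v | d$edges[, 2L] == v]
        expect_false(all(inc %in% u))
      }
    }
  }
})

test_that("legal separators of the ELIG are exactly the nice minimal cuts", {
  el <- build_elig(build_display_graph(fig1_profile()))
  expect_true(separator_is_legal(el, c("2--3", "5--6", "6--7")))
  expect_false(separator_is_legal(el, c("1--a", "3--d")))
  set.seed(47)
  for (i in 1:5) {
    rp <- random_recipe_profile(500L + i, n_labels = 5L, sizes = c(4L, 4L))
    d <- build_display_graph(rp$profile)
    if (max(d$components) > 1L) next
    el <- build_elig(d)
    nice <- Filter(function(f) classify_cut(d, f)$nice, enumerate_minimal_cuts(d))
    legal <- Filter(function(u) separator_is_legal(el, u),
                    enumerate_minimal_separators(el))
    expect_identical(cut_signatures(nice), cut_signatures(legal))
    # parallelism transfers between the two views
    if (length(nice) >= 2L) {
      idx <- utils::combn(min(5L, length(nice)), 2L)
      sigs <- cut_signatures(nice)
      byname <- nice[order(vapply(nice, paste, "", collapse = ";"))]
      for (cix in seq_len(ncol(idx))) {
        f1 <- byname[[idx[1L, cix]]]; f2 <- byname[[idx[2L, cix]]]
        expect_identical(cuts_parallel(d, f1, f2),
                         separators_parallel(el, f1, f2))
      }
    }
  }
})

test_that("a minimal cut with a sole tree edge separates that edge's subtrees", {
  set.seed(53)
  for (i in 1:6) {
    rp <- random_recipe_profile(600L + i)
    d <- build_display_graph(rp$profile)
    if (max(d$components) > 1L) next
    cuts <- enumerate_minimal_cuts(d)
    for (f in cuts[sample.int(length(cuts), min(10L, length(cuts)))]) {
      for (t in seq_along(rp$profile$trees)) {
        sl <- supercut:::cut_tree_slice(d, f, t)
        if (length(sl) != 1L) next
        uv <- supercut:::keys_to_edges(sl)[1L, ]
        comp <- supercut:::graph_components(d$vertices,
                                            supercut:::drop_edges(d$edges, f))
        expect_true(comp[[uv[1L]]] != comp[[uv[2L]]])
      }
    }
  }
})

test_that("cut_to_split induces the reference splits and respects parallelism", {
  d <- build_display_graph(fig1_profile())
  expect_equal(cut_to_split(d, c("1--2", "5--6")), "a,b,c|d,e,f,g")
  expect_equal(cut_to_split(d, c("1--2", "1--c", "4--5")), "a,b|c,d,e,f,g")
  expect_equal(cut_to_split(d, c("2--f", "6--7")), "a,b,c,d,e|f,g")
  expect_error(cut_to_split(d, "1--a"), class = "supercut_domain_error")
  set.seed(59)
  for (i in 1:5) {
    rp <- random_recipe_profile(700L + i)
    dd <- build_display_graph(rp$profile)
    if (max(dd$components) > 1L) next
    nice <- Filter(function(f) classify_cut(dd, f)$nice, enumerate_minimal_cuts(dd))
    if (length(nice) < 2L) next
    idx <- sample.int(length(nice), min(5L, length(nice)))
    for (a in idx) for (b in idx) {
      if (a >= b) next
      if (cuts_parallel(dd, nice[[a]], nice[[b]])) {
        expect_true(splits_compatible(cut_to_split(dd, nice[[a]]),
                                      cut_to_split(dd, nice[[b]])))
      }
    }
  }
})
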