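# Trees, Newick I/O, restriction, splits, and split-set tree construction.

test_that("parse_newick handles plain, rooted and degenerate forms", {
  t1 <- parse_newick("((a,b),c,(d,e));")
  expect_setequal(t1$leaves, c("a", "b", "c", "d", "e"))
  expect_equal(length(t1$vertices) - length(t1$leaves), 3L)
  expect_setequal(tree_splits(t1)$internal,
                  c(split_key(c("a", "b"), c("c", "d", "e")),
                    split_key(c("d", "e"), c("a", "b", "c"))))

  t2 <- parse_newick("(a,b);")
  expect_equal(nrow(t2$edges), 1L)
  expect_length(tree_splits(t2)$internal, 0L)

  # a rooted binary representation loses its degree-two root
  t3 <- parse_newick("((a,b),(c,d));")
  expect_equal(tree_splits(t3)$internal,
               split_key(c("a", "b"), c("c", "d")))
  expect_equal(write_newick(parse_newick("a;")), "a;")

  expect_error(parse_newick("((a,b),c;"), class = "supercut_parse_error")
  expect_error(parse_newick("((a,a),b);"), class = "supercut_domain_error")
})

test_that("newick round trip preserves the split set on random trees", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(2:10, 1L)
    tr <- supercut:::random_binary_tree(letters[seq_len(n)])
    if (stats::runif(1) < 0.4 && n >= 4L) {
      sp <- tree_splits(tr)
      ik <- names(sp$by_edge)[sp$by_edge %in% sp$internal]
      if (length(ik) > 0L) tr <- contract_edges(tr, sample(ik, 1L))
    }
    back <- parse_newick(write_newick(tr))
    expect_setequal(tree_splits(back)$internal, tree_splits(tr)$internal)
    # writing is canonical: a reparse writes identically
    expect_identical(write_newick(back), write_newick(tr))
  }
})

test_that("split sets agree with the phangorn bipartition oracle", {
  skip_if_not_installed("phangorn")
  set.seed(7)
  for (i in 1:25) {
    n <- sample(4:9, 1L)
    tr <- supercut:::random_binary_tree(letters[seq_len(n)])
    ph <- ape::unroot(ape::read.tree(text = write_newick(tr)))
    bip <- phangorn::as.splits(ph)
    labs <- attr(bip, "labels")
    keys <- unique(vapply(bip, function(s) {
      side <- labs[s]
      if (length(side) == 0L || length(side) == length(labs)) return(NA_character_)
      split_key(side, setdiff(labs, side))
    }, ""))
    keys <- keys[!is.na(keys)]
    keys <- keys[!vapply(keys, split_is_trivial, logical(1L))]
    expect_setequal(tree_splits(tr)$internal, keys)
  }
})

test_that("restriction returns the suppressed minimal subtree", {
  t1 <- parse_newick("((a,b),c,(d,e));")
  star <- restrict_tree(t1, c("a", "b", "c"))
  expect_length(tree_splits(star)$internal, 0L)
  expect_setequal(star$leaves, c("a", "b", "c"))
  expect_setequal(tree_splits(restrict_tree(t1, t1$leaves))$internal,
                  tree_splits(t1)$internal)
  q <- restrict_tree(t1, c("a", "b", "d", "e"))
  expect_equal(tree_splits(q)$internal, split_key(c("a", "b"), c("d", "e")))
  expect_error(restrict_tree(t1, c("a", "z")), class = "supercut_domain_error")
  expect_error(restrict_tree(t1, character(0)), class = "supercut_domain_error")
})

test_that("restriction composes: restricting twice equals restricting once", {
  set.seed(11)
  for (i in 1:20) {
    tr <- supercut:::random_binary_tree(letters[1:8])
    y <- sample(letters[1:8], 6L)
    z <- sample(y, 4L)
    a <- restrict_tree(restrict_tree(tr, y), z)
    b <- restrict_tree(tr, z)
    expect_setequal(tree_splits(a)$internal, tree_splits(b)$internal)
  }
})

test_that("tree_splits partitions edges into internal and trivial", {
  t1 <- parse_newick("((a,b),c,(d,e));")
  sp <- tree_splits(t1)
  expect_length(sp$trivial, 5L)
  expect_length(sp$internal, 2L)
  expect_equal(length(sp$by_edge), nrow(t1$edges))
  star <- parse_newick("(a,b,c,d,e,f);")
  expect_length(tree_splits(star)$internal, 0L)
  # the first reference tree of the compatible example
  fig1_t1 <- fig1_profile()$trees[[1L]]
  expect_setequal(tree_splits(fig1_t1)$internal,
                  c(split_key(c("a", "b", "c"), c("d", "e", "f")),
                    split_key(c("a", "b", "c", "f"), c("d", "e"))))
})

test_that("split compatibility follows the empty-intersection rule", {
  expect_true(splits_compatible("a,b,c|d,e,f,g", "a,b,c,f,g|d,e"))
  expect_false(splits_compatible("a,b|c,d", "a,c|b,d"))
  # a trivial split is compatible with every split of the universe
  for (s in c("a,b|c,d,e", "a,c|b,d,e", "a,b,c|d,e")) {
    expect_true(splits_compatible(s, "a|b,c,d,e"))
    expect_true(splits_compatible(s, "a,b,c,d|e"))
  }
})

test_that("tree_from_splits realises compatible sets and rejects incompatible ones", {
  sig <- c("a,b,c|d,e,f,g", "a,b,c,f,g|d,e", "a,b|c,d,e,f,g", "a,b,c,d,e|f,g")
  tr <- tree_from_splits(sig, letters[1:7])
  expect_setequal(tree_splits(tr)$internal, sig)
  star <- tree_from_splits(character(0), letters[1:4])
  expect_length(tree_splits(star)$internal, 0L)
  err <- tryCatch(tree_from_splits(c("a,b|c,d", "a,c|b,d"), letters[1:4]),
                  supercut_incompatible = function(e) e)
  expect_s3_class(err, "supercut_incompatible")
  expect_setequal(err$pair, c("a,b|c,d", "a,c|b,d"))
  expect_error(tree_from_splits("a,b|c,x", letters[1:4]),
               class = "supercut_domain_error")
})

test_that("tree_from_splits is insensitive to split ordering and round-trips", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(4:10, 1L)
    tr <- supercut:::random_binary_tree(letters[seq_len(n)])
    sp <- tree_splits(tr)$internal
    back <- tree_from_splits(sp, tr$leaves)
    expect_setequal(tree_splits(back)$internal, sp)
    shuf <- tree_from_splits(sample(sp), tr$leaves)
    expect_identical(write_newick(shuf), write_newick(back))
  }
})

test_that("adding an incompatible split to a realisable set always raises", {
  set.seed(6)
  for (i in 1:10) {
    tr <- supercut:::random_binary_tree(letters[1:6])
    sp <- tree_splits(tr)$internal
    if (length(sp) == 0L) next
    # find a split incompatible with a member
    cand <- utils::combn(letters[1:6], 3L, simplify = FALSE)
    bad <- NULL
    for (side in cand) {
      k <- split_key(side, setdiff(letters[1:6], side))
      if (any(!vapply(sp, splits_compatible, logical(1L), s2 = k))) { bad <- k; break }
    }
    if (is.null(bad)) next
    expect_error(tree_from_splits(c(sp, bad), letters[1:6]),
                 class = "supercut_incompatible")
  }
})

test_that("displays_and_agrees: identity, refinement, and agrees implies displays", {
  t1 <- parse_newick("((a,b),(c,d));")
  expect_equal(displays_and_agrees(t1, t1), list(displays = TRUE, agrees = TRUE))
  star <- parse_newick("(a,b,c,d);")
  expect_equal(displays_and_agrees(t1, star), list(displays = TRUE, agrees = FALSE))
  expect_error(displays_and_agrees(star, parse_newick("(a,b,z);")),
               class = "supercut_domain_error")
  set.seed(9)
  for (i in 1:30) {
    s <- supercut:::random_binary_tree(letters[1:7])
    sub <- restrict_tree(s, sample(letters[1:7], sample(3:6, 1L)))
    sp <- tree_splits(sub)
    ik <- names(sp$by_edge)[sp$by_edge %in% sp$internal]
    if (length(ik) > 0L && stats::runif(1) < 0.5) sub <- contract_edges(sub, sample(ik, 1L))
    da <- displays_and_agrees(s, sub)
    expect_true(da$displays)
    if (da$agrees) expect_true(da$displays)
  }
})
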