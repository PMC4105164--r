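test_that("indel characters are extracted from gap blocks with truth", {
  rows <- c(A = "AAAA--TTTTGG", B = "AAAA--TTTTGG",
            C = "AAAATTTTTT--", D = "AAAATTTTTTGG")
  aln <- new_alignment(rows, names(rows))
  im <- build_indel_matrix(list(reg1 = aln))
  expect_equal(nrow(im$characters), 2L)
  st <- im$states
  expect_equal(unname(st[1L, ]), c(1L, 1L, 0L, 0L))   # shared block, informative
  expect_equal(unname(st[2L, ]), c(0L, 0L, 1L, 0L))   # single-taxon block
  expect_equal(im$characters$informative, c(TRUE, FALSE))
  # constant columns never become characters
  aln2 <- new_alignment(c(A = "AAT", B = "AAT", C = "AAT", D = "AAT"),
                        c("A", "B", "C", "D"))
  expect_equal(nrow(build_indel_matrix(list(r = aln2))$characters), 0L)
  # mismatched taxon sets are rejected
  aln3 <- new_alignment(c(A = "A-T", X = "AAT"), c("A", "X"))
  expect_error(build_indel_matrix(list(reg1 = aln, reg2 = aln3)),
               "taxon set")
})

test_that("forced four-taxon placements classify as expected", {
  taxa <- c("A", "B", "C", "D")
  tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  im <- make_matrix(taxa, list(c(1L, 1L, 0L, 0L), c(1L, 0L, 1L, 0L),
                               c(1L, 0L, 0L, 0L)))
  mp <- fitch_assign(tree, im, outgroup = "D")
  expect_equal(mp$mapping$min_changes, c(1L, 2L, 1L))
  expect_equal(mp$mapping$class, c("synapomorphy", "homoplasy", "autapomorphy"))
  # the synapomorphy maps to the stem of (A,B)
  expect_match(mp$mapping$branches[1L], "mrca\\(A\\+B\\)")
  # the character present only outside the outgroup is a deletion
  expect_equal(mp$mapping$direction[1L], "-")
})

test_that("Fitch counts equal the exhaustive minimum on random trees", {
  set.seed(13)
  for (i in 1:60) {
    nt <- sample(4:8, 1)
    tree <- ape::rtree(nt, rooted = TRUE)
    tree$tip.label <- paste0("t", seq_len(nt))
    st <- sample(c(0L, 1L), nt, replace = TRUE)
    if (runif(1) < 0.2) st[sample(nt, 1)] <- NA
    if (length(unique(na.omit(st))) < 2) next
    names(st) <- tree$tip.label
    im <- make_matrix(tree$tip.label, list(st))
    mp <- fitch_assign(tree, im, outgroup = "t1")
    expect_equal(mp$mapping$min_changes,
                 bf_fitch_min(mp$tree, st),
                 label = paste("case", i))
  }
})

test_that("Fitch counts agree with an independent parsimony implementation", {
  skip_if_not_installed("phangorn")
  set.seed(14)
  for (i in 1:20) {
    nt <- sample(4:8, 1)
    tree <- ape::rtree(nt, rooted = TRUE)
    tree$tip.label <- paste0("t", seq_len(nt))
    st <- sample(c(0L, 1L), nt, replace = TRUE)
    if (length(unique(st)) < 2) next
    names(st) <- tree$tip.label
    im <- make_matrix(tree$tip.label, list(st))
    mp <- fitch_assign(tree, im, outgroup = "t1")
    dat <- phangorn::phyDat(matrix(as.character(st), ncol = 1,
                                   dimnames = list(tree$tip.label, NULL)),
                            type = "USER", levels = c("0", "1"))
    expect_equal(mp$mapping$min_changes,
                 as.integer(phangorn::parsimony(tree, dat)))
  }
})

test_that("change counts are invariant to the rooting position", {
  set.seed(15)
  tree <- ape::rtree(7, rooted = TRUE)
  tree$tip.label <- paste0("t", 1:7)
  st <- c(1L, 1L, 0L, 1L, 0L, 0L, 1L)
  names(st) <- tree$tip.label
  im <- make_matrix(tree$tip.label, list(st))
  counts <- vapply(tree$tip.label, function(og)
    fitch_assign(tree, im, outgroup = og)$mapping$min_changes, 0L)
  expect_equal(length(unique(counts)), 1L)
})

test_that("characters born of single planted changes map cleanly", {
  # plant one gap per branch of a known tree; every character must come out
  # as a synapomorphy or autapomorphy with the planted clade
  tree <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,(D:1,E:1):1,OUT:1);")
  taxa <- c("A", "B", "C", "D", "E", "OUT")
  clades <- list(c("A", "B"), c("A", "B", "C"), c("D", "E"), "C", "E")
  sts <- lapply(clades, function(cl) {
    s <- setNames(rep(0L, length(taxa)), taxa)
    s[cl] <- 1L
    s
  })
  im <- make_matrix(taxa, sts)
  mp <- fitch_assign(tree, im, outgroup = "OUT")
  expect_true(all(mp$mapping$min_changes == 1L))
  expect_equal(mp$mapping$class,
               ifelse(lengths(clades) >= 2, "synapomorphy", "autapomorphy"))
  sm <- classify_characters(mp)
  expect_equal(unname(sm$by_class[["homoplasy"]]), 0L)
  expect_equal(sm$single_change, length(clades))
  # class partition is total and exclusive
  expect_equal(sum(sm$by_class), nrow(mp$mapping))
})
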