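test_that("ancestors are deterministic and structurally exact", {
  a1 <- make_ancestor(small_cfg(61))
  a2 <- make_ancestor(small_cfg(61))
  expect_identical(a1$record$sequence, a2$record$sequence)
  expect_identical(a1$record$features, a2$record$features)
  p <- detect_quadripartite(a1$record, min_ir = 1000)
  expect_equal(unname(p$junctions), unname(a1$truth$junctions))
  # planted IR pair is exactly reverse-complementary
  irb <- substr(a1$record$sequence, p$irb[1] + 1, p$irb[1] + p$irb[2])
  ira <- substr(a1$record$sequence, p$ira[1] + 1, p$ira[1] + p$ira[2])
  expect_identical(revcomp(ira), irb)
})

test_that("zero-length branches leave every tip identical to the ancestor", {
  anc <- make_ancestor(small_cfg(62))
  cl <- evolve_along_tree(anc, evolution_config("(A:0,B:0);", seed = 1))
  for (tp in cl$tips)
    expect_identical(tp$sequence, anc$record$sequence)
})

test_that("trees are validated", {
  anc <- make_ancestor(small_cfg(63))
  expect_error(evolve_along_tree(anc, evolution_config("(A:-0.1,B:0.1);")),
               "negative branch length")
  expect_error(evolve_along_tree(anc, evolution_config("(A,B);")),
               "branch lengths")
})

test_that("concerted evolution keeps the IR copies identical at every tip", {
  sc <- small_clade(64)
  for (tp in sc$clade$tips) {
    p <- detect_quadripartite(tp, min_ir = 1000)
    irb <- plastcomp:::extract_circular(tp$sequence, p$irb[1], p$irb[2])
    ira <- plastcomp:::extract_circular(tp$sequence, p$ira[1], p$ira[2])
    expect_identical(revcomp(ira), irb)
    expect_gte(p$ir_length, sc$anc$truth$partition[["ir"]] - 50)
  }
})

test_that("non-concerted mode lets the IR copies diverge", {
  anc <- make_ancestor(small_cfg(65))
  cl <- evolve_along_tree(anc, evolution_config(
    "(A:0.02,B:0.02);", seed = 3, ir_concerted = FALSE,
    rate_multipliers = c(IR = 3, LSC = 1, SSC = 1)))
  diverged <- vapply(cl$tips, function(tp) {
    l <- anc$truth$partition[["lsc"]]
    tryCatch({
      detect_quadripartite(tp, min_ir = 1000)
      FALSE
    }, error = function(e) TRUE)
  }, TRUE)
  expect_true(any(diverged))
})

test_that("the truth table replays every tip byte-for-byte", {
  sc <- small_clade(66)
  cl <- sc$clade
  tr <- cl$tree
  nt <- length(tr$tip.label)
  for (lab in tr$tip.label) {
    node <- which(tr$tip.label == lab)
    path <- c()
    while (node != nt + 1L) {
      i <- which(tr$edge[, 2] == node)
      path <- c(i, path)
      node <- tr$edge[i, 1]
    }
    keys <- paste0(tr$edge[path, 1], "->", tr$edge[path, 2])
    evs <- unlist(lapply(keys, function(k) cl$truth$events[[k]]),
                  recursive = FALSE)
    rebuilt <- plastcomp:::materialize_core(
      replay_events(cl$truth$ancestor_core, evs), id = lab)
    expect_identical(rebuilt$sequence, cl$tips[[lab]]$sequence)
    expect_identical(rebuilt$features, cl$tips[[lab]]$features)
  }
})

test_that("annotations lift over through indels", {
  sc <- small_clade(67)
  for (tp in sc$clade$tips) {
    cz <- gene_census(tp)
    expect_equal(cz$total, sc$anc$truth$census$total)
    # features stay in bounds and non-degenerate
    f <- tp$features
    expect_true(all(f$start >= 0 & f$end <= genome_length(tp) &
                      f$end > f$start))
  }
})

test_that("fixture sets round-trip through the readers deterministically", {
  sc <- small_clade(68, tree = "(A:0.001,B:0.002);")
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_fixture_set(sc$clade, d1)
  p2 <- write_fixture_set(sc$clade, d2)
  expect_identical(basename(p1), basename(p2))
  for (k in seq_along(p1))
    expect_identical(readLines(p1[k]), readLines(p2[k]))
  for (lab in names(sc$clade$tips)) {
    back <- read_genbank(file.path(d1, paste0(lab, ".gb")))
    expect_identical(back$sequence, sc$clade$tips[[lab]]$sequence)
    fa <- read_fasta(file.path(d1, paste0(lab, ".fasta")))
    expect_identical(fa$sequence, sc$clade$tips[[lab]]$sequence)
  }
  expect_warning(write_fixture_set(structure(list(tips = list(), tree = NULL,
                                                  truth = list(events = NULL,
                                                               config = NULL)),
                                             class = "synthetic_clade"),
                                   withr::local_tempdir()),
                 "empty")
})
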