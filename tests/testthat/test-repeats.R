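test_that("flush duplications are reported exactly once with zero mismatches", {
  set.seed(7)
  x <- rand_seq(30)
  h <- find_repeats(paste0(x, x))
  expect_equal(nrow(h), 1L)
  expect_equal(h$type, "direct")
  expect_equal(h$length, 30L)
  expect_equal(h$mismatches, 0L)
  expect_equal(c(h$pos1, h$pos2), c(0L, 30L))

  hp <- find_repeats(paste0(x, revcomp(x)))
  expect_equal(nrow(hp), 1L)
  expect_equal(hp$type, "palindromic")
  expect_equal(hp$length, 30L)

  hr <- find_repeats(paste0(x, plastcomp:::str_reverse(x)))
  expect_true("reverse" %in% hr$type)
})

test_that("29-bp duplications isolated by N walls are never reported", {
  set.seed(8)
  for (i in 1:5) {
    x29 <- rand_seq(29)
    s <- paste0(rand_seq(60), "NN", x29, "NN", rand_seq(40), "NN", x29, "NN",
                rand_seq(60))
    expect_equal(nrow(find_repeats(s)), 0L)
    x30 <- rand_seq(30)
    s2 <- paste0(rand_seq(60), "NN", x30, "NN", rand_seq(40), "NN", x30, "NN",
                 rand_seq(60))
    h <- find_repeats(s2)
    expect_equal(nrow(h), 1L)
    expect_equal(h$length, 30L)
  }
})

test_that("seed-and-extend equals the brute-force scan on random sequences", {
  set.seed(9)
  for (i in 1:8) {
    n <- sample(150:400, 1)
    v <- chars(rand_seq(n))
    # plant a mismatched copy pair of a random type
    len <- sample(25:60, 1)
    src <- sample(n - 2 * len - 10, 1)
    dst <- src + len + sample(5:10, 1)
    cp <- v[src:(src + len - 1)]
    nmm <- sample(0:3, 1)
    if (nmm > 0) {
      at <- sample(seq_along(cp), nmm)
      cp[at] <- vapply(cp[at], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    }
    ty <- sample(c("direct", "palindromic", "reverse"), 1)
    v[dst:(dst + len - 1)] <- switch(ty, direct = cp,
                                     palindromic = rc_chars(cp),
                                     reverse = rev(cp))
    s <- paste(v, collapse = "")
    expect_identical(hits_key(find_repeats(s)), hits_key(bf_repeats(s)))
  }
})

test_that("every reported hit verifies its own mismatch budget", {
  set.seed(10)
  anc <- make_ancestor(small_cfg(31))
  st <- strip_duplicate_ir(anc$record, min_ir = 1000)
  h <- find_repeats(st$sequence)
  v <- chars(st$sequence)
  for (i in seq_len(nrow(h))) {
    c1 <- v[(h$pos1[i] + 1):(h$pos1[i] + h$length[i])]
    c2 <- v[(h$pos2[i] + 1):(h$pos2[i] + h$length[i])]
    c2t <- switch(h$type[i], direct = c2, palindromic = rc_chars(c2),
                  reverse = rev(c2))
    expect_equal(sum(c1 != c2t), h$mismatches[i])
    expect_lte(h$mismatches[i], min(3, floor(h$length[i] * 0.10)))
    expect_gte(h$length[i], 30)
  }
})

test_that("results are invariant under reverse complementation", {
  set.seed(12)
  x <- rand_seq(35)
  s <- paste0(rand_seq(80), x, rand_seq(50), x, rand_seq(80))
  h1 <- find_repeats(s)
  h2 <- find_repeats(revcomp(s))
  n <- nchar(s)
  # remap h2 coordinates back to the forward strand
  p1 <- n - (h2$pos2 + h2$length); p2 <- n - (h2$pos1 + h2$length)
  expect_identical(sort(paste(h2$type, pmin(p1, p2), pmax(p1, p2), h2$length)),
                   sort(paste(h1$type, h1$pos1, h1$pos2, h1$length)))
})

test_that("IR stripping retains a single inverted-repeat copy", {
  anc <- make_ancestor(small_cfg(32))
  st <- strip_duplicate_ir(anc$record, min_ir = 1000)
  p <- st$partition
  expect_equal(nchar(st$sequence), genome_length(anc$record) - p$ir_length)
  segs <- plastcomp:::exact_inverted_segments(st$sequence, 1000,
                                              circular = FALSE)
  expect_equal(nrow(segs), 0L)
})

test_that("planted repeats are recovered on the genome scan", {
  anc <- make_ancestor(small_cfg(33))
  # truth coordinates live on the record's own LSC+IRb+SSC prefix; the
  # canonicalised scan may flip strand, so recover on the raw prefix
  p <- detect_quadripartite(anc$record, min_ir = 1000)
  stripped <- substr(anc$record$sequence, 1,
                     genome_length(anc$record) - p$ir_length)
  hits <- find_repeats(stripped)
  tr <- anc$truth$repeats
  for (i in seq_len(nrow(tr))) {
    cover <- hits$type == tr$type[i] &
      hits$pos1 <= tr$pos1[i] & hits$pos1 + hits$length >= tr$pos1[i] + 35 &
      hits$pos2 <= tr$pos2[i] & hits$pos2 + hits$length >= tr$pos2[i] + 35
    expect_true(any(cover), label = paste("planted", tr$type[i], "recovered"))
  }
  annotated <- find_repeats_genome(anc$record, min_ir = 1000)
  expect_true(all(c("location1", "region1") %in% names(annotated)))
  # strand choice cannot change what is found, only where it is reported
  expect_equal(sort(annotated$length[annotated$type == "direct"]),
               sort(hits$length[hits$type == "direct"]))
})

test_that("shared repeat bookkeeping separates shared from unique keys", {
  anc <- make_ancestor(small_cfg(34))
  h <- find_repeats_genome(anc$record, min_ir = 1000)
  sh <- shared_repeat_sets(list(g1 = h, g2 = h))
  expect_equal(sh$shared_by_all, nrow(unique(h[, c("type", "length",
                                                   "region1", "region2")])))
  expect_true(all(sh$unique_counts == 0))
  # a genome with one extra private hit
  h2 <- rbind(h, transform(h[1L, ], length = h$length[1L] + 5L))
  sh2 <- shared_repeat_sets(list(g1 = h, g2 = h2))
  expect_equal(unname(sh2$unique_counts["g2"]), 1)
})

test_that("parameter validation rejects an invalid seed scheme", {
  expect_error(find_repeats("ACGTACGTACGT", min_len = 7), "seed scheme")
})
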