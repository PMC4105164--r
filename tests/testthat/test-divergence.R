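test_that("global alignment handles identical and near-identical inputs", {
  set.seed(5)
  a <- rand_seq(100)
  al <- align_pair(a, a)
  expect_equal(al$L, 100L)
  expect_false(any(grepl("-", al$rows, fixed = TRUE)))
  ev <- count_events(al)
  expect_equal(ev$ns, 0)
  expect_equal(ev$id, 0L)

  al2 <- align_pair("ACGT", "AGT")
  ev2 <- count_events(al2, exclude_terminal_gaps = FALSE)
  expect_equal(ev2$id, 1L)
  expect_equal(ev2$indel_events$length, 1L)
  expect_equal(ev2$ns, 0)

  expect_error(align_pair(rand_seq(20001), "ACGT"), "region-wise")
})

test_that("alignment scores equal exhaustive enumeration on tiny strings", {
  set.seed(6)
  for (i in 1:25) {
    a <- rand_seq(sample(1:8, 1))
    b <- rand_seq(sample(1:8, 1))
    al <- align_pair(a, b)
    expect_equal(attr(al, "score"), bf_align_score(a, b),
                 label = paste(a, "vs", b))
  }
})

test_that("alignment scores agree with an established aligner", {
  skip_if_not_installed("Biostrings")
  set.seed(61)
  mat <- matrix(-3, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                          c("A", "C", "G", "T", "N")))
  diag(mat) <- 2; mat["N", ] <- 0; mat[, "N"] <- 0
  for (i in 1:15) {
    a <- rand_seq(sample(20:120, 1)); b <- rand_seq(sample(20:120, 1))
    al <- align_pair(a, b)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = mat, gapOpening = 8, gapExtension = 1)
    expect_equal(attr(al, "score"), Biostrings::score(pa))
  }
})

test_that("event counting types substitutions and groups gap runs", {
  al <- new_alignment(c("ACG-TT", "ATGCTT"), c("x", "y"))
  ev <- count_events(al, exclude_terminal_gaps = FALSE)
  expect_equal(ev$ns, 1)
  expect_equal(unname(ev$ns_by_type["C:T"]), 1)
  expect_equal(ev$id, 1L)
  expect_equal(ev$indel_events$length, 1L)
  expect_equal(ev$indel_events$bearer, "x")
  expect_equal(sum(ev$ns_by_type), ev$ns)

  # terminal gaps excluded by default; N columns ignored for NS
  al2 <- new_alignment(c("--GNAAT", "ACGTAA-"), c("x", "y"))
  ev2 <- count_events(al2)
  expect_equal(ev2$id, 0L)
  expect_equal(ev2$ns, 0)
  ev2b <- count_events(al2, exclude_terminal_gaps = FALSE)
  expect_equal(ev2b$id, 2L)
})

test_that("count_events is symmetric in its two rows", {
  set.seed(8)
  for (i in 1:20) {
    a <- rand_seq(80)
    vb <- chars(a)
    at <- sample(80, 6)
    vb[at] <- vapply(vb[at], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    b <- paste(c(vb[1:40], vb[46:80]), collapse = "")
    e1 <- count_events(align_pair(a, b, labels = c("a", "b")))
    e2 <- count_events(align_pair(b, a, labels = c("b", "a")))
    expect_equal(e1$ns, e2$ns)
    expect_equal(e1$id, e2$id)
    expect_equal(e1$ns_by_type, e2$ns_by_type)
  }
})

test_that("S/I ratios reproduce the published pairwise values", {
  expect_equal(si_ratio(82, 28), 2.93)
  expect_equal(si_ratio(265, 53), 5.00)
  expect_equal(si_ratio(0, 5), 0.00)
  expect_error(si_ratio(10, 0), "undefined")
})

test_that("indel length spectra bin and normalise correctly", {
  sp <- indel_length_spectrum(c(1, 1, 5))
  expect_equal(sp$count[sp$bin == "1"], 2)
  expect_equal(sp$count[sp$bin == "5-6"], 1)
  expect_equal(sum(sp$fraction), 1)
  sp2 <- indel_length_spectrum(c(1, 2, 3, 4, 5, 6, 7, 10, 11, 200))
  expect_equal(sp2$count, c(1, 1, 2, 2, 2, 2))
  expect_true(all(is.na(indel_length_spectrum(numeric(0))$fraction)))
})

test_that("variability percent implements (NS + ID) / L x 100", {
  a <- strrep("A", 100)
  expect_equal(variability_percent(new_alignment(c(a, a)))$variability, 0)
  # one variable column and one 3-column gap block over 100 columns
  r1 <- paste0(strrep("A", 50), "C", strrep("A", 49))
  r2 <- paste0(strrep("A", 50), "G", strrep("A", 19), "---", strrep("A", 27))
  v <- variability_percent(new_alignment(c(r1, r2)))
  expect_equal(v$ns, 1)
  expect_equal(v$id, 1)
  expect_equal(v$L, 100)
  expect_equal(v$variability, 2.0)
  # a gap block shared by the same rows counts once; different row sets split
  m <- new_alignment(c("AAAA--TT", "AAAA--TT", "AAAATTTT"))
  expect_equal(variability_percent(m)$id, 1)
  m2 <- new_alignment(c("AA--TTTT", "AAAA--TT", "AAAATTTT"))
  expect_equal(variability_percent(m2)$id, 2)
})

test_that("marker screening keeps strictly-above-threshold non-coding regions", {
  vars <- data.frame(region = c("a", "b", "c", "d"),
                     category = c("non-coding", "non-coding", "coding",
                                  "non-coding"),
                     ns = 1, id = 1, L = 100,
                     variability = c(3.2, 1.5, 9.0, 0.4))
  mk <- screen_markers(vars)
  expect_equal(mk$region, "a")   # 1.5 itself is excluded, coding filtered
  expect_equal(nrow(screen_markers(transform(vars, variability = 0))), 0L)
})

test_that("a region evolved five-fold faster ranks first in the screen", {
  set.seed(9)
  mutate_seq <- function(s, rate) {
    v <- chars(s)
    k <- rbinom(1, length(v), rate)
    if (k > 0) {
      at <- sample(length(v), k)
      v[at] <- vapply(v[at], function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    }
    paste(v, collapse = "")
  }
  regions <- setNames(replicate(8, rand_seq(400)), paste0("igs", 1:8))
  rows <- lapply(names(regions), function(nm) {
    rate <- if (nm == "igs3") 0.05 else 0.01
    aln <- align_pair(mutate_seq(regions[[nm]], rate),
                      mutate_seq(regions[[nm]], rate))
    variability_percent(aln, name = nm, category = "non-coding")
  })
  vars <- do.call(rbind, rows)
  mk <- screen_markers(vars, threshold = 0.5)
  expect_equal(mk$region[1L], "igs3")
})

test_that("pairwise genome divergence is symmetric and region-based", {
  sc <- small_clade(51)
  canon <- lapply(sc$clade$tips[c("A", "C")], canonical_orientation,
                  min_ir = 1000)
  d1 <- pairwise_region_divergence(canon[[1]], canon[[2]])
  d2 <- pairwise_region_divergence(canon[[2]], canon[[1]])
  expect_equal(d1$ns, d2$ns)
  expect_equal(d1$id, d2$id)
  expect_equal(d1$ns_by_type, d2$ns_by_type)
  expect_equal(sum(d1$ns_by_type), d1$ns)
  expect_true(all(d1$per_region$variability >= 0 &
                    d1$per_region$variability <= 100))
})

test_that("partition ratios are flat when rates are planted equal", {
  anc <- make_ancestor(ancestor_config(lsc_len = 9000, ssc_len = 3000,
                                       ir_len = 3500, seed = 52,
                                       plant_ssrs = FALSE,
                                       plant_repeats = FALSE))
  cl <- evolve_along_tree(anc, evolution_config(
    "(A:0.01,B:0.01);", seed = 99,
    rate_multipliers = c(IR = 1, LSC = 1, SSC = 1)))
  canon <- lapply(cl$tips, canonical_orientation, min_ir = 1000)
  pr <- partition_divergence_ratios(canon, mode = "positional", min_ir = 1000)
  expect_true(all(abs(pr$raw / pr$raw[1] - 1) < 0.35))
  pf <- partition_divergence_ratios(canon, mode = "functional", min_ir = 1000)
  expect_true(all(abs(pf$raw / pf$raw[1] - 1) < 0.35))
})
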