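test_that("mononucleotide thresholds are exact", {
  s <- paste0("G", strrep("A", 10), "C")
  loci <- find_ssrs(s, circular = FALSE)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$motif, "A/T")
  expect_equal(loci$repeat_count, 10L)
  expect_equal(c(loci$start, loci$end), c(1L, 11L))

  below <- find_ssrs(paste0("C", strrep("A", 9), "G"), circular = FALSE)
  expect_equal(nrow(below), 0L)
})

test_that("runs report only their primitive period", {
  loci <- find_ssrs(paste0("G", strrep("A", 12), "C"), circular = FALSE)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$unit_length, 1L)
  expect_equal(loci$repeat_count, 12L)
  # a dinucleotide run is not additionally reported at period 4
  loci2 <- find_ssrs(paste0("G", strrep("AT", 8), "C"), circular = FALSE)
  expect_equal(nrow(loci2), 1L)
  expect_equal(loci2$unit_length, 2L)
})

test_that("canonical motifs match the strand-independent convention", {
  expect_equal(canonical_motif("T"), "A/T")
  expect_equal(canonical_motif("CTTTTT"), "AAAAAG/CTTTTT")
  expect_equal(canonical_motif("AGGG"), "AGGG/CCCT")
  expect_error(canonical_motif("ATAT"), "primitive")
})

test_that("canonical_motif is constant on rotation/revcomp classes", {
  # exhaustive over dimers, trimers and tetramers; hexamers are covered in
  # the acceptance suite
  for (u in 2:4) {
    motifs <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), u)), 1,
                    paste, collapse = "")
    prim <- motifs[vapply(motifs, plastcomp:::is_primitive, TRUE)]
    for (m in prim) {
      ref <- canonical_motif(m)
      v <- chars(m)
      for (k in seq_len(u)) {
        rot <- paste(c(v[k:u], v[seq_len(k - 1)]), collapse = "")
        expect_identical(canonical_motif(rot), ref)
        expect_identical(canonical_motif(revcomp(rot)), ref)
      }
    }
  }
})

test_that("circular scans catch runs spanning the origin", {
  set.seed(77)
  s <- paste0(strrep("A", 6), "C", rand_seq(60), "G", strrep("A", 5))
  loci <- find_ssrs(s, circular = TRUE)
  wrap <- loci[loci$motif == "A/T" & loci$repeat_count == 11L, ]
  expect_equal(nrow(wrap), 1L)
  expect_equal(wrap$start, nchar(s) - 5L)
  expect_equal(nrow(find_ssrs(s, circular = FALSE)), 0L)
})

test_that("planted SSRs are recovered exactly; sub-threshold plants never appear", {
  for (seed in c(41, 42)) {
    anc <- make_ancestor(small_cfg(seed))
    loci <- find_ssrs(anc$record$sequence)
    tr <- anc$truth$ssrs
    for (i in which(!tr$subthreshold)) {
      hit <- loci$start == tr$start[i] & loci$repeat_count == tr$count[i] &
        loci$unit_length == nchar(tr$unit[i])
      expect_true(any(hit), label = paste("planted", tr$unit[i], tr$count[i]))
    }
    for (i in which(tr$subthreshold)) {
      overlap <- loci$start < tr$end[i] & loci$end > tr$start[i]
      expect_false(any(overlap))
    }
  }
})

test_that("loci verify their tandem structure and never overlap", {
  anc <- make_ancestor(small_cfg(43))
  s <- anc$record$sequence
  loci <- find_ssrs(s)
  v <- chars(s)
  n <- length(v)
  for (i in seq_len(nrow(loci))) {
    idx <- ((loci$start[i]):(loci$end[i] - 1L)) %% n + 1L
    run <- v[idx]
    expect_identical(paste(run, collapse = ""),
                     strrep(loci$unit[i], loci$repeat_count[i]))
  }
  if (nrow(loci) > 1L) {
    iv <- loci[order(loci$start), ]
    expect_true(all(iv$start[-1L] >= iv$end[-nrow(iv)] |
                      iv$end[-1L] <= iv$start[-nrow(iv)]))
  }
})

test_that("total SSR count is invariant under reverse complementation", {
  anc <- make_ancestor(small_cfg(44))
  s <- anc$record$sequence
  l1 <- find_ssrs(s)
  l2 <- find_ssrs(revcomp(s))
  expect_equal(nrow(l1), nrow(l2))
  expect_equal(sort(paste(l1$motif, l1$repeat_count)),
               sort(paste(l2$motif, l2$repeat_count)))
})

test_that("the genome report locates loci and tabulates by motif", {
  anc <- make_ancestor(small_cfg(45))
  rep_ <- ssr_genome_report(anc$record, min_ir = 1000)
  expect_true(all(c("location", "region", "partition") %in% names(rep_$loci)))
  expect_true(all(rep_$loci$partition %in% c("LSC", "SSC", "IR")))
  summ <- rep_$summary
  expect_equal(sum(summ$Number), nrow(rep_$loci))
  expect_equal(summ$LSC + summ$SSC + summ$IR, summ$Number)
  # empty input gives an empty table
  empty <- ssr_summary(find_ssrs("ACGTACGTACGT", circular = FALSE))
  expect_equal(nrow(empty), 0L)
})
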