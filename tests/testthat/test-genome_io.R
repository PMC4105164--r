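test_that("FASTA read normalises and round-trips", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "ACGT"), p)
  rec <- read_fasta(p, circular = FALSE)
  expect_s3_class(rec, "plastome")
  expect_equal(genome_length(rec), 4L)

  writeLines(c(">x", "acgt"), p)
  expect_equal(read_fasta(p)$sequence, "ACGT")

  writeLines(c(">x", "ACRT"), p)
  expect_message(rec <- read_fasta(p), "mapped to N")
  expect_equal(rec$sequence, "ACNT")

  writeLines(character(0), p)
  expect_error(read_fasta(p), "format error")

  anc <- make_ancestor(small_cfg(3))
  write_fasta(anc$record, p)
  back <- read_fasta(p)
  expect_identical(back$sequence, anc$record$sequence)
})

test_that("GenBank write-then-read preserves sequence and features", {
  anc <- make_ancestor(small_cfg(4))
  p <- withr::local_tempfile(fileext = ".gb")
  write_genbank(anc$record, p)
  back <- read_genbank(p)
  expect_identical(back$sequence, anc$record$sequence)
  expect_true(back$circular)
  norm <- function(f) {
    f <- f[order(f$name, f$kind, f$start, f$end), c("name", "kind", "start",
                                                    "end", "strand", "copy_tag")]
    rownames(f) <- NULL
    f
  }
  expect_equal(norm(back$features), norm(anc$record$features))
})

test_that("a minimal hand-written GenBank record parses", {
  p <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       toy 100 bp    DNA     linear PLN",
    "FEATURES             Location/Qualifiers",
    "     source          1..100",
    "     gene            10..40",
    "                     /gene=\"gA\"",
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste0("       61 ", paste(rep("acgtacgtac", 4), collapse = " ")),
    "//"), p)
  rec <- read_genbank(p)
  expect_equal(genome_length(rec), 100L)
  expect_false(rec$circular)
  f <- rec$features
  expect_equal(nrow(f), 1L)
  expect_equal(unname(unlist(f[1L, c("start", "end", "strand")])),
               c("9", "40", "+"))
})

test_that("GenBank errors are informative", {
  p <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       bad 10 bp DNA linear", "FEATURES", "//"), p)
  expect_error(read_genbank(p), "ORIGIN")
  writeLines(c(
    "LOCUS       bad 10 bp DNA linear PLN",
    "FEATURES             Location/Qualifiers",
    "     gene            5..40",
    "                     /gene=\"gX\"",
    "ORIGIN",
    "        1 acgtacgtac", "//"), p)
  expect_error(read_genbank(p), "gX")
})

test_that("functional regions: IGS, introns and coverage", {
  # two genes on a 400 bp circle: IGS between them and a wrapping IGS
  f <- rbind(
    data.frame(name = "A", kind = "gene", start = 0, end = 100, strand = "+",
               copy_tag = NA, feature_id = "A.g", part = 1L),
    data.frame(name = "A", kind = "CDS", start = 0, end = 100, strand = "+",
               copy_tag = NA, feature_id = "A.c", part = 1L),
    data.frame(name = "B", kind = "gene", start = 200, end = 300, strand = "+",
               copy_tag = NA, feature_id = "B.g", part = 1L),
    data.frame(name = "B", kind = "CDS", start = 200, end = 300, strand = "+",
               copy_tag = NA, feature_id = "B.c", part = 1L))
  rec <- plastome_record("toy", strrep("ACGT", 100), TRUE, f)
  regs <- extract_functional_regions(rec)
  igs <- regs[regs$category == "IGS", ]
  expect_setequal(igs$name, c("A/B", "B/A"))
  expect_equal(igs[igs$name == "A/B", c("start", "end")],
               data.frame(start = 100, end = 200), ignore_attr = TRUE)
  expect_equal(sum(igs$end[igs$name == "B/A"] - igs$start[igs$name == "B/A"]),
               100)

  # intron between two exons
  f2 <- rbind(
    data.frame(name = "G", kind = "gene", start = 0, end = 120, strand = "+",
               copy_tag = NA, feature_id = "G.g", part = 1L),
    data.frame(name = "G", kind = "CDS", start = c(0, 80), end = c(50, 120),
               strand = "+", copy_tag = NA, feature_id = "G.c", part = 1:2))
  rec2 <- plastome_record("toy2", strrep("ACGT", 50), TRUE, f2)
  regs2 <- extract_functional_regions(rec2)
  intr <- regs2[regs2$category == "intron", ]
  expect_equal(nrow(intr), 1L)
  expect_equal(intr$end - intr$start, 30)
  expect_equal(intr$name, "G intron")

  # coverage: regions partition a fully annotated synthetic genome up to
  # gene-gene overlaps
  anc <- make_ancestor(small_cfg(5))
  regs3 <- extract_functional_regions(anc$record)
  ov <- find_gene_overlaps(anc$record)
  expect_equal(sum(regs3$end - regs3$start) - sum(ov$overlap_bp),
               genome_length(anc$record))
})

test_that("gene census recovers the planted plan and counts IR genes twice", {
  anc <- make_ancestor(small_cfg(6))
  cz <- gene_census(anc$record)
  tr <- anc$truth$census
  expect_equal(cz$total, tr$total)
  expect_equal(cz$protein_coding, tr$protein_coding)
  expect_equal(cz$trna, tr$trna)
  expect_equal(cz$rrna, tr$rrna)
  expect_equal(cz$total, cz$protein_coding + cz$trna + cz$rrna)
  expect_equal(cz$intron_containing, tr$intron_containing)
  expect_equal(cz$two_intron_genes, tr$two_intron_genes)

  bare <- make_ancestor(ancestor_config(lsc_len = 3000, ssc_len = 1000,
                                        ir_len = 1200, with_genes = FALSE,
                                        plant_ssrs = FALSE,
                                        plant_repeats = FALSE, seed = 1))
  cz0 <- gene_census(bare$record)
  expect_equal(cz0$total, 0L)
  expect_equal(cz0$intron_containing, 0L)
})

test_that("planted gene overlaps are found with exact lengths", {
  anc <- make_ancestor(small_cfg(7))
  ov <- find_gene_overlaps(anc$record)
  key <- paste(pmin(ov$gene_a, ov$gene_b), pmax(ov$gene_a, ov$gene_b))
  expect_true("psbC psbD" %in% key)
  expect_equal(ov$overlap_bp[key == "psbC psbD"], 52)
  expect_true("atpB atpE" %in% key)
  expect_equal(ov$overlap_bp[key == "atpB atpE"], 3)
  # disjoint genes: no overlaps
  f <- rbind(
    data.frame(name = "A", kind = "gene", start = 0, end = 50, strand = "+",
               copy_tag = NA, feature_id = "A.g", part = 1L),
    data.frame(name = "B", kind = "gene", start = 60, end = 90, strand = "+",
               copy_tag = NA, feature_id = "B.g", part = 1L))
  rec <- plastome_record("t", strrep("A", 100), TRUE, f)
  expect_equal(nrow(find_gene_overlaps(rec)), 0L)
})

test_that("classify_location is total and reproduces hyphenated classes", {
  anc <- make_ancestor(small_cfg(8))
  regs <- extract_functional_regions(anc$record)
  igs <- regs[regs$category == "IGS", ][1L, ]
  expect_equal(classify_location(igs$start, igs$end, regs), "IGS")
  cds <- regs[regs$category == "CDS", ][1L, ]
  # an interval spanning from inside a CDS into the adjacent spacer
  expect_equal(classify_location(cds$end - 10, cds$end + 10, regs), "CDS-IGS")
  n <- attr(regs, "genome_length")
  expect_equal(classify_location(0, n, regs), "mixed")
  expect_error(classify_location(-5, 10, regs), "out of genome bounds")
  # totality on random in-bounds intervals
  set.seed(42)
  for (i in 1:50) {
    s <- sample(0:(n - 50), 1); e <- s + sample(1:200, 1)
    cls <- classify_location(s, min(e, n), regs)
    expect_true(is.character(cls) && nchar(cls) > 0)
  }
})

test_that("gc content excludes ambiguity characters", {
  rec <- plastome_record("x", "GGCCNNAT", circular = FALSE)
  expect_equal(gc_content(rec), 4 / 6)
})
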