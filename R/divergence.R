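# Pairwise divergence: global alignment, substitution and indel event
# counting, S/I ratios, indel length spectra, the per-region
# proportion-of-mutational-events statistic [(NS + ID)/L] x 100, hotspot
# marker screening, and partitioned divergence ratios.
#
# One indel event is one maximal run of gap columns with a fixed
# row-membership pattern, counted once regardless of length.

#' Construct a gapped alignment object
#'
#' @param rows character vector of equal-length gapped sequences over
#'   A, C, G, T, N, `-`.
#' @param labels row labels (defaults to names of `rows`).
#' @return object of class `dna_alignment`.
#' @export
new_alignment <- function(rows, labels = names(rows)) {
  stopifnot(length(rows) >= 2L)
  rows <- toupper(rows)
  L <- unique(nchar(rows))
  if (length(L) != 1L) stop("alignment rows differ in length")
  if (is.null(labels)) labels <- paste0("seq", seq_along(rows))
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  allgap <- colSums(m != "-") == 0L
  if (any(allgap)) {
    m <- m[, !allgap, drop = FALSE]
    rows <- apply(m, 1L, paste, collapse = "")
  }
  structure(list(rows = unname(rows), labels = labels,
                 L = nchar(rows[1L])),
            class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("<dna_alignment> ", length(x$rows), " rows x ", x$L, " columns (",
      paste(x$labels, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

aln_matrix <- function(aln) do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))

# maximal runs of columns sharing one non-empty gapped-row pattern
# returns rle-style summary: per run, start column, length, pattern code
gap_block_codes <- function(m) {
  G <- m == "-"
  k <- nrow(G)
  if (k <= 50L) {
    code <- as.vector(crossprod(G + 0, matrix(2^(seq_len(k) - 1L), ncol = 1)))
    code[colSums(G) == 0L] <- 0
  } else {
    pat <- apply(G, 2L, function(col) paste(which(col), collapse = ","))
    code <- match(pat, setdiff(unique(pat), ""))
    code[is.na(code)] <- 0
  }
  rl <- rle(code)
  ends <- cumsum(rl$lengths)
  list(start = ends - rl$lengths + 1L, length = rl$lengths,
       code = rl$values, is_block = rl$values != 0)
}

#' Global pairwise alignment with affine gap costs
#'
#' Needleman-Wunsch global alignment under match +2, mismatch -3, gap open
#' -8, gap extend -1 by default, so a gap of length g costs 8 + g.  N
#' scores 0 against everything.  Implemented in compiled code; agreement
#' with an established aligner under the same scoring is exercised in the
#' test suite.
#'
#' @param a,b DNA strings (each at most 20 kb; larger inputs must be
#'   aligned region-wise or imported).
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @param labels length-2 labels for the rows.
#' @return a `dna_alignment` with the score in attribute `"score"`.
#' @export
align_pair <- function(a, b,
                       scoring = list(match = 2, mismatch = -3,
                                      gap_open = -8, gap_extend = -1),
                       labels = c("a", "b")) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  if (nchar(a) > 20000L || nchar(b) > 20000L)
    stop("sequences over 20 kb: align region-wise (see pairwise_region_divergence) ",
         "or import an external alignment")
  res <- cpp_nw_align(toupper(a), toupper(b),
                      as.integer(scoring$match), as.integer(scoring$mismatch),
                      abs(as.integer(scoring$gap_open)),
                      abs(as.integer(scoring$gap_extend)))
  out <- new_alignment(c(res$a, res$b), labels = labels)
  attr(out, "score") <- res$score
  out
}

#' Read an aligned FASTA file as a `dna_alignment`
#' @param path aligned FASTA (gap character `-`).
#' @return a `dna_alignment`.
#' @export
read_alignment_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  new_alignment(setNames(toupper(as.character(ss)), names(ss)))
}

#' Write a `dna_alignment` as aligned FASTA
#' @param aln a `dna_alignment`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  ss <- Biostrings::BStringSet(setNames(aln$rows, aln$labels))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

SUB_TYPES <- c("A:C", "A:G", "A:T", "C:G", "C:T", "G:T")

#' Count substitution and indel events in a two-row alignment
#'
#' Substitutions (NS) are columns with two distinct non-N bases, typed by
#' unordered base pair; N-containing columns are ignored for NS.  Indel
#' events (ID) are maximal gap runs, one event each regardless of length;
#' terminal gap runs are excluded by default.
#'
#' @param aln a two-row `dna_alignment`.
#' @param exclude_terminal_gaps drop gap runs touching either alignment end
#'   (default TRUE).
#' @return object of class `pairwise_divergence`: `ns` (total), `ns_by_type`
#'   (named six-vector), `indel_events` (data.frame length, column_start,
#'   bearer, terminal), `id`, `si_ratio` (NS/ID, NA when ID = 0),
#'   `aligned_length`, `labels`.
#' @export
count_events <- function(aln, exclude_terminal_gaps = TRUE) {
  if (length(aln$rows) != 2L)
    stop("count_events expects a two-row alignment; use variability_percent ",
         "for multi-row alignments")
  m <- aln_matrix(aln)
  L <- ncol(m)
  g1 <- m[1L, ] == "-"; g2 <- m[2L, ] == "-"
  both <- !g1 & !g2
  subs <- both & m[1L, ] != m[2L, ] & m[1L, ] != "N" & m[2L, ] != "N"
  pair <- apply(rbind(m[1L, subs], m[2L, subs]), 2L,
                function(x) paste(sort(x), collapse = ":"))
  ns_by_type <- setNames(numeric(length(SUB_TYPES)), SUB_TYPES)
  if (length(pair)) {
    tb <- table(pair)
    ns_by_type[names(tb)] <- as.numeric(tb)
  }
  events <- list()
  for (r in 1:2) {
    g <- if (r == 1L) g1 else g2
    if (!any(g)) next
    rl <- rle(g)
    ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
    for (k in which(rl$values)) {
      events[[length(events) + 1L]] <-
        data.frame(length = rl$lengths[k], column_start = starts[k],
                   bearer = aln$labels[r],
                   terminal = starts[k] == 1L || ends[k] == L,
                   stringsAsFactors = FALSE)
    }
  }
  ev <- if (length(events)) do.call(rbind, events)
        else data.frame(length = integer(0), column_start = integer(0),
                        bearer = character(0), terminal = logical(0))
  if (exclude_terminal_gaps) ev <- ev[!ev$terminal, , drop = FALSE]
  ev <- ev[order(ev$column_start), , drop = FALSE]
  rownames(ev) <- NULL
  ns <- sum(ns_by_type)
  id <- nrow(ev)
  structure(list(ns = ns, ns_by_type = ns_by_type, indel_events = ev,
                 id = id, si_ratio = if (id > 0) ns / id else NA_real_,
                 aligned_length = L, labels = aln$labels),
            class = "pairwise_divergence")
}

#' @export
print.pairwise_divergence <- function(x, ...) {
  cat("<pairwise_divergence> ", paste(x$labels, collapse = " vs "), ": NS = ",
      x$ns, ", ID = ", x$id, ", S/I = ",
      if (is.na(x$si_ratio)) "undefined" else sprintf("%.2f", x$si_ratio),
      " over ", x$aligned_length, " columns\n", sep = "")
  invisible(x)
}

#' Substitution-to-indel event ratio
#'
#' @param ns number of nucleotide substitution events.
#' @param id number of indel events; must be positive.
#' @return NS/ID rounded to two decimals.
#' @export
si_ratio <- function(ns, id) {
  if (id == 0) stop("S/I undefined: zero indel events")
  round(ns / id, 2)
}

SPECTRUM_BINS <- c("1", "2", "3-4", "5-6", "7-10", ">10")

#' Indel length spectrum
#'
#' Bins indel event lengths into 1, 2, 3-4, 5-6, 7-10 and >10 bp.
#'
#' @param x a `pairwise_divergence`, an indel-event data.frame, or a
#'   numeric vector of event lengths.
#' @return data.frame: bin, count, fraction (fractions sum to 1).
#' @export
indel_length_spectrum <- function(x) {
  lens <- if (inherits(x, "pairwise_divergence")) x$indel_events$length
          else if (is.data.frame(x)) x$length
          else as.numeric(x)
  if (!length(lens))
    return(data.frame(bin = SPECTRUM_BINS, count = 0,
                      fraction = NA_real_))
  b <- cut(lens, breaks = c(0.5, 1.5, 2.5, 4.5, 6.5, 10.5, Inf),
           labels = SPECTRUM_BINS)
  counts <- as.numeric(table(b))
  data.frame(bin = SPECTRUM_BINS, count = counts,
             fraction = counts / sum(counts))
}

#' Proportion of mutational events in an aligned region
#'
#' Computes `[(NS + ID)/L] x 100` on a multiple alignment, where NS is the
#' number of columns containing at least two distinct non-gap, non-N bases,
#' ID the number of distinct maximal gap blocks (a block is a maximal run
#' of columns sharing one non-empty gapped-row pattern), and L the aligned
#' length in columns.
#'
#' @param aln a `dna_alignment` (two or more rows).
#' @param name region name for the report.
#' @param category "coding" or "non-coding" (or NA).
#' @return one-row data.frame of class `region_variability`: region,
#'   category, ns, id, L, variability (percent).
#' @export
variability_percent <- function(aln, name = NA_character_,
                                category = NA_character_) {
  m <- aln_matrix(aln)
  L <- ncol(m)
  n_distinct <- Reduce(`+`, lapply(c("A", "C", "G", "T"),
                                   function(b) colSums(m == b) > 0L))
  ns <- sum(n_distinct >= 2L)
  id <- sum(gap_block_codes(m)$is_block)
  out <- data.frame(region = name, category = category, ns = ns, id = id,
                    L = L, variability = (ns + id) / L * 100,
                    stringsAsFactors = FALSE)
  class(out) <- c("region_variability", "data.frame")
  out
}

#' Screen divergence hotspot regions
#'
#' @param vars data.frame of region variabilities (rows from
#'   [variability_percent()], rbind-ed).
#' @param threshold percent threshold; regions strictly above it are kept
#'   (default 1.5).
#' @param category restrict to one category (default "non-coding"; NULL
#'   keeps all).
#' @return the qualifying rows sorted by decreasing variability.
#' @export
screen_markers <- function(vars, threshold = 1.5, category = "non-coding") {
  if (!is.null(category)) vars <- vars[!is.na(vars$category) &
                                         vars$category == category, , drop = FALSE]
  out <- vars[vars$variability > threshold, , drop = FALSE]
  out <- out[order(-out$variability), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ------------------------------------------------ region-wise genome pairs

# shared-name region sequences of two annotated canonical records
shared_region_seqs <- function(recA, recB, regionsA = NULL, regionsB = NULL) {
  if (is.null(regionsA)) regionsA <- extract_functional_regions(recA)
  if (is.null(regionsB)) regionsB <- extract_functional_regions(recB)
  keyA <- paste(regionsA$name, regionsA$category)
  keyB <- paste(regionsB$name, regionsB$category)
  # collapse multi-row regions (wrapping IGS) by concatenation in key order
  seq_of <- function(rec, regions, key, k) {
    rows <- which(key == k)
    paste(vapply(rows, function(i)
      substr(rec$sequence, regions$start[i] + 1L, regions$end[i]), ""),
      collapse = "")
  }
  shared <- intersect(unique(keyA), unique(keyB))
  lapply(setNames(shared, shared), function(k) {
    i <- which(keyA == k)[1L]
    list(name = regionsA$name[i], category = regionsA$category[i],
         a = seq_of(recA, regionsA, keyA, k),
         b = seq_of(recB, regionsB, keyB, k),
         midA = floor((regionsA$start[i] + regionsA$end[i]) / 2))
  })
}

#' Region-wise pairwise divergence between two annotated genomes
#'
#' Aligns each shared named region (CDS, intron, IGS, tRNA, rRNA) of the
#' two canonical-orientation genomes with [align_pair()] and sums
#' substitution and indel events, the region-wise unit of whole-genome
#' divergence used throughout the package.
#'
#' @param recA,recB annotated `plastome` objects in canonical orientation.
#' @param regionsA,regionsB optional precomputed `region_set`s.
#' @param max_region_len regions longer than this are skipped with a
#'   warning (default 20000, the pairwise aligner cap).
#' @return list of class `genome_divergence`: `ns`, `id`, `si_ratio`,
#'   `ns_by_type`, `indel_lengths`, `per_region` (data.frame with name,
#'   category, mid (focal-genome midpoint), ns, id, L, variability),
#'   `aligned_length`, `labels`.
#' @export
pairwise_region_divergence <- function(recA, recB, regionsA = NULL,
                                       regionsB = NULL,
                                       max_region_len = 20000) {
  regs <- shared_region_seqs(recA, recB, regionsA, regionsB)
  ns <- 0; id <- 0; L <- 0
  ns_by_type <- setNames(numeric(length(SUB_TYPES)), SUB_TYPES)
  indel_lengths <- numeric(0)
  rows <- list()
  for (rg in regs) {
    if (nchar(rg$a) == 0L || nchar(rg$b) == 0L) next
    if (nchar(rg$a) > max_region_len || nchar(rg$b) > max_region_len) {
      warning("region ", rg$name, " exceeds the aligner cap; skipped")
      next
    }
    aln <- align_pair(rg$a, rg$b, labels = c(recA$id, recB$id))
    ev <- count_events(aln, exclude_terminal_gaps = FALSE)
    ns <- ns + ev$ns; id <- id + ev$id; L <- L + ev$aligned_length
    ns_by_type <- ns_by_type + ev$ns_by_type
    indel_lengths <- c(indel_lengths, ev$indel_events$length)
    rows[[length(rows) + 1L]] <-
      data.frame(name = rg$name, category = rg$category, mid = rg$midA,
                 ns = ev$ns, id = ev$id, L = ev$aligned_length,
                 variability = (ev$ns + ev$id) / ev$aligned_length * 100,
                 stringsAsFactors = FALSE)
  }
  per_region <- do.call(rbind, rows)
  structure(list(ns = ns, id = id,
                 si_ratio = if (id > 0) ns / id else NA_real_,
                 ns_by_type = ns_by_type, indel_lengths = indel_lengths,
                 per_region = per_region, aligned_length = L,
                 labels = c(recA$id, recB$id)),
            class = "genome_divergence")
}

#' Pairwise substitution/indel matrix for a set of genomes
#'
#' @param records named list of annotated canonical `plastome` objects.
#' @return list of class `divergence_matrix`: `ns`, `id`, `si` (matrices),
#'   `pairs` (list of `genome_divergence` keyed "A|B").
#' @export
genome_divergence_matrix <- function(records) {
  ids <- vapply(records, function(r) r$id, "")
  k <- length(records)
  stopifnot(k >= 2L)
  regions <- lapply(records, extract_functional_regions)
  ns <- id <- si <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  pairs <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    d <- pairwise_region_divergence(records[[i]], records[[j]],
                                    regions[[i]], regions[[j]])
    ns[i, j] <- ns[j, i] <- d$ns
    id[i, j] <- id[j, i] <- d$id
    si[i, j] <- si[j, i] <- if (is.na(d$si_ratio)) NA_real_ else round(d$si_ratio, 2)
    pairs[[paste(ids[i], ids[j], sep = "|")]] <- d
  }
  structure(list(ns = ns, id = id, si = si, pairs = pairs),
            class = "divergence_matrix")
}

#' Partitioned divergence ratios for a focal genome
#'
#' Averages per-category divergence (NS + ID)/L of the focal genome against
#' each partner, then normalises to the first category.  Functional mode
#' compares coding (CDS + tRNA + rRNA) : intron : IGS; positional mode
#' compares IR : LSC : SSC (category of a region is taken from the
#' focal-genome partition at the region midpoint).
#'
#' @param records named list of annotated canonical `plastome` objects.
#' @param focal index or id of the focal genome (default 1).
#' @param mode "functional" or "positional".
#' @param min_ir passed to [detect_quadripartite()].
#' @return list of class `partition_ratios`: `ratios` (named, first = 1),
#'   `raw` (mean per-category divergence), `mode`, `focal`.
#' @export
partition_divergence_ratios <- function(records, focal = 1L,
                                        mode = c("functional", "positional"),
                                        min_ir = 10000) {
  mode <- match.arg(mode)
  if (is.character(focal)) focal <- match(focal, vapply(records, function(r) r$id, ""))
  stopifnot(length(records) >= 2L, !is.na(focal))
  frec <- records[[focal]]
  fregions <- extract_functional_regions(frec)
  cats <- if (mode == "functional") c("coding", "intron", "IGS")
          else c("IR", "LSC", "SSC")
  fpart <- if (mode == "positional") detect_quadripartite(frec, min_ir) else NULL
  per_partner <- list()
  for (j in seq_along(records)[-focal]) {
    d <- pairwise_region_divergence(frec, records[[j]], fregions)
    pr <- d$per_region
    grp <- if (mode == "functional") {
      ifelse(pr$category %in% c("CDS", "tRNA", "rRNA"), "coding", pr$category)
    } else {
      vapply(pr$mid, function(p) {
        q <- partition_at(p, fpart)
        q
      }, "")
    }
    div <- vapply(cats, function(cc) {
      rows <- grp == cc
      if (!any(rows)) return(NA_real_)
      sum(pr$ns[rows] + pr$id[rows]) / sum(pr$L[rows])
    }, 0)
    per_partner[[length(per_partner) + 1L]] <- div
  }
  raw <- colMeans(do.call(rbind, per_partner), na.rm = TRUE)
  if (!is.finite(raw[1L]) || raw[1L] == 0)
    stop("zero divergence in the normalising category '", cats[1L], "'")
  structure(list(ratios = round(raw / raw[1L], 1), raw = raw, mode = mode,
                 focal = frec$id),
            class = "partition_ratios")
}

#' @export
print.partition_ratios <- function(x, ...) {
  cat("<partition_ratios> ", x$focal, " (", x$mode, "): ",
      paste(names(x$ratios), collapse = ":"), " = ",
      paste(x$ratios, collapse = ":"), "\n", sep = "")
  invisible(x)
}

#' Region variability table across a set of genomes
#'
#' Builds a star multiple alignment of each shared region (reference = the
#' first genome) and computes the proportion-of-mutational-events statistic
#' per region.
#'
#' @param records named list of annotated canonical `plastome` objects
#'   (two or more).
#' @return data.frame: region, category ("coding"/"non-coding"), ns, id, L,
#'   variability.
#' @export
region_variability_table <- function(records) {
  stopifnot(length(records) >= 2L)
  alns <- multi_region_alignments(records)
  rows <- lapply(names(alns), function(nm) {
    a <- alns[[nm]]
    cat_ <- attr(a, "category")
    variability_percent(a, name = nm,
                        category = if (cat_ %in% c("intron", "IGS")) "non-coding"
                                   else "coding")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
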