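# Dispersed repeats: direct (both copies forward), reverse (second copy
# reversed without complement) and palindromic (second copy
# reverse-complemented) repeat pairs.
#
# A hit is a maximal pair of aligned segments whose Hamming distance fits
# the budget min(max_mismatch, floor(0.10 * length)): extending either end
# by one position would add a disallowed mismatch, run past the sequence
# end, or into an N (N columns act as hard walls and never match).  Hits
# contained in a longer reported hit of the same type are suppressed, as
# are pairs whose copies overlap each other, and hits longer than max_len
# (which removes the global IR pair when scanning a two-IR genome).

default_seed_len <- function(min_len, max_mismatch) {
  max(4L, min(12L, as.integer(ceiling((min_len - max_mismatch) / (max_mismatch + 1)))))
}

repeat_hits_frame <- function() {
  data.frame(type = character(0), length = integer(0), pos1 = integer(0),
             pos2 = integer(0), mismatches = integer(0))
}

# containment suppression + validity filtering shared by the three types.
# key: value constant along the "diagonal" family of each type, so that
# containment of copy1 intervals implies containment of copy2 intervals.
filter_hits <- function(df, min_len, max_mismatch, max_len) {
  if (nrow(df) == 0L) return(df)
  df <- df[df$pos2 >= df$pos1 + df$length, , drop = FALSE]          # no self-overlap
  df <- df[df$length >= min_len & df$length <= max_len, , drop = FALSE]
  df <- df[df$mismatches <= pmin(max_mismatch, floor(df$length * 0.10)), , drop = FALSE]
  if (nrow(df) == 0L) return(df)
  df <- df[!duplicated(df[, c("pos1", "pos2", "length")]), , drop = FALSE]
  df <- df[order(-df$length, df$pos1), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))[-1L]) {
    js <- which(keep[seq_len(i - 1L)])
    for (j in js) {
      if (df$key[j] == df$key[i] &&
          df$pos1[i] >= df$pos1[j] &&
          df$pos1[i] + df$length[i] <= df$pos1[j] + df$length[j]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  df[keep, , drop = FALSE]
}

#' Find dispersed repeats in a DNA sequence
#'
#' Reports maximal direct, reverse and palindromic repeat pairs of at least
#' `min_len` bp whose Hamming distance is at most
#' `min(max_mismatch, floor(0.10 * length))`.  Exact-match seeding
#' guarantees completeness: every qualifying pair contains an exact run of
#' at least `ceiling((min_len - max_mismatch) / (max_mismatch + 1))` bases.
#'
#' @param seq DNA string.
#' @param min_len minimum repeat length (default 30; must be >= 8 for the
#'   seed scheme to be valid).
#' @param max_mismatch maximum Hamming distance between the two copies
#'   (default 3).
#' @param max_len maximum reported length (default 5000), which excludes
#'   the genome-scale inverted-repeat pair.
#' @return data.frame of class `repeat_hits`: `type`, `length`, `pos1`,
#'   `pos2` (0-based starts of the two copies, pos1 < pos2), `mismatches`.
#' @export
find_repeats <- function(seq, min_len = 30, max_mismatch = 3, max_len = 5000) {
  if (min_len < 8) stop("min_len below 8: seed scheme invalid")
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < min_len) {
    out <- repeat_hits_frame()
    class(out) <- c("repeat_hits", "data.frame")
    return(out)
  }
  seed <- default_seed_len(min_len, max_mismatch)
  res <- list()

  w <- cpp_diag_windows(seq, seq, as.integer(min_len), as.integer(max_mismatch),
                        seed, TRUE)
  if (nrow(w)) {
    res$direct <- data.frame(type = "direct", length = w$len, pos1 = w$ia,
                             pos2 = w$ib, mismatches = w$mm,
                             key = w$ib - w$ia)
  }
  vseq <- s2c(seq)
  for (ty in c("palindromic", "reverse")) {
    b <- if (ty == "palindromic") revcomp(seq) else str_reverse(seq)
    w <- cpp_diag_windows(seq, b, as.integer(min_len), as.integer(max_mismatch),
                          seed, FALSE)
    if (nrow(w)) {
      q1 <- w$ia
      q2 <- n - w$ib - w$len
      len <- w$len; mm <- w$mm
      # each physical pair is enumerated twice (mirror diagonals); keep the
      # representative with copy1 left of copy2
      sel <- q2 >= q1
      q1 <- q1[sel]; q2 <- q2[sel]; len <- len[sel]; mm <- mm[sel]
      # a window whose copies overlap around the centre (a contiguous
      # palindrome) is trimmed symmetrically to the maximal
      # non-overlapping pair
      ov <- pmax(0L, q1 + len - q2)
      v <- as.integer(ceiling(ov / 2))
      q2 <- q2 + v
      len <- len - v
      trim <- which(v > 0L & len >= min_len)
      for (i in trim) {
        c1 <- vseq[(q1[i] + 1L):(q1[i] + len[i])]
        c2 <- vseq[(q2[i] + 1L):(q2[i] + len[i])]
        c2 <- if (ty == "palindromic") revcomp_chars(c2) else rev(c2)
        mm[i] <- sum(c1 != c2 | c1 == "N")
      }
      ok <- len >= min_len
      if (any(ok))
        res[[ty]] <- data.frame(type = ty, length = len[ok],
                                pos1 = q1[ok], pos2 = q2[ok],
                                mismatches = mm[ok],
                                key = q1[ok] + q2[ok] + len[ok])
    }
  }
  if (!length(res)) {
    out <- repeat_hits_frame()
  } else {
    out <- do.call(rbind, res)
    parts <- lapply(split(out, out$type), filter_hits,
                    min_len = min_len, max_mismatch = max_mismatch, max_len = max_len)
    out <- do.call(rbind, parts)
    out$key <- NULL
    out <- out[order(out$pos1, out$pos2, out$type), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("repeat_hits", "data.frame"),
            min_len = min_len, max_mismatch = max_mismatch, max_len = max_len)
}

#' Remove the duplicate inverted-repeat copy from a genome
#'
#' Returns the canonical-orientation sequence with IRa removed (LSC + IRb +
#' SSC retained), so repeat scans see a single IR copy.  Positions on the
#' stripped sequence map one-to-one onto the canonical genome.
#'
#' @param record a `plastome`.
#' @param partition optional `quadripartite`; detected if missing.
#' @param min_ir passed to [detect_quadripartite()] when detecting.
#' @return list: `sequence` (stripped string), `record` (canonicalised
#'   record), `partition` (canonical partition), `kept_length`.
#' @export
strip_duplicate_ir <- function(record, partition = NULL, min_ir = 10000) {
  canon <- canonical_orientation(record, partition, min_ir)
  p <- attr(canon, "partition")
  kept <- p$lsc_length + p$ir_length + p$ssc_length
  list(sequence = substr(canon$sequence, 1, kept), record = canon,
       partition = p, kept_length = kept)
}

#' Find and locate dispersed repeats in an annotated genome
#'
#' Scans the IR-stripped canonical sequence with [find_repeats()] and
#' annotates each copy with its functional location class and region name.
#'
#' @param record an annotated `plastome`.
#' @param min_ir,min_len,max_mismatch,max_len detection parameters.
#' @return `repeat_hits` data.frame with added columns `location1`,
#'   `region1`, `location2`, `region2` (coordinates on the canonical
#'   IR-stripped sequence).
#' @export
find_repeats_genome <- function(record, min_ir = 10000, min_len = 30,
                                max_mismatch = 3, max_len = 5000) {
  st <- strip_duplicate_ir(record, min_ir = min_ir)
  hits <- find_repeats(st$sequence, min_len, max_mismatch, max_len)
  regions <- extract_functional_regions(st$record)
  if (nrow(hits)) {
    hits$location1 <- vapply(seq_len(nrow(hits)), function(i)
      classify_location(hits$pos1[i], hits$pos1[i] + hits$length[i], regions), "")
    hits$region1 <- vapply(seq_len(nrow(hits)), function(i)
      region_name_at(hits$pos1[i], hits$pos1[i] + hits$length[i], regions), "")
    hits$location2 <- vapply(seq_len(nrow(hits)), function(i)
      classify_location(hits$pos2[i], hits$pos2[i] + hits$length[i], regions), "")
    hits$region2 <- vapply(seq_len(nrow(hits)), function(i)
      region_name_at(hits$pos2[i], hits$pos2[i] + hits$length[i], regions), "")
  } else {
    hits$location1 <- hits$region1 <- hits$location2 <- hits$region2 <- character(0)
  }
  hits
}

#' Shared and unique repeats across genomes
#'
#' Repeats with identical length and type located in the same homologous
#' region pair are treated as one shared repeat key.
#'
#' @param hits_by_genome named list of annotated `repeat_hits` (from
#'   [find_repeats_genome()]), one per genome.
#' @return list of class `shared_repeats`: `membership` (keys x genomes
#'   logical matrix), `per_genome` (hit counts by type), `shared_by_all`,
#'   `unique_counts`.
#' @export
shared_repeat_sets <- function(hits_by_genome) {
  stopifnot(length(hits_by_genome) >= 2L, !is.null(names(hits_by_genome)))
  keys_of <- function(h) {
    if (nrow(h) == 0L) return(character(0))
    pair <- t(apply(cbind(h$region1, h$region2), 1L, sort))
    unique(paste(h$type, h$length, pair[, 1L], pair[, 2L], sep = "|"))
  }
  key_list <- lapply(hits_by_genome, keys_of)
  all_keys <- sort(unique(unlist(key_list)))
  membership <- vapply(key_list, function(k) all_keys %in% k,
                       logical(length(all_keys)))
  if (length(all_keys) == 1L) membership <- matrix(membership, nrow = 1L,
                                                   dimnames = list(all_keys, names(key_list)))
  rownames(membership) <- all_keys
  n_genomes <- rowSums(membership)
  per_genome <- lapply(hits_by_genome, function(h) table(factor(h$type,
    levels = c("direct", "reverse", "palindromic"))))
  structure(list(membership = membership,
                 per_genome = per_genome,
                 shared_by_all = sum(n_genomes == length(hits_by_genome)),
                 unique_counts = colSums(membership[n_genomes == 1L, , drop = FALSE])),
            class = "shared_repeats")
}
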