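# Microsatellite (SSR) detection: maximal perfect tandem runs of 1-6 bp
# motifs, reported at their primitive period and labelled with a
# strand-independent canonical motif such as "A/T" or "AAAAAG/CTTTTT".

#' Canonical strand-independent motif label
#'
#' Among all cyclic rotations of the motif and of its reverse complement,
#' the lexicographically smallest is the representative; the label is
#' "REP/REVCOMP(REP)".
#'
#' @param motif DNA string of length 1-6; must be primitive (not itself a
#'   repetition of a shorter unit).
#' @return character label.
#' @export
canonical_motif <- function(motif) {
  motif <- toupper(motif)
  u <- nchar(motif)
  stopifnot(u >= 1L, u <= 6L)
  if (!is_primitive(motif))
    stop("motif '", motif, "' is not primitive; reduce to its shortest period")
  rots <- function(x) {
    v <- s2c(x)
    vapply(seq_along(v), function(i) c2s(c(v[i:length(v)], v[seq_len(i - 1L)])), "")
  }
  cand <- c(rots(motif), rots(revcomp(motif)))
  rep_ <- sort(cand)[1L]
  paste0(rep_, "/", revcomp(rep_))
}

is_primitive <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L &&
        identical(motif, strrep(substr(motif, 1L, d), u / d))) return(FALSE)
  }
  TRUE
}

ssr_frame <- function() {
  data.frame(motif = character(0), unit = character(0), unit_length = integer(0),
              repeat_count = integer(0), start = integer(0), end = integer(0))
}

#' Find simple sequence repeats
#'
#' Detects maximal perfect tandem runs meeting per-unit-length thresholds.
#' A run reportable at several unit lengths appears only at its primitive
#' (smallest) period; reported loci never overlap.  On circular sequences
#' the scan wraps the origin (runs crossing the origin report `end` past
#' the sequence length, to be read modulo the length).
#'
#' @param seq DNA string.
#' @param thresholds named numeric: minimum repeat units per unit length
#'   1-6 (defaults 10, 6, 5, 4, 3, 3).
#' @param circular logical; wrap the origin (default TRUE).
#' @return data.frame of class `ssr_loci`: `motif` (canonical), `unit`
#'   (observed unit at the locus start), `unit_length`, `repeat_count`,
#'   `start`, `end` (0-based half-open).
#' @export
find_ssrs <- function(seq, thresholds = c(`1` = 10, `2` = 6, `3` = 5,
                                          `4` = 4, `5` = 3, `6` = 3),
                      circular = TRUE) {
  stopifnot(all(as.character(1:6) %in% names(thresholds)))
  seq <- toupper(seq)
  n <- nchar(seq)
  pad <- if (circular && n > 1L) min(n - 1L, 600L) else 0L
  v <- s2c(if (pad > 0L) paste0(seq, substr(seq, 1L, pad)) else seq)
  N <- length(v)
  loci <- list()
  for (u in 1:6) {
    thr <- thresholds[[as.character(u)]]
    if (N <= u) next
    eq <- v[seq_len(N - u)] == v[(u + 1L):N] & v[seq_len(N - u)] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths + u >= u * thr)) {
      p <- starts[k]                      # 1-based start in padded vector
      span <- r$lengths[k] + u
      count <- span %/% u
      if (count < thr) next
      start0 <- p - 1L
      if (start0 >= n) next               # duplicate of an unwrapped locus
      unit <- c2s(v[p:(p + u - 1L)])
      if (grepl("N", unit, fixed = TRUE) || !is_primitive(unit)) next
      loci[[length(loci) + 1L]] <-
        data.frame(motif = canonical_motif(unit), unit = unit,
                   unit_length = u, repeat_count = count,
                   start = start0, end = start0 + count * u,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(loci)) {
    out <- ssr_frame()
  } else {
    out <- do.call(rbind, loci)
    # drop loci overlapping an accepted locus (smaller period wins, then longer)
    out <- out[order(out$unit_length, -(out$end - out$start), out$start), , drop = FALSE]
    keep <- rep(TRUE, nrow(out))
    ivs <- lapply(seq_len(nrow(out)), function(i)
      split_circular(out$start[i], out$end[i], n))
    for (i in seq_len(nrow(out))[-1L]) {
      for (j in which(keep[seq_len(i - 1L)])) {
        if (interval_overlap_bp(ivs[[i]], ivs[[j]]) > 0) { keep[i] <- FALSE; break }
      }
    }
    out <- out[keep, , drop = FALSE]
    out <- out[order(out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("ssr_loci", "data.frame"), genome_length = n)
}

#' Locate SSRs on an annotated genome and tabulate by motif
#'
#' Runs [find_ssrs()] on the full circular genome (both IR copies included),
#' attaches the functional location class, region name and partition of
#' each locus, and tabulates counts per canonical motif.
#'
#' @param record an annotated `plastome`.
#' @param partition optional `quadripartite`; detected if missing.
#' @param thresholds passed to [find_ssrs()].
#' @param min_ir passed to [detect_quadripartite()] when detecting.
#' @return list of class `ssr_report`: `loci` (annotated `ssr_loci`) and
#'   `summary` (counts per motif by location class and partition).
#' @export
ssr_genome_report <- function(record, partition = NULL,
                              thresholds = c(`1` = 10, `2` = 6, `3` = 5,
                                             `4` = 4, `5` = 3, `6` = 3),
                              min_ir = 10000) {
  if (is.null(partition)) partition <- detect_quadripartite(record, min_ir)
  regions <- extract_functional_regions(record)
  loci <- find_ssrs(record$sequence, thresholds, circular = record$circular)
  n <- genome_length(record)
  if (nrow(loci)) {
    loci$location <- vapply(seq_len(nrow(loci)), function(i)
      classify_location(loci$start[i], loci$end[i], regions), "")
    loci$region <- vapply(seq_len(nrow(loci)), function(i)
      region_name_at(loci$start[i], loci$end[i], regions), "")
    mid <- cmod(floor((loci$start + loci$end) / 2), n)
    loci$partition <- vapply(mid, function(p) partition_at(p, partition), "")
  } else {
    loci$location <- loci$region <- loci$partition <- character(0)
  }
  list(loci = loci, summary = ssr_summary(loci))
}

# which partition (LSC/SSC/IR) contains 0-based position p
partition_at <- function(p, partition) {
  n <- partition$genome_length
  inside <- function(iv) {
    m <- split_circular(iv[1], iv[1] + iv[2], n)
    any(p >= m[, 1] & p < m[, 2])
  }
  if (inside(partition$lsc)) "LSC"
  else if (inside(partition$ssc)) "SSC"
  else "IR"
}

#' Tabulate annotated SSR loci per canonical motif
#'
#' @param loci annotated `ssr_loci` (with `location` and `partition`
#'   columns, as produced by [ssr_genome_report()]).
#' @return data.frame: motif, Number, Intron, IGS, CDS-IGS, CDS, other,
#'   LSC, SSC, IR.
#' @export
ssr_summary <- function(loci) {
  loc_levels <- c("intron", "IGS", "CDS-IGS", "CDS", "other")
  cols <- c("Number", "Intron", "IGS", "CDS-IGS", "CDS", "Other",
            "LSC", "SSC", "IR")
  if (nrow(loci) == 0L) {
    out <- as.data.frame(matrix(numeric(0), ncol = length(cols) + 1L,
                                dimnames = list(NULL, c("motif", cols))))
    return(out)
  }
  loc <- ifelse(loci$location %in% c("CDS-IGS", "IGS-CDS"), "CDS-IGS",
         ifelse(loci$location == "intron", "intron",
         ifelse(loci$location == "IGS", "IGS",
         ifelse(loci$location == "CDS", "CDS", "other"))))
  rows <- lapply(split(seq_len(nrow(loci)), loci$motif), function(ix) {
    data.frame(motif = loci$motif[ix[1L]],
               Number = length(ix),
               Intron = sum(loc[ix] == "intron"),
               IGS = sum(loc[ix] == "IGS"),
               `CDS-IGS` = sum(loc[ix] == "CDS-IGS"),
               CDS = sum(loc[ix] == "CDS"),
               Other = sum(loc[ix] == "other"),
               LSC = sum(loci$partition[ix] == "LSC"),
               SSC = sum(loci$partition[ix] == "SSC"),
               IR = sum(loci$partition[ix] == "IR"),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$Number), , drop = FALSE]
  rownames(out) <- NULL
  out
}
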