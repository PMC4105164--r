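# Quadripartite structure: detection of the inverted-repeat pair and the
# LSC/IRb/SSC/IRa partition of a circular plastome.
#
# Detection finds the maximal pair of disjoint, exactly reverse-complementary
# segments >= min_ir via exact k-mer seeding (k = 25) on the doubled
# sequence, so inverted repeats wrapping the origin are handled.  The two
# single-copy gaps between the IR copies are named LSC (longer) and SSC
# (shorter); IRb is the copy reached first walking forward from the LSC end.

# maximal exact inverted matches of the sequence against itself, as pairs of
# circular segments (start1, start2, len), 0-based
exact_inverted_segments <- function(seq, min_len, circular = TRUE) {
  n <- nchar(seq)
  s2 <- if (circular) paste0(seq, seq) else seq
  m <- nchar(s2)
  rc <- revcomp(s2)
  w <- cpp_diag_windows(s2, rc, as.integer(min_len), 0L, 25L, FALSE)
  if (nrow(w) == 0L) return(w[0, ])
  # segment B (forward coords in s2): rc interval [ib, ib+len) maps back to
  # s2 interval [m - ib - len, m - ib)
  a <- w$ia
  b <- m - w$ib - w$len
  len <- pmin(w$len, n)
  a <- cmod(a, n); b <- cmod(b, n)
  p1 <- pmin(a, b); p2 <- pmax(a, b)
  key <- paste(p1, p2, len)
  keep <- !duplicated(key)
  data.frame(start1 = p1[keep], start2 = p2[keep], len = len[keep])
}

circ_disjoint <- function(s1, s2, len, n) {
  a <- split_circular(s1, s1 + len, n)
  b <- split_circular(s2, s2 + len, n)
  interval_overlap_bp(a, b) == 0
}

#' Detect the LSC/IRb/SSC/IRa partition of a plastome
#'
#' Finds the maximal-length pair of disjoint, exactly reverse-complementary
#' segments of at least `min_ir` bp.  The longer single-copy gap is the LSC,
#' the shorter the SSC; IRb is the IR copy entered first when walking forward
#' from the LSC end.  The four junctions are reported as single coordinates:
#' JLB (LSC|IRb), JSB (IRb|SSC), JSA (SSC|IRa), JLA (IRa|LSC), each the
#' 0-based position of the first base after the boundary.
#'
#' @param record a `plastome` object (circular).
#' @param min_ir minimum inverted-repeat length in bp (default 10000;
#'   excludes dispersed repeats while catching all plastome IRs).
#' @return an object of class `quadripartite` with elements `lsc`, `irb`,
#'   `ssc`, `ira` (each `c(start, length)` in genome coordinates, possibly
#'   wrapping), `junctions` (JLB, JSB, JSA, JLA), `lsc_length`, `ssc_length`,
#'   `ir_length`, `genome_length`, `id`.
#' @export
detect_quadripartite <- function(record, min_ir = 10000) {
  n <- genome_length(record)
  if (n <= 2 * min_ir)
    stop("no quadripartite structure: genome (", n,
         " bp) shorter than twice min_ir")
  segs <- exact_inverted_segments(record$sequence, min_ir, record$circular)
  if (nrow(segs)) {
    ok <- vapply(seq_len(nrow(segs)), function(i)
      circ_disjoint(segs$start1[i], segs$start2[i], segs$len[i], n), TRUE)
    segs <- segs[ok, , drop = FALSE]
  }
  if (nrow(segs) == 0L)
    stop("no quadripartite structure: no disjoint inverted repeat >= ",
         min_ir, " bp found in ", record$id)
  best <- segs[segs$len == max(segs$len), , drop = FALSE]
  if (nrow(best) > 1L)
    stop("ambiguous quadripartite structure: ", nrow(best),
         " inverted-repeat candidates of length ", best$len[1L], " (starts ",
         paste(best$start1, best$start2, sep = "/", collapse = ", "), ")")
  r <- best$len[1L]
  c1 <- best$start1[1L]; c2 <- best$start2[1L]
  # single-copy gaps (circular): from end of one copy to start of the other
  g1_start <- cmod(c1 + r, n); g1_len <- cmod(c2 - g1_start, n)
  g2_start <- cmod(c2 + r, n); g2_len <- cmod(c1 - g2_start, n)
  if (g1_len == g2_len)
    stop("ambiguous quadripartite structure: equal-length single-copy regions")
  if (g1_len > g2_len) {
    lsc <- c(g1_start, g1_len); ssc <- c(g2_start, g2_len)
    irb <- c(c2, r); ira <- c(c1, r)
  } else {
    lsc <- c(g2_start, g2_len); ssc <- c(g1_start, g1_len)
    irb <- c(c1, r); ira <- c(c2, r)
  }
  stopifnot(lsc[2] + ssc[2] + 2 * r == n)
  # exactness of the IR pair at the reported boundaries
  irb_seq <- extract_circular(record$sequence, irb[1], irb[2])
  ira_seq <- extract_circular(record$sequence, ira[1], ira[2])
  stopifnot(identical(revcomp(ira_seq), irb_seq))
  junctions <- c(JLB = irb[1], JSB = cmod(irb[1] + r, n),
                 JSA = ira[1], JLA = cmod(ira[1] + r, n))
  structure(list(lsc = lsc, irb = irb, ssc = ssc, ira = ira,
                 junctions = junctions,
                 lsc_length = lsc[2], ssc_length = ssc[2], ir_length = r,
                 genome_length = n, id = record$id),
            class = "quadripartite")
}

#' @export
print.quadripartite <- function(x, ...) {
  cat("<quadripartite> ", x$id, ": LSC ", x$lsc_length, " | IR ", x$ir_length,
      " | SSC ", x$ssc_length, " (genome ", x$genome_length, " bp)\n",
      "junctions: ", paste(names(x$junctions), x$junctions, sep = "=",
                           collapse = "  "), "\n", sep = "")
  invisible(x)
}

# substring on a circular sequence, 0-based start, may wrap
extract_circular <- function(seq, start, len) {
  n <- nchar(seq)
  start <- cmod(start, n)
  if (start + len <= n) substr(seq, start + 1, start + len)
  else paste0(substr(seq, start + 1, n), substr(seq, 1, start + len - n))
}

# rotate record so that 0-based position `rot` becomes position 0
rotate_record <- function(record, rot) {
  n <- genome_length(record)
  rot <- cmod(rot, n)
  if (rot == 0) return(record)
  seq2 <- paste0(substr(record$sequence, rot + 1, n), substr(record$sequence, 1, rot))
  f <- record$features
  if (nrow(f)) {
    pieces <- lapply(seq_len(nrow(f)), function(i) {
      s <- cmod(f$start[i] - rot, n)
      len <- f$end[i] - f$start[i]
      iv <- split_circular(s, s + len, n)
      cbind(i, iv)
    })
    pieces <- do.call(rbind, pieces)
    f2 <- f[pieces[, 1L], , drop = FALSE]
    f2$start <- pieces[, 2L]; f2$end <- pieces[, 3L]
    f <- merge_feature_parts(f2, n)
  }
  out <- record
  out$sequence <- seq2
  out$features <- f
  out
}

# reverse-complement a whole record, remapping features
revcomp_record <- function(record) {
  n <- genome_length(record)
  f <- record$features
  if (nrow(f)) {
    s <- n - f$end; e <- n - f$start
    f$start <- s; f$end <- e
    f$strand <- ifelse(f$strand == "+", "-", "+")
    f <- merge_feature_parts(f, n)
  }
  out <- record
  out$sequence <- revcomp(record$sequence)
  out$features <- f
  out
}

# after coordinate surgery, re-normalise each feature's interval list:
# merge abutting pieces, renumber parts in transcription order
merge_feature_parts <- function(f, n) {
  pieces <- split(f, f$feature_id)
  out <- lapply(pieces, function(rows) {
    rows <- rows[order(rows$start), , drop = FALSE]
    keep <- list()
    cur <- rows[1L, , drop = FALSE]
    for (i in seq_len(nrow(rows))[-1L]) {
      if (rows$start[i] == cur$end) {
        cur$end <- rows$end[i]
      } else {
        keep[[length(keep) + 1L]] <- cur
        cur <- rows[i, , drop = FALSE]
      }
    }
    keep[[length(keep) + 1L]] <- cur
    rows <- do.call(rbind, keep)
    # wrap-merge: piece ending at n joins piece starting at 0 conceptually;
    # keep both rows, but order parts in transcription order
    if (rows$strand[1L] == "+") rows$part <- seq_len(nrow(rows))
    else rows$part <- rev(seq_len(nrow(rows)))
    rows
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rotate and orient a plastome into canonical form
#'
#' Canonical form places the first LSC base at position 0 with the regions
#' in forward order LSC, IRb, SSC, IRa.  The strand is chosen so that the
#' SSC sequence is lexicographically no greater than its reverse complement,
#' which makes the canonical form invariant to rotation and to
#' reverse-complementation of the input.
#'
#' @param record a `plastome` object.
#' @param partition optional `quadripartite`; detected if missing.
#' @param min_ir passed to [detect_quadripartite()] when detecting.
#' @return the canonicalised `plastome`, with the canonical `quadripartite`
#'   attached as attribute `"partition"`.
#' @export
canonical_orientation <- function(record, partition = NULL, min_ir = 10000) {
  if (is.null(partition)) partition <- detect_quadripartite(record, min_ir)
  n <- partition$genome_length
  ssc_seq <- extract_circular(record$sequence, partition$ssc[1], partition$ssc[2])
  if (revcomp(ssc_seq) < ssc_seq) {
    record <- revcomp_record(record)
    partition <- detect_quadripartite(record, min_ir)
  }
  out <- rotate_record(record, partition$lsc[1])
  l <- partition$lsc_length; r <- partition$ir_length; s <- partition$ssc_length
  canon <- structure(list(lsc = c(0, l), irb = c(l, r), ssc = c(l + r, s),
                          ira = c(l + r + s, r),
                          junctions = c(JLB = l, JSB = l + r, JSA = l + r + s,
                                        JLA = 0),
                          lsc_length = l, ssc_length = s, ir_length = r,
                          genome_length = n, id = record$id),
                     class = "quadripartite")
  attr(out, "partition") <- canon
  out
}

#' Gene-to-junction distance report
#'
#' For each annotated instance of the requested genes, reports the signed
#' distance from the gene end nearest each junction (positive when the end
#' lies downstream of the junction in the forward direction, negative when
#' upstream; a gene whose body spans the junction is flagged) and the
#' overlap of the gene with each IR copy in bp.
#'
#' @param record an annotated `plastome`.
#' @param partition a `quadripartite` for the same record.
#' @param genes gene symbols to report (default the classic boundary genes
#'   ndhF, ycf1, rps19).
#' @return data.frame of class `junction_report`.
#' @export
junction_report <- function(record, partition,
                            genes = c("ndhF", "ycf1", "rps19")) {
  f <- record$features
  n <- partition$genome_length
  rows <- list()
  for (g in genes) {
    inst <- f[f$kind == "gene" & f$name == g, , drop = FALSE]
    if (nrow(inst) == 0L) {
      warning("junction_report: gene '", g, "' not annotated in ", record$id)
      next
    }
    for (fid in unique(inst$feature_id)) {
      rr <- inst[inst$feature_id == fid, , drop = FALSE]
      gs <- min(rr$start); ge <- max(rr$end)
      iv <- cbind(rr$start, rr$end)
      dists <- vapply(partition$junctions, function(J) {
        d1 <- cmod(gs - J, n); d1 <- if (d1 > n / 2) d1 - n else d1
        d2 <- cmod(ge - J, n); d2 <- if (d2 > n / 2) d2 - n else d2
        if (abs(d1) <= abs(d2)) d1 else d2
      }, 0)
      spans <- vapply(partition$junctions, function(J) {
        gs < J && ge > J
      }, TRUE)
      ov_ira <- interval_overlap_bp(iv, split_circular(partition$ira[1],
                                                       partition$ira[1] + partition$ira[2], n))
      ov_irb <- interval_overlap_bp(iv, split_circular(partition$irb[1],
                                                       partition$irb[1] + partition$irb[2], n))
      rows[[length(rows) + 1L]] <-
        data.frame(gene = g, copy = fid,
                   JLB = dists["JLB"], JSB = dists["JSB"],
                   JSA = dists["JSA"], JLA = dists["JLA"],
                   spans = paste(names(spans)[spans], collapse = ","),
                   overlap_ira = ov_ira, overlap_irb = ov_irb,
                   stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(gene = character(0), copy = character(0),
                         JLB = numeric(0), JSB = numeric(0), JSA = numeric(0),
                         JLA = numeric(0), spans = character(0),
                         overlap_ira = numeric(0), overlap_irb = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("junction_report", "data.frame")
  out
}

#' Partition table in the style of a genome-features summary
#' @param records list of annotated `plastome` objects.
#' @param min_ir passed to [detect_quadripartite()].
#' @return data.frame: id, genome_bp, lsc_bp, ssc_bp, ir_bp, gc_percent.
#' @export
structure_table <- function(records, min_ir = 10000) {
  rows <- lapply(records, function(rec) {
    p <- detect_quadripartite(rec, min_ir)
    data.frame(id = rec$id, genome_bp = p$genome_length,
               lsc_bp = p$lsc_length, ssc_bp = p$ssc_length,
               ir_bp = p$ir_length,
               gc_percent = round(100 * gc_content(rec), 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
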