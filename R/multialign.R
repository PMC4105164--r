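# Star (centre-sequence) multiple alignment: every sequence is aligned
# pairwise to a reference and the pairwise alignments are merged on
# reference coordinates, insertions left-justified per column slot.
# Adequate for the closely related, sparsely gapped sequences this package
# compares; not a general progressive aligner.

#' Star multiple alignment against a reference sequence
#'
#' @param seqs named character vector of DNA strings (two or more).
#' @param reference index or name of the centre sequence (default 1).
#' @return a `dna_alignment` with one row per input sequence.
#' @export
star_align <- function(seqs, reference = 1L) {
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  if (is.character(reference)) reference <- match(reference, names(seqs))
  ref <- seqs[[reference]]
  nref <- nchar(ref)
  others <- setdiff(seq_along(seqs), reference)
  # per sequence: insertion block before each ref position p (1..nref+1)
  # and the character aligned to each ref position
  ins <- matrix(0L, nrow = length(seqs), ncol = nref + 1L)
  body <- vector("list", length(seqs))
  inserts <- vector("list", length(seqs))
  body[[reference]] <- s2c(ref)
  inserts[[reference]] <- rep(list(character(0)), nref + 1L)
  for (k in others) {
    aln <- align_pair(ref, seqs[[k]], labels = c("ref", "x"))
    m <- aln_matrix(aln)
    refgap <- m[1L, ] == "-"
    blocks <- rep(list(character(0)), nref + 1L)
    chars <- character(nref)
    chars[cumsum(!refgap)[!refgap]] <- m[2L, !refgap]
    if (any(refgap)) {
      slot_of <- cumsum(!refgap)[refgap] + 1L  # insert before this ref pos
      blocks[unique(slot_of)] <- split(m[2L, refgap], slot_of)
    }
    inserts[[k]] <- blocks
    body[[k]] <- chars
    ins[k, ] <- lengths(blocks)
  }
  slot <- apply(ins, 2L, max)
  out_rows <- vapply(seq_along(seqs), function(k) {
    bs <- vapply(seq_len(nref + 1L), function(p) {
      blk <- inserts[[k]][[p]]
      paste0(paste(blk, collapse = ""), strrep("-", slot[p] - length(blk)))
    }, "")
    paste0(paste0(bs[seq_len(nref)], body[[k]], collapse = ""), bs[nref + 1L])
  }, "")
  new_alignment(setNames(out_rows, names(seqs)), labels = names(seqs))
}

#' Star alignments of all shared regions across annotated genomes
#'
#' For every region name present in all genomes (matched by name and
#' category), builds a star multiple alignment with the first genome as
#' reference.
#'
#' @param records named list of annotated canonical `plastome` objects.
#' @param max_region_len regions longer than this are skipped (default
#'   20000, the pairwise aligner cap).
#' @return named list of `dna_alignment`s, each carrying its region
#'   `category` as an attribute.
#' @export
multi_region_alignments <- function(records, max_region_len = 20000) {
  regions <- lapply(records, extract_functional_regions)
  keys <- lapply(regions, function(r) paste(r$name, r$category))
  shared <- Reduce(intersect, lapply(keys, unique))
  ids <- vapply(records, function(r) r$id, "")
  out <- list()
  for (k in shared) {
    seqs <- vapply(seq_along(records), function(i) {
      rows <- which(keys[[i]] == k)
      paste(vapply(rows, function(j)
        substr(records[[i]]$sequence, regions[[i]]$start[j] + 1L,
               regions[[i]]$end[j]), ""), collapse = "")
    }, "")
    names(seqs) <- ids
    if (any(nchar(seqs) == 0L) || any(nchar(seqs) > max_region_len)) next
    i1 <- which(keys[[1L]] == k)[1L]
    a <- star_align(seqs, reference = 1L)
    attr(a, "category") <- regions[[1L]]$category[i1]
    attr(a, "region") <- regions[[1L]]$name[i1]
    out[[regions[[1L]]$name[i1]]] <- a
  }
  out
}
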