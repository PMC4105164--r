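# Plastome records: sequence + typed feature annotations.
#
# A plastome record holds one circular (or linear) genome sequence and a
# feature table with one row per interval.  Multi-interval features (spliced
# genes, features wrapping the origin) share a feature_id and are ordered by
# `part`.  Coordinates are 0-based half-open on the stored forward strand.

FEATURE_COLS <- c("name", "kind", "start", "end", "strand", "copy_tag",
                  "feature_id", "part")

empty_features <- function() {
  data.frame(name = character(0), kind = character(0),
             start = numeric(0), end = numeric(0), strand = character(0),
             copy_tag = character(0), feature_id = character(0),
             part = integer(0), stringsAsFactors = FALSE)
}

#' Construct a plastome record
#'
#' @param id character label for the genome.
#' @param sequence DNA string over A, C, G, T, N.
#' @param circular logical; is the molecule circular?
#' @param features data.frame with columns `name`, `kind` (gene, CDS, tRNA,
#'   rRNA, exon, intron, other), `start`, `end` (0-based half-open),
#'   `strand` ("+"/"-"), `copy_tag` (distinguishes inverted-repeat
#'   duplicates; NA otherwise), `feature_id`, `part`.
#' @param source provenance label (file path or "synthetic").
#' @return an object of class `plastome`.
#' @export
plastome_record <- function(id, sequence, circular = TRUE,
                            features = empty_features(),
                            source = "synthetic") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) stop("plastome sequence must be non-empty")
  bad <- gsub("[ACGTN]", "", sequence)
  if (nchar(bad) > 0L)
    stop("sequence contains symbols outside {A,C,G,T,N}: ",
         paste(unique(s2c(bad)), collapse = ""))
  if (nrow(features) > 0L) {
    miss <- setdiff(FEATURE_COLS, names(features))
    if (length(miss)) stop("features lack columns: ", paste(miss, collapse = ", "))
    features <- features[, FEATURE_COLS]
    if (any(features$start < 0 | features$end > n | features$start >= features$end)) {
      bad_f <- features$name[features$start < 0 | features$end > n |
                               features$start >= features$end][1L]
      stop("feature '", bad_f, "' has coordinates outside [0, ", n, ")")
    }
    if (!all(features$strand %in% c("+", "-")))
      stop("feature strands must be '+' or '-'")
  }
  structure(list(id = id, sequence = sequence, circular = isTRUE(circular),
                 features = features, source = source),
            class = "plastome")
}

#' @export
print.plastome <- function(x, ...) {
  cat("<plastome> ", x$id, ": ", nchar(x$sequence), " bp, ",
      if (x$circular) "circular" else "linear", ", ",
      length(unique(x$features$feature_id)), " features (",
      sum(x$features$kind == "gene"), " gene rows)\n", sep = "")
  invisible(x)
}

#' Genome length of a plastome record
#' @param record a `plastome` object.
#' @return integer length in bp.
#' @export
genome_length <- function(record) nchar(record$sequence)

#' GC content of a plastome record
#'
#' Ambiguity characters (N) are excluded from the denominator.
#'
#' @param record a `plastome` object.
#' @return GC fraction in `[0, 1]`.
#' @export
gc_content <- function(record) {
  v <- s2c(record$sequence)
  acgt <- sum(v != "N")
  if (acgt == 0L) return(NA_real_)
  sum(v %in% c("G", "C")) / acgt
}

## ---------------------------------------------------------------- GenBank IO

# parse a GenBank location string into (start, end, strand) rows
parse_gb_location <- function(loc, name, n) {
  strand <- "+"
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc)) loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  out <- lapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    if (grepl("\\.\\.", p)) {
      ab <- as.numeric(strsplit(p, "..", fixed = TRUE)[[1L]])
    } else {
      ab <- c(as.numeric(p), as.numeric(p))
    }
    c(ab[1L] - 1, ab[2L])  # 1-based closed -> 0-based half-open
  })
  m <- do.call(rbind, out)
  if (any(m[, 2] > n))
    stop("feature '", name, "' extends beyond sequence length ", n)
  data.frame(start = m[, 1], end = m[, 2], strand = strand,
             part = seq_len(nrow(m)), stringsAsFactors = FALSE)
}

#' Read a GenBank flat file into a plastome record
#'
#' Parses the LOCUS line (circular flag), the feature table (gene, CDS,
#' tRNA, rRNA, exon, intron; `join()`/`complement()` locations resolved to
#' interval lists) and the ORIGIN sequence.
#'
#' @param path path to a GenBank flat file.
#' @return a `plastome` object.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  circular <- length(locus) > 0L && grepl("circular", locus[1L], ignore.case = TRUE)
  id <- if (length(locus)) strsplit(trimws(sub("^LOCUS", "", locus[1L])), "\\s+")[[1L]][1L]
        else tools::file_path_sans_ext(basename(path))

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("GenBank format error: no ORIGIN sequence in ", path)
  seq_lines <- lines[(ori[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) stop("GenBank format error: empty sequence in ", path)
  n <- nchar(sequence)

  fstart <- grep("^FEATURES", lines)
  feats <- empty_features()
  if (length(fstart)) {
    body <- lines[(fstart[1L] + 1L):(ori[1L] - 1L)]
    # a feature header line has a key in columns 6-20
    is_key <- grepl("^ {5}\\S", body)
    idx <- which(is_key)
    recs <- list()
    counter <- new.env(parent = emptyenv())
    for (k in seq_along(idx)) {
      from <- idx[k]
      to <- if (k < length(idx)) idx[k + 1L] - 1L else length(body)
      block <- body[from:to]
      key <- trimws(substr(block[1L], 1, 21))
      # location may continue on lines before the first qualifier
      qual_at <- grep("^\\s+/", block)
      loc_end <- if (length(qual_at)) qual_at[1L] - 1L else length(block)
      loc <- paste0(trimws(substr(block[1L], 22, nchar(block[1L]))),
                    paste(trimws(block[seq_len(loc_end)][-1L]), collapse = ""))
      if (key %in% c("source")) next
      kind <- if (key %in% c("gene", "CDS", "tRNA", "rRNA", "exon", "intron")) key else "other"
      quals <- block[qual_at]
      getq <- function(q) {
        hit <- grep(paste0("^\\s*/", q, "="), quals, value = TRUE)
        if (!length(hit)) return(NA_character_)
        gsub("\"", "", sub(paste0("^\\s*/", q, "="), "", trimws(hit[1L])))
      }
      nm <- getq("gene")
      if (is.na(nm)) nm <- getq("label")
      if (is.na(nm)) nm <- getq("product")
      if (is.na(nm)) nm <- key
      note <- getq("note")
      copy_tag <- if (!is.na(note) && grepl("^copy=", note)) sub("^copy=", "", note)
                  else NA_character_
      iv <- parse_gb_location(loc, nm, n)
      cnt_key <- paste(nm, kind)
      cnt <- (get0(cnt_key, envir = counter) %||% 0L) + 1L
      assign(cnt_key, cnt, envir = counter)
      fid <- paste0(nm, ".", kind, ".", cnt)
      recs[[length(recs) + 1L]] <-
        data.frame(name = nm, kind = kind, start = iv$start, end = iv$end,
                   strand = iv$strand, copy_tag = copy_tag, feature_id = fid,
                   part = iv$part, stringsAsFactors = FALSE)
    }
    if (length(recs)) feats <- do.call(rbind, recs)
  }
  plastome_record(id, sequence, circular, feats, source = path)
}

#' Write a plastome record as a GenBank flat file
#'
#' Inverse of [read_genbank()]: a write-then-read round trip preserves the
#' sequence and all feature intervals exactly.
#'
#' @param record a `plastome` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_genbank <- function(record, path) {
  n <- nchar(record$sequence)
  topo <- if (record$circular) "circular" else "linear"
  out <- c(sprintf("LOCUS       %s %d bp    DNA     %s PLN",
                   record$id, n, topo),
           sprintf("DEFINITION  %s synthetic or derived plastome record.", record$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", n))
  f <- record$features
  if (nrow(f)) {
    for (fid in unique(f$feature_id)) {
      rows <- f[f$feature_id == fid, , drop = FALSE]
      rows <- rows[order(rows$part), , drop = FALSE]
      locs <- sprintf("%d..%d", rows$start + 1, rows$end)
      loc <- if (length(locs) > 1L) paste0("join(", paste(locs, collapse = ","), ")")
             else locs
      if (rows$strand[1L] == "-") loc <- paste0("complement(", loc, ")")
      out <- c(out, sprintf("     %-15s %s", rows$kind[1L], loc),
               sprintf("                     /gene=\"%s\"", rows$name[1L]))
      if (!is.na(rows$copy_tag[1L]))
        out <- c(out, sprintf("                     /note=\"copy=%s\"", rows$copy_tag[1L]))
    }
  }
  out <- c(out, "ORIGIN")
  v <- s2c(tolower(record$sequence))
  for (i in seq(1L, n, by = 60L)) {
    chunk <- v[i:min(i + 59L, n)]
    groups <- split(chunk, (seq_along(chunk) - 1L) %/% 10L)
    out <- c(out, sprintf("%9d %s", i, paste(vapply(groups, c2s, ""), collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

## ------------------------------------------------------------------ FASTA IO

#' Read FASTA into plastome records
#'
#' Sequences are uppercased; symbols outside A, C, G, T, N are mapped to N
#' (with a message giving the count).  Records carry no features.
#'
#' @param path path to a FASTA file.
#' @param circular logical flag stored on each record.
#' @return a single `plastome` if the file holds one sequence, otherwise a
#'   named list of `plastome` objects.
#' @export
read_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path) || file.size(path) == 0L)
    stop("FASTA format error: empty or missing file ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("FASTA format error: ", conditionMessage(e)))
  if (length(ss) == 0L) stop("FASTA format error: no records in ", path)
  recs <- lapply(seq_along(ss), function(i) {
    x <- toupper(as.character(ss[[i]]))
    n_bad <- nchar(gsub("[ACGTN]", "", x))
    if (n_bad > 0L) {
      message("read_fasta: ", n_bad, " non-ACGTN symbol(s) mapped to N in record ",
              names(ss)[i])
      x <- c2s(ifelse(s2c(x) %in% c("A", "C", "G", "T", "N"), s2c(x), "N"))
    }
    plastome_record(strsplit(names(ss)[i], "\\s+")[[1L]][1L], x,
                    circular = circular, source = path)
  })
  names(recs) <- vapply(recs, function(r) r$id, "")
  if (length(recs) == 1L) recs[[1L]] else recs
}

#' Write plastome record(s) as FASTA
#' @param records a `plastome` or list of them.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "plastome")) records <- list(records)
  ss <- Biostrings::DNAStringSet(vapply(records, function(r) r$sequence, ""))
  names(ss) <- vapply(records, function(r) r$id, "")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write the feature table of a record as TSV
#' @param record a `plastome` object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_feature_table <- function(record, path) {
  f <- record$features
  f <- cbind(record = rep(record$id, nrow(f)), f)
  write.table(f, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## -------------------------------------------------------- functional regions

# genomic span(s) of one feature instance as interval matrix (may hold the
# two pieces of an origin-wrapping feature)
feature_span <- function(rows) {
  cbind(min(rows$start), max(rows$end))
}

region_row <- function(name, category, start, end) {
  data.frame(name = name, category = category, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Derive functional regions (CDS, introns, IGS) from annotations
#'
#' Introns are the gaps between consecutive exons of one feature copy,
#' named "gene intron" (with an ordinal when a gene has two).  IGS regions
#' are the maximal inter-gene gaps, named "geneA/geneB" by the flanking
#' genes in genome order; the gap between the last and first gene wraps the
#' origin and is stored as two rows sharing one name.  Overlapping or
#' abutting genes yield no IGS.
#'
#' @param record an annotated `plastome` object.
#' @return a `region_set`: data.frame with columns `name`, `category`
#'   (CDS, intron, IGS, tRNA, rRNA), `start`, `end`, with the genome length
#'   and record id as attributes.
#' @export
extract_functional_regions <- function(record) {
  f <- record$features
  if (nrow(f) == 0L || !any(f$kind == "gene"))
    stop("record '", record$id, "' has no gene features; cannot derive regions")
  n <- genome_length(record)
  out <- list()

  # exonic structure from CDS / tRNA / rRNA features
  coding <- f[f$kind %in% c("CDS", "tRNA", "rRNA"), , drop = FALSE]
  for (fid in unique(coding$feature_id)) {
    rows <- coding[coding$feature_id == fid, , drop = FALSE]
    rows <- rows[order(rows$part), , drop = FALSE]
    cat_ <- rows$kind[1L]
    tag <- rows$copy_tag[1L]
    nm <- if (is.na(tag)) rows$name[1L] else paste0(rows$name[1L], "|", tag)
    out[[length(out) + 1L]] <- region_row(nm, cat_, rows$start, rows$end)
    if (nrow(rows) > 1L) {
      # genome-order gaps between parts; skip origin-wrapping junctions
      ord <- rows[order(rows$start), , drop = FALSE]
      gaps <- data.frame(start = ord$end[-nrow(ord)], end = ord$start[-1L])
      gaps <- gaps[gaps$end > gaps$start, , drop = FALSE]
      if (nrow(gaps)) {
        # number introns in transcription order
        if (rows$strand[1L] == "-") gaps <- gaps[order(-gaps$start), , drop = FALSE]
        inames <- if (nrow(gaps) == 1L) paste(nm, "intron")
                  else paste(nm, "intron", seq_len(nrow(gaps)))
        out[[length(out) + 1L]] <- region_row(inames, "intron", gaps$start, gaps$end)
      }
    }
  }

  # IGS from gene-level spans around the circle
  genes <- f[f$kind == "gene", , drop = FALSE]
  spans <- do.call(rbind, lapply(split(genes, genes$feature_id), function(rows) {
    data.frame(name = rows$name[1L],
               tag = rows$copy_tag[1L],
               start = min(rows$start), end = max(rows$end),
               stringsAsFactors = FALSE)
  }))
  spans$label <- ifelse(is.na(spans$tag), spans$name,
                        paste0(spans$name, "|", spans$tag))
  spans <- spans[order(spans$start, spans$end), , drop = FALSE]
  m <- nrow(spans)
  cover_end <- spans$end[1L]
  last_gene <- spans$label[1L]
  for (i in seq_len(m)[-1L]) {
    if (spans$start[i] > cover_end) {
      out[[length(out) + 1L]] <-
        region_row(paste0(last_gene, "/", spans$label[i]), "IGS",
                   cover_end, spans$start[i])
    }
    if (spans$end[i] >= cover_end) {
      cover_end <- spans$end[i]
      last_gene <- spans$label[i]
    }
  }
  # wrap-around gap between the last-covering gene and the first gene
  if (record$circular) {
    if (cover_end < n || spans$start[1L] > 0) {
      nm <- paste0(last_gene, "/", spans$label[1L])
      if (cover_end < n)
        out[[length(out) + 1L]] <- region_row(nm, "IGS", cover_end, n)
      if (spans$start[1L] > 0)
        out[[length(out) + 1L]] <- region_row(nm, "IGS", 0, spans$start[1L])
    }
  } else if (cover_end < n) {
    out[[length(out) + 1L]] <- region_row(paste0(last_gene, "/."), "IGS", cover_end, n)
  }

  regions <- do.call(rbind, out)
  rownames(regions) <- NULL
  structure(regions, class = c("region_set", "data.frame"),
            genome_length = n, record_id = record$id)
}

#' Gene census of an annotated record
#'
#' Each annotated gene feature instance counts once, so genes duplicated in
#' the inverted repeats count twice.  Genes are classified by symbol prefix
#' (`trn` = tRNA, `rrn` = rRNA, otherwise protein-coding).  Intron-containing
#' genes are counted by unique symbol from the exon structure of their
#' CDS/tRNA/rRNA features.
#'
#' @param record a `plastome` object.
#' @return a list of class `gene_census`: `total`, `protein_coding`, `trna`,
#'   `rrna`, `intron_containing`, `two_intron_genes`.
#' @export
gene_census <- function(record) {
  f <- record$features
  genes <- f[f$kind == "gene", , drop = FALSE]
  inst <- unique(genes[, c("name", "feature_id")])
  cls <- ifelse(grepl("^trn", inst$name), "trna",
                ifelse(grepl("^rrn", inst$name), "rrna", "protein"))
  coding <- f[f$kind %in% c("CDS", "tRNA", "rRNA"), , drop = FALSE]
  n <- genome_length(record)
  # introns are positive gaps between exon parts; abutting parts (e.g. a
  # gene split across a region boundary) and origin-wrapping junctions are
  # contiguous, not introns
  nintrons_of <- function(rows) {
    if (nrow(rows) == 1L) return(0L)
    rows <- rows[order(rows$start), , drop = FALSE]
    gaps <- rows$start[-1L] - rows$end[-nrow(rows)]
    k <- sum(gaps > 0L)
    if (record$circular && rows$start[1L] == 0L && rows$end[nrow(rows)] == n)
      k <- max(0L, k - 1L)  # the apparent gap closes through the origin
    k
  }
  nparts <- vapply(split(coding, coding$feature_id), nintrons_of, 0L)
  fid_name <- vapply(split(coding$name, coding$feature_id), `[`, "", 1L)
  n_intron <- tapply(nparts, fid_name, max)
  intron_names <- names(n_intron)[n_intron >= 1L]
  two_intron <- sort(names(n_intron)[n_intron >= 2L])
  structure(list(total = nrow(inst),
                 protein_coding = sum(cls == "protein"),
                 trna = sum(cls == "trna"),
                 rrna = sum(cls == "rrna"),
                 intron_containing = length(intron_names),
                 two_intron_genes = two_intron),
            class = "gene_census")
}

#' @export
print.gene_census <- function(x, ...) {
  cat("gene census: ", x$total, " genes (", x$protein_coding, " protein-coding, ",
      x$trna, " tRNA, ", x$rrna, " rRNA); ", x$intron_containing,
      " intron-containing", sep = "")
  if (length(x$two_intron_genes))
    cat(" (two introns: ", paste(x$two_intron_genes, collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Find overlapping gene pairs
#'
#' @param record a `plastome` object.
#' @return data.frame with columns `gene_a`, `gene_b`, `overlap_bp` for all
#'   unordered pairs of gene instances with genomic overlap > 0.
#' @export
find_gene_overlaps <- function(record) {
  f <- record$features
  genes <- f[f$kind == "gene", , drop = FALSE]
  ids <- unique(genes$feature_id)
  res <- list()
  if (length(ids) >= 2L) {
    spans <- lapply(ids, function(fid) {
      rows <- genes[genes$feature_id == fid, , drop = FALSE]
      cbind(rows$start, rows$end)
    })
    names(spans) <- ids
    nm <- vapply(ids, function(fid) genes$name[genes$feature_id == fid][1L], "")
    for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1L):length(ids)) {
      ov <- interval_overlap_bp(spans[[i]], spans[[j]])
      if (ov > 0)
        res[[length(res) + 1L]] <- data.frame(gene_a = nm[i], gene_b = nm[j],
                                              overlap_bp = ov,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      overlap_bp = numeric(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Classify the functional location of an interval
#'
#' Fully contained in one region category gives that class; spanning exactly
#' two gives the hyphenated pair (e.g. "CDS-IGS"); three or more, or partial
#' coverage, gives "mixed".
#'
#' @param start,end 0-based half-open interval; `end` may exceed the genome
#'   length for an origin-wrapping interval on a circular genome.
#' @param regions a `region_set` from [extract_functional_regions()].
#' @return a character class label.
#' @export
classify_location <- function(start, end, regions) {
  n <- attr(regions, "genome_length")
  if (end <= start) stop("empty interval")
  if (start < 0 || start >= n || end > 2 * n)
    stop("interval [", start, ",", end, ") out of genome bounds [0,", n, ")")
  iv <- split_circular(start, end, n)
  len <- end - start
  cat_order <- c("CDS", "intron", "IGS", "tRNA", "rRNA")
  ov <- vapply(cat_order, function(cc) {
    rr <- regions[regions$category == cc, , drop = FALSE]
    interval_overlap_bp(iv, cbind(rr$start, rr$end))
  }, 0)
  present <- names(ov)[ov > 0]
  if (length(present) == 1L) {
    if (ov[present] >= len) present else "mixed"
  } else if (length(present) == 2L) {
    paste(present, collapse = "-")
  } else {
    "mixed"
  }
}

# name of the single region with the largest overlap (for repeat/SSR tables)
region_name_at <- function(start, end, regions) {
  n <- attr(regions, "genome_length")
  iv <- split_circular(start, end, n)
  ovs <- vapply(seq_len(nrow(regions)), function(i) {
    interval_overlap_bp(iv, cbind(regions$start[i], regions$end[i]))
  }, 0)
  if (all(ovs == 0)) return(NA_character_)
  regions$name[which.max(ovs)]
}
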