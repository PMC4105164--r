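# Shared low-level helpers: strand arithmetic, circular intervals.
# All coordinates in this package are 0-based, half-open, on the forward
# strand of the genome as stored; GenBank 1-based closed coordinates are
# converted at the file boundary.

#' Reverse complement of a DNA string
#'
#' Accepts A, C, G, T, N (case-insensitive); returns uppercase.
#'
#' @param x character scalar DNA sequence.
#' @return character scalar, the reverse complement.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(x))))
}

# reverse without complement
str_reverse <- function(x) {
  paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
}

s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]
c2s <- function(x) paste(x, collapse = "")

revcomp_chars <- function(v) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[v]))
}

# circular modulo with 0-based coordinates
cmod <- function(x, n) ((x %% n) + n) %% n

# split a possibly wrapping 0-based half-open interval [s, e) with e <= 2n
# into non-wrapping pieces on [0, n)
split_circular <- function(start, end, n) {
  len <- end - start
  start <- cmod(start, n)
  if (len <= 0) return(matrix(numeric(0), ncol = 2L))
  if (start + len <= n) {
    cbind(start, start + len)
  } else {
    rbind(c(start, n), c(0, start + len - n))
  }
}

# overlap in bp of two sets of non-wrapping intervals (matrices with cols s,e)
interval_overlap_bp <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  tot <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    tot <- tot + max(0, min(a[i, 2], b[j, 2]) - max(a[i, 1], b[j, 1]))
  }
  tot
}

# sample of random DNA with a given GC fraction
random_dna <- function(n, gc = 0.373) {
  if (n <= 0) return(character(0))
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
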