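# Independent brute-force oracles and small fixture builders.
# These deliberately re-derive results by exhaustive means, independent of
# the package's seed-and-extend / dynamic-programming code paths.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

rc_chars <- function(v) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[v]))
}

## ---- exhaustive dispersed-repeat scan (per-diagonal delimiter windows)

# enumerate maximal windows between two character vectors along every
# diagonal; returns data.frame(ia, ib, len, mm) in 0-based coordinates
bf_diag_windows <- function(va, vb, min_len, max_mm) {
  na <- length(va); nb <- length(vb)
  out <- list()
  for (d in (-(na - 1L)):(nb - 1L)) {
    lo <- max(1L, 1L - d); hi <- min(na, nb - d)  # a-positions on diagonal
    if (hi - lo + 1L < min_len) next
    xa <- va[lo:hi]; xb <- vb[(lo + d):(hi + d)]
    L <- length(xa)
    isN <- xa == "N" | xb == "N"
    mism <- xa != xb & !isN
    # delimiters: virtual walls at 0 and L+1, N columns, mismatch columns
    dpos <- c(0L, which(isN | mism), L + 1L)
    dwall <- c(TRUE, isN[which(isN | mism)], TRUE)
    cumw <- cumsum(dwall)
    nd <- length(dpos)
    for (k in 0:max_mm) {
      if (nd - k - 1L < 1L) next
      a_idx <- seq_len(nd - k - 1L)
      b_idx <- a_idx + k + 1L
      # interior delimiters must all be real mismatches (no walls)
      interior_walls <- cumw[b_idx - 1L] - cumw[a_idx]
      ws <- dpos[a_idx] + 1L; we <- dpos[b_idx] - 1L
      ok <- interior_walls == 0L & (we - ws + 1L) >= min_len
      if (!any(ok)) next
      out[[length(out) + 1L]] <- data.frame(
        ia = lo + ws[ok] - 2L, ib = lo + d + ws[ok] - 2L,
        len = we[ok] - ws[ok] + 1L, mm = k)
    }
  }
  if (!length(out)) return(data.frame(ia = integer(0), ib = integer(0),
                                      len = integer(0), mm = integer(0)))
  unique(do.call(rbind, out))
}

# brute-force equivalent of find_repeats()
bf_repeats <- function(seq, min_len = 30, max_mismatch = 3, max_len = 5000) {
  v <- chars(toupper(seq)); n <- length(v)
  res <- list()
  w <- bf_diag_windows(v, v, min_len, max_mismatch)
  w <- w[w$ib > w$ia, , drop = FALSE]
  if (nrow(w)) res$direct <- data.frame(type = "direct", length = w$len,
                                        pos1 = w$ia, pos2 = w$ib,
                                        mismatches = w$mm, key = w$ib - w$ia)
  for (ty in c("palindromic", "reverse")) {
    vb <- if (ty == "palindromic") rc_chars(v) else rev(v)
    w <- bf_diag_windows(v, vb, min_len, max_mismatch)
    if (nrow(w)) {
      q1 <- w$ia; q2 <- n - w$ib - w$len
      len <- w$len; mm <- w$mm
      sel <- q2 >= q1
      q1 <- q1[sel]; q2 <- q2[sel]; len <- len[sel]; mm <- mm[sel]
      ov <- pmax(0L, q1 + len - q2)
      tr <- as.integer(ceiling(ov / 2))
      q2 <- q2 + tr; len <- len - tr
      for (i in which(tr > 0L & len >= min_len)) {
        c1 <- v[(q1[i] + 1L):(q1[i] + len[i])]
        c2 <- v[(q2[i] + 1L):(q2[i] + len[i])]
        c2 <- if (ty == "palindromic") rc_chars(c2) else rev(c2)
        mm[i] <- sum(c1 != c2 | c1 == "N")
      }
      ok <- len >= min_len
      if (any(ok))
        res[[ty]] <- data.frame(type = ty, length = len[ok], pos1 = q1[ok],
                                pos2 = q2[ok], mismatches = mm[ok],
                                key = q1[ok] + q2[ok] + len[ok])
    }
  }
  if (!length(res)) return(data.frame(type = character(0), length = integer(0),
                                      pos1 = integer(0), pos2 = integer(0),
                                      mismatches = integer(0)))
  df <- do.call(rbind, res)
  df <- df[df$pos2 >= df$pos1 + df$length, , drop = FALSE]
  df <- df[df$length >= min_len & df$length <= max_len, , drop = FALSE]
  df <- df[df$mismatches <= pmin(max_mismatch, floor(df$length * 0.10)), ,
           drop = FALSE]
  df <- df[!duplicated(df[, c("type", "pos1", "pos2", "length")]), , drop = FALSE]
  # containment suppression within type along the pairing family
  df <- df[order(-df$length), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))[-1L]) {
    for (j in which(keep[seq_len(i - 1L)])) {
      if (df$type[j] == df$type[i] && df$key[j] == df$key[i] &&
          df$pos1[i] >= df$pos1[j] &&
          df$pos1[i] + df$length[i] <= df$pos1[j] + df$length[j]) {
        keep[i] <- FALSE; break
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  df$key <- NULL
  df[order(df$pos1, df$pos2, df$type), , drop = FALSE]
}

hits_key <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(paste(df$type, df$pos1, df$pos2, df$length, df$mismatches))
}

## ---- exhaustive inverted-repeat scan for small circular genomes

bf_longest_inverted <- function(seq, min_len = 200L) {
  n <- nchar(seq)
  s2 <- paste0(seq, seq)
  va <- chars(s2); vb <- chars(plastcomp::revcomp(s2))
  na <- length(va)
  runs <- list()
  for (d in (-(na - 1L)):(na - 1L)) {
    lo <- max(1L, 1L - d); hi <- min(na, na - d)
    if (hi - lo + 1L < min_len) next
    eq <- va[lo:hi] == vb[(lo + d):(hi + d)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    for (k in which(r$values & r$lengths >= min_len)) {
      ws <- lo + ends[k] - r$lengths[k]   # 1-based a-position of run start
      runs[[length(runs) + 1L]] <- c(ia = ws - 1L, ib = ws - 1L + d,
                                     len = r$lengths[k])
    }
  }
  if (!length(runs)) return(NULL)
  w <- as.data.frame(do.call(rbind, runs))
  m <- 2L * n
  a <- w$ia %% n; b <- (m - w$ib - w$len) %% n
  len <- pmin(w$len, n)
  df <- unique(data.frame(p1 = pmin(a, b), p2 = pmax(a, b), len = len))
  # disjoint on the circle
  ok <- vapply(seq_len(nrow(df)), function(i) {
    iv1 <- ((df$p1[i]):(df$p1[i] + df$len[i] - 1L)) %% n
    iv2 <- ((df$p2[i]):(df$p2[i] + df$len[i] - 1L)) %% n
    length(intersect(iv1, iv2)) == 0L
  }, TRUE)
  df <- df[ok, , drop = FALSE]
  if (!nrow(df)) return(NULL)
  df[which.max(df$len), ]
}

## ---- exhaustive affine-gap global alignment score for tiny strings

bf_align_score <- function(a, b, match = 2, mismatch = -3,
                           gap_open = 8, gap_ext = 1) {
  va <- chars(a); vb <- chars(b)
  subsc <- function(x, y) {
    if (x == "N" || y == "N") 0 else if (x == y) match else mismatch
  }
  # plain enumeration with explicit gap-state bookkeeping
  rec2 <- function(i, j, state) {
    if (i > length(va) && j > length(vb)) return(0)
    best <- -Inf
    if (i <= length(va) && j <= length(vb))
      best <- max(best, subsc(va[i], vb[j]) + rec2(i + 1L, j + 1L, "M"))
    if (i <= length(va))
      best <- max(best, -(if (state == "X") gap_ext else gap_open + gap_ext) +
                          rec2(i + 1L, j, "X"))
    if (j <= length(vb))
      best <- max(best, -(if (state == "Y") gap_ext else gap_open + gap_ext) +
                          rec2(i, j + 1L, "Y"))
    best
  }
  rec2(1L, 1L, "M")
}

## ---- exhaustive Fitch minimum for small rooted trees

bf_fitch_min <- function(tree, states) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  tipst <- states[tree$tip.label]
  free_tips <- which(is.na(tipst))
  edges <- tree$edge
  combos_int <- expand.grid(rep(list(0:1), nn))
  best <- Inf
  tip_assign <- tipst
  free_grid <- if (length(free_tips))
    expand.grid(rep(list(0:1), length(free_tips))) else data.frame(x = 0)[, 0]
  for (g in seq_len(max(1L, nrow(free_grid)))) {
    if (length(free_tips)) tip_assign[free_tips] <- as.integer(free_grid[g, ])
    full <- c(tip_assign, rep(0L, nn))
    for (r in seq_len(nrow(combos_int))) {
      full[(nt + 1L):(nt + nn)] <- as.integer(combos_int[r, ])
      ch <- sum(full[edges[, 1L]] != full[edges[, 2L]])
      if (ch < best) best <- ch
    }
  }
  best
}

## ---- hand-built indel character matrices

make_matrix <- function(taxa, states_list, region = "r1") {
  stmat <- do.call(rbind, states_list)
  colnames(stmat) <- taxa
  chars <- data.frame(id = paste0(region, ":", seq_along(states_list)),
                      region = region,
                      length = 1L,
                      informative = vapply(states_list, function(s)
                        sum(s == 1, na.rm = TRUE) >= 2 &&
                          sum(s == 0, na.rm = TRUE) >= 2, TRUE))
  rownames(stmat) <- chars$id
  structure(list(taxa = taxa, characters = chars, states = stmat),
            class = "indel_matrix")
}

## ---- small synthetic fixtures

small_cfg <- function(seed = 1, ...) {
  ancestor_config(lsc_len = 6000, ssc_len = 2000, ir_len = 2500,
                  seed = seed, ...)
}

small_clade <- function(seed = 1, tree = "((A:0.002,B:0.002):0.001,(C:0.003,D:0.002):0.001,OUT:0.006);",
                        ...) {
  anc <- make_ancestor(small_cfg(seed))
  list(anc = anc,
       clade = evolve_along_tree(anc, evolution_config(tree, seed = seed + 100,
                                                       ...)))
}
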