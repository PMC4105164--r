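# Binary indel characters and Fitch parsimony mapping.
#
# Each distinct maximal gap block of a multiple alignment (same column
# span, same gapped-row membership) is one binary character: state 1 =
# taxon carries the gap, state 0 = taxon carries sequence, NA = taxon has
# N across the block.  Characters are mapped onto a rooted tree by Fitch
# parsimony; a single-change character is a synapomorphy (internal branch)
# or autapomorphy (terminal branch), two or more changes is homoplasy.

#' Build a binary indel character matrix from multiple alignments
#'
#' @param alignments named list of multi-row `dna_alignment`s sharing one
#'   taxon set (names are region names).
#' @param min_taxa_present informative flag threshold: a character must be
#'   present in at least this many taxa and absent in at least 2 (default 2).
#' @return object of class `indel_matrix`: `taxa`, `characters`
#'   (data.frame id, region, length, informative), `states` (characters x
#'   taxa matrix of 1/0/NA).
#' @export
build_indel_matrix <- function(alignments, min_taxa_present = 2L) {
  stopifnot(length(alignments) >= 1L)
  taxa <- alignments[[1L]]$labels
  rows <- list(); states <- list()
  for (nm in names(alignments)) {
    aln <- alignments[[nm]]
    if (!setequal(aln$labels, taxa))
      stop("taxon set of region '", nm, "' does not match the first alignment")
    m <- aln_matrix(aln)[match(taxa, aln$labels), , drop = FALSE]
    gaps <- m == "-"
    pat <- apply(gaps, 2L, function(col) paste(which(col), collapse = ","))
    rl <- rle(pat)
    ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
    for (k in which(rl$values != "")) {
      cols <- starts[k]:ends[k]
      carriers <- as.integer(strsplit(rl$values[k], ",", fixed = TRUE)[[1L]])
      st <- rep(0L, length(taxa))
      st[carriers] <- 1L
      # taxa that are entirely N across the block are missing
      allN <- vapply(seq_along(taxa), function(i)
        all(m[i, cols] %in% c("N", "-")) && !(i %in% carriers), TRUE)
      wholly_n <- vapply(seq_along(taxa), function(i)
        all(m[i, cols] == "N"), TRUE)
      st[wholly_n] <- NA_integer_
      n_present <- sum(st == 1L, na.rm = TRUE)
      n_absent <- sum(st == 0L, na.rm = TRUE)
      if (n_present == 0L || n_absent == 0L) next    # constant: not a character
      rows[[length(rows) + 1L]] <-
        data.frame(id = paste0(nm, ":", starts[k], ":", length(cols)),
                   region = nm, length = length(cols),
                   informative = n_present >= min_taxa_present && n_absent >= 2L,
                   stringsAsFactors = FALSE)
      states[[length(states) + 1L]] <- st
    }
  }
  chars <- if (length(rows)) do.call(rbind, rows)
           else data.frame(id = character(0), region = character(0),
                           length = integer(0), informative = logical(0))
  stmat <- if (length(states)) do.call(rbind, states)
           else matrix(integer(0), ncol = length(taxa))
  colnames(stmat) <- taxa
  rownames(stmat) <- chars$id
  structure(list(taxa = taxa, characters = chars, states = stmat),
            class = "indel_matrix")
}

#' @export
print.indel_matrix <- function(x, ...) {
  cat("<indel_matrix> ", nrow(x$characters), " characters x ",
      length(x$taxa), " taxa (", sum(x$characters$informative),
      " informative)\n", sep = "")
  invisible(x)
}

# Fitch down-pass change count + one most-parsimonious reconstruction for a
# binary character on a rooted binary tree (ape phylo, rooted).
# states: named 1/0/NA over tips.  Returns list(changes, node_state, edge_changes).
fitch_one <- function(tree, states, root_pref = 1L) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  sets <- integer(nt + nn)             # bitmask: 1 = state0, 2 = state1
  tipst <- states[tree$tip.label]
  sets[seq_len(nt)] <- ifelse(is.na(tipst), 3L, ifelse(tipst == 1L, 2L, 1L))
  edge <- tree$edge
  po <- ape::reorder.phylo(tree, "postorder")$edge
  changes <- 0L
  kids <- split(po[, 2L], po[, 1L])
  # process each internal node at the first postorder row where all of its
  # children are ready (tips, or internal nodes finished earlier)
  seen <- integer(0)
  for (i in seq_len(nrow(po))) {
    parent <- po[i, 1L]
    if (parent %in% seen) next
    ch <- kids[[as.character(parent)]]
    if (any(sets[ch] == 0L)) next
    inter <- Reduce(bitwAnd, sets[ch])
    if (inter > 0L) {
      sets[parent] <- inter
    } else {
      sets[parent] <- Reduce(bitwOr, sets[ch])
      changes <- changes + length(ch) - 1L
    }
    seen <- c(seen, parent)
  }
  root <- nt + 1L
  # preorder refinement: prefer the parent's state; the root prefers the
  # outgroup state (polarity anchor), falling back to "absent"
  final <- integer(nt + nn)
  pick <- function(set, pref) {
    if (bitwAnd(set, pref) > 0L) pref else if (bitwAnd(set, 1L) > 0L) 1L else 2L
  }
  final[root] <- pick(sets[root], root_pref)
  pre <- po[rev(seq_len(nrow(po))), , drop = FALSE]
  for (i in seq_len(nrow(pre))) {
    p <- pre[i, 1L]; ch <- pre[i, 2L]
    final[ch] <- pick(sets[ch], final[p])
  }
  edge_changes <- final[edge[, 1L]] != final[edge[, 2L]]
  list(changes = changes, node_state = ifelse(final == 2L, 1L, 0L),
       edge_changes = edge_changes, sets = sets)
}

#' Map indel characters onto a tree by Fitch parsimony
#'
#' Roots the tree at the outgroup, computes the Fitch minimum change count
#' per character, one most-parsimonious ancestral reconstruction, the
#' changing branches, and the synapomorphy/autapomorphy/homoplasy class.
#' Missing tip states are treated as compatible with either state.  The
#' polarity of each change is given relative to the reconstructed root
#' state: a branch gaining the gap is a deletion ("-"), a branch losing it
#' an insertion ("+").
#'
#' @param tree an `ape` phylo object, a newick string, or a path to a
#'   newick file.
#' @param matrix an `indel_matrix`.
#' @param outgroup tip label used to root the tree and polarise changes.
#' @return object of class `character_mapping`: `mapping` (data.frame id,
#'   region, length, informative, min_changes, class, branches, direction),
#'   `tree` (the rooted tree used), `taxa`.
#' @export
fitch_assign <- function(tree, matrix, outgroup) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  }
  stopifnot(inherits(tree, "phylo"))
  if (!setequal(tree$tip.label, matrix$taxa))
    stop("tree tips do not match matrix taxa")
  stopifnot(outgroup %in% tree$tip.label)
  tree <- ape::root(ape::unroot(tree), outgroup = outgroup, resolve.root = TRUE)
  if (!ape::is.binary(tree)) {
    message("fitch_assign: resolving polytomies arbitrarily (zero-length branches)")
    tree <- ape::multi2di(tree)
  }
  nt <- length(tree$tip.label)
  rows <- list()
  for (i in seq_len(nrow(matrix$characters))) {
    st <- matrix$states[i, ]
    og <- st[outgroup]
    root_pref <- if (is.na(og)) 1L else if (og == 1L) 2L else 1L
    fit <- fitch_one(tree, st, root_pref = root_pref)
    ch_edges <- which(fit$edge_changes)
    # branch label: child clade of each changing edge
    br <- vapply(ch_edges, function(e) {
      child <- tree$edge[e, 2L]
      if (child <= nt) tree$tip.label[child]
      else paste0("mrca(", paste(sort(ape::extract.clade(tree, child)$tip.label),
                                 collapse = "+"), ")")
    }, "")
    dirs <- vapply(ch_edges, function(e) {
      from <- fit$node_state[tree$edge[e, 1L]]
      if (from == 0L) "-" else "+"     # gained gap = deletion of sequence
    }, "")
    cls <- if (fit$changes == 0L) "invariant"
           else if (fit$changes >= 2L) "homoplasy"
           else if (tree$edge[ch_edges[1L], 2L] <= nt) "autapomorphy"
           else "synapomorphy"
    root_amb <- fit$sets[nt + 1L] == 3L
    direction <- if (root_amb) "±"
                 else if (length(unique(dirs)) == 1L) dirs[1L]
                 else "±"
    rows[[length(rows) + 1L]] <-
      data.frame(id = matrix$characters$id[i],
                 region = matrix$characters$region[i],
                 length = matrix$characters$length[i],
                 informative = matrix$characters$informative[i],
                 min_changes = fit$changes, class = cls,
                 branches = paste(br, collapse = ";"),
                 direction = direction, stringsAsFactors = FALSE)
  }
  mapping <- if (length(rows)) do.call(rbind, rows)
             else data.frame(id = character(0), region = character(0),
                             length = integer(0), informative = logical(0),
                             min_changes = integer(0), class = character(0),
                             branches = character(0), direction = character(0))
  structure(list(mapping = mapping, tree = tree, taxa = matrix$taxa),
            class = "character_mapping")
}

#' @export
print.character_mapping <- function(x, ...) {
  tb <- table(x$mapping$class)
  cat("<character_mapping> ", nrow(x$mapping), " characters: ",
      paste(names(tb), tb, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Summarise a character mapping
#'
#' @param mapping a `character_mapping`.
#' @return list of class `character_summary`: `by_class` (counts),
#'   `single_change` (synapomorphies + autapomorphies), `homoplasy`,
#'   `by_branch` (data.frame branch, n, plus, minus).
#' @export
classify_characters <- function(mapping) {
  mp <- mapping$mapping
  by_class <- table(factor(mp$class, levels = c("synapomorphy", "autapomorphy",
                                                "homoplasy", "invariant")))
  branches <- unlist(strsplit(mp$branches[mp$branches != ""], ";", fixed = TRUE))
  dirs <- unlist(mapply(function(b, d) rep(d, length(strsplit(b, ";")[[1L]])),
                        mp$branches[mp$branches != ""],
                        mp$direction[mp$branches != ""], SIMPLIFY = FALSE))
  by_branch <- if (length(branches)) {
    agg <- split(dirs, branches)
    data.frame(branch = names(agg),
               n = lengths(agg),
               plus = vapply(agg, function(x) sum(x == "+"), 0L),
               minus = vapply(agg, function(x) sum(x == "-"), 0L),
               row.names = NULL, stringsAsFactors = FALSE)
  } else data.frame(branch = character(0), n = integer(0),
                    plus = integer(0), minus = integer(0))
  structure(list(by_class = by_class,
                 single_change = sum(by_class[c("synapomorphy", "autapomorphy")]),
                 homoplasy = by_class[["homoplasy"]],
                 by_branch = by_branch),
            class = "character_summary")
}

#' @export
print.character_summary <- function(x, ...) {
  cat("character classes: ",
      paste(names(x$by_class), as.integer(x$by_class), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
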