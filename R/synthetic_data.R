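# Synthetic plastome evolution.
#
# make_ancestor() builds an annotated circular quadripartite genome: an
# exact planted inverted-repeat pair (IRb = revcomp(IRa), non-extendable at
# its boundaries), gene models with introns, an overlapping gene pair, a
# ycf1 analogue spanning the SSC|IRa junction, planted SSR loci and
# dispersed repeats, all recorded in a ground-truth table.
#
# evolve_along_tree() evolves the ancestor along a newick tree with
# region-specific substitution rates (IR slower than single copy), a
# transition bias, indel events with a 1-bp-dominated length mixture and
# adjacent-sequence duplication for insertions, optional SSR slippage, and
# concerted evolution of the IR pair (mutations are applied to a single IR
# template mirrored into both copies).
#
# Internally a genome is held as a "core" of LSC + IRb + SSC; IRa and its
# annotations are materialised by mirroring IRb.

#' Ancestor configuration for the synthetic plastome generator
#'
#' Defaults emulate a typical ~157 kb camellioid plastome: LSC 86,600 bp,
#' SSC 18,280 bp, IR 26,090 bp, GC fraction 0.373, a ycf1 analogue
#' extending 1,068 bp into IRa and an ndhF analogue starting 3 bp after
#' the IRb|SSC junction.
#'
#' @param lsc_len,ssc_len,ir_len partition lengths in bp.
#' @param gc genome GC fraction.
#' @param seed integer seed for the generator.
#' @param ycf1_ira_overlap bp of the ycf1 analogue inside IRa (capped to
#'   fit small genomes).
#' @param ndhf_jsb_gap bp between the IRb|SSC junction and the ndhF start.
#' @param plant_ssrs,plant_repeats,plant_subthreshold_ssr plant marker loci
#'   and record them in the truth table.
#' @param with_genes plant an annotated gene layout (FALSE gives a bare
#'   quadripartite sequence with no features).
#' @return a list of class `ancestor_config`.
#' @export
ancestor_config <- function(lsc_len = 86600, ssc_len = 18280, ir_len = 26090,
                            gc = 0.373, seed = 1,
                            ycf1_ira_overlap = 1068, ndhf_jsb_gap = 3,
                            plant_ssrs = TRUE, plant_repeats = TRUE,
                            plant_subthreshold_ssr = TRUE, with_genes = TRUE) {
  stopifnot(lsc_len > 0, ssc_len > 0, ir_len > 0, lsc_len > ssc_len,
            gc > 0, gc < 1)
  structure(list(lsc_len = as.integer(lsc_len), ssc_len = as.integer(ssc_len),
                 ir_len = as.integer(ir_len), gc = gc, seed = as.integer(seed),
                 ycf1_ira_overlap = as.integer(ycf1_ira_overlap),
                 ndhf_jsb_gap = as.integer(ndhf_jsb_gap),
                 plant_ssrs = plant_ssrs, plant_repeats = plant_repeats,
                 plant_subthreshold_ssr = plant_subthreshold_ssr,
                 with_genes = with_genes),
            class = "ancestor_config")
}

gene_spec <- function(name, class = "protein", exons, introns = integer(0),
                      strand = "+", overlap_prev = 0L, lead_gap = NA_integer_,
                      at_end = FALSE) {
  list(name = name, class = class, exons = as.integer(exons),
       introns = as.integer(introns), strand = strand,
       overlap_prev = as.integer(overlap_prev), lead_gap = lead_gap,
       at_end = at_end)
}

spec_len <- function(sp) sum(sp$exons) + sum(sp$introns)

# gene plans per partition, scaled to the partition budget
plan_partition <- function(part, len, cfg) {
  gl <- max(60L, min(900L, len %/% 15L))
  tr <- max(40L, min(80L, len %/% 60L))
  il <- max(40L, min(480L, len %/% 40L))
  rr <- max(80L, min(1500L, len %/% 12L))
  e2 <- function(g) c(g %/% 2L, g - g %/% 2L)
  e3 <- function(g) c(g %/% 3L, g %/% 3L, g - 2L * (g %/% 3L))
  specs <- list()
  add <- function(sp) specs[[length(specs) + 1L]] <<- sp
  if (part == "LSC") {
    add(gene_spec("trnH", "trna", tr, strand = "-"))
    add(gene_spec("psbA", "protein", gl, strand = "-"))
    add(gene_spec("atpF", "protein", e2(gl), il))
    add(gene_spec("ycf3", "protein", e3(gl), c(il, il), strand = "-"))
    add(gene_spec("psbC", "protein", gl))
    add(gene_spec("psbD", "protein", gl, overlap_prev = min(52L, gl %/% 2L)))
    add(gene_spec("clpP", "protein", e3(gl), c(il, il), strand = "-"))
    add(gene_spec("rps12", "protein", gl %/% 2L, strand = "-"))
    add(gene_spec("atpB", "protein", gl, strand = "-"))
    add(gene_spec("atpE", "protein", gl %/% 2L, overlap_prev = 3L, strand = "-"))
    add(gene_spec("trnK", "trna", e2(tr), il))
    filler <- 1L
  } else if (part == "SSC") {
    add(gene_spec("ndhF", "protein", gl, strand = "-",
                  lead_gap = cfg$ndhf_jsb_gap))
    add(gene_spec("ndhA", "protein", e2(gl), il, strand = "-"))
    filler <- 1L
  } else { # IR
    add(gene_spec("trnI", "trna", e2(tr), il))
    add(gene_spec("rrn16", "rrna", rr))
    add(gene_spec("trnA", "trna", tr))
    add(gene_spec("rrn23", "rrna", rr))
    add(gene_spec("rrn4.5", "rrna", max(40L, rr %/% 10L)))
    add(gene_spec("rrn5", "rrna", max(40L, rr %/% 10L)))
    add(gene_spec("rps12", "protein", e2(gl %/% 2L), il))
    filler <- 1L
  }
  # keep only the landmarks that fit, then pad with fillers
  min_igs <- 30L
  budget <- floor(len * 0.75)
  kept <- list(); used <- 0L
  for (sp in specs) {
    need <- spec_len(sp) - sp$overlap_prev + min_igs
    if (used + need <= budget) { kept[[length(kept) + 1L]] <- sp; used <- used + need }
  }
  pre <- tolower(substr(part, 1L, 1L))
  repeat {
    sp <- if (filler %% 3L == 0L)
            gene_spec(sprintf("trn%s%02d", toupper(pre), filler), "trna", tr)
          else gene_spec(sprintf("orf%s%02d", pre, filler), "protein", gl)
    need <- spec_len(sp) + min_igs
    if (used + need > budget) break
    kept[[length(kept) + 1L]] <- sp; used <- used + need
    filler <- filler + 1L
  }
  if (part == "LSC" && used + gl %/% 2L + min_igs <= len)
    kept[[length(kept) + 1L]] <- gene_spec("rps19", "protein", gl %/% 2L)
  if (part == "SSC") {
    # ycf1 analogue: its SSC part sits flush against the SSC|IRa junction
    ssc_part <- min(2L * gl, max(60L, len - used - min_igs))
    if (len - used - ssc_part >= min_igs)
      kept[[length(kept) + 1L]] <- gene_spec("ycf1", "protein", ssc_part,
                                             at_end = TRUE)
  }
  kept
}

# lay out gene specs over a partition of the given length; returns the
# sequence (char vector), relative features, and the IGS gaps
assemble_partition <- function(specs, len, gc, reserve_tail = 0L) {
  avail <- len - reserve_tail
  footprint <- sum(vapply(specs, function(sp) spec_len(sp) - sp$overlap_prev, 0L))
  fixed_leads <- vapply(specs, function(sp)
    if (!is.na(sp$lead_gap)) sp$lead_gap else NA_integer_, 0L)
  n_free_gaps <- sum(is.na(fixed_leads) & vapply(specs, function(sp)
    sp$overlap_prev == 0L, TRUE)) + if (any(vapply(specs, function(sp) sp$at_end, TRUE))) 0L else 1L
  slack <- avail - footprint - sum(fixed_leads, na.rm = TRUE)
  if (slack < n_free_gaps * 2L)
    stop("gene plan overflow: partition of ", len, " bp cannot hold ",
         length(specs), " genes")
  gap <- slack %/% max(1L, n_free_gaps)
  extra <- slack - gap * n_free_gaps  # folded into the first free gap
  seqv <- character(0)
  feats <- list(); gaps <- list(); fid_n <- 0L
  pos <- 0L
  push_gap <- function(g) {
    if (g > 0L) {
      gaps[[length(gaps) + 1L]] <<- c(pos, pos + g)
      seqv <<- c(seqv, random_dna(g, gc))
      pos <<- pos + g
    }
  }
  first_free <- TRUE
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    if (sp$overlap_prev > 0L) {
      gs <- pos - sp$overlap_prev
    } else {
      g <- if (!is.na(sp$lead_gap)) sp$lead_gap
           else { gg <- gap + if (first_free) extra else 0L
                  first_free <- FALSE; gg }
      push_gap(g)
      gs <- pos
    }
    glen <- spec_len(sp)
    new_bp <- glen - sp$overlap_prev
    seqv <- c(seqv, random_dna(new_bp, gc))
    pos <- pos + new_bp
    ge <- gs + glen
    fid_n <- fid_n + 1L
    fid <- paste0(sp$name, ".", fid_n)
    kind_code <- switch(sp$class, protein = "CDS", trna = "tRNA", rrna = "rRNA")
    # exon intervals
    es <- gs; rows <- list()
    for (k in seq_along(sp$exons)) {
      rows[[k]] <- c(es, es + sp$exons[k])
      es <- es + sp$exons[k] + if (k <= length(sp$introns)) sp$introns[k] else 0L
    }
    exm <- do.call(rbind, rows)
    feats[[length(feats) + 1L]] <- data.frame(
      name = sp$name, kind = "gene", start = gs, end = ge, strand = sp$strand,
      copy_tag = NA_character_, feature_id = paste0(fid, ".g"), part = 1L,
      stringsAsFactors = FALSE)
    feats[[length(feats) + 1L]] <- data.frame(
      name = sp$name, kind = kind_code, start = exm[, 1L], end = exm[, 2L],
      strand = sp$strand, copy_tag = NA_character_,
      feature_id = paste0(fid, ".c"), part = seq_len(nrow(exm)),
      stringsAsFactors = FALSE)
  }
  # trailing gap absorbs the remainder (zero when the last gene is at_end)
  tail_gap <- len - reserve_tail - pos
  if (length(specs) && specs[[length(specs)]]$at_end && tail_gap != 0L)
    stop("internal: at_end gene not flush with partition end")
  push_gap(tail_gap)
  if (reserve_tail > 0L) push_gap(reserve_tail)
  stopifnot(pos == len, length(seqv) == len)
  list(seq = seqv, features = do.call(rbind, feats),
       gaps = do.call(rbind, gaps))
}

#' Generate a synthetic annotated quadripartite plastome
#'
#' @param config an [ancestor_config()].
#' @return list of class `synthetic_ancestor`: `record` (the full annotated
#'   `plastome`), `core` (internal LSC+IRb+SSC state used by
#'   [evolve_along_tree()]), `truth` (planted partition, gene census, SSR
#'   and repeat tables).
#' @export
make_ancestor <- function(config = ancestor_config()) {
  set.seed(config$seed)
  l <- config$lsc_len; r <- config$ir_len; s <- config$ssc_len
  o <- min(config$ycf1_ira_overlap, r %/% 5L, s %/% 4L)
  if (!isTRUE(config$with_genes)) o <- 0L
  plans <- if (isTRUE(config$with_genes)) {
    list(LSC = plan_partition("LSC", l, config),
         IR = plan_partition("IR", r - o, config),
         SSC = plan_partition("SSC", s, config))
  } else list(LSC = list(), IR = list(), SSC = list())
  a_lsc <- assemble_partition(plans$LSC, l, config$gc)
  a_ir <- assemble_partition(plans$IR, r, config$gc, reserve_tail = o)
  a_ssc <- assemble_partition(plans$SSC, s, config$gc)

  shift_f <- function(f, off) {
    if (is.null(f)) return(empty_features())
    f$start <- f$start + off; f$end <- f$end + off; f
  }
  f_lsc <- shift_f(a_lsc$features, 0L)
  f_ir <- shift_f(a_ir$features, l)
  if (nrow(f_ir)) f_ir$copy_tag <- "B"
  f_ssc <- shift_f(a_ssc$features, l + r)
  feats <- rbind(f_lsc, f_ir, f_ssc)
  # hidden marker for the IRa extension of ycf1 (last o bp of IRb)
  if (o > 0L && any(f_ssc$name == "ycf1")) {
    feats <- rbind(feats, data.frame(
      name = ".ycf1ext", kind = "other", start = l + r - o, end = l + r,
      strand = "-", copy_tag = NA_character_, feature_id = ".ycf1ext.1",
      part = 1L, stringsAsFactors = FALSE))
  }
  seqv <- c(a_lsc$seq, a_ir$seq, a_ssc$seq)

  # ---- plant SSR loci and dispersed repeats inside single-copy IGS gaps
  gaps <- rbind(a_lsc$gaps, a_ssc$gaps + l + r)
  gaps <- gaps[order(-(gaps[, 2L] - gaps[, 1L])), , drop = FALSE]
  gap_i <- 1L
  take_gap <- function(need) {
    while (gap_i <= nrow(gaps)) {
      g <- gaps[gap_i, ]; gap_i <<- gap_i + 1L
      if (g[2L] - g[1L] >= need + 4L) return(g)
    }
    NULL
  }
  truth_ssrs <- list(); truth_reps <- list()
  ssr_hidden <- list()
  plant_run <- function(unit, count, subthreshold = FALSE) {
    run <- s2c(strrep(unit, count))
    need <- length(run) + 2L
    g <- take_gap(need)
    if (is.null(g)) return(invisible(NULL))
    at <- g[1L] + ((g[2L] - g[1L] - need) %/% 2L)  # 0-based, centred
    flank <- if (substr(unit, 1L, 1L) == "C" || substr(unit, nchar(unit), nchar(unit)) == "C")
             "G" else "C"
    seqv[(at + 1L):(at + need)] <<- c(flank, run, flank)
    k <- length(truth_ssrs) + 1L
    truth_ssrs[[k]] <<- data.frame(
      unit = unit, count = count, start = at + 1L, end = at + 1L + length(run),
      subthreshold = subthreshold, stringsAsFactors = FALSE)
    if (!subthreshold) {
      # hidden marker so tree evolution can track and protect the locus
      nm <- sprintf(".ssr%d.u%d", k, nchar(unit))
      ssr_hidden[[k]] <<- data.frame(
        name = nm, kind = "other", start = at + 1L, end = at + 1L + length(run),
        strand = "+", copy_tag = NA_character_, feature_id = paste0(nm, ".1"),
        part = 1L, stringsAsFactors = FALSE)
    }
  }
  if (config$plant_ssrs) {
    plant_run("A", 12L); plant_run("T", 11L); plant_run("A", 10L)
    plant_run("AAAAAG", 3L); plant_run("AGGG", 4L)
    if (config$plant_subthreshold_ssr) plant_run("A", 9L, subthreshold = TRUE)
  }
  if (config$plant_repeats) {
    for (ty in c("direct", "palindromic", "reverse")) {
      x <- random_dna(35L, config$gc)
      g1 <- take_gap(35L); g2 <- take_gap(35L)
      if (is.null(g1) || is.null(g2)) next
      p1 <- g1[1L] + 2L; p2 <- g2[1L] + 2L
      y <- switch(ty, direct = x, palindromic = s2c(revcomp(c2s(x))),
                  reverse = rev(x))
      seqv[(p1 + 1L):(p1 + 35L)] <- x
      seqv[(p2 + 1L):(p2 + 35L)] <- y
      lo <- min(p1, p2); hi <- max(p1, p2)
      truth_reps[[length(truth_reps) + 1L]] <- data.frame(
        type = ty, length = 35L, pos1 = lo, pos2 = hi, stringsAsFactors = FALSE)
    }
  }

  if (length(ssr_hidden))
    feats <- rbind(feats, do.call(rbind, ssr_hidden))
  core <- list(seq = seqv, boundaries = c(lsc = l, ir = r, ssc = s),
               features = feats, gc = config$gc,
               ycf1_ext = o)
  core <- fix_ir_boundaries(core)

  # planted-truth gene census from the plan
  cls <- function(p) vapply(p, function(sp) sp$class, "")
  n_ir <- length(plans$IR)
  census <- list(
    total = length(plans$LSC) + length(plans$SSC) + 2L * n_ir,
    protein_coding = sum(cls(plans$LSC) == "protein") +
      sum(cls(plans$SSC) == "protein") + 2L * sum(cls(plans$IR) == "protein"),
    trna = sum(cls(plans$LSC) == "trna") + sum(cls(plans$SSC) == "trna") +
      2L * sum(cls(plans$IR) == "trna"),
    rrna = sum(cls(plans$LSC) == "rrna") + sum(cls(plans$SSC) == "rrna") +
      2L * sum(cls(plans$IR) == "rrna"),
    intron_containing = length(unique(unlist(lapply(c(plans$LSC, plans$SSC, plans$IR),
      function(sp) if (length(sp$introns)) sp$name else NULL)))),
    two_intron_genes = sort(unique(unlist(lapply(c(plans$LSC, plans$SSC, plans$IR),
      function(sp) if (length(sp$introns) >= 2L) sp$name else NULL)))))

  truth <- list(partition = c(lsc = l, ir = r, ssc = s,
                              genome = l + s + 2L * r),
                junctions = c(JLB = l, JSB = l + r, JSA = l + r + s, JLA = 0L),
                census = census,
                ssrs = if (length(truth_ssrs)) do.call(rbind, truth_ssrs)
                       else NULL,
                repeats = if (length(truth_reps)) do.call(rbind, truth_reps)
                          else NULL,
                ycf1_ira_overlap = o,
                seed = config$seed, config = config)
  structure(list(record = materialize_core(core, id = "ancestor"),
                 core = core, truth = truth),
            class = "synthetic_ancestor")
}

# make the planted IR pair non-extendable at both junctions
fix_ir_boundaries <- function(core) {
  v <- core$seq
  l <- core$boundaries[["lsc"]]; r <- core$boundaries[["ir"]]
  s <- core$boundaries[["ssc"]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  # leftward of IRb pairs with the first LSC base (after IRa, wrapping)
  if (v[l] == comp[[v[1L]]])
    v[l] <- setdiff(c("A", "C", "G", "T"), c(v[l], comp[[v[1L]]]))[1L]
  # rightward of IRb (first SSC base) pairs with the last SSC base
  if (v[l + r + 1L] == comp[[v[l + r + s]]])
    v[l + r + 1L] <- setdiff(c("A", "C", "G", "T"),
                             c(v[l + r + 1L], comp[[v[l + r + s]]]))[1L]
  core$seq <- v
  core
}

# expand a core (LSC+IRb+SSC) into the full annotated circular record
materialize_core <- function(core, id = "synthetic") {
  l <- core$boundaries[["lsc"]]; r <- core$boundaries[["ir"]]
  s <- core$boundaries[["ssc"]]
  irb <- c2s(core$seq[(l + 1L):(l + r)])
  fullv <- c(core$seq, s2c(revcomp(irb)))
  n <- l + s + 2L * r
  f <- core$features
  # IRa-only substitution overrides (non-concerted mode)
  ira_subs <- f[f$name == ".irasub", , drop = FALSE]
  if (nrow(ira_subs)) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    for (i in seq_len(nrow(ira_subs))) {
      q <- ira_subs$start[i] + 1L - l          # 1-based position within IRb
      if (q < 1L || q > r) next                # drifted out of the IR
      fullv[l + r + s + (r - q + 1L)] <- comp[[ira_subs$copy_tag[i]]]
    }
  }
  full <- c2s(fullv)
  hidden <- grepl("^\\.", f$name)
  vis <- f[!hidden, , drop = FALSE]
  # mirror IRb features into IRa
  in_irb <- vis$start >= l & vis$end <= l + r
  mir <- vis[in_irb, , drop = FALSE]
  if (nrow(mir)) {
    ns <- l + r + s + (l + r - mir$end)
    ne <- l + r + s + (l + r - mir$start)
    mir$start <- ns; mir$end <- ne
    mir$strand <- ifelse(mir$strand == "+", "-", "+")
    mir$copy_tag <- "A"
    mir$feature_id <- paste0(mir$feature_id, ".A")
    # keep transcription order of parts
    mir <- merge_feature_parts(mir, n)
  }
  out <- rbind(vis, mir)
  # ycf1 extension into IRa (mirror of the hidden marker at the IRb end)
  ext <- f[f$name == ".ycf1ext", , drop = FALSE]
  if (nrow(ext) && any(out$name == "ycf1")) {
    o1 <- l + r + s + (l + r - ext$end[1L])
    o2 <- l + r + s + (l + r - ext$start[1L])
    if (o2 > o1) {
      for (fid in unique(out$feature_id[out$name == "ycf1"])) {
        rows <- out$feature_id == fid
        out <- rbind(out, data.frame(
          name = "ycf1", kind = out$kind[rows][1L], start = o1, end = o2,
          strand = out$strand[rows][1L], copy_tag = NA_character_,
          feature_id = fid, part = max(out$part[rows]) + 1L,
          stringsAsFactors = FALSE))
      }
    }
  }
  rownames(out) <- NULL
  plastome_record(id, full, circular = TRUE, features = out,
                  source = "synthetic")
}

## ----------------------------------------------------------- tree evolution

#' Evolution configuration for [evolve_along_tree()]
#'
#' @param tree newick string, file path, or `ape` phylo; branch lengths are
#'   expected substitutions per site in the single-copy regions.
#' @param indel_to_sub_ratio indel events per substitution event (default
#'   1/3, matching plastome S/I ratios around 3).
#' @param indel_mix probabilities of the length bins 1, 2, 3-4, 5-6, 7-10
#'   and over-10 bp (default dominated by 1 bp, then 5-6 bp).
#' @param adjacent_duplication_fraction probability that an insertion
#'   copies the adjacent upstream sequence (default 0.8).
#' @param rate_multipliers per-partition rate multipliers (default IR 1,
#'   LSC 3, SSC 3: the IR evolves three-fold slower).
#' @param kappa transition/transversion bias (default 2).
#' @param ir_concerted mirror every IR mutation into both copies
#'   (default TRUE).
#' @param ssr_slippage_rate per-locus slippage events per unit branch
#'   length at planted SSR loci (default 20: replication slippage runs
#'   orders of magnitude faster than point substitution).
#' @param seed integer seed.
#' @return a list of class `evolution_config`.
#' @export
evolution_config <- function(tree,
                             indel_to_sub_ratio = 1 / 3,
                             indel_mix = c(`1` = 0.45, `2` = 0.08,
                                           `3-4` = 0.10, `5-6` = 0.22,
                                           `7-10` = 0.10, `>10` = 0.05),
                             adjacent_duplication_fraction = 0.8,
                             rate_multipliers = c(IR = 1, LSC = 3, SSC = 3),
                             kappa = 2, ir_concerted = TRUE,
                             ssr_slippage_rate = 20, seed = 1) {
  stopifnot(abs(sum(indel_mix) - 1) < 1e-8, all(indel_mix >= 0),
            indel_to_sub_ratio >= 0, all(rate_multipliers >= 0))
  structure(list(tree = tree, indel_to_sub_ratio = indel_to_sub_ratio,
                 indel_mix = indel_mix,
                 adjacent_duplication_fraction = adjacent_duplication_fraction,
                 rate_multipliers = rate_multipliers, kappa = kappa,
                 ir_concerted = ir_concerted,
                 ssr_slippage_rate = ssr_slippage_rate,
                 seed = as.integer(seed)),
            class = "evolution_config")
}

segment_of <- function(pos, bounds) {
  l <- bounds[["lsc"]]; r <- bounds[["ir"]]
  if (pos <= l) "LSC" else if (pos <= l + r) "IR" else "SSC"
}

# apply one recorded event to a core state (deterministic; used both by the
# simulator and by truth-table replay)
apply_event <- function(core, ev) {
  v <- core$seq
  if (ev$type == "sub") {
    stopifnot(v[ev$pos] == ev$from)
    v[ev$pos] <- ev$to
    core$seq <- v
    return(core)
  }
  if (ev$type == "sub_ira") {
    # IRa-only substitution (non-concerted mode): a hidden one-base marker
    # records the base the IRa partner site must carry after mirroring;
    # it rides the ordinary feature liftover through later indels
    nm <- ".irasub"
    core$features <- rbind(core$features, data.frame(
      name = nm, kind = "other", start = ev$pos - 1L, end = ev$pos,
      strand = "+", copy_tag = ev$base,
      feature_id = sprintf(".irasub.%d", nrow(core$features) + 1L),
      part = 1L, stringsAsFactors = FALSE))
    return(core)
  }
  bounds <- core$boundaries
  seg <- segment_of(ev$pos, bounds)
  if (ev$type == "ins") {
    ins <- s2c(ev$content)
    core$seq <- append(v, ins, after = ev$pos)
    delta <- length(ins)
  } else { # del
    del_idx <- (ev$pos + 1L):(ev$pos + ev$len)
    core$seq <- v[-del_idx]
    delta <- -ev$len
  }
  nm <- switch(seg, LSC = "lsc", IR = "ir", SSC = "ssc")
  core$boundaries[[nm]] <- core$boundaries[[nm]] + delta
  core$features <- shift_features(core$features, ev$pos, delta)
  core
}

# coordinate liftover of the feature table through one indel.
# insertion: `delta` > 0 bases inserted after 0-based position `pos`
# (1-based: after index pos).  deletion: `delta` < 0, bases pos+1..pos-delta
# removed (1-based indices).
shift_features <- function(f, pos, delta) {
  if (nrow(f) == 0L) return(f)
  if (delta > 0L) {
    # insertion at 0-based boundary `pos`: starts at/after it shift, ends
    # after it shift (a feature straddling the boundary stretches)
    f$end <- ifelse(f$end > pos, f$end + delta, f$end)
    f$start <- ifelse(f$start >= pos, f$start + delta, f$start)
  } else {
    len <- -delta
    adj <- function(x) x - pmin(len, pmax(0L, x - pos))
    f$start <- adj(f$start); f$end <- adj(f$end)
    f <- f[f$end > f$start, , drop = FALSE]
  }
  f
}

draw_indel_len <- function(mix) {
  bin <- sample(names(mix), 1L, prob = mix)
  switch(bin, `1` = 1L, `2` = 2L, `3-4` = sample(3:4, 1L),
         `5-6` = sample(5:6, 1L), `7-10` = sample(7:10, 1L),
         `>10` = sample(11:20, 1L))
}

# evolve one core along one branch; returns list(core, events)
mutate_core <- function(core, bl, cfg) {
  events <- list()
  rec <- function(ev) events[[length(events) + 1L]] <<- ev
  bounds <- core$boundaries
  segs <- list(LSC = c(1L, bounds[["lsc"]]),
               IR = c(bounds[["lsc"]] + 1L, bounds[["lsc"]] + bounds[["ir"]]),
               SSC = c(bounds[["lsc"]] + bounds[["ir"]] + 1L,
                       sum(bounds)))
  mult <- cfg$rate_multipliers
  comp_sets <- list(A = c("G", "C", "T"), G = c("A", "C", "T"),
                    C = c("T", "A", "G"), T = c("C", "A", "G"))
  # substitutions (first element of each set is the transition partner)
  kap <- cfg$kappa
  p_tr <- kap / (kap + 2)
  for (sg in names(segs)) {
    rng <- segs[[sg]]
    ns <- rbinom(1L, rng[2L] - rng[1L] + 1L, min(1, bl * mult[[sg]]))
    if (ns == 0L) next
    at <- sample(rng[1L]:rng[2L], ns)
    for (p in at) {
      from <- core$seq[p]
      if (from == "N") next
      cand <- comp_sets[[from]]
      to <- if (runif(1L) < p_tr) cand[1L] else sample(cand[2:3], 1L)
      if (sg == "IR" && !cfg$ir_concerted) {
        # copies mutate independently: hit one copy only
        if (runif(1L) < 0.5) {
          ev <- list(type = "sub", pos = p, from = from, to = to)
          core <- apply_event(core, ev); rec(ev)
          # preserve the ancestral base on the IRa partner site
          ev2 <- list(type = "sub_ira", pos = p, base = from)
          core <- apply_event(core, ev2); rec(ev2)
        } else {
          ev <- list(type = "sub_ira", pos = p, base = to)
          core <- apply_event(core, ev); rec(ev)
        }
      } else {
        ev <- list(type = "sub", pos = p, from = from, to = to)
        core <- apply_event(core, ev); rec(ev)
      }
    }
  }
  # indel events, rate proportional to the local substitution rate
  exp_sub <- sum(vapply(names(segs), function(sg)
    (segs[[sg]][2L] - segs[[sg]][1L] + 1L) * bl * mult[[sg]], 0))
  n_ind <- rpois(1L, exp_sub * cfg$indel_to_sub_ratio)
  seg_w <- vapply(names(segs), function(sg)
    (segs[[sg]][2L] - segs[[sg]][1L] + 1L) * mult[[sg]], 0)
  planted <- core$features[grepl("^\\.ssr", core$features$name), , drop = FALSE]
  for (k in seq_len(n_ind)) {
    bounds <- core$boundaries
    segs <- list(LSC = c(1L, bounds[["lsc"]]),
                 IR = c(bounds[["lsc"]] + 1L, bounds[["lsc"]] + bounds[["ir"]]),
                 SSC = c(bounds[["lsc"]] + bounds[["ir"]] + 1L, sum(bounds)))
    len <- draw_indel_len(cfg$indel_mix)
    ok <- FALSE
    for (try in 1:25) {
      sg <- sample(names(segs), 1L, prob = seg_w)
      rng <- segs[[sg]]
      if (rng[2L] - rng[1L] < len + 2L) next
      pos <- sample(rng[1L]:(rng[2L] - len - 1L), 1L)  # event after this base
      # indels never split a planted SSR (slippage is modelled separately)
      pl <- core$features[grepl("^\\.ssr", core$features$name), , drop = FALSE]
      if (nrow(pl) && any(pos < pl$end & (pos + len) > pl$start)) next
      ok <- TRUE; break
    }
    if (!ok) next
    if (runif(1L) < 0.5 && pos > len + 1L) {
      dup <- runif(1L) < cfg$adjacent_duplication_fraction
      content <- if (dup) c2s(core$seq[(pos - len + 1L):pos])
                 else c2s(random_dna(len, core$gc))
      ev <- list(type = "ins", pos = pos, len = len, content = content,
                 duplicated = dup)
    } else {
      ev <- list(type = "del", pos = pos, len = len)
    }
    core <- apply_event(core, ev); rec(ev)
  }
  # SSR slippage at planted loci: unit count +/- 1
  if (cfg$ssr_slippage_rate > 0 && nrow(planted)) {
    p_slip <- -expm1(-bl * cfg$ssr_slippage_rate)
    for (i in seq_len(nrow(planted))) {
      if (runif(1L) > p_slip) next
      pl <- core$features[core$features$feature_id == planted$feature_id[i], ,
                          drop = FALSE]
      if (nrow(pl) == 0L) next
      u <- as.integer(sub(".*\\.u", "", pl$name[1L]))
      if (!is.finite(u) || pl$end[1L] - pl$start[1L] < 2L * u) next
      if (runif(1L) < 0.5) {
        ev <- list(type = "ins", pos = pl$start[1L] + u,
                   len = u, content = c2s(core$seq[(pl$start[1L] + 1L):(pl$start[1L] + u)]),
                   duplicated = TRUE, slippage = TRUE)
      } else {
        ev <- list(type = "del", pos = pl$start[1L], len = u, slippage = TRUE)
      }
      core <- apply_event(core, ev); rec(ev)
    }
  }
  list(core = core, events = events)
}

#' Evolve a synthetic ancestor along a phylogeny
#'
#' @param ancestor a `synthetic_ancestor` from [make_ancestor()] (or its
#'   `core`).
#' @param config an [evolution_config()].
#' @return list of class `synthetic_clade`: `tips` (named list of annotated
#'   `plastome` records), `tree` (phylo), `truth` (per-edge event lists and
#'   per-tip partition boundaries; replaying the events against the
#'   ancestor core reproduces each tip exactly).
#' @export
evolve_along_tree <- function(ancestor, config) {
  core0 <- if (inherits(ancestor, "synthetic_ancestor")) ancestor$core
           else ancestor
  tr <- config$tree
  if (is.character(tr)) tr <- if (file.exists(tr)) ape::read.tree(tr)
                              else ape::read.tree(text = tr)
  stopifnot(inherits(tr, "phylo"))
  if (is.null(tr$edge.length)) stop("tree must have branch lengths")
  if (any(tr$edge.length < 0)) stop("negative branch length in tree")
  if (anyDuplicated(tr$tip.label)) stop("tree tips must be uniquely labeled")
  set.seed(config$seed)
  nt <- length(tr$tip.label)
  root <- nt + 1L
  states <- list(); states[[root]] <- core0
  events_by_edge <- list()
  pre <- ape::reorder.phylo(tr, "cladewise")$edge
  elen <- ape::reorder.phylo(tr, "cladewise")$edge.length
  tips <- list(); tip_bounds <- list()
  for (i in seq_len(nrow(pre))) {
    par <- pre[i, 1L]; ch <- pre[i, 2L]
    res <- mutate_core(states[[par]], elen[i], config)
    states[[ch]] <- res$core
    events_by_edge[[paste0(par, "->", ch)]] <- res$events
    if (ch <= nt) {
      lab <- tr$tip.label[ch]
      tips[[lab]] <- materialize_core(res$core, id = lab)
      tip_bounds[[lab]] <- res$core$boundaries
    }
  }
  structure(list(tips = tips, tree = tr,
                 truth = list(events = events_by_edge,
                              tip_boundaries = tip_bounds,
                              ancestor_core = core0, config = config)),
            class = "synthetic_clade")
}

#' Replay a recorded event list against a core state
#'
#' Deterministically re-applies the per-branch events recorded by
#' [evolve_along_tree()]; used to verify that the truth table is complete.
#'
#' @param core a core state (e.g. `ancestor$core`).
#' @param events list of event records for one branch (or several branches
#'   concatenated in order).
#' @return the resulting core state.
#' @export
replay_events <- function(core, events) {
  for (ev in events) core <- apply_event(core, ev)
  core
}

#' Write a synthetic clade as a fixture directory
#'
#' Emits GenBank and FASTA per tip, the newick tree, truth TSVs and the
#' configuration, with deterministic file names.
#'
#' @param clade a `synthetic_clade`.
#' @param out_dir output directory (created if needed).
#' @return invisible character vector of written paths.
#' @export
write_fixture_set <- function(clade, out_dir) {
  if (length(clade$tips) == 0L) {
    warning("empty tip set; nothing written")
    return(invisible(character(0)))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (lab in names(clade$tips)) {
    p1 <- file.path(out_dir, paste0(lab, ".gb"))
    p2 <- file.path(out_dir, paste0(lab, ".fasta"))
    write_genbank(clade$tips[[lab]], p1)
    write_fasta(clade$tips[[lab]], p2)
    paths <- c(paths, p1, p2)
  }
  pt <- file.path(out_dir, "tree.nwk")
  ape::write.tree(clade$tree, pt)
  ev <- clade$truth$events
  rows <- list()
  for (edge in names(ev)) for (e in ev[[edge]]) {
    rows[[length(rows) + 1L]] <-
      data.frame(edge = edge, type = e$type, pos = e$pos,
                 len = e$len %||% 1L,
                 detail = if (e$type == "sub") paste0(e$from, ">", e$to)
                          else e$content %||% "",
                 stringsAsFactors = FALSE)
  }
  pe <- file.path(out_dir, "truth_events.tsv")
  write.table(if (length(rows)) do.call(rbind, rows)
              else data.frame(edge = character(0)),
              pe, sep = "\t", quote = FALSE, row.names = FALSE)
  cfgp <- file.path(out_dir, "config.txt")
  cfg <- clade$truth$config
  writeLines(paste0(names(cfg)[names(cfg) != "tree"], "=",
                    vapply(cfg[names(cfg) != "tree"], function(x)
                      paste(format(x), collapse = ","), "")), cfgp)
  invisible(c(paths, pt, pe, cfgp))
}
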