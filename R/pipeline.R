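# End-to-end comparative run: structure, junctions, repeats, SSRs,
# divergence, hotspot markers, partition ratios, and (given a tree) indel
# character mapping, with TSV reports and a JSON manifest.

#' Configuration for [run_compare()]
#'
#' @param genomes character vector of GenBank/FASTA paths, or a (named)
#'   list of `plastome` objects.
#' @param tree optional newick path/string or phylo; enables the
#'   indel-mapping stage.
#' @param outgroup tip label used to root the tree (defaults to the last
#'   genome).
#' @param out_dir output directory for the report bundle.
#' @param stages character vector of stages to run (default all):
#'   "structure", "junctions", "repeats", "ssr", "divergence", "markers",
#'   "ratios", "indel_map".
#' @param min_ir,repeat_min_len,repeat_max_mismatch,ssr_thresholds,marker_threshold
#'   stage thresholds (see the stage functions).
#' @param seed seed for any stochastic stage.
#' @return a list of class `run_config`.
#' @export
run_config <- function(genomes, tree = NULL, outgroup = NULL,
                       out_dir = tempfile("plastcomp_run_"),
                       stages = c("structure", "junctions", "repeats", "ssr",
                                  "divergence", "markers", "ratios",
                                  "indel_map"),
                       min_ir = 10000, repeat_min_len = 30,
                       repeat_max_mismatch = 3,
                       ssr_thresholds = c(`1` = 10, `2` = 6, `3` = 5,
                                          `4` = 4, `5` = 3, `6` = 3),
                       marker_threshold = 1.5, seed = 1) {
  stopifnot(length(genomes) >= 1L, min_ir > 0, repeat_min_len > 0,
            marker_threshold > 0)
  structure(list(genomes = genomes, tree = tree, outgroup = outgroup,
                 out_dir = out_dir, stages = stages, min_ir = min_ir,
                 repeat_min_len = repeat_min_len,
                 repeat_max_mismatch = repeat_max_mismatch,
                 ssr_thresholds = ssr_thresholds,
                 marker_threshold = marker_threshold, seed = seed),
            class = "run_config")
}

load_genomes <- function(genomes) {
  if (is.character(genomes)) {
    recs <- lapply(genomes, function(p) {
      if (grepl("\\.(gb|gbk|genbank)$", p, ignore.case = TRUE)) read_genbank(p)
      else read_fasta(p, circular = TRUE)
    })
  } else if (inherits(genomes, "plastome")) {
    recs <- list(genomes)
  } else recs <- genomes
  names(recs) <- vapply(recs, function(r) r$id, "")
  recs
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full comparative pipeline
#'
#' Executes the requested stages over the input genomes and writes one TSV
#' per report plus a JSON manifest (package version, configuration echo,
#' file checksums, per-stage status).  A failing stage is recorded in the
#' manifest and does not abort the remaining stages.
#'
#' @param config a [run_config()].
#' @return invisible list of the computed tables (`structure`, `junctions`,
#'   `repeats`, `repeat_sharing`, `ssr_loci`, `ssr_summary`, `divergence`,
#'   `variability`, `markers`, `ratios`, `indel_map`), plus `manifest`.
#' @export
run_compare <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  recs <- load_genomes(config$genomes)
  status <- list(); out <- list(); files <- character(0)
  stage <- function(name, expr) {
    if (!name %in% config$stages) { status[[name]] <<- "skipped"; return(invisible(NULL)) }
    t0 <- proc.time()[[3L]]
    res <- tryCatch(expr, error = function(e) {
      status[[name]] <<- paste0("failed: ", conditionMessage(e))
      message("stage ", name, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(status[[name]]))
      status[[name]] <<- sprintf("ok (%.1fs)", proc.time()[[3L]] - t0)
    res
  }

  # canonical orientation is unconditional preprocessing so that stage
  # toggles never change another stage's coordinates
  canon <- tryCatch(lapply(recs, canonical_orientation, min_ir = config$min_ir),
                    error = function(e) {
                      message("canonicalisation failed (", conditionMessage(e),
                              "); using records as supplied")
                      recs
                    })
  stage("structure", {
    tab <- structure_table(recs, config$min_ir)
    files <- c(files, write_tsv(tab, file.path(config$out_dir, "structure.tsv")))
    out$structure <- tab
  })

  stage("junctions", {
    jr <- do.call(rbind, lapply(canon, function(r) {
      p <- attr(r, "partition")
      if (is.null(p)) p <- detect_quadripartite(r, config$min_ir)
      cbind(record = r$id, junction_report(r, p))
    }))
    files <- c(files, write_tsv(jr, file.path(config$out_dir, "junctions.tsv")))
    out$junctions <- jr
  })

  stage("repeats", {
    hits <- lapply(canon, find_repeats_genome, min_ir = config$min_ir,
                   min_len = config$repeat_min_len,
                   max_mismatch = config$repeat_max_mismatch)
    tab <- do.call(rbind, lapply(names(hits), function(id)
      if (nrow(hits[[id]])) cbind(genome = id, as.data.frame(hits[[id]])) else NULL))
    files <- c(files, write_tsv(tab %||% data.frame(),
                                 file.path(config$out_dir, "repeats.tsv")))
    out$repeats <- tab
    if (length(hits) >= 2L) {
      sh <- shared_repeat_sets(hits)
      out$repeat_sharing <- sh
      files <- c(files, write_tsv(
        data.frame(key = rownames(sh$membership), sh$membership,
                   check.names = FALSE),
        file.path(config$out_dir, "repeat_sharing.tsv")))
    }
  })

  stage("ssr", {
    reps <- lapply(canon, function(r)
      ssr_genome_report(r, attr(r, "partition"),
                        thresholds = config$ssr_thresholds,
                        min_ir = config$min_ir))
    loci <- do.call(rbind, lapply(names(reps), function(id)
      if (nrow(reps[[id]]$loci)) cbind(genome = id, as.data.frame(reps[[id]]$loci))
      else NULL))
    summ <- do.call(rbind, lapply(names(reps), function(id)
      if (nrow(reps[[id]]$summary)) cbind(genome = id, reps[[id]]$summary)
      else NULL))
    files <- c(files, write_tsv(loci %||% data.frame(),
                                 file.path(config$out_dir, "ssr_loci.tsv")),
                write_tsv(summ %||% data.frame(),
                          file.path(config$out_dir, "ssr_summary.tsv")))
    out$ssr_loci <- loci; out$ssr_summary <- summ
  })

  multi_ok <- length(canon) >= 2L &&
    all(vapply(canon, function(r) nrow(r$features) > 0L, TRUE))
  if (!multi_ok)
    message("single genome or unannotated input: comparative stages limited ",
            "to structural, repeat and SSR reports")

  dv <- NULL
  stage("divergence", {
    if (!multi_ok) stop("needs >= 2 annotated genomes")
    dv <- genome_divergence_matrix(canon)
    m <- dv$ns
    m[upper.tri(m)] <- dv$id[upper.tri(dv$id)]
    diag(m) <- 0
    tab <- data.frame(genome = rownames(m), m, check.names = FALSE)
    files <- c(files, write_tsv(tab, file.path(config$out_dir, "divergence.tsv")))
    out$divergence <- dv
  })

  stage("markers", {
    if (!multi_ok) stop("needs >= 2 annotated genomes")
    vars <- region_variability_table(canon)
    mk <- screen_markers(vars, threshold = config$marker_threshold)
    files <- c(files, write_tsv(vars, file.path(config$out_dir, "variability.tsv")),
                write_tsv(mk, file.path(config$out_dir, "markers.tsv")))
    out$variability <- vars; out$markers <- mk
  })

  stage("ratios", {
    if (!multi_ok) stop("needs >= 2 annotated genomes")
    rows <- list()
    for (mode in c("functional", "positional")) {
      pr <- partition_divergence_ratios(canon, focal = 1L, mode = mode,
                                        min_ir = config$min_ir)
      rows[[mode]] <- data.frame(focal = pr$focal, mode = mode,
                                 categories = paste(names(pr$ratios),
                                                    collapse = ":"),
                                 ratios = paste(pr$ratios, collapse = ":"),
                                 stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    files <- c(files, write_tsv(tab, file.path(config$out_dir, "ratios.tsv")))
    out$ratios <- tab
  })

  stage("indel_map", {
    if (is.null(config$tree)) stop("no tree supplied")
    if (!multi_ok) stop("needs >= 2 annotated genomes")
    alns <- multi_region_alignments(canon)
    im <- build_indel_matrix(alns)
    og <- config$outgroup %||% names(canon)[length(canon)]
    mp <- fitch_assign(config$tree, im, outgroup = og)
    files <- c(files, write_tsv(mp$mapping,
                                 file.path(config$out_dir, "indel_map.tsv")))
    out$indel_map <- mp
  })

  manifest <- list(
    package = "plastcomp",
    version = as.character(utils::packageVersion("plastcomp")),
    seed = config$seed,
    genomes = names(recs),
    thresholds = list(min_ir = config$min_ir,
                      repeat_min_len = config$repeat_min_len,
                      repeat_max_mismatch = config$repeat_max_mismatch,
                      ssr = as.list(config$ssr_thresholds),
                      marker_threshold = config$marker_threshold),
    stages = status,
    files = as.list(setNames(unname(tools::md5sum(files)), basename(files))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}
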