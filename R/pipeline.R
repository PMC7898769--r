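#' IAP type frequency report
#'
#' Tabulates element types: the LTR name for solo LTRs, the LTR and internal
#' names joined by " - " for fully-structured elements, and a trailing "||"
#' marker for incomplete (fragmented) elements.  Frequencies are reported as
#' the fraction of the set and relative to the set's most common type;
#' optional subsets (e.g. candidate elements) are tabulated alongside the
#' genome-wide counts.
#'
#' @param catalogue an `rm_catalogue`.
#' @param subsets optional named list of element-ID vectors.
#' @return data frame with columns `set`, `type`, `count`, `fraction`,
#'   `rel_freq` (count over the most common type's count within the set).
#' @export
iap_type_frequency_report <- function(catalogue, subsets = NULL) {
  stopifnot(inherits(catalogue, "rm_catalogue"))
  el <- catalogue$elements
  type_of <- function(i) {
    names_ <- strsplit(el$subelements[i], ",", fixed = TRUE)[[1]]
    role <- subelement_role(names_, catalogue$registry)
    ltr <- unique(names_[role == "ltr"])
    int <- unique(names_[role == "internal"])
    lab <- paste(c(ltr, int)[c(ltr, int) != ""], collapse = " - ")
    if (el$structure[i] == "SOLO_LTR") lab <- paste(ltr, collapse = " - ")
    if (el$structure[i] == "FULL") lab <- paste(c(ltr[1], int[1]), collapse = " - ")
    if (is_fragmented(el$structure[i])) lab <- paste0(lab, " ||")
    lab
  }
  el$type <- vapply(seq_len(nrow(el)), type_of, character(1))
  tab_one <- function(ids, set) {
    sub <- el[el$element_id %in% ids, , drop = FALSE]
    if (nrow(sub) == 0L) {
      return(data.frame(set = character(), type = character(),
                        count = integer(), fraction = numeric(),
                        rel_freq = numeric(), stringsAsFactors = FALSE))
    }
    t <- sort(table(sub$type), decreasing = TRUE)
    data.frame(set = set, type = names(t), count = as.integer(t),
               fraction = as.integer(t) / sum(t),
               rel_freq = as.integer(t) / max(t),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- tab_one(el$element_id, "all")
  for (nm in names(subsets)) {
    out <- rbind(out, tab_one(subsets[[nm]], nm))
  }
  rownames(out) <- NULL
  out
}

default_config <- function() {
  list(
    annotation = NULL, genome = NULL, sample_sheet = NULL, out_dir = "vmscreen_out",
    registry = NULL,
    mend = list(max_gap = 2000, iap_only = TRUE),
    screen = list(),
    kmer = list(),
    log_level = "INFO"
  )
}

pipe_log <- function(level, cfg, ...) {
  if (identical(cfg$log_level, "QUIET")) return(invisible())
  message("[", level, "] ", ...)
}

run_stage <- function(name, cfg, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the end-to-end screening pipeline
#'
#' Wires the stages together: mend the annotation, screen the catalogue for
#' variably methylated elements, extract candidate 5' LTR sequences, and run
#' the k-mer enrichment of candidate LTRs against the remaining LTRs.  Every
#' filter's survivor count is logged, all stage outputs are written under
#' `out_dir`, and a run manifest (parameters, input checksums, stage list,
#' counts) makes runs auditable and reproducible.
#'
#' @param config a named list, or path to a YAML file with the same shape:
#'   top-level `annotation`, `genome`, `sample_sheet`, `out_dir`, optional
#'   `registry` (registry TSV) and per-stage sections `mend` (`max_gap`,
#'   `iap_only`), `screen` (arguments of [screen_params()]) and `kmer`
#'   (arguments of [kmer_params()]).
#' @return invisibly, a list with `catalogue`, `screen`, `motifs` and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  for (f in c("annotation", "genome", "sample_sheet")) {
    if (is.null(cfg[[f]])) stop("config is missing '", f, "'")
    if (!file.exists(cfg[[f]])) stop("config path for '", f,
                                     "' does not exist: ", cfg[[f]])
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  registry <- if (is.null(cfg$registry)) default_iap_registry()
  else read_iap_registry(cfg$registry)

  ## stage 1: mend
  cat_mended <- run_stage("mend", cfg, {
    feats <- parse_rm_annotation(cfg$annotation, registry,
                                 iap_only = isTRUE(cfg$mend$iap_only))
    pipe_log("INFO", cfg, "mend: ", nrow(feats), " annotation features")
    cat0 <- group_into_elements(feats, registry)
    cat0 <- patch_boundary_splits(cat0)
    before <- summarize_catalogue(cat0)
    pipe_log("INFO", cfg, "mend: ", before$n_elements, " elements before (",
             round(100 * before$fragmented_fraction), "% fragmented)")
    m <- mend_fragmented(cat0, max_gap = cfg$mend$max_gap %||% 2000)
    after <- summarize_catalogue(m)
    pipe_log("INFO", cfg, "mend: ", after$n_elements, " elements after (",
             round(100 * after$fragmented_fraction), "% fragmented)")
    write_catalogue(m, file.path(cfg$out_dir, "catalogue_mended.tsv"))
    write_catalogue_bed(m, file.path(cfg$out_dir, "catalogue_mended.bed"))
    m
  })

  ## stage 2: screen
  genome <- run_stage("screen", cfg, {
    gs <- Biostrings::readDNAStringSet(cfg$genome)
    names(gs) <- sub("\\s.*", "", names(gs))
    gs
  })
  scr <- run_stage("screen", cfg, {
    sheet <- read_sample_sheet(cfg$sample_sheet)
    if (!"path" %in% names(sheet)) {
      stop("sample sheet needs a 'path' column for the pipeline")
    }
    coverage <- lapply(stats::setNames(sheet$path, sheet$sample_id),
                       read_coverage)
    sp <- do.call(screen_params, cfg$screen)
    s <- screen_catalogue(cat_mended, coverage, sheet, sp,
                          cpg_positions = find_cpg_sites(genome))
    pipe_log("INFO", cfg, "screen: ", nrow(s$edges), " edges, ",
             sum(s$edges$passed_sample_filter), " pass the sample filter, ",
             sum(s$edges$candidate), " candidate edges")
    write_screen_table(s, file.path(cfg$out_dir, "screen_edges.tsv"))
    cand <- screen_candidates(s)
    write_catalogue_bed(cand, file.path(cfg$out_dir, "candidates.bed"))
    s
  })

  ## stage 3: candidate 5' LTR extraction
  ltrs <- run_stage("extract_ltrs", cfg, {
    cand_ids <- screen_candidates(scr)$element_id
    fg <- five_prime_ltr_sequences(cat_mended, genome, cand_ids)
    bg <- five_prime_ltr_sequences(
      cat_mended, genome,
      setdiff(cat_mended$elements$element_id, cand_ids))
    pipe_log("INFO", cfg, "extract_ltrs: ", length(fg), " candidate and ",
             length(bg), " background 5' LTRs")
    if (length(fg)) {
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(fg),
        file.path(cfg$out_dir, "candidate_5ltr.fa"))
    }
    list(fg = fg, bg = bg)
  })

  ## stage 4: k-mer enrichment
  motifs <- run_stage("kmers", cfg, {
    kp <- do.call(kmer_params, cfg$kmer)
    m <- find_enriched_motifs(ltrs$fg, ltrs$bg, kp,
                              all_seqs = c(ltrs$fg, ltrs$bg))
    pipe_log("INFO", cfg, "kmers: ", attr(m, "n_kmers_enumerated"),
             " k-mers enumerated, ", attr(m, "n_kmers_filtered"),
             " kept, ", nrow(m), " merged motifs")
    utils::write.table(as.data.frame(m),
                       file.path(cfg$out_dir, "motifs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    m
  })

  manifest <- list(
    stages = c("mend", "screen", "extract_ltrs", "kmers"),
    parameters = cfg[setdiff(names(cfg), "out_dir")],
    inputs = lapply(stats::setNames(nm = c("annotation", "genome",
                                           "sample_sheet")),
                    function(f) unname(tools::md5sum(cfg[[f]]))),
    counts = list(
      n_elements = nrow(cat_mended$elements),
      fragmented_fraction = summarize_catalogue(cat_mended)$fragmented_fraction,
      n_edges = nrow(scr$edges),
      n_edges_passing_filter = sum(scr$edges$passed_sample_filter),
      n_candidate_elements = nrow(screen_candidates(scr)),
      n_kmers_enumerated = attr(motifs, "n_kmers_enumerated"),
      n_kmers_filtered = attr(motifs, "n_kmers_filtered"),
      n_motifs = nrow(motifs)
    )
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(list(catalogue = cat_mended, screen = scr, motifs = motifs,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
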