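#' Parse a RepeatMasker-style annotation table
#'
#' Reads a UCSC rmsk-style tab-separated table into a feature data frame.
#' Both the UCSC table-browser header (`genoName`, `genoStart`, `genoEnd`,
#' `strand`, `repName`, `repClass`, `repFamily`, `id`) and the plain layout
#' (`chrom`, `start`, `end`, `strand`, `rep_name`, `rep_class_family`,
#' `element_id`) are accepted; a header line is auto-detected.  All
#' coordinates are 0-based half-open (UCSC table convention).
#'
#' @param file path to a TSV file (possibly gzipped), or a data frame already
#'   holding the columns above.
#' @param registry an [iap_registry] used when `iap_only = TRUE`.
#' @param iap_only drop rows whose `rep_name` is not in the registry.
#' @return data frame with columns `chrom`, `start`, `end`, `strand`,
#'   `rep_name`, `rep_class_family`, `element_id`, sorted by (chrom, start).
#' @export
parse_rm_annotation <- function(file, registry = default_iap_registry(),
                                iap_only = FALSE) {
  if (is.data.frame(file)) {
    df <- file
    names(df)[names(df) == "genoName"] <- "chrom"
    names(df)[names(df) == "genoStart"] <- "start"
    names(df)[names(df) == "genoEnd"] <- "end"
    names(df)[names(df) == "repName"] <- "rep_name"
    names(df)[names(df) == "id"] <- "element_id"
    if (!"rep_class_family" %in% names(df) &&
        all(c("repClass", "repFamily") %in% names(df))) {
      df$rep_class_family <- paste(df$repClass, df$repFamily, sep = "/")
    }
  } else {
    first <- readLines(file, n = 1L)
    fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
    has_header <- length(fields) >= 2 && is.na(suppressWarnings(as.numeric(fields[2])))
    raw <- utils::read.table(file, sep = "\t", header = has_header,
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "")
    if (!has_header) {
      nm <- c("chrom", "start", "end", "strand", "rep_name",
              "rep_class_family", "element_id")
      if (ncol(raw) < length(nm)) {
        stop("annotation table has ", ncol(raw), " columns; expected >= 7")
      }
      names(raw)[seq_along(nm)] <- nm
    } else {
      names(raw)[names(raw) == "genoName"] <- "chrom"
      names(raw)[names(raw) == "genoStart"] <- "start"
      names(raw)[names(raw) == "genoEnd"] <- "end"
      names(raw)[names(raw) == "repName"] <- "rep_name"
      names(raw)[names(raw) == "id"] <- "element_id"
      if (!"rep_class_family" %in% names(raw) &&
          all(c("repClass", "repFamily") %in% names(raw))) {
        raw$rep_class_family <- paste(raw$repClass, raw$repFamily, sep = "/")
      }
    }
    df <- raw
  }
  need <- c("chrom", "start", "end", "strand", "rep_name",
            "rep_class_family", "element_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation is missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[need]
  df$start <- suppressWarnings(as.integer(df$start))
  df$end <- suppressWarnings(as.integer(df$end))
  df$element_id <- suppressWarnings(as.integer(df$element_id))
  bad <- which(is.na(df$start) | is.na(df$end) | is.na(df$element_id) |
                 df$start >= df$end | df$element_id < 0)
  if (length(bad)) {
    stop("malformed annotation row at line ", bad[1],
         " (non-numeric or inverted coordinates, or negative id)")
  }
  badstrand <- which(!df$strand %in% c("+", "-"))
  if (length(badstrand)) {
    stop("unknown strand symbol '", df$strand[badstrand[1]],
         "' at line ", badstrand[1])
  }
  if (iap_only) df <- df[df$rep_name %in% registry$iap_types, , drop = FALSE]
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Classify the structure of one element
#'
#' An element is `FULL` (fully-structured) when its internal portion is
#' flanked by LTR subelements at both element-relative ends, `SOLO_LTR` when
#' it consists of LTR subelement(s) only, and fragmented otherwise:
#' `FRAG_NO5` / `FRAG_NO3` when exactly one flanking LTR is missing (5' and
#' 3' are strand-aware), `FRAG_INTERNAL_ONLY` when only internal portions are
#' annotated, and `FRAG_OTHER` for remaining arrangements (e.g. an LTR
#' sandwiched between internal portions).
#'
#' @param features data frame of the element's rows (same chrom and strand).
#' @param registry an [iap_registry].
#' @return a single string, one of `FULL`, `SOLO_LTR`, `FRAG_NO5`,
#'   `FRAG_NO3`, `FRAG_INTERNAL_ONLY`, `FRAG_OTHER`.
#' @export
classify_structure <- function(features, registry = default_iap_registry()) {
  if (nrow(features) == 0L) stop("cannot classify an element with no features")
  ord <- order(features$start)
  if (features$strand[1] == "-") ord <- rev(ord)  # element orientation, 5' first
  role <- subelement_role(features$rep_name[ord], registry)
  if (all(role == "ltr")) return("SOLO_LTR")
  if (all(role == "internal")) return("FRAG_INTERNAL_ONLY")
  first_ltr <- role[1] == "ltr"
  last_ltr <- role[length(role)] == "ltr"
  if (first_ltr && last_ltr) return("FULL")
  if (first_ltr) return("FRAG_NO3")
  if (last_ltr) return("FRAG_NO5")
  "FRAG_OTHER"
}

structure_levels <- c("FULL", "SOLO_LTR", "FRAG_NO5", "FRAG_NO3",
                      "FRAG_INTERNAL_ONLY", "FRAG_OTHER")

## Rebuild the element table from the features + group index column `.elem`.
rebuild_elements <- function(features, registry) {
  if (nrow(features) == 0L) {
    return(data.frame(elem = integer(), element_id = integer(),
                      chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      structure = character(), n_features = integer(),
                      subelements = character(), stringsAsFactors = FALSE))
  }
  idx <- split(seq_len(nrow(features)), features$.elem)
  rows <- lapply(idx, function(i) {
    f <- features[i, , drop = FALSE]
    f <- f[order(f$start), , drop = FALSE]
    ord_names <- if (f$strand[1] == "-") rev(f$rep_name) else f$rep_name
    data.frame(
      elem = f$.elem[1],
      element_id = min(f$element_id),
      chrom = f$chrom[1],
      strand = f$strand[1],
      start = min(f$start),
      end = max(f$end),
      structure = classify_structure(f, registry),
      n_features = nrow(f),
      subelements = paste(ord_names, collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  el <- do.call(rbind, rows)
  el <- el[order(el$chrom, el$start, el$end), , drop = FALSE]
  rownames(el) <- NULL
  el
}

new_rm_catalogue <- function(features, registry) {
  structure(list(features = features,
                 elements = rebuild_elements(features, registry),
                 registry = registry),
            class = "rm_catalogue")
}

#' Group annotation features into repeat elements
#'
#' Features sharing an element ID are grouped into one element.  RepeatMasker
#' reuses IDs across loci, so groups are additionally split on chromosome or
#' strand changes (with a warning) and on intra-ID gaps larger than
#' `max_intra_gap` (guard against absurd elements).
#'
#' @param features data frame from [parse_rm_annotation()].
#' @param registry an [iap_registry].
#' @param max_intra_gap split a group when consecutive features are further
#'   apart than this many bp (default 50000).
#' @return An object of class `rm_catalogue`: list with `features` (the input
#'   rows plus a group index column `.elem`), `elements` (one row per element
#'   with envelope, structure and subelement string) and `registry`.
#' @export
group_into_elements <- function(features, registry = default_iap_registry(),
                                max_intra_gap = 50000L) {
  features <- features[order(features$chrom, features$start, features$end), ,
                       drop = FALSE]
  rownames(features) <- NULL
  if (nrow(features) == 0L) {
    features$.elem <- integer(0)
    return(new_rm_catalogue(features, registry))
  }
  ## group on (id, chrom, strand): features of one id may be interleaved with
  ## nested insertions of other elements, so runs of sorted rows won't do
  key <- paste(features$element_id, features$chrom, features$strand)
  per_id <- split(paste(features$chrom, features$strand), features$element_id)
  multi <- names(per_id)[vapply(per_id, function(x) length(unique(x)) > 1, logical(1))]
  if (length(multi)) {
    warning("element id(s) ", paste(utils::head(multi, 5), collapse = ", "),
            if (length(multi) > 5) ", ..." else "",
            " span multiple chromosomes/strands; split into separate elements")
  }
  elem <- integer(nrow(features))
  nxt <- 0L
  for (idx in split(seq_len(nrow(features)), key)) {
    ## idx is sorted by start already; split further on large intra-id gaps
    s <- features$start[idx]
    e <- cummax(features$end[idx])
    brk <- c(TRUE, s[-1L] - e[-length(e)] > max_intra_gap)
    grp <- cumsum(brk)
    elem[idx] <- nxt + grp
    nxt <- nxt + max(grp)
  }
  features$.elem <- elem
  new_rm_catalogue(features, registry)
}

#' Patch elements split at 500 kb boundaries
#'
#' The rmsk table is produced in 500 kb bins, so an element spanning a bin
#' boundary appears as two entries with separate element IDs, one ending
#' exactly at a multiple of `boundary_interval` and the other starting there.
#' Such pairs (same chromosome and strand) are unified under one element ID.
#' The match is exact (slack 0): the artefact is a binning artefact.
#'
#' @param catalogue an `rm_catalogue`.
#' @param boundary_interval bin width in bp (default 500,000).
#' @return the patched `rm_catalogue`.
#' @export
patch_boundary_splits <- function(catalogue, boundary_interval = 500000L) {
  stopifnot(inherits(catalogue, "rm_catalogue"))
  el <- catalogue$elements
  if (nrow(el) < 2L) return(catalogue)
  feats <- catalogue$features
  repeat {
    merged <- FALSE
    el <- el[order(el$chrom, el$start, el$end), , drop = FALSE]
    for (i in seq_len(nrow(el) - 1L)) {
      a <- el[i, ]; b <- el[i + 1L, ]
      if (a$chrom == b$chrom && a$strand == b$strand &&
          a$elem != b$elem &&
          a$end == b$start && a$end %% boundary_interval == 0L) {
        feats$.elem[feats$.elem == b$elem] <- a$elem
        merged <- TRUE
        break
      }
    }
    if (!merged) break
    el <- rebuild_elements(feats, catalogue$registry)
  }
  new_rm_catalogue(feats, catalogue$registry)
}

## Strand-aware missing-flank flags for an element row.
missing_flanks <- function(structure) {
  switch(structure,
         FULL = c(five = FALSE, three = FALSE),
         SOLO_LTR = c(five = FALSE, three = FALSE),
         FRAG_NO5 = c(five = TRUE, three = FALSE),
         FRAG_NO3 = c(five = FALSE, three = TRUE),
         FRAG_INTERNAL_ONLY = c(five = TRUE, three = TRUE),
         FRAG_OTHER = c(five = TRUE, three = TRUE),
         stop("unknown structure ", structure))
}

is_fragmented <- function(structure) {
  !structure %in% c("FULL", "SOLO_LTR")
}

## Find the best merge partner for element `i` at `edge` ("five"/"three").
## Returns the row index of the partner in `el` or NA.  `blocked` marks
## elements already consumed this pass.
find_mend_partner <- function(el, i, edge, max_gap, blocked) {
  e <- el[i, ]
  ## genomic side of the requested element-relative edge
  left_side <- (edge == "five") == (e$strand == "+")
  cand <- which(el$chrom == e$chrom & el$strand == e$strand &
                  seq_len(nrow(el)) != i & !blocked)
  if (!length(cand)) return(NA_integer_)
  if (left_side) {
    gap <- e$start - el$end[cand]
    onside <- el$start[cand] < e$start
  } else {
    gap <- el$start[cand] - e$end
    onside <- el$end[cand] > e$end
  }
  ok <- onside & gap <= max_gap
  cand <- cand[ok]; gap <- gap[ok]
  if (!length(cand)) return(NA_integer_)
  ## partner must be missing the LTR facing AWAY from us: for our missing 5'
  ## LTR the upstream partner missing its own 3' LTR ranks first, then a solo
  ## LTR, then a fully-structured element.
  facing_missing <- if (edge == "five") "three" else "five"
  rank <- vapply(cand, function(j) {
    s <- el$structure[j]
    if (is_fragmented(s) && missing_flanks(s)[[facing_missing]]) 1L
    else if (s == "SOLO_LTR") 2L
    else if (s == "FULL") 3L
    else NA_integer_  # fragmented partner with the facing LTR present: no rule
  }, integer(1))
  keep <- !is.na(rank)
  cand <- cand[keep]; gap <- gap[keep]; rank <- rank[keep]
  if (!length(cand)) return(NA_integer_)
  ## heuristic order first, then nearest, then 5'-most in element orientation
  fivemost <- if (e$strand == "+") el$start[cand] else -el$end[cand]
  cand[order(rank, gap, fivemost)][1]
}

#' Mend fragmented elements
#'
#' Attempts to restore fully-structured elements from annotation fragments.
#' For each fragmented element missing a 5' LTR the heuristic tries, in
#' order: (1) merging with an adjacent fragmented element missing a 3' LTR;
#' (2) merging with an adjacent solo LTR; (3) merging with an adjacent
#' fully-structured element (which may produce a double or higher-order
#' fully-structured element).  The symmetric procedure applies to a missing
#' 3' LTR, and elements annotated as internal-only are mended on both edges.
#' A partner qualifies when the facing envelope boundaries are within
#' `max_gap` bp (overlapping envelopes count as adjacent); merging never
#' crosses a chromosome or strand.
#'
#' Fragmented elements are processed in genomic order; within one element the
#' 5' mend is attempted before the 3' mend; each partner is consumed at most
#' once per pass; passes repeat until a fixpoint, so chains of fragments
#' coalesce.  Ties among equally ranked partners go to the nearest, then the
#' 5'-most.
#'
#' @param catalogue an `rm_catalogue`.
#' @param max_gap maximum gap in bp between facing boundaries (default 2000).
#' @param registry an [iap_registry]; defaults to the catalogue's own.
#' @return the mended `rm_catalogue` (feature rows unchanged, regrouped).
#' @export
mend_fragmented <- function(catalogue, max_gap = 2000L, registry = NULL) {
  stopifnot(inherits(catalogue, "rm_catalogue"))
  if (is.null(registry)) registry <- catalogue$registry
  feats <- catalogue$features
  el <- rebuild_elements(feats, registry)
  repeat {
    changed <- FALSE
    blocked <- rep(FALSE, nrow(el))
    ## union of elem groups accumulated this pass
    union_to <- stats::setNames(el$elem, as.character(el$elem))
    for (i in seq_len(nrow(el))) {
      if (blocked[i] || !is_fragmented(el$structure[i])) next
      miss <- missing_flanks(el$structure[i])
      for (edge in c("five", "three")) {
        if (!miss[[edge]]) next
        j <- find_mend_partner(el, i, edge, max_gap, blocked)
        if (is.na(j)) next
        union_to[as.character(el$elem[j])] <- union_to[[as.character(el$elem[i])]]
        blocked[j] <- TRUE
        blocked[i] <- TRUE  # no longer available as someone else's partner
        changed <- TRUE
      }
    }
    if (!changed) break
    ## resolve unions (partner chains point through union_to)
    resolve <- function(x) {
      seen <- character(0)
      key <- as.character(x)
      while (union_to[[key]] != x) {
        seen <- c(seen, key)
        x <- union_to[[key]]
        key <- as.character(x)
      }
      x
    }
    feats$.elem <- vapply(feats$.elem, resolve, numeric(1))
    el <- rebuild_elements(feats, registry)
  }
  new_rm_catalogue(feats, registry)
}

#' Summarise a repeat catalogue
#'
#' @param catalogue an `rm_catalogue`.
#' @return An object of class `catalogue_summary`: list with `n_elements`,
#'   `n_full`, `n_solo_ltr`, `n_fragmented` and `fragmented_fraction`
#'   (0 when the catalogue is empty).
#' @export
summarize_catalogue <- function(catalogue) {
  stopifnot(inherits(catalogue, "rm_catalogue"))
  s <- catalogue$elements$structure
  n <- length(s)
  n_full <- sum(s == "FULL")
  n_solo <- sum(s == "SOLO_LTR")
  n_frag <- n - n_full - n_solo
  structure(list(
    n_elements = n,
    n_full = n_full,
    n_solo_ltr = n_solo,
    n_fragmented = n_frag,
    fragmented_fraction = if (n == 0L) 0 else n_frag / n
  ), class = "catalogue_summary")
}

#' @export
print.catalogue_summary <- function(x, ...) {
  cat("Repeat catalogue:", x$n_elements, "elements\n")
  cat(sprintf("  fully-structured: %d\n  solo LTR:         %d\n", x$n_full,
              x$n_solo_ltr))
  cat(sprintf("  fragmented:       %d (%.1f%%)\n", x$n_fragmented,
              100 * x$fragmented_fraction))
  invisible(x)
}

#' @export
print.rm_catalogue <- function(x, ...) {
  cat("rm_catalogue:", nrow(x$elements), "elements /", nrow(x$features),
      "annotation features\n")
  print(summary(x))
  invisible(x)
}

#' @export
summary.rm_catalogue <- function(object, ...) summarize_catalogue(object)

#' @export
as.data.frame.rm_catalogue <- function(x, ...) x$elements

#' Write / read a mended catalogue
#'
#' The element-level TSV has one row per element: `element_id`, `chrom`,
#' `start`, `end`, `strand`, `structure` and the comma-joined subelement
#' names (5' to 3' in element orientation).  Coordinates are 0-based
#' half-open.  `write_catalogue_bed` exports element envelopes as BED6 with
#' the element ID in the name column.
#'
#' @param catalogue an `rm_catalogue`.
#' @param path output/input file path.
#' @return `read_catalogue` returns the element data frame.
#' @export
write_catalogue <- function(catalogue, path) {
  el <- catalogue$elements
  out <- el[c("element_id", "chrom", "start", "end", "strand", "structure",
              "subelements")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalogue
#' @export
read_catalogue <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("element_id", "chrom", "start", "end", "strand", "structure")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("catalogue file missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' @rdname write_catalogue
#' @export
write_catalogue_bed <- function(catalogue, path) {
  el <- if (inherits(catalogue, "rm_catalogue")) catalogue$elements else catalogue
  bed <- data.frame(el$chrom, el$start, el$end,
                    paste0("element_", el$element_id), 0L, el$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
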