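#' Screen parameters
#'
#' Thresholds for the edge-methylation variability screen.  Defaults follow
#' the IAP screen: the mean of the 8 CpGs nearest each LTR edge, a sample
#' being informative at an edge only with at least 20 methylation calls over
#' those CpGs and at least 4 CpGs covered, an edge surviving only with at
#' least 5 informative samples in every cell type, and a candidate calling
#' threshold of a 10% inter-individual methylation range.
#'
#' @param n_edge_cpgs CpGs per edge window (default 8).
#' @param min_calls minimum methylation calls across the window (default 20).
#' @param min_covered_cpgs minimum covered CpGs in the window (default 4).
#' @param min_informative_samples minimum informative samples per group
#'   (default 5).
#' @param range_threshold candidate threshold on the screen statistic
#'   (default 0.10).
#' @param edge_max_dist optional cap (bp) on the distance of a window CpG
#'   from the edge; unset for the IAP screen, 200 for the LINE/SINE/non-ERV
#'   screen.
#' @param statistic how per-group ranges combine into the screen statistic:
#'   `"min"` (variability required in every group; default) or `"max"`.
#' @param mean_method `"pooled"` (sum of methylated calls over sum of all
#'   calls; default) or `"per_cpg"` (mean of per-CpG fractions).
#' @return list of class `screen_params`.
#' @export
screen_params <- function(n_edge_cpgs = 8L, min_calls = 20L,
                          min_covered_cpgs = 4L,
                          min_informative_samples = 5L,
                          range_threshold = 0.10, edge_max_dist = NULL,
                          statistic = c("min", "max"),
                          mean_method = c("pooled", "per_cpg")) {
  statistic <- match.arg(statistic)
  mean_method <- match.arg(mean_method)
  stopifnot(n_edge_cpgs >= 1, min_calls >= 1, min_covered_cpgs >= 1,
            min_informative_samples >= 1,
            range_threshold > 0, range_threshold < 1)
  structure(list(n_edge_cpgs = as.integer(n_edge_cpgs),
                 min_calls = as.integer(min_calls),
                 min_covered_cpgs = as.integer(min_covered_cpgs),
                 min_informative_samples = as.integer(min_informative_samples),
                 range_threshold = range_threshold,
                 edge_max_dist = edge_max_dist,
                 statistic = statistic,
                 mean_method = mean_method),
            class = "screen_params")
}

#' Edge CpG windows of an element
#'
#' For each outward-facing edge of the element, the `n_edge_cpgs` CpGs inside
#' the element nearest that edge (and, when `edge_max_dist` is set, within
#' that many bp of it).  Fewer CpGs are returned when the element contains
#' fewer; an element without internal CpGs yields empty windows.  Edges are
#' element-relative: the `five_prime` edge of a minus-strand element is its
#' genomic right end.
#'
#' @param element one element row (`chrom`, `start`, `end`, `strand`).
#' @param cpg_positions integer vector of 0-based CpG positions on the
#'   element's chromosome (sorted).
#' @param params a [screen_params()] object.
#' @return list with sorted position vectors `five_prime` and `three_prime`.
#' @export
build_edge_windows <- function(element, cpg_positions,
                               params = screen_params()) {
  inside <- cpg_positions[cpg_positions >= element$start &
                            cpg_positions < element$end]
  pick <- function(dist) {
    ok <- seq_along(inside)
    if (!is.null(params$edge_max_dist)) ok <- ok[dist[ok] <= params$edge_max_dist]
    ok <- ok[order(dist[ok])]
    sort(inside[utils::head(ok, params$n_edge_cpgs)])
  }
  d_left <- inside - element$start
  d_right <- (element$end - 1L) - inside
  if (identical(element$strand, "-")) {
    list(five_prime = pick(d_right), three_prime = pick(d_left))
  } else {
    list(five_prime = pick(d_left), three_prime = pick(d_right))
  }
}

#' Per-sample edge methylation summary
#'
#' Pools methylation calls over the window CpGs for one sample: the edge mean
#' is the pooled-count mean (sum of methylated calls over sum of all calls)
#' by default, and the sample is informative at the edge when it has at least
#' `min_calls` calls and at least `min_covered_cpgs` covered CpGs.
#'
#' @param window sorted CpG positions (from [build_edge_windows()]).
#' @param calls coverage data frame for the sample restricted to the
#'   element's chromosome (`pos`, `n_meth`, `n_unmeth`), as from
#'   [read_coverage()].
#' @param params a [screen_params()] object.
#' @return list with `mean_meth` (NA when no calls), `total_calls`,
#'   `covered_cpgs`, `informative`.
#' @export
sample_edge_methylation <- function(window, calls, params = screen_params()) {
  i <- match(window, calls$pos)
  i <- i[!is.na(i)]
  m <- calls$n_meth[i]
  u <- calls$n_unmeth[i]
  tot <- m + u
  covered <- sum(tot > 0)
  total_calls <- sum(tot)
  mean_meth <- if (total_calls == 0) NA_real_
  else if (params$mean_method == "pooled") sum(m) / total_calls
  else mean((m / tot)[tot > 0])
  list(mean_meth = mean_meth,
       total_calls = total_calls,
       covered_cpgs = covered,
       informative = total_calls >= params$min_calls &&
         covered >= params$min_covered_cpgs)
}

#' Per-cell-type methylation range at one edge
#'
#' Ranges (max minus min, no trimming of extremes) are computed over the
#' informative samples of each group.  The edge passes the sample filter when
#' every group has at least `min_informative_samples` informative samples;
#' the screen statistic combines the group ranges (minimum by default) and
#' the edge is a candidate when it passes the filter and the statistic
#' reaches `range_threshold`.
#'
#' @param summaries data frame with one row per sample: columns `group`,
#'   `mean_meth`, `informative`.
#' @param params a [screen_params()] object.
#' @param groups optional group levels (defaults to those present).
#' @return list with per-group `n_informative` and `range` (named vectors),
#'   `passed_sample_filter`, `statistic` (NA when the filter fails) and
#'   `candidate`.
#' @export
edge_range <- function(summaries, params = screen_params(), groups = NULL) {
  if (is.null(groups)) groups <- sort(unique(summaries$group))
  n_inf <- numeric(0); rng <- numeric(0)
  for (g in groups) {
    s <- summaries[summaries$group == g & summaries$informative, , drop = FALSE]
    n_inf[[g]] <- nrow(s)
    rng[[g]] <- if (nrow(s) == 0L) NA_real_
    else max(s$mean_meth) - min(s$mean_meth)
  }
  passed <- all(n_inf >= params$min_informative_samples)
  stat <- if (!passed) NA_real_
  else if (params$statistic == "min") min(rng) else max(rng)
  list(n_informative = n_inf, range = rng,
       passed_sample_filter = passed,
       statistic = stat,
       candidate = passed && stat >= params$range_threshold)
}

## per-chromosome count matrices (positions x samples) for fast window sums
coverage_matrices <- function(coverage, cpg_positions) {
  chroms <- names(cpg_positions)
  sample_ids <- names(coverage)
  out <- list()
  for (ch in chroms) {
    pos <- sort(unique(cpg_positions[[ch]]))
    M <- matrix(0L, length(pos), length(sample_ids),
                dimnames = list(NULL, sample_ids))
    U <- M
    for (s in sample_ids) {
      cc <- coverage[[s]]
      cc <- cc[cc$chrom == ch, , drop = FALSE]
      i <- match(cc$pos, pos)
      keep <- !is.na(i)
      M[i[keep], s] <- cc$n_meth[keep]
      U[i[keep], s] <- cc$n_unmeth[keep]
    }
    out[[ch]] <- list(pos = pos, meth = M, unmeth = U)
  }
  out
}

#' Screen a repeat catalogue for variably methylated elements
#'
#' Runs the edge-methylation variability screen over every element: builds
#' the outward-edge CpG windows, summarises each sample's edge methylation,
#' applies the informativeness and sample-count filters, computes per-group
#' inter-individual ranges, and ranks edges by the screen statistic.  An
#' element is a candidate when any of its edges is.
#'
#' @param catalogue an `rm_catalogue`, or an element data frame with columns
#'   `element_id`, `chrom`, `start`, `end`, `strand` (e.g. from
#'   [read_catalogue()] or [prepare_non_iap_elements()]).
#' @param coverage named list (by `sample_id`) of coverage data frames from
#'   [read_coverage()].
#' @param samples data frame with `sample_id` and `group`.
#' @param params a [screen_params()] object.
#' @param cpg_positions optional named list (per chromosome) of 0-based CpG
#'   positions, e.g. from [find_cpg_sites()].  When `NULL`, the union of
#'   covered positions across samples is used.
#' @return object of class `vm_screen`: list with `edges` (one row per edge,
#'   ranked by statistic), `sample_edges` (the per-sample audit table),
#'   `samples` and `params`.
#' @export
screen_catalogue <- function(catalogue, coverage, samples,
                             params = screen_params(),
                             cpg_positions = NULL) {
  el <- if (inherits(catalogue, "rm_catalogue")) catalogue$elements
  else catalogue
  if (nrow(samples) == 0L) stop("no samples supplied")
  miss <- setdiff(samples$sample_id, names(coverage))
  if (length(miss)) stop("coverage missing for sample(s): ",
                         paste(miss, collapse = ", "))
  samples <- samples[order(samples$sample_id), , drop = FALSE]
  coverage <- coverage[samples$sample_id]
  ## accept raw six-column-dialect frames as well as read_coverage() output
  coverage <- lapply(coverage, function(cc) {
    if (!"pos" %in% names(cc)) read_coverage(cc) else cc
  })
  groups <- sort(unique(samples$group))
  if (is.null(cpg_positions)) {
    cpg_positions <- list()
    for (s in names(coverage)) {
      cc <- coverage[[s]]
      for (ch in unique(cc$chrom)) {
        cpg_positions[[ch]] <- c(cpg_positions[[ch]], cc$pos[cc$chrom == ch])
      }
    }
    cpg_positions <- lapply(cpg_positions, function(p) sort(unique(p)))
  }
  missing_chroms <- setdiff(unique(el$chrom), names(cpg_positions))
  if (length(missing_chroms)) {
    warning("no CpG/coverage information for chromosome(s): ",
            paste(missing_chroms, collapse = ", "))
  }
  mats <- coverage_matrices(coverage, cpg_positions)
  edge_rows <- list()
  audit_rows <- list()
  for (i in seq_len(nrow(el))) {
    e <- el[i, ]
    mat <- mats[[e$chrom]]
    pos_here <- if (is.null(mat)) integer(0) else mat$pos
    win <- build_edge_windows(e, pos_here, params)
    for (edge in c("five_prime", "three_prime")) {
      w <- win[[edge]]
      ridx <- match(w, pos_here)
      if (length(ridx)) {
        m <- mat$meth[ridx, , drop = FALSE]
        u <- mat$unmeth[ridx, , drop = FALSE]
        tot <- m + u
        total_calls <- colSums(tot)
        covered <- colSums(tot > 0)
        mean_meth <- if (params$mean_method == "pooled") {
          ifelse(total_calls > 0, colSums(m) / pmax(total_calls, 1L), NA_real_)
        } else {
          frac <- m / tot
          apply(frac, 2, function(x) if (all(is.na(x))) NA_real_
                else mean(x, na.rm = TRUE))
        }
      } else {
        ns <- nrow(samples)
        total_calls <- stats::setNames(rep(0L, ns), samples$sample_id)
        covered <- total_calls
        mean_meth <- stats::setNames(rep(NA_real_, ns), samples$sample_id)
      }
      informative <- total_calls >= params$min_calls &
        covered >= params$min_covered_cpgs
      summ <- data.frame(sample_id = samples$sample_id,
                         group = samples$group,
                         mean_meth = as.numeric(mean_meth),
                         total_calls = as.integer(total_calls),
                         covered_cpgs = as.integer(covered),
                         informative = as.logical(informative),
                         stringsAsFactors = FALSE)
      er <- edge_range(summ, params, groups = groups)
      row <- data.frame(element_id = e$element_id, chrom = e$chrom,
                        start = e$start, end = e$end, strand = e$strand,
                        edge = edge, n_window_cpgs = length(w),
                        stringsAsFactors = FALSE)
      for (g in groups) {
        row[[paste0("n_informative_", g)]] <- er$n_informative[[g]]
        row[[paste0("range_", g)]] <- er$range[[g]]
      }
      row$passed_sample_filter <- er$passed_sample_filter
      row$statistic <- er$statistic
      row$candidate <- er$candidate
      edge_rows[[length(edge_rows) + 1L]] <- row
      summ$element_id <- e$element_id
      summ$edge <- edge
      audit_rows[[length(audit_rows) + 1L]] <- summ
    }
  }
  edges <- do.call(rbind, edge_rows)
  edges <- edges[order(-ifelse(is.na(edges$statistic), -Inf, edges$statistic),
                       edges$element_id), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 sample_edges = do.call(rbind, audit_rows),
                 samples = samples, params = params),
            class = "vm_screen")
}

#' Candidate elements of a screen
#'
#' @param screen a `vm_screen` object.
#' @return data frame of candidate elements (best edge per element), ranked
#'   by the screen statistic.
#' @export
screen_candidates <- function(screen) {
  e <- screen$edges[screen$edges$candidate %in% TRUE, , drop = FALSE]
  e[!duplicated(e$element_id), , drop = FALSE]
}

#' @export
print.vm_screen <- function(x, ...) {
  e <- x$edges
  cat("VM screen:", length(unique(e$element_id)), "elements,",
      nrow(e), "edges\n")
  cat("  edges passing sample filter:", sum(e$passed_sample_filter), "\n")
  cat("  candidate edges (range >=", x$params$range_threshold, "):",
      sum(e$candidate), "in", nrow(screen_candidates(x)), "elements\n")
  invisible(x)
}

#' @export
summary.vm_screen <- function(object, ...) {
  e <- object$edges
  list(n_elements = length(unique(e$element_id)),
       n_edges = nrow(e),
       n_passed_filter = sum(e$passed_sample_filter),
       n_candidate_edges = sum(e$candidate),
       n_candidate_elements = nrow(screen_candidates(object)))
}

#' Write screen outputs
#'
#' @param screen a `vm_screen`.
#' @param path output TSV (edge table) path.
#' @export
write_screen_table <- function(screen, path) {
  utils::write.table(screen$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Prepare non-IAP repeat elements for screening
#'
#' For LINE, SINE and non-ERV LTR screens the annotation is only repaired by
#' combining adjacent features of the same class on the same strand within
#' `max_join_gap` bp of each other; windows for these elements should use the
#' first CpGs within 200 bp of each edge (`screen_params(edge_max_dist =
#' 200)`).
#'
#' @param features data frame from [parse_rm_annotation()] (one repeat
#'   class).
#' @param max_join_gap joining distance in bp (default 100).
#' @return element data frame (`element_id`, `chrom`, `start`, `end`,
#'   `strand`, `structure = "JOINED"`, `n_features`) usable with
#'   [screen_catalogue()].
#' @export
prepare_non_iap_elements <- function(features, max_join_gap = 100L) {
  if (nrow(features) == 0L) {
    return(data.frame(element_id = integer(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      structure = character(), n_features = integer()))
  }
  f <- features[order(features$chrom, features$strand,
                      features$rep_class_family, features$start), , drop = FALSE]
  same <- c(FALSE, f$chrom[-1L] == f$chrom[-nrow(f)] &
              f$strand[-1L] == f$strand[-nrow(f)] &
              f$rep_class_family[-1L] == f$rep_class_family[-nrow(f)])
  grp <- integer(nrow(f))
  grp[1] <- 1L
  cur_end <- f$end[1]
  for (i in seq_len(nrow(f))[-1L]) {
    if (same[i] && f$start[i] - cur_end <= max_join_gap) {
      grp[i] <- grp[i - 1L]
      cur_end <- max(cur_end, f$end[i])
    } else {
      grp[i] <- grp[i - 1L] + 1L
      cur_end <- f$end[i]
    }
  }
  el <- do.call(rbind, lapply(split(seq_len(nrow(f)), grp), function(i) {
    data.frame(element_id = min(f$element_id[i]), chrom = f$chrom[i][1],
               start = min(f$start[i]), end = max(f$end[i]),
               strand = f$strand[i][1], structure = "JOINED",
               n_features = length(i), stringsAsFactors = FALSE)
  }))
  el <- el[order(el$chrom, el$start), , drop = FALSE]
  rownames(el) <- NULL
  el
}
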