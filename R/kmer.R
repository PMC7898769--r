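#' K-mer enrichment parameters
#'
#' Defaults follow the LTR sequence-enrichment procedure: 15-mers present in
#' two or more foreground LTRs, kept when present in at least 5 foreground
#' LTRs with at least 20-fold enrichment over the background set, assembled
#' by k-1 overlap, trimmed to the enrichment-maximising substring of length
#' at least 10, and flagged against a 2% genome-wide presence cap.
#'
#' @param k k-mer length (default 15, must be >= 2).
#' @param min_initial_presence minimum foreground presence to enumerate a
#'   k-mer (default 2).
#' @param min_filter_presence minimum foreground presence to keep a k-mer
#'   (default 5).
#' @param min_fold minimum fold enrichment to keep a k-mer (default 20).
#' @param max_bg_fraction cap on the fraction of all LTRs containing a final
#'   sequence (default 0.02).
#' @param pseudocount added to a zero background presence when computing fold
#'   enrichment (default 0.5).
#' @param trim_min_len minimum trimmed sequence length (default 10).
#' @param canonical count k-mers jointly with their reverse complements
#'   (default FALSE: LTR regulatory sequence is orientation-specific and all
#'   sequences are oriented 5' to 3').
#' @return list of class `kmer_params`.
#' @export
kmer_params <- function(k = 15L, min_initial_presence = 2L,
                        min_filter_presence = 5L, min_fold = 20,
                        max_bg_fraction = 0.02, pseudocount = 0.5,
                        trim_min_len = 10L, canonical = FALSE) {
  if (k < 2) stop("k must be >= 2")
  stopifnot(min_initial_presence >= 1, min_filter_presence >= 1,
            min_fold > 0, max_bg_fraction > 0, pseudocount > 0,
            trim_min_len >= 1)
  structure(list(k = as.integer(k),
                 min_initial_presence = as.integer(min_initial_presence),
                 min_filter_presence = as.integer(min_filter_presence),
                 min_fold = min_fold, max_bg_fraction = max_bg_fraction,
                 pseudocount = pseudocount,
                 trim_min_len = as.integer(trim_min_len),
                 canonical = canonical),
            class = "kmer_params")
}

## unique k-mers of one sequence (k-mers containing non-ACGT skipped)
seq_kmers <- function(seq, k, canonical = FALSE) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  km <- substring(seq, 1:(n - k + 1L), k:n)
  km <- km[!grepl("[^ACGT]", km)]
  if (canonical) {
    rc <- vapply(km, revcomp, character(1), USE.NAMES = FALSE)
    km <- pmin(km, rc)
  }
  unique(km)
}

#' Presence counts of k-mers across sequences
#'
#' Presence counting: a k-mer counts once per sequence regardless of how
#' often it occurs within it.  Sequences shorter than `k` contribute nothing;
#' k-mers containing a non-ACGT character are skipped.  No reverse-complement
#' canonicalisation is applied unless `canonical = TRUE`.
#'
#' @param sequences character vector of sequences oriented 5' to 3'.
#' @param k k-mer length (>= 2).
#' @param canonical see [kmer_params()].
#' @return named integer vector: presence count per k-mer.
#' @export
kmer_presence_counts <- function(sequences, k, canonical = FALSE) {
  if (k < 2) stop("k must be >= 2")
  sequences <- toupper(as.character(sequences))
  all_km <- unlist(lapply(sequences, seq_kmers, k = k, canonical = canonical),
                   use.names = FALSE)
  if (!length(all_km)) return(stats::setNames(integer(0), character(0)))
  tab <- table(all_km)
  stats::setNames(as.integer(tab), names(tab))
}

#' Fold enrichment of presence fractions
#'
#' `fold = (fg_presence / n_fg) / (bg_presence / n_bg)`, with `pseudocount`
#' substituted for a zero background presence so that enrichment stays
#' finite; a zero foreground presence gives fold 0.
#'
#' @param fg_presence,bg_presence presence counts (vectorised).
#' @param n_fg,n_bg set sizes (> 0).
#' @param pseudocount see [kmer_params()].
#' @return numeric vector of fold enrichments.
#' @export
fold_enrichment <- function(fg_presence, bg_presence, n_fg, n_bg,
                            pseudocount = 0.5) {
  stopifnot(n_fg > 0, n_bg > 0)
  bg_eff <- ifelse(bg_presence == 0, pseudocount, bg_presence)
  (fg_presence / n_fg) / (bg_eff / n_bg)
}

#' Enumerate and score foreground k-mers against a background
#'
#' Counts k-mer presence in the foreground set, keeps k-mers present in at
#' least `min_initial_presence` foreground sequences, counts their presence
#' in the background set and computes fold enrichment.
#'
#' @param fg_seqs,bg_seqs character vectors of oriented sequences.
#' @param params a [kmer_params()] object.
#' @return data frame `seq`, `fg_presence`, `bg_presence`, `fold` (one row
#'   per enumerated k-mer) with attributes `n_fg`, `n_bg`.
#' @export
enumerate_kmers <- function(fg_seqs, bg_seqs, params = kmer_params()) {
  k <- params$k
  fg_counts <- kmer_presence_counts(fg_seqs, k, params$canonical)
  fg_counts <- fg_counts[fg_counts >= params$min_initial_presence]
  kmers <- names(fg_counts)
  if (length(kmers)) {
    bg_sets <- lapply(toupper(bg_seqs), seq_kmers, k = k,
                      canonical = params$canonical)
    bg_tab <- table(factor(unlist(bg_sets, use.names = FALSE), levels = kmers))
    bg_counts <- as.integer(bg_tab)
  } else {
    bg_counts <- integer(0)
  }
  df <- data.frame(seq = kmers,
                   fg_presence = as.integer(fg_counts),
                   bg_presence = bg_counts,
                   stringsAsFactors = FALSE)
  df$fold <- fold_enrichment(df$fg_presence, df$bg_presence,
                             length(fg_seqs), length(bg_seqs),
                             params$pseudocount)
  attr(df, "n_fg") <- length(fg_seqs)
  attr(df, "n_bg") <- length(bg_seqs)
  rownames(df) <- NULL
  df
}

#' Filter scored k-mers
#'
#' Keeps k-mers present in at least `min_filter_presence` foreground
#' sequences and enriched at least `min_fold`-fold.
#'
#' @param records data frame from [enumerate_kmers()].
#' @param params a [kmer_params()] object.
#' @return the filtered data frame.
#' @export
filter_kmers <- function(records, params = kmer_params()) {
  out <- records[records$fg_presence >= params$min_filter_presence &
                   records$fold >= params$min_fold, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("n_fg", "n_bg")) attr(out, a) <- attr(records, a)
  out
}

## directed k-1 overlap edges among k-mers: a -> b iff suffix(a) == prefix(b)
overlap_edges <- function(kmers, k) {
  pref <- substr(kmers, 1L, k - 1L)
  suf <- substr(kmers, 2L, k)
  from <- integer(0); to <- integer(0)
  by_pref <- split(seq_along(kmers), pref)
  for (i in seq_along(kmers)) {
    j <- by_pref[[suf[i]]]
    j <- j[j != i]
    if (length(j)) {
      from <- c(from, rep(i, length(j)))
      to <- c(to, j)
    }
  }
  cbind(from, to)
}

#' Group k-mers by k-1 overlap
#'
#' Two k-mers are connected when the length-(k-1) suffix of one equals the
#' length-(k-1) prefix of the other (in either direction); groups are the
#' connected components of that graph (singletons allowed).
#'
#' @param kmers character vector of distinct k-mers (all length `k`).
#' @param k k-mer length.
#' @return list of character vectors, one per component, ordered by first
#'   member.
#' @export
group_by_overlap <- function(kmers, k) {
  if (!length(kmers)) return(list())
  stopifnot(all(nchar(kmers) == k))
  ed <- overlap_edges(kmers, k)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ed[, 1]), to = as.character(ed[, 2])),
    directed = TRUE,
    vertices = data.frame(name = as.character(seq_along(kmers))))
  comp <- igraph::components(g, mode = "weak")$membership
  comp <- comp[as.character(seq_along(kmers))]
  unname(lapply(split(kmers, comp), identity))
}

## all simple paths maximising total weight; exhaustive DFS for small
## components, greedy best-extension beyond `exact_limit` nodes
best_overlap_path <- function(kmers, k, weights, exact_limit = 14L) {
  n <- length(kmers)
  if (n == 1L) return(1L)
  ed <- overlap_edges(kmers, k)
  adj <- lapply(seq_len(n), function(i) ed[ed[, 1] == i, 2])
  best <- list(score = -Inf, path = integer(0))
  if (n <= exact_limit) {
    dfs <- function(path, used, score) {
      if (score > best$score ||
          (score == best$score && length(path) > length(best$path))) {
        best <<- list(score = score, path = path)
      }
      for (j in adj[[path[length(path)]]]) {
        if (!used[j]) {
          used[j] <- TRUE
          dfs(c(path, j), used, score + weights[j])
          used[j] <- FALSE
        }
      }
    }
    for (s in seq_len(n)) {
      used <- rep(FALSE, n); used[s] <- TRUE
      dfs(s, used, weights[s])
    }
  } else {
    for (s in seq_len(n)) {
      path <- s; used <- rep(FALSE, n); used[s] <- TRUE
      score <- weights[s]
      repeat {
        nxt <- adj[[path[length(path)]]]
        nxt <- nxt[!used[nxt]]
        if (!length(nxt)) break
        j <- nxt[which.max(weights[nxt])]
        path <- c(path, j); used[j] <- TRUE; score <- score + weights[j]
      }
      if (score > best$score ||
          (score == best$score && length(path) > length(best$path))) {
        best <- list(score = score, path = path)
      }
    }
  }
  best$path
}

#' Merge a k-1 overlap component into extended sequences
#'
#' Lays the k-mers of one component out along a maximal simple path of the
#' directed overlap graph, yielding the shortest superstring consistent with
#' the k-1 overlaps.  On branching graphs the path maximising the total
#' foreground presence of included k-mers wins; members left off the path are
#' regrouped and merged recursively, so every member ends up a substring of
#' some extended sequence.
#'
#' @param kmers character vector: one overlap component.
#' @param k k-mer length.
#' @param weights per-k-mer weights (foreground presence); defaults to 1.
#' @return list of lists, each with `extended_seq` and `members`.
#' @export
merge_component <- function(kmers, k, weights = NULL) {
  if (!length(kmers)) return(list())
  if (is.null(weights)) weights <- rep(1, length(kmers))
  path <- best_overlap_path(kmers, k, weights)
  ext <- kmers[path[1]]
  for (j in path[-1]) ext <- paste0(ext, substr(kmers[j], k, k))
  covered <- vapply(kmers, function(x) grepl(x, ext, fixed = TRUE), logical(1))
  out <- list(list(extended_seq = ext, members = kmers[covered]))
  left <- which(!covered)
  if (length(left)) {
    for (grp in group_by_overlap(kmers[left], k)) {
      w <- weights[left][match(grp, kmers[left])]
      out <- c(out, merge_component(grp, k, w))
    }
  }
  out
}

## presence of a literal subsequence across a sequence set
subseq_presence <- function(pattern, seqs) {
  sum(vapply(seqs, function(s) grepl(pattern, s, fixed = TRUE), logical(1),
             USE.NAMES = FALSE))
}

#' Trim an extended sequence to the enrichment-maximising substring
#'
#' Scores every substring of length at least `trim_min_len` by its fold
#' enrichment (substring presence per sequence, same pseudocount rule as the
#' k-mer stage) in the foreground versus background sets and returns the
#' maximiser.  Ties go to the longer substring, then the 5'-most.  When the
#' extended sequence is shorter than `trim_min_len` it is returned untrimmed
#' with `untrimmed = TRUE`.
#'
#' @param extended_seq the merged sequence.
#' @param fg_seqs,bg_seqs foreground/background sequence sets.
#' @param params a [kmer_params()] object.
#' @return list with `trimmed_seq`, `fg_presence`, `bg_presence`, `fold`,
#'   `untrimmed`.
#' @export
trim_to_max_enrichment <- function(extended_seq, fg_seqs, bg_seqs,
                                   params = kmer_params()) {
  n <- nchar(extended_seq)
  n_fg <- length(fg_seqs); n_bg <- length(bg_seqs)
  score_one <- function(sub) {
    fg <- subseq_presence(sub, fg_seqs)
    bg <- subseq_presence(sub, bg_seqs)
    list(fg = fg, bg = bg,
         fold = fold_enrichment(fg, bg, n_fg, n_bg, params$pseudocount))
  }
  if (n < params$trim_min_len) {
    sc <- score_one(extended_seq)
    return(list(trimmed_seq = extended_seq, fg_presence = sc$fg,
                bg_presence = sc$bg, fold = sc$fold, untrimmed = TRUE))
  }
  best <- NULL
  for (len in seq(n, params$trim_min_len)) {       # longer first
    for (start in seq_len(n - len + 1L)) {         # 5'-most first
      sub <- substr(extended_seq, start, start + len - 1L)
      sc <- score_one(sub)
      if (is.null(best) || sc$fold > best$fold) {
        best <- list(trimmed_seq = sub, fg_presence = sc$fg,
                     bg_presence = sc$bg, fold = sc$fold, untrimmed = FALSE)
      }
    }
  }
  best
}

#' Discover sequences enriched in a foreground LTR set
#'
#' The full procedure: enumerate k-mers present in at least
#' `min_initial_presence` foreground sequences, score fold enrichment against
#' the background set, filter (`min_filter_presence`, `min_fold`), group the
#' survivors by k-1 overlap, merge each group into extended sequence(s), trim
#' each to its enrichment-maximising substring, and deduplicate.  Motifs are
#' ordered by fold (descending), then sequence.
#'
#' @param fg_seqs,bg_seqs character vectors of oriented LTR sequences.
#' @param params a [kmer_params()] object.
#' @param all_seqs optional set of all LTRs genome-wide used for the
#'   `passes_bg_cap` flag (presence in no more than `max_bg_fraction` of
#'   them); defaults to `c(fg_seqs, bg_seqs)`.
#' @return object of class `vm_motifs`: a data frame with one row per motif
#'   (`trimmed_seq`, `extended_seq`, `n_members`, `fg_presence`,
#'   `bg_presence`, `fold`, `all_presence`, `all_fraction`, `passes_bg_cap`,
#'   `untrimmed`) with counts of the enumeration stages in attributes.
#' @export
find_enriched_motifs <- function(fg_seqs, bg_seqs, params = kmer_params(),
                                 all_seqs = NULL) {
  if (is.null(all_seqs)) all_seqs <- c(fg_seqs, bg_seqs)
  if (!length(fg_seqs) || !length(bg_seqs)) {
    out <- data.frame(
      trimmed_seq = character(), extended_seq = character(),
      n_members = integer(), fg_presence = integer(),
      bg_presence = integer(), fold = numeric(), all_presence = integer(),
      all_fraction = numeric(), passes_bg_cap = logical(),
      untrimmed = logical(), stringsAsFactors = FALSE)
    attr(out, "n_kmers_enumerated") <- 0L
    attr(out, "n_kmers_filtered") <- 0L
    attr(out, "n_fg") <- length(fg_seqs)
    attr(out, "n_bg") <- length(bg_seqs)
    class(out) <- c("vm_motifs", "data.frame")
    return(out)
  }
  records <- enumerate_kmers(fg_seqs, bg_seqs, params)
  kept <- filter_kmers(records, params)
  comps <- group_by_overlap(kept$seq, params$k)
  rows <- list()
  for (comp in comps) {
    w <- kept$fg_presence[match(comp, kept$seq)]
    for (m in merge_component(comp, params$k, w)) {
      tr <- trim_to_max_enrichment(m$extended_seq, fg_seqs, bg_seqs, params)
      all_presence <- subseq_presence(tr$trimmed_seq, all_seqs)
      rows[[length(rows) + 1L]] <- data.frame(
        trimmed_seq = tr$trimmed_seq,
        extended_seq = m$extended_seq,
        n_members = length(m$members),
        fg_presence = tr$fg_presence,
        bg_presence = tr$bg_presence,
        fold = tr$fold,
        all_presence = all_presence,
        all_fraction = all_presence / length(all_seqs),
        passes_bg_cap = all_presence / length(all_seqs) <= params$max_bg_fraction,
        untrimmed = tr$untrimmed,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    trimmed_seq = character(), extended_seq = character(),
    n_members = integer(), fg_presence = integer(), bg_presence = integer(),
    fold = numeric(), all_presence = integer(), all_fraction = numeric(),
    passes_bg_cap = logical(), untrimmed = logical(),
    stringsAsFactors = FALSE)
  out <- out[!duplicated(out$trimmed_seq), , drop = FALSE]
  out <- out[order(-out$fold, out$trimmed_seq), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_kmers_enumerated") <- nrow(records)
  attr(out, "n_kmers_filtered") <- nrow(kept)
  attr(out, "n_fg") <- length(fg_seqs)
  attr(out, "n_bg") <- length(bg_seqs)
  class(out) <- c("vm_motifs", "data.frame")
  out
}

#' @export
print.vm_motifs <- function(x, ...) {
  cat("Enriched sequences:", nrow(x), "motif(s) (",
      attr(x, "n_kmers_enumerated"), "k-mers enumerated,",
      attr(x, "n_kmers_filtered"), "kept )\n")
  if (nrow(x)) {
    print.data.frame(utils::head(
      x[c("trimmed_seq", "fg_presence", "bg_presence", "fold",
          "passes_bg_cap")], 10))
  }
  invisible(x)
}

#' Motif presence report
#'
#' Per-motif presence counts and fractions in the foreground, an optional
#' secondary set (e.g. tissue-specific candidates) and the set of all LTRs,
#' plus the aggregate number of foreground sequences containing at least one
#' motif.
#'
#' @param motifs a `vm_motifs` object or character vector of sequences.
#' @param fg_seqs foreground sequences.
#' @param secondary_seqs optional secondary set.
#' @param all_seqs optional genome-wide set (for `passes_bg_cap`).
#' @param params a [kmer_params()] object.
#' @return list with `table` (per-motif counts/fractions) and
#'   `n_fg_with_motif`.
#' @export
presence_report <- function(motifs, fg_seqs, secondary_seqs = NULL,
                            all_seqs = NULL, params = kmer_params()) {
  seqs <- if (is.character(motifs)) motifs else motifs$trimmed_seq
  has_any <- rep(FALSE, length(fg_seqs))
  rows <- lapply(seqs, function(m) {
    hit_fg <- vapply(fg_seqs, grepl, logical(1), pattern = m, fixed = TRUE,
                     USE.NAMES = FALSE)
    has_any <<- has_any | hit_fg
    row <- data.frame(motif = m, fg_presence = sum(hit_fg),
                      fg_fraction = mean(hit_fg), stringsAsFactors = FALSE)
    if (!is.null(secondary_seqs)) {
      p <- subseq_presence(m, secondary_seqs)
      row$secondary_presence <- p
      row$secondary_fraction <- p / length(secondary_seqs)
    }
    if (!is.null(all_seqs)) {
      p <- subseq_presence(m, all_seqs)
      row$all_presence <- p
      row$all_fraction <- p / length(all_seqs)
      row$passes_bg_cap <- p / length(all_seqs) <= params$max_bg_fraction
    }
    row
  })
  tab <- if (length(rows)) do.call(rbind, rows) else data.frame()
  list(table = tab, n_fg_with_motif = sum(has_any))
}
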