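# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive full rescans and plain loops, sharing no
# internals with the package beyond the exported role/structure helpers.

# -- feature construction ----------------------------------------------------

feat <- function(chrom, start, end, strand, rep_name, id,
                 family = "LTR/ERVK") {
  n <- max(length(chrom), length(start), length(end), length(rep_name))
  if (length(start) == 0L) n <- 0L
  data.frame(chrom = rep_len(chrom, n), start = as.integer(rep_len(start, n)),
             end = as.integer(rep_len(end, n)),
             strand = rep_len(strand, n), rep_name = rep_len(rep_name, n),
             rep_class_family = rep_len(family, n),
             element_id = as.integer(rep_len(id, n)),
             stringsAsFactors = FALSE)
}

# a quick catalogue from a list of feature rows
make_cat <- function(...) {
  group_into_elements(do.call(rbind, list(...)))
}

# random catalogue of unstructured features (adversarial input for the
# conservation/idempotence properties; not necessarily mendable)
random_features <- function(n_feat, seed) {
  set.seed(seed)
  reg <- default_iap_registry()
  pos <- sort(sample.int(200000L, n_feat))
  len <- sample(100:2000, n_feat, replace = TRUE)
  feat(chrom = sample(c("chr1", "chr2"), n_feat, replace = TRUE),
       start = pos, end = pos + len,
       strand = sample(c("+", "-"), n_feat, replace = TRUE),
       rep_name = sample(reg$iap_types, n_feat, replace = TRUE),
       id = sample.int(max(3L, n_feat %/% 2L), n_feat, replace = TRUE))
}

# -- mending oracle ----------------------------------------------------------

# Naive re-derivation of the mending fixpoint: every pass recomputes element
# envelopes and structures from scratch and scans all pairs for the best
# partner (heuristic rank, then gap, then 5'-most), consuming each element at
# most once per pass.  Returns the mended element count and structure table.
oracle_mend <- function(catalogue, max_gap = 2000) {
  reg <- catalogue$registry
  feats <- catalogue$features   # has .elem group labels
  rebuild <- function(feats) {
    groups <- split(seq_len(nrow(feats)), feats$.elem)
    do.call(rbind, lapply(groups, function(i) {
      f <- feats[i, ]
      data.frame(elem = f$.elem[1], chrom = f$chrom[1], strand = f$strand[1],
                 start = min(f$start), end = max(f$end),
                 structure = classify_structure(f, reg),
                 stringsAsFactors = FALSE)
    }))
  }
  missing_edge <- function(s, edge) {
    if (edge == "five") s %in% c("FRAG_NO5", "FRAG_INTERNAL_ONLY", "FRAG_OTHER")
    else s %in% c("FRAG_NO3", "FRAG_INTERNAL_ONLY", "FRAG_OTHER")
  }
  repeat {
    el <- rebuild(feats)
    el <- el[order(el$chrom, el$start, el$end), ]
    n <- nrow(el)
    consumed <- rep(FALSE, n)
    merges <- list()
    for (i in seq_len(n)) {
      if (consumed[i]) next
      si <- el$structure[i]
      if (si %in% c("FULL", "SOLO_LTR")) next
      for (edge in c("five", "three")) {
        if (!missing_edge(si, edge)) next
        # genomic side of this element-relative edge
        left <- (edge == "five") == (el$strand[i] == "+")
        best <- NULL
        for (j in seq_len(n)) {
          if (j == i || consumed[j]) next
          if (el$chrom[j] != el$chrom[i] || el$strand[j] != el$strand[i]) next
          if (left) {
            if (!(el$start[j] < el$start[i])) next
            gap <- el$start[i] - el$end[j]
          } else {
            if (!(el$end[j] > el$end[i])) next
            gap <- el$start[j] - el$end[i]
          }
          if (gap > max_gap) next
          sj <- el$structure[j]
          facing <- if (edge == "five") "three" else "five"
          rank <- if (!sj %in% c("FULL", "SOLO_LTR") &&
                        missing_edge(sj, facing)) 1
          else if (sj == "SOLO_LTR") 2
          else if (sj == "FULL") 3
          else NA
          if (is.na(rank)) next
          fivemost <- if (el$strand[i] == "+") el$start[j] else -el$end[j]
          key <- c(rank, gap, fivemost)
          if (is.null(best) ||
              (key[1] < best$key[1]) ||
              (key[1] == best$key[1] && key[2] < best$key[2]) ||
              (key[1] == best$key[1] && key[2] == best$key[2] &&
                 key[3] < best$key[3])) {
            best <- list(j = j, key = key)
          }
        }
        if (!is.null(best)) {
          merges[[length(merges) + 1L]] <- c(el$elem[i], el$elem[best$j])
          consumed[best$j] <- TRUE
          consumed[i] <- TRUE
        }
      }
    }
    if (!length(merges)) break
    for (m in merges) {
      feats$.elem[feats$.elem == m[2]] <- m[1]
    }
  }
  el <- rebuild(feats)
  list(n_elements = nrow(el),
       structures = sort(table(el$structure)),
       elem_sets = sort(vapply(split(paste(feats$chrom, feats$start,
                                           feats$end), feats$.elem),
                               paste, character(1), collapse = ";")))
}

# comparable fingerprint of a mended rm_catalogue
mend_fingerprint <- function(catalogue) {
  feats <- catalogue$features
  list(n_elements = nrow(catalogue$elements),
       structures = sort(table(catalogue$elements$structure)),
       elem_sets = sort(vapply(split(paste(feats$chrom, feats$start,
                                           feats$end), feats$.elem),
                               paste, character(1), collapse = ";")))
}

# -- screen oracle -----------------------------------------------------------

# Brute-force recomputation of the screen from raw counts with plain loops.
oracle_screen <- function(elements, coverage, samples, params) {
  # per-chromosome CpG positions: union of covered positions
  cpg <- list()
  for (s in names(coverage)) {
    cc <- coverage[[s]]
    for (ch in unique(cc$chrom)) {
      cpg[[ch]] <- sort(unique(c(cpg[[ch]], cc$pos[cc$chrom == ch])))
    }
  }
  res <- list()
  for (i in seq_len(nrow(elements))) {
    e <- elements[i, ]
    pos <- cpg[[e$chrom]]
    inside <- pos[pos >= e$start & pos < e$end]
    for (edge in c("five_prime", "three_prime")) {
      genomic_left <- (edge == "five_prime") == (e$strand == "+")
      d <- if (genomic_left) inside - e$start else (e$end - 1) - inside
      keep <- seq_along(inside)
      if (!is.null(params$edge_max_dist)) {
        keep <- keep[d[keep] <= params$edge_max_dist]
      }
      w <- inside[keep[order(d[keep])][seq_len(min(params$n_edge_cpgs,
                                                   length(keep)))]]
      per_group_range <- numeric(0); per_group_n <- integer(0)
      for (g in sort(unique(samples$group))) {
        means <- c()
        for (s in samples$sample_id[samples$group == g]) {
          cc <- coverage[[s]]
          cc <- cc[cc$chrom == e$chrom & cc$pos %in% w, ]
          tot <- sum(cc$n_meth + cc$n_unmeth)
          ncov <- sum(cc$n_meth + cc$n_unmeth > 0)
          if (tot >= params$min_calls && ncov >= params$min_covered_cpgs) {
            means <- c(means, sum(cc$n_meth) / tot)
          }
        }
        per_group_n[[g]] <- length(means)
        per_group_range[[g]] <- if (length(means)) max(means) - min(means) else NA
      }
      passed <- all(per_group_n >= params$min_informative_samples)
      stat <- if (!passed) NA else if (params$statistic == "min") {
        min(per_group_range)
      } else max(per_group_range)
      res[[paste(e$element_id, edge)]] <- list(
        element_id = e$element_id, edge = edge,
        n_informative = per_group_n, range = per_group_range,
        passed = passed, statistic = stat,
        candidate = passed && !is.na(stat) && stat >= params$range_threshold)
    }
  }
  res
}

# -- k-mer oracles -----------------------------------------------------------

oracle_kmer_presence <- function(seqs, k) {
  all_kmers <- unique(unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    km <- vapply(1:(n - k + 1), function(i) substr(s, i, i + k - 1),
                 character(1))
    km[!grepl("[^ACGT]", km)]
  })))
  counts <- vapply(all_kmers, function(km) {
    sum(vapply(seqs, function(s) grepl(km, s, fixed = TRUE), logical(1)))
  }, integer(1))
  counts[order(names(counts))]
}

oracle_overlap_components <- function(kmers, k) {
  n <- length(kmers)
  if (n == 0) return(list())
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j &&
        (substr(kmers[i], 2, k) == substr(kmers[j], 1, k - 1) ||
           substr(kmers[j], 2, k) == substr(kmers[i], 1, k - 1))) {
      adj[i, j] <- TRUE; adj[j, i] <- TRUE
    }
  }
  comp <- rep(0L, n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      if (comp[v] > 0) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  unname(lapply(split(kmers, comp), sort))
}

oracle_trim <- function(extended, fg, bg, params) {
  n <- nchar(extended)
  best <- NULL
  for (start in 1:n) for (end in start:n) {
    len <- end - start + 1
    if (len < params$trim_min_len) next
    sub <- substr(extended, start, end)
    fgp <- sum(vapply(fg, function(s) grepl(sub, s, fixed = TRUE), logical(1)))
    bgp <- sum(vapply(bg, function(s) grepl(sub, s, fixed = TRUE), logical(1)))
    fold <- (fgp / length(fg)) /
      ((if (bgp == 0) params$pseudocount else bgp) / length(bg))
    better <- is.null(best) || fold > best$fold ||
      (fold == best$fold && len > nchar(best$sub)) ||
      (fold == best$fold && len == nchar(best$sub) && start < best$start)
    if (better) best <- list(sub = sub, fold = fold, start = start,
                             fg = fgp, bg = bgp)
  }
  best
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
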