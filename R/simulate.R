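#' Simulation parameters
#'
#' Parameters of the synthetic test bed.  The defaults emulate the study
#' design the screen was developed on: 8 individuals with one B and one T
#' cell sample each (16 WGBS samples), Poisson per-CpG coverage of mean 10,
#' a hypermethylated background in which per-element per-sample methylation
#' is drawn from Beta(380, 20) (mean 0.95, about 1% spread, matching
#' uniformly hypermethylated non-variable elements), constitutively variable
#' (CVM) elements whose per-individual level is Uniform(0.05, 0.95) and
#' shared across cell types, and tissue-specific (TSVM) elements variable in
#' the first group only.  Elements are laid down as LTR-internal-LTR with
#' identical flanking LTRs; a fraction are solo LTRs.  CpG sites are
#' guaranteed inside LTRs by imposing a CG every `cpg_interval` bp.
#'
#' @param n_elements number of elements.
#' @param ltr_length,internal_length subelement lengths in bp.
#' @param solo_fraction fraction of elements that are solo LTRs.
#' @param genome_length total genome length in bp; `NULL` sizes the genome
#'   automatically.
#' @param min_spacing minimum gap between elements and to the chromosome
#'   ends (default 2500, beyond the 2000 bp mending reach).
#' @param fragmentation_rate probability that a full element's annotation is
#'   split into several element IDs.
#' @param frag_gap_max maximum bp eroded from each facing boundary at an
#'   annotation split (simulated nested-TE gap; keep < 2000).
#' @param n_boundary_splits number of elements placed across 500 kb bin
#'   boundaries and split there into two IDs.
#' @param n_samples individuals per group.
#' @param groups cell-type labels; the first is the TSVM-variable group.
#' @param coverage_mean expected per-CpG calls per sample.
#' @param meth_background `c(shape1, shape2)` of the hypermethylated Beta.
#' @param vm_fraction,tsvm_fraction fractions of elements assigned the CVM
#'   and TSVM regimes (`vm_fraction + tsvm_fraction <= 1`).
#' @param cpg_interval spacing of guaranteed CpGs within LTRs (bp).
#' @param mutation_rate per-base substitution rate between an element's LTR
#'   and the family consensus.
#' @param motif optional 15-mer planted into foreground LTRs.
#' @param n_carriers number of CVM elements carrying the motif.
#' @param seed integer seed; every operation derives a named stream from it.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_elements = 50L, ltr_length = 300L,
                       internal_length = 1500L, solo_fraction = 0.2,
                       genome_length = NULL, min_spacing = 2500L,
                       fragmentation_rate = 0.3, frag_gap_max = 150L,
                       n_boundary_splits = 0L, n_samples = 8L,
                       groups = c("B", "T"), coverage_mean = 10,
                       meth_background = c(380, 20), vm_fraction = 0.1,
                       tsvm_fraction = 0.05, cpg_interval = 25L,
                       mutation_rate = 0.05, motif = NULL, n_carriers = 0L,
                       seed = 1L) {
  stopifnot(n_elements >= 1, ltr_length > 0, internal_length > 0,
            solo_fraction >= 0, solo_fraction <= 1,
            fragmentation_rate >= 0, fragmentation_rate <= 1,
            frag_gap_max >= 0, n_samples >= 1, length(groups) >= 1,
            coverage_mean >= 0, length(meth_background) == 2,
            all(meth_background > 0), vm_fraction >= 0, tsvm_fraction >= 0,
            vm_fraction + tsvm_fraction <= 1, cpg_interval >= 2,
            mutation_rate >= 0, mutation_rate < 1)
  if (!is.null(motif)) {
    motif <- toupper(motif)
    if (grepl("[^ACGT]", motif)) stop("motif must be over {A,C,G,T}")
    if (nchar(motif) > ltr_length) stop("motif longer than the LTR")
  }
  structure(as.list(environment()), class = "sim_params")
}

## named seed stream: one global seed feeds an independent, reproducible
## stream per operation, so adding operations never shifts existing draws
stream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 1000000007
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, name))
  expr
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## impose CG dinucleotides at fixed offsets (1-based) within a sequence
impose_cpgs <- function(seq, offsets) {
  v <- strsplit(seq, "")[[1]]
  for (o in offsets) {
    v[o] <- "C"; v[o + 1L] <- "G"
  }
  paste(v, collapse = "")
}

mutate_seq <- function(seq, rate) {
  v <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  if (length(hit)) v[hit] <- sample(c("A", "C", "G", "T"), length(hit),
                                    replace = TRUE)
  paste(v, collapse = "")
}

#' Simulate a toy genome with embedded repeat elements
#'
#' Lays fully-structured (LTR-internal-LTR) and solo LTR elements onto a
#' uniform-random background sequence.  The two LTRs of a full element are
#' identical; LTRs across elements are mutated copies of a family consensus
#' with guaranteed CpG sites.  Each element gets a methylation regime
#' (HYPER / CVM / TSVM per `vm_fraction` and `tsvm_fraction`) and a strand;
#' an optional 15-mer motif is planted into the oriented 5' LTR of
#' `n_carriers` CVM elements (CVM elements being the foreground of the
#' k-mer analysis).  Deterministic given `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @return list of class `vm_sim` with `genome` (named character vector, one
#'   chromosome `chr1`), `truth` (list: `elements` data frame with regimes
#'   and types, `features` true annotation rows with `element_id`, `motif`
#'   plant record) and `params`.
#' @export
simulate_genome <- function(params = sim_params()) {
  with_stream(params$seed, "genome", {
    p <- params
    n <- p$n_elements
    n_solo <- round(p$solo_fraction * n)
    is_solo <- rep(FALSE, n)
    if (n_solo > 0) is_solo[sample(n, n_solo)] <- TRUE
    span <- ifelse(is_solo, p$ltr_length, 2L * p$ltr_length + p$internal_length)
    strand <- sample(c("+", "-"), n, replace = TRUE)

    ## regimes
    n_cvm <- round(p$vm_fraction * n)
    n_tsvm <- round(p$tsvm_fraction * n)
    regime <- rep("HYPER", n)
    pick <- sample(n, n_cvm + n_tsvm)
    regime[pick[seq_len(n_cvm)]] <- "CVM"
    if (n_tsvm > 0) regime[pick[n_cvm + seq_len(n_tsvm)]] <- "TSVM"

    ## placement: boundary-split elements straddle successive 500 kb
    ## multiples; all others follow with random spacing >= min_spacing
    nb <- min(p$n_boundary_splits, sum(!is_solo))
    boundary_elem <- utils::head(which(!is_solo), nb)
    start <- integer(n)
    cursor <- p$min_spacing
    for (i in seq_len(n)) {
      if (i %in% boundary_elem) {
        b <- 500000L * ceiling((cursor + p$min_spacing + p$ltr_length +
                                  p$internal_length %/% 2L) / 500000L)
        start[i] <- b - p$ltr_length - p$internal_length %/% 2L
      } else {
        start[i] <- cursor + sample(p$min_spacing:(p$min_spacing + 500L), 1L)
      }
      cursor <- start[i] + span[i]
    }
    need <- cursor + p$min_spacing
    glen <- p$genome_length
    if (is.null(glen)) glen <- need
    if (glen < need) {
      stop("elements do not fit genome: genome_length must be >= ", need)
    }

    ## sequences
    ltr_consensus <- random_dna(p$ltr_length)
    cpg_off <- seq(3L, p$ltr_length - 1L, by = p$cpg_interval)
    ltr_consensus <- impose_cpgs(ltr_consensus, cpg_off)
    ltr_type_pool <- c("IAPLTR1_Mm", "IAPLTR2_Mm", "IAPLTR1a_Mm")
    int_type_pool <- c("IAPEz-int", "IAPEy-int")
    ltr_type <- sample(ltr_type_pool, n, replace = TRUE, prob = c(.5, .3, .2))
    int_type <- ifelse(is_solo, NA_character_,
                       sample(int_type_pool, n, replace = TRUE, prob = c(.7, .3)))
    ltr_seq <- vapply(seq_len(n), function(i) {
      impose_cpgs(mutate_seq(ltr_consensus, p$mutation_rate), cpg_off)
    }, character(1))

    ## motif planting into the oriented 5' LTR of CVM carriers
    motif_rec <- NULL
    if (!is.null(p$motif) && p$n_carriers > 0) {
      cvm_idx <- which(regime == "CVM")
      if (p$n_carriers > length(cvm_idx)) {
        stop("n_carriers exceeds the number of CVM elements")
      }
      carriers <- sort(sample(cvm_idx, p$n_carriers))
      offs <- integer(length(carriers))
      for (ci in seq_along(carriers)) {
        i <- carriers[ci]
        off <- sample(seq_len(p$ltr_length - nchar(p$motif) + 1L), 1L)
        substr(ltr_seq[i], off, off + nchar(p$motif) - 1L) <- p$motif
        offs[ci] <- off
      }
      motif_rec <- list(seq = p$motif, carriers = carriers, offsets = offs)
    }

    ## assemble genome (element sequence written in genomic orientation)
    chrom_v <- strsplit(random_dna(glen), "")[[1]]
    feats <- list()
    for (i in seq_len(n)) {
      if (is_solo[i]) {
        elem_seq <- ltr_seq[i]
        parts <- data.frame(rep_name = ltr_type[i],
                            off = 0L, len = p$ltr_length,
                            stringsAsFactors = FALSE)
      } else {
        internal <- random_dna(p$internal_length)
        elem_seq <- paste0(ltr_seq[i], internal, ltr_seq[i])
        parts <- data.frame(
          rep_name = c(ltr_type[i], int_type[i], ltr_type[i]),
          off = c(0L, p$ltr_length, p$ltr_length + p$internal_length),
          len = c(p$ltr_length, p$internal_length, p$ltr_length),
          stringsAsFactors = FALSE)
      }
      if (strand[i] == "-") {
        elem_seq <- revcomp(elem_seq)
        ## element-oriented parts map to mirrored genomic offsets
        parts$off <- span[i] - (parts$off + parts$len)
        parts <- parts[rev(seq_len(nrow(parts))), , drop = FALSE]
      }
      chrom_v[(start[i] + 1L):(start[i] + span[i])] <-
        strsplit(elem_seq, "")[[1]]
      feats[[i]] <- data.frame(
        chrom = "chr1",
        start = start[i] + parts$off,
        end = start[i] + parts$off + parts$len,
        strand = strand[i],
        rep_name = parts$rep_name,
        rep_class_family = "LTR/ERVK",
        element_id = i,
        stringsAsFactors = FALSE)
    }
    genome <- stats::setNames(paste(chrom_v, collapse = ""), "chr1")
    elements <- data.frame(
      element_id = seq_len(n), chrom = "chr1", start = start,
      end = start + span, strand = strand,
      structure = ifelse(is_solo, "SOLO_LTR", "FULL"),
      ltr_type = ltr_type, int_type = int_type, regime = regime,
      stringsAsFactors = FALSE)
    structure(list(genome = genome,
                   truth = list(elements = elements,
                                features = do.call(rbind, feats),
                                motif = motif_rec),
                   params = p),
              class = "vm_sim")
  })
}

#' Fragment a true annotation
#'
#' Produces the rmsk-style annotation the pipeline sees: with probability
#' `fragmentation_rate` a full element's rows are split into two or three
#' element IDs at subelement boundaries, with up to `frag_gap_max` bp eroded
#' from each facing boundary (simulating nested-TE gaps).  Elements placed
#' over 500 kb boundaries are always split there, cutting the spanning row
#' in two.  The true parent element of every row is retained.
#'
#' @param sim a `vm_sim` from [simulate_genome()].
#' @return data frame of annotation rows (`chrom`, `start`, `end`, `strand`,
#'   `rep_name`, `rep_class_family`, `element_id`, plus `true_element` for
#'   auditing); `element_id`s of fragments are fresh.
#' @export
fragment_annotation <- function(sim) {
  stopifnot(inherits(sim, "vm_sim"))
  p <- sim$params
  with_stream(p$seed, "fragment", {
    feats <- sim$truth$features
    feats$true_element <- feats$element_id
    out <- list()
    next_id <- max(feats$element_id) + 1L
    for (i in unique(feats$element_id)) {
      f <- feats[feats$element_id == i, , drop = FALSE]
      f <- f[order(f$start), , drop = FALSE]
      el <- sim$truth$elements[sim$truth$elements$element_id == i, ]
      boundary <- p$n_boundary_splits > 0 &&
        any(el$start < 500000L * seq_len(10L) & 500000L * seq_len(10L) < el$end)
      if (boundary) {
        b <- 500000L * which(el$start < 500000L * seq_len(10L) &
                               500000L * seq_len(10L) < el$end)[1]
        left <- f[f$start < b, , drop = FALSE]
        right <- f[f$end > b, , drop = FALSE]
        cut <- left$end > b
        left$end[cut] <- b
        cutr <- right$start < b
        right$start[cutr] <- b
        right <- right[!(right$start >= right$end), , drop = FALSE]
        left$element_id <- i
        right$element_id <- next_id
        next_id <- next_id + 1L
        out[[length(out) + 1L]] <- rbind(left, right)
        next
      }
      if (nrow(f) >= 2L && stats::runif(1) < p$fragmentation_rate) {
        n_cuts <- sample(seq_len(nrow(f) - 1L), 1L)
        cuts <- sort(sample(nrow(f) - 1L, n_cuts))   # split after these rows
        piece <- cumsum(c(1L, seq_len(nrow(f) - 1L) %in% cuts))
        for (cpos in cuts) {
          if (p$frag_gap_max > 0) {
            f$end[cpos] <- f$end[cpos] -
              sample(0:min(p$frag_gap_max, f$end[cpos] - f$start[cpos] - 1L), 1L)
            f$start[cpos + 1L] <- f$start[cpos + 1L] +
              sample(0:min(p$frag_gap_max,
                           f$end[cpos + 1L] - f$start[cpos + 1L] - 1L), 1L)
          }
        }
        f$element_id <- c(i, next_id + seq_len(max(piece) - 1L) - 1L)[piece]
        next_id <- next_id + max(piece) - 1L
      }
      out[[length(out) + 1L]] <- f
    }
    ann <- do.call(rbind, out)
    ann <- ann[order(ann$chrom, ann$start), , drop = FALSE]
    rownames(ann) <- NULL
    ann
  })
}

#' Simulate per-sample bisulphite coverage
#'
#' For every CpG site and sample, total calls are Poisson(`coverage_mean`)
#' and methylated calls are Binomial with the element's per-sample true
#' level: HYPER elements (and non-element background CpGs) draw
#' Beta(`meth_background`) levels; CVM elements draw one
#' Uniform(0.05, 0.95) level per individual, shared across cell types; TSVM
#' elements are variable (uniform per individual) in the first group and
#' hypermethylated in the others.  CpGs with zero total calls are omitted,
#' as in real coverage files.  Deterministic given `params$seed`.
#'
#' @param sim a `vm_sim` from [simulate_genome()].
#' @return list with `samples` (sample sheet: `sample_id`, `group`,
#'   `individual`), `coverage` (named list of six-column-dialect data frames
#'   with columns `chrom`, `start`, `end`, `pct`, `n_meth`, `n_unmeth`),
#'   `levels` (elements x samples matrix of true levels) and `cpg_positions`.
#' @export
simulate_coverage <- function(sim) {
  stopifnot(inherits(sim, "vm_sim"))
  p <- sim$params
  el <- sim$truth$elements
  samples <- do.call(rbind, lapply(p$groups, function(g) {
    data.frame(sample_id = sprintf("ind%02d_%s", seq_len(p$n_samples), g),
               group = g, individual = seq_len(p$n_samples),
               stringsAsFactors = FALSE)
  }))
  rownames(samples) <- NULL
  ns <- nrow(samples)
  a <- p$meth_background[1]; b <- p$meth_background[2]

  levels <- with_stream(p$seed, "levels", {
    L <- matrix(NA_real_, nrow(el), ns,
                dimnames = list(el$element_id, samples$sample_id))
    for (i in seq_len(nrow(el))) {
      L[i, ] <- switch(el$regime[i],
        HYPER = stats::rbeta(ns, a, b),
        CVM = stats::runif(p$n_samples, 0.05, 0.95)[samples$individual],
        TSVM = {
          u <- stats::runif(p$n_samples, 0.05, 0.95)
          ifelse(samples$group == p$groups[1],
                 u[samples$individual], stats::rbeta(ns, a, b))
        })
    }
    L
  })

  cpg <- find_cpg_sites(sim$genome)[["chr1"]]
  ## map each CpG to its element (0 = background)
  idx <- rep(0L, length(cpg))
  for (i in seq_len(nrow(el))) {
    idx[cpg >= el$start[i] & cpg < el$end[i]] <- i
  }
  coverage <- with_stream(p$seed, "coverage", {
    bg_level <- matrix(stats::rbeta(ns, a, b), nrow = 1)  # per-sample background
    out <- list()
    for (s in seq_len(ns)) {
      pvec <- ifelse(idx > 0, levels[pmax(idx, 1L), s], bg_level[1, s])
      tot <- stats::rpois(length(cpg), p$coverage_mean)
      meth <- stats::rbinom(length(cpg), tot, pvec)
      keep <- tot > 0
      out[[samples$sample_id[s]]] <- data.frame(
        chrom = rep("chr1", sum(keep)), start = cpg[keep], end = cpg[keep],
        pct = round(100 * meth[keep] / tot[keep], 2),
        n_meth = meth[keep], n_unmeth = tot[keep] - meth[keep],
        stringsAsFactors = FALSE)
    }
    out
  })
  list(samples = samples, coverage = coverage, levels = levels,
       cpg_positions = list(chr1 = cpg))
}

#' Plant a motif into LTR sequences
#'
#' Substitutes `motif` in place at a seeded random offset in each carrier
#' sequence; non-carriers are untouched.  Offsets are recorded for truth
#' checking.
#'
#' @param ltr_sequences character vector.
#' @param motif sequence over `{A,C,G,T}`.
#' @param carrier_indices indices of carrier sequences.
#' @param seed integer seed.
#' @return list with `sequences` and `offsets` (1-based, named by carrier
#'   index).
#' @export
plant_motifs <- function(ltr_sequences, motif, carrier_indices, seed = 1L) {
  motif <- toupper(motif)
  if (grepl("[^ACGT]", motif)) stop("motif must be over {A,C,G,T}")
  if (length(carrier_indices) &&
      (min(carrier_indices) < 1 || max(carrier_indices) > length(ltr_sequences))) {
    stop("carrier index out of range")
  }
  with_stream(seed, "plant", {
    offsets <- integer(0)
    for (i in carrier_indices) {
      n <- nchar(ltr_sequences[i])
      if (n < nchar(motif)) stop("sequence ", i, " shorter than the motif")
      off <- sample(seq_len(n - nchar(motif) + 1L), 1L)
      substr(ltr_sequences[i], off, off + nchar(motif) - 1L) <- motif
      offsets[[as.character(i)]] <- off
    }
    list(sequences = ltr_sequences, offsets = offsets)
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper chaining [simulate_genome()], [fragment_annotation()]
#' and [simulate_coverage()]; optionally writes everything to a directory as
#' the pipeline's file formats (genome FASTA, rmsk-style annotation TSV,
#' per-sample coverage TSVs, sample sheet, truth JSON).
#'
#' @param params a [sim_params()] object.
#' @param dir optional output directory.
#' @return list of class `vm_sim_dataset`: `genome`, `truth`, `annotation`,
#'   `samples`, `coverage`, `levels`, `cpg_positions`, `params` (and `paths`
#'   when written).
#' @export
simulate_vm_dataset <- function(params = sim_params(), dir = NULL) {
  sim <- simulate_genome(params)
  ann <- fragment_annotation(sim)
  cov <- simulate_coverage(sim)
  out <- list(genome = sim$genome, truth = sim$truth, annotation = ann,
              samples = cov$samples, coverage = cov$coverage,
              levels = cov$levels, cpg_positions = cov$cpg_positions,
              params = params)
  class(out) <- "vm_sim_dataset"
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(genome = file.path(dir, "genome.fa"),
                  annotation = file.path(dir, "annotation.tsv"),
                  samples = file.path(dir, "samples.tsv"),
                  truth = file.path(dir, "truth.json"))
    gs <- Biostrings::DNAStringSet(out$genome)
    Biostrings::writeXStringSet(gs, paths$genome)
    utils::write.table(
      ann[c("chrom", "start", "end", "strand", "rep_name",
            "rep_class_family", "element_id")],
      paths$annotation, sep = "\t", quote = FALSE, row.names = FALSE)
    sheet <- out$samples
    sheet$path <- paste0("coverage_", sheet$sample_id, ".tsv")
    utils::write.table(sheet, paths$samples, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    for (s in names(out$coverage)) {
      utils::write.table(out$coverage[[s]],
                         file.path(dir, paste0("coverage_", s, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
    jsonlite::write_json(
      list(elements = sim$truth$elements, motif = sim$truth$motif),
      paths$truth, auto_unbox = TRUE, digits = NA, null = "null")
    out$paths <- paths
  }
  out
}
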