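#' Read a per-CpG bisulphite coverage file
#'
#' Reads the six-column coverage dialect (chrom, start, end, % methylation,
#' count methylated, count unmethylated; no header; positions 0-based).
#' Records on the two strands of one CpG dyad (consecutive positions) are
#' merged by summing counts onto the plus-strand C position.  The percentage
#' column is ignored in favour of the raw counts; a warning is issued when it
#' disagrees with the counts beyond rounding.
#'
#' @param file path to a TSV (gzip allowed), or a data frame with columns in
#'   the order above.
#' @return data frame with columns `chrom`, `pos`, `n_meth`, `n_unmeth`,
#'   sorted by (chrom, pos).
#' @export
read_coverage <- function(file) {
  if (is.data.frame(file)) {
    df <- file
  } else {
    df <- tryCatch(
      utils::read.table(file, sep = "\t", header = FALSE,
                        stringsAsFactors = FALSE,
                        col.names = c("chrom", "start", "end", "pct",
                                      "n_meth", "n_unmeth")),
      error = function(e) {
        if (grepl("no lines available", conditionMessage(e))) {
          data.frame(chrom = character(), start = integer(), end = integer(),
                     pct = numeric(), n_meth = integer(), n_unmeth = integer())
        } else stop(e)
      })
  }
  if (ncol(df) < 6L) stop("coverage file needs 6 columns, got ", ncol(df))
  names(df)[1:6] <- c("chrom", "start", "end", "pct", "n_meth", "n_unmeth")
  if (nrow(df) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      n_meth = integer(), n_unmeth = integer()))
  }
  if (any(df$n_meth < 0 | df$n_unmeth < 0)) {
    stop("negative methylation counts in coverage input")
  }
  tot <- df$n_meth + df$n_unmeth
  with_calls <- tot > 0
  implied <- ifelse(with_calls, 100 * df$n_meth / pmax(tot, 1L), 0)
  off <- with_calls & abs(implied - df$pct) > 1
  if (any(off)) {
    warning(sum(off), " coverage record(s) have a % methylation column ",
            "inconsistent with the counts (beyond rounding); counts are used")
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  ## merge runs of consecutive positions (the two strands of a dyad) onto the
  ## first (plus-strand C) position
  brk <- c(TRUE, df$chrom[-1L] != df$chrom[-nrow(df)] |
             df$start[-1L] != df$start[-nrow(df)] + 1L)
  grp <- cumsum(brk)
  out <- data.frame(
    chrom = df$chrom[brk],
    pos = as.integer(df$start[brk]),
    n_meth = as.integer(tapply(df$n_meth, grp, sum)),
    n_unmeth = as.integer(tapply(df$n_unmeth, grp, sum)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Read a sample sheet
#'
#' Tab-separated with a header and columns `sample_id`, `group` and
#' optionally `path` (per-sample coverage file, relative to the sheet's
#' directory unless absolute).
#'
#' @param file path to the sheet.
#' @return data frame with at least `sample_id` and `group`.
#' @export
read_sample_sheet <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample sheet")
  if (any(!nzchar(df$group))) stop("empty group label in sample sheet")
  if ("path" %in% names(df) && !is.data.frame(file) && is.character(file)) {
    rel <- !grepl("^(/|[A-Za-z]:)", df$path)
    df$path[rel] <- file.path(dirname(file), df$path[rel])
  }
  df
}
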