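#' IAP subelement registry
#'
#' A registry maps RepeatMasker subelement names to their role within an
#' element: `"ltr"` (a long terminal repeat) or `"internal"` (part of the
#' proviral internal portion).  The default registry covers the 25 IAP
#' subelement types used to define the mouse IAP catalogue: 15 LTR types and
#' 10 internal types.  Typing follows the naming convention that internal
#' portions end in `-int`, with one explicit exception (`IAPLTR4_I`, an
#' internal sequence despite its name).
#'
#' @param iap_types character vector of subelement names making up the family.
#' @param internal_types subset of `iap_types` that are internal portions.
#'   When `NULL`, roles are inferred from the naming convention
#'   (`-int` suffix or an `_I` suffix).
#' @return An object of class `iap_registry`: a list with elements
#'   `iap_types`, `internal_types` and `ltr_types` (disjoint, union equal to
#'   `iap_types`).
#' @examples
#' reg <- default_iap_registry()
#' length(reg$ltr_types)      # 15
#' length(reg$internal_types) # 10
#' @export
iap_registry <- function(iap_types, internal_types = NULL) {
  iap_types <- unique(as.character(iap_types))
  if (is.null(internal_types)) {
    internal_types <- iap_types[grepl("(-int|_I)$", iap_types)]
  }
  internal_types <- unique(as.character(internal_types))
  if (!all(internal_types %in% iap_types)) {
    stop("internal_types must be a subset of iap_types")
  }
  structure(
    list(
      iap_types = iap_types,
      internal_types = internal_types,
      ltr_types = setdiff(iap_types, internal_types)
    ),
    class = "iap_registry"
  )
}

#' @rdname iap_registry
#' @export
default_iap_registry <- function() {
  iap_registry(c(
    "IAPLTR1a_Mm", "IAPEY2_LTR", "IAPEy-int", "IAPEY3_LTR", "IAPLTR2b",
    "IAPLTR2_Mm", "IAPEz-int", "IAPEY4_I-int", "IAP-d-int", "IAPEY3-int",
    "RLTR10B2", "IAP1-MM_I-int", "IAP1-MM_LTR", "IAPLTR2a2_Mm", "IAPLTR4",
    "IAPLTR1_Mm", "IAPEY3C_LTR", "IAPLTR4_I", "IAPLTR3", "IAPLTR3-int",
    "IAPEY5_LTR", "IAPEY5_I-int", "IAPEY_LTR", "IAPEY4_LTR", "IAPA_MM-int"
  ))
}

#' Read or write a subelement registry file
#'
#' The registry is kept overridable as a two-column tab-separated file
#' (`name`, `role`) so that the LTR/internal mapping is configuration, not
#' code.  `role` must be `"ltr"` or `"internal"`.
#'
#' @param path file path.
#' @param registry an `iap_registry` (for writing).
#' @return `read_iap_registry` returns an `iap_registry`.
#' @export
read_iap_registry <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("name", "role") %in% names(df))) {
    stop("registry file needs columns 'name' and 'role'")
  }
  bad <- setdiff(unique(df$role), c("ltr", "internal"))
  if (length(bad)) stop("unknown registry role(s): ", paste(bad, collapse = ", "))
  iap_registry(df$name, internal_types = df$name[df$role == "internal"])
}

#' @rdname read_iap_registry
#' @export
write_iap_registry <- function(registry, path) {
  df <- data.frame(
    name = registry$iap_types,
    role = ifelse(registry$iap_types %in% registry$internal_types,
                  "internal", "ltr"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Role of subelement names
#'
#' Names absent from the registry fall back to the naming convention
#' (`-int`/`_I` suffix means internal); this lets the same machinery classify
#' synthetic or non-IAP repeat families.
#'
#' @param names character vector of subelement names.
#' @param registry an `iap_registry`.
#' @return character vector, `"ltr"` or `"internal"` per name.
#' @export
subelement_role <- function(names, registry = default_iap_registry()) {
  role <- ifelse(grepl("(-int|_I)$", names), "internal", "ltr")
  role[names %in% registry$internal_types] <- "internal"
  role[names %in% registry$ltr_types] <- "ltr"
  role
}

#' @export
print.iap_registry <- function(x, ...) {
  cat("IAP subelement registry:", length(x$iap_types), "types (",
      length(x$ltr_types), "LTR,", length(x$internal_types), "internal )\n")
  invisible(x)
}
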