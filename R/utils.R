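`%||%` <- function(a, b) if (is.null(a)) b else a

# em dash used by the reference table for "absent at this stage"
ABSENT_MARK <- "—"

#' Canonicalize species names
#'
#' Collapses whitespace, normalises genus capitalisation, lower-cases the
#' specific epithet, retains infraspecific rank tokens (`subsp.`, `var.`,
#' `f.`) with their epithets, and drops anything else (typically author
#' abbreviations).
#'
#' @param x character vector of species names.
#' @return character vector of canonical names.
#' @examples
#' canonicalize_species("  CAREX  atrofusca   subsp. minor  (L.) Kuek.")
#' @export
canonicalize_species <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  ranks <- c("subsp." = "subsp.", "subsp" = "subsp.", "ssp." = "subsp.",
             "ssp" = "subsp.", "var." = "var.", "var" = "var.", "f." = "f.")
  vapply(x, function(nm) {
    if (!nzchar(nm)) stop("empty species name", call. = FALSE)
    tok <- strsplit(nm, " ", fixed = TRUE)[[1]]
    genus <- paste0(toupper(substr(tok[1], 1, 1)),
                    tolower(substr(tok[1], 2, nchar(tok[1]))))
    out <- genus
    if (length(tok) >= 2L) out <- c(out, tolower(tok[2]))
    i <- 3L
    while (i <= length(tok)) {
      t <- tolower(tok[i])
      if (t %in% names(ranks) && i < length(tok)) {
        out <- c(out, ranks[[t]], tolower(tok[i + 1L]))
        i <- i + 2L
      } else {
        i <- i + 1L
      }
    }
    paste(out, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

# shared argument checks
stopifnot_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (strict && x <= lower)
    stop(sprintf("'%s' must be > %s", name, lower), call. = FALSE)
  if (!strict && x < lower)
    stop(sprintf("'%s' must be >= %s", name, lower), call. = FALSE)
  invisible(x)
}

# renormalize a non-negative utilization profile to proportions
as_profile <- function(p, name = "profile") {
  if (!is.numeric(p) || anyNA(p))
    stop(sprintf("'%s' must be numeric without NA", name), call. = FALSE)
  if (any(p < 0))
    stop(sprintf("'%s' must be non-negative", name), call. = FALSE)
  s <- sum(p)
  if (s <= 0) stop(sprintf("'%s' sums to zero", name), call. = FALSE)
  p / s
}
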