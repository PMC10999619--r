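#' Read quadrat survey records
#'
#' Reads a CSV of quadrat survey observations — one row per species per 1 m²
#' plot — validates it and returns a `survey_records` data frame. Required
#' columns: `site`, `transect`, `stage`, `quadrat`, `species`, `height`,
#' `cover`, `abundance`. Cover given in percent is converted to a fraction in
#' \[0, 1\] on read; species names are canonicalized with
#' [canonicalize_species()].
#'
#' @param path path to a CSV file with a header row.
#' @param dialect list of reading options: `cover_unit` one of `"auto"`
#'   (default; treat as percent when any value exceeds 1), `"fraction"` or
#'   `"percent"`; `height_unit` an opaque label carried through as metadata
#'   (only relative heights are ever used downstream).
#' @return a data frame of class `survey_records` with columns
#'   `site`, `transect`, `stage`, `quadrat`, `species`, `height`, `cover`,
#'   `abundance`, and attributes `height_unit` and `cover_unit`.
#' @seealso [write_survey_records()], [community_matrix()]
#' @export
read_survey_records <- function(path, dialect = list()) {
  if (!file.exists(path)) stop("survey file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("site", "transect", "stage", "quadrat", "species",
                "height", "cover", "abundance")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- df[required]

  cover_unit <- dialect$cover_unit %||% "auto"
  cover_unit <- match.arg(cover_unit, c("auto", "fraction", "percent"))
  if (cover_unit == "auto")
    cover_unit <- if (any(df$cover > 1, na.rm = TRUE)) "percent" else "fraction"
  if (cover_unit == "percent") df$cover <- df$cover / 100

  df$species <- canonicalize_species(df$species)
  out <- validate_survey_records(df)
  attr(out, "height_unit") <- dialect$height_unit %||% "unspecified"
  attr(out, "cover_unit") <- cover_unit
  out
}

#' Validate quadrat survey records
#'
#' Checks the survey-record invariants: cover in \[0, 1\], positive height,
#' non-negative integer abundance, and uniqueness of the
#' (stage, quadrat, species) key. Called by [read_survey_records()] and usable
#' directly on programmatically built data frames.
#'
#' @param records data frame with the survey-record columns.
#' @return the validated records, classed `survey_records`.
#' @export
validate_survey_records <- function(records) {
  df <- as.data.frame(records)
  for (col in c("height", "cover", "abundance"))
    if (!is.numeric(df[[col]]))
      stop("validation error: column '", col, "' must be numeric", call. = FALSE)

  bad <- which(df$cover < 0 | df$cover > 1 | is.na(df$cover))
  if (length(bad))
    stop("validation error: cover outside [0, 1] (or >100%) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  bad <- which(!(df$height > 0) | is.na(df$height))
  if (length(bad))
    stop("validation error: non-positive height at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  bad <- which(df$abundance < 0 | df$abundance != round(df$abundance) |
                 is.na(df$abundance))
  if (length(bad))
    stop("validation error: negative or non-integer abundance at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)

  key <- paste(df$stage, df$quadrat, df$species, sep = " / ")
  dup <- unique(key[duplicated(key)])
  if (length(dup))
    stop("validation error: duplicate (stage, quadrat, species) key(s): ",
         paste(utils::head(dup, 5), collapse = "; "), call. = FALSE)

  df$stage <- as.character(df$stage)
  class(df) <- c("survey_records", "data.frame")
  df
}

#' Write quadrat survey records
#'
#' Inverse of [read_survey_records()]: writes a UTF-8 CSV with the standard
#' header. Cover is written as a fraction, so a read-back round-trips
#' canonicalized records exactly.
#'
#' @param records a `survey_records` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey_records <- function(records, path) {
  cols <- c("site", "transect", "stage", "quadrat", "species",
            "height", "cover", "abundance")
  write.csv(as.data.frame(records)[cols], path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Build a species-by-resource-state utilization matrix for one stage
#'
#' The resource states are the survey's sampling units: individual quadrats
#' (default) or transects (quadrats pooled by summing). The utilization
#' measure is the species' abundance in the unit, or a per-quadrat importance
#' component (the within-quadrat mean of relative height, relative cover and
#' relative abundance). Species absent from every state at the stage are
#' dropped; rows are normalized to utilization proportions \eqn{p_{ij}} with
#' \eqn{\sum_j p_{ij} = 1}.
#'
#' @param records a `survey_records` data frame.
#' @param stage the stage label to subset to (e.g. `"S1"`).
#' @param state_def `"quadrat"` or `"transect"`; what a resource state is.
#' @param measure `"abundance"` or `"iv_component"`.
#' @return an object of class `community_matrix`: a list with elements
#'   `stage`, `species`, `states`, `values` (raw utilization, species x
#'   state), `p` (row-normalized proportions), `state_def`, `measure`.
#' @examples
#' rec <- data.frame(site = 1, transect = 1, stage = "S1",
#'                   quadrat = paste0("q", 1:3),
#'                   species = "Poa annua", height = 10, cover = 0.2,
#'                   abundance = c(2, 2, 2))
#' cm <- community_matrix(validate_survey_records(rec), "S1")
#' cm$p  # (1/3, 1/3, 1/3)
#' @export
community_matrix <- function(records, stage,
                             state_def = c("quadrat", "transect"),
                             measure = c("abundance", "iv_component")) {
  state_def <- match.arg(state_def)
  measure <- match.arg(measure)
  df <- as.data.frame(records)
  df <- df[df$stage == stage, , drop = FALSE]
  if (nrow(df) == 0L) stop("no records at stage '", stage, "'", call. = FALSE)

  df$state <- if (state_def == "quadrat") as.character(df$quadrat)
              else paste(df$site, df$transect, sep = ":")

  if (measure == "abundance") {
    df$value <- as.numeric(df$abundance)
  } else {
    # within-quadrat importance component, then pooled over the state's quadrats
    qid <- as.character(df$quadrat)
    rel <- function(x, g) x / ave(x, g, FUN = sum)
    df$value <- (rel(df$height, qid) + rel(df$cover, qid) +
                   rel(df$abundance + 0.0, qid)) / 3
    df$value[is.na(df$value)] <- 0
  }

  species <- sort(unique(df$species))
  states <- sort(unique(df$state))
  if (length(states) < 2L)
    stop("stage '", stage, "' has fewer than 2 resource states; ",
         "niche breadth is undefined", call. = FALSE)

  values <- matrix(0, length(species), length(states),
                   dimnames = list(species, states))
  idx <- cbind(match(df$species, species), match(df$state, states))
  for (k in seq_len(nrow(df)))
    values[idx[k, 1], idx[k, 2]] <- values[idx[k, 1], idx[k, 2]] + df$value[k]

  keep <- rowSums(values) > 0
  values <- values[keep, , drop = FALSE]
  if (nrow(values) == 0L)
    stop("no species with positive utilization at stage '", stage, "'",
         call. = FALSE)
  p <- values / rowSums(values)

  structure(list(stage = stage, species = rownames(values), states = states,
                 values = values, p = p, state_def = state_def,
                 measure = measure),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("community_matrix: stage ", x$stage, ", ", length(x$species),
      " species x ", length(x$states), " ", x$state_def, " states (measure: ",
      x$measure, ")\n", sep = "")
  invisible(x)
}
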