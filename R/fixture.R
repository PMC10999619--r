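# md5 of the shipped species-by-stage reference table; guards transcription
SPECIES_TABLE_MD5 <- "c851ba2536b7479774b5eb3030fd265e"

#' Load the packaged species-by-stage reference table
#'
#' Returns the packaged transcription of the study's species table: 46
#' species with, for each of the three degradation stages (S1 healthy swamp
#' wetland, S2 slightly degraded wet meadow, S3 degraded dry meadow), the
#' importance value, Levins niche width and stable-module group letter
#' (`a`–`e`), `NA` where the species was present but unassigned, and absence
#' marked by `NA` values with `present_sX = FALSE`. One cell of the printed
#' source ("0.01/100") is transcribed as width 1.00, with the raw string kept
#' in the `note` column.
#'
#' @param check_integrity verify the file checksum before parsing
#'   (default `TRUE`).
#' @return a data frame of class `species_stage_table` with columns
#'   `species_no`, `species`, `iv_s1`, `b_s1`, `grp_s1`, ..., `grp_s3`,
#'   `present_s1`..`present_s3`, `note`.
#' @export
load_species_table <- function(check_integrity = TRUE) {
  path <- system.file("extdata", "species_stage_table.csv",
                      package = "nicheweb", mustWork = TRUE)
  if (isTRUE(check_integrity)) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, SPECIES_TABLE_MD5))
      stop("integrity error: species table checksum mismatch (",
           md5, " != ", SPECIES_TABLE_MD5, ")", call. = FALSE)
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                  colClasses = "character")
  df <- data.frame(species_no = as.integer(raw$species_no),
                   species = raw$species, stringsAsFactors = FALSE)
  for (s in c("s1", "s2", "s3")) {
    iv <- raw[[paste0("iv_", s)]]
    b <- raw[[paste0("b_", s)]]
    grp <- raw[[paste0("grp_", s)]]
    absent <- iv == ABSENT_MARK
    df[[paste0("iv_", s)]] <- ifelse(absent, NA, suppressWarnings(as.numeric(iv)))
    df[[paste0("b_", s)]] <- ifelse(absent, NA, suppressWarnings(as.numeric(b)))
    df[[paste0("grp_", s)]] <- ifelse(absent | grp == "N/A", NA, grp)
    df[[paste0("present_", s)]] <- !absent
  }
  df$note <- raw$note

  if (nrow(df) != 46L)
    stop("integrity error: expected 46 species rows, found ", nrow(df),
         call. = FALSE)
  if (!identical(sort(df$species_no), 1:46))
    stop("integrity error: species_no must be 1..46 without repeats",
         call. = FALSE)
  class(df) <- c("species_stage_table", "data.frame")
  df
}

#' Count species and genera in a species table
#'
#' Species are counted as distinct canonical names; genera as distinct first
#' tokens of the binomial. (Families are not derivable from binomials and are
#' not counted.)
#'
#' @param table a `species_stage_table` or any data frame with a `species`
#'   column.
#' @return a list with `n_species` and `n_genera`.
#' @examples
#' count_taxa(data.frame(species = "Poa annua"))  # 1 species, 1 genus
#' @export
count_taxa <- function(table) {
  if (nrow(table) == 0L) stop("empty species table", call. = FALSE)
  sp <- unique(canonicalize_species(table$species))
  genera <- unique(vapply(strsplit(sp, " ", fixed = TRUE), `[[`, "", 1L))
  list(n_species = length(sp), n_genera = length(genera))
}

#' Per-stage module partitions from a species table
#'
#' Converts the group-letter columns of a [load_species_table()] table into
#' one membership vector per stage, as consumed by [stable_groups()]:
#' species with a group letter share that letter as module label; species
#' present but unassigned each get a unique singleton label; absent species
#' are omitted from that stage.
#'
#' @param table a `species_stage_table`.
#' @param label_by `"species"` (default) or `"species_no"`; what to name the
#'   membership entries by.
#' @return named list of per-stage named character vectors
#'   (name = species, value = module label).
#' @export
stage_partitions <- function(table, label_by = c("species", "species_no")) {
  label_by <- match.arg(label_by)
  stages <- c(S1 = "s1", S2 = "s2", S3 = "s3")
  out <- lapply(names(stages), function(S) {
    s <- stages[[S]]
    present <- table[[paste0("present_", s)]]
    grp <- table[[paste0("grp_", s)]][present]
    nm <- if (label_by == "species") table$species[present]
          else as.character(table$species_no[present])
    lab <- ifelse(is.na(grp), paste0(S, "_singleton_", nm), grp)
    stats::setNames(lab, nm)
  })
  names(out) <- names(stages)
  out
}

#' Percent change in niche width between two stages
#'
#' Computes `100 * (B_ref - B_cmp) / B_ref`: positive when the width shrinks
#' from the reference stage to the comparison stage.
#'
#' @param x a `species_stage_table` (widths taken from its `b_sX` columns) or
#'   a long data frame with columns `species`, `stage`, `B` as produced by
#'   [niche_width_table()].
#' @param species species name as printed in the table.
#' @param ref_stage,cmp_stage stage labels (`"S1"`, `"S2"`, `"S3"`).
#' @return percent change (single number).
#' @export
width_change <- function(x, species, ref_stage, cmp_stage) {
  UseMethod("width_change")
}

#' @export
width_change.species_stage_table <- function(x, species, ref_stage, cmp_stage) {
  row <- x[x$species == species, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("species '", species, "' not found in table", call. = FALSE)
  pick <- function(stage) {
    s <- tolower(stage)
    if (!isTRUE(row[[paste0("present_", s)]]))
      stop("species '", species, "' absent at stage ", stage, call. = FALSE)
    row[[paste0("b_", s)]]
  }
  b_ref <- pick(ref_stage)
  b_cmp <- pick(cmp_stage)
  100 * (b_ref - b_cmp) / b_ref
}

#' @export
width_change.data.frame <- function(x, species, ref_stage, cmp_stage) {
  pick <- function(stage) {
    b <- x$B[x$species == species & x$stage == stage]
    if (length(b) != 1L)
      stop("species '", species, "' absent at stage ", stage, call. = FALSE)
    b
  }
  b_ref <- pick(ref_stage)
  100 * (b_ref - pick(cmp_stage)) / b_ref
}
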