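#' Species frequency (quadrat occupancy) at a stage
#'
#' Frequency of a species is the fraction of the stage's quadrats in which it
#' occurs. Quadrats are identified by their `quadrat` id; quadrats with no
#' records at all are invisible to the survey and hence to the denominator.
#'
#' @param records a `survey_records` data frame.
#' @param stage stage label.
#' @return named numeric vector of occupancy fractions in \[0, 1\], one per
#'   species present at the stage.
#' @export
species_frequency <- function(records, stage) {
  df <- as.data.frame(records)
  df <- df[df$stage == stage, , drop = FALSE]
  if (nrow(df) == 0L) stop("no records at stage '", stage, "'", call. = FALSE)
  n_quadrats <- length(unique(df$quadrat))
  occ <- tapply(df$quadrat, df$species, function(q) length(unique(q)))
  sort_by_name(occ / n_quadrats)
}

sort_by_name <- function(x) x[order(names(x))]

#' Species importance values at a stage
#'
#' The importance value of a species is the mean of its relative height,
#' relative cover and relative frequency within the stage. Height and cover
#' are first averaged over the quadrats where the species occurs (absence is
#' accounted for by the frequency term), then each of the three metrics is
#' relativized across species — either to the stage maximum
#' (`normalization = "max"`, the default, each relative metric peaking at 1)
#' or to the stage total (`normalization = "sum"`, relative metrics and hence
#' importance values summing to 1).
#'
#' @param records a `survey_records` data frame.
#' @param stage stage label.
#' @param normalization `"max"` or `"sum"`.
#' @return a data frame of class `importance_result` with columns `species`,
#'   `rel_height`, `rel_cover`, `rel_frequency`, `iv`; attributes `stage` and
#'   `normalization`.
#' @examples
#' rec <- data.frame(site = 1, transect = 1, stage = "S1",
#'                   quadrat = rep(c("q1", "q2"), c(2, 1)),
#'                   species = c("A a", "B b", "A a"),
#'                   height = c(20, 10, 20), cover = c(0.4, 0.1, 0.4),
#'                   abundance = 1)
#' importance_value(validate_survey_records(rec), "S1", "sum")
#' @export
importance_value <- function(records, stage, normalization = c("max", "sum")) {
  normalization <- match.arg(normalization)
  df <- as.data.frame(records)
  df <- df[df$stage == stage, , drop = FALSE]
  if (nrow(df) == 0L) stop("no records at stage '", stage, "'", call. = FALSE)

  height <- sort_by_name(tapply(df$height, df$species, mean))
  cover <- sort_by_name(tapply(df$cover, df$species, mean))
  freq <- species_frequency(records, stage)

  relativize <- function(x, what) {
    base <- if (normalization == "max") max(x) else sum(x)
    if (base <= 0)
      stop("all-zero metric across species: ", what, call. = FALSE)
    x / base
  }
  rel_h <- relativize(height, "height")
  rel_c <- relativize(cover, "cover")
  rel_f <- relativize(freq, "frequency")

  out <- data.frame(species = names(height),
                    rel_height = unname(rel_h),
                    rel_cover = unname(rel_c),
                    rel_frequency = unname(rel_f),
                    stringsAsFactors = FALSE)
  out$iv <- (out$rel_height + out$rel_cover + out$rel_frequency) / 3
  attr(out, "stage") <- stage
  attr(out, "normalization") <- normalization
  class(out) <- c("importance_result", "data.frame")
  out
}
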