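#' Levins niche breadth
#'
#' \eqn{B = 1 / \sum_j p_j^2} for a utilization profile \eqn{p} over \eqn{r}
#' resource states, ranging from 1 (all utilization in one state; perfect
#' specialist) to \eqn{r} (uniform utilization; perfect generalist). The
#' standardized breadth is \eqn{B_{std} = (B - 1) / (r - 1) \in [0, 1]}.
#' Profiles are renormalized to proportions if they do not already sum to 1.
#'
#' @param p non-negative utilization profile of length `r >= 2`.
#' @return list with `B`, `B_std` and `r`.
#' @examples
#' levins_width(rep(1, 4))$B          # 4: uniform over 4 states
#' levins_width(c(0.7, 0.2, 0.1))$B   # 1/0.54
#' @export
levins_width <- function(p) {
  p <- as_profile(p)
  if (length(p) < 2L)
    stop("profile must span at least 2 resource states", call. = FALSE)
  B <- 1 / sum(p^2)
  list(B = B, B_std = (B - 1) / (length(p) - 1), r = length(p))
}

#' Pairwise niche overlap between two utilization profiles
#'
#' Two variants over equal-length profiles \eqn{p_i}, \eqn{p_k}:
#' \describe{
#'   \item{pianka}{\eqn{O_{ik} = \sum_j p_{ij} p_{kj} /
#'     \sqrt{\sum_j p_{ij}^2 \sum_j p_{kj}^2}} — the cosine similarity of the
#'     profiles; symmetric, in \[0, 1\], equal to 1 iff the profiles are
#'     proportional.}
#'   \item{levins}{\eqn{O_{ik} = \sum_j p_{ij} p_{kj} / \sum_j p_{ij}^2} —
#'     asymmetric (overlap of species k onto species i's niche); satisfies
#'     the reciprocity identity
#'     \eqn{O_{ik} \sum_j p_{ij}^2 = O_{ki} \sum_j p_{kj}^2}.}
#' }
#'
#' @param p_i,p_k non-negative utilization profiles of equal length.
#' @param method `"pianka"` (default) or `"levins"`.
#' @return single overlap value.
#' @examples
#' niche_overlap(c(1, 0), c(0.5, 0.5), "pianka")  # 1/sqrt(2)
#' niche_overlap(c(1, 0), c(0.5, 0.5), "levins")  # 0.5
#' @export
niche_overlap <- function(p_i, p_k, method = c("pianka", "levins")) {
  method <- match.arg(method)
  if (length(p_i) != length(p_k))
    stop("profiles must have equal length", call. = FALSE)
  p_i <- as_profile(p_i, "p_i")
  p_k <- as_profile(p_k, "p_k")
  num <- sum(p_i * p_k)
  if (method == "pianka") num / sqrt(sum(p_i^2) * sum(p_k^2))
  else num / sum(p_i^2)
}

#' Pairwise niche overlap matrix for a community
#'
#' Applies [niche_overlap()] to every ordered species pair of a
#' [community_matrix()] (or a plain species-by-state proportion matrix with
#' row names). The diagonal is `NA`.
#'
#' @param x a `community_matrix`, or a numeric matrix of row-normalized
#'   utilization profiles (species in rows).
#' @param method `"pianka"` or `"levins"`.
#' @return object of class `overlap_matrix`: list with `stage`, `species`,
#'   `method` and `values` (square matrix; symmetric for pianka).
#' @export
overlap_matrix <- function(x, method = c("pianka", "levins")) {
  method <- match.arg(method)
  if (inherits(x, "community_matrix")) {
    p <- x$p
    stage <- x$stage
  } else {
    p <- as.matrix(x)
    p <- p / rowSums(p)
    stage <- attr(x, "stage") %||% NA_character_
  }
  if (nrow(p) < 2L) stop("need at least 2 species", call. = FALSE)

  cross <- p %*% t(p)            # sum_j p_ij p_kj
  ss <- rowSums(p^2)             # sum_j p_ij^2
  values <- if (method == "pianka") cross / sqrt(outer(ss, ss))
            else cross / ss      # row i divided by sum_j p_ij^2
  diag(values) <- NA_real_
  dimnames(values) <- list(rownames(p), rownames(p))

  structure(list(stage = stage, species = rownames(p), method = method,
                 values = values),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat("overlap_matrix (", x$method, "): stage ", x$stage, ", ",
      length(x$species), " species\n", sep = "")
  invisible(x)
}

# the off-diagonal values a summary should run over: unordered pairs for the
# symmetric pianka index, all ordered pairs for the asymmetric levins index
overlap_values <- function(ov) {
  v <- ov$values
  if (ov$method == "pianka") v[upper.tri(v)] else v[row(v) != col(v)]
}

#' Classify niche overlap values into intervals
#'
#' Bins pairwise overlaps into the three conventional intervals — low
#' (< 0.3), intermediate (0.3–0.8, boundaries included) and high (> 0.8) —
#' and reports the mean overlap. For the symmetric pianka index each
#' unordered pair is counted once; for the asymmetric levins index both
#' ordered directions are counted.
#'
#' @param ov an `overlap_matrix`.
#' @return object of class `overlap_classification`: list with `stage`,
#'   `method`, `n_pairs`, `counts`, `proportions` (named `low`, `mid`,
#'   `high`, summing to 1) and `mean_overlap`.
#' @export
classify_overlaps <- function(ov) {
  stopifnot(inherits(ov, "overlap_matrix"))
  v <- overlap_values(ov)
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no species pairs to classify", call. = FALSE)
  counts <- c(low = sum(v < 0.3),
              mid = sum(v >= 0.3 & v <= 0.8),
              high = sum(v > 0.8))
  structure(list(stage = ov$stage, method = ov$method, n_pairs = length(v),
                 counts = counts, proportions = counts / length(v),
                 mean_overlap = mean(v)),
            class = "overlap_classification")
}

#' @export
print.overlap_classification <- function(x, ...) {
  cat("overlap spectrum, stage ", x$stage, " (", x$method, ", ", x$n_pairs,
      " pairs)\n", sep = "")
  pct <- sprintf("%.2f%%", 100 * x$proportions)
  cat("  <0.3: ", pct[1], "   0.3-0.8: ", pct[2], "   >0.8: ", pct[3],
      "   mean: ", sprintf("%.2f", x$mean_overlap), "\n", sep = "")
  invisible(x)
}

#' Ordinary least-squares regression of niche width on importance value
#'
#' Fits `y ~ x` by OLS via [stats::lm()] and reports slope, intercept,
#' \eqn{R^2} (squared Pearson correlation) and n. Used to examine whether
#' more dominant species occupy broader niches.
#'
#' @param x predictor (e.g. importance values).
#' @param y response (e.g. Levins widths).
#' @return list of class `iv_width_regression` with `slope`, `intercept`,
#'   `r_squared`, `n` and the underlying `model`.
#' @export
iv_width_regression <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance in x", call. = FALSE)
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (stats::var(y) == 0) 0
                             else unname(cor(x, y)^2),
                 n = length(x), model = fit),
            class = "iv_width_regression")
}

#' @export
print.iv_width_regression <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): y = %.4f + %.4f x,  R^2 = %.4f\n",
              x$n, x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' Levins niche widths for all species at all stages
#'
#' Builds a [community_matrix()] per stage and computes [levins_width()] for
#' every species present there.
#'
#' @param records a `survey_records` data frame.
#' @param state_def,measure passed to [community_matrix()].
#' @return long data frame with columns `species`, `stage`, `B`, `B_std`, `r`.
#' @export
niche_width_table <- function(records, state_def = "quadrat",
                              measure = "abundance") {
  df <- as.data.frame(records)
  stages <- sort(unique(df$stage))
  rows <- lapply(stages, function(s) {
    cm <- community_matrix(records, s, state_def = state_def,
                           measure = measure)
    B <- 1 / rowSums(cm$p^2)
    r <- ncol(cm$p)
    data.frame(species = cm$species, stage = s, B = unname(B),
               B_std = unname((B - 1) / (r - 1)), r = r,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
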