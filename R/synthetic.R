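#' Configuration for the synthetic community generator
#'
#' Defaults mirror the emulated survey design: 46 species over 3 degradation
#' stages, 6 sites x 3 transects x 3 quadrats = 54 one-square-metre quadrats
#' per stage, and a stage-wise homogenization weight (0.1, 0.4, 0.7) that
#' pulls every species' utilization profile toward a stage-shared optimum,
#' so mean niche overlap rises along the gradient.
#'
#' @param n_species number of species.
#' @param n_sites,n_transects number of sites and transects per site used to
#'   label quadrats.
#' @param n_quadrats_per_stage quadrats (resource states) per stage; default
#'   `n_sites * n_transects * 3`.
#' @param stages ordered stage labels.
#' @param homogenization per-stage scalar in \[0, 1\], one per stage,
#'   non-decreasing by default: weight of the stage-shared profile blended
#'   into each species' own profile.
#' @param breadth_mix either a length-2 range — per-species symmetric
#'   Dirichlet concentrations are drawn log-uniformly from it (low values
#'   give specialists, high values generalists) — or a length-`n_species`
#'   vector of concentrations.
#' @param abundance_scale expected individuals (or clumps) per occupied
#'   quadrat under a uniform profile; per-quadrat counts are Poisson with
#'   mean `abundance_scale * r * p_ij` for `r` quadrats.
#' @param height_meanlog,height_sdlog log-normal parameters for species mean
#'   heights (arbitrary length units; only relative heights matter).
#' @param cover_halfsat abundance at which simulated cover reaches
#'   `1 - exp(-1)`; cover is `1 - exp(-abundance / cover_halfsat)`.
#' @param seed integer seed; per-stage sub-seeds are derived from it so that
#'   adding a stage never perturbs earlier stages.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_species = 46L,
                             n_sites = 6L,
                             n_transects = 3L,
                             n_quadrats_per_stage = NULL,
                             stages = c("S1", "S2", "S3"),
                             homogenization = c(0.1, 0.4, 0.7),
                             breadth_mix = c(0.05, 5),
                             abundance_scale = 20,
                             height_meanlog = log(15),
                             height_sdlog = 0.5,
                             cover_halfsat = 25,
                             seed = 1L) {
  cfg <- list(n_species = as.integer(n_species),
              n_sites = as.integer(n_sites),
              n_transects = as.integer(n_transects),
              n_quadrats_per_stage =
                as.integer(n_quadrats_per_stage %||% (n_sites * n_transects * 3L)),
              stages = as.character(stages),
              homogenization = as.numeric(homogenization),
              breadth_mix = as.numeric(breadth_mix),
              abundance_scale = as.numeric(abundance_scale),
              height_meanlog = height_meanlog,
              height_sdlog = height_sdlog,
              cover_halfsat = cover_halfsat,
              seed = as.integer(seed))
  for (f in c("n_species", "n_sites", "n_transects", "n_quadrats_per_stage",
              "abundance_scale", "cover_halfsat"))
    stopifnot_scalar_number(cfg[[f]], f, lower = 0, strict = TRUE)
  if (cfg$n_quadrats_per_stage < 2L)
    stop("need at least 2 quadrats per stage", call. = FALSE)
  if (length(cfg$stages) < 1L || anyDuplicated(cfg$stages))
    stop("stages must be distinct labels", call. = FALSE)
  if (length(cfg$homogenization) != length(cfg$stages))
    stop("homogenization must have one value per stage", call. = FALSE)
  if (any(cfg$homogenization < 0 | cfg$homogenization > 1))
    stop("homogenization must lie in [0, 1]", call. = FALSE)
  if (is.unsorted(cfg$homogenization))
    stop("homogenization must be non-decreasing across stages ",
         "(the gradient homogenizes communities)", call. = FALSE)
  if (!length(cfg$breadth_mix) %in% c(2L, cfg$n_species) ||
      any(cfg$breadth_mix <= 0))
    stop("breadth_mix must be a positive length-2 range or one ",
         "concentration per species", call. = FALSE)
  class(cfg) <- c("synthetic_config", "list")
  cfg
}

# deterministic sub-seed per stage, kept inside 32-bit integer range
stage_seed <- function(seed, k) as.integer((seed + 7919 * k) %% .Machine$integer.max)

rdirichlet1 <- function(r, alpha) {
  x <- rgamma(r, shape = alpha)
  if (sum(x) < 1e-300) {            # extreme specialist: mass underflows
    x <- numeric(r)
    x[sample.int(r, 1L)] <- 1
    return(x)
  }
  x / sum(x)
}

#' Generate a synthetic quadrat survey with known niche structure
#'
#' For each stage, each species draws a latent utilization profile over the
#' stage's quadrats from a symmetric Dirichlet with its own concentration
#' (specialists vs generalists), blended toward a stage-shared profile with
#' the stage's homogenization weight. Per-quadrat abundances are Poisson
#' around `abundance_scale * r * p_ij`; a zero count is a genuine absence.
#' Heights are species-level log-normal; cover saturates with abundance.
#' The same seed always yields the identical record set.
#'
#' @param config a [synthetic_config()] (or a list of its arguments).
#' @param seed optional override of `config$seed`.
#' @return object of class `synthetic_community`: list with
#'   \describe{
#'     \item{records}{a validated `survey_records` data frame,}
#'     \item{truth}{per stage: `profiles` (species x quadrat matrix of true
#'       \eqn{p_{ij}}), `B` (true Levins breadths), `overlap` (true pairwise
#'       Pianka matrix), `mean_overlap`,}
#'     \item{config}{the configuration used.}
#'   }
#' @export
generate_community <- function(config = synthetic_config(), seed = NULL) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  n <- config$n_species
  r <- config$n_quadrats_per_stage

  # species-level parameters: one stream, independent of the stage streams
  set.seed(config$seed)
  alpha <- if (length(config$breadth_mix) == 2L)
    exp(runif(n, log(config$breadth_mix[1]), log(config$breadth_mix[2])))
  else config$breadth_mix
  genus_pool <- sprintf("Genari%02d", 1:18)
  species_names <- paste(genus_pool[(seq_len(n) - 1L) %% 18L + 1L],
                         sprintf("species%02d", seq_len(n)))
  meanlog <- rnorm(n, config$height_meanlog, 0.3)

  quadrat_site <- (seq_len(r) - 1L) %% config$n_sites + 1L
  quadrat_transect <- ((seq_len(r) - 1L) %/% config$n_sites) %%
    config$n_transects + 1L

  truth <- list()
  recs <- list()
  for (k in seq_along(config$stages)) {
    stg <- config$stages[k]
    set.seed(stage_seed(config$seed, k))
    shared <- rdirichlet1(r, 2)
    own <- t(vapply(alpha, function(a) rdirichlet1(r, a), numeric(r)))
    h <- config$homogenization[k]
    p <- (1 - h) * own + h * matrix(shared, n, r, byrow = TRUE)
    rownames(p) <- species_names
    colnames(p) <- sprintf("%s_q%03d", stg, seq_len(r))

    lambda <- config$abundance_scale * r * p
    N <- matrix(rpois(n * r, lambda), n, r, dimnames = dimnames(p))
    heights <- matrix(rlnorm(n * r, meanlog, config$height_sdlog), n, r)
    cover <- 1 - exp(-N / config$cover_halfsat)

    present <- which(N > 0, arr.ind = TRUE)
    recs[[stg]] <- data.frame(
      site = quadrat_site[present[, 2]],
      transect = quadrat_transect[present[, 2]],
      stage = stg,
      quadrat = colnames(p)[present[, 2]],
      species = species_names[present[, 1]],
      height = round(heights[present], 2),
      cover = round(cover[present], 4),
      abundance = N[present],
      stringsAsFactors = FALSE)

    ov <- overlap_matrix(p, method = "pianka")
    truth[[stg]] <- list(profiles = p,
                         B = 1 / rowSums(p^2),
                         overlap = ov$values,
                         mean_overlap = mean(overlap_values(ov)))
  }
  records <- validate_survey_records(do.call(rbind, recs))
  rownames(records) <- NULL
  structure(list(records = records, truth = truth, config = config),
            class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat("synthetic_community: ", x$config$n_species, " species, ",
      length(x$config$stages), " stages, ",
      x$config$n_quadrats_per_stage, " quadrats/stage, seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Generate a degradation series of synthetic communities
#'
#' Wraps [generate_community()] for a config whose homogenization increases
#' strictly across stages, and returns the per-stage pieces together with
#' the true mean pairwise Pianka overlap per stage — which increases along
#' the gradient by construction.
#'
#' @inheritParams generate_community
#' @param monotone_check error if homogenization is not strictly increasing
#'   (default `TRUE`).
#' @return object of class `degradation_series`: list with `stages`,
#'   `records` (all stages), `truth`, `true_mean_overlap` (named vector) and
#'   `config`.
#' @export
degradation_series <- function(config = synthetic_config(), seed = NULL,
                               monotone_check = TRUE) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  if (isTRUE(monotone_check) &&
      any(diff(config$homogenization) <= 0))
    stop("homogenization must be strictly increasing across stages ",
         "for a degradation series", call. = FALSE)
  com <- generate_community(config, seed)
  structure(list(stages = config$stages,
                 records = com$records,
                 truth = com$truth,
                 true_mean_overlap =
                   vapply(com$truth, `[[`, 0, "mean_overlap"),
                 config = com$config),
            class = "degradation_series")
}
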