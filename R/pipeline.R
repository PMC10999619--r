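default_params <- function() {
  list(state_def = "quadrat", measure = "abundance",
       iv_normalization = "max", overlap_method = "pianka",
       threshold = 0, symmetrize = "mean", module_method = "greedy",
       min_shared_stages = 2L)
}

#' Run the full stage-wise niche analysis pipeline
#'
#' Chains the whole analysis for every stage present in the input: species
#' richness, importance values, Levins niche widths, pairwise overlaps and
#' their interval spectrum, the weighted overlap network, modularity-based
#' modules — then cross-stage stable module groups. Inputs come from a survey
#' CSV or from the synthetic generator; every analysis choice is an explicit
#' config key. With a fixed seed the run (and its written files) is fully
#' deterministic; a manifest JSON echoing every parameter is written next to
#' the outputs.
#'
#' @param config a path to a YAML file or an equivalent nested list with
#'   elements:
#'   \describe{
#'     \item{input}{either `list(csv = "path")` or
#'       `list(generate = list(...))` with [synthetic_config()] arguments;}
#'     \item{params}{any of `state_def`, `measure`, `iv_normalization`,
#'       `overlap_method`, `threshold`, `symmetrize`, `module_method`,
#'       `min_shared_stages` (defaults as in the individual functions);}
#'     \item{seed}{integer seed for generated input;}
#'     \item{output}{`list(dir = "path")`, optional — when present, tidy CSV
#'       /TSV outputs and `manifest.json` are written there.}
#'   }
#' @return (invisibly) object of class `pipeline_result`: list with
#'   `stage_reports` (per stage: `stage`, `richness`, `iv`, `widths`,
#'   `classification`, `network`, `partition`, `files`), `stable_groups`,
#'   `params`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  params <- modifyList(default_params(), config$params %||% list())
  seed <- config$seed %||% 1L

  if (!is.null(config$input$csv)) {
    records <- read_survey_records(config$input$csv,
                                   dialect = config$input$dialect %||% list())
    input_desc <- list(csv = config$input$csv)
  } else if (!is.null(config$input$generate)) {
    gen_args <- config$input$generate
    if (is.null(gen_args$seed)) gen_args$seed <- seed
    com <- generate_community(do.call(synthetic_config, gen_args))
    records <- com$records
    input_desc <- list(generate = gen_args)
  } else {
    stop("config$input must provide either 'csv' or 'generate'",
         call. = FALSE)
  }

  out_dir <- config$output$dir %||% NULL
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(df, name) {
    if (is.null(out_dir)) return(NULL)
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
    path
  }

  stages <- sort(unique(records$stage))
  reports <- list()
  partitions <- list()
  presence <- list()
  class_rows <- list()

  for (stg in stages) {
    message("[nicheweb] stage ", stg)
    cm <- community_matrix(records, stg, state_def = params$state_def,
                           measure = params$measure)
    iv <- importance_value(records, stg,
                           normalization = params$iv_normalization)
    widths <- niche_width_table(records[records$stage == stg, ],
                                state_def = params$state_def,
                                measure = params$measure)
    ov <- overlap_matrix(cm, method = params$overlap_method)
    cls <- classify_overlaps(ov)
    net <- build_network(ov, threshold = params$threshold,
                         symmetrize = params$symmetrize)
    part <- detect_modules(net, method = params$module_method)
    partitions[[stg]] <- part
    presence[[stg]] <- cm$species

    keep <- if (ov$method == "pianka") upper.tri(ov$values)
            else row(ov$values) != col(ov$values)
    pairs <- which(keep & !is.na(ov$values), arr.ind = TRUE)
    pair_df <- data.frame(stage = stg,
                          species_i = ov$species[pairs[, 1]],
                          species_k = ov$species[pairs[, 2]],
                          overlap = ov$values[pairs],
                          stringsAsFactors = FALSE)
    files <- c(
      iv = emit(cbind(stage = stg, as.data.frame(iv)),
                sprintf("importance_%s.csv", stg)),
      widths = emit(widths, sprintf("niche_width_%s.csv", stg)),
      overlaps = emit(pair_df, sprintf("overlap_pairs_%s.csv", stg)),
      modules = emit(data.frame(stage = stg,
                                species = names(part$membership),
                                module = as.integer(part$membership)),
                     sprintf("modules_%s.csv", stg)))
    if (!is.null(out_dir)) {
      net_path <- file.path(out_dir, sprintf("network_%s.tsv", stg))
      export_network(net, net_path, format = "tsv", partition = part)
      files <- c(files, network = net_path)
    }
    class_rows[[stg]] <- data.frame(
      stage = stg, n_pairs = cls$n_pairs,
      pct_low = 100 * cls$proportions[["low"]],
      pct_mid = 100 * cls$proportions[["mid"]],
      pct_high = 100 * cls$proportions[["high"]],
      mean_overlap = cls$mean_overlap)
    reports[[stg]] <- list(stage = stg, richness = nrow(widths), iv = iv,
                           widths = widths, classification = cls,
                           network = net, partition = part,
                           files = files)
  }

  class_df <- do.call(rbind, class_rows)
  rownames(class_df) <- NULL
  emit(class_df, "overlap_classification.csv")

  groups <- NULL
  if (length(stages) >= 2L) {
    groups <- stable_groups(partitions, presence,
                            min_shared_stages = params$min_shared_stages)
    gdf <- if (length(groups))
      data.frame(group = rep(letters[seq_along(groups)], lengths(groups)),
                 species = unlist(groups), row.names = NULL)
    else data.frame(group = character(), species = character())
    emit(gdf, "stable_groups.csv")
  } else {
    message("[nicheweb] single stage: stable-group step skipped")
  }

  manifest <- list(package = "nicheweb",
                   version = as.character(utils::packageVersion("nicheweb")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = seed, input = input_desc, params = params,
                   stages = stages)
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(structure(list(stage_reports = reports,
                           classification = class_df,
                           stable_groups = groups,
                           params = params, manifest = manifest),
                      class = "pipeline_result"))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", length(x$stage_reports), "stage(s)\n")
  print(x$classification)
  if (!is.null(x$stable_groups)) print(x$stable_groups)
  invisible(x)
}

#' Verify the packaged species table against its printed source values
#'
#' Recomputes every quantity derivable from the packaged species-by-stage
#' table and compares it with the corresponding printed value: total species
#' and genus counts, the maximum S1 niche width and that species' importance
#' value, the Triglochin palustre width decreases from S1 to S2 and S3
#' (printed from 2 d.p. table values, hence the percentage-point tolerance),
#' and the five stable module groups recovered from the per-stage group
#' partitions.
#'
#' @param tolerance_pp tolerance in percentage points for the width-change
#'   checks (default 0.05).
#' @return data frame of class `fixture_verification` with columns `check`,
#'   `expected`, `observed`, `pass`; attribute `ok` is `TRUE` when every
#'   check passes.
#' @export
verify_fixture <- function(tolerance_pp = 0.05) {
  tab <- load_species_table()
  taxa <- count_taxa(tab)
  w_max <- max(tab$b_s1, na.rm = TRUE)
  sp_max <- tab$species[which.max(tab$b_s1)]
  iv_max <- tab$iv_s1[which.max(tab$b_s1)]
  d12 <- width_change(tab, "Triglochin palustre", "S1", "S2")
  d13 <- width_change(tab, "Triglochin palustre", "S1", "S3")

  groups <- stable_groups(stage_partitions(tab, label_by = "species_no"))
  expected_groups <- list(
    a = c("6", "8", "17", "22", "25", "27", "42"),
    b = c("2", "9", "18", "26", "32", "45"),
    c = c("12", "37"), d = c("35", "38"), e = c("15", "41"))
  got_groups <- lapply(groups, function(g) sort(as.integer(g)))
  exp_sorted <- lapply(expected_groups, function(g) sort(as.integer(g)))
  groups_ok <- length(got_groups) == length(exp_sorted) &&
    all(vapply(exp_sorted, function(e)
      any(vapply(got_groups, identical, TRUE, e)), TRUE))

  checks <- data.frame(
    check = c("n_species", "n_genera", "max_s1_width",
              "max_s1_width_species", "max_s1_width_iv",
              "triglochin_s1_s2_decrease_pct",
              "triglochin_s1_s3_decrease_pct", "stable_groups_a_to_e"),
    expected = c("46", "33", "4.92", "Triglochin palustre", "0.07",
                 "79.66", "40.70", "5 groups: 7/6/2/2/2 members"),
    observed = c(as.character(taxa$n_species), as.character(taxa$n_genera),
                 sprintf("%.2f", w_max), sp_max, sprintf("%.2f", iv_max),
                 sprintf("%.4f", d12), sprintf("%.4f", d13),
                 sprintf("%d groups: %s members", length(got_groups),
                         paste(lengths(got_groups), collapse = "/"))),
    pass = c(taxa$n_species == 46L, taxa$n_genera == 33L,
             isTRUE(all.equal(w_max, 4.92)),
             sp_max == "Triglochin palustre",
             isTRUE(all.equal(iv_max, 0.07)),
             abs(d12 - 79.66) <= tolerance_pp,
             abs(d13 - 40.70) <= tolerance_pp,
             groups_ok),
    stringsAsFactors = FALSE)
  attr(checks, "ok") <- all(checks$pass)
  class(checks) <- c("fixture_verification", "data.frame")
  checks
}

#' @export
print.fixture_verification <- function(x, ...) {
  df <- x
  class(df) <- "data.frame"
  print(df, row.names = FALSE)
  cat(if (attr(x, "ok")) "all checks passed\n" else "CHECKS FAILED\n")
  invisible(x)
}
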