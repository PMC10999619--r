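#' Build a weighted niche-overlap network
#'
#' Nodes are species; an edge joins species i and k when their symmetrized
#' overlap exceeds `threshold` (strictly), with the overlap as edge weight.
#' The asymmetric Levins overlaps are symmetrized by the chosen rule;
#' symmetrization is a no-op for the already-symmetric Pianka index.
#' Species left without any edge are retained as isolated nodes.
#'
#' @param ov an [overlap_matrix()].
#' @param threshold minimum retained weight (edges require weight >
#'   threshold); must be non-negative. Default 0: every positive overlap
#'   becomes an edge.
#' @param symmetrize `"mean"`, `"max"` or `"min"` of the two ordered-pair
#'   values.
#' @return object of class `overlap_network`: list with `stage`, `species`,
#'   `weights` (symmetric matrix, zero where no edge), `threshold`,
#'   `symmetrize`, `method`.
#' @export
build_network <- function(ov, threshold = 0,
                          symmetrize = c("mean", "max", "min")) {
  stopifnot(inherits(ov, "overlap_matrix"))
  symmetrize <- match.arg(symmetrize)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("threshold must be a single non-negative number", call. = FALSE)
  V <- ov$values
  V[is.na(V)] <- 0
  W <- switch(symmetrize,
              mean = (V + t(V)) / 2,
              max = pmax(V, t(V)),
              min = pmin(V, t(V)))
  diag(W) <- 0
  W[W <= threshold] <- 0
  structure(list(stage = ov$stage, species = ov$species, weights = W,
                 threshold = threshold, symmetrize = symmetrize,
                 method = ov$method),
            class = "overlap_network")
}

#' @export
print.overlap_network <- function(x, ...) {
  n_edges <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat("overlap_network: stage ", x$stage, ", ", length(x$species),
      " species, ", n_edges, " edges (threshold ", x$threshold, ", ",
      x$symmetrize, "-symmetrized ", x$method, ")\n", sep = "")
  invisible(x)
}

#' Convert an overlap network to an igraph object
#'
#' @param network an `overlap_network`.
#' @param partition optional `module_partition`; stored as node attribute
#'   `module`.
#' @param species_no optional named integer vector mapping species to node
#'   label numbers; stored as node attribute `species_no`.
#' @return an undirected weighted [igraph::graph].
#' @export
as_igraph <- function(network, partition = NULL, species_no = NULL) {
  g <- igraph::graph_from_adjacency_matrix(network$weights,
                                           mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g <- igraph::set_graph_attr(g, "stage", as.character(network$stage))
  g <- igraph::set_graph_attr(g, "threshold", network$threshold)
  g <- igraph::set_graph_attr(g, "symmetrize", network$symmetrize)
  g <- igraph::set_graph_attr(g, "method", network$method)
  if (!is.null(partition)) {
    mem <- partition$membership[network$species]
    g <- igraph::set_vertex_attr(g, "module", value = as.integer(mem))
  }
  if (!is.null(species_no)) {
    no <- species_no[network$species]
    g <- igraph::set_vertex_attr(g, "species_no", value = as.integer(no))
  }
  g
}

#' Export a niche-overlap network to file
#'
#' Writes GraphML (via igraph, with stage/threshold metadata as graph
#' attributes) or a flat TSV holding one `node` row per species (with
#' optional module and species-number attributes) and one `edge` row per
#' edge. Both formats round-trip through [import_network()] losslessly,
#' including isolated nodes.
#'
#' @inheritParams as_igraph
#' @param path output file path.
#' @param format `"graphml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "tsv"),
                           partition = NULL, species_no = NULL) {
  if (!is.character(format) || !all(format %in% c("graphml", "tsv")))
    stop("unknown format: ", paste(setdiff(format, c("graphml", "tsv")),
                                   collapse = ", "), call. = FALSE)
  format <- match.arg(format)
  if (format == "graphml") {
    g <- as_igraph(network, partition, species_no)
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  sp <- network$species
  mem <- if (!is.null(partition)) as.integer(partition$membership[sp])
         else rep(NA_integer_, length(sp))
  no <- if (!is.null(species_no)) as.integer(species_no[sp])
        else rep(NA_integer_, length(sp))
  nodes <- data.frame(type = "node", from = sp, to = NA_character_,
                      weight = NA_real_, module = mem, species_no = no,
                      stringsAsFactors = FALSE)
  W <- network$weights
  ut <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  edges <- data.frame(type = "edge", from = sp[ut[, 1]], to = sp[ut[, 2]],
                      weight = W[ut], module = NA_integer_,
                      species_no = NA_integer_, stringsAsFactors = FALSE)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# overlap_network\tstage=%s\tthreshold=%.15g\tsymmetrize=%s\tmethod=%s",
                     network$stage, network$threshold, network$symmetrize,
                     network$method), con)
  utils::write.table(rbind(nodes, edges), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Import a niche-overlap network written by [export_network()]
#'
#' @param path file path.
#' @param format `"graphml"` or `"tsv"`.
#' @return an `overlap_network`; node attributes `module`/`species_no`, when
#'   present, are attached as attributes `membership` and `species_no`.
#' @export
import_network <- function(path, format = c("graphml", "tsv")) {
  if (!is.character(format) || !all(format %in% c("graphml", "tsv")))
    stop("unknown format: ", paste(setdiff(format, c("graphml", "tsv")),
                                   collapse = ", "), call. = FALSE)
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    sp <- igraph::vertex_attr(g, "name")
    W <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight",
                                               sparse = FALSE))
    dimnames(W) <- list(sp, sp)
    net <- structure(list(stage = igraph::graph_attr(g, "stage"),
                          species = sp, weights = W,
                          threshold = igraph::graph_attr(g, "threshold"),
                          symmetrize = igraph::graph_attr(g, "symmetrize"),
                          method = igraph::graph_attr(g, "method")),
                     class = "overlap_network")
    if ("module" %in% igraph::vertex_attr_names(g))
      attr(net, "membership") <-
        setNames(igraph::vertex_attr(g, "module"), sp)
    if ("species_no" %in% igraph::vertex_attr_names(g))
      attr(net, "species_no") <-
        setNames(igraph::vertex_attr(g, "species_no"), sp)
    return(net)
  }
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  meta <- strsplit(sub("^# overlap_network\t", "", header), "\t")[[1]]
  meta <- setNames(sub("^[^=]*=", "", meta), sub("=.*$", "", meta))
  df <- read.csv(path, sep = "\t", skip = 1L, stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8")
  sp <- df$from[df$type == "node"]
  W <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
  e <- df[df$type == "edge", , drop = FALSE]
  W[cbind(match(e$from, sp), match(e$to, sp))] <- e$weight
  W <- W + t(W)
  net <- structure(list(stage = meta[["stage"]], species = sp, weights = W,
                        threshold = as.numeric(meta[["threshold"]]),
                        symmetrize = meta[["symmetrize"]],
                        method = meta[["method"]]),
                   class = "overlap_network")
  mem <- df$module[df$type == "node"]
  if (any(!is.na(mem))) attr(net, "membership") <- setNames(mem, sp)
  no <- df$species_no[df$type == "node"]
  if (any(!is.na(no))) attr(net, "species_no") <- setNames(no, sp)
  net
}

#' Species groups with stable module membership across stages
#'
#' Given one module partition per degradation stage, finds the maximal
#' disjoint species groups in which every member pair (i) co-occurs in at
#' least `min_shared_stages` stages and (ii) is assigned to the same module
#' in every stage where both are present. These are the cross-stage "stable
#' module groups" of the analysis. Groups have at least 2 members; the
#' result does not depend on the order the stages are given in.
#'
#' @param partitions list of per-stage memberships: each a named vector
#'   (name = species, value = module label) or a `module_partition`.
#' @param presence optional list of per-stage species vectors; defaults to
#'   the names of each partition.
#' @param min_shared_stages minimum number of stages a pair must share
#'   (default 2).
#' @return object of class `stable_groups`: list of character vectors of
#'   species, ordered by decreasing size then alphabetically; attribute
#'   `min_shared_stages`.
#' @export
stable_groups <- function(partitions, presence = NULL, min_shared_stages = 2L) {
  if (length(partitions) < 2L)
    stop("need partitions for at least 2 stages", call. = FALSE)
  parts <- lapply(partitions, function(p) {
    if (inherits(p, "module_partition")) p$membership else p
  })
  if (any(vapply(parts, function(p) is.null(names(p)), TRUE)))
    stop("each partition must be named by species", call. = FALSE)
  presence <- presence %||% lapply(parts, names)

  species <- sort(unique(unlist(presence)))
  n <- length(species)
  compat <- matrix(FALSE, n, n, dimnames = list(species, species))
  pres_mat <- vapply(presence, function(p) species %in% p, logical(n))
  if (n > 0) {
    for (i in seq_len(n - 1L)) for (k in (i + 1L):n) {
      shared <- which(pres_mat[i, ] & pres_mat[k, ])
      if (length(shared) < min_shared_stages) next
      same <- vapply(shared, function(s) {
        p <- parts[[s]]
        si <- species[i]; sk <- species[k]
        si %in% names(p) && sk %in% names(p) &&
          identical(p[[si]], p[[sk]])
      }, logical(1))
      compat[i, k] <- compat[k, i] <- all(same)
    }
  }

  g <- igraph::graph_from_adjacency_matrix(compat, mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- list()
  for (c_id in unique(comp)) {
    members <- species[comp == c_id]
    if (length(members) < 2L) next
    # the co-moduled relation is usually transitive (components are cliques);
    # if not, peel off maximal cliques deterministically
    sub <- compat[members, members, drop = FALSE]
    if (all(sub[upper.tri(sub)])) {
      groups[[length(groups) + 1L]] <- sort(members)
    } else {
      gs <- igraph::induced_subgraph(g, members)
      remaining <- members
      while (length(remaining) >= 2L) {
        gr <- igraph::induced_subgraph(g, remaining)
        cl <- igraph::largest_cliques(gr)
        cl <- lapply(cl, function(v) sort(igraph::V(gr)$name[v]))
        cl <- cl[order(vapply(cl, paste, "", collapse = "|"))]
        best <- cl[[1]]
        if (length(best) < 2L) break
        groups[[length(groups) + 1L]] <- best
        remaining <- setdiff(remaining, best)
      }
    }
  }
  ord <- order(-lengths(groups),
               vapply(groups, function(g) g[1], ""))
  structure(groups[ord], min_shared_stages = min_shared_stages,
            class = "stable_groups")
}

#' @export
print.stable_groups <- function(x, ...) {
  cat("stable module groups (pairs sharing >= ",
      attr(x, "min_shared_stages"), " stages):\n", sep = "")
  if (length(x) == 0L) cat("  none\n")
  for (i in seq_along(x))
    cat("  ", letters[min(i, 26)], ": ", paste(x[[i]], collapse = ", "),
        "\n", sep = "")
  invisible(x)
}
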