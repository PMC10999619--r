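test_that("network building thresholds symmetrized overlaps", {
  v <- matrix(0.5, 3, 3)
  net <- build_network(manual_overlap(v), threshold = 0)
  expect_equal(sum(net$weights[upper.tri(net$weights)] > 0), 3L)

  net06 <- build_network(manual_overlap(v), threshold = 0.6)
  expect_equal(sum(net06$weights > 0), 0L)
  expect_equal(length(net06$species), 3L)  # isolated nodes retained

  expect_error(build_network(manual_overlap(v), threshold = -1),
               "non-negative")

  # asymmetric levins pair symmetrized by the chosen rule
  lv <- matrix(0, 2, 2)
  lv[1, 2] <- 0.5
  lv[2, 1] <- 1.0
  ovl <- manual_overlap(lv, method = "levins")
  ovl$values <- lv; diag(ovl$values) <- NA  # keep asymmetry
  expect_equal(build_network(ovl, symmetrize = "mean")$weights[1, 2], 0.75)
  expect_equal(build_network(ovl, symmetrize = "max")$weights[1, 2], 1.0)
  expect_equal(build_network(ovl, symmetrize = "min")$weights[1, 2], 0.5)
})

test_that("modularity matches hand computations and igraph", {
  W <- two_triangles()
  expect_equal(modularity_q(W, c(1, 1, 1, 2, 2, 2)), 0.5)
  expect_equal(modularity_q(W, rep(1, 6)), 0)
  W2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(modularity_q(W2, c(1, 2)), -0.5)
  expect_error(modularity_q(matrix(0, 3, 3), c(1, 2, 3)), "edgeless")

  set.seed(31)
  for (i in 1:20) {
    A <- random_graph(sample(5:12, 1))
    if (sum(A) == 0) next
    mem <- sample(1:3, nrow(A), replace = TRUE)
    g <- igraph::graph_from_adjacency_matrix(A, "undirected", weighted = TRUE)
    expect_equal(modularity_q(A, mem),
                 igraph::modularity(g, mem, weights = igraph::E(g)$weight),
                 tolerance = 1e-9)
  }
})

test_that("Q is invariant under global edge-weight rescaling", {
  set.seed(41)
  A <- random_graph(9)
  mem <- sample(1:3, 9, replace = TRUE)
  expect_equal(modularity_q(A, mem), modularity_q(A * 13.7, mem),
               tolerance = 1e-12)
})

test_that("module detection recovers planted structure with every method", {
  W <- two_triangles()
  for (method in c("greedy", "multilevel", "exhaustive")) {
    part <- detect_modules(W, method)
    expect_equal(part$Q, 0.5, tolerance = 1e-12)
    expect_equal(part$n_modules, 2L)
    expect_equal(unname(part$membership[1:3]), rep(part$membership[[1]], 3))
  }

  # complete uniform graph has no modular structure
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  for (method in c("greedy", "exhaustive")) {
    part <- detect_modules(K4, method)
    expect_equal(part$Q, 0, tolerance = 1e-12)
    expect_equal(part$n_modules, 1L)
  }

  # barbell: two triangles joined by one weak edge split at the bridge
  Wb <- two_triangles()
  Wb[3, 4] <- Wb[4, 3] <- 0.01
  for (method in c("greedy", "multilevel", "exhaustive")) {
    part <- detect_modules(Wb, method)
    expect_equal(part$n_modules, 2L)
    expect_equal(unname(part$membership[1:3]), rep(part$membership[[1]], 3))
    expect_equal(unname(part$membership[4:6]), rep(part$membership[[4]], 3))
  }
})

test_that("heuristics never beat the exhaustive oracle on small graphs", {
  set.seed(51)
  for (i in 1:30) {
    A <- random_graph(sample(4:8, 1))
    if (sum(A) == 0) next
    qx <- detect_modules(A, "exhaustive")$Q
    expect_lte(detect_modules(A, "greedy")$Q, qx + 1e-12)
    expect_lte(detect_modules(A, "multilevel")$Q, qx + 1e-12)
  }
})

test_that("exhaustive search refuses large graphs; isolated nodes stay singleton", {
  A <- random_graph(13, p_edge = 1)
  expect_error(detect_modules(A, "exhaustive"), "limit 12")

  W <- two_triangles()
  W8 <- rbind(cbind(W, 0, 0), 0, 0)  # two isolated nodes appended
  dimnames(W8) <- list(c(letters[1:6], "g", "h"), c(letters[1:6], "g", "h"))
  part <- detect_modules(W8, "greedy")
  expect_equal(part$n_modules, 2L)   # isolated singletons not counted
  expect_equal(length(unique(part$membership)), 4L)
  expect_false(part$membership[["g"]] == part$membership[["h"]])
  # reported count equals the count in the maximizing partition itself
  expect_equal(part$n_modules,
               length(unique(part$membership[rowSums(W8) > 0])))

  part2 <- detect_modules(W, "greedy")
  expect_equal(part2$membership, detect_modules(W, "greedy")$membership)
})

test_that("detection is deterministic and invariant to weight rescaling", {
  set.seed(61)
  A <- random_graph(10)
  p1 <- detect_modules(A, "greedy")
  p2 <- detect_modules(A * 5, "greedy")
  expect_identical(p1$membership, p2$membership)
  expect_equal(p1$Q, p2$Q, tolerance = 1e-12)
})

test_that("network export round-trips through GraphML and TSV", {
  v <- matrix(0, 4, 4)
  v[1, 2] <- v[2, 1] <- 0.9
  v[2, 3] <- v[3, 2] <- 0.4
  dimnames(v) <- list(paste0("Sp s", 1:4), paste0("Sp s", 1:4))
  net <- build_network(manual_overlap(v), threshold = 0.1)
  part <- detect_modules(net, "greedy")
  no <- setNames(1:4, net$species)

  for (fmt in c("graphml", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_network(net, path, format = fmt, partition = part,
                   species_no = no)
    back <- import_network(path, format = fmt)
    expect_equal(back$weights[net$species, net$species], net$weights,
                 tolerance = 1e-12)
    expect_equal(back$threshold, net$threshold)
    expect_equal(unname(attr(back, "species_no")[net$species]), 1:4)
    expect_setequal(back$species, net$species)  # isolated node survives
  }
  expect_error(export_network(net, tempfile(), format = "dot"),
               "unknown format")
})

test_that("stable groups honor co-occurrence and shared-module rules", {
  p1 <- c(A = "m1", B = "m1", C = "m2", D = "m2", E = "m3")
  p2 <- c(A = "x", B = "x", C = "y", D = "z", E = "z")
  p3 <- c(A = "u", B = "u", C = "v", D = "v")
  gr <- stable_groups(list(p1, p2, p3))
  expect_equal(gr[[1]], c("A", "B"))
  expect_equal(length(gr), 1L)  # C-D disagree in stage 2; E only shares with D once

  # all species co-moduled everywhere -> one all-species group
  q <- c(A = "m", B = "m", C = "m")
  gr2 <- stable_groups(list(q, q))
  expect_equal(gr2[[1]], c("A", "B", "C"))

  # a species present in a single stage cannot satisfy min_shared_stages = 2
  r1 <- c(A = "m", B = "m", Z = "m")
  r2 <- c(A = "m", B = "m")
  gr3 <- stable_groups(list(r1, r2))
  expect_equal(gr3[[1]], c("A", "B"))
  expect_false("Z" %in% unlist(gr3))
})

test_that("stable groups are invariant to stage order", {
  tab <- load_species_table()
  parts <- stage_partitions(tab)
  g1 <- stable_groups(parts)
  g2 <- stable_groups(rev(parts))
  expect_equal(unclass(g1), unclass(g2), ignore_attr = TRUE)
})

test_that("the reference table's partitions yield the five lettered groups", {
  tab <- load_species_table()
  gr <- stable_groups(stage_partitions(tab, label_by = "species_no"))
  sets <- lapply(gr, function(g) sort(as.integer(g)))
  expect_true(any(vapply(sets, identical, TRUE, c(12L, 37L))))
  expect_true(any(vapply(sets, identical, TRUE, c(35L, 38L))))
  expect_true(any(vapply(sets, identical, TRUE, c(15L, 41L))))
  expect_equal(sort(lengths(sets)), c(2L, 2L, 2L, 6L, 7L))
})
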