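test_that("Levins breadth matches closed forms and hand arithmetic", {
  u <- levins_width(rep(1, 4))
  expect_equal(u$B, 4)
  expect_equal(u$B_std, 1)
  s <- levins_width(c(0, 1, 0))
  expect_equal(s$B, 1)
  expect_equal(s$B_std, 0)
  expect_equal(levins_width(c(0.7, 0.2, 0.1))$B, 1 / 0.54)
  expect_error(levins_width(c(0, 0)), "zero")
  expect_error(levins_width(1), "at least 2")
})

test_that("breadth is bounded by [1, r] and grows when mixed toward uniform", {
  set.seed(21)
  for (i in 1:50) {
    r <- sample(2:20, 1)
    p <- as.vector(random_profiles(1, r))
    b <- levins_width(p)
    expect_gte(b$B, 1)
    expect_lte(b$B, r + 1e-9)
    expect_gte(b$B_std, 0)
    expect_lte(b$B_std, 1 + 1e-9)
    t <- runif(1)
    mixed <- (1 - t) * p + t / r
    expect_gte(levins_width(mixed)$B, b$B - 1e-12)
  }
})

test_that("pairwise overlap matches the hand-computed oracles", {
  expect_equal(niche_overlap(c(0.2, 0.8), c(0.2, 0.8), "pianka"), 1)
  expect_equal(niche_overlap(c(1, 0), c(0, 1), "pianka"), 0)
  expect_equal(niche_overlap(c(1, 0), c(0, 1), "levins"), 0)
  expect_equal(niche_overlap(c(1, 0), c(0.5, 0.5), "pianka"),
               0.5 / sqrt(1 * 0.5))
  expect_equal(niche_overlap(c(1, 0), c(0.5, 0.5), "levins"), 0.5)
  expect_equal(niche_overlap(c(0.5, 0.5), c(1, 0), "levins"), 1.0)
  expect_error(niche_overlap(c(1, 0), c(1, 0, 0)), "equal length")
})

test_that("pianka overlap is symmetric, in [0,1], and 1 iff proportional", {
  set.seed(5)
  for (i in 1:30) {
    p <- random_profiles(2, 6)
    o12 <- niche_overlap(p[1, ], p[2, ], "pianka")
    expect_equal(o12, niche_overlap(p[2, ], p[1, ], "pianka"))
    expect_gte(o12, 0)
    expect_lte(o12, 1 + 1e-12)
    if (abs(o12 - 1) < 1e-12) expect_equal(p[1, ], p[2, ])
    expect_equal(niche_overlap(p[1, ], 3 * p[1, ], "pianka"), 1)
  }
})

test_that("the Levins reciprocity identity holds on random profiles", {
  set.seed(9)
  for (i in 1:100) {
    p <- random_profiles(2, sample(3:12, 1))
    o_ik <- niche_overlap(p[1, ], p[2, ], "levins")
    o_ki <- niche_overlap(p[2, ], p[1, ], "levins")
    expect_equal(o_ik * sum(p[1, ]^2), o_ki * sum(p[2, ]^2),
                 tolerance = 1e-12)
  }
})

test_that("overlap matrices populate all ordered pairs consistently", {
  p <- rbind(a = c(0.5, 0.5, 0), b = c(0.5, 0.5, 0), c = c(0, 0, 1))
  ov <- overlap_matrix(p, "pianka")
  expect_equal(ov$values["a", "b"], 1)
  expect_equal(ov$values["a", "c"], 0)
  expect_true(is.na(ov$values["a", "a"]))

  set.seed(13)
  q <- random_profiles(5, 8)
  rownames(q) <- paste0("sp", 1:5)
  lev <- overlap_matrix(q, "levins")
  for (i in 1:5) for (k in 1:5) {
    if (i == k) next
    expect_equal(lev$values[i, k], niche_overlap(q[i, ], q[k, ], "levins"),
                 tolerance = 1e-12)
  }
  pia <- overlap_matrix(q, "pianka")
  expect_equal(pia$values, t(pia$values))
})

test_that("overlap classification bins by the <0.3 / 0.3-0.8 / >0.8 scheme", {
  v <- matrix(0, 3, 3)
  v[1, 2] <- v[2, 1] <- 0.1
  v[1, 3] <- v[3, 1] <- 0.5
  v[2, 3] <- v[3, 2] <- 0.9
  cls <- classify_overlaps(manual_overlap(v))
  expect_equal(unname(cls$proportions), rep(1 / 3, 3))
  expect_equal(cls$mean_overlap, 0.5)
  expect_equal(sum(cls$proportions), 1)

  # boundary values land in the middle bin
  vb <- matrix(0, 3, 3)
  vb[1, 2] <- vb[2, 1] <- 0.3
  vb[1, 3] <- vb[3, 1] <- 0.8
  vb[2, 3] <- vb[3, 2] <- 0.1
  clb <- classify_overlaps(manual_overlap(vb))
  expect_equal(unname(clb$counts), c(1, 2, 0))

  va <- matrix(0.2, 3, 3)
  expect_equal(unname(classify_overlaps(manual_overlap(va))$proportions),
               c(1, 0, 0))
})

test_that("levins classification runs over ordered pairs, pianka over unordered", {
  set.seed(17)
  q <- random_profiles(4, 6)
  rownames(q) <- paste0("sp", 1:4)
  expect_equal(classify_overlaps(overlap_matrix(q, "pianka"))$n_pairs, 6L)
  expect_equal(classify_overlaps(overlap_matrix(q, "levins"))$n_pairs, 12L)
})

test_that("the IV-width regression matches closed-form OLS", {
  exact <- iv_width_regression(1:5, 2 * (1:5))
  expect_equal(exact$slope, 2)
  expect_equal(exact$r_squared, 1)
  expect_equal(iv_width_regression(c(1, 2, 3), c(4, 4, 4))$r_squared, 0)
  fit <- iv_width_regression(c(1, 2, 3), c(1, 3, 2))
  expect_equal(fit$slope, 0.5)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 0.25)
  expect_equal(fit$n, 3L)
  expect_error(iv_width_regression(c(2, 2, 2), c(1, 2, 3)), "zero variance")
  expect_error(iv_width_regression(1:2, 1:2), "at least 3")
})

test_that("the width table covers each species only where present", {
  rec <- toy_records(data.frame(
    stage = c("S1", "S1", "S1", "S2", "S2"),
    quadrat = c("a1", "a2", "a1", "b1", "b2"),
    species = c("A a", "A a", "B b", "A a", "A a"),
    abundance = c(2L, 2L, 1L, 3L, 1L)))
  wt <- niche_width_table(rec)
  expect_equal(sort(wt$stage[wt$species == "B b"]), "S1")
  expect_equal(nrow(wt[wt$species == "A a", ]), 2L)
  expect_true(all(wt$r == 2L))
  expect_equal(wt$B[wt$species == "A a" & wt$stage == "S1"], 2)
})
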