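test_that("survey CSV reading validates, converts cover and canonicalizes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site,transect,stage,quadrat,species,height,cover,abundance",
               "1,1,S1,q1,Kobresia  tibetica,12.5,40,8",
               "1,1,S1,q2,Leymus secalinus,30,15,3"), path)
  rec <- read_survey_records(path)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$cover, c(0.40, 0.15))  # percent input divided by 100
  expect_equal(rec$species[1], "Kobresia tibetica")

  writeLines(c("site,transect,stage,quadrat,species,height,abundance",
               "1,1,S1,q1,Poa annua,10,2"), path)
  expect_error(read_survey_records(path), "missing required column")

  writeLines(c("site,transect,stage,quadrat,species,height,cover,abundance",
               "1,1,S1,q1,Poa annua,10,-5,2"), path)
  expect_error(read_survey_records(path), "cover")

  writeLines(c("site,transect,stage,quadrat,species,height,cover,abundance",
               "1,1,S1,q1,Poa annua,10,0.2,-1"), path)
  expect_error(read_survey_records(path), "abundance")

  writeLines(c("site,transect,stage,quadrat,species,height,cover,abundance",
               "1,1,S1,q1,Poa annua,10,0.2,2",
               "1,2,S1,q1,Poa annua,11,0.3,1"), path)
  expect_error(read_survey_records(path), "S1 / q1 / Poa annua")
})

test_that("write-then-read round-trips canonicalized records", {
  rec <- toy_records(data.frame(quadrat = c("q1", "q2", "q1"),
                                species = c("Poa annua", "Poa annua",
                                            "Carex atrofusca subsp. minor"),
                                height = c(10, 12, 5), cover = c(0.2, 0.3, 0.1),
                                abundance = c(2L, 3L, 1L)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey_records(rec, path)
  back <- read_survey_records(path)
  expect_equal(as.data.frame(back), as.data.frame(rec),
               ignore_attr = TRUE)
})

test_that("species name canonicalization strips authorities, keeps rank tokens", {
  expect_equal(canonicalize_species("  CAREX  atrofusca   subsp. minor (L.) Kuek."),
               "Carex atrofusca subsp. minor")
  expect_equal(canonicalize_species("Iris lactea var. chinensis"),
               "Iris lactea var. chinensis")
  expect_equal(canonicalize_species("poa Annua L."), "Poa annua")
})

test_that("community matrix normalizes rows and drops empty species", {
  rec <- toy_records(data.frame(quadrat = c("q1", "q2", "q3"),
                                abundance = c(2L, 2L, 2L)))
  cm <- community_matrix(rec, "S1")
  expect_s3_class(cm, "community_matrix")
  expect_equal(unname(cm$p[1, ]), rep(1 / 3, 3))

  rec2 <- toy_records(data.frame(quadrat = c("q1", "q2", "q3"),
                                 species = c("A a", "B b", "B b"),
                                 abundance = c(5L, 1L, 1L)))
  cm2 <- community_matrix(rec2, "S1")
  expect_equal(unname(cm2$p["A a", ]), c(1, 0, 0))
  expect_true(all(abs(rowSums(cm2$p) - 1) < 1e-9))
})

test_that("community matrix is invariant to record row order", {
  set.seed(11)
  rec <- toy_records(data.frame(
    quadrat = rep(paste0("q", 1:4), each = 3),
    species = rep(c("A a", "B b", "C c"), 4),
    height = runif(12, 5, 30), cover = runif(12, 0.05, 0.6),
    abundance = rpois(12, 4) + 1L))
  cm1 <- community_matrix(rec, "S1")
  cm2 <- community_matrix(rec[sample(nrow(rec)), ], "S1")
  expect_identical(cm1$p, cm2$p)
})

test_that("transect pooling sums quadrat abundances", {
  # hand-summed: transect 1 holds 1+2 = 3, transect 2 holds 3+4 = 7
  rec <- toy_records(data.frame(transect = c(1L, 1L, 2L, 2L),
                                quadrat = paste0("q", 1:4),
                                abundance = 1:4))
  cm <- community_matrix(rec, "S1", state_def = "transect")
  expect_equal(unname(cm$values[1, ]), c(3, 7))
  expect_equal(unname(cm$p[1, ]), c(0.3, 0.7))
})

test_that("a stage with fewer than two resource states is rejected", {
  rec <- toy_records(data.frame(quadrat = "q1", abundance = 3L))
  expect_error(community_matrix(rec, "S1"), "fewer than 2 resource states")
})
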