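test_that("trait matrix TSV round-trips bit-exactly and derives occurrence", {
  meta <- make_meta(1, 1, 0)
  m <- make_matrix(list(t1 = c(0L, 1L), t2 = c(5L, 0L), t3 = c(2L, 3L)), meta)
  expect_identical(unname(occurrence(m)), unname(unclass(m) >= 1L))
  expect_equal(unclass(m)["t2", "A1"], 5L)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_trait_matrix(m, path)
  back <- load_trait_matrix(path)
  expect_identical(unclass(back), unclass(m))
  expect_identical(trait_ids(back), trait_ids(m))
})

test_that("trait id schemes are enforced", {
  meta <- make_meta(0, 1, 1)
  expect_silent(make_matrix(list("c.37.1" = c(1L, 0L)), meta, id_scheme = "SCOP_FSF"))
  expect_error(make_matrix(list("GO:0008658" = c(1L, 0L)), meta, id_scheme = "SCOP_FSF"),
               "SCOP_FSF scheme")
  expect_silent(make_matrix(list("GO:0008658" = c(1L, 0L)), meta, id_scheme = "GO_TERM"))
  expect_error(make_matrix(list("c.37.1" = c(1L, 0L)), meta, id_scheme = "GO_TERM"),
               "GO_TERM scheme")
})

test_that("malformed cells and duplicate ids are rejected with locations", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("trait_id\torg1\torg2", "t1\t1\t-2", "t2\t0\t1"), path)
  expect_error(load_trait_matrix(path), "t1.*org2")

  writeLines(c("trait_id\torg1\torg2", "t1\t1\t0.5", "t2\t0\t1"), path)
  expect_error(load_trait_matrix(path), "non-negative integer")

  writeLines(c("trait_id\torg1\torg2", "t1\t1\t0", "t1\t0\t1"), path)
  expect_error(load_trait_matrix(path), "duplicate trait")
})

test_that("organism metadata is validated and superkingdoms normalised", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("organism_id\tsuperkingdom\tlifestyle\tannotation_coverage",
               "org1\tBacteria\tfree_living\t0.62",
               "org2\tArchaea\tparasitic\t0.40",
               "org3\teukarya\tunknown\t"), path)
  md <- load_organism_metadata(path)
  expect_identical(md$superkingdom, c("B", "A", "E"))
  expect_identical(md$lifestyle[2], "parasitic")
  expect_true(is.na(md$annotation_coverage[3]))

  writeLines(c("organism_id\tsuperkingdom\tlifestyle\tannotation_coverage",
               "org3\tVirus\tfree_living\t1"), path)
  expect_error(load_organism_metadata(path), "unknown superkingdom")

  writeLines(c("organism_id\tsuperkingdom\tlifestyle", "org1\tB\tfree_living"), path)
  expect_error(load_organism_metadata(path), "annotation_coverage")
})

test_that("coverage filter is inclusive at the threshold", {
  meta <- organism_metadata(c("lo", "at", "hi"), c("B", "B", "E"),
                            annotation_coverage = c(0.49, 0.50, 0.90))
  m <- make_matrix(list(t1 = c(1L, 1L, 1L)), meta)
  out <- filter_dataset(m, meta, dataset_config(coverage_threshold = 0.5))
  expect_identical(organism_ids(out), c("at", "hi"))
  expect_equal(attr(out, "filter_report")$n_dropped_coverage, 1L)
})

test_that("exclusion and zero-occurrence removals obey the count identity", {
  meta <- make_meta(1, 2, 1)
  m <- make_matrix(list(t1 = c(1L, 1L, 1L, 1L),
                        t2 = c(0L, 1L, 0L, 0L),   # only in B1
                        t3 = c(0L, 0L, 0L, 1L),   # excluded by list
                        t4 = c(2L, 0L, 0L, 0L)),  # only in A1
                   meta)
  meta$annotation_coverage <- c(1, 0.2, 1, 1)  # drops B1
  cfg <- dataset_config(coverage_threshold = 0.5, exclusion_list = "t3")
  out <- filter_dataset(m, meta, cfg)
  rep <- attr(out, "filter_report")
  expect_identical(trait_ids(out), c("t1", "t4"))
  expect_equal(rep$n_excluded, 1L)
  expect_equal(rep$n_zero_occurrence, 1L)  # t2 emptied by dropping B1
  expect_equal(rep$n_traits_out, rep$n_traits_in - rep$n_excluded - rep$n_zero_occurrence)
})

test_that("filtering is idempotent and the identity config is a no-op", {
  set.seed(11)
  d <- random_dataset(25, 3, 5, 4)
  d$meta$annotation_coverage <- runif(nrow(d$meta))
  d$meta$lifestyle <- sample(c("free_living", "parasitic"), nrow(d$meta), TRUE)
  cfg <- dataset_config(coverage_threshold = 0.5, free_living_only = TRUE,
                        exclusion_list = c("t001", "t002"))
  strip <- function(m) {
    m <- unclass(m)
    attr(m, "filter_report") <- NULL
    m
  }
  once <- filter_dataset(d$matrix, d$meta, cfg)
  twice <- filter_dataset(once, d$meta, cfg)
  expect_identical(strip(twice), strip(once))
  # a second pass removes nothing further
  rep2 <- attr(twice, "filter_report")
  expect_equal(rep2$n_excluded + rep2$n_zero_occurrence +
                 rep2$n_dropped_coverage + rep2$n_dropped_lifestyle, 0L)

  idm <- filter_dataset(d$matrix, d$meta, dataset_config(coverage_threshold = 0))
  expect_identical(strip(idm), strip(d$matrix))
})

test_that("matrix organisms missing from metadata are reported", {
  meta <- make_meta(1, 1, 1)
  m <- make_matrix(list(t1 = c(1L, 1L, 1L)), meta)
  expect_error(filter_dataset(m, meta[-2, ], dataset_config()), "B1")
})

test_that("free-living filter keeps only free-living organisms", {
  meta <- organism_metadata(c("x", "y", "z"), c("A", "B", "E"),
                            lifestyle = c("free_living", "parasitic", "free_living"))
  m <- make_matrix(list(t1 = c(1L, 1L, 1L)), meta)
  out <- filter_dataset(m, meta, dataset_config(free_living_only = TRUE))
  expect_identical(organism_ids(out), c("x", "z"))
  expect_equal(attr(out, "filter_report")$n_dropped_lifestyle, 1L)
})

test_that("exclusion list files support comments and blanks", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# flagged traits", "t1", "", "t2  # trailing note", "t1"), path)
  expect_identical(load_exclusion_list(path), c("t1", "t2"))
})

test_that("run manifest echoes config and digests inputs", {
  path <- withr::local_tempfile(fileext = ".json")
  input <- withr::local_tempfile(fileext = ".tsv")
  writeLines("trait_id\to1", input)
  cfg <- dataset_config(hgt_threshold = 0.7)
  man <- write_run_manifest(cfg, path, inputs = c(matrix = input), seed = 42L)
  back <- jsonlite::read_json(path)
  expect_equal(back$config$hgt_threshold, 0.7)
  expect_equal(back$seed, 42L)
  expect_match(back$input_md5$matrix, "^[0-9a-f]{32}$")
})
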