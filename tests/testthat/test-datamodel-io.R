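# Readers, validation and network round-trips.

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("census reader round-trips well-formed rows and derives month index", {
  path <- write_lines_tmp(c(
    "community,date,plant,duration_min,flowers_observed,visitor,individuals,flowers_contacted",
    "CB,2011-01-05,pA,7.5,12,vA,2,5",
    "CB,2011-02-05,pA,7.5,10,vB,1,3",
    "CB,2011-02-05,pB,7.5,8,NONE,0,0"))
  cen <- read_census(path, season_start = c(CB = "2011-01-01"))
  expect_equal(nrow(cen), 3)
  expect_equal(cen$month_index, c(1L, 2L, 2L))
  expect_s3_class(cen$date, "Date")
})

test_that("census validation names offending rows and never drops silently", {
  path <- write_lines_tmp(c(
    "community,date,plant,duration_min,flowers_observed,visitor,individuals,flowers_contacted",
    "CB,2011-01-05,pA,7.5,12,vA,2,5",
    "CB,2011-01-05,pB,7.5,12,vA,2,-1"))
  expect_error(read_census(path), "row 2.*flowers_contacted")

  # a NONE census must carry zero individuals and contacts
  path2 <- write_lines_tmp(c(
    "community,date,plant,duration_min,flowers_observed,visitor,individuals,flowers_contacted",
    "CB,2011-01-05,pA,7.5,12,NONE,1,0"))
  expect_error(read_census(path2), "row 1.*individuals must be 0")

  # effort must be consistent within one (community, date, plant) census
  path3 <- write_lines_tmp(c(
    "community,date,plant,duration_min,flowers_observed,visitor,individuals,flowers_contacted",
    "CB,2011-01-05,pA,7.5,12,vA,1,2",
    "CB,2011-01-05,pA,6.0,12,vB,1,2"))
  expect_error(read_census(path3), "duration_min inconsistent")

  # missing column is a schema error
  path4 <- write_lines_tmp(c("community,date,plant", "CB,2011-01-05,pA"))
  expect_error(read_census(path4), "missing required column")
})

test_that("empty census file yields empty collection with a warning", {
  path <- write_lines_tmp(paste(
    c("community", "date", "plant", "duration_min", "flowers_observed",
      "visitor", "individuals", "flowers_contacted"), collapse = ","))
  expect_warning(cen <- read_census(path), "no rows")
  expect_equal(nrow(cen), 0)
})

test_that("survey reader validates areas and derives density", {
  path <- write_lines_tmp(c(
    "community,date,plant,open_flowers,area_m2",
    "CB,2011-01-07,pA,30,0.25",
    "CB,2011-01-21,pA,0,0.25"))
  sur <- read_surveys(path)
  expect_equal(sur$density, c(120, 0))
  path2 <- write_lines_tmp(c(
    "community,date,plant,open_flowers,area_m2",
    "CB,2011-01-07,pA,30,0"))
  expect_error(read_surveys(path2), "row 1.*area_m2")
})

test_that("taxonomy reader enforces the functional-group vocabulary and name uniqueness", {
  ok <- write_lines_tmp(c("name,guild,group",
                          "vA,visitor,hoverflies",
                          "pA,plant,Asteraceae"))
  tax <- read_taxonomy(ok)
  expect_equal(nrow(tax), 2)

  bad_group <- write_lines_tmp(c("name,guild,group",
                                 "vA,visitor,rodents"))
  expect_error(read_taxonomy(bad_group), "rodents.*not in controlled")
  # vocabulary is extensible / can be disabled
  expect_silent(read_taxonomy(bad_group, groups = NULL))

  dup <- write_lines_tmp(c("name,guild,group",
                           "vA,visitor,flies",
                           "vA,visitor,beetles"))
  expect_error(read_taxonomy(dup), "duplicate species name")
  # the same name in the other guild is fine
  both <- write_lines_tmp(c("name,guild,group",
                            "zz,visitor,flies",
                            "zz,plant,Fabaceae"))
  expect_equal(nrow(read_taxonomy(both)), 2)
})

test_that("network files round-trip losslessly with metadata", {
  w <- matrix(c(0.2, 0, 1 / 3, 0.7), 2, 2,
              dimnames = list(c("pA", "pB"), c("vA", "vB")))
  k <- matrix(c(6L, 0L, 2L, 9L), 2, 2,
              dimnames = dimnames(w))
  net <- interaction_network(w, k, community = "CM", period = "month:2")
  path <- withr::local_tempfile(fileext = ".csv")
  write_network(net, path)
  back <- read_network(path)
  expect_identical(back$community, "CM")
  expect_identical(back$period, "month:2")
  expect_equal(back$weights, net$weights, tolerance = 0)
  expect_equal(back$counts, net$counts, tolerance = 0)

  expect_error(read_network(write_lines_tmp("not,a,network")),
               "not a pollinet network")
})

test_that("all-zero rows and columns are pruned with a warning when emptied", {
  w <- matrix(0, 1, 1, dimnames = list("pA", "vA"))
  expect_warning(net <- interaction_network(w, community = "X"),
                 "empty after pruning")
  expect_equal(length(net$plants), 0)

  # pruning never removes a species with positive weight
  w2 <- matrix(c(0.5, 0, 0, 0), 2, 2,
               dimnames = list(c("pA", "pB"), c("vA", "vB")))
  net2 <- interaction_network(w2, community = "X")
  expect_equal(net2$plants, "pA")
  expect_equal(net2$visitors, "vA")
})

test_that("network marginals equal recomputed sums", {
  m <- rand_count_matrix(3, 4)
  net <- interaction_network(m, m, community = "X")
  mar <- network_marginals(net, "counts")
  expect_equal(mar$row_totals, rowSums(net$counts))
  expect_equal(mar$col_totals, colSums(net$counts))
  expect_equal(mar$grand_total, sum(net$counts))
})
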