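test_that("GenAlEx round trip is the identity on allele content and populations", {
  d <- tiny_dataset()
  f <- withr::local_tempfile(fileext = ".csv")
  write_genalex(d, f)
  back <- read_genalex(f)
  expect_equal(back$allele_1, d$allele_1)
  expect_equal(back$allele_2, d$allele_2)
  expect_equal(as.character(back$population), as.character(d$population))
  expect_equal(loci(back), loci(d))
})

test_that("a hand-written two-individual file parses as written", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,2,1,2", "Individual,Population,L1,",
               "i1,A,180,182", "i2,A,180,180"), f)
  d <- read_genalex(f)
  expect_equal(n_individuals(d), 2L)
  expect_equal(loci(d), "L1")
  expect_equal(d$allele_1, c(180L, 180L))
  expect_equal(d$allele_2, c(182L, 180L))
})

test_that("missing code 0 maps to NA and only there", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("2,2,1,2", "Individual,Population,L1,,L2,",
               "i1,A,0,0,100,102", "i2,A,180,180,100,100"), f)
  d <- read_genalex(f)
  expect_true(is.na(d$allele_1[d$individual == "i1" & d$locus == "L1"]))
  expect_false(anyNA(d$allele_1[-1]))
})

test_that("the study-shaped fixture written and re-read keeps N = 242", {
  d <- make_study_fixture(seed = 11)
  f <- withr::local_tempfile(fileext = ".csv")
  write_genalex(d, f)
  back <- read_genalex(f)
  expect_equal(n_individuals(back), 242L)
  expect_equal(population_sizes(back)$n,
               c(26L, 26L, 22L, 22L, 29L, 21L, 13L, 25L, 24L, 19L, 15L))
})

test_that("malformed GenAlEx input is rejected with a pointed error", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("not,a,header", "Individual,Population,L1,", "i1,A,180,182"), f)
  expect_error(read_genalex(f), "counts row")
  writeLines(c("1,1,1,1", "Individual,Population,L1,,X", "i1,A,180,182"), f)
  expect_error(read_genalex(f), "odd number of allele columns")
  writeLines(c("1,1,1,1", "Individual,Population,L1,", "i1,A,180"), f)
  expect_error(read_genalex(f), "too few columns")
  writeLines(c("1,2,1,1", "Individual,Population,L1,",
               "i1,A,180,182", "i2,B,180,180"), f)
  expect_error(read_genalex(f), "population blocks")
})

test_that("STRUCTURE output has two rows per individual with -9 for missing", {
  d <- genotype_tibble(
    individual = c("i1", "i1"), population = c("A", "A"),
    locus = c("L1", "L2"),
    allele_1 = c(180L, NA), allele_2 = c(182L, NA)
  )
  f <- withr::local_tempfile(fileext = ".str")
  write_structure(d, f)
  lines <- readLines(f)
  expect_length(lines, 3L)  # header + 2 rows
  expect_match(lines[2], "180\t-9")
  expect_match(lines[3], "182\t-9")
})

test_that("STRUCTURE round trip preserves allele content; fixture has 2N data rows", {
  d <- make_study_fixture(seed = 11)
  f <- withr::local_tempfile(fileext = ".str")
  write_structure(d, f)
  expect_length(readLines(f), 1L + 2L * 242L)
  back <- read_structure(f, data_labels = populations(d))
  expect_equal(back$allele_1, d$allele_1)
  expect_equal(back$allele_2, d$allele_2)
  expect_equal(as.character(back$population), as.character(d$population))
})

test_that("validation reports missing fractions, monomorphic loci and tiny populations", {
  d <- make_study_fixture(seed = 11)
  i <- which(d$individual == d$individual[1] & d$locus == "L01")
  d$allele_1[i] <- NA
  d$allele_2[i] <- NA
  rep <- validate_genotypes(d)
  expect_equal(sum(rep$per_locus$n_missing), 1L)
  expect_equal(rep$per_locus$missing_fraction[rep$per_locus$locus == "L01"], 1 / 242)
  expect_equal(sum(rep$per_locus$n_missing) / (242 * 15), 1 / 3630)
  expect_length(rep$warnings, 0L)

  tiny <- genotype_tibble(
    individual = c("x", "y1", "y2"), population = c("A", "B", "B"),
    locus = "L1", allele_1 = c(100L, 100L, 102L), allele_2 = c(100L, 100L, 102L)
  )
  expect_match(validate_genotypes(tiny)$warnings, "N <= 1", all = FALSE)
})

test_that("genotype pairs are stored sorted and one-population membership is enforced", {
  d <- genotype_tibble("i1", "A", "L1", 184L, 180L)
  expect_equal(d$allele_1, 180L)
  expect_equal(d$allele_2, 184L)
  expect_error(
    genotype_tibble(c("i1", "i1"), c("A", "B"), c("L1", "L2"),
                    c(1L, 1L), c(1L, 1L)),
    "more than one population"
  )
})
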