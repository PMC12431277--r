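test_that("CSV round-trip preserves a normalised table bit-identically", {
  tab <- tibble::tibble(
    genotype = c("P1", "P1", "F1xM1", "F1xM1"),
    generation = c("parent", "parent", "hybrid", "hybrid"),
    female = c(NA, NA, "P1", "P1"),
    male = c(NA, NA, "P2", "P2"),
    year = 2019L, rep = c(1L, 2L, 1L, 2L),
    trait = "Zn", value = c(50.2, 48.1, 71.5, 69.9)
  )
  # P2 must exist as a parent for referential integrity
  tab <- dplyr::bind_rows(
    tab,
    tibble::tibble(genotype = "P2", generation = "parent",
                   female = NA_character_, male = NA_character_,
                   year = 2019L, rep = 1:2, trait = "Zn",
                   value = c(60, 61))
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_phenotype_table(tab, path)
  back <- read_phenotype_table(path)
  expect_identical(nrow(back), nrow(tab))
  expect_equal(back$value, tab$value)
  expect_identical(back$genotype, tab$genotype)
  # second round trip is bit-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_phenotype_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
  expect_identical(sum(back$generation == "hybrid"), 2L)
})

test_that("schema mapping renames columns and reports missing ones", {
  tab <- tibble::tibble(
    ID = "P1", generation = "parent", female = NA_character_,
    male = NA_character_, year = 2019L, rep = 1:2, trait = "Ca",
    conc = c(20, 21)
  )
  out <- as_phenotype_table(tab, schema = c(genotype = "ID", value = "conc"))
  expect_named(out, c("genotype", "generation", "female", "male", "year",
                      "rep", "trait", "value"))
  expect_error(as_phenotype_table(tab), "missing column")
  expect_error(as_phenotype_table(tab, schema = c(genotype = "nope")),
               "not found")
})

test_that("invariant violations are rejected", {
  base <- toy_2x2()
  dup <- dplyr::bind_rows(base, base[1, ])
  expect_error(validate_phenotype_table(dup), "duplicate")
  neg <- base; neg$value[2] <- -3
  expect_error(validate_phenotype_table(neg), "negative")
  badtrait <- base; badtrait$trait <- "Se"
  expect_error(validate_phenotype_table(badtrait), "unknown trait")
  orphan <- base
  orphan$generation[1:2] <- "hybrid"
  orphan$female[1:2] <- "X1"; orphan$male[1:2] <- "X2"
  expect_error(validate_phenotype_table(orphan), "referential")
  # non-numeric value surfaces the row index
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("genotype,generation,female,male,year,rep,trait,value",
               "P1,parent,,,2019,1,Ca,10",
               "P1,parent,,,2019,2,Ca,oops"), tmp)
  expect_error(read_phenotype_table(tmp), "non-numeric")
})

test_that("validate_design infers the factorial structure", {
  sim <- simulate_ncii(study_sim_config("Ca", seed = 11))
  des <- validate_design(sim$table)
  expect_length(des$females, 12)
  expect_length(des$males, 14)
  expect_identical(nrow(des$crosses), 118L)
  expect_true(all(des$counts$n_crosses >= 1))

  # 2x2 full factorial: every parent appears in exactly 2 crosses
  cfg <- sim_config(n_females = 2, n_males = 2, n_crosses = 4,
                    years = "2019", reps = 2,
                    resid_var_by_year = c("2019" = 0.5), seed = 4)
  des2 <- validate_design(simulate_ncii(cfg)$table)
  expect_identical(nrow(des2$crosses), 4L)
  expect_true(all(des2$counts$n_crosses == 2))

  # a token on both sides of the design is an error
  bad <- simulate_ncii(cfg)$table
  bad$male[bad$generation == "hybrid"] <-
    sub("^M01$", "F01", bad$male[bad$generation == "hybrid"])
  expect_error(validate_design(bad), "both female and male")
})
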