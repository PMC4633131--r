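# Panel data model, CSV dialect, and harmonization steps.

test_that("well-formed CSV parses to the same records and round-trips", {
  p <- tiny_panel()
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, path)
  p2 <- read_panel(path)
  expect_s3_class(p2, "food_panel")
  expect_equal(nrow(p2), 6L)
  expect_identical(as.data.frame(p2), as.data.frame(p))

  # second round trip is bit-identical at the file level too
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_panel(p2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("schema mapping handles renamed columns and missing cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Area,Year,GDPpc,Pop,KcalTotal,KcalAnimal",
               "AAA,1990,500,1000000,2100,150",
               "BBB,1990,,5000000,2700,",
               "CCC,1990,20000,20000000,3300,900"), path)
  schema <- c(country = "Area", year = "Year", income = "GDPpc",
              population = "Pop", total_cal = "KcalTotal",
              animal_cal = "KcalAnimal")
  p <- read_panel(path, schema = schema)
  expect_equal(nrow(p), 3L)
  expect_true(is.na(p$income[2]) && is.na(p$animal_cal[2]))
  expect_equal(n_complete_pairs(p), 2L)
})

test_that("invariant violations and malformed cells are named errors", {
  bad <- tiny_panel()
  bad$animal_cal[1] <- bad$total_cal[1] + 100
  expect_error(food_panel(bad), "animal_cal exceeds total_cal")

  neg <- tiny_panel()
  neg$income[2] <- -5
  expect_error(food_panel(neg), "income must be > 0")

  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("country,year,income,population,total_cal,animal_cal",
               "AAA,1990,abc,1,2100,150"), path)
  expect_error(read_panel(path), "malformed numeric cell.*income.*row 1")
})

test_that("a large panel with injected gaps reports the complete-pair count", {
  # historical-panel scale: 162 countries x 47 years = 7614 records,
  # thinned so exactly 5889 complete observation pairs remain
  panel <- gen_panel(synth_spec(seed = 31))
  expect_equal(nrow(panel), 7614L)
  set.seed(31)
  holes <- sample.int(nrow(panel), 7614L - 5889L)
  panel$income[holes] <- NA_real_
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, path)
  expect_equal(n_complete_pairs(read_panel(path)), 5889L)
})

test_that("income deflation multiplies, is idempotent, and inverts", {
  p <- tiny_panel()
  defl <- data.frame(country = "*",
                     base_pair = c("US$1990->US$2005", "US$2005->US$1990"),
                     factor = c(1.35, 1 / 1.35))
  p90 <- p
  p90$income <- c(100, 200, 300, 100, 200, 300)
  out <- deflate_income(p90, defl, from = "US$1990", to = "US$2005")
  expect_equal(out$income, c(135, 270, 405, 135, 270, 405))

  same <- deflate_income(p, defl, from = "US$2005", to = "US$2005")
  expect_identical(same$income, p$income)

  back <- deflate_income(out, defl, from = "US$2005", to = "US$1990")
  expect_equal(back$income, p90$income, tolerance = 1e-9)

  # country-specific factor beats the wildcard; missing factor errors
  defl2 <- rbind(defl, data.frame(country = "AAA",
                                  base_pair = "US$1990->US$2005",
                                  factor = 2))
  out2 <- deflate_income(p90, defl2, from = "US$1990", to = "US$2005")
  expect_equal(out2$income[out2$country == "AAA"], c(200, 200))
  expect_error(
    deflate_income(p90, defl[0, ], from = "US$1990", to = "US$2005"),
    "no deflator")
})

test_that("regional gap fill uses the donor-weighted mean and only fills holes", {
  p <- tiny_panel()
  map <- data.frame(country = c("AAA", "BBB", "CCC"), region = "AFR")
  expect_identical(plain_records(fill_missing_regional(p, map)),
                   plain_records(p))

  holed <- p
  holed$total_cal[1] <- NA_real_  # AAA 1990
  filled <- fill_missing_regional(holed, map)
  # independent oracle: weighted mean over the two 1990 donors
  donors <- p[p$year == 1990 & p$country != "AAA", ]
  expect_equal(filled$total_cal[1],
               sum(donors$total_cal * donors$population) /
                 sum(donors$population))
  expect_equal(attr(filled, "n_filled"), 1L)
  # every originally present cell untouched, cell by cell
  for (col in c("income", "population", "total_cal", "animal_cal")) {
    present <- !is.na(holed[[col]])
    expect_identical(filled[[col]][present], holed[[col]][present])
  }

  unw <- fill_missing_regional(holed, map, weighted = FALSE)
  expect_equal(unw$total_cal[1], mean(donors$total_cal))

  all_gone <- p
  all_gone$total_cal[p$year == 1990] <- NA_real_
  expect_error(fill_missing_regional(all_gone, map),
               "no donor country.*AFR.*1990")
})

test_that("coverage exclusion reports the excluded population share", {
  p <- tiny_panel()
  expect_identical(plain_records(exclude_uncovered(p, unique(p$country))),
                   plain_records(p))

  # build a world where the uncovered country holds exactly 2.1% of people
  w <- food_panel(data.frame(
    country = c("AAA", "BBB", "CCC"), year = 2000L,
    income = c(1000, 2000, 3000), population = c(50e6, 47.9e6, 2.1e6),
    total_cal = 2500, animal_cal = 400))
  out <- exclude_uncovered(w, c("AAA", "BBB"))
  expect_equal(attr(out, "excluded_share"), 0.021, tolerance = 1e-12)
  expect_identical(attr(out, "excluded_countries"), "CCC")
  # identity: share == 1 - covered/total
  expect_equal(attr(out, "excluded_share"),
               1 - sum(out$population) / sum(w$population),
               tolerance = 1e-12)

  empty <- exclude_uncovered(w, character())
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "excluded_share"), 1)
})
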