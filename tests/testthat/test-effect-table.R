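test_that("packaged glottic table has the printed dimensions and cells", {
  tab <- glottic_table1()
  expect_equal(dim(tab$log_or), c(9, 14))
  expect_equal(sum(!is.na(tab$log_or)), 56)

  # spot-checks of printed cells
  expect_equal(tab$log_or["elicin_2019", "aci"], 0.51)
  expect_equal(tab$se["elicin_2019", "aci"], 0.16)
  expect_equal(tab$log_or["gultekin_2012", "aci"], 0.73)
  expect_equal(tab$se["gultekin_2012", "aci"], 0.28)
  expect_equal(tab$log_or["raitiola_2000", "t_substage"], 1.48)
  expect_equal(tab$se["raitiola_2000", "t_substage"], 0.46)
  # an observed zero is an estimate, not a missing cell
  expect_equal(tab$log_or["bignardi_2004", "tumor_grading"], 0)
  expect_equal(tab$se["bignardi_2004", "tumor_grading"], 0.02)

  # Raitiola reports exactly ACI, T substage and vocal cord mobility
  rai <- !is.na(tab$log_or["raitiola_2000", ])
  expect_equal(names(which(rai)), c("aci", "t_substage", "cord_mobility"))

  # checksum pinning every printed value
  expect_equal(sum(tab$log_or, na.rm = TRUE), 19.59)
  expect_equal(sum(tab$se, na.rm = TRUE), 26.50)
  expect_true(all(tab$se[!is.na(tab$se)] > 0))
})

test_that("builtin table matches the shipped long CSV cell-for-cell", {
  csv <- system.file("extdata", "glottic_table1.csv", package = "mfmeta")
  tab <- read_effect_table(csv, "long")
  ref <- glottic_table1()
  # the long reader orders factors by first appearance; align before comparing
  expect_setequal(colnames(tab$log_or), colnames(ref$log_or))
  expect_equal(tab$log_or[rownames(ref$log_or), colnames(ref$log_or)],
               ref$log_or)
  expect_equal(tab$se[rownames(ref$se), colnames(ref$se)], ref$se)
})

test_that("reading handles minimal input and rejects malformed cells", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines("study,factor,log_or,se\ns1,aci,0.0,1.0", p)
  tab <- read_effect_table(p, "long")
  expect_equal(dim(tab$log_or), c(1, 1))
  expect_false(anyNA(tab$log_or))

  writeLines("study,factor,log_or,se\ns1,aci,0.0,0", p)
  expect_error(read_effect_table(p, "long"), "s1.*aci")

  writeLines("study,factor,log_or,se\ns1,aci,0.1,0.2\ns1,aci,0.3,0.2", p)
  expect_error(read_effect_table(p, "long"), "duplicate")

  writeLines("study,factor,log_or,se\ns1,aci,abc,0.2", p)
  expect_error(read_effect_table(p, "long"), "non-numeric")

  writeLines('study,aci\ns1,"0.5 [0.2]"', p)
  expect_error(read_effect_table(p, "wide"), "cannot parse")
})

test_that("write/read round-trips both layouts including missingness", {
  tab <- glottic_table1()
  for (layout in c("long", "wide")) {
    p <- withr::local_tempfile(fileext = ".csv")
    write_effect_table(tab, p, layout)
    back <- read_effect_table(p, layout)
    expect_equal(back$log_or[rownames(tab$log_or), colnames(tab$log_or)],
                 tab$log_or, info = layout)
    expect_equal(back$se[rownames(tab$se), colnames(tab$se)],
                 tab$se, info = layout)
    # writing what was loaded reproduces the file content
    p2 <- withr::local_tempfile(fileext = ".csv")
    write_effect_table(back, p2, layout)
    expect_identical(readLines(p2),
                     readLines({write_effect_table(back, p, layout); p}),
                     info = layout)
  }
})

test_that("validation names the offending cell", {
  y <- matrix(c(0.5, 0.2), 1, 2, dimnames = list("s1", c("a", "b")))
  s <- matrix(c(0.2, -0.1), 1, 2, dimnames = dimnames(y))
  expect_error(effect_table(y, s), "s1.*b")
  s2 <- matrix(c(0.2, NA), 1, 2, dimnames = dimnames(y))
  expect_error(effect_table(y, s2), "mismatch")
})

test_that("minimum-study filter keeps 14 factors at k = 2 and is idempotent", {
  tab <- glottic_table1()
  f2 <- filter_min_studies(tab, 2)
  expect_equal(ncol(f2$log_or), 14)
  expect_equal(f2$log_or, tab$log_or)

  # identity at k = 1
  expect_equal(filter_min_studies(tab, 1)$log_or, tab$log_or)

  # manual per-column tally: only ACI reaches 9 reporting studies
  f9 <- filter_min_studies(tab, 9)
  expect_equal(colnames(f9$log_or), "aci")
  expect_equal(nrow(f9$log_or), 9)

  # idempotency at an intermediate threshold that drops factors and studies
  f3 <- filter_min_studies(tab, 4)
  expect_equal(filter_min_studies(f3, 4)$log_or, f3$log_or)

  expect_error(filter_min_studies(tab, 0), "k must be")
})

test_that("reporting counts match a manual tally of the fixture", {
  cnt <- reporting_counts(glottic_table1())
  expect_equal(unname(cnt),
               c(9, 7, 2, 2, 3, 3, 3, 2, 2, 7, 2, 4, 7, 3))
  # the published posterior table prints 8 for ACI and 6 for T substage;
  # the printed data table itself has 9 and 7 entries - the package keeps
  # the data table as printed
  expect_equal(unname(cnt["aci"]), 9)
  expect_equal(unname(cnt["t_substage"]), 7)

  one <- tiny_table()
  expect_true(all(reporting_counts(one) %in% 0:3))
})

test_that("drop_cell blanks a single estimate and drops emptied studies", {
  tab <- glottic_table1()
  d <- drop_cell(tab, "elicin_2019", "aci")
  expect_true(is.na(d$log_or["elicin_2019", "aci"]))
  expect_equal(sum(!is.na(d$log_or)), 55)

  # blanking the only estimate of a study removes the study
  d2 <- drop_cell(select_factors(tab, c("aci", "t_substage")),
                  "almamgani_2013", "aci")
  expect_false("almamgani_2013" %in% rownames(d2$log_or))
  expect_error(drop_cell(tab, "elicin_2019", "ott"), "already missing")
})
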