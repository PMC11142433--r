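test_that("catalog defines the 25 measurements across four elements", {
  cat <- measurement_catalog()
  expect_equal(nrow(cat), 25)
  counts <- table(cat$element)
  expect_equal(counts[["maxilla"]], 6)
  expect_equal(counts[["premaxilla"]], 8)
  expect_equal(counts[["quadrate"]], 6)
  expect_equal(counts[["fibula"]], 5)
  expect_false(any(duplicated(paste(cat$element, cat$code))))
})

test_that("CSV round trip preserves a table, empty cells are missing", {
  tab <- measurement_table(tiny_maxilla_df())
  expect_equal(nrow(tab), 3)
  expect_equal(sum(is.na(tab$jcp_DV)), 1)
  path <- tempfile(fileext = ".csv")
  write_measurements(tab, path)
  back <- read_measurements(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("validation rejects schema violations", {
  bad_code <- data.frame(specimen_id = "F1", element = "fibula",
                         side = "left", jcp_DV = 100)
  expect_error(measurement_table(bad_code), "not valid for this element")
  neg <- tiny_maxilla_df(); neg$jpp_ML[2] <- -3
  expect_error(measurement_table(neg), "non-positive")
  dup <- rbind(tiny_maxilla_df(), tiny_maxilla_df()[1, ])
  expect_error(measurement_table(dup), "duplicate")
  unk <- tiny_maxilla_df(); unk$bogus <- 1
  expect_error(measurement_table(unk), "unknown column")
})

test_that("complete_cases filters per element and preserves order", {
  tab <- measurement_table(tiny_maxilla_df())
  cc1 <- complete_cases(tab, "maxilla", "jcp_DV")
  expect_equal(cc1$specimen_id, c("A", "C"))
  # all rows complete for these two codes: identity
  cc2 <- complete_cases(tab, "maxilla", c("jpp_ML", "jpm_AP"))
  expect_equal(cc2$specimen_id, tab$specimen_id)
  expect_error(complete_cases(tab, "maxilla", "pg_ML"), "not valid")
})

test_that("complete cases for a superset of codes are a subset of cases", {
  cfg <- synthetic_config(seed = 11L)
  tab <- generate_population(cfg)
  codes <- element_codes("maxilla")
  for (k in 2:length(codes)) {
    sub <- complete_cases(tab, "maxilla", codes[seq_len(k)])
    sup <- complete_cases(tab, "maxilla", codes[seq_len(k - 1)])
    expect_true(all(sub$specimen_id %in% sup$specimen_id))
  }
})

test_that("log10_values transforms mm and demands complete cases", {
  tab <- measurement_table(tiny_maxilla_df())
  cc <- complete_cases(tab, "maxilla", "jcp_DV")
  expect_equal(log10_values(cc, "maxilla", "jcp_DV"), log10(c(131, 240)))
  expect_error(log10_values(tab, "maxilla", "jcp_DV"), "complete cases")
  one <- measurement_table(data.frame(specimen_id = "X", element = "maxilla",
                                      side = "left", jcp_DV = 130.6))
  expect_equal(round(log10_values(one, "maxilla", "jcp_DV"), 4), 2.1159)
  # scaling all mm by 10 adds exactly 1 on the log10 scale
  ten <- measurement_table(within(tiny_maxilla_df(), {
    jcp_DV <- jcp_DV * 10; jpp_ML <- jpp_ML * 10; jpm_AP <- jpm_AP * 10
  }))
  cc10 <- complete_cases(ten, "maxilla", "jcp_DV")
  expect_equal(log10_values(cc10, "maxilla", "jcp_DV"),
               log10_values(cc, "maxilla", "jcp_DV") + 1)
})

test_that("nominal tooth characters tally over assessable specimens", {
  df <- data.frame(
    specimen_id = sprintf("M%02d", 1:36), element = "maxilla",
    side = "left",
    socket_present = c(rep("yes", 28), rep("no", 4),
                       rep("indeterminate", 4)),
    tooth_present = c(rep("yes", 20), rep("no", 8), rep("no", 4),
                      rep("indeterminate", 4))
  )
  tab <- measurement_table(df)
  socket <- tally_nominal(tab, "socket_present")
  expect_equal(socket$n_assessable, 32)
  expect_equal(socket$no, 4)
  tooth <- tally_nominal(tab, "tooth_present")
  expect_equal(tooth$yes, 20)
  expect_error(tally_nominal(tab, "ribbing"), "unknown nominal")
  all_ind <- measurement_table(data.frame(
    specimen_id = "Z", element = "quadrate", side = "left"))
  expect_equal(tally_nominal(all_ind, "tooth_present")$n_assessable, 0)
})
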