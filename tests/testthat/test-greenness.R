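test_that("reagent penalties follow the amount-times-hazard rule", {
  expect_equal(reagent_penalty(5, 0, "warning"), 0L)   # water
  expect_equal(reagent_penalty(3, 3, "danger"), 6L)    # methanol < 10 mL
  expect_equal(reagent_penalty(50, 3, "danger"), 12L)  # methanol 10-100 mL
  expect_equal(reagent_penalty(150, 3, "danger"), 18L)
  expect_equal(reagent_penalty(0, 3, "danger"), 0L)
  expect_equal(reagent_penalty(5, 2, "warning"), 2L)
  expect_error(reagent_penalty(-1, 2), "non-negative")
})

test_that("energy and waste penalties follow their step rules", {
  expect_equal(energy_penalty(0.05), 0L)
  expect_equal(energy_penalty(1.0), 1L)
  expect_equal(energy_penalty(2.0), 2L)
  expect_equal(waste_penalty(0), 0L)
  expect_equal(waste_penalty(5, treated = TRUE), 3L)
  expect_equal(waste_penalty(5, treated = FALSE), 6L)
  expect_equal(waste_penalty(50, treated = FALSE), 8L)
})

test_that("the published eco-scale columns reproduce exactly", {
  pharma <- ecoscale_score(ecoscale_profile("proposed_pharma"))
  expect_equal(pharma$total_penalty, 3L)
  expect_equal(pharma$score, 97L)
  expect_equal(pharma$verdict, "excellent")

  plasma <- ecoscale_score(ecoscale_profile("proposed_plasma"))
  expect_equal(plasma$total_penalty, 9L)
  expect_equal(plasma$score, 91L)
  expect_equal(plasma$verdict, "excellent")

  hplc <- ecoscale_score(ecoscale_profile("hplc_fpv"))
  expect_equal(hplc$total_penalty, 27L)
  expect_equal(hplc$score, 73L)
  expect_equal(hplc$verdict, "acceptable")

  for (m in c("spectro_fpv_pharma", "spectro_fpv_plasma")) {
    expect_equal(ecoscale_score(ecoscale_profile(m))$score, 91L)
  }
  expect_equal(ecoscale_score(ecoscale_profile("reported_cef_mfx"))$score, 97L)
})

test_that("eco-scale scoring is permutation-invariant and additive", {
  items <- ecoscale_profile("hplc_fpv")
  base <- ecoscale_score(items)$score
  set.seed(2)
  expect_equal(ecoscale_score(sample(items))$score, base)
  # splitting one item into two with the same total leaves the score alone
  split_items <- c(items[-1], list(ecoscale_item("methanol a", "reagent", 7),
                                   ecoscale_item("methanol b", "reagent", 5)))
  expect_equal(ecoscale_score(split_items)$score, base)
})

test_that("scores floor at zero and verdict thresholds are sharp", {
  heavy <- list(ecoscale_item("solvent farm", "reagent", 120))
  r <- ecoscale_score(heavy)
  expect_equal(r$score, 0L)
  expect_equal(r$verdict, "inadequate")
  expect_equal(ecoscale_score(list(ecoscale_item("x", "waste", 24)))$verdict,
               "excellent")
  expect_equal(ecoscale_score(list(ecoscale_item("x", "waste", 25)))$verdict,
               "acceptable")
  expect_equal(ecoscale_score(list(ecoscale_item("x", "waste", 49)))$verdict,
               "acceptable")
  expect_equal(ecoscale_score(list(ecoscale_item("x", "waste", 50)))$verdict,
               "inadequate")
  expect_error(ecoscale_score(list()), "at least one")
  expect_error(ecoscale_item("x", "reagent", -1), "non-negative")
  expect_error(ecoscale_item("x", "fuel", 1), "arg")
})

test_that("GAPI pentagrams validate their field set and count colors", {
  all_green <- setNames(rep("green", 15),
                        names(gapi_profile("pharma")$fields))
  s <- gapi_summary(gapi_pentagram(all_green))
  expect_equal(s$green_count, 15)
  expect_equal(s$green_count + s$yellow_count + s$red_count, 15)

  expect_error(gapi_pentagram(all_green[-3]), "missing GAPI fields: transport")
  bad <- all_green
  bad["storage"] <- "blue"
  expect_error(gapi_pentagram(bad), "storage")
})

test_that("the packaged GAPI profiles carry the published green-zone counts", {
  pharma <- gapi_summary(gapi_profile("pharma"))
  expect_equal(pharma$green_count, 9)
  plasma <- gapi_summary(gapi_profile("plasma"))
  expect_equal(plasma$green_count, 7)
  for (s in list(pharma, plasma)) {
    expect_equal(s$green_count + s$yellow_count + s$red_count, 15)
    expect_true(s$quantification)
    expect_match(s$report, "quantification performed")
  }
})

test_that("greenness results serialize to JSON", {
  js <- jsonlite::fromJSON(greenness_to_json(
    ecoscale_score(ecoscale_profile("proposed_pharma")),
    gapi_profile("pharma")
  ))
  expect_equal(js$ecoscale$score, 97)
  expect_equal(js$gapi$green_count, 9)
})
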