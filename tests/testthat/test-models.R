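# Model vocabulary, catalogs, validation and serialization.

test_that("catalog profiles load with the declared model counts and k values", {
  expect_setequal(catalog_profiles(),
                  c("caerulescens", "mentalis", "palliatus", "ruficapillus"))
  rufi <- build_catalog("ruficapillus")
  expect_length(rufi, 12)
  expect_equal(count_free_parameters(rufi$VI), 13)
  expect_equal(count_free_parameters(rufi$I), 5)
  ment <- build_catalog("mentalis")
  expect_length(ment, 13)
  expect_equal(count_free_parameters(ment$X), 14)
  expect_equal(count_free_parameters(ment$I), 8)
  expect_equal(count_free_parameters(build_catalog("caerulescens")$VI), 13)
  # the X-type model is the VI-type plus one growth rate
  expect_setequal(setdiff(rownames(param_bounds(ment$X)),
                          rownames(param_bounds(build_catalog("caerulescens")$VI))),
                  "g_C")
})

test_that("catalog selection and overrides are checked", {
  expect_error(build_catalog("nosuchtaxon"), "unknown catalog profile")
  expect_error(build_catalog("ruficapillus", models = c("VI", "XCIX")),
               "unknown model name")
  expect_error(build_catalog("ruficapillus", overrides = list(read_model)),
               "malformed override")
  sub <- build_catalog("ruficapillus", models = c("I", "VI"))
  expect_named(sub, c("I", "VI"))
})

test_that("every shipped model validates at its bounds midpoint and k counts free symbols", {
  for (profile in catalog_profiles()) {
    for (m in build_catalog(profile)) {
      expect_length(validate_model(m, midpoint_params(m)), 0)
      free <- vapply(m$params, function(p) {
        is.null(p$fixed) && p$lower < p$upper
      }, TRUE)
      expect_identical(count_free_parameters(m), sum(free))
    }
  }
})

test_that("models round-trip through YAML serialization", {
  for (m in build_catalog("caerulescens", models = c("I", "VI", "XV"))) {
    path <- tempfile(fileext = ".yaml")
    write_model(m, path)
    m2 <- read_model(path)
    expect_equal(m2, m)
  }
})

test_that("a fully fixed model has zero free parameters", {
  expect_equal(count_free_parameters(const_model()), 0)
})

test_that("validate_model reports violations as data", {
  vi <- build_catalog("caerulescens", models = "VI")[[1]]
  good <- midpoint_params(vi)
  expect_length(validate_model(vi, good), 0)

  bad <- good
  bad[["tmig_AB_C"]] <- 2.5e6   # older than the outer divergence
  v <- validate_model(vi, bad)
  expect_true(any(grepl("postdates the split", v)))

  bad <- good
  bad[["p_A_B"]] <- 1.2
  v <- validate_model(vi, bad)
  expect_true(any(grepl("outside", v)))

  bad <- good
  bad[["tdiv_ABC"]] <- bad[["tdiv_AB"]] / 2
  v <- validate_model(vi, bad)
  expect_true(any(grepl("more recent than inner", v)))
})

test_that("the published caerulescens point estimates satisfy the VI-type model", {
  pres <- table5_presets()$caerulescens_like
  expect_length(validate_model(pres$model, pres$params), 0)
})

test_that("anchor_sizes fixes every size parameter", {
  vi <- build_catalog("caerulescens", models = "VI")[[1]]
  am <- anchor_sizes(vi, 2e5)
  expect_equal(count_free_parameters(am), 10)
  expect_false(any(grepl("^Ne", rownames(param_bounds(am)))))
  expect_equal(midpoint_params(am)[["Ne_A"]], 2e5)
})
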