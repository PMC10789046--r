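test_that("unit conversion uses the standard clinical-chemistry factors", {
  # creatinine molar mass 113.12 g/mol -> 88.4 umol/L per mg/dL
  expect_equal(convert_lab_unit(1.0, "SCr", "mg/dL", "umol/L"), 88.4)
  # glucose molar mass 180.16 g/mol; 50 mg/dL sits just below the GTT
  # comparator's 2.8 mmol/L hypoglycemia cut-off
  expect_equal(convert_lab_unit(50, "BG_fasting", "mg/dL", "mmol/L"),
               50 / 18.016)
  expect_lt(convert_lab_unit(50, "BG_fasting", "mg/dL", "mmol/L"), 2.8)
  # identity when units are equal
  expect_identical(convert_lab_unit(3.3, "K", "mmol/L", "mmol/L"), 3.3)
  # cells/uL to 10^9/L (the neutrophil rule is written per uL)
  expect_equal(convert_lab_unit(3900, "neutrophils", "/uL", "10^9/L"), 3.9)
})

test_that("conversion round-trips within 1e-9 relative tolerance", {
  cases <- list(
    list(v = 1.37, a = "SCr", u = "mg/dL", w = "umol/L"),
    list(v = 84, a = "BG_fasting", u = "mg/dL", w = "mmol/L"),
    list(v = 7.2, a = "WBC", u = "10^9/L", w = "/uL"),
    list(v = 4.1, a = "K", u = "mmol/L", w = "mEq/L")
  )
  for (cs in cases) {
    back <- convert_lab_unit(
      convert_lab_unit(cs$v, cs$a, cs$u, cs$w), cs$a, cs$w, cs$u)
    expect_equal(back, cs$v, tolerance = 1e-9)
  }
})

test_that("units outside an analyte's whitelist are rejected by name", {
  expect_error(convert_lab_unit(3.3, "K", "mg/dL", "mmol/L"), "analyte K")
  expect_error(convert_lab_unit(1, "nonsense", "mg/dL", "mmol/L"),
               "unknown analyte")
})
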