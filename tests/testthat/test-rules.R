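test_that("liver injury R ratio and pattern branches match hand computation", {
  # (150/40) / (80/150) = 3.75 / 0.5333... = 7.03125
  res <- liver_injury_rule(150, 80, 40, 150)
  expect_equal(res$r_value, (150 / 40) / (80 / 150))
  expect_equal(res$pattern, "hepatocellular")
  # both enzymes at their ULN: R = 1, no injury
  res <- liver_injury_rule(40, 150, 40, 150)
  expect_equal(res$r_value, 1)
  expect_equal(res$pattern, "none")
  # ALP-dominant: R = (40/40)/(400/150) = 0.375 <= 2 with ALP >= 2 ULN
  res <- liver_injury_rule(40, 400, 40, 150)
  expect_equal(res$r_value, 0.375)
  expect_equal(res$pattern, "cholestatic")
  # both criteria with intermediate R -> mixed:
  # alt = 3*40 = 120, alp = 2*150 = 300 -> R = 3/2 = 1.5 (cholestatic);
  # push R into (2,5): alt 150, alp 300 -> R = (150/40)/(300/150) = 1.875 no;
  # alt 180, alp 300 -> R = 4.5/2 = 2.25 -> mixed
  res <- liver_injury_rule(180, 300, 40, 150)
  expect_equal(res$pattern, "mixed")
  expect_error(liver_injury_rule(-1, 80), "positive")
})

test_that("AKI creatinine branches fire per the delta and baseline rules", {
  # 0.35 mg/dL rise within 48 h qualifies
  s <- data.frame(time = c(0, 24), value = c(0.6, 0.95))
  expect_equal(aki_rule(s), 24)
  # 0.29 rise, ratio 1.48: neither branch
  s <- data.frame(time = c(0, 24), value = c(0.6, 0.89))
  expect_length(aki_rule(s), 0)
  # 1.5 x baseline within 7 days (delta below 0.3 per step)
  s <- data.frame(time = c(0, 60, 120), value = c(0.4, 0.5, 0.62),
                  is_baseline = c(TRUE, FALSE, FALSE))
  expect_equal(aki_rule(s), 120)
  # same rise spread beyond 7 days of baseline does not qualify
  s <- data.frame(time = c(0, 100, 180), value = c(0.4, 0.5, 0.62))
  expect_length(aki_rule(s), 0)
  # empty series is not an error
  expect_length(aki_rule(NULL, NULL), 0)
})

test_that("AKI urine branch requires a sustained sub-0.5 run above 6 h", {
  u <- data.frame(time = c(0, 7), value = c(0.4, 1.0))
  expect_equal(aki_rule(NULL, u), 6)
  # broken run: never exceeds 6 h continuously
  u <- data.frame(time = c(0, 3, 5, 9), value = c(0.4, 0.8, 0.4, 0.45))
  expect_length(aki_rule(NULL, u), 0)
  # exactly 6 h does not qualify (duration must exceed 6 h)
  u <- data.frame(time = c(0, 6), value = c(0.4, 1.0))
  expect_length(aki_rule(NULL, u), 0)
})
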