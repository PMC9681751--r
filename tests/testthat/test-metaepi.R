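test_that("dichotomize groups high with unclear against low", {
  expect_equal(dichotomize(c("high", "unclear", "low", "not_assessed")),
               c("exposed", "exposed", "unexposed", "excluded"))
  expect_equal(dichotomize(NA_character_), "excluded")
  expect_error(dichotomize("dubious"), "unknown rating")
})

test_that("eligibility requires >= 3 studies and both rating groups", {
  ok <- toy_ma("MA1", c(0.2, 0.5, 0.9), rep(0.1, 3), c("low", "high", "unclear"))
  no_contrast <- toy_ma("MA2", c(0.2, 0.5, 0.9), rep(0.1, 3),
                        c("high", "high", "unclear"))
  too_small <- toy_ma("MA3", c(0.2, 0.5), rep(0.1, 2), c("low", "high"))
  unrated <- toy_ma("MA4", c(0.2, 0.5, 0.9, 1.2), rep(0.1, 4),
                    c("low", "high", "not_assessed", "not_assessed"))
  ds <- toy_dataset(rbind(ok, no_contrast, too_small, unrated))
  res <- filter_eligible_mas(ds, "randomization")
  expect_equal(res$eligible, "MA1")
  expect_setequal(res$log$ma_id, c("MA2", "MA3", "MA4"))
  expect_equal(res$log$reason[res$log$ma_id == "MA2"], "no_rating_contrast")
  expect_equal(res$log$reason[res$log$ma_id == "MA3"], "fewer_than_min_studies")
  # MA4 keeps only 2 rated studies
  expect_equal(res$log$reason[res$log$ma_id == "MA4"], "fewer_than_min_studies")
})

test_that("characteristics with fewer than min_mas eligible MAs are skipped", {
  ds9 <- toy_elig_dataset(9)
  r9 <- run_characteristic(ds9, "randomization")
  expect_true(r9$skipped)
  expect_match(r9$reason, "fewer than 10")
  ds10 <- toy_elig_dataset(10)
  r10 <- run_characteristic(ds10, "randomization")
  expect_false(r10$skipped)
  expect_equal(r10$n_mas, 10)
  # threshold is configurable
  r9b <- run_characteristic(ds9, "randomization", run_config(min_mas = 5))
  expect_false(r9b$skipped)
})

test_that("run_characteristic is invariant to MA and arm order", {
  ds <- simulate_dataset(sim_config(n_mas = 15, seed = 31))
  r1 <- run_characteristic(ds, "randomization")
  set.seed(99)
  perm <- sample(nrow(ds$studies))
  ds2 <- ds
  ds2$studies <- ds$studies[perm, ]
  ds2$mas <- ds$mas[sample(nrow(ds$mas)), ]
  r2 <- run_characteristic(ds2, "randomization")
  # REML's bounded search leaves float-order noise below its 1e-8 tolerance
  expect_equal(r2$pooled_dmsd, r1$pooled_dmsd, tolerance = 1e-6)
  expect_equal(r2$se, r1$se, tolerance = 1e-6)
  expect_equal(r2$n_mas, r1$n_mas)
  expect_equal(r2$n_arms, r1$n_arms)
})

test_that("n_arms equals the sum of exposed and unexposed arms of contributing MAs", {
  ds <- simulate_dataset(sim_config(n_mas = 20, seed = 32))
  r <- run_characteristic(ds, "attrition")
  expect_false(r$skipped)
  expect_equal(r$n_arms, sum(r$per_ma$n_high_unclear + r$per_ma$n_low))
  expect_true(all(r$per_ma$n_high_unclear >= 1 & r$per_ma$n_low >= 1))
})

test_that("an injected bias effect yields a positive pooled DMSD", {
  ds <- simulate_dataset(sim_config(n_mas = 60, studies_meanlog = log(15),
                                    delta = c(randomization = 0.6), seed = 33))
  r <- run_characteristic(ds, "randomization")
  expect_gt(r$pooled_dmsd, 0)
  expect_gt(r$ci_low, 0)
})

test_that("direction alignment: flipping a benefit_negative MA's smds changes nothing", {
  ds <- simulate_dataset(sim_config(n_mas = 12, seed = 34))
  r1 <- run_characteristic(ds, "randomization")
  # re-encode one benefit_positive MA as benefit_negative with flipped smds
  id <- ds$mas$ma_id[ds$mas$expected_direction == "benefit_positive"][1]
  ds2 <- ds
  ds2$mas$expected_direction[ds2$mas$ma_id == id] <- "benefit_negative"
  rows <- ds2$studies$ma_id == id
  ds2$studies$smd[rows] <- -ds2$studies$smd[rows]
  r2 <- run_characteristic(ds2, "randomization")
  expect_equal(r2$pooled_dmsd, r1$pooled_dmsd, tolerance = 1e-10)
})

test_that("unclear-direction MAs are excluded by default, or aligned by pooled sign", {
  ds <- simulate_dataset(sim_config(n_mas = 20, seed = 35))
  id <- ds$mas$ma_id[1]
  ds$mas$expected_direction[1] <- "unclear"
  r <- run_characteristic(ds, "randomization")
  expect_false(id %in% r$per_ma$ma_id)
  expect_true("unclear_direction_excluded" %in% r$exclusions$reason)
  r2 <- run_characteristic(ds, "randomization",
                           run_config(unclear_direction_policy = "pooled_sign"))
  expect_true(id %in% r2$per_ma$ma_id)
  expect_gte(r2$n_mas, r$n_mas)
})

test_that("robust sensitivity equals the primary analysis on point estimates", {
  ds <- simulate_dataset(sim_config(n_mas = 25, seed = 36))
  r <- run_characteristic(ds, "randomization")
  rr <- run_sensitivity_robust(ds, "randomization")
  expect_true(rr$robust)
  shared <- intersect(r$per_ma$ma_id, rr$per_ma$ma_id)
  expect_equal(rr$per_ma$dmsd[match(shared, rr$per_ma$ma_id)],
               r$per_ma$dmsd[match(shared, r$per_ma$ma_id)], tolerance = 1e-10)
})

test_that("single-study (single-cluster) MAs are excluded from the robust analysis", {
  # 10 eligible MAs; one more whose 3 rated arms all come from one study
  ds <- toy_elig_dataset(10)
  one_study <- toy_ma("MAX", c(0.1, 0.6, 0.9, 0.8), rep(0.1, 4),
                      c("low", "low", "high", "unclear"),
                      study_id = c(1, 1, 1, 1))
  # need >= 3 distinct studies for eligibility; give it 3 studies but run
  # robust on a variant where all arms share a cluster cannot pass
  # eligibility, so instead check robust_se's error path through the pipeline
  # with a 3-study MA collapsed to one study id post-eligibility is not
  # constructible; assert the documented robust_se error directly
  fit <- meta_regress_binary(c(0.1, 0.6, 0.9), rep(0.1, 3), c(0, 1, 1))
  expect_error(robust_se(fit, rep("S1", 3)), "insufficient clusters")
  expect_s3_class(run_sensitivity_robust(toy_dataset(rbind(one_study)),
                                         "randomization"), "metaepi_result")
})

test_that("run_all returns one result per characteristic in canonical order", {
  ds <- simulate_dataset(sim_config(n_mas = 15, seed = 37))
  res <- run_all(ds)
  expect_length(res, 10)
  expect_equal(names(res), rob_characteristics)
  tab <- as.data.frame(res)
  expect_equal(nrow(tab), 10)
  expect_equal(tab$characteristic, rob_characteristics)

  empty <- toy_elig_dataset(1)
  empty$studies <- empty$studies[0, ]
  res0 <- run_all(empty)
  expect_true(all(vapply(res0, `[[`, logical(1), "skipped")))
  expect_equal(as.data.frame(res0)$reason, rep("no data", 10))
})
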