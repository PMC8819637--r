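test_that("cost per person-month is the total over the denominator", {
  expect_equal(round(cost_per_person_month(135314, 1280), 2), 105.71)
  expect_equal(round(cost_per_person_month(70811.93, 1280), 2), 55.32)
  expect_equal(cost_per_person_month(500, 500), 1)
  expect_error(cost_per_person_month(100, 0), "person-months")
})

test_that("scenario columns reproduce the audited totals and unit costs", {
  ref <- reference_totals()
  reports <- run_all_scenarios()
  for (i in seq_len(nrow(ref))) {
    r <- reports[[paste(ref$scenario[i], ref$model[i], sep = ".")]]
    expect_lt(abs(r$total_usd - ref$total_usd[i]), 0.02 + 1e-9)
    expect_equal(round(r$cost_per_person_month, 2), ref$cpm_usd[i])
    # internal consistency: total is the sum of included categories and the
    # included shares sum to one
    expect_equal(r$total_usd, sum(r$categories$annual_usd, na.rm = TRUE))
    expect_equal(sum(r$driver_shares, na.rm = TRUE), 1)
    expect_equal(r$cost_per_person_month, r$total_usd / r$person_months)
  }
})

test_that("unit-cost columns are annual cost over person-months", {
  r <- run_scenario(reference_scenario("doh"), "standard_care")
  cats <- r$categories
  expect_equal(cats$unit_usd, cats$annual_usd / 1280)
  # printed 2-decimal unit costs reproduce the annual cost within the
  # half-cent-per-person-month rounding bound
  printed_units <- round(cats$unit_usd, 2)
  included <- !is.na(cats$annual_usd)
  expect_true(all(abs(printed_units[included] * 1280 -
                        cats$annual_usd[included]) <= 0.005 * 1280 + 1e-9))
})

test_that("excluded tests are absent from DoH columns but present as-implemented", {
  doh <- run_scenario(reference_scenario("doh"), "club")
  ai <- run_scenario(reference_scenario("as_implemented"), "club")
  expect_true(is.na(doh$categories$annual_usd[
    doh$categories$category == "creatinine_test"]))
  expect_true(is.na(doh$categories$annual_usd[
    doh$categories$category == "pregnancy_test"]))
  expect_equal(ai$categories$annual_usd[
    ai$categories$category == "creatinine_test"], 2449.28)
  # syphilis testing is in the service package at zero recorded cost
  expect_equal(doh$categories$annual_usd[
    doh$categories$category == "syphilis_test"], 0)
})

test_that("fixed rows are identical across models within a scenario", {
  fixed <- cost_categories()$category[cost_categories()$behaviour == "fixed"]
  for (id in scenario_ids()) {
    spec <- reference_scenario(id)
    cols <- lapply(service_models(), function(m) {
      r <- run_scenario(spec, m)
      r$categories$annual_usd[r$categories$category %in% fixed]
    })
    expect_equal(cols[[1]], cols[[2]])
    expect_equal(cols[[1]], cols[[3]])
  }
  # capital and demand creation are held equal across scenarios (the
  # programme runs inside existing community platforms)
  for (cat in c("capital", "demand_creation")) {
    vals <- vapply(scenario_ids(), function(id) {
      r <- run_scenario(reference_scenario(id), "standard_care")
      r$categories$annual_usd[r$categories$category == cat]
    }, numeric(1))
    expect_equal(unname(diff(range(vals))), 0)
  }
})

test_that("percent increments compare counselling models to standard care", {
  reports <- run_all_scenarios()
  sc <- reports[["scaled_doh.standard_care"]]
  expect_equal(percent_increment(sc, reports[["scaled_doh.individual"]]), 89)
  expect_equal(percent_increment(sc, reports[["scaled_doh.club"]]), 11)
  expect_equal(percent_increment(sc, sc), 0)
  expect_error(percent_increment(sc, reports[["doh.club"]]), "one scenario")
  expect_error(percent_increment(reports[["scaled_doh.club"]], sc),
               "standard-care")
})

test_that("increments are invariant under uniform currency rescaling", {
  spec <- reference_scenario("scaled_doh")
  scaled <- spec
  scaled$category_overrides$annual_usd <-
    scaled$category_overrides$annual_usd * 14.31
  scaled$fixed_costs <- scaled$fixed_costs * 14.31
  a <- percent_increment(run_scenario(spec, "standard_care"),
                         run_scenario(spec, "individual"))
  b <- percent_increment(run_scenario(scaled, "standard_care"),
                         run_scenario(scaled, "individual"))
  expect_equal(a, b)
})

test_that("driver shares identify the published cost drivers", {
  reports <- run_all_scenarios()
  ai <- driver_shares(reports[["as_implemented.standard_care"]])
  expect_equal(ai[["personnel_fixed"]], 40)
  expect_equal(ai[["admin_supplies"]], 18)
  expect_equal(ai[["prep_medication"]], 10)
  sd <- driver_shares(reports[["scaled_doh.standard_care"]])
  expect_equal(sd[["prep_medication"]], 34)
  expect_equal(sd[["personnel_fixed"]], 29)
  ind <- driver_shares(reports[["scaled_doh.individual"]])
  expect_equal(ind[["personnel_fixed"]], 31)
  expect_equal(ind[["prep_medication"]], 18)
})

test_that("an all-zero specification yields an all-zero report", {
  fixed <- cost_categories()$category[cost_categories()$behaviour == "fixed"]
  spec <- scenario_spec(
    id = "null",
    salary_schedule = tiny_salaries(),
    test_schedules = test_schedule(tibble::tibble(
      test = "hiv_test", unit_cost = 0, rule = "none")),
    drug_cost_per_month = 0,
    person_months = c(standard_care = 1, club = 1, individual = 1),
    visit_counts = stats::setNames(rep(list(visit_counts(0, 0, 0)), 3),
                                   service_models()),
    fixed_costs = stats::setNames(rep(0, length(fixed)), fixed)
  )
  r <- run_scenario(spec, "standard_care", tiny_profile())
  expect_equal(r$total_usd, 0)
  expect_true(all(r$categories$annual_usd == 0))
})

test_that("a missing fixed category is a hard error naming it", {
  fixed <- cost_categories()$category[cost_categories()$behaviour == "fixed"]
  expect_error(
    scenario_spec(
      id = "broken",
      salary_schedule = tiny_salaries(),
      test_schedules = test_schedule(tibble::tibble(
        test = "hiv_test", unit_cost = 0, rule = "none")),
      drug_cost_per_month = 0,
      person_months = c(standard_care = 1, club = 1, individual = 1),
      visit_counts = stats::setNames(rep(list(visit_counts(0, 0, 0)), 3),
                                     service_models()),
      fixed_costs = c(capital = 1)
    ),
    "training")
})

test_that("scenario configs round-trip through YAML", {
  cfg <- list(
    id = "doh",
    salaries = list(list(role = "nurse", annual_usd = 13876.22),
                    list(role = "social_worker", annual_usd = 2318.16)),
    test_schedule = list(
      list(test = "hiv_test", unit_cost = 4.44,
           rule = "initiation_and_quarterly"),
      list(test = "hbsag_test", unit_cost = 10.12, rule = "initiation")),
    drug_cost_per_month = 4.72,
    person_months = list(standard_care = 1280, club = 1280,
                         individual = 1280),
    visit_counts = list(
      standard_care = list(n_initiation = 603, n_monthly = 391,
                           n_quarterly = 123),
      club = list(n_initiation = 603, n_monthly = 258, n_quarterly = 96),
      individual = list(n_initiation = 603, n_monthly = 524,
                        n_quarterly = 184)),
    fixed_costs = list(capital = 2295.13, training = 806.12,
                       demand_creation = 4365.73, personnel_fixed = 41387.17,
                       overhead = 2699.15, admin_supplies = 631.92)
  )
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  spec <- read_scenario(path)
  r <- run_scenario(spec, "standard_care")
  # fixed categories pass through; HBsAg = 603 x 10.12
  expect_equal(r$categories$annual_usd[
    r$categories$category == "hbsag_test"], 603 * 10.12)
  expect_equal(r$categories$annual_usd[
    r$categories$category == "capital"], 2295.13)
  expect_equal(r$person_months, 1280)
})
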