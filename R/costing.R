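#' Salary schedules and per-minute personnel pricing
#'
#' Annual salaries (including allowances) are converted to hourly rates by
#' dividing by 2080 hours — 8 hours per day for 260 working days a year,
#' excluding standard holidays and leave — and to per-minute rates by a further
#' division by 60. Counsellor (social-worker) pay differs by service model in
#' the as-implemented scenario (health-club vs individual effective-use
#' counsellors), so schedule rows may optionally be model-specific; a row with
#' `model = NA` applies to any model without a more specific row.
#'
#' @param salaries Data frame with columns `role`, `annual_usd` and optionally
#'   `model` (NA = any model).
#' @param workdays_per_year Working days per year (default 260).
#' @param hours_per_day Working hours per day (default 8).
#' @return A list of class `salary_schedule`.
#' @export
salary_schedule <- function(salaries, workdays_per_year = 260,
                            hours_per_day = 8) {
  salaries <- tibble::as_tibble(salaries)
  stopifnot(all(c("role", "annual_usd") %in% names(salaries)))
  if (!("model" %in% names(salaries))) salaries$model <- NA_character_
  if (any(salaries$annual_usd <= 0)) {
    stop("annual salaries must be positive", call. = FALSE)
  }
  if (workdays_per_year <= 0 || hours_per_day <= 0) {
    stop("workdays and hours per day must be positive", call. = FALSE)
  }
  structure(list(salaries = salaries,
                 workdays_per_year = workdays_per_year,
                 hours_per_day = hours_per_day),
            class = "salary_schedule")
}

lookup_salary <- function(schedule, role, model = NULL) {
  s <- schedule$salaries
  if (!is.null(model)) {
    hit <- s$role == role & !is.na(s$model) & s$model == model
    if (any(hit)) return(s$annual_usd[hit][1])
  }
  hit <- s$role == role & is.na(s$model)
  if (any(hit)) return(s$annual_usd[hit][1])
  stop(sprintf("no salary on schedule for role '%s'%s", role,
               if (is.null(model)) "" else sprintf(" (model '%s')", model)),
       call. = FALSE)
}

#' Hourly and per-minute personnel cost
#'
#' @param schedule A [salary_schedule()].
#' @param role Staff role to price.
#' @param model Optional service model, for model-specific counsellor salaries.
#' @return USD per hour (`hourly_cost`) or per minute (`per_minute_cost`).
#' @examples
#' s <- salary_schedule(data.frame(role = "nurse", annual_usd = 25474.91))
#' hourly_cost(s, "nurse")  # 12.25 when rounded to cents
#' @export
per_minute_cost <- function(schedule, role, model = NULL) {
  stopifnot(inherits(schedule, "salary_schedule"))
  annual <- lookup_salary(schedule, role, model)
  annual / (schedule$workdays_per_year * schedule$hours_per_day * 60)
}

#' @rdname per_minute_cost
#' @export
hourly_cost <- function(schedule, role, model = NULL) {
  per_minute_cost(schedule, role, model) * 60
}

#' Annualized cost of a capital item
#'
#' Capital purchases are spread over their useful life as an equivalent annual
#' payment using the annuity factor at the discount rate:
#' `price * r / (1 - (1 + r)^-life)`. At `r = 0` this reduces to straight-line
#' `price / life`. The default rate is 3% per year (sensitivity range 0–5%)
#' with a 3-year useful life for all capital items.
#'
#' @param price Purchase price (USD).
#' @param useful_life Useful life in years (> 0).
#' @param discount_rate Annual discount rate in `[0, 1)`; negative rates are
#'   rejected.
#' @return Equivalent annual cost in USD.
#' @examples
#' annualize_capital(300, 3, 0)      # 100
#' annualize_capital(1000, 3, 0.03)  # 353.53
#' @export
annualize_capital <- function(price, useful_life = 3, discount_rate = 0.03) {
  if (any(price < 0)) stop("price must be non-negative", call. = FALSE)
  if (useful_life <= 0) stop("useful life must be positive", call. = FALSE)
  if (discount_rate < 0 || discount_rate >= 1) {
    stop("discount rate must be in [0, 1)", call. = FALSE)
  }
  if (discount_rate == 0) return(price / useful_life)
  price * discount_rate / (1 - (1 + discount_rate)^(-useful_life))
}

#' Overhead allocated to PrEP provision
#'
#' Site overheads (utilities, rental, maintenance) are shared across all
#' services at the community platform; the PrEP programme is charged the
#' fraction of total client activities accounted for by PrEP visits.
#'
#' @param total_overhead Total annual site overhead (USD).
#' @param prep_activity_fraction Fraction of all client activities that are
#'   PrEP visits, in `[0, 1]`.
#' @return Allocated overhead (USD).
#' @export
allocate_overhead <- function(total_overhead, prep_activity_fraction) {
  if (total_overhead < 0) stop("overhead must be non-negative", call. = FALSE)
  if (prep_activity_fraction < 0 || prep_activity_fraction > 1) {
    stop("activity fraction must be in [0, 1]", call. = FALSE)
  }
  total_overhead * prep_activity_fraction
}

#' Annual medication cost
#'
#' The drug cost per month of supply (including, in the as-implemented
#' scenario, importation and central storage/distribution fees) times the
#' number of person-months of PrEP dispensed.
#'
#' @param unit_cost_per_month USD per month of supply.
#' @param person_months Person-months of PrEP dispensed.
#' @return Annual medication cost (USD).
#' @export
medication_cost <- function(unit_cost_per_month, person_months) {
  if (unit_cost_per_month < 0 || person_months < 0) {
    stop("unit cost and person-months must be non-negative", call. = FALSE)
  }
  unit_cost_per_month * person_months
}

#' Visit counts for one service model over the costing year
#'
#' @param n_initiation,n_monthly,n_quarterly Attended visit counts.
#' @param n_reminders Reminder contacts (calls/texts); defaults to one per
#'   attended visit.
#' @param person_months Person-months of PrEP dispensed; defaults to total
#'   attended dispensing visits (every attended visit dispenses one month).
#' @return A list of class `visit_counts`.
#' @export
visit_counts <- function(n_initiation, n_monthly, n_quarterly,
                         n_reminders = n_initiation + n_monthly + n_quarterly,
                         person_months = n_initiation + n_monthly + n_quarterly) {
  counts <- list(n_initiation = n_initiation, n_monthly = n_monthly,
                 n_quarterly = n_quarterly, n_reminders = n_reminders,
                 person_months = person_months)
  if (any(unlist(counts) < 0)) {
    stop("visit counts must be non-negative", call. = FALSE)
  }
  structure(counts, class = "visit_counts")
}

event_count <- function(counts, visit_type) {
  switch(visit_type,
         initiation = counts$n_initiation,
         monthly_refill = counts$n_monthly,
         quarterly_refill = counts$n_quarterly,
         reminder_contact = counts$n_reminders,
         stop("unknown visit type: ", visit_type, call. = FALSE))
}

#' Annual variable personnel cost for one service model
#'
#' Sums, over visit types and roles, mean active minutes times the per-minute
#' personnel cost times the number of events. Per-client cells are charged once
#' per attended visit; club per-group social-worker cells are charged once per
#' group session, with `ceiling(n_visits / group_size)` sessions.
#'
#' @param profile A [staff_time_profile()] covering every cell used.
#' @param counts A [visit_counts()] for the model.
#' @param schedule A [salary_schedule()].
#' @param model One of [service_models()].
#' @param group_size Clients per group counselling session (club model).
#' @return Annual variable personnel cost (USD).
#' @export
variable_personnel_cost <- function(profile, counts, schedule, model,
                                    group_size = 7) {
  assert_model(model)
  stopifnot(inherits(counts, "visit_counts"))
  if (group_size < 1) stop("group size must be >= 1", call. = FALSE)

  total <- 0
  for (vt in c("initiation", "monthly_refill", "quarterly_refill")) {
    n <- event_count(counts, vt)
    for (role in staff_roles()) {
      cell <- profile_cell(profile, model, vt, role)
      n_charges <- if (cell$per_group) ceiling(n / group_size) else n
      total <- total + cell$minutes * n_charges *
        per_minute_cost(schedule, role, model)
    }
  }
  # reminder calls/texts: social-worker time per participant-visit
  rem <- profile_cell(profile, model, "reminder_contact", "social_worker",
                      default = 0)
  total + rem$minutes * counts$n_reminders *
    per_minute_cost(schedule, "social_worker", model)
}

#' Test schedules and annual testing cost
#'
#' A test schedule gives, per laboratory test, the unit cost (including
#' clinical supplies) and the event rule determining how many tests the visit
#' log implies: `"initiation"` (once per initiator, e.g. HBsAg),
#' `"initiation_and_quarterly"` (at initiation and every attended quarterly
#' visit, e.g. HIV serology under the 3-monthly retesting rule),
#' `"quarterly"`, `"none"` (test excluded from the scenario), or a fixed
#' `n_override` count where the event count is known directly.
#'
#' @param tests Data frame with columns `test`, `unit_cost`, `rule`, and
#'   optionally `n_override`.
#' @return A tibble of class `test_schedule`.
#' @export
test_schedule <- function(tests) {
  tests <- tibble::as_tibble(tests)
  stopifnot(all(c("test", "unit_cost", "rule") %in% names(tests)))
  if (!("n_override" %in% names(tests))) tests$n_override <- NA_real_
  ok_rule <- tests$rule %in% c("initiation", "initiation_and_quarterly",
                               "quarterly", "none")
  if (!all(ok_rule)) {
    stop("unknown test rule: ",
         paste(unique(tests$rule[!ok_rule]), collapse = ", "), call. = FALSE)
  }
  if (any(tests$unit_cost < 0)) {
    stop("unit costs must be non-negative", call. = FALSE)
  }
  class(tests) <- c("test_schedule", class(tests))
  tests
}

#' Annual cost per laboratory test
#'
#' Unit cost of each test times the number of tests implied by the visit
#' counts and the schedule's event rules. Tests with rule `"none"` cost zero.
#'
#' @param schedule A [test_schedule()].
#' @param counts A [visit_counts()].
#' @return Tibble with columns `test`, `n_tests`, `annual_usd`.
#' @export
test_costs <- function(schedule, counts) {
  stopifnot(inherits(schedule, "test_schedule"),
            inherits(counts, "visit_counts"))
  n <- vapply(seq_len(nrow(schedule)), function(i) {
    if (!is.na(schedule$n_override[i])) return(schedule$n_override[i])
    switch(schedule$rule[i],
           initiation = counts$n_initiation,
           initiation_and_quarterly = counts$n_initiation + counts$n_quarterly,
           quarterly = counts$n_quarterly,
           none = 0)
  }, numeric(1))
  if (any(n < 0)) stop("test counts must be non-negative", call. = FALSE)
  tibble::tibble(test = schedule$test, n_tests = n,
                 annual_usd = n * schedule$unit_cost)
}
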