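# small builders shared across test files

tiny_profile <- function() {
  staff_time_profile(tibble::tribble(
    ~model,          ~visit_type,        ~role,           ~minutes,
    "standard_care", "initiation",       "nurse",         34,
    "standard_care", "initiation",       "social_worker", 19,
    "standard_care", "monthly_refill",   "nurse",         6,
    "standard_care", "monthly_refill",   "social_worker", 1,
    "standard_care", "quarterly_refill", "nurse",         16,
    "standard_care", "quarterly_refill", "social_worker", 1,
    "standard_care", "reminder_contact", "social_worker", 2
  ))
}

tiny_salaries <- function() {
  salary_schedule(tibble::tibble(
    role = c("nurse", "social_worker"),
    annual_usd = c(25474.91, 4587.16)
  ))
}

# one-segment-per-row observation builder
obs_rows <- function(obs_id, model, visit_type, role, minutes,
                     flag = "service") {
  tibble::tibble(obs_id = obs_id, model = model, visit_type = visit_type,
                 role = role, minutes = minutes, flag = flag)
}

ledger_row <- function(category, amount, model = "shared",
                       date = "2019-01-15", currency = "USD") {
  tibble::tibble(date = date, category = category, amount = amount,
                 currency = currency, service_model = model)
}

sc_mix <- function() list(initiation = 0.54, monthly_refill = 0.35,
                          quarterly_refill = 0.11)
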