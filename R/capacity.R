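#' Bottleneck clinic-capacity model
#'
#' The nurse and the social worker serve each client in series, not in
#' parallel, so daily throughput is constrained by the staff member with the
#' greater total service time across the visit types. The model estimates the
#' maximum clients servable per day under a given visit-type mix, and from it
#' an annual person-month capacity — the at-scale denominators of the
#' scaled-DoH scenario. Club group-counselling sessions charge the social
#' worker's per-group time once per group of up to `group_size` clients.
#'
#' The published at-scale person-month volumes are not re-derivable from the
#' published staff times and mixes alone (the underlying worksheet is not
#' available), so the scenario engine takes person-month volumes as inputs and
#' this estimator is exposed as a documented, parameterized model.
#'
#' @name capacity
NULL

# Total per-day service minutes per role, summed over the three visit types
# (per-group club cells enter at their raw per-group minutes, matching how the
# published totals are formed).
role_total_minutes <- function(profile, model) {
  vts <- c("initiation", "monthly_refill", "quarterly_refill")
  vapply(staff_roles(), function(role) {
    sum(vapply(vts, function(vt) {
      profile_cell(profile, model, vt, role)$minutes
    }, numeric(1)))
  }, numeric(1))
}

#' Bottleneck role for a service model
#'
#' The role with the larger total service time across initiation, monthly and
#' quarterly visits. Ties resolve deterministically to the nurse.
#'
#' @param profile A [staff_time_profile()].
#' @param model One of [service_models()].
#' @return `"nurse"` or `"social_worker"`.
#' @export
bottleneck <- function(profile, model) {
  assert_model(model)
  totals <- role_total_minutes(profile, model)
  if (totals["social_worker"] > totals["nurse"]) "social_worker" else "nurse"
}

# Minutes role spends serving n clients/day under the mix, honouring per-group
# cells.
role_day_minutes <- function(profile, model, role, mix, n, group_size) {
  vts <- c("initiation", "monthly_refill", "quarterly_refill")
  total <- 0
  for (vt in vts) {
    cell <- profile_cell(profile, model, vt, role)
    n_vt <- n * mix[[vt]]
    charge <- if (cell$per_group) ceiling(n_vt / group_size) else n_vt
    total <- total + cell$minutes * charge
  }
  total
}

#' Daily client capacity and annual person-months for one service model
#'
#' Finds the largest whole number of clients per day whose bottleneck-role
#' service time fits in the working day, given the visit-type mix. Without
#' per-group cells this is the closed form
#' `floor(workday / sum_i mix_i * t_i(bottleneck))`; with club groups the
#' charge is stepwise, so the count is found by integer search. Annual
#' person-month capacity assumes every attended visit dispenses one month of
#' PrEP, so it equals clients/day times workdays/year.
#'
#' @param profile A [staff_time_profile()].
#' @param mix One row of [reference_visit_mix()] (or a list with elements
#'   `initiation`, `monthly_refill`, `quarterly_refill` summing to 1).
#' @param model One of [service_models()].
#' @param workday_minutes Productive minutes per working day (default 480,
#'   matching the 8-hour salary assumption).
#' @param group_size Clients per club counselling group (default 7).
#' @param workdays_per_year Working days per year (default 260).
#' @return A list of class `capacity_estimate`: `model`, `bottleneck_role`,
#'   `clients_per_day` (overall and by role), `clients_by_visit_type`,
#'   `groups_per_day` (club only, else `NA`), `annual_person_months`.
#' @export
daily_capacity <- function(profile, mix, model, workday_minutes = 480,
                           group_size = 7, workdays_per_year = 260) {
  assert_model(model)
  if (workday_minutes < 0) stop("workday must be >= 0", call. = FALSE)
  if (group_size < 1) stop("group size must be >= 1", call. = FALSE)
  fractions <- c(mix$initiation, mix$monthly_refill, mix$quarterly_refill)
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop("visit-mix fractions must be non-negative and sum to 1",
         call. = FALSE)
  }

  role <- bottleneck(profile, model)
  per_client <- role_day_minutes(profile, model, role, mix, 1, Inf) # no grouping
  if (role_day_minutes(profile, model, role, mix, 1, group_size) == 0) {
    stop("bottleneck role has zero service time under this mix: ",
         "capacity is unbounded; refusing to report it", call. = FALSE)
  }

  max_n <- function(r) {
    # stepwise in n because of ceiling(); search up from the no-grouping bound
    pc <- role_day_minutes(profile, model, r, mix, 1, Inf)
    n <- if (pc > 0) floor(workday_minutes / pc) else 0
    while (role_day_minutes(profile, model, r, mix, n + 1, group_size) <=
           workday_minutes) {
      n <- n + 1
    }
    while (n > 0 && role_day_minutes(profile, model, r, mix, n, group_size) >
           workday_minutes) {
      n <- n - 1
    }
    n
  }

  by_role <- vapply(staff_roles(), max_n, numeric(1))
  n <- by_role[[role]]
  by_type <- stats::setNames(
    n * fractions, c("initiation", "monthly_refill", "quarterly_refill"))
  groups <- if (model == "club") {
    ceiling(by_type[["monthly_refill"]] / group_size) +
      ceiling(by_type[["quarterly_refill"]] / group_size)
  } else {
    NA_real_
  }
  structure(list(
    model = model,
    bottleneck_role = role,
    clients_per_day = n,
    clients_per_day_by_role = by_role,
    clients_by_visit_type = by_type,
    groups_per_day = groups,
    workday_minutes = workday_minutes,
    annual_person_months = n * workdays_per_year
  ), class = "capacity_estimate")
}

#' @export
print.capacity_estimate <- function(x, ...) {
  cat(sprintf("Capacity estimate: %s\n", x$model))
  cat(sprintf("  bottleneck role:      %s\n", x$bottleneck_role))
  cat(sprintf("  clients/day:          %d\n", as.integer(x$clients_per_day)))
  if (!is.na(x$groups_per_day)) {
    cat(sprintf("  group sessions/day:   %d\n", as.integer(x$groups_per_day)))
  }
  cat(sprintf("  annual person-months: %d\n",
              as.integer(x$annual_person_months)))
  invisible(x)
}
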