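#' Time-and-motion observation logs
#'
#' Each observation times one staff member (nurse or social worker) through one
#' visit, recorded as segments flagged `service`, `waiting` or `research`.
#' Only service-flagged segments count towards the costed activity time:
#' waiting time for participants and time spent on research procedures are
#' stripped. Because the costing needs means (for per-minute pricing) while
#' programme reports use medians and interquartile ranges, the module exposes
#' both summaries from the same log.
#'
#' The tabular interface is one row per segment with columns
#' `obs_id, model, visit_type, role, minutes, flag`.
#'
#' @name time_motion
NULL

segment_flags <- function() c("service", "waiting", "research")

#' Validate an observation segment table
#'
#' @param obs Data frame with columns `obs_id`, `model`, `visit_type`, `role`,
#'   `minutes`, `flag` (one row per timed segment).
#' @return The validated tibble.
#' @export
validate_observations <- function(obs) {
  required <- c("obs_id", "model", "visit_type", "role", "minutes", "flag")
  missing <- setdiff(required, names(obs))
  if (length(missing)) {
    stop("observation log is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  obs <- tibble::as_tibble(obs)
  if (any(obs$minutes < 0) || anyNA(obs$minutes)) {
    stop("segment minutes must be non-negative", call. = FALSE)
  }
  if (!all(obs$flag %in% segment_flags())) {
    stop("segment flags must be one of: ",
         paste(segment_flags(), collapse = ", "), call. = FALSE)
  }
  if (!all(obs$model %in% service_models())) {
    stop("unknown service model in observation log", call. = FALSE)
  }
  if (!all(obs$visit_type %in% visit_types())) {
    stop("unknown visit type in observation log", call. = FALSE)
  }
  if (!all(obs$role %in% staff_roles())) {
    stop("unknown staff role in observation log", call. = FALSE)
  }
  obs
}

#' Read an observation log from CSV
#' @param path Path to a CSV with header
#'   `obs_id,model,visit_type,role,minutes,flag`.
#' @return A validated observation tibble.
#' @export
read_observations <- function(path) {
  validate_observations(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Active minutes of one observation
#'
#' Sums the service-flagged segments of a single observation, discarding
#' waiting and research time.
#'
#' @param minutes Numeric vector of segment durations (non-negative).
#' @param flag Character vector of segment flags, same length as `minutes`.
#' @return Total active (service) minutes.
#' @examples
#' active_minutes(c(30, 10, 5), c("service", "waiting", "research"))  # 30
#' @export
active_minutes <- function(minutes, flag) {
  if (length(minutes) == 0L) {
    stop("an observation must contain at least one segment", call. = FALSE)
  }
  if (length(minutes) != length(flag)) {
    stop("`minutes` and `flag` must have the same length", call. = FALSE)
  }
  if (any(minutes < 0) || anyNA(minutes)) {
    stop("segment minutes must be non-negative", call. = FALSE)
  }
  if (!all(flag %in% segment_flags())) {
    stop("segment flags must be one of: ",
         paste(segment_flags(), collapse = ", "), call. = FALSE)
  }
  sum(minutes[flag == "service"])
}

# Per-observation active minutes by role, one row per (obs_id, role).
observation_role_totals <- function(obs) {
  obs <- validate_observations(obs)
  obs |>
    dplyr::group_by(.data$obs_id, .data$model, .data$visit_type, .data$role) |>
    dplyr::summarise(
      active_minutes = active_minutes(.data$minutes, .data$flag),
      .groups = "drop"
    )
}

# Per-observation visit-level totals: nurse + social worker combined.
# An obs_id identifies one observed visit; both roles' timings for that visit
# share the id.
observation_visit_totals <- function(obs) {
  observation_role_totals(obs) |>
    dplyr::group_by(.data$obs_id, .data$model, .data$visit_type) |>
    dplyr::summarise(active_minutes = sum(.data$active_minutes),
                     .groups = "drop")
}

# Quartiles by linear interpolation between order statistics (stats::quantile
# type 7). The convention is fixed so that summaries are stable across runs.
duration_quartiles <- function(x) {
  stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
}

#' Median and IQR of active visit time
#'
#' Visit-level summaries combine nurse and social-worker active time for each
#' observed visit, then report the median and interquartile range per group.
#' Quartiles use linear interpolation between order statistics.
#'
#' @param obs Observation segment table (see [validate_observations()]).
#' @param by Character vector of grouping columns, a subset of
#'   `c("model", "visit_type")`.
#' @return A tibble with one row per observed group: `n`, `median_minutes`,
#'   `iqr_low`, `iqr_high`. Groups with no observations are simply absent.
#' @export
summarize_durations <- function(obs, by = c("model", "visit_type")) {
  stopifnot(all(by %in% c("model", "visit_type")))
  totals <- observation_visit_totals(obs)
  totals |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_minutes = duration_quartiles(.data$active_minutes)[2],
      iqr_low = duration_quartiles(.data$active_minutes)[1],
      iqr_high = duration_quartiles(.data$active_minutes)[3],
      .groups = "drop"
    )
}

#' Staff-time profiles
#'
#' A staff-time profile holds the mean active minutes per
#' (service model, visit type, role) cell — the costing-grade summary of the
#' time-and-motion data. Most cells are minutes per client; in the club model
#' the social worker runs group counselling sessions, so club monthly and
#' quarterly social-worker cells are minutes per group and carry
#' `per_group = TRUE`.
#'
#' @param df Data frame with columns `model`, `visit_type`, `role`, `minutes`
#'   and optionally `per_group` (defaults to the club social-worker rule).
#' @return A tibble of class `staff_time_profile`.
#' @export
staff_time_profile <- function(df) {
  required <- c("model", "visit_type", "role", "minutes")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("profile is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  if (any(df$minutes < 0)) stop("profile minutes must be >= 0", call. = FALSE)
  if (!("per_group" %in% names(df))) {
    df$per_group <- df$model == "club" &
      df$role == "social_worker" &
      df$visit_type %in% c("monthly_refill", "quarterly_refill")
  }
  if (anyDuplicated(df[c("model", "visit_type", "role")])) {
    stop("duplicate profile cells", call. = FALSE)
  }
  class(df) <- c("staff_time_profile", class(df))
  df
}

#' Mean active minutes per profile cell from an observation log
#'
#' Arithmetic mean of active minutes per (model, visit type, role). Initiation
#' procedures are identical in all arms, so initiation observations are pooled
#' across models and the pooled mean is replicated into each model's
#' initiation cells.
#'
#' @param obs Observation segment table.
#' @return A [staff_time_profile()].
#' @export
build_profile <- function(obs) {
  totals <- observation_role_totals(obs)
  init <- totals[totals$visit_type == "initiation", , drop = FALSE]
  rest <- totals[totals$visit_type != "initiation", , drop = FALSE]

  cells <- rest |>
    dplyr::group_by(.data$model, .data$visit_type, .data$role) |>
    dplyr::summarise(minutes = mean(.data$active_minutes), .groups = "drop")

  if (nrow(init)) {
    pooled <- init |>
      dplyr::group_by(.data$role) |>
      dplyr::summarise(minutes = mean(.data$active_minutes), .groups = "drop")
    init_cells <- tidyr::crossing(model = service_models(),
                                  visit_type = "initiation", pooled)
    cells <- dplyr::bind_rows(init_cells[names(cells)], cells)
  }
  staff_time_profile(cells)
}

#' Look up one profile cell
#'
#' @param profile A [staff_time_profile()].
#' @param model,visit_type,role Cell coordinates.
#' @param default If `NULL` (default) a missing cell is a hard error naming the
#'   cell; otherwise the value returned for a missing cell.
#' @return A list with `minutes` and `per_group`.
#' @export
profile_cell <- function(profile, model, visit_type, role, default = NULL) {
  hit <- profile$model == model & profile$visit_type == visit_type &
    profile$role == role
  if (!any(hit)) {
    if (is.null(default)) {
      stop(sprintf("staff-time profile has no cell (%s, %s, %s)",
                   model, visit_type, role), call. = FALSE)
    }
    return(list(minutes = default, per_group = FALSE))
  }
  list(minutes = profile$minutes[hit][1], per_group = profile$per_group[hit][1])
}

#' Cells missing from a profile
#'
#' @param profile A [staff_time_profile()].
#' @param models Service models that must be covered.
#' @return Tibble of (model, visit_type, role) combinations (over the three
#'   visit types initiation/monthly/quarterly) absent from the profile.
#' @export
missing_profile_cells <- function(profile, models = service_models()) {
  need <- tidyr::crossing(
    model = models,
    visit_type = c("initiation", "monthly_refill", "quarterly_refill"),
    role = staff_roles()
  )
  dplyr::anti_join(need, profile, by = c("model", "visit_type", "role"))
}
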