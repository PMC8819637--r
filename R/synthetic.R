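#' Seeded synthetic-data generators
#'
#' Generators for the three raw inputs the pipeline ingests — enrolment/visit
#' logs, time-and-motion observation logs and expenditure ledgers — with the
#' statistical structure the analysis assumes, so every stage runs and is
#' testable without access to trial records. All generators are pure functions
#' of `(config, seed)`: the same configuration and seed reproduce the same
#' tables.
#'
#' The retention model emulates the trial's dispensing pattern: 603 initiators
#' accruing about 1280 person-months, median 1 month on PrEP (IQR 1–2).
#' A single geometric dropout cannot match both that median and the mean of
#' 1280/603 = 2.123 months, so retention is a two-stage geometric: a
#' participant returns after the initiation month with probability
#' `continue_first` and thereafter continues month to month with probability
#' `continue_later`, capped at 12 scheduled months. The defaults
#' (`continue_first = 0.45`, `continue_later = 0.5994`) give median 1 and mean
#' `1 + continue_first / (1 - continue_later) = 2.123` months.
#'
#' @param seed Integer seed.
#' @param n_participants Number of PrEP initiators (default 603).
#' @param continue_first Probability of returning after the initiation month.
#' @param continue_later Monthly continuation probability thereafter.
#' @param max_months Scheduled follow-up horizon in months (default 12).
#' @param duration_sdlog Log-scale SD of observed segment durations.
#' @param obs_counts Named counts of time-and-motion observations:
#'   `initiation`, `standard_care`, `club`, `individual` (defaults 9/15/8/18,
#'   totalling 50).
#' @param ledger_targets Tibble `scenario`-free ledger targets: columns
#'   `model` (or `"shared"`), `category`, `total_usd`. Defaults to the
#'   published as-implemented columns (fixed categories shared, variable per
#'   model).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_participants = 603L,
                             continue_first = 0.45,
                             continue_later = 0.5994,
                             max_months = 12L,
                             duration_sdlog = 0.3,
                             obs_counts = c(initiation = 9L,
                                            standard_care = 15L,
                                            club = 8L,
                                            individual = 18L),
                             ledger_targets = default_ledger_targets()) {
  stopifnot(continue_first >= 0, continue_first <= 1,
            continue_later >= 0, continue_later <= 1,
            n_participants >= 0, max_months >= 1)
  structure(list(seed = as.integer(seed),
                 n_participants = as.integer(n_participants),
                 continue_first = continue_first,
                 continue_later = continue_later,
                 max_months = as.integer(max_months),
                 duration_sdlog = duration_sdlog,
                 obs_counts = obs_counts,
                 ledger_targets = ledger_targets),
            class = "generator_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# months 1,2,4,5,7,8,10,11 are monthly refills; 3,6,9,12 quarterly
label_month <- function(month) {
  ifelse(month %% 3 == 0, "quarterly_refill", "monthly_refill")
}

#' Generate an enrolment/visit log
#'
#' Each participant contributes an initiation visit (dispensing month 1) and
#' then attended follow-up visits under the retention model, labelled monthly
#' or quarterly by month number. Every attended visit dispenses one month of
#' PrEP, so a participant's person-months equal their visit count.
#'
#' @param config A [generator_config()].
#' @return Tibble with columns `participant_id`, `arm` (service model,
#'   allocated 1:1:1), `month` (0 = initiation), `visit_type`.
#' @export
gen_enrolment <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    n <- config$n_participants
    arms <- rep(service_models(), length.out = n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      # months on PrEP: initiation dispenses the first month; return after it
      # with probability continue_first, then month-to-month continuation
      d <- 1L
      if (stats::runif(1) < config$continue_first) {
        d <- 2L
        while (d < config$max_months &&
               stats::runif(1) < config$continue_later) {
          d <- d + 1L
        }
      }
      months <- 0:(d - 1L)
      rows[[i]] <- tibble::tibble(
        participant_id = i, arm = arms[i], month = months,
        visit_type = ifelse(months == 0L, "initiation", label_month(months))
      )
    }
    dplyr::bind_rows(rows)
  })
}

#' Person-months and duration summary of a visit log
#'
#' @param visits A visit log from [gen_enrolment()].
#' @return List with `total_person_months`, `mean_months`, `median_months`,
#'   `iqr_months` and per-arm person-month totals.
#' @export
enrolment_summary <- function(visits) {
  per <- visits |>
    dplyr::group_by(.data$participant_id, .data$arm) |>
    dplyr::summarise(months = dplyr::n(), .groups = "drop")
  q <- stats::quantile(per$months, c(0.25, 0.75), type = 7, names = FALSE)
  list(
    total_person_months = sum(per$months),
    mean_months = mean(per$months),
    median_months = stats::median(per$months),
    iqr_months = q,
    by_arm = tapply(per$months, per$arm, sum)
  )
}

#' Visit counts per model from a visit log
#' @param visits A visit log from [gen_enrolment()].
#' @param model One of [service_models()].
#' @return A [visit_counts()].
#' @export
visit_counts_from_log <- function(visits, model) {
  assert_model(model)
  v <- visits[visits$arm == model, ]
  visit_counts(
    n_initiation = sum(v$visit_type == "initiation"),
    n_monthly = sum(v$visit_type == "monthly_refill"),
    n_quarterly = sum(v$visit_type == "quarterly_refill")
  )
}

# Target median active minutes per (model, visit_type, role): visit-level
# medians with the published nurse/social-worker split.
default_duration_targets <- function() {
  tibble::tribble(
    ~model,          ~visit_type,        ~role,           ~median_minutes,
    "standard_care", "initiation",       "nurse",         32,
    "standard_care", "initiation",       "social_worker", 19,
    "standard_care", "monthly_refill",   "nurse",         5.5,
    "standard_care", "monthly_refill",   "social_worker", 0.5,
    "standard_care", "quarterly_refill", "nurse",         15.5,
    "standard_care", "quarterly_refill", "social_worker", 1.5,
    "club",          "monthly_refill",   "nurse",         2,
    "club",          "monthly_refill",   "social_worker", 41,
    "club",          "quarterly_refill", "nurse",         19,
    "club",          "quarterly_refill", "social_worker", 38,
    "individual",    "monthly_refill",   "nurse",         5,
    "individual",    "monthly_refill",   "social_worker", 25,
    "individual",    "quarterly_refill", "nurse",         20.2,
    "individual",    "quarterly_refill", "social_worker", 25.8
  )
}

#' Generate a time-and-motion observation log
#'
#' Produces segment-level observations: per observed visit, one service
#' segment per role with log-normal duration located at the target median
#' (log-normal medians equal `exp(meanlog)`, so targets are hit exactly in
#' median), plus waiting and research segments that downstream processing must
#' strip. Initiation observations are assigned round-robin across models
#' (initiation procedures are identical in all arms); follow-up observations
#' alternate monthly/quarterly at roughly 2:1.
#'
#' @param config A [generator_config()].
#' @param targets Duration targets (`model`, `visit_type`, `role`,
#'   `median_minutes`); defaults to the published visit-level medians split by
#'   role.
#' @return A validated observation tibble (see [validate_observations()]).
#' @export
gen_observations <- function(config, targets = default_duration_targets()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed + 1L, {
    oc <- config$obs_counts
    plan <- list()
    init_models <- rep(service_models(), length.out = oc[["initiation"]])
    for (i in seq_along(init_models)) {
      plan[[length(plan) + 1L]] <- list(model = init_models[i],
                                        visit_type = "initiation")
    }
    for (model in c("standard_care", "club", "individual")) {
      n <- oc[[model]]
      vts <- rep(c("monthly_refill", "monthly_refill", "quarterly_refill"),
                 length.out = n)
      for (vt in vts) {
        plan[[length(plan) + 1L]] <- list(model = model, visit_type = vt)
      }
    }

    rows <- vector("list", length(plan))
    for (k in seq_along(plan)) {
      p <- plan[[k]]
      segs <- list()
      for (role in staff_roles()) {
        tgt <- targets[targets$model == p$model &
                         targets$visit_type == p$visit_type &
                         targets$role == role, ]
        # club initiations etc. fall back to the standard-care target
        if (!nrow(tgt) && p$visit_type == "initiation") {
          tgt <- targets[targets$model == "standard_care" &
                           targets$visit_type == "initiation" &
                           targets$role == role, ]
        }
        if (!nrow(tgt)) next
        minutes <- stats::rlnorm(1, meanlog = log(tgt$median_minutes),
                                 sdlog = config$duration_sdlog)
        segs[[length(segs) + 1L]] <- tibble::tibble(
          role = role, minutes = minutes, flag = "service")
      }
      # excludable time: participant waiting and research procedures
      segs[[length(segs) + 1L]] <- tibble::tibble(
        role = "nurse",
        minutes = stats::rlnorm(2, meanlog = log(c(8, 4)), sdlog = 0.5),
        flag = c("waiting", "research"))
      obs <- dplyr::bind_rows(segs)
      obs$obs_id <- k
      obs$model <- p$model
      obs$visit_type <- p$visit_type
      rows[[k]] <- obs
    }
    validate_observations(dplyr::bind_rows(rows)[
      , c("obs_id", "model", "visit_type", "role", "minutes", "flag")])
  })
}

#' Default ledger targets: the published as-implemented cost columns
#'
#' Fixed categories are shared site-level costs; variable categories are
#' per-model.
#' @return Tibble `model`, `category`, `total_usd`.
#' @export
default_ledger_targets <- function() {
  tab <- reference_cost_table()
  tab <- tab[tab$scenario == "as_implemented" & !is.na(tab$annual_usd), ]
  fixed <- cost_categories()$category[cost_categories()$behaviour == "fixed"]
  shared <- tab[tab$model == "standard_care" & tab$category %in% fixed, ]
  shared$model <- "shared"
  varpart <- tab[!(tab$category %in% fixed), ]
  out <- dplyr::bind_rows(shared, varpart)[, c("model", "category", "annual_usd")]
  names(out)[3] <- "total_usd"
  out
}

#' Generate an itemized expenditure ledger
#'
#' Splits each (model, category) target into 1–10 items with random dates in
#' the costing window; the last item takes the remainder so itemized entries
#' sum to the target exactly and [aggregate_ledger()] recovers the targets by
#' construction. Zero targets produce no entries.
#'
#' @param config A [generator_config()].
#' @return A validated ledger tibble (USD entries).
#' @export
gen_ledger <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  targets <- config$ledger_targets
  with_seed(config$seed + 2L, {
    window <- costing_window()
    days <- seq(window[1], window[2], by = "day")
    rows <- vector("list", nrow(targets))
    for (i in seq_len(nrow(targets))) {
      total <- targets$total_usd[i]
      if (is.na(total) || total == 0) next
      k <- sample.int(10L, 1L)
      cuts <- sort(stats::runif(k - 1L, 0, total))
      amounts <- diff(c(0, cuts, total))
      # guard against degenerate zero-width splits
      amounts <- amounts[amounts > 0]
      if (!length(amounts)) amounts <- total
      amounts[length(amounts)] <- total - sum(amounts[-length(amounts)])
      rows[[i]] <- tibble::tibble(
        date = sample(days, length(amounts), replace = TRUE),
        category = targets$category[i],
        amount = amounts,
        currency = "USD",
        service_model = targets$model[i]
      )
    }
    validate_ledger(dplyr::bind_rows(rows))
  })
}

#' Write a full synthetic fixture set
#'
#' Writes `observations.csv`, `visits.csv` and `ledger.csv` under `outdir`.
#'
#' @param config A [generator_config()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the named list of written paths.
#' @export
write_synthetic_fixtures <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    observations = file.path(outdir, "observations.csv"),
    visits = file.path(outdir, "visits.csv"),
    ledger = file.path(outdir, "ledger.csv")
  )
  utils::write.csv(gen_observations(config), paths$observations,
                   row.names = FALSE)
  utils::write.csv(gen_enrolment(config), paths$visits, row.names = FALSE)
  utils::write.csv(gen_ledger(config), paths$ledger, row.names = FALSE)
  invisible(paths)
}
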