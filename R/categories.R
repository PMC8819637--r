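#' Cost category taxonomy
#'
#' The costing distinguishes fixed costs (independent of client volume) from
#' variable costs (scaling with visits and person-months dispensed). Fixed:
#' capital, training, demand creation, supervisory personnel, facility
#' overheads and administrative supplies. Variable: direct service-delivery
#' personnel time, PrEP medication, miscellaneous medical consumables and the
#' laboratory tests (HIV serology, HBsAg, creatinine, pregnancy, syphilis).
#' Syphilis testing is part of the service-delivery package but carried zero
#' recorded cost in every scenario, so it appears as a category with zero
#' default cost rather than being dropped.
#'
#' @return A tibble with columns `category` and `behaviour`
#'   (`"fixed"`/`"variable"`), in canonical reporting order.
#' @export
cost_categories <- function() {
  tibble::tibble(
    category = c(
      "capital", "training", "demand_creation", "personnel_fixed",
      "overhead", "admin_supplies",
      "personnel_variable", "prep_medication", "misc_medical_supplies",
      "hiv_test", "hbsag_test", "creatinine_test", "pregnancy_test",
      "syphilis_test"
    ),
    behaviour = c(rep("fixed", 6L), rep("variable", 8L))
  )
}

#' The three PrEP service-delivery models
#'
#' Standard care is community-based medication dispensary with passive
#' adherence support; clubs add group-based effective-use counselling;
#' individual adds one-on-one effective-use counselling. Counselling is
#' task-shifted from nurses to trained lay counsellors (social workers).
#'
#' @return Character vector of the three model identifiers.
#' @export
service_models <- function() c("standard_care", "club", "individual")

#' Visit types recognised by the costing
#'
#' Monthly refill visits occur at months 1, 2, 4, 5, 7, 8, 10 and 11;
#' quarterly refill visits (adding blood tests and a pregnancy test) at months
#' 3, 6, 9 and 12. Reminder contacts are the scheduling calls/texts sent
#' before each visit.
#'
#' @return Character vector of visit-type identifiers.
#' @export
visit_types <- function() {
  c("initiation", "monthly_refill", "quarterly_refill", "reminder_contact")
}

#' Staff roles observed in service delivery
#' @return Character vector of role identifiers.
#' @export
staff_roles <- function() c("nurse", "social_worker")

assert_model <- function(model) {
  if (!(is.character(model) && length(model) == 1L &&
        model %in% service_models())) {
    stop("`model` must be one of: ",
         paste(service_models(), collapse = ", "), call. = FALSE)
  }
  model
}

assert_category <- function(category) {
  bad <- setdiff(category, cost_categories()$category)
  if (length(bad)) {
    stop("unknown cost categories: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  category
}
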