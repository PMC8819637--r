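#' Expenditure ledgers
#'
#' Programme expenditure (invoices, receipts, claim forms, contracts) is
#' represented as a ledger: one row per entry with a date, a cost category, an
#' amount with its currency, and the service-delivery model it is attributable
#' to. Site-level costs shared by all three models carry
#' `service_model = "shared"` and are attributed in full to each model
#' (fixed rows are identical across the three models' cost columns).
#'
#' @name ledger
NULL

#' Start and end of the costing window
#'
#' The costing period runs from 1 November 2018 to 1 November 2019; entries
#' dated outside it are rejected.
#' @return A length-2 Date vector `c(start, end)`.
#' @export
costing_window <- function() as.Date(c("2018-11-01", "2019-11-01"))

#' Validate a ledger table
#'
#' @param ledger Data frame with columns `date`, `category`, `amount`,
#'   `currency`, `service_model`.
#' @param window Length-2 Date vector of acceptable entry dates (inclusive).
#' @return The validated ledger as a tibble with `date` parsed to `Date`.
#' @export
validate_ledger <- function(ledger, window = costing_window()) {
  required <- c("date", "category", "amount", "currency", "service_model")
  missing <- setdiff(required, names(ledger))
  if (length(missing)) {
    stop("ledger is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ledger <- tibble::as_tibble(ledger)
  ledger$date <- as.Date(ledger$date)
  if (anyNA(ledger$date)) stop("unparseable ledger dates", call. = FALSE)
  assert_category(ledger$category)
  if (!all(ledger$currency %in% c("ZAR", "USD"))) {
    stop("ledger currency must be ZAR or USD", call. = FALSE)
  }
  ok_model <- ledger$service_model %in% c(service_models(), "shared")
  if (!all(ok_model)) {
    stop("unknown service_model in ledger: ",
         paste(unique(ledger$service_model[!ok_model]), collapse = ", "),
         call. = FALSE)
  }
  if (any(ledger$amount < 0)) stop("negative ledger amounts", call. = FALSE)
  outside <- ledger$date < window[1] | ledger$date > window[2]
  if (any(outside)) {
    stop(sum(outside), " ledger entr", if (sum(outside) == 1L) "y" else "ies",
         " dated outside the costing window ",
         window[1], " to ", window[2], call. = FALSE)
  }
  ledger
}

#' Read an expenditure ledger from CSV
#'
#' Expects header `date,category,amount,currency,service_model`; category
#' strings must match [cost_categories()] exactly.
#'
#' @param path Path to a CSV file.
#' @param window Costing window passed to [validate_ledger()].
#' @return A validated ledger tibble.
#' @export
read_ledger <- function(path, window = costing_window()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_ledger(raw, window = window)
}

#' Aggregate a ledger into per-category annual cost for one model
#'
#' Sums entries attributable to `model` (its own entries plus `"shared"`
#' entries), converting ZAR amounts to USD at `rate`. Every category is
#' present in the output, defaulting to zero.
#'
#' @param ledger A ledger tibble (see [validate_ledger()]).
#' @param model One of [service_models()].
#' @param rate ZAR-per-USD exchange rate.
#' @return A tibble with columns `category`, `behaviour`, `annual_usd`, one row
#'   per category in canonical order.
#' @export
aggregate_ledger <- function(ledger, model, rate = default_exchange_rate()) {
  assert_model(model)
  ledger <- validate_ledger(ledger)
  keep <- ledger[ledger$service_model %in% c(model, "shared"), , drop = FALSE]
  usd <- ifelse(keep$currency == "ZAR", zar_to_usd(keep$amount, rate),
                keep$amount)
  sums <- tapply(usd, factor(keep$category, levels = cost_categories()$category),
                 sum, default = 0)
  out <- cost_categories()
  out$annual_usd <- as.numeric(sums[out$category])
  out$annual_usd[is.na(out$annual_usd)] <- 0
  out
}
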