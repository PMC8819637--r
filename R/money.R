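#' Money amounts and currency conversion
#'
#' Costs were collected in South African Rand (ZAR) and reported in US dollars
#' (USD) at the average market exchange rate over the costing year,
#' 14.31 ZAR per USD. A `money` object is a non-negative value tagged with its
#' currency; all internal arithmetic is done at full precision and rounding to
#' two decimals happens only at report boundaries.
#'
#' @param value Non-negative numeric amount.
#' @param currency One of `"ZAR"`, `"USD"`.
#' @return An object of class `money`.
#' @examples
#' m <- money(14.31, "ZAR")
#' convert_currency(m, "USD")
#' @export
money <- function(value, currency = c("USD", "ZAR")) {
  currency <- match.arg(currency)
  if (!is.numeric(value) || length(value) != 1L || is.na(value)) {
    stop("`value` must be a single non-missing number", call. = FALSE)
  }
  if (value < 0) stop("cost amounts must be non-negative", call. = FALSE)
  structure(list(value = as.numeric(value), currency = currency),
            class = "money")
}

#' @export
print.money <- function(x, ...) {
  cat(sprintf("%.2f %s\n", x$value, x$currency))
  invisible(x)
}

#' @export
format.money <- function(x, ...) sprintf("%.2f %s", x$value, x$currency)

#' Default ZAR-per-USD exchange rate for the costing year
#'
#' Average monthly market rate over the November 2018 to November 2019 costing
#' window.
#' @return A single number (ZAR per 1 USD).
#' @export
default_exchange_rate <- function() 14.31

#' Convert a money amount between ZAR and USD
#'
#' @param amount A [money()] object.
#' @param target Target currency, `"USD"` or `"ZAR"`.
#' @param rate Positive exchange rate, ZAR per 1 USD.
#' @return A [money()] object in the target currency. Converting to the amount's
#'   own currency returns it unchanged.
#' @examples
#' convert_currency(money(100, "USD"), "ZAR")  # 1431 ZAR
#' @export
convert_currency <- function(amount, target = c("USD", "ZAR"),
                             rate = default_exchange_rate()) {
  target <- match.arg(target)
  stopifnot(inherits(amount, "money"))
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate <= 0) {
    stop("exchange `rate` must be a single positive number", call. = FALSE)
  }
  if (amount$currency == target) return(amount)
  value <- if (target == "USD") amount$value / rate else amount$value * rate
  money(value, target)
}

#' Vectorised ZAR to USD conversion
#' @param x Numeric vector of ZAR amounts.
#' @param rate Positive exchange rate, ZAR per 1 USD.
#' @return Numeric vector of USD amounts.
#' @export
zar_to_usd <- function(x, rate = default_exchange_rate()) {
  if (rate <= 0) stop("exchange `rate` must be positive", call. = FALSE)
  x / rate
}
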