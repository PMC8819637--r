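#' Renderers for cost tables and duration summaries
#'
#' Money stays at full precision inside the pipeline; these renderers apply
#' 2-decimal rounding, thousands separators and em-dashes for excluded
#' categories only at the presentation boundary.
#'
#' @name render
NULL

fmt_money <- function(x) {
  ifelse(is.na(x), "–",
         formatC(round(x, 2), format = "f", digits = 2, big.mark = ","))
}

parse_money <- function(x) {
  out <- suppressWarnings(as.numeric(gsub(",", "", x)))
  out[x == "–"] <- NA_real_
  out
}

#' Render cost reports as a wide annual/unit cost table
#'
#' One paired pair of columns (annual cost, unit cost per person-month) per
#' (scenario, model) report, rows in canonical category order plus a total
#' row. Values are 2-decimal strings with thousands separators; excluded
#' categories render as an em-dash.
#'
#' @param reports A list of `cost_report`s (1–9, no duplicated
#'   scenario/model).
#' @return A tibble of formatted strings; first column `category`.
#' @export
render_cost_table <- function(reports) {
  if (!length(reports) || length(reports) > 9) {
    stop("render_cost_table takes 1-9 reports", call. = FALSE)
  }
  keys <- vapply(reports, function(r) paste(r$scenario, r$model, sep = "."),
                 character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate (scenario, model) reports: ",
         paste(keys[duplicated(keys)], collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(category = c(cost_categories()$category, "total"))
  for (r in reports) {
    key <- paste(r$scenario, r$model, sep = ".")
    annual <- c(r$categories$annual_usd, r$total_usd)
    unit <- c(r$categories$unit_usd, r$cost_per_person_month)
    out[[paste0(key, ".annual")]] <- fmt_money(annual)
    out[[paste0(key, ".unit")]] <- fmt_money(unit)
  }
  out
}

#' Parse a rendered cost table back to numbers
#'
#' Inverse of [render_cost_table()] at 2-decimal precision.
#'
#' @param rendered A tibble from [render_cost_table()].
#' @return The same tibble with numeric value columns.
#' @export
parse_cost_table <- function(rendered) {
  out <- rendered
  for (col in setdiff(names(out), "category")) {
    out[[col]] <- parse_money(out[[col]])
  }
  out
}

#' Write a rendered cost table to CSV
#' @param rendered A tibble from [render_cost_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cost_table <- function(rendered, path) {
  utils::write.csv(rendered, path, row.names = FALSE)
  invisible(path)
}

#' Render duration summaries as "median (IQR: lo, hi)" text
#'
#' @param summaries A tibble from [summarize_durations()].
#' @return The tibble with an added character column `text`.
#' @examples
#' # a median of 6 with quartiles 5 and 9 renders as "6 minutes (IQR: 5, 9)"
#' @export
render_summary <- function(summaries) {
  fmt1 <- function(x) {
    ifelse(abs(x - round(x)) < 1e-9, format(round(x)),
           formatC(x, format = "f", digits = 1))
  }
  summaries$text <- sprintf("%s minutes (IQR: %s, %s)",
                            fmt1(summaries$median_minutes),
                            fmt1(summaries$iqr_low),
                            fmt1(summaries$iqr_high))
  summaries
}
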