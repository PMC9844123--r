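#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a sort report into one row per metric
#'
#' @param x a `sort_report`.
#' @param ... unused.
#' @return tibble with columns `metric`, `value`, `unit`.
#' @export
tidy.sort_report <- function(x, ...) {
  tibble::tibble(
    metric = c("n_total", "n_gated", "n_actuated", "n_aborted", "n_collected",
               "initial_purity", "target_purity", "enrichment", "recovery",
               "throughput", "cv_before", "cv_after"),
    value = c(x$n_total, x$n_gated, x$n_actuated, x$n_aborted, x$n_collected,
              x$initial_purity, x$target_purity, x$enrichment, x$recovery,
              x$throughput, x$cv_before, x$cv_after),
    unit = c("events", "events", "events", "events", "events",
             "%", "%", "fold", "%", "events/s", "%", "%")
  )
}

#' One-row summary of a sort report
#'
#' @param x a `sort_report`.
#' @param ... unused.
#' @return one-row tibble with the headline metrics.
#' @export
glance.sort_report <- function(x, ...) {
  tibble::tibble(n_total = x$n_total, initial_purity = x$initial_purity,
                 target_purity = x$target_purity, enrichment = x$enrichment,
                 recovery = x$recovery, throughput = x$throughput)
}

#' @export
tidy.sort_run <- function(x, ...) tidy(x$report, ...)

#' @export
glance.sort_run <- function(x, ...) glance(x$report, ...)
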