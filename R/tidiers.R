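#' Tidy a reliability table
#'
#' @param x a `balance_reliability` object.
#' @param ... unused.
#' @return a plain tibble, one row per variable.
#' @method tidy balance_reliability
#' @export
tidy.balance_reliability <- function(x, ...) {
  as_tibble(unclass_first(x))
}

#' Summarise a reliability analysis in one row
#'
#' @param x a `balance_reliability` object.
#' @param ... unused.
#' @return one-row tibble: subjects, variables analysed, ICC summary and the
#'   count of starred (most reliable) variables.
#' @method glance balance_reliability
#' @export
glance.balance_reliability <- function(x, ...) {
  tibble(
    n_subjects = attr(x, "n_subjects"),
    n_variables = nrow(x),
    icc_measures = attr(x, "measures"),
    icc_min = min(x$icc), icc_median = stats::median(x$icc),
    icc_max = max(x$icc),
    n_starred = sum(x$star)
  )
}

#' Tidy a patient-monitoring result
#'
#' @param x a `balance_mbd` object.
#' @param ... unused.
#' @return a plain tibble, one row per variable.
#' @method tidy balance_mbd
#' @export
tidy.balance_mbd <- function(x, ...) {
  as_tibble(unclass_first(x))
}

#' Summarise a patient-monitoring result in one row
#'
#' @param x a `balance_mbd` object.
#' @param ... unused.
#' @return one-row tibble: variables assessed and how many changes were at
#'   least probably (>= 75%) or very likely (>= 95%) relevant.
#' @method glance balance_mbd
#' @export
glance.balance_mbd <- function(x, ...) {
  tibble(
    n_variables = nrow(x),
    n_probable = sum(x$p_change >= 75),
    n_very_likely = sum(x$p_change >= 95),
    n_negative = sum(x$direction == "negative" & x$p_change >= 75),
    n_positive = sum(x$direction == "positive" & x$p_change >= 75)
  )
}

unclass_first <- function(x) {
  class(x) <- setdiff(class(x), c("balance_reliability", "balance_mbd"))
  x
}
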