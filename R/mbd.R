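#' Probabilities that an individual change is negative, trivial or positive
#'
#' The magnitude-based decision (MBD) step for individual monitoring: the
#' true change underlying an observed pre/post difference is modelled as
#' `Normal(post - pre, sd = mdc / 1.96)` — equivalently `sd = sqrt(2) * SEM`,
#' the sampling SD of a difference of two measurements — and located
#' relative to the relevance band `(-mdc, +mdc)`:
#' `p_neg = P(change < -mdc)`, `p_pos = P(change > +mdc)`, and `p_triv` the
#' remainder. The three percentages sum to 100 exactly before rounding.
#'
#' @param pre,post measured values before and after treatment (vectorized).
#' @param mdc minimal detectable change threshold, > 0, same units.
#' @return tibble with columns `xdif`, `p_neg`, `p_triv`, `p_pos`
#'   (unrounded percentages).
#' @examples
#' change_probabilities(pre = 41.0, post = 25.4, mdc = 7.2)
#' @export
change_probabilities <- function(pre, post, mdc) {
  if (any(mdc <= 0)) {
    abort_invalid("`mdc` thresholds must be > 0.", "balancemdc_invalid_threshold")
  }
  xdif <- post - pre
  sd_change <- mdc / 1.96
  # both tails via the same routine so pre/post swap mirrors them exactly
  p_neg <- 100 * pnorm(-mdc, mean = xdif, sd = sd_change)
  p_pos <- 100 * pnorm(mdc, mean = xdif, sd = sd_change, lower.tail = FALSE)
  tibble(
    xdif = xdif,
    p_neg = p_neg,
    p_triv = pmax(100 - p_neg - p_pos, 0), # guard the fp remainder at 0
    p_pos = p_pos
  )
}

#' Qualitative probability-of-change label
#'
#' The conventional qualitative scale for MBD probabilities: most unlikely
#' (<1%), very unlikely (1-5%), unlikely (5-25%), possibly (25-75%),
#' probably (75-95%), very likely (95-99%), most likely (>99%).
#'
#' @param p probability of a relevant change, in percent (0-100), vectorized.
#' @return ordered factor of labels.
#' @examples
#' classify_probability(c(0.5, 86, 99.5))
#' @export
classify_probability <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 100)) {
    stop_invalid("`p` must be a percentage in [0, 100].")
  }
  cut(p, breaks = c(-Inf, 1, 5, 25, 75, 95, 99 + 1e-12, Inf), right = FALSE,
      labels = c("most unlikely", "very unlikely", "unlikely", "possibly",
                 "probably", "very likely", "most likely"),
      ordered_result = TRUE)
}

#' Monitor an individual patient's pre/post change
#'
#' Applies the MBD procedure with MDC thresholds to every variable shared by
#' the pre- and post-treatment panels: computes the difference
#' `xdif = post - pre`, the (%-, %0, %+) triplet from
#' [change_probabilities()], the probability of a relevant change
#' `p_change = max(p_neg, p_pos)` with its direction, and the qualitative
#' label. An optional interpretation layer annotates each change as
#' improvement or worsening under the convention that static sway variables
#' decreasing, and LOS variables increasing, indicate better balance; it
#' never alters the statistics.
#'
#' @param pre,post balance-variable tibbles with columns `variable`, `value`
#'   and optionally `task` (as produced by [extract_variables()] or read
#'   from file).
#' @param thresholds MDC threshold table: columns `variable`, `mdc95`
#'   (optionally `task`), all `mdc95 > 0`.
#' @param annotate_direction add the improvement/worsening annotation
#'   (default TRUE when a `task` column is present).
#' @return a `balance_mbd` tibble, one row per shared variable in the pre
#'   panel's order: `pre`, `post`, `xdif`, `mdc`, `p_neg`, `p_triv`,
#'   `p_pos`, `p_change`, `p_outside`, `direction`, `label` (and
#'   `interpretation` when annotated). Variables present in only one panel
#'   are dropped with a warning; a shared variable missing a threshold is an
#'   error.
#' @examples
#' p01 <- patient01_example()
#' monitor_patient(p01$pre, p01$post, p01$thresholds)
#' @export
monitor_patient <- function(pre, post, thresholds,
                            annotate_direction = "task" %in% names(pre)) {
  pre <- as_tibble(pre); post <- as_tibble(post)
  thresholds <- as_tibble(thresholds)
  for (nm in list(list(pre, "pre"), list(post, "post"))) {
    if (!all(c("variable", "value") %in% names(nm[[1]]))) {
      stop_invalid_spec(sprintf("`%s` must have columns variable, value.", nm[[2]]))
    }
  }
  if (!all(c("variable", "mdc95") %in% names(thresholds))) {
    stop_config("`thresholds` must have columns variable, mdc95.")
  }
  keys <- Reduce(intersect, list(
    intersect(c("task", "variable"), names(pre)),
    intersect(c("task", "variable"), names(post))))

  key_of <- function(x) do.call(paste, c(x[keys], sep = "\r"))
  shared <- intersect(key_of(pre), key_of(post))
  only_one <- c(setdiff(key_of(pre), key_of(post)),
                setdiff(key_of(post), key_of(pre)))
  if (length(only_one) > 0) {
    warn(paste0("skipping variables present in only one session: ",
                paste(gsub("\r", " / ", only_one), collapse = "; ")))
  }
  pre_s <- pre[key_of(pre) %in% shared, ]
  res <- dplyr::inner_join(
    dplyr::rename(pre_s[c(keys, "value")], pre = "value"),
    dplyr::rename(post[c(keys, "value")], post = "value"),
    by = keys)

  thr_keys <- intersect(keys, names(thresholds))
  thr <- dplyr::left_join(res, thresholds[c(thr_keys, "mdc95")], by = thr_keys)
  if (anyNA(thr$mdc95)) {
    missing <- thr$variable[is.na(thr$mdc95)]
    stop_config(paste0("no MDC threshold for: ",
                       paste(unique(missing), collapse = ", ")))
  }
  probs <- change_probabilities(thr$pre, thr$post, thr$mdc95)
  out <- dplyr::bind_cols(
    thr[c(keys, "pre", "post")],
    tibble(xdif = probs$xdif, mdc = thr$mdc95,
           p_neg = probs$p_neg, p_triv = probs$p_triv, p_pos = probs$p_pos)
  )
  out <- out |>
    dplyr::mutate(
      p_change = pmax(.data$p_neg, .data$p_pos),
      p_outside = .data$p_neg + .data$p_pos,
      direction = dplyr::case_when(
        .data$p_neg > .data$p_pos ~ "negative",
        .data$p_pos > .data$p_neg ~ "positive",
        TRUE ~ "trivial"
      ),
      label = classify_probability(.data$p_change)
    )
  if (isTRUE(annotate_direction) && "task" %in% names(out)) {
    out$interpretation <- interpret_change(out$task, out$direction)
  }
  structure(out, class = c("balance_mbd", class(out)))
}

# static sway decreasing = improvement; LOS increasing = improvement
interpret_change <- function(task, direction) {
  dplyr::case_when(
    direction == "trivial" ~ "no relevant change",
    task == "LOS" & direction == "positive" ~ "improvement",
    task == "LOS" & direction == "negative" ~ "worsening",
    direction == "negative" ~ "improvement",
    TRUE ~ "worsening"
  )
}

#' Format a patient-monitoring result for reporting
#'
#' One row per variable with `Value Pre`, `Value Post`, `Difference`, `MDC`
#' (one decimal, half-up) and the integer-rounded `% (- / 0 / +)` triplet.
#'
#' @param res a [monitor_patient()] result.
#' @return tibble in display form.
#' @export
format_monitor <- function(res) {
  fmt1 <- function(x) formatC(round_half_up(x, 1), format = "f", digits = 1)
  out <- tibble(
    Variables = res$variable,
    `Value Pre` = fmt1(res$pre),
    `Value Post` = fmt1(res$post),
    Difference = fmt1(res$xdif),
    MDC = fmt1(res$mdc),
    `% (- / 0 / +)` = sprintf("%d/%d/%d",
                              round_half_up(res$p_neg),
                              round_half_up(res$p_triv),
                              round_half_up(res$p_pos)),
    Probability = as.character(res$label)
  )
  if ("task" %in% names(res)) {
    out <- dplyr::bind_cols(tibble(`Balance Tasks` = res$task), out)
  }
  out
}

#' @rdname format_monitor
#' @param path file path for the delimited report.
#' @export
write_monitor_report <- function(res, path) {
  readr::write_csv(format_monitor(res), path)
  invisible(path)
}
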