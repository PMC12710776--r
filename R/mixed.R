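# Nested-eye mixed-effects comparisons.
#
# When both eyes of each subject enter the analysis, observations are not
# independent: session (and, in the two-way form, age group) are fixed
# effects and subject is a random intercept, fitted by REML. Degrees of
# freedom and p values use the Satterthwaite method; pairwise session
# contrasts within groups are Sidak-adjusted.

#' Mixed-effects session comparison (one- or two-way)
#'
#' Fits `value ~ session + (1 | subject)` (or
#' `value ~ session * group + (1 | subject)` when `table$group` is present)
#' by REML via `lmerTest`. A singular fit (zero between-subject variance)
#' falls back to the fixed-effects analogue (`lm`) with a logged note.
#'
#' @param table Long tibble with columns `subject`, `eye`, `session`,
#'   `value`, and optionally `group`.
#' @return List of class `ffa_mixed`: `fixed` (tidy fixed-effect tibble),
#'   `pairwise` (Sidak-adjusted session contrasts, two-way form only),
#'   `session_estimate` (PM minus AM), `singular`, `fit`.
#' @export
mixed_effects_compare <- function(table) {
  need <- c("subject", "session", "value")
  if (!all(need %in% names(table))) {
    abort("`table` must have subject, session and value columns.",
          class = "ffa_parameter_error")
  }
  if (dplyr::n_distinct(table$subject) < 3) {
    abort("At least 3 subjects are required.", class = "ffa_parameter_error")
  }
  table$session <- factor(table$session, levels = c("AM", "PM"))
  two_way <- "group" %in% names(table) && dplyr::n_distinct(table$group) > 1
  form <- if (two_way) {
    value ~ session * group + (1 | subject)
  } else {
    value ~ session + (1 | subject)
  }
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(form, data = table, REML = TRUE)
  ))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    inform("Singular mixed-effects fit (no between-subject variance); falling back to fixed-effects model.")
    fixed_form <- if (two_way) value ~ session * group else value ~ session
    lmfit <- stats::lm(fixed_form, data = table)
    sm <- summary(lmfit)$coefficients
    fixed <- tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                            std_error = sm[, 2], statistic = sm[, 3],
                            df = lmfit$df.residual, p = sm[, 4])
    fit_obj <- lmfit
  } else {
    sm <- summary(fit)$coefficients
    fixed <- tibble::tibble(term = rownames(sm), estimate = sm[, "Estimate"],
                            std_error = sm[, "Std. Error"],
                            statistic = sm[, "t value"], df = sm[, "df"],
                            p = sm[, "Pr(>|t|)"])
    fit_obj <- fit
  }
  pairwise <- NULL
  if (two_way) {
    emm <- emmeans::emmeans(fit_obj, ~ session | group)
    pw <- summary(emmeans::contrast(emm, method = "pairwise"), adjust = "sidak")
    pairwise <- tibble::as_tibble(pw)
  }
  session_estimate <- fixed$estimate[fixed$term == "sessionPM"]
  structure(list(fixed = fixed, pairwise = pairwise,
                 session_estimate = unname(session_estimate),
                 singular = singular, two_way = two_way, fit = fit_obj),
            class = "ffa_mixed")
}

#' @export
print.ffa_mixed <- function(x, ...) {
  cat(sprintf("<ffa_mixed %s%s: session (PM - AM) estimate %.4g>\n",
              if (x$two_way) "two-way" else "one-way",
              if (x$singular) ", fixed-effects fallback" else "",
              x$session_estimate))
  print(x$fixed)
  invisible(x)
}
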