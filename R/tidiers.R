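# broom-style tidiers for fitted objects.

#' Turn a result object into a tidy tibble
#'
#' Thin broom-style generics so results drop into tidy workflows without a
#' hard broom dependency.
#' @param x Object to tidy or summarise.
#' @param ... Method arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidy
#' @export
tidy.ffa_comparison <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ffa_comparison")
  tibble::as_tibble(out)
}

#' @rdname tidy
#' @export
glance.ffa_comparison <- function(x, ...) {
  tibble::tibble(
    n_comparisons = nrow(x),
    n_significant = sum(x$p < 0.05, na.rm = TRUE),
    n_significant_adj = if ("p_adj" %in% names(x)) {
      sum(x$p_adj < 0.05, na.rm = TRUE)
    } else {
      NA_integer_
    },
    tests_used = paste(sort(unique(x$test)), collapse = ",")
  )
}

#' @rdname tidy
#' @export
tidy.ffa_mixed <- function(x, ...) {
  x$fixed
}

#' @rdname tidy
#' @export
glance.ffa_mixed <- function(x, ...) {
  tibble::tibble(session_estimate = x$session_estimate,
                 singular = x$singular, two_way = x$two_way)
}
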