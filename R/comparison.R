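new_comparison <- function(method, statistic_name, statistic, p_value, n,
                           groups = NULL, note = NULL) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(
    list(method = method, statistic_name = statistic_name,
         statistic = statistic, p_value = p_value, n = n, groups = groups,
         note = note),
    class = "memic_comparison"
  )
}

#' @export
print.memic_comparison <- function(x, ...) {
  cat(sprintf("<%s>\n  %s = %.6g, p = %.4g\n  n = %s\n", x$method,
              x$statistic_name, x$statistic, x$p_value,
              paste(sprintf("%s: %d", names(x$n), x$n), collapse = ", ")))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Tidy a comparison result
#'
#' @param x A `memic_comparison`.
#' @param ... Unused.
#' @return A one-row tibble with `method`, `statistic`, `p_value` and the
#'   group sample sizes.
#' @method tidy memic_comparison
#' @export
tidy.memic_comparison <- function(x, ...) {
  out <- tibble::tibble(method = x$method, statistic = x$statistic,
                        p_value = x$p_value)
  for (nm in names(x$n)) out[[paste0("n_", nm)]] <- x$n[[nm]]
  out
}

#' @rdname tidy.memic_comparison
#' @method glance memic_comparison
#' @export
glance.memic_comparison <- function(x, ...) tidy.memic_comparison(x)
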