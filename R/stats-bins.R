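# Student (or Welch) two-sample t-test robust to degenerate inputs:
# identical samples give t = 0, p = 1; zero variance with different means
# gives p = 0.
two_sample_t <- function(x, y, welch = FALSE) {
  if (length(x) == length(y) && all(sort(x) == sort(y))) {
    return(list(statistic = 0, df = length(x) + length(y) - 2, p_value = 1))
  }
  if (sd(x) == 0 && sd(y) == 0) {
    return(list(statistic = Inf * sign(mean(x) - mean(y)),
                df = length(x) + length(y) - 2, p_value = 0))
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Per-bin t-tests against the first bin
#'
#' For a binned positive-fraction profile with replicates, tests each
#' distance bin's replicate fractions against the first (most proximal)
#' bin's by a two-sided unpaired Student's t-test.  The first bin compared
#' against itself is reported with `t = 0`, `p = 1`.  No multiple-testing
#' correction is applied by default; set `p_adjust = "holm"` to add one.
#'
#' @param profiles A `memic_binned` from [binned_fraction()] with at least
#'   2 replicates, or any data frame with `replicate`, `bin_lo`, `bin_hi`
#'   and `fraction` columns.
#' @param welch Use the Welch (unequal-variance) t statistic instead of
#'   Student's.
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return A tibble with one row per bin: `bin_lo`, `bin_hi`, `n_rep`,
#'   `mean_fraction`, `statistic`, `df`, `p_value`.
#' @export
bins_vs_first_bin <- function(profiles, welch = FALSE,
                              p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  need <- c("replicate", "bin_lo", "bin_hi", "fraction")
  if (!all(need %in% names(profiles))) {
    abort(paste0("`profiles` needs columns: ", paste(need, collapse = ", ")))
  }
  if (length(unique(profiles$replicate)) < 2L) {
    abort("need at least 2 replicates")
  }
  bins <- profiles |>
    dplyr::distinct(.data$bin_lo, .data$bin_hi) |>
    dplyr::arrange(.data$bin_lo)
  frac_by_bin <- purrr::map(bins$bin_lo, function(lo) {
    profiles$fraction[profiles$bin_lo == lo]
  })
  n_rep <- vapply(frac_by_bin, length, integer(1))
  usable <- n_rep >= 2L
  if (!usable[1]) {
    abort("first bin has fewer than 2 replicate fractions")
  }
  first <- frac_by_bin[[1]]

  out <- purrr::map_dfr(which(usable), function(i) {
    res <- if (i == 1L) {
      list(statistic = 0, df = 2 * length(first) - 2, p_value = 1)
    } else {
      two_sample_t(frac_by_bin[[i]], first, welch = welch)
    }
    tibble::tibble(bin_lo = bins$bin_lo[i], bin_hi = bins$bin_hi[i],
                   n_rep = n_rep[i],
                   mean_fraction = mean(frac_by_bin[[i]]),
                   statistic = res$statistic, df = res$df,
                   p_value = res$p_value)
  })
  if (p_adjust == "holm") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "holm")
  }
  out
}
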