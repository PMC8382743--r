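#' One-way ANOVA on replicate half-max positions
#'
#' Compares the half-maximal gradient positions of several treatment groups
#' (each with replicate chambers) by a fixed-effects one-way ANOVA.
#' Replicates with an undefined half-max (no gradient; `NA`/`NaN`/`Inf`)
#' are dropped and counted; a group reduced below 2 replicates is an error.
#' When every group mean is identical (zero between-group variance) the
#' test degenerates to `F = 0`, `p = 1` by convention.
#'
#' @param groups Either a named list mapping group label to a numeric
#'   vector of replicate half-max positions (um), or a data frame with
#'   columns `group` and `half_max_um`.
#' @return A `memic_comparison` with the F statistic, p-value and per-group
#'   replicate counts; `n_excluded` non-finite replicates are noted.
#' @export
#' @examples
#' compare_half_max(list(narrow = c(900, 950, 980),
#'                       wide = c(930, 960, 940)))
compare_half_max <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("group", "half_max_um") %in% names(groups))) {
      abort("data frame input needs columns `group` and `half_max_um`")
    }
    groups <- split(groups$half_max_um, groups$group)
  }
  if (length(groups) < 2L) abort("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    abort("groups must be named")
  }
  n_excluded <- sum(vapply(groups, function(g) sum(!is.finite(g)),
                           integer(1)))
  groups <- purrr::map(groups, function(g) g[is.finite(g)])
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L)) {
    abort(sprintf("group '%s' has fewer than 2 finite replicates",
                  names(groups)[which(sizes < 2L)[1]]))
  }

  dat <- tibble::tibble(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), sizes))
  )
  grand <- mean(dat$value)
  ssb <- sum(sizes * (vapply(groups, mean, numeric(1)) - grand)^2)
  if (ssb <= .Machine$double.eps * sum(dat$value^2 + 1)) {
    fstat <- 0; p <- 1
  } else {
    a <- stats::anova(stats::lm(value ~ group, data = dat))
    fstat <- a[["F value"]][1]
    p <- a[["Pr(>F)"]][1]
  }
  new_comparison(
    method = "one-way ANOVA on half-max positions",
    statistic_name = "F", statistic = fstat, p_value = p,
    n = sizes, groups = names(groups),
    note = if (n_excluded > 0) {
      sprintf("%d replicate(s) with undefined half-max excluded", n_excluded)
    }
  )
}
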