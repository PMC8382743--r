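# Two-sided Wilcoxon rank-sum (Mann-Whitney) test.  For groups of at most
# `exact_max` observations each the permutation distribution of the rank sum
# is enumerated exhaustively (midranks, so ties are handled exactly); larger
# groups use the tie-corrected normal approximation with continuity
# correction.  The rank-sum distribution under the permutation null is
# symmetric about n1 (N + 1) / 2, so the two-sided p-value is the
# probability of a rank sum at least as far from that centre.
rank_sum_test <- function(x, y, exact_max = 10L) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (n1 < 2L || n2 < 2L) abort("need at least 2 observations per group")
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  U <- R1 - n1 * (n1 + 1) / 2

  if (n1 <= exact_max && n2 <= exact_max) {
    combos <- combn(N, n1)
    sums <- colSums(matrix(r[combos], nrow = n1))
    p <- mean(abs(sums - mu) >= abs(R1 - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      # all values identical: no evidence either way
      p <- 1
    } else {
      dev <- abs(R1 - mu)
      z <- max(dev - 0.5, 0) / sqrt(sigma2) # continuity correction
      p <- min(1, 2 * pnorm(-z))
    }
    method <- "normal approximation"
  }
  list(statistic = U, p_value = p, method = method)
}

#' Proximal-versus-distal rank-sum test
#'
#' Compares a per-cell value between the cells nearest the chamber opening
#' and the cells deepest inside it: the `n_each` smallest-distance cells
#' against the `n_each` largest-distance cells, by a two-sided Wilcoxon
#' rank-sum (Mann-Whitney) test.  The default group size of 10,000 cells
#' matches the scale of full-chamber image cytometry; when the table holds
#' fewer than `2 * n_each` cells the group size is clamped to half the table
#' with a warning.  Small groups (at most 10 each) are tested by exact
#' enumeration of the permutation distribution, larger ones by the
#' tie-corrected normal approximation.
#'
#' @param table Cell table with `distance_um` assigned.
#' @param value Name of the value column.
#' @param n_each Cells per group (default 10,000).
#' @param include_outside Include cells flagged outside the chamber.
#' @return A `memic_comparison` (see [tidy.memic_comparison()]).
#' @export
proximal_distal_test <- function(table, value, n_each = 10000L,
                                 include_outside = FALSE) {
  if (!value %in% names(table)) abort(paste0("column not found: ", value))
  if (!"distance_um" %in% names(table)) {
    abort("distances not assigned; run assign_distance() first")
  }
  dat <- table
  if (!include_outside && "outside_chamber" %in% names(dat)) {
    dat <- dat[!dat$outside_chamber, , drop = FALSE]
  }
  dat <- dat[!is.na(dat$distance_um) & !is.na(dat[[value]]), , drop = FALSE]
  N <- nrow(dat)
  if (n_each > floor(N / 2)) {
    n_each <- floor(N / 2)
    warn(sprintf("table has %d cells; clamping group size to %d", N, n_each))
  }
  if (n_each < 2L) abort("fewer than 2 cells per group")

  ord <- order(dat$distance_um)
  proximal <- dat[[value]][ord[seq_len(n_each)]]
  distal <- dat[[value]][ord[seq(N - n_each + 1L, N)]]
  res <- rank_sum_test(proximal, distal)
  new_comparison(
    method = paste0("proximal-distal rank-sum test (", res$method, ")"),
    statistic_name = "U", statistic = res$statistic, p_value = res$p_value,
    n = c(proximal = as.integer(n_each), distal = as.integer(n_each)),
    groups = c("proximal", "distal")
  )
}
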