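# Thomas algorithm for a tridiagonal system; a = sub-, b = main,
# c = super-diagonal.
solve_tridiag <- function(a, b, d, rhs) {
  n <- length(b)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- d[1] / b[1]
  dp[1] <- rhs[1] / b[1]
  for (i in 2:n) {
    m <- b[i] - a[i] * cp[i - 1]
    cp[i] <- d[i] / m
    dp[i] <- (rhs[i] - a[i] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

sim_grid <- function(spec) {
  n <- as.integer(round(spec$length_um / spec$dx_um)) + 1L
  list(x = seq(0, spec$length_um, length.out = n), n = n)
}

# Michaelis-Menten utilisation u(c); Km = 0 gives zeroth-order consumption
# switched off where the medium is exhausted.
utilisation <- function(conc, Km, floor_tol) {
  if (Km > 0) conc / (conc + Km) else as.numeric(conc > floor_tol)
}

#' Steady-state concentration profile
#'
#' Solves the diffusion-consumption balance
#' `D c'' = (rho q / h) u(c)` with `c(0) = c0` and `c'(L) = 0` on a uniform
#' grid.  For `Km > 0` (Michaelis-Menten utilisation) a Picard iteration
#' is used: the utilisation is linearised about the current iterate and
#' the tridiagonal system solved exactly until the sup-norm update falls
#' below `tol`.  For `Km = 0` the problem is a linear complementarity
#' (obstacle) problem -- zeroth-order consumption wherever medium remains,
#' exactly zero concentration and zero flux beyond the anoxic front -- and
#' is solved by a primal active-set method: the anoxic front index is
#' adjusted until the solution is non-negative and no exhausted node
#' receives more diffusive inflow than the cells there could consume.
#' The result matches the closed-form parabola behind [anoxic_front()].
#'
#' @param spec A [chamber_spec()].
#' @param tol Convergence tolerance on the sup-norm update, relative to
#'   the reservoir concentration (Picard branch only).
#' @param max_iter Maximum iterations.
#' @return A `memic_steady` tibble with columns `x_um` and `conc`;
#'   attributes `spec`, `anoxic_front_um` (first grid point with exhausted
#'   medium, `NA` if none), `iterations` and `residual`.
#' @export
#' @examples
#' ss <- steady_state(chamber_spec(dx_um = 50))
#' attr(ss, "anoxic_front_um")
steady_state <- function(spec, tol = 1e-12, max_iter = 1000L) {
  stopifnot(inherits(spec, "chamber_spec"))
  g <- sim_grid(spec)
  n <- g$n
  c0 <- spec$reservoir_concentration
  D <- spec$diffusivity
  dx <- spec$dx_um
  rate <- spec$cell_density * spec$per_cell_consumption /
    spec$medium_height_um # volumetric consumption (conc/s)

  if (rate == 0) {
    out <- tibble::tibble(x_um = g$x, conc = rep(c0, n))
    return(new_memic_steady(out, spec, iterations = 0L, residual = 0))
  }

  if (spec$Km > 0) {
    # Picard: D c'' = rate * c / (c_prev + Km), solved exactly each sweep
    conc <- rep(c0, n)
    iter <- 0L
    res <- Inf
    while (iter < max_iter && res > tol * c0) {
      iter <- iter + 1L
      k <- rate / (conc + spec$Km)
      a <- rep(D / dx^2, n); b <- -2 * D / dx^2 - k; d <- rep(D / dx^2, n)
      rhs <- rep(0, n)
      a[1] <- 0; b[1] <- 1; d[1] <- 0; rhs[1] <- c0 # Dirichlet
      a[n] <- 2 * D / dx^2                          # Neumann mirror
      newc <- solve_tridiag(a, b, d, rhs)
      res <- max(abs(newc - conc))
      conc <- newc
    }
    if (res > tol * c0) {
      warn(sprintf("steady state not fully converged: residual %.3g after %d iterations",
                   res, iter))
    }
    out <- tibble::tibble(x_um = g$x, conc = conc)
    return(new_memic_steady(out, spec, iterations = iter, residual = res))
  }

  # Km = 0: active-set solve of the obstacle problem.  `front` is the first
  # exhausted node (n + 1 when medium lasts to the sealed wall).
  front <- n + 1L
  iter <- 0L
  conc <- rep(c0, n)
  repeat {
    iter <- iter + 1L
    if (iter > max_iter + n) abort("active-set iteration failed to terminate")
    m <- min(front - 1L, n) # unknown nodes 1..m
    a <- rep(D / dx^2, m); b <- rep(-2 * D / dx^2, m); d <- rep(D / dx^2, m)
    rhs <- rep(rate, m)
    a[1] <- 0; b[1] <- 1; d[1] <- 0; rhs[1] <- c0
    if (front > n) {
      a[m] <- 2 * D / dx^2; d[m] <- 0 # Neumann at the sealed wall
    } else {
      d[m] <- 0 # neighbour front node fixed at zero
    }
    sol <- solve_tridiag(a, b, d, rhs)
    neg <- which(sol <= 0)
    if (length(neg)) {
      front <- neg[1] # shrink the oxygenated region
      next
    }
    conc <- c(sol, rep(0, n - m))
    if (front <= n && D * sol[m] / dx^2 > rate) {
      # the exhausted node just past the front would receive more inflow
      # than its cells consume: the front lies further in
      front <- front + 1L
      next
    }
    break
  }
  act <- seq(2, min(front - 1L, n - 1L))
  residual <- max(abs(D * (conc[act - 1L] - 2 * conc[act] + conc[act + 1L]) /
                        dx^2 - rate))
  out <- tibble::tibble(x_um = g$x, conc = conc)
  new_memic_steady(out, spec, iterations = iter, residual = residual)
}

new_memic_steady <- function(tbl, spec, iterations, residual) {
  front_idx <- which(tbl$conc <= 1e-6 * spec$reservoir_concentration)
  attr(tbl, "spec") <- spec
  attr(tbl, "anoxic_front_um") <-
    if (length(front_idx)) tbl$x_um[front_idx[1]] else NA_real_
  attr(tbl, "iterations") <- iterations
  attr(tbl, "residual") <- residual
  class(tbl) <- c("memic_steady", class(tbl))
  tbl
}

#' Time course of gradient formation
#'
#' Integrates `dc/dt = D c_xx - (rho q / h) u(c)` from a uniformly
#' nutrient-rich initial state `c(x, 0) = c0`, with the reservoir clamping
#' `c(0, t) = c0` and zero flux at the sealed wall.  The default
#' Crank-Nicolson scheme is unconditionally stable; the explicit scheme
#' (kept for cross-checking) enforces `D dt / dx^2 <= 0.5`.  In the
#' implicit scheme the consumption term is linearised as
#' `k(c_m) c_{m+1}` with `k = rate * u(c_m) / c_m`, which keeps the update
#' positivity-preserving without clamping chatter at the anoxic front;
#' concentrations therefore stay in `[0, c0]` and decrease monotonically
#' in time at every position.
#'
#' @param spec A [chamber_spec()]; `duration_s`, `dt_s` and `scheme` control
#'   the integration.
#' @param save_every_s Interval (s) between saved frames (default 3600,
#'   i.e. hourly); the initial state and the final time are always saved.
#' @return A `memic_timecourse`: list with `x_um`, `times_s`, and `conc`
#'   (matrix, grid points x saved times).
#' @export
time_course <- function(spec, save_every_s = 3600) {
  stopifnot(inherits(spec, "chamber_spec"))
  g <- sim_grid(spec)
  n <- g$n
  c0 <- spec$reservoir_concentration
  D <- spec$diffusivity
  dx <- spec$dx_um
  dt <- spec$dt_s
  rate <- spec$cell_density * spec$per_cell_consumption /
    spec$medium_height_um
  floor_tol <- 1e-9 * c0
  n_steps <- as.integer(ceiling(spec$duration_s / dt))
  save_stride <- max(1L, as.integer(round(save_every_s / dt)))

  lam <- D * dt / dx^2
  theta <- if (spec$scheme == "crank-nicolson") 0.5 else 0
  delta <- 1e-12 * c0 # guard for the k = rate*u/c linearisation

  conc <- rep(c0, n)
  saved <- list(conc)
  times <- 0
  for (m in seq_len(n_steps)) {
    u <- utilisation(conc, spec$Km, floor_tol)
    # explicit part (1 - theta) * lam * L c^m
    lap <- c(0, conc[1:(n - 2)] - 2 * conc[2:(n - 1)] + conc[3:n],
             2 * (conc[n - 1] - conc[n]))
    if (theta > 0) {
      k <- rate * u / pmax(conc, delta)
      al <- rep(-theta * lam, n)
      bl <- 1 + 2 * theta * lam + dt * k
      dl <- rep(-theta * lam, n)
      al[1] <- 0; bl[1] <- 1; dl[1] <- 0
      al[n] <- -2 * theta * lam
      rhs <- conc + (1 - theta) * lam * lap
      rhs[1] <- c0
      conc <- solve_tridiag(al, bl, dl, rhs)
    } else {
      conc <- conc + lam * lap - dt * rate * u
      conc[1] <- c0
    }
    conc <- pmin(pmax(conc, 0), c0)
    if (m %% save_stride == 0L || m == n_steps) {
      saved <- c(saved, list(conc))
      times <- c(times, m * dt)
    }
  }
  structure(
    list(x_um = g$x, times_s = times,
         conc = matrix(unlist(saved), nrow = n,
                       dimnames = list(NULL, paste0("t", times))),
         spec = spec),
    class = "memic_timecourse"
  )
}

#' @export
print.memic_timecourse <- function(x, ...) {
  cat(sprintf("<memic_timecourse> %d grid points x %d frames (0 to %g h)\n",
              length(x$x_um), length(x$times_s),
              max(x$times_s) / 3600))
  invisible(x)
}

#' Tidy a simulated time course
#'
#' @param x A `memic_timecourse`.
#' @param ... Unused.
#' @return A long tibble: `x_um`, `time_s`, `time_h`, `conc` (and
#'   `signal` if a reporter has been applied).
#' @method tidy memic_timecourse
#' @export
tidy.memic_timecourse <- function(x, ...) {
  out <- tidyr::expand_grid(time_s = x$times_s, x_um = x$x_um)
  out <- dplyr::arrange(out, .data$time_s, .data$x_um)
  out$conc <- as.vector(x$conc)
  out$time_h <- out$time_s / 3600
  if (!is.null(x$signal)) out$signal <- as.vector(x$signal)
  dplyr::relocate(out, "x_um", "time_s", "time_h", "conc")
}
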