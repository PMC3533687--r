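#' Parameters of the dyad-state replication-dilution model
#'
#' `p_m` is the maintenance efficiency: the probability that the
#' daughter strand opposite a methylated template is remethylated after
#' replication. `p_d` is the de novo rate per unmethylated dyad copy per
#' division, and `p_a` the active-removal rate per methylated cytosine
#' per division (applied after replication/maintenance).
#'
#' @param p_m,p_d,p_a probabilities in \[0, 1\]
#' @return list of class `dyad_params`
#' @export
dyad_params <- function(p_m = 0, p_d = 0, p_a = 0) {
  for (p in c(p_m, p_d, p_a)) {
    if (length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      stop("all rates must be single probabilities in [0, 1]")
    }
  }
  structure(list(p_m = p_m, p_d = p_d, p_a = p_a), class = "dyad_params")
}

.check_dist <- function(dist) {
  stopifnot(length(dist) == 3, all(dist >= 0))
  if (abs(sum(dist) - 1) > 1e-9) stop("dyad-state fractions must sum to 1")
  setNames(as.numeric(dist), c("M", "H", "U"))
}

#' One replication division of the dyad-state distribution
#'
#' Population expectation over both daughters of every dyad. An `M`
#' (fully methylated) dyad hands each daughter a methylated template:
#' the daughter is `M` with probability `p_m`, else hemimethylated `H`.
#' An `H` dyad's methylated-strand daughter behaves likewise, while the
#' unmethylated-strand daughter is `H` with probability `p_d`, else `U`;
#' a `U` dyad's daughters gain a methyl group (`H`) with probability
#' `p_d`. Active removal then strips each methylated cytosine
#' independently with probability `p_a` (`M -> H` at `2 p_a (1 - p_a)`,
#' `M -> U` at `p_a^2`, `H -> U` at `p_a`).
#'
#' @param dist fractions over (M, H, U), summing to 1
#' @param params a [dyad_params()]
#' @return named fractions over (M, H, U) after one division
#' @export
dilution_step <- function(dist, params) {
  dist <- .check_dist(dist)
  stopifnot(inherits(params, "dyad_params"))
  p_m <- params$p_m; p_d <- params$p_d; p_a <- params$p_a
  # replication + maintenance/de novo, expectation over both daughters
  m1 <- dist[["M"]] * p_m + dist[["H"]] * p_m / 2
  h1 <- dist[["M"]] * (1 - p_m) +
    dist[["H"]] * ((1 - p_m) / 2 + p_d / 2) +
    dist[["U"]] * p_d
  u1 <- dist[["H"]] * (1 - p_d) / 2 + dist[["U"]] * (1 - p_d)
  # active removal per methylated cytosine
  m2 <- m1 * (1 - p_a)^2
  h2 <- m1 * 2 * p_a * (1 - p_a) + h1 * (1 - p_a)
  u2 <- m1 * p_a^2 + h1 * p_a + u1
  out <- c(M = m2, H = h2, U = u2)
  out / sum(out)
}

#' Iterate the dilution model over successive divisions
#'
#' @param initial fractions over (M, H, U)
#' @param params a [dyad_params()]
#' @param n_steps number of divisions (>= 0)
#' @return (n_steps + 1) x 3 matrix of distributions; row 1 is the
#'   initial distribution unchanged
#' @export
dilution_trajectory <- function(initial, params, n_steps) {
  stopifnot(n_steps >= 0)
  dist <- .check_dist(initial)
  out <- matrix(NA_real_, n_steps + 1, 3,
                dimnames = list(step = 0:n_steps, c("M", "H", "U")))
  out[1, ] <- dist
  if (n_steps > 0) {
    for (s in seq_len(n_steps)) {
      dist <- dilution_step(dist, params)
      out[s + 1, ] <- dist
    }
  }
  out
}

#' Methylated-cytosine fraction of a dyad-state distribution
#'
#' `f = f_M + f_H / 2`: both cytosines of an M dyad and one of an H dyad
#' are methylated.
#'
#' @param dist fractions over (M, H, U)
#' @return scalar fraction
#' @export
methylated_fraction <- function(dist) {
  dist <- .check_dist(dist)
  dist[["M"]] + dist[["H"]] / 2
}

# Unchecked scalar version of dilution_step for tight fitting loops;
# must stay in lockstep with dilution_step (a test enforces agreement).
.step_fast <- function(m, h, u, p_m, p_d, p_a) {
  m1 <- m * p_m + h * p_m / 2
  h1 <- m * (1 - p_m) + h * ((1 - p_m) / 2 + p_d / 2) + u * p_d
  u1 <- h * (1 - p_d) / 2 + u * (1 - p_d)
  m2 <- m1 * (1 - p_a)^2
  h2 <- m1 * 2 * p_a * (1 - p_a) + h1 * (1 - p_a)
  u2 <- m1 * p_a^2 + h1 * p_a + u1
  s <- m2 + h2 + u2
  c(m2 / s, h2 / s, u2 / s)
}

# Multinomial log-likelihood of observed counts at timepoints 2..T given
# the model prediction from the first timepoint's empirical distribution.
.dilution_loglik <- function(params, counts, divisions, initial) {
  ll <- 0
  d <- c(initial[[1]], initial[[2]], initial[[3]])
  for (t in seq_along(divisions)) {
    for (s in seq_len(divisions[t])) {
      d <- .step_fast(d[1], d[2], d[3], params$p_m, params$p_d, params$p_a)
    }
    p <- pmax(d, 1e-12)
    p <- p / sum(p)
    cnt <- counts[t + 1, ]
    n <- sum(cnt)
    ll <- ll + lgamma(n + 1) - sum(lgamma(cnt + 1)) + sum(cnt * log(p))
  }
  ll
}

#' Fit dilution-model parameters to dyad-state counts over time
#'
#' Maximizes the multinomial log-likelihood of observed (M, H, U) counts
#' at successive timepoints under the model trajectory started from the
#' first timepoint's empirical distribution. A coarse grid search over
#' `(p_m, p_d, p_a)` seeds a box-constrained (L-BFGS-B) local
#' refinement. The returned profile slice scans `p_m` with the other
#' rates held at their estimates.
#'
#' @param counts integer matrix, timepoints x 3 (columns M, H, U)
#' @param divisions divisions between successive timepoints (length
#'   `nrow(counts) - 1`)
#' @param grid_step coarse grid spacing for each rate
#' @param refine run the local refinement (default TRUE)
#' @param profile_step spacing of the `p_m` profile slice
#' @return list: params ([dyad_params()]), loglik, pm_profile
#'   (data.frame p_m/loglik), convergence
#' @export
fit_dilution <- function(counts, divisions, grid_step = 0.05,
                         refine = TRUE, profile_step = 0.02) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L) {
    stop("at least two timepoints are required to fit the model")
  }
  if (ncol(counts) != 3L) stop("counts must have columns (M, H, U)")
  if (any(rowSums(counts) == 0)) {
    stop("degenerate counts: a timepoint has zero observations")
  }
  stopifnot(length(divisions) == nrow(counts) - 1L, all(divisions >= 1))
  initial <- counts[1, ] / sum(counts[1, ])

  grid <- seq(0, 1, by = grid_step)
  best <- list(ll = -Inf, par = c(0, 0, 0))
  # per-p_m profile over the coarse grid; the likelihood can be sharply
  # peaked in p_m at large counts, so refinement is multi-started from
  # the best (p_d, p_a) of every leading p_m slice rather than from the
  # single best grid point
  slice_best <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    pm <- grid[i]
    sb <- list(ll = -Inf, par = c(pm, 0, 0))
    for (pd in grid) for (pa in grid) {
      ll <- .dilution_loglik(dyad_params(pm, pd, pa), counts, divisions,
                             initial)
      if (ll > sb$ll) sb <- list(ll = ll, par = c(pm, pd, pa))
    }
    slice_best[[i]] <- sb
    if (sb$ll > best$ll) best <- sb
  }
  convergence <- NA_integer_
  if (refine) {
    obj <- function(par) {
      par <- pmin(pmax(par, 0), 1)  # finite-difference steps at the box edge
      -.dilution_loglik(dyad_params(par[1], par[2], par[3]), counts,
                        divisions, initial)
    }
    lls <- vapply(slice_best, `[[`, 0, "ll")
    starts <- slice_best[order(lls, decreasing = TRUE)[seq_len(min(8,
                                                                   length(lls)))]]
    for (st in starts) {
      opt <- optim(st$par, obj, method = "L-BFGS-B", lower = 0, upper = 1)
      if (-opt$value > best$ll) {
        best <- list(ll = -opt$value, par = pmin(pmax(opt$par, 0), 1))
        convergence <- opt$convergence
      }
    }
  }
  pm_grid <- seq(0, 1, by = profile_step)
  prof <- vapply(pm_grid, function(pm) {
    .dilution_loglik(dyad_params(pm, best$par[2], best$par[3]), counts,
                     divisions, initial)
  }, 0)
  list(params = dyad_params(best$par[1], best$par[2], best$par[3]),
       loglik = best$ll,
       pm_profile = data.frame(p_m = pm_grid, loglik = prof),
       convergence = convergence)
}

#' Simulate multinomial dyad-state counts along a model trajectory
#'
#' Convenience generator for parameter-recovery studies: runs the
#' deterministic trajectory and draws multinomial counts at each
#' observed timepoint.
#'
#' @param initial fractions over (M, H, U)
#' @param params a [dyad_params()]
#' @param divisions divisions between successive observations
#' @param n_dyads dyads sampled per timepoint
#' @param seed integer seed
#' @return integer matrix (length(divisions) + 1) x 3
#' @export
simulate_dyad_counts <- function(initial, params, divisions,
                                 n_dyads = 10000L, seed = 1L) {
  set.seed(seed)
  dist <- .check_dist(initial)
  out <- matrix(0L, length(divisions) + 1, 3,
                dimnames = list(NULL, c("M", "H", "U")))
  out[1, ] <- as.integer(rmultinom(1, n_dyads, dist))
  for (t in seq_along(divisions)) {
    for (s in seq_len(divisions[t])) dist <- dilution_step(dist, params)
    out[t + 1, ] <- as.integer(rmultinom(1, n_dyads, dist))
  }
  out
}
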