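#' Simulate hairpin bisulfite reads under passive/active demethylation
#'
#' Each read is one molecule with `n_positions` CpG dyads (default 5, the
#' number of CG dinucleotides in the LINE1Tf hairpin amplicon). Dyads are
#' fully methylated (`M`) with probability `p_full`, hemimethylated with
#' probability `p_hemi`, otherwise unmethylated (`U`); positions drop out
#' as missing (`.`) with probability `p_missing`. Hemimethylated dyads
#' carry their methylated C on the top (`T`) or bottom (`B`) strand:
#'
#' * `passive` — one template strand per molecule (top/bottom with equal
#'   probability); every hemimethylated dyad's meC sits on that strand,
#'   as expected when the new strand is never maintained after
#'   replication.
#' * `active` — each hemimethylated dyad picks its strand independently
#'   with probability 0.5, as expected for strand-agnostic removal.
#' * `mixed` — a per-dyad switching probability `switch_prob`
#'   interpolates: each dyad keeps the molecule's template strand with
#'   probability `1 - switch_prob`, else redraws at random
#'   (`switch_prob = 1` reproduces `active`, `0` reproduces `passive`).
#'
#' @param n_reads number of molecules (> 0)
#' @param n_positions CpG dyads per molecule (>= 1)
#' @param mechanism `"passive"`, `"active"` or `"mixed"`
#' @param params list with `p_hemi`, `p_full`, `p_missing`,
#'   `switch_prob`
#' @param seed integer seed
#' @return character matrix of class `hairpin_reads`
#'   (`n_reads x n_positions`) over `{M, T, B, U, .}`
#' @export
simulate_hairpin_reads <- function(n_reads, n_positions = 5L,
                                   mechanism = c("passive", "active",
                                                 "mixed"),
                                   params = list(), seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (length(n_reads) != 1L || is.na(n_reads) || n_reads <= 0) {
    stop("n_reads must be a positive integer")
  }
  stopifnot(n_positions >= 1L)
  p <- utils::modifyList(list(p_hemi = 0.3, p_full = 0.05, p_missing = 0,
                              switch_prob = 0.5), params)
  stopifnot(p$p_hemi >= 0, p$p_full >= 0, p$p_hemi + p$p_full <= 1,
            p$p_missing >= 0, p$p_missing <= 1,
            p$switch_prob >= 0, p$switch_prob <= 1)
  set.seed(seed)
  n_reads <- as.integer(n_reads)
  n_positions <- as.integer(n_positions)

  u <- matrix(runif(n_reads * n_positions), n_reads, n_positions)
  state <- matrix("U", n_reads, n_positions)
  state[u < p$p_full] <- "M"
  hemi <- u >= p$p_full & u < p$p_full + p$p_hemi

  template <- sample(c("T", "B"), n_reads, replace = TRUE)
  strand <- matrix(template, n_reads, n_positions)
  switch_p <- switch(mechanism, passive = 0, active = 1, mixed = p$switch_prob)
  if (switch_p > 0) {
    redraw <- matrix(runif(n_reads * n_positions) < switch_p,
                     n_reads, n_positions)
    rnd <- matrix(sample(c("T", "B"), n_reads * n_positions, replace = TRUE),
                  n_reads, n_positions)
    strand[redraw] <- rnd[redraw]
  }
  state[hemi] <- strand[hemi]
  if (p$p_missing > 0) {
    state[matrix(runif(n_reads * n_positions) < p$p_missing,
                 n_reads, n_positions)] <- "."
  }
  rownames(state) <- sprintf("read_%06d", seq_len(n_reads))
  structure(state, class = c("hairpin_reads", class(state)))
}
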