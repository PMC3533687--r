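#' Sample sheet for the expression time course
#'
#' One RNA sample per stage (mixed-sex through E11.5, sexed at E13.5 and
#' E16.5), mirroring one pooled library per time point.
#'
#' @return data.frame with columns sample, stage, sex
#' @export
expression_samples <- function() {
  data.frame(
    sample = c("E6.5", "E9.5", "E10.5", "E11.5", "E13.5_male",
               "E13.5_female", "E16.5_male", "E16.5_female"),
    stage = c("E6.5", "E9.5", "E10.5", "E11.5", "E13.5", "E13.5",
              "E16.5", "E16.5"),
    sex = c("mixed", "mixed", "mixed", "mixed", "male", "female",
            "male", "female"),
    stringsAsFactors = FALSE
  )
}

#' Default planted expression clusters
#'
#' Two planted clusters on a log2 scale over the default sample sheet: a
#' pluripotency-network-like cluster peaking at E11.5 with a steep
#' decline toward E16.5, and a meiosis-network-like cluster rising from
#' E13.5 with female E13.5/E16.5 samples highest.
#'
#' @param samples sample sheet from [expression_samples()]
#' @param n_genes genes per planted cluster
#' @return named list of cluster specs (`n`, `trajectory` in log2 units)
#' @export
default_cluster_spec <- function(samples = expression_samples(),
                                 n_genes = 30L) {
  traj_pluri <- c(4, 6, 7, 8, 5, 5, 2, 2)
  traj_meio <- c(1, 1, 1.5, 2, 5, 8, 5, 9)
  names(traj_pluri) <- names(traj_meio) <- samples$sample
  list(
    pluripotency = list(n = n_genes, trajectory = traj_pluri),
    meiosis = list(n = n_genes, trajectory = traj_meio)
  )
}

#' Simulate a gene-by-sample expression matrix with planted clusters
#'
#' In-cluster genes follow their cluster's log2 trajectory plus Gaussian
#' noise; background genes get an uncorrelated per-gene baseline (a flat
#' profile plus noise), a fraction of which are fully silent (0).
#' Expression values are `2^x` of the log2 profiles, so they are strictly
#' positive except for silent genes. Background complexity is held
#' constant across samples. A gene-body methylation vector for the E16.5
#' male sample, positively coupled to that sample's expression, is
#' attached for methylation-expression correlation demos.
#'
#' @param samples sample sheet from [expression_samples()]
#' @param cluster_spec list as from [default_cluster_spec()]
#' @param n_background number of uncorrelated background genes
#' @param noise_sd per-gene Gaussian noise on the log2 scale
#' @param silent_fraction fraction of background genes with zero
#'   expression everywhere
#' @param seed integer seed
#' @return list of class `expression_sim`: `expr` (gene x sample
#'   matrix), `labels` (named cluster membership, `"background"` for
#'   unplanted genes), `samples`, `gene_body_meth` (percent, for the
#'   E16.5 male sample)
#' @export
simulate_expression <- function(samples = expression_samples(),
                                cluster_spec = default_cluster_spec(samples),
                                n_background = 1940L, noise_sd = 0.5,
                                silent_fraction = 0.05, seed = 1L) {
  stopifnot(length(cluster_spec) >= 2, n_background >= 0, noise_sd >= 0)
  ns <- nrow(samples)
  for (cl in names(cluster_spec)) {
    if (length(cluster_spec[[cl]]$trajectory) != ns) {
      stop("trajectory length for cluster '", cl,
           "' does not match the number of samples (", ns, ")")
    }
  }
  set.seed(seed)
  rows <- list()
  labels <- character()
  for (cl in names(cluster_spec)) {
    spec <- cluster_spec[[cl]]
    lg <- matrix(rep(spec$trajectory, each = spec$n), spec$n, ns) +
      matrix(rnorm(spec$n * ns, sd = noise_sd), spec$n, ns)
    rows[[cl]] <- 2^lg
    labels <- c(labels, rep(cl, spec$n))
  }
  if (n_background > 0) {
    base <- runif(n_background, 0, 8)
    lg <- matrix(base, n_background, ns) +
      matrix(rnorm(n_background * ns, sd = max(noise_sd, 0.25)),
             n_background, ns)
    bg <- 2^lg
    n_sil <- round(silent_fraction * n_background)
    if (n_sil > 0) bg[seq_len(n_sil), ] <- 0
    rows[["background"]] <- bg
    labels <- c(labels, rep("background", n_background))
  }
  expr <- do.call(rbind, rows)
  rownames(expr) <- sprintf("gene_%05d", seq_len(nrow(expr)))
  colnames(expr) <- samples$sample
  names(labels) <- rownames(expr)

  # gene-body methylation restored by E16.5 de novo activity in males,
  # positively coupled to transcription
  e16m <- expr[, samples$sample[samples$stage == "E16.5" &
                                  samples$sex == "male"][1]]
  gbm <- 20 + 6 * log2(e16m + 1) + rnorm(length(e16m), sd = 5)
  gbm <- pmin(pmax(gbm, 0), 100)
  names(gbm) <- rownames(expr)

  structure(list(expr = expr, labels = labels, samples = samples,
                 gene_body_meth = gbm),
            class = "expression_sim")
}

#' Simulate per-target RNA-seq read tallies for repeat consensus targets
#'
#' Produces read counts mapped to the LINE1Tf and LINE1A consensus
#' sequences and to two constantly expressed single-copy comparator
#' genes, plus per-sample totals. The female E16.5 sample carries a
#' LINE1-specific transcriptional burst.
#'
#' @param samples sample sheet from [expression_samples()]
#' @param total_reads sequencing depth per sample
#' @param base_fraction named baseline read fractions per target
#' @param burst_factor LINE1 fold-change in female E16.5
#' @param seed integer seed
#' @return list: `counts` (target x sample matrix), `totals` (per-sample
#'   read totals), `targets` (repeat targets), `comparators`
#' @export
simulate_repeat_counts <- function(samples = expression_samples(),
                                   total_reads = 1e6,
                                   base_fraction = c(LINE1Tf = 0.001,
                                                     LINE1A = 0.0005,
                                                     Cnpy3 = 0.0002,
                                                     Pdia5 = 0.0002),
                                   burst_factor = 8, seed = 1L) {
  set.seed(seed)
  ns <- nrow(samples)
  frac <- matrix(base_fraction, length(base_fraction), ns,
                 dimnames = list(names(base_fraction), samples$sample))
  burst_col <- samples$stage == "E16.5" & samples$sex == "female"
  frac[c("LINE1Tf", "LINE1A"), burst_col] <-
    frac[c("LINE1Tf", "LINE1A"), burst_col] * burst_factor
  counts <- matrix(rpois(length(frac), frac * total_reads),
                   nrow(frac), ns, dimnames = dimnames(frac))
  list(counts = counts,
       totals = setNames(rep(total_reads, ns), samples$sample),
       targets = c("LINE1Tf", "LINE1A"),
       comparators = c("Cnpy3", "Pdia5"))
}
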