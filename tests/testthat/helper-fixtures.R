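# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

small_genome_config <- function(seed = 7L, ...) {
  synthetic_genome_config(
    chrom_lengths = c(chr1 = 9e5, chr2 = 6e5, chrX = 4e5),
    n_features = c(CGI = 30, CGI_X = 10, DMR_maternal = 8,
                   DMR_paternal = 5, germline_promoter = 8, promoter = 20,
                   promoter_nonCGI = 20, VEC = 8, IAP = 12, LINE1 = 15,
                   exon = 10, intron = 10),
    seed = seed, ...)
}

# default mixed-sex time course at 20x, cached
small_sim <- function() {
  if (is.null(.fixtures$sim)) {
    ann <- generate_annotation(small_genome_config())
    .fixtures$sim <- simulate_methylome(
      ann, default_stage_specs(coverage = 20), seed = 3L)
  }
  .fixtures$sim
}

small_feature_stage_medians <- function() {
  if (is.null(.fixtures$sm)) {
    sim <- small_sim()
    fm <- feature_methylation(sim, sim$annotation)
    .fixtures$sm <- stage_medians(fm)
  }
  .fixtures$sm
}

# Build a call table by hand (one row per site).
make_calls <- function(chrom, pos, meth, unmeth, strand = "+",
                       context = "CG") {
  data.table::data.table(chrom = chrom, pos = pos, strand = strand,
                         context = context, count_methylated = meth,
                         count_unmethylated = unmeth)
}

# Minimal meth_matrix for classifier tests: a percentage matrix whose
# columns are stage keys.
make_stage_matrix <- function(pct) {
  structure(list(pct = pct,
                 total = matrix(1000, nrow(pct), ncol(pct),
                                dimnames = dimnames(pct)),
                 rows = data.frame(id = rownames(pct),
                                   stringsAsFactors = FALSE),
                 n_cpg = setNames(rep(10L, nrow(pct)), rownames(pct)),
                 samples = data.frame(sample = colnames(pct),
                                      stringsAsFactors = FALSE),
                 context = "CG", min_total = 10),
            class = "meth_matrix")
}

# Independent per-CpG summation oracle for probe/feature methylation
# (plain loops, no interval machinery).
oracle_interval_pct <- function(calls, intervals, min_total) {
  out <- rep(NA_real_, nrow(intervals))
  dy <- ifelse(calls$strand == "-" & calls$context == "CG",
               calls$pos - 1, calls$pos)
  for (i in seq_len(nrow(intervals))) {
    sel <- calls$chrom == intervals$chrom[i] &
      dy >= intervals$start[i] & dy < intervals$end[i] &
      calls$context == "CG"
    m <- sum(calls$count_methylated[sel])
    u <- sum(calls$count_unmethylated[sel])
    if (m + u >= min_total && m + u > 0) out[i] <- 100 * m / (m + u)
  }
  out
}

# Explicit 3x3 stochastic-matrix oracle for the dilution step.
oracle_dilution_step <- function(dist, p_m, p_d, p_a) {
  R <- rbind(
    M = c(p_m, 1 - p_m, 0),
    H = c(p_m / 2, (1 - p_m) / 2 + p_d / 2, (1 - p_d) / 2),
    U = c(0, p_d, 1 - p_d)
  )
  A <- rbind(
    M = c((1 - p_a)^2, 2 * p_a * (1 - p_a), p_a^2),
    H = c(0, 1 - p_a, p_a),
    U = c(0, 0, 1)
  )
  colnames(R) <- colnames(A) <- c("M", "H", "U")
  v <- as.numeric(dist) %*% R %*% A
  setNames(as.numeric(v / sum(v)), c("M", "H", "U"))
}
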