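# Normalize the calls argument: accepts a methylome_sim or a named list
# of call tables; returns list(calls = <named list>, samples = <df>)
.as_call_set <- function(calls, samples = NULL) {
  if (inherits(calls, "methylome_sim")) {
    return(list(calls = calls$calls, samples = calls$samples))
  }
  if (is.data.frame(calls)) calls <- list(sample = as.data.table(calls))
  if (!is.list(calls) || is.null(names(calls))) {
    stop("calls must be a methylome_sim or a named list of call tables")
  }
  if (is.null(samples)) {
    samples <- data.frame(sample = names(calls), stringsAsFactors = FALSE)
  }
  list(calls = lapply(calls, as.data.table), samples = samples)
}

# Collapse bottom-strand CG calls onto the dyad position (the C on the
# top strand); CHH calls keep their own position.
.dyad_positions <- function(dt, ctx) {
  if (ctx == "CG") ifelse(dt$strand == "-", dt$pos - 1, dt$pos) else dt$pos
}

# Sum methylated/unmethylated counts of contained cytosines per interval
# for every sample. Both strands of a dyad count toward the interval
# containing the dyad position. Returns a meth_matrix.
.aggregate_meth <- function(cs, intervals, min_total, ctx) {
  stopifnot(all(c("chrom", "start", "end", "id") %in% names(intervals)))
  if (nrow(intervals) == 0L) stop("interval set is empty")
  gr_int <- GRanges(intervals$chrom,
                    IRanges(intervals$start + 1, intervals$end))
  n <- nrow(intervals)
  samples <- cs$samples$sample
  pct <- total <- matrix(NA_real_, n, length(samples),
                         dimnames = list(intervals$id, samples))
  covered <- vector("list", length(samples))
  for (k in seq_along(samples)) {
    dt <- cs$calls[[samples[k]]]
    dt <- dt[context == ctx]
    if (nrow(dt) == 0L) {
      total[, k] <- 0
      next
    }
    dy <- .dyad_positions(dt, ctx)
    gr <- GRanges(dt$chrom, IRanges(dy + 1, dy + 1))
    hits <- findOverlaps(gr, gr_int)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    agg <- data.table(row = sh, meth = dt$count_methylated[qh],
                      unmeth = dt$count_unmethylated[qh], dyad = dy[qh])
    res <- agg[, .(meth = sum(meth), unmeth = sum(unmeth),
                   n_cpg = uniqueN(dyad)), by = row]
    tot <- res$meth + res$unmeth
    total[, k] <- 0
    total[res$row, k] <- tot
    ok <- tot >= min_total & tot > 0
    pct[res$row[ok], k] <- 100 * res$meth[ok] / tot[ok]
    covered[[k]] <- res[, c("row", "n_cpg")]
  }
  cov_all <- rbindlist(covered)
  n_cpg <- integer(n)
  if (nrow(cov_all)) {
    mx <- cov_all[, .(n_cpg = max(n_cpg)), by = row]
    n_cpg[mx$row] <- mx$n_cpg
  }
  structure(list(pct = pct, total = total, rows = intervals,
                 n_cpg = setNames(n_cpg, intervals$id),
                 samples = cs$samples, context = ctx,
                 min_total = min_total),
            class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat("meth_matrix:", nrow(x$pct), "rows x", ncol(x$pct), "samples (",
      x$context, "context, min total count", x$min_total, ")\n")
  cat(sum(is.na(x$pct)), "missing cells\n")
  invisible(x)
}

#' Tile chromosomes into abutting fixed-width probes
#'
#' Non-overlapping windows cover each chromosome completely; the last
#' partial window is kept. Coordinates are 0-based half-open.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp)
#' @param window_bp window width (>= 1)
#' @return data.frame: chrom, start, end, id
#' @export
tile_genome <- function(chrom_lengths, window_bp) {
  stopifnot(window_bp >= 1, all(chrom_lengths > 0))
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = window_bp)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_bp, len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  out
}

#' Weighted methylation percentage per tiling probe
#'
#' Per probe, percentage = 100 * sum(methylated) / sum(total) over the
#' CpG calls it contains (read-count "weighted" definition). Probes with
#' total informative count below `min_total_count` are flagged missing
#' (NA), never reported as 0.
#'
#' @param calls a [simulate_methylome()] result or named list of call
#'   tables (CG context is used)
#' @param probes data.frame from [tile_genome()] (or any interval table
#'   with chrom/start/end/id)
#' @param min_total_count minimum summed count for a defined percentage
#' @param samples optional sample sheet when `calls` is a plain list
#' @return a `meth_matrix`
#' @export
probe_methylation <- function(calls, probes, min_total_count = 10,
                              samples = NULL) {
  cs <- .as_call_set(calls, samples)
  .aggregate_meth(cs, probes, min_total_count, "CG")
}

#' Weighted methylation percentage per annotated feature
#'
#' As [probe_methylation()], keyed by feature id; both strand calls of a
#' dyad count toward the feature containing the dyad.
#'
#' @param calls calls as in [probe_methylation()]
#' @param features a `feature_set` or a data.frame with
#'   chrom/start/end/id/class
#' @param min_total_count minimum summed count for a defined percentage
#' @param samples optional sample sheet
#' @return a `meth_matrix` whose `rows` carry the feature class
#' @export
feature_methylation <- function(calls, features, min_total_count = 10,
                                samples = NULL) {
  if (inherits(features, "feature_set")) features <- features$features
  cs <- .as_call_set(calls, samples)
  .aggregate_meth(cs, features, min_total_count, "CG")
}

#' Global methylation level per sample and per-stage replicate medians
#'
#' The per-sample global level is the unweighted mean (or median) of the
#' non-missing probe percentages; the per-stage summary is the median
#' across replicates of the same stage/sex.
#'
#' @param mat a `meth_matrix`
#' @param stat `"mean"` (default) or `"median"` across probes
#' @return list: `per_sample` (sample, value, n_used), `per_stage`
#'   (stage key, value) when stage metadata is present
#' @export
global_summary <- function(mat, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  stopifnot(inherits(mat, "meth_matrix"), nrow(mat$pct) > 0)
  fn <- if (stat == "mean") mean else median
  value <- vapply(seq_len(ncol(mat$pct)), function(k) {
    v <- mat$pct[, k]
    v <- v[!is.na(v)]
    if (!length(v)) {
      stop("all probes missing for sample '", colnames(mat$pct)[k], "'")
    }
    fn(v)
  }, 0)
  per_sample <- data.frame(sample = colnames(mat$pct), value = value,
                           n_used = colSums(!is.na(mat$pct)),
                           stringsAsFactors = FALSE, row.names = NULL)
  out <- list(per_sample = per_sample)
  sm <- mat$samples
  if (!is.null(sm$stage)) {
    key <- stage_key(sm$stage, sm$sex)
    med <- tapply(per_sample$value, key, median)
    out$per_stage <- data.frame(stage = names(med), value = as.numeric(med),
                                stringsAsFactors = FALSE, row.names = NULL)
  }
  out
}

#' Percentiles of the probe methylation distribution per sample
#'
#' @param mat a `meth_matrix`
#' @param percentiles percentile grid (0-100)
#' @return matrix samples x percentiles
#' @export
methylation_distribution <- function(mat, percentiles = seq(0, 100, 10)) {
  stopifnot(inherits(mat, "meth_matrix"),
            all(percentiles >= 0 & percentiles <= 100))
  t(vapply(seq_len(ncol(mat$pct)), function(k) {
    v <- mat$pct[, k]
    if (all(is.na(v))) stop("no non-missing probes for sample '",
                            colnames(mat$pct)[k], "'")
    quantile(v, probs = percentiles / 100, na.rm = TRUE, names = FALSE)
  }, numeric(length(percentiles)))) |>
    (\(m) {
      dimnames(m) <- list(colnames(mat$pct), paste0("p", percentiles))
      m
    })()
}

#' Bisulfite conversion efficiency from CHH calls over 1 kb probes
#'
#' A probe counts as "100% converted" iff its summed methylated CHH
#' count is 0 and its total CHH count reaches `min_total_count`; the
#' per-sample efficiency is the fraction of such probes among qualifying
#' probes.
#'
#' @param calls calls containing CHH context rows
#' @param chrom_lengths named chromosome lengths used to build the
#'   tiling (ignored when `probes` is given)
#' @param window_bp probe width, default 1000
#' @param min_total_count minimum CHH observations for a probe to
#'   qualify (default 20)
#' @param probes optional explicit probe table
#' @param samples optional sample sheet
#' @return list: `fraction` (named per-sample fraction of fully
#'   converted probes), `per_probe` (the CHH `meth_matrix`)
#' @export
conversion_efficiency <- function(calls, chrom_lengths = NULL,
                                  window_bp = 1000, min_total_count = 20,
                                  probes = NULL, samples = NULL) {
  cs <- .as_call_set(calls, samples)
  if (is.null(probes)) {
    if (is.null(chrom_lengths) && inherits(calls, "methylome_sim")) {
      chrom_lengths <- calls$annotation$chrom_lengths
    }
    if (is.null(chrom_lengths)) {
      stop("either probes or chrom_lengths must be supplied")
    }
    probes <- tile_genome(chrom_lengths, window_bp)
  }
  mm <- .aggregate_meth(cs, probes, min_total_count, "CHH")
  frac <- vapply(seq_len(ncol(mm$total)), function(k) {
    qualifying <- mm$total[, k] >= min_total_count
    if (!any(qualifying)) {
      stop("no probes with at least ", min_total_count,
           " CHH observations for sample '", colnames(mm$total)[k], "'")
    }
    meth_frac <- mm$pct[qualifying, k]
    mean(meth_frac == 0)
  }, 0)
  names(frac) <- colnames(mm$total)
  list(fraction = frac, per_probe = mm)
}

#' Correlation between probe CpG density and methylation level
#'
#' Pearson (product-moment) correlation, per sample, between the number
#' of distinct CpG dyads covered in a probe and its methylation
#' percentage. Zero variance in either variable yields an undefined
#' flag, not an error.
#'
#' @param mat a `meth_matrix` from [probe_methylation()]
#' @return data.frame: sample, r, defined
#' @export
cg_density_correlation <- function(mat) {
  stopifnot(inherits(mat, "meth_matrix"))
  res <- lapply(seq_len(ncol(mat$pct)), function(k) {
    v <- mat$pct[, k]
    ok <- !is.na(v)
    x <- mat$n_cpg[ok]
    y <- v[ok]
    if (sum(ok) < 3 || sd(x) == 0 || sd(y) == 0) {
      data.frame(sample = colnames(mat$pct)[k], r = NA_real_,
                 defined = FALSE, stringsAsFactors = FALSE)
    } else {
      data.frame(sample = colnames(mat$pct)[k], r = cor(x, y),
                 defined = TRUE, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, res)
}

#' Collapse replicate columns to per-stage medians
#'
#' Classification operates on per-stage replicate medians, matching the
#' median lines drawn through replicate points in global summaries.
#' Cells missing in every replicate stay missing.
#'
#' @param mat a `meth_matrix` whose sample sheet has stage/sex/replicate
#' @return a `meth_matrix` with one column per stage/sex key
#' @export
stage_medians <- function(mat) {
  stopifnot(inherits(mat, "meth_matrix"))
  sm <- mat$samples
  if (is.null(sm$stage)) stop("sample sheet lacks stage metadata")
  key <- stage_key(sm$stage, sm$sex)
  ukeys <- unique(key)
  pct <- matrix(NA_real_, nrow(mat$pct), length(ukeys),
                dimnames = list(rownames(mat$pct), ukeys))
  total <- matrix(0, nrow(mat$pct), length(ukeys),
                  dimnames = list(rownames(mat$pct), ukeys))
  for (u in ukeys) {
    cols <- which(key == u)
    sub <- mat$pct[, cols, drop = FALSE]
    med <- apply(sub, 1, median, na.rm = TRUE)
    med[!is.finite(med)] <- NA_real_
    pct[, u] <- med
    total[, u] <- rowSums(mat$total[, cols, drop = FALSE])
  }
  samples <- data.frame(sample = ukeys,
                        stage = sm$stage[match(ukeys, key)],
                        sex = sm$sex[match(ukeys, key)],
                        stringsAsFactors = FALSE)
  structure(list(pct = pct, total = total, rows = mat$rows,
                 n_cpg = mat$n_cpg, samples = samples,
                 context = mat$context, min_total = mat$min_total),
            class = "meth_matrix")
}
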