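# Pull one stage/sex column from a stage-median meth_matrix, with an
# informative error when absent.
.stage_column <- function(mat, key) {
  if (!key %in% colnames(mat$pct)) {
    stop("stage column '", key, "' absent from the methylation matrix")
  }
  mat$pct[, key]
}

#' Select late-demethylating features (>threshold at every early stage)
#'
#' A feature is selected iff its methylation strictly exceeds the
#' threshold at every rule stage (default: all mixed-sex time points
#' E6.5 through E11.5, i.e. prior to E13.5). Features missing at any
#' rule stage are excluded from selection and reported separately.
#'
#' @param mat a per-stage `meth_matrix` (see [stage_medians()])
#' @param threshold percent methylation cutoff (strict `>`)
#' @param stages stage keys the rule must hold at
#' @return list: `selected` (feature ids), `excluded_missing` (ids
#'   undetermined because of missing values)
#' @export
select_late_demethylaters <- function(mat, threshold = 25,
                                      stages = c("E6.5", "E9.5", "E10.5",
                                                 "E11.5")) {
  stopifnot(inherits(mat, "meth_matrix"), threshold >= 0, threshold <= 100,
            length(stages) >= 1)
  sub <- vapply(stages, function(s) .stage_column(mat, s),
                numeric(nrow(mat$pct)))
  sub <- matrix(sub, nrow = nrow(mat$pct),
                dimnames = list(rownames(mat$pct), stages))
  missing_any <- apply(is.na(sub), 1, any)
  pass <- !missing_any & apply(sub > threshold, 1, all)
  list(selected = rownames(sub)[pass],
       excluded_missing = rownames(sub)[missing_any])
}

#' Select demethylation-resistant features at E13.5 per sex
#'
#' Selection on the single E13.5 value for the given sex, strict `>`.
#'
#' @param mat a per-stage `meth_matrix`
#' @param sex `"male"` or `"female"`
#' @param stage stage label (default `"E13.5"`)
#' @param threshold percent methylation cutoff
#' @return list as in [select_late_demethylaters()]
#' @export
select_resistant <- function(mat, sex = c("male", "female"),
                             stage = "E13.5", threshold = 25) {
  sex <- match.arg(sex)
  key <- if (stage %in% colnames(mat$pct)) stage else stage_key(stage, sex)
  select_late_demethylaters(mat, threshold = threshold, stages = key)
}

#' Annotate features with edge-to-edge distance to the nearest IAP
#'
#' Distance is the minimum gap in bp to any IAP interval (0 when
#' overlapping); a feature is IAP-proximal iff its distance is strictly
#' below the cutoff. With no IAPs the distance is reported as `Inf` and
#' nothing is proximal.
#'
#' @param features feature table (data.frame with chrom/start/end/id) or
#'   a `feature_set` (whose IAP class rows supply `iaps` by default)
#' @param iaps IAP interval table; defaults to the `IAP` class rows of
#'   `features`
#' @param cutoff proximity cutoff in bp (strict `<`), default 2000
#' @return data.frame: id, iap_dist, proximal
#' @export
annotate_iap_proximity <- function(features, iaps = NULL, cutoff = 2000) {
  if (inherits(features, "feature_set")) features <- features$features
  if (is.null(iaps)) iaps <- features[features$class == "IAP", , drop = FALSE]
  query <- if (is.null(features$class)) {
    features
  } else {
    features[features$class != "IAP", , drop = FALSE]
  }
  out <- data.frame(id = query$id, iap_dist = Inf, proximal = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(iaps) == 0L || nrow(query) == 0L) return(out)
  gr_q <- GRanges(query$chrom, IRanges(query$start + 1, query$end))
  gr_i <- GRanges(iaps$chrom, IRanges(iaps$start + 1, iaps$end))
  near <- distanceToNearest(gr_q, gr_i)
  qh <- S4Vectors::queryHits(near)
  out$iap_dist[qh] <- S4Vectors::mcols(near)$distance
  out$proximal <- out$iap_dist < cutoff
  out
}

#' Resistant fraction as a function of distance to the nearest IAP
#'
#' Bins features by IAP distance and reports the fraction passing the
#' E13.5 resistance rule per bin; empty bins are omitted.
#'
#' @param mat a per-stage `meth_matrix` covering the features
#' @param proximity result of [annotate_iap_proximity()]
#' @param breaks distance bin edges in bp (left-closed, right-open;
#'   values beyond the last edge are dropped)
#' @param sex sex for the resistance rule
#' @param threshold resistance threshold (percent)
#' @return data.frame: bin_start, bin_end, n, resistant_fraction
#' @export
resistance_vs_distance <- function(mat, proximity,
                                   breaks = seq(0, 4000, by = 500),
                                   sex = "male", threshold = 25) {
  res <- select_resistant(mat, sex = sex, threshold = threshold)
  sel <- proximity$id %in% res$selected
  bin <- findInterval(proximity$iap_dist, breaks,
                      rightmost.closed = FALSE)
  keep <- bin >= 1 & bin < length(breaks) & is.finite(proximity$iap_dist)
  if (!any(keep)) {
    return(data.frame(bin_start = numeric(), bin_end = numeric(),
                      n = integer(), resistant_fraction = numeric()))
  }
  tab <- data.table(bin = bin[keep], resistant = sel[keep])
  agg <- tab[, .(n = .N, resistant_fraction = mean(resistant)), by = bin]
  setorder(agg, bin)
  data.frame(bin_start = breaks[agg$bin], bin_end = breaks[agg$bin + 1],
             n = agg$n, resistant_fraction = agg$resistant_fraction)
}

#' Identify variably erased CGIs (VECs)
#'
#' A VEC is resistant at E13.5 in at least one sex and not IAP-proximal.
#' The per-feature variability summary reports the range of methylation
#' across all stage columns and a sex-bias sign: +1 for features
#' resistant in male only (male-biased escape), -1 for female only, 0
#' for both sexes.
#'
#' @param resistant_male,resistant_female id sets from
#'   [select_resistant()] (their `selected` component, or the lists)
#' @param proximity result of [annotate_iap_proximity()]
#' @param mat per-stage `meth_matrix` for the variability summary
#' @return data.frame: id, sex_bias, meth_range, resistant_male,
#'   resistant_female
#' @export
identify_vecs <- function(resistant_male, resistant_female, proximity,
                          mat = NULL) {
  if (is.list(resistant_male)) resistant_male <- resistant_male$selected
  if (is.list(resistant_female)) resistant_female <- resistant_female$selected
  ids <- union(resistant_male, resistant_female)
  proximal <- proximity$id[proximity$proximal]
  ids <- setdiff(ids, proximal)
  rm <- ids %in% resistant_male
  rf <- ids %in% resistant_female
  out <- data.frame(id = ids,
                    sex_bias = ifelse(rm & !rf, 1L, ifelse(rf & !rm, -1L, 0L)),
                    resistant_male = rm, resistant_female = rf,
                    meth_range = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(mat) && nrow(out)) {
    rng <- apply(mat$pct[out$id, , drop = FALSE], 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) diff(range(v)) else NA_real_
    })
    out$meth_range <- as.numeric(rng)
  }
  out
}

# Weighted methylation over an arbitrary region per sample.
.region_methylation <- function(cs, chrom, start, end, min_total) {
  if (end <= start) {
    return(setNames(rep(NA_real_, length(cs$samples$sample)),
                    cs$samples$sample))
  }
  iv <- data.frame(chrom = chrom, start = start, end = end, id = "region",
                   stringsAsFactors = FALSE)
  mm <- .aggregate_meth(cs, iv, min_total, "CG")
  setNames(mm$pct[1, ], colnames(mm$pct))
}

#' CGI core versus flank methylation profile
#'
#' Computes the weighted methylation of a CGI interval ("core") and of
#' its two pooled flanks separately, per sample, together with the
#' core-minus-flank difference. Flanks are clipped at chromosome ends; a
#' flank without covered CpGs is missing.
#'
#' @param calls calls as in [probe_methylation()]
#' @param cgi one feature row (data.frame with chrom/start/end)
#' @param flank_bp flank width each side (default 2000)
#' @param chrom_lengths named lengths for clipping (taken from a
#'   `methylome_sim` when available)
#' @param min_total_count minimum count per part
#' @param samples optional sample sheet
#' @return data.frame: sample, core, flank, difference
#' @export
core_vs_flank_profile <- function(calls, cgi, flank_bp = 2000,
                                  chrom_lengths = NULL,
                                  min_total_count = 10, samples = NULL) {
  stopifnot(flank_bp > 0, nrow(cgi) == 1)
  if (is.null(chrom_lengths) && inherits(calls, "methylome_sim")) {
    chrom_lengths <- calls$annotation$chrom_lengths
  }
  cs <- .as_call_set(calls, samples)
  chrom_len <- if (!is.null(chrom_lengths)) chrom_lengths[[cgi$chrom]] else Inf
  core <- .region_methylation(cs, cgi$chrom, cgi$start, cgi$end,
                              min_total_count)
  # pooled flanks: aggregate both flank intervals as one unit
  fl <- data.frame(chrom = cgi$chrom,
                   start = c(max(0, cgi$start - flank_bp), cgi$end),
                   end = c(cgi$start, min(chrom_len, cgi$end + flank_bp)),
                   id = "flank", stringsAsFactors = FALSE)
  fl <- fl[fl$end > fl$start, , drop = FALSE]
  flank <- if (nrow(fl)) {
    mm <- .aggregate_meth(cs, data.frame(chrom = fl$chrom[1],
                                         start = fl$start, end = fl$end,
                                         id = paste0("flank", seq_len(nrow(fl))),
                                         stringsAsFactors = FALSE),
                          min_total = 0, "CG")
    # pool the two flank parts by counts
    meth <- colSums(mm$total * mm$pct / 100, na.rm = TRUE)
    tot <- colSums(mm$total)
    v <- ifelse(tot >= min_total_count & tot > 0, 100 * meth / tot, NA_real_)
    setNames(v, colnames(mm$pct))
  } else {
    setNames(rep(NA_real_, length(cs$samples$sample)), cs$samples$sample)
  }
  data.frame(sample = names(core), core = as.numeric(core),
             flank = as.numeric(flank),
             difference = as.numeric(core) - as.numeric(flank),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Overlap enrichment of a selected set for site-bearing features
#'
#' Enrichment ratio = (hit fraction among selected) / (hit fraction
#' among background), with a hypergeometric upper-tail probability for
#' observing at least as many hits in the selection by chance.
#'
#' @param selected ids of the selected features (must be a subset of
#'   `background`)
#' @param background ids of the background universe
#' @param hits ids carrying the site (e.g. a binding motif)
#' @return list: ratio, p_value, k (hits in selection), n_selected,
#'   K (hits in background), N (background size), defined
#' @export
overlap_enrichment <- function(selected, background, hits) {
  if (!all(selected %in% background)) {
    stop("selected must be a subset of background")
  }
  N <- length(unique(background))
  n <- length(unique(selected))
  K <- length(intersect(unique(background), unique(hits)))
  k <- length(intersect(unique(selected), unique(hits)))
  if (K == 0L) {
    return(list(ratio = NA_real_, p_value = NA_real_, k = k,
                n_selected = n, K = K, N = N, defined = FALSE))
  }
  ratio <- (k / n) / (K / N)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(ratio = ratio, p_value = p, k = k, n_selected = n, K = K, N = N,
       defined = TRUE)
}
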