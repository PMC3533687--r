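# Accept an expression_sim or a plain matrix
.as_expr_matrix <- function(expr) {
  if (inherits(expr, "expression_sim")) expr$expr else as.matrix(expr)
}

#' Expression-complexity profile per sample
#'
#' Counts genes per sample falling into log-scaled expression bands.
#' Zero-expression genes are tallied in a separate `silent` band; the
#' remaining bands are delimited by `band_edges` on the expression scale
#' (left-open, right-closed on the log scale; the first band starts just
#' above 0 and the last is unbounded above).
#'
#' @param expr expression matrix (genes x samples) or `expression_sim`
#' @param band_edges increasing positive edges; the default `c(4, 64)`
#'   yields broad low / intermediate / high bands
#' @return data.frame: sample then one count column per band
#' @export
complexity_profile <- function(expr, band_edges = c(4, 64)) {
  expr <- .as_expr_matrix(expr)
  stopifnot(all(band_edges > 0), !is.unsorted(band_edges, strictly = TRUE))
  edges <- c(0, band_edges, Inf)
  labels <- if (length(band_edges) == 2) {
    c("silent", "low", "intermediate", "high")
  } else {
    c("silent", paste0("band_", seq_len(length(band_edges) + 1)))
  }
  counts <- vapply(seq_len(ncol(expr)), function(k) {
    x <- expr[, k]
    silent <- sum(x == 0)
    inner <- table(cut(x[x > 0], breaks = edges, right = TRUE))
    c(silent, as.integer(inner))
  }, integer(length(band_edges) + 2))
  out <- data.frame(sample = colnames(expr), t(counts),
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[-1] <- labels
  out
}

#' Cluster genes by time-course profile similarity
#'
#' Per-gene log2 profiles are standardized to zero mean and unit
#' variance across samples; average-linkage hierarchical clustering on
#' correlation distance (1 - r) is cut at `1 - similarity`, and clusters
#' below `min_size` are discarded. Genes with constant profiles cannot
#' be standardized and are excluded with a report. Cluster ids are
#' deterministic: ordered by decreasing size, ties broken by the lowest
#' member gene id.
#'
#' @param expr expression matrix (genes x samples) or `expression_sim`
#' @param min_size smallest reported cluster (>= 2)
#' @param similarity profile correlation threshold in (0, 1)
#' @return list of class `profile_clusters`: `clusters` (list of
#'   data.frames id/members/profile), `assignment` (named integer, 0 =
#'   unclustered), `excluded_constant` (gene ids)
#' @export
cluster_profiles <- function(expr, min_size = 5L, similarity = 0.7) {
  expr <- .as_expr_matrix(expr)
  if (ncol(expr) < 2L) stop("at least two samples are required")
  stopifnot(min_size >= 2L, similarity > 0, similarity < 1)
  lg <- log2(expr + 1)
  sds <- apply(lg, 1, sd)
  constant <- sds == 0 | is.na(sds)
  excluded <- rownames(lg)[constant]
  lg <- lg[!constant, , drop = FALSE]
  assignment <- setNames(integer(nrow(expr)), rownames(expr))
  clusters <- list()
  if (nrow(lg) >= 2L) {
    z <- t(scale(t(lg)))
    d <- as.dist(1 - cor(t(z)))
    hc <- hclust(d, method = "average")
    cut <- cutree(hc, h = 1 - similarity)
    sizes <- table(cut)
    keep <- as.integer(names(sizes)[sizes >= min_size])
    if (length(keep)) {
      info <- lapply(keep, function(k) {
        members <- sort(names(cut)[cut == k])
        list(members = members, size = length(members),
             first = members[1])
      })
      ord <- order(-vapply(info, `[[`, 0L, "size"),
                   vapply(info, `[[`, "", "first"))
      info <- info[ord]
      for (i in seq_along(info)) {
        members <- info[[i]]$members
        assignment[members] <- i
        prof <- colMeans(z[members, , drop = FALSE])
        clusters[[i]] <- list(id = i, members = members,
                              profile = prof,
                              dispersion = apply(z[members, , drop = FALSE],
                                                 2, sd))
      }
    }
  }
  structure(list(clusters = clusters, assignment = assignment,
                 excluded_constant = excluded),
            class = "profile_clusters")
}

#' @export
print.profile_clusters <- function(x, ...) {
  cat("profile_clusters:", length(x$clusters), "clusters;",
      sum(x$assignment > 0), "genes assigned,",
      length(x$excluded_constant), "constant genes excluded\n")
  invisible(x)
}

#' Mean, dispersion and peak stage of a cluster's trajectory
#'
#' Per-sample mean and standard deviation of the member genes'
#' log2-expression, and the peak sample (argmax of the mean; ties break
#' to the earliest sample in column order).
#'
#' @param members gene ids of the cluster (or a cluster entry from
#'   [cluster_profiles()])
#' @param expr expression matrix or `expression_sim`
#' @return list: `summary` (data.frame sample/mean/sd), `peak` (sample
#'   name of the maximum mean)
#' @export
cluster_trajectory_summary <- function(members, expr) {
  if (is.list(members) && !is.null(members$members)) {
    members <- members$members
  }
  expr <- .as_expr_matrix(expr)
  stopifnot(length(members) >= 1, all(members %in% rownames(expr)))
  lg <- log2(expr[members, , drop = FALSE] + 1)
  mu <- colMeans(lg)
  sdv <- apply(lg, 2, function(v) if (length(v) > 1) sd(v) else 0)
  if (length(members) == 1L) sdv <- rep(0, length(mu))
  peak <- colnames(expr)[which.max(mu)]
  list(summary = data.frame(sample = colnames(expr), mean = mu, sd = sdv,
                            stringsAsFactors = FALSE, row.names = NULL),
       peak = peak)
}

#' Percentage of reads mapping to repeat-consensus targets
#'
#' @param counts target x sample read-count matrix (repeat consensus
#'   targets plus single-copy comparator genes)
#' @param totals per-sample total read counts (> 0)
#' @return matrix of percentages (targets x samples)
#' @export
repeat_expression_fraction <- function(counts, totals) {
  counts <- as.matrix(counts)
  totals <- totals[colnames(counts)]
  if (any(is.na(totals)) || any(totals <= 0)) {
    stop("every sample needs a positive total read count")
  }
  pct <- sweep(counts, 2, totals, "/") * 100
  if (any(colSums(pct) > 100 + 1e-9)) {
    stop("target counts exceed the per-sample totals")
  }
  pct
}

#' Rank correlation between gene-body methylation and expression
#'
#' Spearman correlation, robust to the heavy right tail of expression.
#'
#' @param meth per-gene gene-body methylation (percent)
#' @param expr per-gene expression for the same genes
#' @return list: rho, sign, n, defined
#' @export
methylation_expression_correlation <- function(meth, expr) {
  ok <- !is.na(meth) & !is.na(expr)
  meth <- meth[ok]; expr <- expr[ok]
  if (length(meth) < 3L) stop("at least three paired genes are required")
  if (sd(meth) == 0 || sd(expr) == 0) {
    return(list(rho = NA_real_, sign = NA_integer_, n = length(meth),
                defined = FALSE))
  }
  rho <- cor(meth, expr, method = "spearman")
  list(rho = rho, sign = sign(rho), n = length(meth), defined = TRUE)
}

#' De novo promoter methylation gain in up- versus down-regulated genes
#'
#' Splits genes by the sign of their expression change between two
#' stages and compares the mean promoter methylation gain between the
#' groups, with a two-sided permutation tail probability for the group
#' difference. Genes with no expression change belong to neither group.
#'
#' @param meth_before,meth_after per-gene promoter methylation at the
#'   two stages (percent)
#' @param expr_before,expr_after per-gene expression at the two stages
#' @param n_perm permutation count
#' @param seed integer seed for the permutation draw
#' @return list: mean_gain_up, mean_gain_down, difference, p_perm, n_up,
#'   n_down, tested (FALSE with a reason when a group is empty)
#' @export
denovo_vs_expression_change <- function(meth_before, meth_after,
                                        expr_before, expr_after,
                                        n_perm = 1000L, seed = 1L) {
  stopifnot(length(meth_before) == length(meth_after),
            length(expr_before) == length(expr_after),
            length(meth_before) == length(expr_before))
  gain <- meth_after - meth_before
  dir <- sign(expr_after - expr_before)
  up <- gain[dir > 0]
  down <- gain[dir < 0]
  res <- list(mean_gain_up = if (length(up)) mean(up) else NA_real_,
              mean_gain_down = if (length(down)) mean(down) else NA_real_,
              n_up = length(up), n_down = length(down))
  if (!length(up) || !length(down)) {
    res$difference <- NA_real_
    res$p_perm <- NA_real_
    res$tested <- FALSE
    res$reason <- "one expression-change group is empty"
    return(res)
  }
  obs <- mean(up) - mean(down)
  pool <- c(up, down)
  n_up <- length(up)
  set.seed(seed)
  perm <- replicate(n_perm, {
    idx <- sample.int(length(pool), n_up)
    mean(pool[idx]) - mean(pool[-idx])
  })
  res$difference <- obs
  res$p_perm <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  res$tested <- TRUE
  res
}
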