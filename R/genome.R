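#' Feature classes known to the annotation generator and BED reader
#'
#' `CGI` are bulk (autosomal, non-promoter) CpG islands; `CGI_X` are
#' X-linked CGIs subject to random X inactivation; `DMR_maternal` /
#' `DMR_paternal` are imprinted germline DMR cores; `germline_promoter`
#' are CGI promoters of germline-specific (meiosis/gametogenesis) genes,
#' methylated in soma; `promoter` are ordinary CGI promoters;
#' `promoter_nonCGI` are CpG-poor promoters, a subset of which sit near
#' an IAP; `VEC` are variably erased CGIs; `IAP` and `LINE1` are
#' retrotransposon copies; `exon`/`intron` are gene-body parts.
#'
#' @export
FEATURE_CLASSES <- c("CGI", "CGI_X", "DMR_maternal", "DMR_paternal",
                     "germline_promoter", "promoter", "promoter_nonCGI",
                     "VEC", "IAP", "LINE1", "exon", "intron")

# fixed feature lengths (bp) for classes without a sampled length
.FIXED_LEN <- c(DMR_maternal = 1000, DMR_paternal = 1000,
                germline_promoter = 1000, promoter = 1000,
                promoter_nonCGI = 1000, IAP = 2000, LINE1 = 1000,
                exon = 300, intron = 800)

# CpG dyad spacing (bp) per class; CGI-like classes are CpG dense
.CPG_SPACING <- c(CGI = 10, CGI_X = 10, DMR_maternal = 10, DMR_paternal = 10,
                  germline_promoter = 10, promoter = 10, VEC = 10,
                  promoter_nonCGI = 50, IAP = 20, LINE1 = 20,
                  exon = 60, intron = 60)

#' Configuration for the synthetic genome annotation
#'
#' Coordinates are 0-based half-open throughout. Features are laid out in
#' non-overlapping slots so that features never overlap one another;
#' X-linked CGIs are placed on the chromosome flagged as X, all other
#' classes on autosomes. A configurable fraction of CpG-poor promoters is
#' placed downstream of an IAP copy at a sampled edge-to-edge distance
#' (these IAPs count toward the IAP total).
#'
#' @param chrom_lengths named vector of chromosome lengths in bp; must
#'   include `x_chrom`
#' @param x_chrom name of the X chromosome
#' @param n_features named integer vector of copy numbers per feature
#'   class (see [FEATURE_CLASSES])
#' @param cgi_length length range (bp) for CGI/CGI_X/VEC features
#' @param iap_proximal_fraction fraction of `promoter_nonCGI` features
#'   paired with an IAP
#' @param iap_distance_range promoter-to-IAP edge-to-edge distance range
#'   (bp) for paired placements
#' @param slot_bp placement slot width (bp); one feature (or one
#'   IAP+promoter pair) per slot
#' @param bulk_cpg_spacing spacing of background (non-feature) CpG dyads
#' @param chh_spacing spacing of CHH sites used for conversion control
#' @param seed integer seed making the annotation deterministic
#' @return a validated config list of class `genome_config`
#' @export
synthetic_genome_config <- function(chrom_lengths = c(chr1 = 4e6, chr2 = 3e6,
                                                      chrX = 3e6),
                                    x_chrom = "chrX",
                                    n_features = c(CGI = 200, CGI_X = 40,
                                                   DMR_maternal = 20,
                                                   DMR_paternal = 15,
                                                   germline_promoter = 30,
                                                   promoter = 150,
                                                   promoter_nonCGI = 100,
                                                   VEC = 30, IAP = 60,
                                                   LINE1 = 100, exon = 100,
                                                   intron = 100),
                                    cgi_length = c(500, 2000),
                                    iap_proximal_fraction = 0.3,
                                    iap_distance_range = c(0, 3500),
                                    slot_bp = 8000,
                                    bulk_cpg_spacing = 100,
                                    chh_spacing = 50,
                                    seed = 1L) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("chrom_lengths must be a named vector")
  }
  if (any(chrom_lengths <= 0)) stop("all chromosome lengths must be > 0")
  if (!x_chrom %in% names(chrom_lengths)) {
    stop("x_chrom '", x_chrom, "' not in chrom_lengths")
  }
  full <- setNames(integer(length(FEATURE_CLASSES)), FEATURE_CLASSES)
  unknown <- setdiff(names(n_features), FEATURE_CLASSES)
  if (length(unknown)) {
    stop("unknown feature class(es): ", paste(unknown, collapse = ", "))
  }
  full[names(n_features)] <- as.integer(n_features)
  if (any(full < 0)) stop("feature counts must be non-negative")
  stopifnot(length(cgi_length) == 2, cgi_length[1] > 0,
            cgi_length[2] >= cgi_length[1],
            iap_proximal_fraction >= 0, iap_proximal_fraction <= 1,
            iap_distance_range[1] >= 0,
            iap_distance_range[2] >= iap_distance_range[1],
            slot_bp > 0, bulk_cpg_spacing >= 2, chh_spacing >= 1)
  max_pair <- .FIXED_LEN[["IAP"]] + iap_distance_range[2] +
    .FIXED_LEN[["promoter_nonCGI"]]
  if (slot_bp < max(cgi_length[2], .FIXED_LEN, max_pair)) {
    stop("slot_bp too small for the largest feature / IAP-promoter pair")
  }
  structure(list(chrom_lengths = chrom_lengths, x_chrom = x_chrom,
                 n_features = full, cgi_length = cgi_length,
                 iap_proximal_fraction = iap_proximal_fraction,
                 iap_distance_range = iap_distance_range,
                 slot_bp = slot_bp, bulk_cpg_spacing = bulk_cpg_spacing,
                 chh_spacing = chh_spacing, seed = as.integer(seed)),
            class = "genome_config")
}

# CpG dyad positions for one feature interval (position of the top-strand C)
.feature_cpgs <- function(start, end, spacing) {
  p <- seq(start + 2L, by = spacing, length.out = max(0L, (end - start - 3L) %/% spacing + 1L))
  p[p <= end - 2L]
}

#' Generate a synthetic genome annotation
#'
#' Deterministic for a fixed seed: produces non-overlapping feature
#' intervals with per-feature CpG dyad positions, background (bulk) CpG
#' dyads on a regular grid between features, and genome-wide CHH sites
#' for conversion-efficiency control.
#'
#' @param config a [synthetic_genome_config()]
#' @return object of class `feature_set`: list with `features`
#'   (data.frame: chrom, start, end, id, class, x_linked, iap_dist),
#'   `cpgs` (data.table: chrom, pos, dyn_class, feature_id), `chh`
#'   (data.table: chrom, pos), `chrom_lengths`, `x_chrom`, `config`
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "genome_config"))
  set.seed(config$seed)
  lens <- config$chrom_lengths
  nf <- config$n_features
  n_prox <- round(config$iap_proximal_fraction * nf[["promoter_nonCGI"]])
  if (nf[["IAP"]] < n_prox) {
    stop("n_features['IAP'] must be at least the number of IAP-paired ",
         "promoters (", n_prox, ")")
  }

  slot_tab <- do.call(rbind, lapply(names(lens), function(ch) {
    n_slot <- lens[[ch]] %/% config$slot_bp
    if (n_slot < 1L) return(NULL)
    data.frame(chrom = ch, slot = as.numeric(seq_len(n_slot) - 1L) * config$slot_bp,
               stringsAsFactors = FALSE)
  }))
  x_slots <- slot_tab[slot_tab$chrom == config$x_chrom, ]
  a_slots <- slot_tab[slot_tab$chrom != config$x_chrom, ]
  x_slots <- x_slots[sample.int(nrow(x_slots)), ]
  a_slots <- a_slots[sample.int(nrow(a_slots)), ]

  take_slots <- function(pool, n, class) {
    if (nrow(pool$df) < n) {
      stop("chromosomes too short to host requested features of class '",
           class, "' (need ", n, " slots, have ", nrow(pool$df), ")")
    }
    out <- pool$df[seq_len(n), , drop = FALSE]
    pool$df <- pool$df[-seq_len(n), , drop = FALSE]
    list(pool = pool, slots = out)
  }

  feat <- list()
  a_pool <- list(df = a_slots)
  x_pool <- list(df = x_slots)

  place <- function(slots, len, offset = NULL) {
    if (is.null(offset)) {
      room <- config$slot_bp - len
      offset <- floor(runif(nrow(slots), 0, room + 1))
    }
    start <- slots$slot + offset
    data.frame(chrom = slots$chrom, start = start, end = start + len,
               stringsAsFactors = FALSE)
  }

  # paired IAP + promoter_nonCGI placements
  if (n_prox > 0) {
    tk <- take_slots(a_pool, n_prox, "promoter_nonCGI")
    a_pool <- tk$pool
    iap_len <- .FIXED_LEN[["IAP"]]
    prom_len <- .FIXED_LEN[["promoter_nonCGI"]]
    d <- floor(runif(n_prox, config$iap_distance_range[1],
                     config$iap_distance_range[2] + 1))
    iap <- place(tk$slots, iap_len, offset = 0)
    prom <- data.frame(chrom = iap$chrom, start = iap$end + d,
                       end = iap$end + d + prom_len, stringsAsFactors = FALSE)
    iap$class <- "IAP"; prom$class <- "promoter_nonCGI"
    prom$iap_dist <- as.numeric(d)
    iap$iap_dist <- 0
    feat <- c(feat, list(iap, prom))
  }

  sampled_len <- function(n) {
    floor(runif(n, config$cgi_length[1], config$cgi_length[2] + 1))
  }
  singles <- c("CGI", "DMR_maternal", "DMR_paternal", "germline_promoter",
               "promoter", "promoter_nonCGI", "VEC", "IAP", "LINE1",
               "exon", "intron")
  for (cl in singles) {
    n <- nf[[cl]] - if (cl %in% c("IAP", "promoter_nonCGI")) n_prox else 0L
    if (n <= 0L) next
    tk <- take_slots(a_pool, n, cl)
    a_pool <- tk$pool
    if (cl %in% c("CGI", "VEC")) {
      len <- sampled_len(n)
      df <- do.call(rbind, lapply(seq_len(n), function(i) {
        place(tk$slots[i, , drop = FALSE], len[i])
      }))
    } else {
      df <- place(tk$slots, .FIXED_LEN[[cl]])
    }
    df$class <- cl
    df$iap_dist <- NA_real_
    feat <- c(feat, list(df))
  }
  if (nf[["CGI_X"]] > 0L) {
    tk <- take_slots(x_pool, nf[["CGI_X"]], "CGI_X")
    len <- sampled_len(nf[["CGI_X"]])
    df <- do.call(rbind, lapply(seq_len(nf[["CGI_X"]]), function(i) {
      place(tk$slots[i, , drop = FALSE], len[i])
    }))
    df$class <- "CGI_X"
    df$iap_dist <- NA_real_
    feat <- c(feat, list(df))
  }

  features <- do.call(rbind, feat)
  if (is.null(features)) {
    features <- data.frame(chrom = character(), start = numeric(),
                           end = numeric(), class = character(),
                           iap_dist = numeric(), stringsAsFactors = FALSE)
  }
  features <- features[order(features$chrom, features$start), , drop = FALSE]
  rownames(features) <- NULL
  cnt <- stats::ave(seq_len(nrow(features)), features$class, FUN = seq_along)
  features$id <- sprintf("%s_%04d", features$class, cnt)
  features$x_linked <- features$class == "CGI_X"

  # realized edge-to-edge distance to the nearest IAP (constructed pairs
  # keep their sampled distance; everything else gets Inf here and is
  # re-derived downstream by annotate_iap_proximity)
  features$iap_dist[is.na(features$iap_dist)] <- Inf

  # per-feature CpG dyads
  cpg_list <- lapply(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    p <- .feature_cpgs(f$start, f$end, .CPG_SPACING[[f$class]])
    if (!length(p)) return(NULL)
    data.table(chrom = f$chrom, pos = as.numeric(p), dyn_class = f$class,
               feature_id = f$id)
  })
  cpgs <- rbindlist(cpg_list)

  # bulk CpGs on a grid, excluding feature footprints
  bulk_list <- lapply(names(lens), function(ch) {
    p <- seq(1, lens[[ch]] - 2, by = config$bulk_cpg_spacing)
    fch <- features[features$chrom == ch, , drop = FALSE]
    if (nrow(fch)) {
      inside <- rep(FALSE, length(p))
      for (i in seq_len(nrow(fch))) {
        inside <- inside | (p >= fch$start[i] & p < fch$end[i])
      }
      p <- p[!inside]
    }
    if (!length(p)) return(NULL)
    data.table(chrom = ch, pos = as.numeric(p), dyn_class = "bulk",
               feature_id = NA_character_)
  })
  cpgs <- rbindlist(c(list(cpgs), bulk_list))
  setkey(cpgs, chrom, pos)

  chh <- rbindlist(lapply(names(lens), function(ch) {
    data.table(chrom = ch,
               pos = as.numeric(seq(3, lens[[ch]] - 1, by = config$chh_spacing)))
  }))

  structure(list(features = features, cpgs = cpgs, chh = chh,
                 chrom_lengths = lens, x_chrom = config$x_chrom,
                 config = config),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("feature_set:", nrow(x$features), "features on",
      length(x$chrom_lengths), "chromosomes;",
      nrow(x$cpgs), "CpG dyads,", nrow(x$chh), "CHH sites\n")
  print(table(x$features$class))
  invisible(x)
}
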