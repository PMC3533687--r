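#' Default two-phase demethylation dynamics profile
#'
#' Encodes the trajectory policy per feature class. Unprotected sequence
#' loses methylation passively: with maintenance methylation off, every
#' division halves the methylated fraction. Protected classes (imprinted
#' DMR cores, X-linked CGIs in cells carrying an inactive X, CGI
#' promoters of germline-specific genes) hold their level through the
#' migration phase and are erased upon gonadal entry (default erasure
#' stage E13.5). IAPs are resistant throughout; variably erased CGIs
#' (VECs) hold a per-feature, sex-biased residual level. E16.5 male
#' samples gain de novo methylation toward a target level at de
#' novo-eligible classes; no de novo gain occurs at any earlier stage.
#'
#' @param bulk_initial initial (E6.5 epiblast) methylated fraction of
#'   bulk genomic CpGs
#' @param conversion_failure bisulfite conversion-failure rate: the
#'   probability an unmethylated C reads as methylated (inflates both
#'   apparent CG and CHH methylation)
#' @param denovo_target fraction reached by de novo methylation in E16.5
#'   male germ cells
#' @param erase_stage stage at which protected classes are erased
#' @param protected_until last stage of the protection window; erasure
#'   before this is a configuration error
#' @param vec_level_range per-feature residual methylation range for VECs
#'   in the male germline
#' @param vec_female_scale multiplier on the male VEC level giving the
#'   female level (< 1: male-biased escape from erasure)
#' @param iap_protect_level,iap_protect_decay_bp IAP neighbourhood
#'   protection: a CpG-poor promoter at edge-to-edge distance d from an
#'   IAP is held at `iap_protect_level * exp(-d / iap_protect_decay_bp)`
#'   if that exceeds its passive level
#' @param class_initial named overrides of per-class initial fractions
#' @return list of class `dynamics_profile`
#' @export
default_dynamics_profile <- function(bulk_initial = 0.71,
                                     conversion_failure = 0.002,
                                     denovo_target = 0.5,
                                     erase_stage = "E13.5",
                                     protected_until = "E11.5",
                                     vec_level_range = c(0.05, 0.65),
                                     vec_female_scale = 0.6,
                                     iap_protect_level = 0.9,
                                     iap_protect_decay_bp = 1500,
                                     class_initial = NULL) {
  initial <- c(bulk = bulk_initial, CGI = 0.15, CGI_X = 0.5,
               DMR_maternal = 0.5, DMR_paternal = 0.5,
               germline_promoter = 0.8, promoter = 0.15,
               promoter_nonCGI = bulk_initial, VEC = NA_real_,
               IAP = 0.9, LINE1 = bulk_initial, exon = bulk_initial,
               intron = bulk_initial)
  if (!is.null(class_initial)) {
    bad <- setdiff(names(class_initial), names(initial))
    if (length(bad)) stop("unknown class(es) in class_initial: ",
                          paste(bad, collapse = ", "))
    initial[names(class_initial)] <- class_initial
  }
  protected <- c("CGI_X", "DMR_maternal", "DMR_paternal", "germline_promoter")
  resistant <- c("IAP", "VEC")
  denovo <- c("bulk", "promoter_nonCGI", "LINE1", "exon", "intron")
  prof <- structure(list(initial = initial,
                         protected_classes = protected,
                         resistant_classes = resistant,
                         denovo_classes = denovo,
                         protected_until = protected_until,
                         erase_stage = erase_stage,
                         conversion_failure = conversion_failure,
                         denovo_target = denovo_target,
                         vec_level_range = vec_level_range,
                         vec_female_scale = vec_female_scale,
                         iap_protect_level = iap_protect_level,
                         iap_protect_decay_bp = iap_protect_decay_bp),
                    class = "dynamics_profile")
  validate_dynamics_profile(prof)
  prof
}

validate_dynamics_profile <- function(profile) {
  fr <- c(profile$initial[!is.na(profile$initial)],
          profile$conversion_failure, profile$denovo_target,
          profile$vec_level_range, profile$vec_female_scale,
          profile$iap_protect_level)
  if (any(fr < 0 | fr > 1)) stop("all profile fractions must lie in [0, 1]")
  if (stage_index(profile$erase_stage) <= stage_index(profile$protected_until)) {
    stop("configuration error: erasure stage (", profile$erase_stage,
         ") must come after the protection window end (",
         profile$protected_until, ")")
  }
  invisible(profile)
}

#' True methylated fraction of a feature class at a stage
#'
#' The deterministic trajectory rule used by [simulate_methylome()]:
#' passive halving per division for unprotected classes, level holding
#' and scheduled erasure for protected classes, constant levels for
#' resistant classes, sex-dependent X-linked CGI levels (0 male, 0.5
#' female, 0.25 in a 50/50 mixed pool), IAP-neighbourhood protection
#' decaying with distance, and de novo gain in E16.5 males.
#'
#' @param profile a [default_dynamics_profile()]
#' @param class feature class (or `"bulk"`)
#' @param stage,sex,divisions sample stage label, sex
#'   (`"male"`/`"female"`/`"mixed"`) and cumulative divisions since E6.5
#' @param iap_dist edge-to-edge distance (bp) to the nearest IAP
#'   (relevant for `promoter_nonCGI`); `Inf` for none
#' @param vec_level per-feature male-germline VEC residual level
#' @return true methylated fraction in \[0, 1\]
#' @export
expected_class_level <- function(profile, class, stage, sex = "mixed",
                                 divisions = 0, iap_dist = Inf,
                                 vec_level = NA_real_) {
  si <- stage_index(stage)
  erased <- si >= stage_index(profile$erase_stage)
  lvl <- if (class == "VEC") {
    stopifnot(!is.na(vec_level))
    switch(sex, male = vec_level,
           female = vec_level * profile$vec_female_scale,
           mixed = vec_level * (1 + profile$vec_female_scale) / 2)
  } else if (class %in% profile$resistant_classes) {
    profile$initial[[class]]
  } else if (class == "CGI_X") {
    init <- switch(sex, male = 0, female = profile$initial[["CGI_X"]],
                   mixed = profile$initial[["CGI_X"]] / 2)
    if (erased) 0 else init
  } else if (class %in% profile$protected_classes) {
    if (erased) 0 else profile$initial[[class]]
  } else {
    profile$initial[[class]] * 2^(-divisions)
  }
  if (class == "promoter_nonCGI" && is.finite(iap_dist)) {
    lvl <- max(lvl, profile$iap_protect_level *
                 exp(-iap_dist / profile$iap_protect_decay_bp))
  }
  if (stage == "E16.5" && sex == "male" && class %in% profile$denovo_classes) {
    lvl <- max(lvl, profile$denovo_target)
  }
  lvl
}

#' Simulate per-stage bisulfite cytosine call tables
#'
#' For every sample in `stages`, each CpG dyad's true methylated fraction
#' follows [expected_class_level()] for its class; observed counts are
#' drawn independently per strand with Poisson coverage at the sample's
#' mean and binomial methylated counts at the apparent fraction
#' `m + (1 - m) * conversion_failure`. CHH sites are truly unmethylated,
#' so their apparent methylation equals the conversion-failure rate.
#' Top-strand calls are reported at the dyad position, bottom-strand
#' calls at position + 1 (the paired C on the opposite strand).
#'
#' @param annotation a [generate_annotation()] result
#' @param stages sample sheet as from [default_stage_specs()]
#' @param profile a [default_dynamics_profile()]
#' @param seed integer seed; the full output is deterministic given it
#' @param keep_chh simulate CHH context calls (needed for conversion
#'   control; can be switched off to save memory)
#' @return object of class `methylome_sim`: list with `calls` (named
#'   list of data.tables: chrom, pos, strand, context, count_methylated,
#'   count_unmethylated), `samples`, `annotation`, `profile`,
#'   `vec_levels` (per-feature male VEC residual levels)
#' @export
simulate_methylome <- function(annotation, stages = default_stage_specs(),
                               profile = default_dynamics_profile(),
                               seed = 1L, keep_chh = TRUE) {
  stopifnot(inherits(annotation, "feature_set"))
  validate_dynamics_profile(profile)
  ord <- stage_index(stages$stage)
  if (is.unsorted(stages$divisions[order(ord)])) {
    stop("divisions must be non-decreasing along the stage order")
  }
  set.seed(seed)

  cpgs <- annotation$cpgs
  vec_ids <- annotation$features$id[annotation$features$class == "VEC"]
  vec_levels <- setNames(runif(length(vec_ids), profile$vec_level_range[1],
                               profile$vec_level_range[2]), vec_ids)
  iap_dist <- setNames(annotation$features$iap_dist, annotation$features$id)

  calls <- vector("list", nrow(stages))
  names(calls) <- stages$sample
  for (i in seq_len(nrow(stages))) {
    st <- stages[i, ]
    lvl <- numeric(nrow(cpgs))
    classes <- unique(cpgs$dyn_class)
    for (cl in classes) {
      sel <- which(cpgs$dyn_class == cl)
      if (cl == "VEC") {
        fid <- cpgs$feature_id[sel]
        lvl[sel] <- vapply(fid, function(f) {
          expected_class_level(profile, "VEC", st$stage, st$sex,
                               st$divisions, vec_level = vec_levels[[f]])
        }, 0)
      } else if (cl == "promoter_nonCGI") {
        fid <- cpgs$feature_id[sel]
        d <- iap_dist[fid]
        ud <- unique(d)
        l_by_d <- vapply(ud, function(dd) {
          expected_class_level(profile, cl, st$stage, st$sex, st$divisions,
                               iap_dist = dd)
        }, 0)
        lvl[sel] <- l_by_d[match(d, ud)]
      } else {
        lvl[sel] <- expected_class_level(profile, cl, st$stage, st$sex,
                                         st$divisions)
      }
    }
    p_obs <- lvl + (1 - lvl) * profile$conversion_failure
    n <- nrow(cpgs)
    cov_top <- rpois(n, st$coverage)
    cov_bot <- rpois(n, st$coverage)
    m_top <- rbinom(n, cov_top, p_obs)
    m_bot <- rbinom(n, cov_bot, p_obs)
    cg <- data.table(
      chrom = rep(cpgs$chrom, 2L),
      pos = c(cpgs$pos, cpgs$pos + 1),
      strand = rep(c("+", "-"), each = n),
      context = "CG",
      count_methylated = c(m_top, m_bot),
      count_unmethylated = c(cov_top - m_top, cov_bot - m_bot)
    )
    cg <- cg[count_methylated + count_unmethylated > 0L]
    if (keep_chh) {
      chh <- annotation$chh
      nh <- nrow(chh)
      cov_h <- rpois(nh, st$coverage)
      m_h <- rbinom(nh, cov_h, profile$conversion_failure)
      chh_dt <- data.table(
        chrom = chh$chrom, pos = chh$pos,
        strand = sample(c("+", "-"), nh, replace = TRUE),
        context = "CHH",
        count_methylated = m_h, count_unmethylated = cov_h - m_h
      )
      chh_dt <- chh_dt[count_methylated + count_unmethylated > 0L]
      cg <- rbindlist(list(cg, chh_dt))
    }
    setorder(cg, chrom, pos, strand)
    calls[[i]] <- cg
  }

  structure(list(calls = calls, samples = stages, annotation = annotation,
                 profile = profile, vec_levels = vec_levels),
            class = "methylome_sim")
}

#' @export
print.methylome_sim <- function(x, ...) {
  cat("methylome_sim:", length(x$calls), "samples,",
      nrow(x$annotation$cpgs), "CpG dyads\n")
  print(x$samples[, c("sample", "stage", "sex", "replicate", "divisions",
                      "coverage")])
  invisible(x)
}
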