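#' Developmental stage order for the PGC time course
#'
#' The stage roster runs from the E6.5 epiblast (the tissue PGCs are
#' specified from) through migrating PGCs (E9.5, E10.5, E11.5) to gonadal
#' PGCs (E13.5) and mitotically/meiotically arrested germ cells (E16.5).
#'
#' @export
PGC_STAGES <- c("E6.5", "E9.5", "E10.5", "E11.5", "E13.5", "E16.5")

stage_index <- function(stage) {
  i <- match(stage, PGC_STAGES)
  if (anyNA(i)) {
    stop("unknown stage label(s): ", paste(stage[is.na(i)], collapse = ", "))
  }
  i
}

#' Column/sample keys combining stage and sex
#'
#' Mixed-sex samples are keyed by stage alone (`"E9.5"`); sexed samples
#' append the sex (`"E13.5_male"`).
#'
#' @param stage stage label(s)
#' @param sex `"mixed"`, `"male"` or `"female"`
#' @return character key(s)
#' @export
stage_key <- function(stage, sex) {
  ifelse(sex == "mixed", stage, paste(stage, sex, sep = "_"))
}

#' Default stage specification for a simulated PGC time course
#'
#' One row per sample. The roster mirrors the profiled series: mixed-sex
#' E6.5 epiblast and E9.5/E10.5/E11.5 PGCs, then male and female samples
#' at E13.5 and E16.5. `divisions` is the cumulative number of cell
#' divisions since E6.5 driving passive dilution (defaults: 2 per stage
#' interval up to E13.5, none between E13.5 and E16.5 when germ cells
#' arrest).
#'
#' @param replicates number of replicates per stage/sex sample
#' @param coverage mean read coverage per CpG strand
#' @param divisions named integer vector, cumulative divisions per stage
#' @param sex_mode `"mixed"` for the default roster, `"female"` or
#'   `"male"` for a single-sex lineage (all stages sexed)
#' @return data.frame with columns sample, stage, sex, replicate,
#'   divisions, coverage
#' @export
default_stage_specs <- function(replicates = 2L, coverage = 10,
                                divisions = c("E6.5" = 0L, "E9.5" = 2L,
                                              "E10.5" = 4L, "E11.5" = 6L,
                                              "E13.5" = 8L, "E16.5" = 8L),
                                sex_mode = c("mixed", "female", "male")) {
  sex_mode <- match.arg(sex_mode)
  stopifnot(replicates >= 1L, coverage > 0)
  if (is.unsorted(divisions[PGC_STAGES])) {
    stop("cumulative divisions must be non-decreasing along the stage order")
  }
  if (sex_mode == "mixed") {
    roster <- data.frame(
      stage = c("E6.5", "E9.5", "E10.5", "E11.5",
                "E13.5", "E13.5", "E16.5", "E16.5"),
      sex = c("mixed", "mixed", "mixed", "mixed",
              "male", "female", "male", "female"),
      stringsAsFactors = FALSE
    )
  } else {
    roster <- data.frame(stage = PGC_STAGES, sex = sex_mode,
                         stringsAsFactors = FALSE)
  }
  specs <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    out <- roster
    out$replicate <- r
    out
  }))
  specs$divisions <- as.integer(divisions[specs$stage])
  specs$coverage <- coverage
  specs$sample <- paste0(stage_key(specs$stage, specs$sex), "_r",
                         specs$replicate)
  rownames(specs) <- NULL
  specs[, c("sample", "stage", "sex", "replicate", "divisions", "coverage")]
}
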