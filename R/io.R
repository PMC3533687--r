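# Provenance header written at the top of every TSV output.
.tsv_header <- function(extra = character()) {
  c(paste0("# pgcmeth ", as.character(utils::packageVersion("pgcmeth"))),
    if (length(extra)) paste0("# ", names(extra), "=", unname(extra)))
}

.CALL_COLS <- c("chrom", "pos", "strand", "context", "count_methylated",
                "count_unmethylated")

#' Write a cytosine call table as tab-separated text
#'
#' Dialect: commented provenance header, then a header row and six
#' columns — chrom, pos (0-based), strand (+/-), context (CG|CHH),
#' count_methylated, count_unmethylated.
#'
#' @param calls data.frame/data.table of calls
#' @param path output file
#' @param meta named character vector added to the commented header
#' @return the path, invisibly
#' @export
write_cytosine_calls <- function(calls, path, meta = character()) {
  stopifnot(all(.CALL_COLS %in% names(calls)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.tsv_header(meta), con)
  write.table(as.data.frame(calls)[, .CALL_COLS], con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cytosine call table
#'
#' Validates every row: six columns, strand in +/-, context CG or CHH,
#' non-negative integer counts. Malformed rows are rejected with their
#' line numbers. An empty file yields an empty table with a warning.
#'
#' @param path input file
#' @return data.table of calls
#' @export
read_cytosine_calls <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  body <- which(!is_comment)
  if (!length(body)) {
    warning("empty cytosine call file: ", path)
    return(data.table(chrom = character(), pos = numeric(),
                      strand = character(), context = character(),
                      count_methylated = integer(),
                      count_unmethylated = integer()))
  }
  header_line <- body[1]
  hdr <- strsplit(lines[header_line], "\t", fixed = TRUE)[[1]]
  if (!identical(hdr, .CALL_COLS)) {
    stop("unexpected column header in ", path, " (line ", header_line, ")")
  }
  data_lines <- body[-1]
  if (!length(data_lines)) {
    warning("cytosine call file has no data rows: ", path)
    return(data.table(chrom = character(), pos = numeric(),
                      strand = character(), context = character(),
                      count_methylated = integer(),
                      count_unmethylated = integer()))
  }
  parts <- strsplit(lines[data_lines], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 6L)) {
    stop("malformed rows (expected 6 fields) at line(s): ",
         paste(data_lines[nfield != 6L], collapse = ", "))
  }
  m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  dt <- data.table(chrom = m[, 1], pos = suppressWarnings(as.numeric(m[, 2])),
                   strand = m[, 3], context = m[, 4],
                   count_methylated = suppressWarnings(as.integer(m[, 5])),
                   count_unmethylated = suppressWarnings(as.integer(m[, 6])))
  bad_ctx <- !dt$context %in% c("CG", "CHH")
  if (any(bad_ctx)) {
    stop("unknown context token at line(s): ",
         paste(data_lines[bad_ctx], collapse = ", "),
         " (allowed: CG, CHH)")
  }
  bad <- is.na(dt$pos) | dt$pos < 0 | !dt$strand %in% c("+", "-") |
    is.na(dt$count_methylated) | dt$count_methylated < 0 |
    is.na(dt$count_unmethylated) | dt$count_unmethylated < 0
  if (any(bad)) {
    stop("malformed rows at line(s): ",
         paste(data_lines[bad], collapse = ", "))
  }
  dt
}

#' Write features as BED6 with the class in the name field
#'
#' The name field is `<class>:<id>`; score is 0 and strand `.` (feature
#' strand is not modelled). Coordinates stay 0-based half-open.
#'
#' @param features feature data.frame or `feature_set`
#' @param path output file
#' @return the path, invisibly
#' @export
write_features_bed <- function(features, path) {
  if (inherits(features, "feature_set")) features <- features$features
  stopifnot(all(c("chrom", "start", "end", "id", "class") %in%
                  names(features)))
  bed <- data.frame(chrom = features$chrom,
                    start = format(features$start, scientific = FALSE,
                                   trim = TRUE),
                    end = format(features$end, scientific = FALSE,
                                 trim = TRUE),
                    name = paste(features$class, features$id, sep = ":"),
                    score = 0, strand = ".", stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  write.table(bed, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED6 feature file
#'
#' Validates start < end, known class tokens in the name field, and
#' that same-class intervals do not overlap (overlaps are reported with
#' both offending ids).
#'
#' @param path input BED6 file
#' @return data.frame: chrom, start, end, id, class, x_linked
#' @export
read_features_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), id = character(),
                      class = character(), x_linked = logical(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 6L)) {
    stop("BED6 requires 6 fields; short row(s) at line(s): ",
         paste(which(lengths(parts) < 6L), collapse = ", "))
  }
  m <- matrix(unlist(lapply(parts, `[`, 1:6)), ncol = 6L, byrow = TRUE)
  start <- as.numeric(m[, 2]); end <- as.numeric(m[, 3])
  if (any(is.na(start) | is.na(end))) stop("non-numeric BED coordinates")
  bad <- start >= end
  if (any(bad)) {
    stop("start >= end at line(s): ", paste(which(bad), collapse = ", "))
  }
  name <- strsplit(m[, 4], ":", fixed = TRUE)
  class <- vapply(name, `[`, "", 1)
  id <- vapply(name, function(x) if (length(x) > 1) x[2] else x[1], "")
  unknown <- !class %in% FEATURE_CLASSES
  if (any(unknown)) {
    stop("unknown feature class token(s): ",
         paste(unique(class[unknown]), collapse = ", "),
         " (allowed: ", paste(FEATURE_CLASSES, collapse = ", "), ")")
  }
  df <- data.frame(chrom = m[, 1], start = start, end = end, id = id,
                   class = class, x_linked = class == "CGI_X",
                   stringsAsFactors = FALSE)
  for (cl in unique(df$class)) {
    sub <- df[df$class == cl, ]
    sub <- sub[order(sub$chrom, sub$start), ]
    if (nrow(sub) > 1) {
      same <- sub$chrom[-1] == sub$chrom[-nrow(sub)]
      ovl <- same & sub$start[-1] < sub$end[-nrow(sub)]
      if (any(ovl)) {
        i <- which(ovl)[1]
        stop("overlapping same-class intervals: ", sub$id[i], " and ",
             sub$id[i + 1], " (class ", cl, ")")
      }
    }
  }
  df
}

#' Write hairpin reads as tab-separated state strings
#'
#' One row per molecule: read id, then the dyad states concatenated
#' over `{M, T, B, U, .}`.
#'
#' @param reads `hairpin_reads` matrix
#' @param path output file
#' @return the path, invisibly
#' @export
write_hairpin_reads <- function(reads, path) {
  m <- .as_hairpin_matrix(reads)
  ids <- rownames(m)
  if (is.null(ids)) ids <- sprintf("read_%06d", seq_len(nrow(m)))
  writeLines(paste(ids, apply(m, 1, paste, collapse = ""), sep = "\t"),
             path)
  invisible(path)
}

#' Read hairpin reads written by [write_hairpin_reads()]
#'
#' @param path input file
#' @return `hairpin_reads` character matrix
#' @export
read_hairpin_reads <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) stop("no hairpin reads in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("malformed hairpin rows at line(s): ",
         paste(which(lengths(parts) != 2L), collapse = ", "))
  }
  ids <- vapply(parts, `[`, "", 1)
  states <- vapply(parts, `[`, "", 2)
  m <- .as_hairpin_matrix(setNames(states, ids))
  structure(m, class = c("hairpin_reads", class(m)))
}

#' Write an expression matrix as gene-by-sample TSV
#'
#' @param expr matrix or `expression_sim`
#' @param path output file
#' @return the path, invisibly
#' @export
write_expression_tsv <- function(expr, path) {
  expr <- .as_expr_matrix(expr)
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.tsv_header(), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_expression_tsv()]
#'
#' @param path input file
#' @return numeric matrix, genes x samples
#' @export
read_expression_tsv <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, skip = "gene")
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- dt[[1]]
  m
}

#' Write a methylation matrix with a sidecar metadata header
#'
#' The commented header carries the sample sheet (sample, stage, sex,
#' replicate) line by line; the body is row id plus one percentage
#' column per sample (missing cells as NA).
#'
#' @param mat a `meth_matrix`
#' @param path output file
#' @return the path, invisibly
#' @export
write_meth_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "meth_matrix"))
  sm <- mat$samples
  meta <- vapply(seq_len(nrow(sm)), function(i) {
    paste(unlist(sm[i, ]), collapse = "/")
  }, "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.tsv_header(setNames(meta, rep("sample", length(meta)))), con)
  df <- data.frame(id = rownames(mat$pct), mat$pct, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
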