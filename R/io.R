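#' Read a serial-passage log
#'
#' UTF-8 TSV with a header row; columns as in [passage_records()]. Densities
#' may be written in scientific notation; blank cells become `NA` (allowed
#' for the phage fields of host-only assays and the cell fields of
#' phage-only passages, never both).
#'
#' @param path TSV file path.
#' @return A validated `passage_record` tibble, rows in file order.
#' @export
read_passage_log <- function(path) {
  # missing columns are reported by the validator below, not by the parser
  df <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    day_index = "i", lineage_id = "c", regime = "c",
    n_i_phage = "d", n_f_phage = "d", n_i_cell = "d", n_f_cell = "d",
    dilution_factor = "d", duration = "d"
  ), progress = FALSE))
  spec_problems <- readr::problems(df)
  if (nrow(spec_problems) > 0L) {
    coevo_stop(sprintf("malformed value at row %d, column %s",
                       spec_problems$row[1L], spec_problems$col[1L]),
               "coevo_format_error")
  }
  validate_passage_records(df)
}

#' Write a serial-passage log
#'
#' @param records a `passage_record` tibble.
#' @param path output TSV path.
#' @return `records`, invisibly.
#' @export
write_passage_log <- function(records, path) {
  readr::write_tsv(records[PASSAGE_COLUMNS], path, progress = FALSE)
  invisible(records)
}

#' Read time courses from a long-format TSV
#'
#' Columns `entity`, `time`, `value`, optionally `time_unit` (constant per
#' entity; default hours). Returns one [time_course()] per entity.
#'
#' @param path TSV file path.
#' @return A named list of `time_course` objects.
#' @export
read_time_courses <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    entity = "c", time = "d", value = "d", .default = "c"
  ), progress = FALSE)
  if (!all(c("entity", "time", "value") %in% names(df))) {
    coevo_stop("missing required column(s): entity, time, value",
               "coevo_format_error")
  }
  if (!"time_unit" %in% names(df)) df$time_unit <- "hours"
  out <- lapply(split(df, df$entity), function(d) {
    d <- d[order(d$time), ]
    time_course(d$entity[1L], d$time, d$value, time_unit = d$time_unit[1L])
  })
  out[unique(df$entity)]
}

#' Write time courses to a long-format TSV
#'
#' @param tcs a `time_course` or list of them.
#' @param path output TSV path.
#' @return `tcs`, invisibly.
#' @export
write_time_courses <- function(tcs, path) {
  if (inherits(tcs, "time_course")) tcs <- list(tcs)
  df <- do.call(rbind, lapply(tcs, function(tc) {
    tibble::tibble(entity = tc$entity, time = tc$times, value = tc$values,
                   time_unit = tc$time_unit)
  }))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(tcs)
}

#' Read a genome annotation from a gene map (and optional FASTA)
#'
#' The gene map is a TSV with columns `name`, `start`, `end` in 1-based
#' inclusive genome coordinates, plus either a `genome_length` column
#' (constant) or a FASTA reference whose length defines it.
#'
#' @param gene_map TSV path.
#' @param fasta optional single-record FASTA path (RNA or DNA alphabet);
#'   when given, its length must match `genome_length` if both are present.
#' @param genome_length optional explicit genome length; required when the
#'   gene map has no `genome_length` column and no FASTA is given.
#' @return A [genome_annotation()]. Without a reference sequence the
#'   annotation supports coordinate arithmetic but not codon annotation.
#' @export
read_genome_annotation <- function(gene_map, fasta = NULL, genome_length = NULL) {
  genes <- readr::read_tsv(gene_map, col_types = readr::cols(
    name = "c", start = "i", end = "i", .default = "i"
  ), progress = FALSE)
  if (is.null(genome_length) && "genome_length" %in% names(genes)) {
    genome_length <- genes$genome_length[1L]
  }
  ref <- NULL
  if (!is.null(fasta)) {
    set <- Biostrings::readBStringSet(fasta)
    if (length(set) != 1L) {
      coevo_stop("reference FASTA must contain exactly one record",
                 "coevo_format_error")
    }
    ref <- toupper(as.character(set[[1L]]))
    if (!is.null(genome_length) && nchar(ref) != genome_length) {
      coevo_stop(sprintf("FASTA length %d does not match genome_length %d",
                         nchar(ref), genome_length),
                 "coevo_validation_error")
    }
    genome_length <- nchar(ref)
  }
  if (is.null(genome_length)) {
    coevo_stop("genome_length not given and no FASTA provided", "coevo_format_error")
  }
  genome_annotation(genome_length, genes[c("name", "start", "end")], ref)
}

#' Read cross-coculture fitness assay records
#'
#' TSV with the columns of [fitness_assay_records()].
#'
#' @param path TSV file path.
#' @return A `fitness_assay_record` tibble.
#' @export
read_fitness_assays <- function(path) {
  df <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    host_id = "c", phage_id = "c", replicate_id = "i",
    od600_initial = "d", od600_7h = "d",
    pfu_0h = "d", pfu_7h = "d", pfu_late = "d"
  ), progress = FALSE))
  need <- c("host_id", "phage_id", "replicate_id", "od600_initial",
            "od600_7h", "pfu_0h", "pfu_7h", "pfu_late")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    coevo_stop(paste0("missing required column(s): ",
                      paste(missing_cols, collapse = ", ")),
               "coevo_format_error")
  }
  do.call(fitness_assay_records, as.list(df[need]))
}

#' Write cross-coculture fitness assay records
#'
#' @param records a `fitness_assay_record` tibble.
#' @param path output TSV path.
#' @return `records`, invisibly.
#' @export
write_fitness_assays <- function(records, path) {
  readr::write_tsv(tibble::as_tibble(records), path, progress = FALSE)
  invisible(records)
}
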