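#' @section Domain model:
#' The package represents a serial-transfer experiment with a small set of
#' plain containers: passage records (one row per daily transfer), time
#' courses (one measured entity sampled over hours), a genome annotation
#' (gene coordinates, optionally with the reference sequence), a mutation
#' status matrix (sites x sequenced populations), and fitness assay records
#' (one row per replicate cross-coculture).
#' @name coevo-data-model
NULL

coevo_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "coevo_error", "error", "condition")))
}

# valid entity names for a time course
TC_ENTITIES <- c("free_phage", "infected_cells", "total_cells", "od600")

PASSAGE_COLUMNS <- c(
  "day_index", "lineage_id", "regime", "n_i_phage", "n_f_phage",
  "n_i_cell", "n_f_cell", "dilution_factor", "duration"
)

#' Build a table of serial-passage records
#'
#' One row per daily transfer cycle of one lineage. Phage fields
#' (`n_i_phage`, `n_f_phage`, PFU/ml) may be `NA` in host-only assays and
#' cell fields (`n_i_cell`, `n_f_cell`, CFU/ml) may be `NA` in phage-only
#' passages, but never both. The dilution factor is the fold-dilution
#' applied when starting the passage (> 1), so that the initial density of
#' day \eqn{d} equals the final density of day \eqn{d-1} divided by it.
#'
#' @param day_index integer day number, >= 1.
#' @param lineage_id character lineage label.
#' @param regime `"copropagation"` or `"phage_only"`.
#' @param n_i_phage,n_f_phage initial/final free-phage density (PFU/ml).
#' @param n_i_cell,n_f_cell initial/final viable-cell density (CFU/ml).
#' @param dilution_factor fold dilution at the start of the passage (> 1).
#' @param duration passage duration in hours (> 0).
#' @return A tibble of class `passage_record`.
#' @examples
#' passage_records(day_index = 1:2, lineage_id = "1", regime = "copropagation",
#'                 n_i_phage = c(1e7, 2e7), n_f_phage = c(1.6e8, 8e7),
#'                 n_i_cell = c(1e7, 1e7), n_f_cell = c(3e8, 3e8),
#'                 dilution_factor = 8, duration = 24)
#' @export
passage_records <- function(day_index, lineage_id, regime,
                            n_i_phage = NA_real_, n_f_phage = NA_real_,
                            n_i_cell = NA_real_, n_f_cell = NA_real_,
                            dilution_factor, duration = 24) {
  df <- tibble::tibble(
    day_index = as.integer(day_index),
    lineage_id = as.character(lineage_id),
    regime = as.character(regime),
    n_i_phage = as.numeric(n_i_phage),
    n_f_phage = as.numeric(n_f_phage),
    n_i_cell = as.numeric(n_i_cell),
    n_f_cell = as.numeric(n_f_cell),
    dilution_factor = as.numeric(dilution_factor),
    duration = as.numeric(duration)
  )
  validate_passage_records(df)
}

validate_passage_records <- function(df) {
  missing_cols <- setdiff(PASSAGE_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    coevo_stop(paste0("missing required column(s): ",
                      paste(missing_cols, collapse = ", ")),
               "coevo_format_error")
  }
  df <- df[PASSAGE_COLUMNS]
  bad_regime <- !df$regime %in% c("copropagation", "phage_only")
  if (any(bad_regime)) {
    coevo_stop(paste0("unknown regime in row(s) ",
                      paste(which(bad_regime), collapse = ", ")),
               "coevo_validation_error")
  }
  for (col in c("n_i_phage", "n_f_phage", "n_i_cell", "n_f_cell")) {
    x <- df[[col]]
    bad <- !is.na(x) & (!is.finite(x) | x < 0)
    if (any(bad)) {
      coevo_stop(sprintf("negative or non-finite %s in row %d", col, which(bad)[1L]),
                 "coevo_validation_error")
    }
  }
  phage_absent <- is.na(df$n_i_phage) & is.na(df$n_f_phage)
  cell_absent <- is.na(df$n_i_cell) & is.na(df$n_f_cell)
  if (any(phage_absent & cell_absent)) {
    coevo_stop(sprintf("row %d has neither phage nor cell densities",
                       which(phage_absent & cell_absent)[1L]),
               "coevo_validation_error")
  }
  bad_dil <- is.na(df$dilution_factor) | df$dilution_factor <= 1
  if (any(bad_dil)) {
    coevo_stop(sprintf("dilution_factor must be > 1 (row %d)", which(bad_dil)[1L]),
               "coevo_validation_error")
  }
  if (any(is.na(df$duration) | df$duration <= 0)) {
    coevo_stop("duration must be > 0 hours", "coevo_validation_error")
  }
  if (any(is.na(df$day_index) | df$day_index < 1L)) {
    coevo_stop("day_index must be >= 1", "coevo_validation_error")
  }
  class(df) <- c("passage_record", class(df))
  df
}

#' Construct a measured time course
#'
#' A strictly increasing time grid with the matching non-negative
#' measurements of one entity: free phage (PFU/ml), infected cells (PFU/ml,
#' measured as infective centres), total cells (CFU/ml), or OD600.
#'
#' @param entity one of `"free_phage"`, `"infected_cells"`, `"total_cells"`,
#'   `"od600"`.
#' @param times numeric times; hours unless `time_unit = "minutes"`.
#' @param values numeric non-negative measurements, same length as `times`.
#' @param time_unit `"hours"` (default) or `"minutes"`.
#' @return An object of class `time_course`.
#' @export
time_course <- function(entity, times, values, time_unit = c("hours", "minutes")) {
  time_unit <- match.arg(time_unit)
  entity <- match.arg(entity, TC_ENTITIES)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    coevo_stop("times and values must have equal length", "coevo_validation_error")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    coevo_stop("times must be strictly increasing", "coevo_validation_error")
  }
  if (any(!is.finite(values) | values < 0)) {
    coevo_stop("values must be finite and non-negative", "coevo_validation_error")
  }
  structure(
    list(entity = entity, times = times, values = values, time_unit = time_unit),
    class = "time_course"
  )
}

#' @export
print.time_course <- function(x, ...) {
  cat(sprintf("<time_course> %s: %d points over [%g, %g] %s\n",
              x$entity, length(x$times),
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA, x$time_unit))
  invisible(x)
}

#' Construct a genome annotation
#'
#' Gene coordinates on a small (viral) genome. Coordinates are 1-based and
#' inclusive; genes may overlap (read-through genes share a start codon).
#' Position `p` within a gene maps to genome position `start + p - 1`.
#'
#' @param genome_length genome length in bases.
#' @param genes data frame with columns `name`, `start`, `end` (1-based,
#'   inclusive).
#' @param reference_sequence optional single reference sequence of length
#'   `genome_length`; RNA (`ACGU`) or DNA (`ACGT`) alphabet.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genome_length, genes, reference_sequence = NULL) {
  genome_length <- as.integer(genome_length)
  genes <- tibble::as_tibble(genes)
  need <- c("name", "start", "end")
  if (!all(need %in% names(genes))) {
    coevo_stop("gene table needs columns name, start, end", "coevo_format_error")
  }
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  bad <- genes$start < 1L | genes$end < genes$start | genes$end > genome_length
  if (any(bad)) {
    coevo_stop(sprintf("gene '%s' has coordinates outside 1..%d",
                       genes$name[bad][1L], genome_length),
               "coevo_validation_error")
  }
  if (!is.null(reference_sequence)) {
    reference_sequence <- toupper(as.character(reference_sequence))
    if (nchar(reference_sequence) != genome_length) {
      coevo_stop(sprintf("reference sequence length %d != genome_length %d",
                         nchar(reference_sequence), genome_length),
                 "coevo_validation_error")
    }
  }
  structure(
    list(genome_length = genome_length, genes = genes[need],
         reference_sequence = reference_sequence),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d bases, %d gene(s)%s\n",
              x$genome_length, nrow(x$genes),
              if (is.null(x$reference_sequence)) "" else ", with reference sequence"))
  print(x$genes)
  invisible(x)
}

#' Build a table of cross-coculture fitness assay records
#'
#' One row per replicate pairing of a host population with a phage
#' population. Host fitness uses the 7 h OD600 against the inoculation OD
#' (0.03 by protocol); phage fitness uses the larger of the 7 h and late
#' (22-29.5 h) free-phage titres against the titre just after infection.
#'
#' @param host_id,phage_id population labels.
#' @param replicate_id integer replicate number within a pairing.
#' @param od600_initial inoculation OD600 (> 0; protocol value 0.03).
#' @param od600_7h OD600 at 7 h.
#' @param pfu_0h,pfu_7h,pfu_late free-phage titres (PFU/ml) just after
#'   infection, at 7 h, and at 22-29.5 h. May be `NA` in host-only assays.
#' @return A tibble of class `fitness_assay_record`.
#' @export
fitness_assay_records <- function(host_id, phage_id, replicate_id = 1L,
                                  od600_initial = 0.03, od600_7h = NA_real_,
                                  pfu_0h = NA_real_, pfu_7h = NA_real_,
                                  pfu_late = NA_real_) {
  df <- tibble::tibble(
    host_id = as.character(host_id), phage_id = as.character(phage_id),
    replicate_id = as.integer(replicate_id),
    od600_initial = as.numeric(od600_initial), od600_7h = as.numeric(od600_7h),
    pfu_0h = as.numeric(pfu_0h), pfu_7h = as.numeric(pfu_7h),
    pfu_late = as.numeric(pfu_late)
  )
  if (any(!is.na(df$od600_initial) & df$od600_initial <= 0)) {
    coevo_stop("od600_initial must be > 0", "coevo_validation_error")
  }
  class(df) <- c("fitness_assay_record", class(df))
  df
}
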