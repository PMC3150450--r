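STATUS_LEVELS <- c("absent", "polymorphic", "fixed")

# canonical symbols used in the published-table encoding and their ASCII aliases
STATUS_SYMBOLS <- c("absent" = "", "polymorphic" = "±", "fixed" = "+")
STATUS_ALIASES <- c("0" = "absent", "0.5" = "polymorphic", "1" = "fixed")

#' Construct a mutation status matrix
#'
#' Sites by sequenced populations, each cell one of `"absent"` (population
#' carries the ancestral base), `"polymorphic"` (segregating), or `"fixed"`
#' (population carries the evolved base). The ancestral population itself
#' may be polymorphic at a site (a heterogeneous founding stock).
#'
#' @param sites data frame with columns `genome_position`, `ancestral_nt`,
#'   `evolved_nt`; one row per site, each genome position at most once per
#'   (ancestral, evolved) pair.
#' @param populations data frame with columns `population_id`, `generation`
#'   (replication-generation stamp; `NA` for reference columns that belong
#'   to no lineage), and `lineages` (comma-separated lineage labels the
#'   population belongs to; `""` for none). Within each lineage, rows must
#'   appear in non-decreasing generation order with the ancestral
#'   (lowest-generation) population first.
#' @param status character matrix (`nrow(sites)` x `nrow(populations)`)
#'   with entries in `c("absent", "polymorphic", "fixed")`.
#' @return An object of class `mutation_status_matrix` with derived
#'   element `lineages`: a named list of ordered population id vectors.
#' @export
mutation_status_matrix <- function(sites, populations, status) {
  sites <- tibble::as_tibble(sites)
  populations <- tibble::as_tibble(populations)
  if (!all(c("genome_position", "ancestral_nt", "evolved_nt") %in% names(sites))) {
    coevo_stop("sites needs columns genome_position, ancestral_nt, evolved_nt",
               "coevo_format_error")
  }
  if (!all(c("population_id", "generation") %in% names(populations))) {
    coevo_stop("populations needs columns population_id, generation",
               "coevo_format_error")
  }
  if (!"lineages" %in% names(populations)) populations$lineages <- ""
  sites$genome_position <- as.integer(sites$genome_position)
  if (anyDuplicated(sites$genome_position)) {
    coevo_stop("each site must appear exactly once", "coevo_validation_error")
  }
  status <- as.matrix(status)
  if (!all(dim(status) == c(nrow(sites), nrow(populations)))) {
    coevo_stop("status must be a sites x populations matrix", "coevo_validation_error")
  }
  if (!all(status %in% STATUS_LEVELS)) {
    coevo_stop("status entries must be absent/polymorphic/fixed",
               "coevo_validation_error")
  }
  dimnames(status) <- list(as.character(sites$genome_position),
                           populations$population_id)
  lineages <- derive_lineages(populations)
  structure(
    list(sites = sites, populations = populations, status = status,
         lineages = lineages),
    class = "mutation_status_matrix"
  )
}

derive_lineages <- function(populations) {
  labels <- strsplit(as.character(populations$lineages), ",[ ]*")
  ids <- unique(unlist(labels))
  ids <- ids[!is.na(ids) & nzchar(ids)]
  out <- list()
  for (lin in ids) {
    member <- vapply(labels, function(l) lin %in% l, logical(1L))
    gen <- populations$generation[member]
    if (anyNA(gen)) {
      coevo_stop(sprintf("lineage '%s' has a population without a generation stamp", lin),
                 "coevo_validation_error")
    }
    if (is.unsorted(gen)) {
      coevo_stop(sprintf("populations of lineage '%s' are not in non-decreasing generation order", lin),
                 "coevo_validation_error")
    }
    out[[lin]] <- populations$population_id[member]
  }
  out
}

#' @export
print.mutation_status_matrix <- function(x, ...) {
  cat(sprintf("<mutation_status_matrix> %d site(s) x %d population(s), %d lineage(s)\n",
              nrow(x$sites), nrow(x$populations), length(x$lineages)))
  invisible(x)
}

decode_status_symbol <- function(symbols, row, col_name) {
  symbols <- ifelse(is.na(symbols), "", trimws(symbols))
  out <- rep(NA_character_, length(symbols))
  for (s in names(STATUS_SYMBOLS)) out[symbols == STATUS_SYMBOLS[[s]]] <- s
  for (a in names(STATUS_ALIASES)) out[symbols == a] <- STATUS_ALIASES[[a]]
  bad <- which(is.na(out))
  if (length(bad) > 0L) {
    coevo_stop(sprintf("unknown status symbol '%s' at row %d, column '%s'",
                       symbols[bad[1L]], row[bad[1L]], col_name),
               "coevo_format_error")
  }
  out
}

#' Read a mutation status matrix from TSV files
#'
#' The status file has columns `genome_position`, `ancestral_nt`,
#' `evolved_nt` followed by one column per sequenced population, with cells
#' encoded as blank (ancestral sequence), `"±"` (heterogeneous with the
#' ancestral and evolved base), or `"+"` (evolved sequence fixed); the ASCII
#' aliases `0`, `0.5`, `1` are accepted. The populations file has columns
#' `population_id`, `generation`, `lineages`.
#'
#' @param status_path TSV of site statuses.
#' @param populations_path TSV of population metadata.
#' @return A [mutation_status_matrix()].
#' @export
read_mutation_matrix <- function(status_path, populations_path) {
  raw <- readr::read_tsv(status_path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("genome_position", "ancestral_nt", "evolved_nt")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    coevo_stop(paste0("missing required column(s): ",
                      paste(missing_cols, collapse = ", ")),
               "coevo_format_error")
  }
  pops <- readr::read_tsv(populations_path,
                          col_types = readr::cols(
                            population_id = "c", generation = "d",
                            lineages = "c"),
                          progress = FALSE)
  pops$lineages[is.na(pops$lineages)] <- ""
  pop_cols <- setdiff(names(raw), need)
  if (!setequal(pop_cols, pops$population_id)) {
    coevo_stop("status columns do not match the populations file",
               "coevo_format_error")
  }
  pop_cols <- pops$population_id  # keep populations-file order
  status <- vapply(pop_cols, function(p) {
    decode_status_symbol(raw[[p]], seq_len(nrow(raw)), p)
  }, character(nrow(raw)))
  sites <- tibble::tibble(
    genome_position = as.integer(gsub(",", "", raw$genome_position)),
    ancestral_nt = raw$ancestral_nt,
    evolved_nt = raw$evolved_nt
  )
  mutation_status_matrix(sites, pops, matrix(status, nrow = nrow(raw),
                                             dimnames = list(NULL, pop_cols)))
}

#' Write a mutation status matrix to TSV files
#'
#' Inverse of [read_mutation_matrix()]; statuses are written with the
#' canonical blank/`"±"`/`"+"` symbols.
#'
#' @param x a [mutation_status_matrix()].
#' @param status_path,populations_path output TSV paths.
#' @return `x`, invisibly.
#' @export
write_mutation_matrix <- function(x, status_path, populations_path) {
  stopifnot(inherits(x, "mutation_status_matrix"))
  symbols <- STATUS_SYMBOLS[x$status]
  dim(symbols) <- dim(x$status)
  out <- cbind(
    tibble::tibble(genome_position = x$sites$genome_position,
                   ancestral_nt = x$sites$ancestral_nt,
                   evolved_nt = x$sites$evolved_nt),
    tibble::as_tibble(matrix(symbols, nrow = nrow(x$status),
                             dimnames = list(NULL, x$populations$population_id)))
  )
  readr::write_tsv(out, status_path, progress = FALSE)
  readr::write_tsv(x$populations, populations_path, progress = FALSE)
  invisible(x)
}
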