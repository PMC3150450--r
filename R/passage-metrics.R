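#' Replication generations across one passage
#'
#' The doubling count implied by the density change across a passage,
#' \eqn{g = \log_2(N_f / N_i)}, from the defining relation
#' \eqn{N_f / N_i = 2^g}. Negative when the population shrank.
#'
#' @param n_i,n_f initial and final density (> 0), PFU/ml or CFU/ml.
#' @return Generations (dimensionless), vectorised.
#' @examples
#' passage_generations(1e7, 8e7)  # 3 doublings
#' @export
passage_generations <- function(n_i, n_f) {
  if (any(!is.finite(n_i) | n_i <= 0) || any(!is.finite(n_f) | n_f <= 0)) {
    coevo_stop("densities must be positive and finite", "coevo_domain_error")
  }
  log2(n_f / n_i)
}

#' Fold amplification across one passage
#'
#' @inheritParams passage_generations
#' @return `n_f / n_i` (dimensionless), vectorised.
#' @export
amplification_fold <- function(n_i, n_f) {
  if (any(!is.finite(n_i) | n_i <= 0) || any(!is.finite(n_f) | n_f <= 0)) {
    coevo_stop("densities must be positive and finite", "coevo_domain_error")
  }
  n_f / n_i
}

#' Cumulative replication generations over a passage series
#'
#' Per-passage generations are `log2(n_f / n_i)` for the chosen entity;
#' where an initial density is missing it is derived from the previous
#' day's final density divided by the current day's dilution factor. The
#' cumulative total is the prefix sum.
#'
#' @param records a `passage_record` tibble, ordered by day, one lineage.
#' @param entity `"phage"` (PFU fields) or `"cells"` (CFU fields).
#' @return A tibble of class `generation_series` with columns `day_index`,
#'   `n_i`, `n_f`, `generations`, `cumulative`.
#' @export
cumulative_generations <- function(records, entity = c("phage", "cells")) {
  entity <- match.arg(entity)
  if (nrow(records) == 0L) {
    out <- tibble::tibble(day_index = integer(), n_i = numeric(),
                          n_f = numeric(), generations = numeric(),
                          cumulative = numeric())
    class(out) <- c("generation_series", class(out))
    return(out)
  }
  if (length(unique(records$lineage_id)) > 1L) {
    coevo_stop("records must come from a single lineage", "coevo_data_error")
  }
  if (is.unsorted(records$day_index, strictly = TRUE)) {
    coevo_stop("records must be ordered by day_index", "coevo_data_error")
  }
  cols <- if (entity == "phage") c("n_i_phage", "n_f_phage") else c("n_i_cell", "n_f_cell")
  n_i <- records[[cols[1L]]]
  n_f <- records[[cols[2L]]]
  if (anyNA(n_f)) {
    coevo_stop(sprintf("missing final density on day %d",
                       records$day_index[which(is.na(n_f))[1L]]),
               "coevo_data_error")
  }
  for (d in seq_along(n_i)) {
    if (is.na(n_i[d])) {
      if (d == 1L) {
        coevo_stop("initial density of the first passage is missing",
                   "coevo_data_error")
      }
      n_i[d] <- n_f[d - 1L] / records$dilution_factor[d]
    }
  }
  g <- passage_generations(n_i, n_f)
  out <- tibble::tibble(day_index = records$day_index, n_i = n_i, n_f = n_f,
                        generations = g, cumulative = cumsum(g))
  class(out) <- c("generation_series", class(out))
  out
}

#' Host fitness from a cross-coculture growth assay
#'
#' \eqn{\log_{10}(OD_{600,7h} / OD_{600,0h})}: decades of biomass gain over
#' the 7 h assay, from the protocol inoculation OD of 0.03.
#'
#' @param od600_7h OD600 at 7 h (> 0).
#' @param od600_initial inoculation OD600 (> 0; default 0.03).
#' @return Dimensionless fitness, vectorised.
#' @export
host_fitness <- function(od600_7h, od600_initial = 0.03) {
  if (any(!is.finite(od600_7h) | od600_7h <= 0) ||
      any(!is.finite(od600_initial) | od600_initial <= 0)) {
    coevo_stop("OD values must be positive and finite", "coevo_domain_error")
  }
  log10(od600_7h / od600_initial)
}

#' Phage fitness from a cross-coculture amplification assay
#'
#' \eqn{\log_{10}(\mathrm{PFU}_{max} / \mathrm{PFU}_{0h})} where the
#' maximum is taken over the 7 h and late (22-29.5 h) titres. May be
#' negative when the phage failed to amplify.
#'
#' @param pfu_0h titre just after infection (> 0), PFU/ml.
#' @param pfu_7h,pfu_late titres at 7 h and 22-29.5 h; at least one of the
#'   two must be present per assay.
#' @return Dimensionless fitness, vectorised.
#' @export
phage_fitness <- function(pfu_0h, pfu_7h = NA_real_, pfu_late = NA_real_) {
  if (any(!is.finite(pfu_0h) | pfu_0h <= 0)) {
    coevo_stop("pfu_0h must be positive and finite", "coevo_domain_error")
  }
  both_absent <- is.na(pfu_7h) & is.na(pfu_late)
  if (any(both_absent)) {
    coevo_stop("at least one post-infection titre is required", "coevo_data_error")
  }
  pfu_max <- pmax(pfu_7h, pfu_late, na.rm = TRUE)
  log10(pfu_max / pfu_0h)
}

#' Build host and phage fitness grids from assay records
#'
#' Computes per-replicate host and phage fitness for every assayed
#' host x phage pairing; replicates are never averaged silently.
#' Combinations absent from the input are unavailable (`NA` in the grid).
#'
#' @param records a `fitness_assay_record` tibble.
#' @return A list of class `fitness_matrix` with elements `host` and
#'   `phage`: tidy tibbles (`host_id`, `phage_id`, `replicate_id`,
#'   `fitness`), plus `hosts` and `phages` label vectors.
#' @export
build_fitness_matrix <- function(records) {
  records <- tibble::as_tibble(records)
  key <- paste(records$host_id, records$phage_id, records$replicate_id)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    coevo_stop(sprintf("duplicate replicate for combination %s", dup),
               "coevo_data_error")
  }
  host_rows <- !is.na(records$od600_7h)
  host <- tibble::tibble(
    host_id = records$host_id[host_rows], phage_id = records$phage_id[host_rows],
    replicate_id = records$replicate_id[host_rows],
    fitness = host_fitness(records$od600_7h[host_rows],
                           records$od600_initial[host_rows])
  )
  phage_rows <- !is.na(records$pfu_0h) &
    !(is.na(records$pfu_7h) & is.na(records$pfu_late))
  phage <- tibble::tibble(
    host_id = records$host_id[phage_rows], phage_id = records$phage_id[phage_rows],
    replicate_id = records$replicate_id[phage_rows],
    fitness = phage_fitness(records$pfu_0h[phage_rows],
                            records$pfu_7h[phage_rows],
                            records$pfu_late[phage_rows])
  )
  structure(
    list(host = host, phage = phage,
         hosts = unique(records$host_id), phages = unique(records$phage_id)),
    class = "fitness_matrix"
  )
}

#' Cast one grid of a fitness matrix to wide form
#'
#' @param x a `fitness_matrix`.
#' @param which `"host"` or `"phage"`.
#' @param fun summary applied to replicates (default mean).
#' @return A hosts x phages numeric matrix (`NA` where unavailable).
#' @export
fitness_grid <- function(x, which = c("host", "phage"), fun = mean) {
  which <- match.arg(which)
  df <- x[[which]]
  out <- matrix(NA_real_, length(x$hosts), length(x$phages),
                dimnames = list(x$hosts, x$phages))
  if (nrow(df) > 0L) {
    agg <- tapply(df$fitness, list(df$host_id, df$phage_id), fun)
    out[rownames(agg), colnames(agg)] <- agg
  }
  out
}
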