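#' Site-status substitution process parameters
#'
#' Ground-truth generator for the mutation-accumulation estimators. New
#' mutant sites arise as Poisson events at
#' `rate_per_base_per_generation * genome_length` (scaled per gene by
#' `gene_rate_multipliers`); each site is observed as polymorphic while
#' within `polymorphic_dwell` generations of its origin, then either fixes
#' or reverts to absent with probability `reversion_prob`.
#'
#' @param rate_per_base_per_generation substitution rate (>= 0).
#' @param polymorphic_dwell generations a new site spends polymorphic
#'   before resolving.
#' @param reversion_prob probability a polymorphic site reverts instead of
#'   fixing, in `[0, 1]`.
#' @param gene_rate_multipliers named numeric vector of per-gene relative
#'   rates (genes absent from the vector, and intergenic bases, have
#'   multiplier 1).
#' @param seed integer seed.
#' @return A list of class `substitution_process_params`.
#' @export
substitution_process_params <- function(rate_per_base_per_generation,
                                        polymorphic_dwell = 0,
                                        reversion_prob = 0,
                                        gene_rate_multipliers = numeric(),
                                        seed = 1L) {
  if (rate_per_base_per_generation < 0) {
    coevo_stop("rate must be >= 0", "coevo_parameter_error")
  }
  if (reversion_prob < 0 || reversion_prob > 1) {
    coevo_stop("reversion_prob must be in [0, 1]", "coevo_parameter_error")
  }
  if (any(gene_rate_multipliers < 0)) {
    coevo_stop("gene multipliers must be >= 0", "coevo_parameter_error")
  }
  structure(
    list(rate_per_base_per_generation = rate_per_base_per_generation,
         polymorphic_dwell = polymorphic_dwell,
         reversion_prob = reversion_prob,
         gene_rate_multipliers = gene_rate_multipliers,
         seed = as.integer(seed)),
    class = "substitution_process_params"
  )
}

per_base_multipliers <- function(annotation, gene_rate_multipliers) {
  mult <- rep(1, annotation$genome_length)
  for (g in names(gene_rate_multipliers)) {
    row <- annotation$genes[annotation$genes$name == g, ]
    if (nrow(row) == 0L) {
      coevo_stop(sprintf("gene '%s' not in annotation", g), "coevo_lookup_error")
    }
    for (i in seq_len(nrow(row))) {
      mult[row$start[i]:row$end[i]] <- gene_rate_multipliers[[g]]
    }
  }
  mult
}

#' Simulate a mutation-status history
#'
#' Draws mutant sites along a lineage and reports their statuses at the
#' requested sampling generations as a [mutation_status_matrix()] (one
#' lineage, ancestral population first, all-ancestral). Sites that are
#' absent at every sampled generation are dropped, mirroring the fact that
#' only observed mutations enter a real sequencing table.
#'
#' @param sub a [substitution_process_params()].
#' @param annotation a [genome_annotation()]; supplies the genome length,
#'   gene map, and (when present) the ancestral base at each site.
#' @param sampling_generations strictly increasing positive generation
#'   numbers at which populations are sequenced.
#' @param seed optional integer overriding `sub$seed`.
#' @return A [mutation_status_matrix()] whose populations are `Anc`
#'   (generation 0) and one `G<generation>` column per sampling point,
#'   all in lineage `"1"`. Attribute `genome_length` is set.
#' @export
simulate_mutation_history <- function(sub, annotation, sampling_generations,
                                      seed = NULL) {
  gens <- as.numeric(sampling_generations)
  if (length(gens) < 1L || any(gens <= 0) || is.unsorted(gens, strictly = TRUE)) {
    coevo_stop("sampling_generations must be strictly increasing and positive",
               "coevo_parameter_error")
  }
  seed <- if (is.null(seed)) sub$seed else as.integer(seed)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  L <- annotation$genome_length
  mult <- per_base_multipliers(annotation, sub$gene_rate_multipliers)
  g_max <- max(gens)
  n_events <- rpois(1L, sub$rate_per_base_per_generation * sum(mult) * g_max)
  n_events <- min(n_events, L)  # at most one observed mutation per site
  pops <- tibble::tibble(
    population_id = c("Anc", paste0("G", gens)),
    generation = c(0, gens),
    lineages = "1"
  )
  if (n_events == 0L) {
    empty_sites <- tibble::tibble(genome_position = integer(),
                                  ancestral_nt = character(),
                                  evolved_nt = character())
    m <- mutation_status_matrix(
      empty_sites, pops,
      matrix(character(), 0L, nrow(pops),
             dimnames = list(NULL, pops$population_id)))
    attr(m, "genome_length") <- L
    return(m)
  }
  positions <- sort(sample.int(L, n_events, prob = mult))
  origin <- runif(n_events, 0, g_max)
  reverts <- runif(n_events) < sub$reversion_prob
  status_at <- function(gen) {
    s <- rep("absent", n_events)
    poly <- origin <= gen & gen < origin + sub$polymorphic_dwell
    resolved <- gen >= origin + sub$polymorphic_dwell
    s[poly] <- "polymorphic"
    s[resolved & !reverts] <- "fixed"
    s  # resolved & reverts stay "absent"
  }
  status <- cbind(Anc = rep("absent", n_events),
                  vapply(gens, status_at, character(n_events)))
  colnames(status) <- pops$population_id
  seen <- rowSums(status != "absent") > 0
  positions <- positions[seen]
  status <- status[seen, , drop = FALSE]

  anc <- if (!is.null(annotation$reference_sequence)) {
    vapply(positions, function(p)
      substr(annotation$reference_sequence, p, p), character(1L))
  } else {
    sample(c("A", "C", "G", "U"), length(positions), replace = TRUE)
  }
  evo <- vapply(anc, function(a)
    sample(setdiff(c("A", "C", "G", "U"), chartr("T", "U", a)), 1L),
    character(1L))
  m <- mutation_status_matrix(
    tibble::tibble(genome_position = positions, ancestral_nt = anc,
                   evolved_nt = unname(evo)),
    pops, status)
  attr(m, "genome_length") <- L
  m
}
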