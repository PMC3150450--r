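#' Weight of a site status
#'
#' The polymorphism weighting used throughout the mutation-accumulation
#' calculus: an absent mutation counts 0, a polymorphic (segregating) site
#' counts 0.5, and a fixed site counts 1.
#'
#' @param status character vector over
#'   `c("absent", "polymorphic", "fixed")`.
#' @return Numeric weights in `{0, 0.5, 1}`.
#' @export
status_weight <- function(status) {
  w <- c(absent = 0, polymorphic = 0.5, fixed = 1)[status]
  if (anyNA(w)) coevo_stop("invalid status", "coevo_domain_error")
  unname(w)
}

lineage_populations <- function(matrix, lineage_id) {
  lineage_id <- as.character(lineage_id)
  pops <- matrix$lineages[[lineage_id]]
  if (is.null(pops)) {
    coevo_stop(sprintf("lineage '%s' not found", lineage_id), "coevo_lookup_error")
  }
  pops
}

#' Cumulative weighted mutation series along a lineage
#'
#' Between consecutive sequenced populations of a lineage the change at
#' each site contributes the absolute difference of its weights
#' (`|Δweight|`, weights 0 / 0.5 / 1 for absent / polymorphic / fixed), so
#' a mutation that appears, fixes, and later reverts is counted on both
#' legs. The ancestral population is the first state; a site already
#' polymorphic in the ancestor starts at weight 0.5.
#'
#' @param matrix a [mutation_status_matrix()].
#' @param lineage_id lineage label present in `matrix$lineages`.
#' @return A list of class `cumulative_mutation_series`: `lineage_id`,
#'   `series` (tibble `population_id`, `generation`, `increment`,
#'   `cumulative`, with the ancestor at increment 0), and `ledger`
#'   (tibble `genome_position`, `from`, `to`, `increment` for every
#'   non-zero per-site increment).
#' @export
cumulative_mutation_series <- function(matrix, lineage_id) {
  pops <- lineage_populations(matrix, lineage_id)
  w <- matrix(status_weight(matrix$status[, pops, drop = FALSE]),
              nrow = nrow(matrix$sites),
              dimnames = list(rownames(matrix$status), pops))
  increments <- numeric(length(pops))
  ledger <- list()
  for (j in seq_along(pops)[-1L]) {
    delta <- abs(w[, j] - w[, j - 1L])
    increments[j] <- sum(delta)
    hit <- which(delta > 0)
    if (length(hit) > 0L) {
      ledger[[length(ledger) + 1L]] <- tibble::tibble(
        genome_position = matrix$sites$genome_position[hit],
        from = pops[j - 1L], to = pops[j], increment = delta[hit]
      )
    }
  }
  gen <- matrix$populations$generation[match(pops, matrix$populations$population_id)]
  structure(
    list(
      lineage_id = as.character(lineage_id),
      series = tibble::tibble(population_id = pops, generation = gen,
                              increment = increments,
                              cumulative = cumsum(increments)),
      ledger = if (length(ledger)) do.call(rbind, ledger) else
        tibble::tibble(genome_position = integer(), from = character(),
                       to = character(), increment = numeric())
    ),
    class = "cumulative_mutation_series"
  )
}

#' @export
print.cumulative_mutation_series <- function(x, ...) {
  cat(sprintf("<cumulative_mutation_series> lineage %s: %.1f weighted mutations over %g generations\n",
              x$lineage_id, tail(x$series$cumulative, 1L),
              tail(x$series$generation, 1L)))
  print(x$series)
  invisible(x)
}

#' Mutation fixation rate from a weighted count and its exposure
#'
#' `rate = count / (genome_length * generations)`, in mutations per base
#' per replication generation.
#'
#' @param count weighted mutation count (>= 0).
#' @param genome_length bases (> 0).
#' @param generations replication generations (> 0).
#' @return A list of class `rate_estimate`: `rate`, `count`,
#'   `genome_length`, `generations`.
#' @examples
#' fixation_rate(2, 4.73e6, 163)$rate  # 2.59e-9 per bp per generation
#' @export
fixation_rate <- function(count, genome_length, generations) {
  if (count < 0) coevo_stop("count must be >= 0", "coevo_domain_error")
  if (genome_length <= 0 || generations <= 0) {
    coevo_stop("exposure (genome_length x generations) must be positive",
               "coevo_domain_error")
  }
  structure(
    list(rate = count / (genome_length * generations), count = count,
         genome_length = genome_length, generations = generations),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> %.3g per base per generation (%g mutations / %g bases / %g generations)\n",
              x$rate, x$count, x$genome_length, x$generations))
  invisible(x)
}

#' Per-lineage fixation rates, group summaries, and rate ratio
#'
#' For each lineage: the final cumulative weighted mutation count (from
#' [cumulative_mutation_series()]) divided by the genome length and the
#' lineage's final generation total. Groups (e.g. copropagation vs
#' phage-only propagation) are summarised by mean and sample SD, and the
#' ratio of the two group means is reported.
#'
#' @param matrix a [mutation_status_matrix()].
#' @param groups named list of two character vectors of lineage ids,
#'   e.g. `list(copropagation = c("1","2"), phage_only = c("3","4"))`.
#' @param genome_length bases (default 4217).
#' @param generations optional named vector of per-lineage generation
#'   totals; defaults to the generation stamp of each lineage's last
#'   sequenced population.
#' @return A list of class `lineage_rate_summary`: `lines` (tibble with
#'   lineage, group, count, generations, rate), `groups` (tibble with
#'   group, n, mean, sd), and `ratio` (first group mean over second;
#'   `NA` with a warning when the second mean is 0).
#' @export
lineage_rate_summary <- function(matrix, groups,
                                 genome_length = matrix_genome_length(matrix),
                                 generations = NULL) {
  if (length(groups) != 2L) coevo_stop("need exactly 2 groups", "coevo_data_error")
  if (any(lengths(groups) < 1L)) coevo_stop("empty group", "coevo_data_error")
  if (is.null(generations)) generations <- lineage_final_generations(matrix)
  lines <- do.call(rbind, lapply(names(groups), function(gname) {
    do.call(rbind, lapply(groups[[gname]], function(lin) {
      cms <- cumulative_mutation_series(matrix, lin)
      count <- tail(cms$series$cumulative, 1L)
      gen <- generations[[as.character(lin)]]
      tibble::tibble(lineage = as.character(lin), group = gname,
                     count = count, generations = gen,
                     rate = fixation_rate(count, genome_length, gen)$rate)
    }))
  }))
  grp <- do.call(rbind, lapply(names(groups), function(gname) {
    r <- lines$rate[lines$group == gname]
    tibble::tibble(group = gname, n = length(r), mean = mean(r),
                   sd = if (length(r) >= 2L) sd(r) else NA_real_)
  }))
  ratio <- if (grp$mean[2L] == 0) {
    warning("second group mean rate is 0; ratio undefined")
    NA_real_
  } else grp$mean[1L] / grp$mean[2L]
  structure(list(lines = lines, groups = grp, ratio = ratio,
                 genome_length = genome_length),
            class = "lineage_rate_summary")
}

matrix_genome_length <- function(matrix) {
  attr(matrix, "genome_length") %||% 4217L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lineage_rate_summary <- function(x, ...) {
  print(x$lines)
  print(x$groups)
  cat(sprintf("rate ratio (%s / %s) = %.3g\n",
              x$groups$group[1L], x$groups$group[2L], x$ratio))
  invisible(x)
}

#' Welch's t test between two groups of per-lineage rates
#'
#' @param group_a,group_b numeric rate vectors (>= 2 each).
#' @return List with `t`, `df`, `p_value` (see [welch_t()]).
#' @export
rate_welch_t <- function(group_a, group_b) {
  welch_t(group_a, group_b)
}

#' Exact binomial test for gene-level mutation bias
#'
#' Tallies the weighted mutation count at sites inside a gene against the
#' total weighted count, and tests the in-gene fraction against the gene's
#' length fraction of the genome with the exact two-tailed binomial test.
#' Two tallies are available: `"cumulative"` (default) sums the
#' `|Δweight|` increments of [cumulative_mutation_series()] over the given
#' lineages, matching the convention of the cumulative-accumulation
#' analysis; `"final"` sums the status weights of each lineage's final
#' sequenced population. Half-integer weighted counts are doubled to
#' integers for the exact test (weights in {0, 0.5, 1} guarantee
#' integrality after doubling), preserving the observed fraction;
#' `half_integer = "round"` rounds instead.
#'
#' @param matrix a [mutation_status_matrix()].
#' @param annotation a [genome_annotation()] containing the gene.
#' @param gene_name gene to test.
#' @param lineages lineage ids entering the tally (default: all).
#' @param tally `"cumulative"` or `"final"`.
#' @param half_integer `"double"` (default) or `"round"`.
#' @return A list of class `gene_bias_result`: `k_in_gene`, `n_total`
#'   (weighted), `fraction`, `p0` (gene length fraction), `k`, `n` (the
#'   integers tested), `p_value`.
#' @export
gene_bias_binomial <- function(matrix, annotation, gene_name,
                               lineages = names(matrix$lineages),
                               tally = c("cumulative", "final"),
                               half_integer = c("double", "round")) {
  tally <- match.arg(tally)
  half_integer <- match.arg(half_integer)
  g <- annotation$genes[annotation$genes$name == gene_name, ]
  if (nrow(g) != 1L) {
    coevo_stop(sprintf("gene '%s' not in annotation", gene_name),
               "coevo_lookup_error")
  }
  in_gene <- matrix$sites$genome_position >= g$start &
    matrix$sites$genome_position <= g$end
  if (tally == "cumulative") {
    per_site <- numeric(nrow(matrix$sites))
    names(per_site) <- as.character(matrix$sites$genome_position)
    for (lin in lineages) {
      led <- cumulative_mutation_series(matrix, lin)$ledger
      if (nrow(led) > 0L) {
        inc <- tapply(led$increment, as.character(led$genome_position), sum)
        per_site[names(inc)] <- per_site[names(inc)] + inc
      }
    }
  } else {
    finals <- vapply(lineages, function(lin) {
      pops <- lineage_populations(matrix, lin)
      pops[length(pops)]
    }, character(1L))
    per_site <- rowSums(matrix(
      status_weight(matrix$status[, finals, drop = FALSE]),
      nrow = nrow(matrix$sites)))
  }
  k_w <- sum(per_site[in_gene])
  n_w <- sum(per_site)
  if (n_w == 0) {
    warning("total weighted count is 0; test undefined")
    return(structure(list(k_in_gene = 0, n_total = 0, fraction = NA_real_,
                          p0 = (g$end - g$start + 1) / annotation$genome_length,
                          k = 0L, n = 0L, p_value = NA_real_),
                     class = "gene_bias_result"))
  }
  p0 <- (g$end - g$start + 1) / annotation$genome_length
  if (half_integer == "double") {
    k <- as.integer(round(2 * k_w)); n <- as.integer(round(2 * n_w))
  } else {
    # half-up rounding, so .5 counts never vanish by round-half-even
    k <- as.integer(floor(k_w + 0.5)); n <- as.integer(floor(n_w + 0.5))
  }
  structure(
    list(k_in_gene = k_w, n_total = n_w, fraction = k_w / n_w, p0 = p0,
         k = k, n = n, p_value = binomial_two_tailed(k, n, p0)),
    class = "gene_bias_result"
  )
}

#' @export
print.gene_bias_result <- function(x, ...) {
  cat(sprintf("gene bias: %.1f of %.1f weighted mutations in gene (%.1f%%) vs length fraction %.2f%%; exact binomial p = %.4g\n",
              x$k_in_gene, x$n_total, 100 * x$fraction, 100 * x$p0, x$p_value))
  invisible(x)
}

GENETIC_CODE_RNA <- {
  codes <- Biostrings::GENETIC_CODE
  names(codes) <- chartr("T", "U", names(codes))
  codes
}

AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
              `*` = "Stop")

translate_codon <- function(codon) {
  aa <- GENETIC_CODE_RNA[[chartr("T", "U", codon)]]
  if (is.null(aa)) coevo_stop(sprintf("cannot translate codon %s", codon),
                              "coevo_domain_error")
  aa
}

# alternative initiation codons still decoded as fMet at gene starts
INITIATOR_CODONS <- c("AUG", "GUG", "UUG", "AUU", "AUA", "CUG")

#' Annotate a point mutation against the genome annotation
#'
#' Maps a genome position into every overlapping gene (read-through genes
#' yield one record each), computes the 1-based gene position
#' (`genome_position - gene_start + 1`), codon index
#' (`ceiling(gene_position / 3)`), the codon change, and the amino-acid
#' change by translating the ancestral and mutant codons. A start-codon
#' substitution to an alternative initiator (e.g. AUG to GUG) is classed
#' synonymous with change `Met→Met`, since initiation still delivers
#' fMet. Positions outside every gene are untranslated regions (UTR).
#'
#' @param genome_position 1-based position.
#' @param ancestral_nt,evolved_nt single bases (RNA alphabet; DNA `T` is
#'   accepted and treated as `U`).
#' @param annotation a [genome_annotation()] with a reference sequence.
#' @return A tibble with one row per overlapping gene (or one UTR row):
#'   `genome_position`, `region`, `gene_position`, `codon_index`,
#'   `codon_change`, `amino_acid_change`, `class`
#'   (`"synonymous"`/`"nonsynonymous"`/`"UTR"`).
#' @export
annotate_mutation <- function(genome_position, ancestral_nt, evolved_nt,
                              annotation) {
  if (is.null(annotation$reference_sequence)) {
    coevo_stop("annotation has no reference sequence; codon annotation unavailable",
               "coevo_data_error")
  }
  pos <- as.integer(genome_position)
  if (pos < 1L || pos > annotation$genome_length) {
    coevo_stop("position outside the genome", "coevo_domain_error")
  }
  norm <- function(nt) chartr("Tt", "Uu", toupper(nt))
  ancestral_nt <- norm(ancestral_nt)
  evolved_nt <- norm(evolved_nt)
  ref <- annotation$reference_sequence
  ref_nt <- norm(substr(ref, pos, pos))
  if (ref_nt != ancestral_nt) {
    coevo_stop(sprintf("ancestral base %s does not match reference %s at %d",
                       ancestral_nt, ref_nt, pos),
               "coevo_consistency_error")
  }
  genes <- annotation$genes
  hits <- which(genes$start <= pos & genes$end >= pos)
  if (length(hits) == 0L) {
    return(tibble::tibble(genome_position = pos, region = "UTR",
                          gene_position = NA_integer_, codon_index = NA_integer_,
                          codon_change = NA_character_,
                          amino_acid_change = NA_character_, class = "UTR"))
  }
  do.call(rbind, lapply(hits, function(i) {
    start <- genes$start[i]
    gene_pos <- pos - start + 1L
    codon_index <- ceiling(gene_pos / 3)
    codon_start <- start + 3L * (codon_index - 1L)
    codon <- norm(substr(ref, codon_start, codon_start + 2L))
    offset <- gene_pos - 3L * (codon_index - 1L)
    mutant <- codon
    substr(mutant, offset, offset) <- evolved_nt
    aa_anc <- translate_codon(codon)
    aa_mut <- translate_codon(mutant)
    if (codon_index == 1L && codon == "AUG" && mutant %in% INITIATOR_CODONS) {
      aa_mut <- "M"  # alternative start codon, still initiates with fMet
    }
    cls <- if (aa_anc == aa_mut) "synonymous" else "nonsynonymous"
    tibble::tibble(
      genome_position = pos, region = genes$name[i], gene_position = gene_pos,
      codon_index = codon_index,
      codon_change = paste0(codon, "→", mutant),
      amino_acid_change = paste0(AA_THREE[[aa_anc]], "→", AA_THREE[[aa_mut]]),
      class = cls
    )
  }))
}

#' Annotate every site of a mutation status matrix
#'
#' @param matrix a [mutation_status_matrix()].
#' @param annotation a [genome_annotation()] with a reference sequence.
#' @return A tibble with one row per site x overlapping gene (UTR sites
#'   give one row), columns as in [annotate_mutation()] plus
#'   `ancestral_nt`, `evolved_nt`.
#' @export
annotate_matrix <- function(matrix, annotation) {
  out <- do.call(rbind, lapply(seq_len(nrow(matrix$sites)), function(i) {
    s <- matrix$sites[i, ]
    ann <- annotate_mutation(s$genome_position, s$ancestral_nt, s$evolved_nt,
                             annotation)
    ann$ancestral_nt <- s$ancestral_nt
    ann$evolved_nt <- s$evolved_nt
    ann
  }))
  out
}

#' Upper-tail Poisson test for an observed mutation count
#'
#' Under a reference substitution rate, the expected count over the
#' exposure is `lambda = reference_rate * genome_length * generations`;
#' the p-value is `P(X >= observed)` for `X ~ Poisson(lambda)`.
#'
#' @param observed_count observed (integer) mutation count.
#' @param genome_length bases.
#' @param generations replication generations.
#' @param reference_rate per base per generation.
#' @return List with `lambda` and `p_value`.
#' @export
poisson_rate_test <- function(observed_count, genome_length, generations,
                              reference_rate) {
  if (genome_length <= 0 || generations <= 0 || reference_rate < 0) {
    coevo_stop("exposure and rate must be positive", "coevo_domain_error")
  }
  lambda <- reference_rate * genome_length * generations
  p <- ppois(observed_count - 1L, lambda, lower.tail = FALSE)
  list(lambda = lambda, p_value = p)
}

#' Bottleneck effective population size
#'
#' The per-passage bottleneck approximates Ne in a serial-transfer
#' experiment: the number of phage that actually found the next burst,
#' `initial_phage_count * infecting_fraction`.
#'
#' @param initial_phage_count phage entering the passage.
#' @param infecting_fraction fraction in (0, 1] that infect and burst.
#' @return A list of class `ne_estimate`: `initial_phage_count`,
#'   `infecting_fraction`, `bottleneck_size`.
#' @export
bottleneck_ne <- function(initial_phage_count, infecting_fraction) {
  if (infecting_fraction <= 0 || infecting_fraction > 1) {
    coevo_stop("infecting_fraction must be in (0, 1]", "coevo_domain_error")
  }
  structure(
    list(initial_phage_count = initial_phage_count,
         infecting_fraction = infecting_fraction,
         bottleneck_size = initial_phage_count * infecting_fraction),
    class = "ne_estimate"
  )
}
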