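#' Bundled Qβ study fixtures
#'
#' The package ships a transcription of the published site-status table for
#' the eight sequenced Qβ populations (two copropagation lineages, lines 1
#' and 2, sampled at replication generations 54, 109, 163, and 165; two
#' phage-only propagation lineages, lines 3 and 4, sampled at generations
#' 94, 169, and 168; plus the deposited reference sequence column), the
#' gene coordinate map of the 4,217-base genome, and a synthetic reference
#' sequence that embeds the published codon contexts at every mutated site.
#'
#' @name qbeta-fixtures
NULL

qbeta_extdata <- function(file) {
  system.file("extdata", file, package = "coevo", mustWork = TRUE)
}

#' Qβ mutation status matrix (published-table transcription)
#'
#' @return A [mutation_status_matrix()] with 14 sites and 9 population
#'   columns (the deposited NCBI sequence plus the ancestor and seven
#'   evolved populations across four lineages).
#' @export
qbeta_mutation_matrix <- function() {
  read_mutation_matrix(qbeta_extdata("qbeta_mutation_status.tsv"),
                       qbeta_extdata("qbeta_populations.tsv"))
}

#' Qβ genome annotation
#'
#' Gene coordinates inferred from the published gene-position offsets
#' (1-based, inclusive): A2 at 61-1323, coat at 1344-1742, the read-through
#' A1 at 1344-2333 sharing the coat start codon, and the replicase at
#' 2352-4118. The A2 CDS covers 1263/4217 = 29.95% of the genome.
#'
#' @param with_reference attach the synthetic reference sequence (needed
#'   for codon annotation).
#' @return A [genome_annotation()].
#' @export
qbeta_annotation <- function(with_reference = TRUE) {
  ann <- read_genome_annotation(qbeta_extdata("qbeta_gene_map.tsv"),
                                genome_length = 4217L)
  if (with_reference) {
    ann <- genome_annotation(ann$genome_length, ann$genes,
                             qbeta_synthetic_reference())
  }
  ann
}

#' Synthetic Qβ reference sequence
#'
#' A 4,217-base RNA sequence for exercising codon annotation. This is NOT
#' the deposited Qβ genome: the background is pseudo-random (fixed
#' internal seed), with the published codon context embedded at every site
#' of the bundled mutation table (ancestral codons, start and stop codons
#' of the four genes, and the coat read-through UGA stop), so that codon
#' and amino-acid annotation of those sites reproduces the published calls.
#'
#' @return A single character string over the RNA alphabet `ACGU`.
#' @export
qbeta_synthetic_reference <- function() {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(4217L)
  seq <- sample(c("A", "C", "G", "U"), 4217L, replace = TRUE)

  put <- function(pos, codon) {
    seq[pos:(pos + nchar(codon) - 1L)] <<- strsplit(codon, "")[[1L]]
  }
  # untranslated-region sites
  put(47L, "G")
  put(52L, "A")
  # A2 (start 61): start/stop codons and the ancestral codons of the
  # mutated sites (codon i occupies start + 3*(i-1) .. start + 3*i - 1)
  put(61L, "AUG");  put(1321L, "UAA")
  put(64L, "CCU");  put(220L, "CUA");  put(517L, "GAA"); put(568L, "GGG")
  put(787L, "GGC"); put(829L, "GUU");  put(1255L, "ACC"); put(1288L, "AGU")
  # coat / read-through A1 (shared start 1344); the coat stop is the
  # leaky UGA read through into A1
  put(1344L, "AUG"); put(1740L, "UGA"); put(2331L, "UAA")
  put(1371L, "GGU"); put(1794L, "AUU"); put(2247L, "AGC")
  # replicase
  put(2352L, "AUG"); put(4116L, "UAA")
  paste(seq, collapse = "")
}

#' Lineage groupings and generation totals of the Qβ study design
#'
#' @return `qbeta_lineage_groups()`: a named list with the copropagation
#'   lineage ids (`"1"`, `"2"`) and the phage-only propagation lineage ids
#'   (`"3"`, `"4"`).
#' @export
qbeta_lineage_groups <- function() {
  list(copropagation = c("1", "2"), phage_only = c("3", "4"))
}

#' Final replication-generation totals per lineage
#'
#' @param matrix a [mutation_status_matrix()]; defaults to the bundled one.
#' @return Named numeric vector: the generation stamp of the last sequenced
#'   population of each lineage.
#' @rdname qbeta_lineage_groups
#' @export
lineage_final_generations <- function(matrix = qbeta_mutation_matrix()) {
  vapply(matrix$lineages, function(pops) {
    gens <- matrix$populations$generation[match(pops, matrix$populations$population_id)]
    max(gens)
  }, numeric(1L))
}
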