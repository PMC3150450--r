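test_that("status weights implement the 0 / 0.5 / 1 convention", {
  expect_equal(status_weight("fixed"), 1)
  expect_equal(status_weight("polymorphic"), 0.5)
  expect_equal(status_weight("absent"), 0)
  expect_error(status_weight("weird"), class = "coevo_domain_error")
})

single_site_matrix <- function(statuses, gens = seq(0, by = 50, length.out = length(statuses))) {
  pops <- tibble::tibble(
    population_id = c("Anc", paste0("t", seq_along(statuses[-1]))),
    generation = gens, lineages = "L"
  )
  mutation_status_matrix(
    tibble::tibble(genome_position = 100L, ancestral_nt = "A", evolved_nt = "G"),
    pops, matrix(statuses, nrow = 1)
  )
}

test_that("cumulative counting reproduces the worked single-site trajectories", {
  # appear (1), de-fix (0.5), disappear (0.5): the four-population worked case
  m <- single_site_matrix(c("absent", "fixed", "polymorphic", "absent"))
  s <- cumulative_mutation_series(m, "L")
  expect_equal(s$series$increment, c(0, 1, 0.5, 0.5))
  expect_equal(s$series$cumulative, c(0, 1, 1.5, 2.0))

  # appear (1) then de-fix (0.5): the three-population worked case
  m2 <- single_site_matrix(c("absent", "fixed", "polymorphic"))
  expect_equal(cumulative_mutation_series(m2, "L")$series$cumulative, c(0, 1, 1.5))

  # an ancestrally polymorphic site contributes 0.5 when it fixes
  m3 <- single_site_matrix(c("polymorphic", "fixed", "fixed"))
  expect_equal(cumulative_mutation_series(m3, "L")$series$cumulative, c(0, 0.5, 0.5))

  m4 <- single_site_matrix(c("absent", "absent", "absent"))
  expect_equal(cumulative_mutation_series(m4, "L")$series$cumulative, c(0, 0, 0))

  expect_error(cumulative_mutation_series(m4, "nope"), class = "coevo_lookup_error")
})

test_that("cumulative series are non-decreasing, additive, and order-invariant", {
  m <- qbeta_mutation_matrix()
  for (lin in names(m$lineages)) {
    s <- cumulative_mutation_series(m, lin)$series
    expect_true(all(diff(s$cumulative) >= 0))
    expect_equal(s$cumulative, cumsum(s$increment))
  }
  # permuting site order leaves the totals unchanged
  perm <- sample.int(nrow(m$sites))
  m_perm <- mutation_status_matrix(m$sites[perm, ], m$populations,
                                   m$status[perm, ])
  for (lin in names(m$lineages)) {
    expect_equal(cumulative_mutation_series(m_perm, lin)$series$cumulative,
                 cumulative_mutation_series(m, lin)$series$cumulative)
  }
})

test_that("the bundled table yields the published per-line counts", {
  m <- qbeta_mutation_matrix()
  finals <- vapply(c("1", "2", "3", "4"), function(lin)
    tail(cumulative_mutation_series(m, lin)$series$cumulative, 1), numeric(1))
  expect_equal(unname(finals), c(7.5, 7.0, 2.0, 2.5))
})

test_that("fixation rate is count over exposure", {
  expect_equal(fixation_rate(2, 4.73e6, 163)$rate, 2 / (4.73e6 * 163))
  expect_equal(signif(fixation_rate(2, 4.73e6, 163)$rate, 2), 2.6e-9)
  expect_equal(fixation_rate(0, 4217, 163)$rate, 0)
  expect_equal(signif(fixation_rate(7.5, 4217, 163)$rate, 3), 1.09e-5)
  expect_error(fixation_rate(2, 0, 163), class = "coevo_domain_error")
})

test_that("lineage rate summaries aggregate counts, SDs, and the group ratio", {
  m <- qbeta_mutation_matrix()
  summ <- lineage_rate_summary(m, qbeta_lineage_groups())
  expect_equal(summ$lines$count, c(7.5, 7.0, 2.0, 2.5))
  expect_equal(signif(summ$groups$mean, 2), c(1.0e-5, 3.2e-6))
  expect_equal(signif(summ$groups$sd, 2), c(6.0e-7, 5.1e-7))
  expect_equal(summ$ratio, summ$groups$mean[1] / summ$groups$mean[2])

  # identical counts give SD exactly 0
  pops <- tibble::tibble(population_id = c("Anc", "e1"), generation = c(0, 100),
                         lineages = c("a,b", "a,b"))
  sites <- tibble::tibble(genome_position = 1L, ancestral_nt = "A", evolved_nt = "G")
  twin <- mutation_status_matrix(sites, pops, matrix(c("absent", "fixed"), 1))
  s2 <- lineage_rate_summary(twin, list(g1 = "a", g2 = "b"),
                             genome_length = 1000)
  expect_equal(s2$groups$sd, c(NA_real_, NA_real_))  # single line per group
  twin2 <- lineage_rate_summary(twin, list(g1 = c("a", "b"), g2 = c("a", "b")),
                                genome_length = 1000)
  expect_equal(twin2$groups$sd, c(0, 0))

  # a mutation-free comparison group leaves the ratio undefined
  none <- mutation_status_matrix(sites, pops, matrix(c("absent", "absent"), 1))
  expect_warning(s3 <- lineage_rate_summary(none, list(g1 = "a", g2 = "b"),
                                            genome_length = 1000),
                 "undefined")
  expect_true(is.na(s3$ratio))
})

test_that("rate comparison matches the closed-form Welch oracle", {
  expect_equal(rate_welch_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  r <- rate_welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  a <- c(1.09e-5, 1.01e-5, 1.2e-5)
  b <- c(2.8e-6, 3.5e-6)
  o <- welch_oracle(a, b)
  r2 <- rate_welch_t(a, b)
  expect_equal(r2$t, o$t, tolerance = 1e-10)
  expect_equal(r2$df, o$df, tolerance = 1e-10)
  expect_equal(r2$p_value, o$p, tolerance = 1e-10)
})

test_that("gene bias tallies the weighted counts and doubles half-integers", {
  m <- qbeta_mutation_matrix()
  ann <- qbeta_annotation(with_reference = FALSE)
  bias <- gene_bias_binomial(m, ann, "A2", lineages = c("1", "2"))
  expect_equal(bias$k_in_gene, 9.5)
  expect_equal(bias$n_total, 14.5)
  expect_equal(round(100 * bias$fraction, 1), 65.5)
  expect_equal(bias$k, 19L)
  expect_equal(bias$n, 29L)
  expect_equal(bias$p0, 1263 / 4217)
  expect_lt(bias$p_value, 0.05)
  expect_equal(bias$p_value,
               binom_two_tailed_oracle(19, 29, 1263 / 4217), tolerance = 1e-12)
  # rounding mode keeps the same verdict here
  biasr <- gene_bias_binomial(m, ann, "A2", lineages = c("1", "2"),
                              half_integer = "round")
  expect_equal(biasr$k, 10L)
  expect_equal(biasr$n, 15L)  # half-up rounding of 14.5
  expect_error(gene_bias_binomial(m, ann, "nope"), class = "coevo_lookup_error")
})

test_that("annotation reproduces every printed coding row of the bundled table", {
  ann <- qbeta_annotation()
  m <- qbeta_mutation_matrix()
  out <- annotate_matrix(m, ann)
  expected <- tibble::tribble(
    ~genome_position, ~region, ~gene_position, ~codon_change, ~amino_acid_change, ~class,
    66L,   "A2",   6L,   "CCU→CCA", "Pro→Pro", "synonymous",
    221L,  "A2",   161L, "CUA→CGA", "Leu→Arg", "nonsynonymous",
    519L,  "A2",   459L, "GAA→GAG", "Glu→Glu", "synonymous",
    569L,  "A2",   509L, "GGG→GAG", "Gly→Glu", "nonsynonymous",
    789L,  "A2",   729L, "GGC→GGU", "Gly→Gly", "synonymous",
    830L,  "A2",   770L, "GUU→GCU", "Val→Ala", "nonsynonymous",
    1257L, "A2",   1197L, "ACC→ACU", "Thr→Thr", "synonymous",
    1288L, "A2",   1228L, "AGU→GGU", "Ser→Gly", "nonsynonymous",
    1344L, "coat", 1L,    "AUG→GUG", "Met→Met", "synonymous",
    1344L, "A1",   1L,    "AUG→GUG", "Met→Met", "synonymous",
    1371L, "coat", 28L,   "GGU→CGU", "Gly→Arg", "nonsynonymous",
    1371L, "A1",   28L,   "GGU→CGU", "Gly→Arg", "nonsynonymous",
    1795L, "A1",   452L,  "AUU→ACU", "Ile→Thr", "nonsynonymous",
    2249L, "A1",   906L,  "AGC→AGU", "Ser→Ser", "synonymous"
  )
  coding <- out[out$class != "UTR",
                c("genome_position", "region", "gene_position", "codon_change",
                  "amino_acid_change", "class")]
  expect_equal(as.data.frame(coding), as.data.frame(expected),
               ignore_attr = TRUE)
  # the printed amino-acid positions are the codon indices
  expect_equal(out$codon_index[out$genome_position == 569 & out$region == "A2"], 170L)
  expect_equal(out$codon_index[out$genome_position == 2249], 302L)
  # untranslated sites carry no codon fields
  utr <- out[out$class == "UTR", ]
  expect_equal(utr$genome_position, c(47L, 52L))
  expect_true(all(is.na(utr$codon_change)))
})

test_that("annotation refuses a reference mismatch", {
  ann <- qbeta_annotation()
  expect_error(annotate_mutation(569, "C", "A", ann),
               "does not match", class = "coevo_consistency_error")
})

test_that("the Poisson rate comparison has the right tail", {
  expect_equal(poisson_rate_test(0, 4.73e6, 163, 1.7e-10)$p_value, 1)
  r <- poisson_rate_test(2, 4.73e6, 163, 1.7e-10)
  lambda <- 1.7e-10 * 4.73e6 * 163
  expect_equal(r$lambda, lambda)
  expect_equal(r$p_value, 1 - exp(-lambda) * (1 + lambda), tolerance = 1e-12)
  expect_lt(r$p_value, 0.01)
  # a huge expected count makes any small observation unremarkable
  expect_equal(poisson_rate_test(2, 4.73e6, 163, 1e-3)$p_value, 1)
})

test_that("bottleneck Ne is the infecting fraction of the inoculum", {
  expect_equal(bottleneck_ne(1e6, 0.01)$bottleneck_size, 1e4)
  expect_equal(bottleneck_ne(1e5, 0.01)$bottleneck_size, 1e3)
  expect_equal(bottleneck_ne(3e6, 1)$bottleneck_size, 3e6)
  expect_error(bottleneck_ne(1e6, 0), class = "coevo_domain_error")
})
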