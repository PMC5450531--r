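# Per-gene and per-species codon statistics

test_that("codon counting skips ambiguous codons and conserves totals", {
  cts <- count_codons("ATGTTGTAA")
  expect_equal(unname(cts[c("ATG", "TTG", "TAA")]), c(1L, 1L, 1L))
  expect_equal(sum(cts), 3L)

  ctn <- count_codons("ATGNNNTTG")
  expect_equal(sum(ctn), 2L)
  expect_equal(attr(ctn, "skipped"), 1L)

  expect_error(count_codons("ATGTT"), "multiple of 3")

  sp <- generate_species(generator_spec("cons", n_genes = 40, seed = 5))
  m <- codon_count_matrix(sp$truth$orf)
  expect_equal(unname(rowSums(m) + attr(m, "skipped")),
               nchar(sp$truth$orf) / 3)
})

test_that("counts, RSCU, positional GC and GC3s match brute-force oracles", {
  set.seed(11)
  for (rep in 1:50) {
    gene <- random_gene(sample(30:120, 1),
                        alphabet = c(SENSE, "TAA", "NNA"))
    cts <- count_codons(gene)
    octs <- oracle_count_codons(gene)
    expect_equal(unname(cts), unname(octs))
    expect_equal(attr(cts, "skipped"), attr(octs, "skipped"))
    expect_equal(rscu(cts), oracle_rscu(cts))
    expect_equal(gc_by_position(cts), oracle_gc_positions(cts))
    expect_equal(gc3s(cts), oracle_gc3s(cts))
  }
})

test_that("RSCU agrees with seqinr and sums to family size", {
  # stated leucine example: TTG=2, TTA=1, rest absent
  r <- rscu(c(TTG = 2, TTA = 1))
  expect_equal(unname(r[c("TTG", "TTA", "CTT", "CTC", "CTA", "CTG")]),
               c(4, 2, 0, 0, 0, 0))
  expect_equal(sum(r[FAMS$L]), 6)
  # all six leucine codons once -> each exactly 1
  expect_equal(unname(rscu(stats::setNames(rep(1, 6), FAMS$L))[FAMS$L]),
               rep(1, 6))
  # absent family -> missing
  expect_true(all(is.na(rscu(c(TTG = 2))[FAMS$A])))

  set.seed(21)
  gene <- random_gene(400)
  mine <- rscu(count_codons(gene))
  sq <- seqinr::uco(strsplit(tolower(gene), "")[[1]], index = "rscu")
  names(sq) <- toupper(names(sq))
  common <- names(mine)[!is.na(mine)]
  expect_equal(mine[setdiff(common, c("ATG", "TGG"))],
               sq[setdiff(common, c("ATG", "TGG"))], tolerance = 1e-12)
  # normalisation property on random counts
  for (rep in 1:20) {
    r <- rscu(random_counts())
    for (aa in names(FAMS)) {
      fam <- FAMS[[aa]]
      if (length(fam) > 1 && !anyNA(r[fam]))
        expect_equal(sum(r[fam]), length(fam))
    }
  }
})

test_that("positional GC identities hold", {
  expect_equal(unname(gc_by_position(c(GCG = 5))), c(1, 1, 1, 1))
  expect_equal(unname(gc_by_position(c(ATA = 5))), c(0, 0, 0, 0))
  expect_equal(unname(gc_by_position(c(GCG = 5, ATA = 5))),
               c(0.5, 0.5, 0.5, 0.5))
  set.seed(31)
  for (rep in 1:20) {
    g <- gc_by_position(random_counts())
    expect_equal(unname(g["gc"]), mean(g[c("gc1", "gc2", "gc3")]))
  }
  expect_error(gc_by_position(stats::setNames(integer(64), ALL_CODONS)),
               "no codons")
})

test_that("GC3s follows the synonymous-site convention", {
  expect_true(is.na(gc3s(c(ATG = 10))))            # no synonymous sites
  expect_equal(gc3s(c(GCC = 3, GCA = 1)), 0.75)
  expect_equal(gc3s(c(GCC = 3, GCA = 1, ATG = 50, TGG = 50, TAA = 5)), 0.75)
})

test_that("Nc hits its anchors and respects its bounds", {
  uniform <- stats::setNames(rep(10L, 64), ALL_CODONS)
  uniform[STOPS] <- 0L
  expect_equal(effective_number_of_codons(uniform), 61)

  one <- stats::setNames(integer(64), ALL_CODONS)
  for (fam in FAMS) one[fam[1]] <- 10L
  expect_equal(effective_number_of_codons(one), 20)

  set.seed(41)
  for (rep in 1:25) {
    nc <- effective_number_of_codons(random_counts(lambda = 5))
    if (!is.na(nc)) expect_true(nc >= 20 && nc <= 61)
  }
})

test_that("Nc missing-class rules behave as documented", {
  # only single-codon amino acids observed -> undefined
  expect_true(is.na(effective_number_of_codons(c(ATG = 50, TGG = 10))))
  # a whole multi-member class unobserved -> undefined (here: no 4-fold)
  cts <- stats::setNames(integer(64), ALL_CODONS)
  for (aa in names(FAMS)) {
    fam <- FAMS[[aa]]
    if (length(fam) %in% c(2, 3, 6)) cts[fam] <- 3L
  }
  expect_true(is.na(effective_number_of_codons(cts)))
  # missing isoleucine class is interpolated from the 2- and 4-fold means
  cts2 <- stats::setNames(integer(64), ALL_CODONS)
  for (aa in names(FAMS)) {
    fam <- FAMS[[aa]]
    if (aa != "I" && length(fam) > 1) cts2[fam] <- 3L
  }
  nc2 <- effective_number_of_codons(cts2)
  expect_false(is.na(nc2))
  # oracle: per-class F for exactly-equal usage n=3*k per family
  f_of <- function(k) { n <- 3 * k; (n * (1 / k) - 1) / (n - 1) }
  f2 <- f_of(2); f4 <- f_of(4); f6 <- f_of(6); f3 <- (f2 + f4) / 2
  expect_equal(nc2, min(61, 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6))
})

test_that("CBI and Fop match direct arithmetic", {
  opt <- c("GCC", "TTG", "AAC")   # Ala, Leu, Asn
  # all codons optimal
  allopt <- c(GCC = 10, TTG = 5, AAC = 5)
  expect_equal(codon_bias_index(allopt, opt), 1)
  expect_equal(frequency_optimal_codons(allopt, opt), 1)
  # uniform synonymous usage -> CBI ~ 0, Fop = usage-weighted 1/k
  unif <- stats::setNames(integer(64), ALL_CODONS)
  unif[FAMS$A] <- 6L; unif[FAMS$L] <- 4L; unif[FAMS$N] <- 12L
  expect_equal(codon_bias_index(unif, opt), 0)
  expect_equal(frequency_optimal_codons(unif, opt),
               (6 + 4 + 12) / (24 + 24 + 24))
  # toy gene against hand arithmetic
  cts <- c(GCC = 7, GCA = 3, TTG = 1, CTT = 4, AAC = 5)
  n_opt <- 7 + 1 + 5
  n_tot <- 10 + 5 + 5
  n_ran <- 10 / 4 + 5 / 6 + 5 / 2
  expect_equal(codon_bias_index(cts, opt),
               (n_opt - n_ran) / (n_tot - n_ran))
  expect_equal(frequency_optimal_codons(cts, opt), n_opt / n_tot)
  # no usage of any amino acid with an optimal codon -> undefined
  expect_true(is.na(codon_bias_index(c(GGG = 5), "GCC")))
  expect_true(is.na(frequency_optimal_codons(c(GGG = 5), "GCC")))
  expect_error(codon_bias_index(cts, c("GCC", "GCA")), "more than one")
  expect_error(codon_bias_index(cts, character(0)), "empty")
})

test_that("optimal-codon inference recovers planted preferences", {
  # two planted populations: sharply biased high-GC genes vs neutral ones
  biased <- generate_species(generator_spec(
    "hi", n_genes = 150, theta_gc3 = 0.85, theta_gc3_sd = 0.02,
    preference_concentration = 0.4, contamination_fraction = 0,
    seed = 91))
  neutral <- generate_species(generator_spec(
    "lo", n_genes = 150, theta_gc3 = 0.5, theta_gc3_sd = 0.02,
    preference_concentration = 50, contamination_fraction = 0,
    seed = 92))
  seqs <- c(stats::setNames(biased$truth$orf, paste0("b", 1:150)),
            stats::setNames(neutral$truth$orf, paste0("n", 1:150)))
  m <- codon_count_matrix(seqs)
  ca <- codon_ca(m[, genetic_code()$variable_codons], n_axes = 2)
  opt <- determine_optimal_codons(m, ca, quantile = 0.1)
  expect_true(nrow(opt) > 0)
  expect_false(anyDuplicated(opt$amino_acid) > 0)
  # recovered codons should match the biased generator's preferred set
  # for at least 90% of the 4- and 6-fold families it reports
  pref <- stats::setNames(biased$preferred$codon, biased$preferred$amino_acid)
  big <- opt$amino_acid[lengths(FAMS[opt$amino_acid]) >= 4]
  expect_gte(length(big), 6)
  agree <- mean(stats::setNames(opt$codon, opt$amino_acid)[big] == pref[big])
  expect_gte(agree, 0.9)
  # a homogeneous neutral population yields far fewer candidates than a
  # structured one (selecting CA extremes induces some self-selection,
  # so "empty" is only approached, never guaranteed)
  mn <- codon_count_matrix(stats::setNames(neutral$truth$orf,
                                           paste0("n", 1:150)))
  can <- codon_ca(mn[, genetic_code()$variable_codons], n_axes = 2)
  optn <- determine_optimal_codons(mn, can, quantile = 0.1)
  expect_lt(nrow(optn), nrow(opt) / 2)
  expect_lte(nrow(optn), 8)
  # two exactly identical groups: no codon can be significant
  ident <- m[rep(1, 100), , drop = FALSE] + 1L
  rownames(ident) <- paste0("i", 1:100)
  cai <- codon_ca(ident[, genetic_code()$variable_codons], n_axes = 2)
  expect_equal(nrow(determine_optimal_codons(ident, cai, quantile = 0.1)),
               0)
  expect_error(determine_optimal_codons(m, ca, quantile = 0.01),
               "at least 10")
})

test_that("species summaries aggregate per-gene indices correctly", {
  sp <- generate_species(generator_spec("agg", n_genes = 30, seed = 71))
  m <- codon_count_matrix(sp$truth$orf)
  gi <- gene_indices(m)
  s <- summarize_species(gi, counts = m, stops = 4, species = "agg")
  expect_equal(s$genes, 30)
  expect_equal(s$codons, sum(rowSums(m)))
  expect_equal(s$stops, 4L)
  expect_equal(s$nc, mean(gi$nc, na.rm = TRUE))
  expect_gte(s$codons, s$genes)

  one <- gene_indices(m[1, , drop = FALSE])
  s1 <- summarize_species(one, counts = m[1, , drop = FALSE])
  expect_equal(s1$nc, one$nc)
  expect_equal(s1$gc3s, gc3s(m[1, ]))

  two <- data.frame(id = c("a", "b"), n_codons = c(100L, 100L),
                    skipped = 0L, nc = c(50, 60), gc = 0.5, gc1 = 0.5,
                    gc2 = 0.5, gc3 = 0.5, gc3s = c(0.4, 0.6),
                    cbi = NA_real_, fop = NA_real_)
  expect_equal(summarize_species(two)$nc, 55)

  # short genes get NA indices but keep their rows
  gi2 <- gene_indices(c(g1 = strrep("GCTGCC", 20), g2 = "GCTGCCGCA"))
  expect_equal(nrow(gi2), 2)
  expect_true(is.na(gi2$nc[2]) && is.na(gi2$gc[2]))
  expect_equal(gi2$n_codons[2], 3L)
})
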