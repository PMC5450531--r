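# Correspondence analysis and the expected-Nc null curve

test_that("CA reproduces the chi-squared geometry of small tables", {
  # perfect association in a 2x2 -> total inertia exactly 1
  m <- rbind(g1 = c(10, 0), g2 = c(0, 10))
  colnames(m) <- c("GCC", "GCA")
  fit <- codon_ca(m, n_axes = 1)
  expect_equal(fit$total_inertia, 1)

  # rows identical up to scale -> independence model exact
  m2 <- rbind(a = c(2, 4, 6), b = c(4, 8, 12), c = c(1, 2, 3))
  colnames(m2) <- c("GCA", "GCC", "GCG")
  fit2 <- codon_ca(m2)
  expect_equal(fit2$total_inertia, 0, tolerance = 1e-12)
  expect_true(all(abs(fit2$row_coordinates) < 1e-8))

  # total inertia equals brute-force chi-squared / N on random tables
  set.seed(52)
  for (rep in 1:20) {
    r <- sample(3:8, 1); k <- sample(3:8, 1)
    x <- matrix(rpois(r * k, 5) + 1, r, k,
                dimnames = list(paste0("g", 1:r),
                                sample(SENSE, k)))
    fit <- codon_ca(x, n_axes = 2)
    expect_equal(fit$total_inertia, oracle_chisq_over_n(x),
                 tolerance = 1e-10)
    expect_true(all(diff(fit$inertia) < 1e-12))      # non-increasing
    expect_lte(length(fit$inertia), min(r, k) - 1)
  }

  expect_error(codon_ca(matrix(0, 2, 2)), "degenerate")
  expect_error(codon_ca(rbind(c(1, 1), c(0, 0))), "all-zero rows")
})

test_that("CA singular values agree with an independent implementation", {
  set.seed(62)
  x <- matrix(rpois(12 * 8, 6) + 1, 12, 8,
              dimnames = list(paste0("g", 1:12), sample(SENSE, 8)))
  fit <- codon_ca(x, n_axes = 4)
  ref <- MASS::corresp(x, nf = 4)
  expect_equal(sqrt(fit$inertia[1:4]), unname(ref$cor[1:4]),
               tolerance = 1e-8)
  # principal coordinates agree up to axis sign
  for (k in 1:3) {
    a <- fit$row_coordinates[, k]
    b <- ref$rscore[, k] * ref$cor[k]
    expect_equal(abs(stats::cor(a, b)), 1, tolerance = 1e-8)
    expect_equal(sort(abs(a)), sort(abs(b)), tolerance = 1e-8)
  }
})

test_that("the full-rank CA reconstructs the relative matrix", {
  set.seed(72)
  x <- matrix(rpois(10 * 6, 8) + 1, 10, 6,
              dimnames = list(paste0("g", 1:10), sample(SENSE, 6)))
  n <- sum(x); p <- x / n
  r <- rowSums(p); cc <- colSums(p)
  fit <- codon_ca(x, n_axes = min(dim(x)) - 1)
  # P = r c' + D_sqrt(r) (sum_k row_std_k d_k col_std_k') D_sqrt(c)
  rs <- sweep(fit$row_coordinates, 1, sqrt(r), "*")
  cs <- sweep(fit$column_coordinates, 1, sqrt(cc), "*")
  d <- sqrt(fit$inertia[seq_len(ncol(rs))])
  s_hat <- rs %*% diag(1 / d, length(d)) %*% t(cs)
  recon <- outer(r, cc) +
    sweep(sweep(s_hat, 1, sqrt(r), "*"), 2, sqrt(cc), "*")
  expect_equal(unname(recon), unname(p), tolerance = 1e-10)
})

test_that("axis 1 is oriented along GC3 and correlates with GC3s", {
  sp <- generate_species(generator_spec("ca", n_genes = 200,
                                        theta_gc3 = 0.75,
                                        theta_gc3_sd = 0.08, seed = 82))
  m <- codon_count_matrix(sp$truth$orf)
  fit <- codon_ca(m[, genetic_code()$variable_codons])
  gi <- gene_indices(m)
  third_gc <- rowSums(m[, genetic_code()$variable_codons][,
    substr(genetic_code()$variable_codons, 3, 3) %in% c("G", "C")]) /
    rowSums(m[, genetic_code()$variable_codons])
  expect_gte(stats::cor(fit$row_coordinates[, 1], third_gc), 0)

  res <- axis_gc3s_correlation(fit, gi)
  expect_equal(res$abs_r, abs(res$r))
  expect_gt(res$abs_r, 0.9)     # GC3s drives axis 1 in a biased species

  # exact and null correlation endpoints on a synthetic fit object
  fake <- structure(list(row_coordinates = cbind(axis1 = gi$gc3s)),
                    class = "codon_ca")
  rownames(fake$row_coordinates) <- gi$id
  expect_equal(axis_gc3s_correlation(fake, gi)$abs_r, 1)
  expect_lt(axis_gc3s_correlation(
    fake, transform(gi, gc3s = sample(gc3s)))$abs_r, 0.2)
  expect_true(is.na(axis_gc3s_correlation(fit, gi[1:2, ])$r))
})

test_that("a biased species couples axis 1 to GC3s more than a neutral one", {
  wins <- 0L
  for (i in 1:5) {
    hi <- generate_species(generator_spec("hi", n_genes = 120,
                                          theta_gc3 = 0.8,
                                          theta_gc3_sd = 0.08,
                                          seed = 900 + i))
    lo <- generate_species(generator_spec("lo", n_genes = 120,
                                          theta_gc3 = 0.5,
                                          theta_gc3_sd = 0.02,
                                          seed = 950 + i))
    r_of <- function(sp) {
      m <- codon_count_matrix(sp$truth$orf)
      fit <- codon_ca(m[, genetic_code()$variable_codons])
      axis_gc3s_correlation(fit, gene_indices(m))$abs_r
    }
    if (r_of(hi) > r_of(lo)) wins <- wins + 1L
  }
  expect_gte(wins, 5)
})

test_that("the simulated Nc null curve matches its analytic reference", {
  curve <- enc_null_curve(n_points = 600, gene_length_codons = 300,
                          seed = 123)
  pts <- curve$points
  expect_true(all(pts$nc <= 61 + 1e-9, na.rm = TRUE))

  # with long genes (small finite-length bias) the mean near s = 0.5
  # sits at the closed-form value
  long <- enc_null_curve(n_points = 150, gene_length_codons = 3000,
                         seed = 124)
  mid_long <- long$points$nc[long$points$s > 0.45 & long$points$s < 0.55]
  expect_lt(abs(mean(mid_long, na.rm = TRUE) - wright_enc(0.5)), 0.5)

  # near-symmetry about 0.5 (exact symmetry is broken only by the
  # isoleucine family, whose third positions split 1 G/C : 2 A/T) and
  # maximum at the centre
  mid <- pts$nc[pts$s > 0.45 & pts$s < 0.55]
  lo <- mean(pts$nc[pts$s > 0.15 & pts$s < 0.25], na.rm = TRUE)
  hi <- mean(pts$nc[pts$s > 0.75 & pts$s < 0.85], na.rm = TRUE)
  expect_lt(abs(lo - hi), 1.5)
  expect_gt(mean(mid, na.rm = TRUE), lo)
  expect_gt(mean(mid, na.rm = TRUE), hi)

  # strong bias approaches the one-codon-per-family floor from above
  top <- mean(pts$nc[pts$s > 0.95], na.rm = TRUE)
  expect_lt(top, 35)
  expect_gte(min(pts$nc, na.rm = TRUE), 20)

  # determinism
  curve2 <- enc_null_curve(n_points = 50, seed = 9)
  curve3 <- enc_null_curve(n_points = 50, seed = 9)
  expect_identical(curve2$points, curve3$points)
})

test_that("Nc offsets against the null curve recover planted restriction", {
  curve <- enc_null_curve(n_points = 800, seed = 77)
  # a species exactly on the curve has offset ~ 0
  s0 <- data.frame(species = "on", gc3s = 0.5,
                   nc = predict(curve, 0.5))
  expect_equal(enc_offset(s0, curve)$offset, 0)
  # observed above the curve -> negative offset with a warning
  sneg <- data.frame(species = "above", gc3s = 0.5,
                     nc = predict(curve, 0.5) + 2)
  expect_warning(off <- enc_offset(sneg, curve), "above")
  expect_lt(off$offset, 0)
  expect_error(predict(curve, 1.5), "outside")

  # within-family preference tuned to depress Nc by about four codons
  sp <- generate_species(generator_spec("tuned", n_genes = 250,
                                        theta_gc3 = 0.5, theta_gc3_sd = 0,
                                        preference_concentration = 4,
                                        seed = 88))
  gi <- gene_indices(sp$truth$orf)
  sm <- summarize_species(gi, species = "tuned")
  off <- enc_offset(sm, curve)$offset
  expect_gt(off, 2.5)
  expect_lt(off, 5.5)
})
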