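toy_sets <- function() {
  a <- ortholog_set(c(h = "AC", m = "AD", r = "AE"))
  b <- ortholog_set(c(m = "KL", r = "KM", c = "KN"))
  list(a = a, b = b)
}

test_that("species concatenation keeps the intersection in order", {
  ts <- toy_sets()
  cm <- concat_by_species(ts$a, ts$b)
  expect_equal(cm$species, c("m", "r"))
  expect_equal(unname(cm$seqs), c("ADKL", "AEKM"))
  expect_equal(cm$boundary, 2)
  d1 <- ortholog_set(c(x = "AA")); d2 <- ortholog_set(c(y = "CC"))
  expect_error(concat_by_species(d1, d2), "shared species")
})

test_that("a simulated 961-species pair concatenates to 961 rows", {
  gen <- generate_coevolving_msa(len_a = 8, len_b = 8, n_species = 961,
                                 n_planted = 0, seed = 4)
  cm <- concat_by_species(gen$set_a, gen$set_b)
  expect_equal(length(cm$seqs), 961)
  expect_equal(nchar(cm$seqs[[1]]), 16)
})

# A small alignment with one perfectly covarying inter-protein pair among
# otherwise independent uniform columns.
planted_toy <- function(n = 500, len = 6, seed = 1) {
  set.seed(seed)
  aa <- gtpcoupling:::AA_ALPHABET
  m <- matrix(sample(aa, n * 2 * len, replace = TRUE), n, 2 * len)
  flip <- runif(n) < 0.5
  m[flip, 3] <- "A";  m[!flip, 3] <- "C"
  m[flip, len + 4] <- "C"; m[!flip, len + 4] <- "A"
  sp <- sprintf("S%03d", seq_len(n))
  a <- apply(m[, seq_len(len)], 1, paste, collapse = "")
  b <- apply(m[, len + seq_len(len)], 1, paste, collapse = "")
  names(a) <- names(b) <- sp
  list(a = ortholog_set(a), b = ortholog_set(b), pair = c(3, 4))
}

test_that("a perfectly covarying pair dominates the inter-protein couplings", {
  toy <- planted_toy()
  cm <- compute_couplings(concat_by_species(toy$a, toy$b))
  S <- cm$raw
  planted <- S[toy$pair[1], toy$pair[2]]
  expect_true(all(planted > S[-((toy$pair[2] - 1) * nrow(S) + toy$pair[1])]))
  # and exceeds everything an all-independent alignment produces
  set.seed(9)
  aa <- gtpcoupling:::AA_ALPHABET
  m <- matrix(sample(aa, 500 * 12, replace = TRUE), 500, 12)
  sp <- sprintf("S%03d", 1:500)
  a2 <- apply(m[, 1:6], 1, paste, collapse = ""); names(a2) <- sp
  b2 <- apply(m[, 7:12], 1, paste, collapse = ""); names(b2) <- sp
  cm0 <- compute_couplings(concat_by_species(ortholog_set(a2), ortholog_set(b2)))
  expect_lt(max(cm0$raw), planted)
})

test_that("coupling maps are invariant to row order", {
  toy <- planted_toy(n = 120)
  cm1 <- compute_couplings(concat_by_species(toy$a, toy$b))
  set.seed(1)
  perm <- sample(120)
  a_perm <- ortholog_set(toy$a$seqs[perm])
  cm2 <- compute_couplings(concat_by_species(a_perm, toy$b))
  expect_equal(cm1$raw, cm2$raw, tolerance = 1e-10)
})

test_that("APC leaves an independent alignment centred near zero", {
  set.seed(10)
  aa <- gtpcoupling:::AA_ALPHABET
  m <- matrix(sample(aa, 400 * 30, replace = TRUE), 400, 30)
  sp <- sprintf("S%03d", 1:400)
  a <- apply(m[, 1:15], 1, paste, collapse = ""); names(a) <- sp
  b <- apply(m[, 16:30], 1, paste, collapse = ""); names(b) <- sp
  cm <- compute_couplings(concat_by_species(ortholog_set(a), ortholog_set(b)))
  expect_lt(abs(mean(cm$raw)) / sd(cm$raw), 0.05)
})

test_that("mostly-gapped columns are removed with a warning", {
  sp <- sprintf("S%03d", 1:60)
  a <- rep("A-CD", 60); substr(a[1:20], 2, 2) <- "K"   # col 2: 2/3 gaps
  names(a) <- sp
  b <- rep("KLMN", 60); names(b) <- sp
  set.seed(1)  # add variation so nothing else is degenerate
  a <- vapply(a, function(s) { substr(s, 4, 4) <- sample(c("D","E","F"), 1); s }, "")
  b <- vapply(b, function(s) { substr(s, 1, 1) <- sample(c("K","R","H"), 1); s }, "")
  cmsa <- concat_by_species(ortholog_set(a), ortholog_set(b))
  expect_warning(cm <- compute_couplings(cmsa), "gaps")
  expect_false("2" %in% rownames(cm$raw))
})

test_that("Gaussian convolution: impulse, uniform and near-zero sigma", {
  toyS <- matrix(0, 25, 25); toyS[13, 13] <- 1
  map <- structure(list(raw = toyS, convolved = NULL, boundary = 25,
                        metadata = list()), class = "coupling_map")
  out <- gaussian_convolve(map, 2)
  expect_equal(sum(out$convolved), 1, tolerance = 1e-12)  # kernel mass
  expect_equal(which.max(out$convolved), which.max(toyS)) # centred
  uni <- map; uni$raw <- matrix(3, 25, 25)
  expect_equal(gaussian_convolve(uni, 2)$convolved, uni$raw,
               tolerance = 1e-12)
  expect_equal(gaussian_convolve(map, 1e-3)$convolved, toyS, tolerance = 1e-9)
  expect_error(gaussian_convolve(map, 0))
})

test_that("top-fraction threshold is the expected order statistic", {
  expect_equal(top_fraction_threshold(1:100, 0.05), 96)
  expect_equal(top_fraction_threshold(1:20, 0.05), 20)      # ceiling rule
  ties <- c(rep(95, 10), 1:90)   # boundary tie: all tied values included
  expect_equal(top_fraction_threshold(ties, 0.05), 95)
  expect_error(top_fraction_threshold(1:10), "20 scores")
})

test_that("randomization outcomes follow the k/N convention", {
  out <- randomization_outcome(3, 100)
  expect_identical(out$p_value, 0.03)
  expect_identical(randomization_outcome(0, 100)$p_value, 0)
  expect_equal(out$p_value_plus, 4 / 101)
  expect_error(randomization_outcome(5, 0))
  expect_error(randomization_outcome(101, 100))
})

test_that("simulated alignments are reproducible under a seed", {
  g1 <- generate_coevolving_msa(len_a = 10, len_b = 10, n_species = 50, seed = 6)
  g2 <- generate_coevolving_msa(len_a = 10, len_b = 10, n_species = 50, seed = 6)
  expect_identical(g1$set_a$seqs, g2$set_a$seqs)
  expect_identical(g1$truth$pairs, g2$truth$pairs)
})

test_that("the species-shuffle test is conservative on signal-free pairs", {
  # true null: the two ortholog sets evolve on independent trees, so the
  # species pairing carries neither coupling nor shared phylogeny (a
  # shared tree alone already constitutes detectable inter-protein signal;
  # see the methods vignette on phylogenetic confounding)
  ps <- sapply(1:12, function(s) {
    ga <- generate_coevolving_msa(len_a = 12, len_b = 12, n_species = 80,
                                  n_planted = 0, seed = 100 + s)
    gb <- generate_coevolving_msa(len_a = 12, len_b = 12, n_species = 80,
                                  n_planted = 0, seed = 900 + s)
    rt <- suppressWarnings(
      randomization_test(ga$set_a, gb$set_b, n_replicates = 10, seed = s))
    rt$outcome$p_value
  })
  expect_lte(mean(ps <= 0.05), 0.25)   # not concentrated below 0.05
})

test_that("a planted interface is detected by the randomization test", {
  gen <- generate_coevolving_msa(len_a = 20, len_b = 20, n_species = 200,
                                 n_planted = 4, seed = 15)
  rt <- randomization_test(gen$set_a, gen$set_b, n_replicates = 20, seed = 2)
  expect_lte(rt$outcome$p_value, 0.1)
  expect_equal(rt$outcome$n_replicates, 20)
  # alternative statistics run and produce valid outcomes
  for (st in c("count", "top_min")) {
    r2 <- randomization_test(gen$set_a, gen$set_b, n_replicates = 5,
                             statistic = st, seed = 3)
    expect_gte(r2$outcome$p_value, 0)
    expect_lte(r2$outcome$p_value, 1)
  }
})

test_that("pseudolikelihood couplings also rank a planted pair first", {
  toy <- planted_toy(n = 150, len = 4, seed = 2)
  cm <- compute_couplings(concat_by_species(toy$a, toy$b),
                          method = "pseudolikelihood")
  tp <- top_coupling_pairs(cm, 1)
  expect_equal(c(tp$i, tp$j), toy$pair)
})
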