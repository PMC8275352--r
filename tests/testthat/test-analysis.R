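flat_table <- function(k, E = 5) energy_table(rep(E, 4^k), k)

point_mass_table <- function(kmer, k, low = 0, high = 40) {
  e <- rep(high, 4^k)
  e[encode_sequence(kmer, k) + 1L] <- low
  energy_table(e, k)
}

test_that("Boltzmann probabilities normalize and match closed forms", {
  expect_equal(unname(boltzmann_probs(flat_table(3))), rep(1 / 64, 64))
  two <- energy_table(c(0, log(3), rep(60, 14)), 2)
  p <- boltzmann_probs(two)
  expect_equal(unname(p[1:2]), c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # stable under a large common offset
  shifted <- energy_table(two$energies + 500, 2)
  expect_equal(boltzmann_probs(shifted), p, tolerance = 1e-12)
})

test_that("top k-mers are ordered, tie-broken lexicographically, renormalized", {
  t1 <- point_mass_table("AAA", 3)
  top <- top_kmers(t1)
  expect_equal(top$kmer[1], "AAA")
  expect_equal(sum(top$prob), 1, tolerance = 1e-12)
  flat <- top_kmers(flat_table(3), n = 5)
  expect_equal(flat$kmer, c("AAA", "AAC", "AAG", "AAU", "ACA"))
  expect_equal(flat$prob, rep(0.2, 5))
  expect_error(top_kmers(flat_table(2), n = 17), "between 1 and")
})

test_that("spacer distribution reports NB pmf, P(d>0) and small tail", {
  sp <- spacer_from_natural(r = 1, p = 0.2, S = 1e4)
  out <- spacer_distribution(sp)
  expect_equal(out$p_gt0, 0.8, tolerance = 1e-12)
  expect_equal(out$pmf, dnbinom(out$d, size = 1, prob = 0.2))
  expect_lt(out$tail_mass, 1e-6)
  # p -> 1: all mass at d = 0, adjacent cores
  sp1 <- spacer_params(rho = 0.5, pi = 30, log_s = log(100))
  expect_lt(spacer_distribution(sp1)$p_gt0, 1e-10)
})

test_that("bipartite classification thresholds P(d>0)", {
  core <- flat_table(3)
  adj <- bmf_model(core, core, spacer_params(0.5, 30, log(100)))
  expect_equal(classify_bipartite(adj), "adjacent")
  bip <- bmf_model(core, core, spacer_from_natural(1, 0.2, 100))
  expect_equal(classify_bipartite(bip), "bipartite") # P(d>0) = 0.8
  expect_equal(classify_bipartite(bip, threshold = 0.9), "adjacent")
})

test_that("core similarity is Pearson correlation of Boltzmann vectors", {
  sp <- spacer_from_natural(2, 0.3, 100)
  ta <- point_mass_table("AAA", 3, low = 2, high = 14)
  same <- bmf_model(ta, ta, sp)
  expect_equal(core_similarity(same), 1, tolerance = 1e-12)
  uniform <- bmf_model(flat_table(3), flat_table(3), sp)
  expect_true(is.na(core_similarity(uniform)))
  ta2 <- point_mass_table("AA", 2, low = 0, high = 8)
  tb2 <- point_mass_table("CC", 2, low = 0, high = 8)
  m2 <- bmf_model(ta2, tb2, sp)
  byhand <- cor(boltzmann_probs(ta2), boltzmann_probs(tb2))
  expect_equal(core_similarity(m2), byhand, tolerance = 1e-12)
  expect_lt(core_similarity(m2), 0)
})

test_that("motif entropy spans [0, 2] with the expected landmarks", {
  sp <- spacer_from_natural(2, 0.3, 100)
  expect_equal(motif_entropy(bmf_model(flat_table(3), flat_table(3), sp)), 2)
  point <- bmf_model(point_mass_table("ACG", 3), point_mass_table("ACG", 3),
                     sp)
  expect_equal(motif_entropy(point), 0, tolerance = 1e-10)
  # equal mass on all A/C-only k-mers: each position split 1/2 A, 1/2 C,
  # hence 1 bit per position
  ac_kmers <- kmer_strings(3)[grepl("^[AC]+$", kmer_strings(3))]
  e <- rep(40, 64)
  for (m in ac_kmers) e[encode_sequence(m, 3) + 1L] <- 0
  tab <- energy_table(e, 3)
  m_half <- bmf_model(tab, tab, sp)
  expect_equal(motif_entropy(m_half), 1, tolerance = 1e-10)
})

test_that("motif entropy is invariant under alphabet relabeling", {
  set.seed(13)
  e <- rnorm(64, 10, 2)
  perm <- c(U = "A", G = "C", A = "G", C = "U") # a permutation of letters
  km <- kmer_strings(3)
  relabeled <- chartr("ACGU", "GUCA", km)
  e2 <- e[match(km, relabeled)]
  sp <- spacer_from_natural(2, 0.3, 100)
  m1 <- bmf_model(energy_table(e, 3), energy_table(e, 3), sp)
  m2 <- bmf_model(energy_table(e2, 3), energy_table(e2, 3), sp)
  expect_equal(motif_entropy(m1), motif_entropy(m2), tolerance = 1e-12)
})

test_that("repetitiveness scores repeat-compatible cores", {
  sp <- spacer_from_natural(2, 0.3, 100)
  aaa <- bmf_model(point_mass_table("AAA", 3), point_mass_table("AAA", 3), sp)
  expect_equal(repetitiveness(aaa), 1, tolerance = 1e-10)
  acac <- bmf_model(point_mass_table("ACA", 3), point_mass_table("CAC", 3),
                    sp)
  expect_equal(repetitiveness(acac), 1, tolerance = 1e-10)
  ugc <- bmf_model(point_mass_table("UGC", 3), point_mass_table("UGC", 3), sp)
  expect_equal(repetitiveness(ugc), 0, tolerance = 1e-10)
})

test_that("random-model baselines are seeded, complex and non-repetitive", {
  b1 <- random_model_baseline(3, n_samples = 30, seed = 5)
  b2 <- random_model_baseline(3, n_samples = 30, seed = 5)
  expect_identical(b1, b2)
  expect_true(all(b1$entropy >= 0 & b1$entropy <= 2))
  expect_true(all(b1$repetitiveness >= 0 & b1$repetitiveness <= 1))
  # sd-1 energies over 64 k-mers stay near-uniform
  expect_gt(median(b1$entropy), 1.9)
  expect_lt(median(b1$repetitiveness), 0.5)
})

test_that("the motif summary assembles normalized components", {
  set.seed(99)
  m <- random_model(3)
  s <- motif_summary(m)
  expect_equal(sum(s$probs_a), 1, tolerance = 1e-12)
  expect_equal(sum(s$probs_b), 1, tolerance = 1e-12)
  expect_equal(sum(s$top_a$prob), 1, tolerance = 1e-12)
  expect_lte(sum(s$spacer$pmf), 1 + 1e-12)
  expect_output(print(s), "core A top k-mers")
  path <- tempfile(fileext = ".tsv")
  write_motif_summary(s, path)
  tab <- read.delim(path)
  expect_true(all(c("core_a", "core_b", "spacer", "summary") %in%
                  tab$section))
})
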