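test_that("Poisson dose probabilities are exact and sum to one", {
  p0 <- mutation_count_probabilities(dose_model(0))
  expect_equal(unlist(p0), c(P0 = 1, P1 = 0, Pmore = 0))
  p6 <- mutation_count_probabilities(dose_model(6))
  expect_equal(p6$P0, exp(-6))
  expect_equal(round(p6$P0, 5), 0.00248)
  expect_equal(round(p6$P1, 5), 0.01487)
  expect_equal(round(p6$Pmore, 5), 0.98265)
  expect_equal(mutation_count_probabilities(dose_model(log(2)))$P0, 0.5)
  for (lam in c(0.1, 0.5, 1, 2, 4, 6, 10)) {
    p <- mutation_count_probabilities(dose_model(lam))
    expect_equal(p$P0 + p$P1 + p$Pmore, 1)
  }
  expect_error(dose_model(-1), "non-negative")
})

test_that("dose_for_target inverts the fraction of mutated clones", {
  expect_equal(dose_for_target(0.5), log(2))
  expect_equal(dose_for_target(0.95), log(20))
  expect_equal(dose_for_target(1 - exp(-6)), 6)
  expect_error(dose_for_target(1), "in \\(0, 1\\)")
})

test_that("simulated mutant genomes recover the configured dose", {
  cfg <- screen_sim_config(genome = genome_map("toy", 1e6), lambda = 6,
                           causative_fraction = 0.1, n_mutants = 10000,
                           seed = 19)
  sim <- simulate_mutant_genomes(cfg)
  counts <- vapply(sim$genomes, function(g) length(g$positions), 0)
  se <- sqrt(6 / 10000)
  expect_lt(abs(mean(counts) - 6), 3 * se)
  # causative flags are Bernoulli(0.1) per mutation
  frac <- sum(vapply(sim$genomes, function(g) sum(g$causative), 0)) /
    sum(counts)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / sum(counts)))
  # positions uniform: mean near G/2
  pos <- unlist(lapply(sim$genomes, `[[`, "positions"))
  expect_lt(abs(mean(pos) - 5e5), 3 * (1e6 / sqrt(12)) / sqrt(length(pos)))
})

test_that("screen retention follows the causative model", {
  g <- genome_map("toy", 1e6)
  none <- simulate_mutant_genomes(
    screen_sim_config(genome = g, lambda = 6, causative_fraction = 0,
                      n_mutants = 500, seed = 2))
  expect_equal(none$n_screened, 0)
  all_caus <- simulate_mutant_genomes(
    screen_sim_config(genome = g, lambda = 6, causative_fraction = 1,
                      n_mutants = 5000, seed = 3))
  expected <- 1 - exp(-6)
  expect_lt(abs(all_caus$retention - expected),
            3 * sqrt(expected * (1 - expected) / 5000) + 1e-9)
})

test_that("detection thinning is Bernoulli with the stated sensitivity", {
  set.seed(5)
  expect_true(all(simulate_detection(1:100, 1)))
  expect_false(any(simulate_detection(1:100, 0)))
  kept <- simulate_detection(seq_len(10000), 0.9)
  expect_lt(abs(mean(kept) - 0.9), 3 * sqrt(0.9 * 0.1 / 10000))
})

test_that("replacement extents follow the survival-function model", {
  fm <- fragment_model(1e5)
  set.seed(7)
  ext <- sample_replacement_extent(fm, 1e5)
  expect_true(all(ext$left_bp >= 0 & ext$left_bp <= 1e5))
  expect_true(all(ext$right_bp >= 0 & ext$right_bp <= 1e5))
  # marginal co-replacement matches the Wu curve at 20 kb
  emp <- mean(ext$right_bp >= 20000)
  expect_lt(abs(emp - 0.512), 3 * sqrt(0.512 * 0.488 / 1e5))
})

test_that("transduction replaces loci by signed offset, with nesting", {
  g <- genome_map("toy", 5e5)
  fm <- fragment_model(1e5)
  set.seed(9)
  # locus at the marker reference point is always replaced
  tr0 <- simulate_transduction(250000, TRUE, 250000, fm, 200, g)
  expect_true(all(tr0$replaced))
  expect_true(all(tr0$reverted))

  # empirical replacement at d = 20 kb matches the closed form
  tr <- simulate_transduction(270000, TRUE, 250000, fm, 1e5, g)
  emp <- mean(tr$replaced[, 1])
  expect_lt(abs(emp - 0.512), 3 * sqrt(0.512 * 0.488 / 1e5))
  expect_equal(tr$reverted, tr$replaced[, 1])

  # same-side pair at 20/30 kb: near-not-far fraction = separation prob
  tr2 <- simulate_transduction(c(270000, 280000), c(TRUE, FALSE), 250000,
                               fm, 1e5, g)
  sep <- mean(tr2$replaced[, 1] & !tr2$replaced[, 2])
  expect_lt(abs(sep - 0.169), 3 * sqrt(0.169 * 0.831 / 1e5))
  # nesting: replacing the far locus implies replacing the near one
  expect_false(any(tr2$replaced[, 2] & !tr2$replaced[, 1]))

  # wraparound: loci on opposite sides are replaced independently
  tr3 <- simulate_transduction(c(20000, 495000), c(TRUE, TRUE), 10000,
                               fm, 5000, g)
  expect_gt(mean(tr3$replaced[, 1]), 0.6)  # d = 10 kb right, f = 0.729
  expect_gt(mean(tr3$replaced[, 2]), 0.5)  # d = 15 kb left, f = 0.614
})

test_that("deconvolution simulation tallies conserve repetitions", {
  g <- genome_map("toy", 5e5)
  lib <- uniform_library(g, 5e4)
  cfg <- screen_sim_config(genome = g, lambda = 6,
                           causative_fraction = 0.2, n_reps = 200,
                           seed = 23)
  s <- run_deconvolution_sim(cfg, lib, plate_noise_model(log_sd = 0.1))
  expect_equal(s$successes + sum(s$failure_modes), 200)
  expect_gte(s$wilson_ci[["lower"]], 0)
  expect_lte(s$wilson_ci[["upper"]], 1)
  expect_gte(s$wilson_ci[["upper"]], s$success_rate)
  expect_lte(s$wilson_ci[["lower"]], s$success_rate)
})

test_that("undetectable mutations are tallied as WGS failures", {
  g <- genome_map("toy", 5e5)
  lib <- uniform_library(g, 5e4)
  cfg <- screen_sim_config(genome = g, lambda = 6,
                           causative_fraction = 0.2,
                           detection_sensitivity = 0, n_reps = 50,
                           seed = 29)
  s <- run_deconvolution_sim(cfg, lib)
  expect_equal(s$success_rate, 0)
  expect_equal(s$failure_modes[["causative_undetected_by_WGS"]], 50)
})

test_that("simulation results are reproducible from the seed", {
  g <- genome_map("toy", 5e5)
  lib <- uniform_library(g, 5e4)
  cfg <- screen_sim_config(genome = g, lambda = 6,
                           causative_fraction = 0.2, n_reps = 100,
                           seed = 31)
  s1 <- run_deconvolution_sim(cfg, lib)
  s2 <- run_deconvolution_sim(cfg, lib)
  expect_identical(s1$successes, s2$successes)
  expect_identical(s1$failure_modes, s2$failure_modes)
})

test_that("the config constructor validates its inputs", {
  g <- genome_map("toy", 1e5)
  expect_error(screen_sim_config(genome = g), "seed")
  expect_error(screen_sim_config(genome = g, seed = 1, lambda = -1),
               "lambda")
  expect_error(screen_sim_config(genome = g, seed = 1,
                                 causative_fraction = 1.5), "\\[0, 1\\]")
  expect_error(screen_sim_config(genome = g, seed = 1, n_picks = 0),
               "n_picks")
  expect_error(run_deconvolution_sim(
    screen_sim_config(genome = g, seed = 1, causative_fraction = 0),
    point_library(100, g)), "causative_fraction")
})

test_that("fixture generation is byte-reproducible and self-consistent", {
  d1 <- file.path(tempdir(), "fx_a")
  d2 <- file.path(tempdir(), "fx_b")
  p1 <- generate_fixtures(1234, d1, genome_length_bp = 3e5)
  p2 <- generate_fixtures(1234, d2, genome_length_bp = 3e5)
  for (nm in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[[nm]])),
                     unname(tools::md5sum(p2[[nm]])), label = nm)
  }
  genome <- genome_map("synthetic", 3e5)
  genes <- load_gene_features(p1$genes_tsv, genome)
  genes_gff <- load_gene_features(p1$genes_gff3, genome)
  expect_equal(genes[c("gene_id", "start_bp", "end_bp", "strand")],
               genes_gff[c("gene_id", "start_bp", "end_bp", "strand")])
  lib <- load_marker_table(p1$markers_tsv, genome)
  expect_equal(nrow(lib$markers), floor(3e5 / 5e4))
  variants <- load_variants(p1$variants_vcf, genome)
  expect_true(all(variants$var_class == "SNV"))
  plate <- load_plate(p1$plate_tsv)
  expect_true(all(c("WT_REF", "MUT_REF") %in% plate$group))
  cfg <- read_sim_config(p1$sim_config)
  expect_equal(cfg$seed, 1234)
})

test_that("variant counts across fixture seeds track the Poisson dose", {
  counts <- vapply(1:30, function(s) {
    d <- file.path(tempdir(), paste0("fxp_", s))
    p <- generate_fixtures(s, d, genome_length_bp = 2e5, lambda = 6)
    v <- load_variants(p$variants_vcf, genome_map("synthetic", 2e5))
    nrow(v)
  }, 0)
  expect_lt(abs(mean(counts) - 6), 3 * sqrt(6 / 30))
})

test_that("the Wilson interval behaves at the boundaries", {
  ci <- wilson_interval(0, 100)
  expect_equal(ci[["lower"]], 0)
  expect_gt(ci[["upper"]], 0)
  ci2 <- wilson_interval(100, 100)
  expect_equal(ci2[["upper"]], 1)
  expect_lt(ci2[["lower"]], 1)
  ci3 <- wilson_interval(50, 100)
  expect_lt(ci3[["lower"]], 0.5)
  expect_gt(ci3[["upper"]], 0.5)
})
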