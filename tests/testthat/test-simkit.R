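test_that("labeled_abundance follows the approach-to-equilibrium law", {
  # closed-form checks: zero at t=0, half of equilibrium after one half-life
  expect_equal(labeled_abundance(0, 50, 0.3), 0)
  expect_equal(labeled_abundance(log(2) / 0.3, 50, 0.3), 25)
  expect_equal(labeled_abundance(6, 100, 0.2), 100 * (1 - exp(-1.2)),
               tolerance = 1e-12)
  expect_equal(round(labeled_abundance(6, 100, 0.2), 3), 69.881)
  # monotone in t and bounded by Yeq, converged beyond ~30 half-lives
  t <- seq(0, 400, by = 0.5)
  y <- labeled_abundance(t, 80, 0.11)
  expect_true(all(diff(y) >= 0))
  expect_true(all(y <= 80))
  expect_lt(abs(labeled_abundance(31 / 0.11, 80, 0.11) - 80), 1e-9 * 80)
  expect_error(labeled_abundance(-1, 10, 0.1), "time")
  expect_error(labeled_abundance(5, 10, 0), "alpha")
})

test_that("draw_transcript_params is seeded, scaled and degenerate-safe", {
  d <- sim_design(n_transcripts = 1000, seed = 1)
  a <- draw_transcript_params(d)
  b <- draw_transcript_params(d)
  expect_identical(a, b)  # fixed seed, bitwise
  expect_true(all(a$k_syn > 0 & a$alpha > 0 & a$m_eq > 0))
  expect_equal(a$m_eq * a$alpha, a$k_syn, tolerance = 1e-12)
  expect_equal(sum(a$m_eq), 60000, tolerance = 1e-9)
  # scale 0 puts every alpha at the lognormal location
  c0 <- draw_transcript_params(d, alpha_meanlog = log(0.259), alpha_sdlog = 0)
  expect_equal(unique(c0$alpha), 0.259, tolerance = 1e-12)
  # lognormal median equals exp(location)
  expect_lt(abs(median(a$alpha) - 0.259) / 0.259, 0.10)
  expect_error(draw_transcript_params(sim_design(n_transcripts = 0, seed = 1)),
               "n_transcripts")
})

test_that("apply_genotype_shift rescales rates and preserves the balance", {
  d <- sim_design(n_transcripts = 5000, seed = 2)
  truth <- draw_transcript_params(d)
  # identity shift
  id <- apply_genotype_shift(truth, genotype_spec("x", 90))
  expect_equal(id$alpha, truth$alpha)
  expect_equal(id$k_syn, truth$k_syn)
  # deterministic global decay shift: median ratio exact
  mut <- apply_genotype_shift(truth, mutant_spec())
  expect_equal(median(truth$alpha) / median(mut$alpha), 3.2, tolerance = 1e-12)
  expect_equal(median(truth$k_syn) / median(mut$k_syn), 3.7, tolerance = 1e-12)
  expect_equal(mut$m_eq * mut$alpha, mut$k_syn, tolerance = 1e-12)
  # lognormal jitter has median one
  jit <- apply_genotype_shift(truth, genotype_spec("y", 90, decay_factor = 0.5),
                              jitter_sdlog = 0.1, seed = 9)
  expect_lt(abs(median(truth$alpha / jit$alpha) - 2) / 2, 0.05)
  expect_error(genotype_spec("z", 90, decay_factor = 0), "factors")
})

test_that("genotype growth rates match ln2 over doubling time", {
  expect_equal(wt_spec()$alpha_growth, log(2) / 90, tolerance = 1e-12)
  expect_equal(round(wt_spec()$alpha_growth, 4), 0.0077)
  expect_equal(round(mutant_spec()$alpha_growth, 4), 0.0046)
})

test_that("simulated labeling counts follow the forward model", {
  # one host gene, huge Poisson library: time profile matches the kinetic law
  d <- sim_design(n_transcripts = 1, n_spike_genes = 2, library_size = 1e9,
                  nb_dispersion = 0, seed = 3)
  truth <- tibble::tibble(gene_id = "g1", k_syn = 0.15 * 400, alpha = 0.15,
                          m_eq = 400)
  tab <- simulate_labeling_counts(truth, wt_spec(), d)
  cnt <- tab$counts["g1", ]
  tm <- tab$samples$time_min
  times_u <- sort(unique(tm))
  prof <- vapply(times_u, function(x) mean(cnt[tm == x]), numeric(1))
  expected <- (1 - exp(-0.15 * times_u)) / (1 - exp(-0.15 * 90))
  expect_equal(prof / prof[length(prof)], expected, tolerance = 1e-3)
  # same seed twice -> identical tables
  expect_identical(simulate_labeling_counts(truth, wt_spec(), d)$counts,
                   tab$counts)
  # saturating kinetics: counts flat across times within NB noise
  d2 <- sim_design(n_transcripts = 1, n_spike_genes = 2, library_size = 1e6,
                   nb_dispersion = 0, seed = 4)
  fast <- tibble::tibble(gene_id = "g1", k_syn = 2 * 500, alpha = 2,
                         m_eq = 500)
  tab2 <- simulate_labeling_counts(fast, wt_spec(), d2)
  cnt2 <- tab2$counts["g1", ]
  expect_lt(diff(range(cnt2)) / mean(cnt2), 0.05)
})

test_that("spike genes sit at equilibrium and host/spike reads split by design", {
  d <- sim_design(n_transcripts = 50, n_spike_genes = 10, seed = 5)
  truth <- draw_transcript_params(d)
  mu <- expected_labeling_counts(truth, wt_spec(), d)
  spikes <- mu$counts[mu$genes$species == "spike", ]
  # expected spike reads identical in every sample (pre-labeled spike cells)
  expect_equal(apply(spikes, 1, function(r) diff(range(r))),
               rep(0, 10), ignore_attr = TRUE)
  # at saturation, host:spike expected reads honor the 14:1 RNA ratio
  sat <- mu$counts[, mu$samples$time_min == 90][, 1]
  host_sat <- sum(sat[mu$genes$species == "host"])
  spike_sat <- sum(sat[mu$genes$species == "spike"])
  expect_gt(host_sat / spike_sat, 13.5)
  expect_lt(host_sat / spike_sat, 14.5)
})

test_that("normalized expected counts are proportional to labeled abundance", {
  d <- sim_design(n_transcripts = 20, n_spike_genes = 5, seed = 6)
  truth <- draw_transcript_params(d)
  mu <- expected_labeling_counts(truth, wt_spec(), d)
  # emulate unequal sequencing depth, then undo it with spike size factors
  depths <- rep(c(1.4, 0.7, 1.0, 2.1, 0.5), length.out = ncol(mu$counts))
  scaled <- count_table(sweep(mu$counts, 2, depths, "*"), mu$genes,
                        mu$samples, normalized = TRUE)
  norm <- normalize_counts(scaled, spike_size_factors(scaled))
  for (g in which(norm$genes$species == "host")[1:5]) {
    y <- norm$counts[g, ]
    model <- labeled_abundance(norm$samples$time_min, truth$m_eq[g],
                               truth$alpha[g])
    ratio <- y / model
    expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
  }
})

test_that("shutoff series halve per half-life and respect the seed", {
  s <- simulate_shutoff_series(4.2, times = c(0, 4.2, 8.4), noise_cv = 0)
  expect_equal(s$signal / s$signal[1], c(1, 0.5, 0.25), tolerance = 1e-12)
  expect_equal(s$signal[1], 100)  # S0 exactly at t = 0
  s2 <- simulate_shutoff_series(3.6, times = c(0, 3.6), noise_cv = 0)
  expect_equal(s2$signal[2] / s2$signal[1], 0.5, tolerance = 1e-12)
  n1 <- simulate_shutoff_series(4.2, noise_cv = 0.1, seed = 8)
  n2 <- simulate_shutoff_series(4.2, noise_cv = 0.1, seed = 8)
  expect_identical(n1, n2)
  expect_error(simulate_shutoff_series(0), "half_life")
})
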