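test_that("taxonomy and sample generation are sized and seeded correctly", {
  cfg <- sim_config(n_families = 3, genera_per_family = 2,
                    species_per_genus = 2, n_samples = 8, seed = 4)
  tax <- generate_taxonomy(cfg)
  expect_equal(nrow(tax), 12)
  expect_equal(length(unique(tax$family)), 3)
  # genus is the first token of each binomial
  expect_equal(vapply(strsplit(tax$species, " "), `[[`, "", 1L), tax$genus)

  s1 <- generate_samples(cfg, tax)
  s2 <- generate_samples(cfg, tax)
  expect_identical(s1, s2)
  expect_true(all(s1$species %in% tax$species))
  expect_equal(sum(table(s1$plant_part)), 8)
  expect_equal(sum(table(s1$plant_type)), 8)

  expect_error(sim_config(n_families = 1, genera_per_family = 2,
                          species_per_genus = 2, n_samples = 10),
               "without replacement")
})

test_that("simulation is reproducible and insensitive to added tools", {
  cfg <- sim_config(n_samples = 10, seed = 99)
  tax <- generate_taxonomy(cfg)
  samples <- generate_samples(cfg, tax)
  prof <- default_tool_profiles()[1:3]
  r1 <- simulate_records(prof, samples, tax, cfg)
  r2 <- simulate_records(prof, samples, tax, cfg)
  expect_identical(r1, r2)
  # adding a tool leaves the existing tools' records untouched
  r3 <- simulate_records(default_tool_profiles()[1:4], samples, tax, cfg)
  keep <- r3$tool %in% names(prof)
  expect_identical(as.data.frame(r3[keep, ]), as.data.frame(r1))
})

test_that("degenerate profiles behave as promised", {
  cfg <- sim_config(n_samples = 12, seed = 3)
  tax <- generate_taxonomy(cfg)
  samples <- generate_samples(cfg, tax)

  perfect <- tool_profile("perfect", c(species_correct = 1), rho = 0)
  rec <- simulate_records(list(perfect), samples, tax, cfg)
  sc <- score_records(rec)
  expect_true(all(sc$first_choice == 100))
  ct <- consistency_table(rec, tax)
  expect_true(all(ct$consistency_C == 4))

  # rho = 1: replicates of a sample are verbatim copies
  sticky <- tool_profile("sticky", c(species_correct = 0.3,
                                     misleading = 0.4, unknown = 0.3),
                         rho = 1)
  rec2 <- simulate_records(list(sticky), samples, tax, cfg)
  for (s in unique(rec2$sample)) {
    runs <- split(rec2[rec2$sample == s, c("position", "suggested_name",
                                           "category")],
                  rec2$replicate[rec2$sample == s])
    for (r in runs) expect_equal(unname(r), unname(runs[[1]]),
                                 ignore_attr = TRUE)
  }
})

test_that("threshold metrics converge to the profile's expectation", {
  # P(first-choice score >= 80) = 0.6 by construction
  p <- c(species_correct = 0.3, genus_correct = 0.2, very_close = 0.1,
         family_correct = 0.2, unknown = 0.2)
  cfg <- sim_config(n_samples = 38, seed = 17)
  tax <- generate_taxonomy(cfg)
  samples <- generate_samples(cfg, tax)
  pct <- numeric(200)
  for (i in 1:200) {
    cfg_i <- sim_config(n_samples = 38, seed = 20000 + i)
    rec <- simulate_records(list(tool_profile("t", p, rho = 0.4)),
                            samples, tax, cfg_i)
    pct[i] <- accuracy_thresholds(score_records(rec)$first_choice)["pct_ge_80"]
  }
  se <- stats::sd(pct) / sqrt(length(pct))
  expect_lt(abs(mean(pct) - 60), 3 * se + 1e-9)
})

test_that("profile probabilities and rho are recovered within 3 SE", {
  p_true <- c(species_correct = 0.2, genus_correct = 0.5, unknown = 0.2,
              misleading = 0.1)
  cfg <- sim_config(n_families = 60, genera_per_family = 4,
                    species_per_genus = 4, n_samples = 900,
                    n_replicates = 5, seed = 23)
  tax <- generate_taxonomy(cfg)
  samples <- generate_samples(cfg, tax)

  for (rho_true in c(0, 0.5)) {
    rec <- simulate_records(list(tool_profile("t", p_true, rho = rho_true)),
                            samples, tax, cfg)
    est <- recover_profile(rec)
    n <- cfg$n_samples
    se_p <- sqrt(0.5 * 0.5 / n)
    expect_lt(abs(est$category_probabilities["genus_correct"] - 0.5),
              3 * se_p)
    n_pairs <- n * (cfg$n_replicates - 1)
    q <- sum(p_true^2)
    p_match <- rho_true + (1 - rho_true) * q
    se_rho <- sqrt(p_match * (1 - p_match) / n_pairs) / (1 - q)
    expect_lt(abs(est$rho - rho_true), 3 * se_rho + 1e-9)
  }

  # rho = 1 is recovered exactly
  rec1 <- simulate_records(list(tool_profile("t", p_true, rho = 1)),
                           samples, tax, cfg)
  expect_equal(recover_profile(rec1)$rho, 1)
  expect_error(recover_profile(rec1[rec1$replicate == 1, ]),
               "two replicates")
})

test_that("stochastically ordered profiles are recovered in mean-score order", {
  cfg <- sim_config(n_families = 30, genera_per_family = 3,
                    species_per_genus = 3, n_samples = 200, seed = 29)
  tax <- generate_taxonomy(cfg)
  samples <- generate_samples(cfg, tax)
  profs <- list(
    tool_profile("strong", c(species_correct = 0.7, genus_correct = 0.2,
                             unknown = 0.1)),
    tool_profile("mid", c(species_correct = 0.4, genus_correct = 0.3,
                          unknown = 0.3)),
    tool_profile("weak", c(species_correct = 0.1, genus_correct = 0.2,
                           unknown = 0.7)))
  rec <- simulate_records(profs, samples, tax, cfg)
  ps <- per_sample_scores(score_records(rec))
  means <- tapply(ps$score, ps$tool, mean)
  expect_true(means["strong"] > means["mid"])
  expect_true(means["mid"] > means["weak"])
})
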