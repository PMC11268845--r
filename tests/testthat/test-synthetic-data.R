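test_that("parent genomes are seeded, homozygous and sized to config", {
  cfg <- small_config(n_markers = 100, seed = 1)
  g1 <- simulate_parent_genomes(cfg)
  g2 <- simulate_parent_genomes(cfg)
  expect_identical(g1, g2)
  expect_true(all(g1 %in% c(0, 2)))
  p <- attr(g1, "allele_freq")
  expect_true(all(p >= 0.1 & p <= 0.9))

  wide <- simulate_parent_genomes(small_config(n_markers = 6200))
  expect_equal(ncol(wide), 6200)
})

test_that("pollinator derivation respects family sizes and parental origin", {
  cfg <- sim_config(n_markers = 60, family_sizes = c(50, 50, 50, 50, 51),
                    seed = 2)
  par <- simulate_parent_genomes(cfg)
  pol <- derive_pollinators(par, cfg)
  expect_equal(nrow(pol$genotypes), 251)
  expect_equal(as.integer(table(pol$families)), c(50, 50, 50, 50, 51))
  expect_true(all(pol$genotypes %in% c(0, 2)))
  # monomorphic parental loci cannot segregate
  mono <- which(par["P1", ] == par["L1", ])
  fam1 <- pol$genotypes[pol$families == "P1", mono, drop = FALSE]
  expect_true(all(sweep(fam1, 2, par["P1", mono]) == 0))
  # every marker equals one of the two parental dosages
  for (k in seq_len(5)) {
    fk <- par[paste0("P", k), ]
    sub <- pol$genotypes[pol$families == paste0("P", k), , drop = FALSE]
    ok <- sweep(sub, 2, fk, "==") | sweep(sub, 2, par["L1", ], "==")
    expect_true(all(ok))
  }
})

test_that("a single recombination block copies a whole parent", {
  cfg <- sim_config(n_markers = 40, family_sizes = c(3, 3, 3, 3, 3),
                    n_both = 2, n_t1_only = 1, n_t2_only = 1,
                    n_blocks = 1, seed = 3)
  par <- simulate_parent_genomes(cfg)
  pol <- derive_pollinators(par, cfg)
  for (i in seq_len(nrow(pol$genotypes))) {
    fam <- as.character(pol$families[i])
    expect_true(all(pol$genotypes[i, ] == par[fam, ]) ||
                  all(pol$genotypes[i, ] == par["L1", ]))
  }
})

test_that("crossing design yields the configured hybrid counts", {
  cfg <- sim_config(seed = 4)
  ped <- make_crossing_design(paste0("pol", 1:251), cfg)
  expect_equal(nrow(ped), 410)
  expect_false(anyDuplicated(ped$hybrid_id) > 0)
  per_pol <- table(ped$pollinator_id)
  expect_true(all(per_pol %in% c(1, 2)))
  expect_equal(sum(per_pol == 2), 159)

  one <- sim_config(n_both = 0, n_t1_only = 1, n_t2_only = 0, seed = 4)
  expect_equal(nrow(make_crossing_design(paste0("pol", 1:251), one)), 1)
  two <- sim_config(n_both = 2, n_t1_only = 0, n_t2_only = 0, seed = 4)
  ped2 <- make_crossing_design(paste0("pol", 1:251), two)
  expect_equal(nrow(ped2), 4)
  expect_equal(as.integer(table(ped2$tester_id)), c(2, 2))

  small <- sim_config(seed = 4)
  expect_error(make_crossing_design(paste0("pol", 1:100), small),
               "exceed")
})

test_that("hybrid genotypes are the deterministic F1 of inbred parents", {
  pol <- matrix(c(2, 0, 2, 2), 1, 4,
                dimnames = list("polA", paste0("mk", 1:4)))
  tst <- matrix(c(0, 0, 2, 0, 2, 2, 0, 2), 2, 4, byrow = TRUE,
                dimnames = list(c("M1", "M2"), paste0("mk", 1:4)))
  ped <- data.frame(hybrid_id = c("h1", "h2"),
                    pollinator_id = c("polA", "polA"),
                    tester_id = c("M1", "M2"), family = "P1")
  H <- synthesize_hybrid_genotypes(pol, tst, ped)
  expect_equal(unname(H["h1", ]), c(1, 0, 2, 1))
  expect_equal(unname(H["h2", ]), c(2, 1, 1, 2))
  # heterozygous loci = half the dosage Hamming distance of the parents
  expect_equal(sum(H["h1", ] == 1), sum(abs(pol[1, ] - tst["M1", ])) / 2)
  # full sibs are identical
  ped2 <- ped; ped2$tester_id <- "M1"; ped2$hybrid_id <- c("a", "b")
  H2 <- synthesize_hybrid_genotypes(pol, tst, ped2)
  expect_equal(unname(H2["a", ]), unname(H2["b", ]))
  # heterozygous parents are rejected
  badpol <- pol; badpol[1, 1] <- 1
  expect_error(synthesize_hybrid_genotypes(badpol, tst, ped),
               "heterozygous")
})

test_that("trait architecture hits its target variance and edge cases", {
  pop <- small_population()
  cfg <- small_config()
  arch <- simulate_trait_architecture(pop$hybrids, cfg, "yield")
  expect_equal(var(arch$values), arch$var_g, tolerance = 1e-10)
  expect_equal(arch$var_g, target_genetic_variance(cfg, "yield"))
  # monomorphic genotypes -> all genotypic values equal
  flat <- matrix(2, 10, 30, dimnames = list(paste0("i", 1:10),
                                            paste0("mk", 1:30)))
  a0 <- simulate_trait_architecture(flat, small_config(), "yield")
  expect_true(all(a0$values == a0$values[1]))
  # h2 = 1 with non-zero error variances is infeasible
  expect_error(target_genetic_variance(small_config(h2_targets =
                                                      c(yield = 1)),
                                       "yield"), "infeasible")
})

test_that("noise-free trials reproduce genotypic values exactly", {
  cfg <- small_config(var_env = 0, var_year = 0, var_loc = 0,
                      var_gxe = 0, var_row = 0, var_col = 0,
                      var_resid = 0, h2_targets = c(yield = 1))
  gv <- setNames(rnorm(30), paste0("g", 1:30))
  plots <- simulate_field_trial(gv, cfg)
  test_plots <- plots[!plots$is_check, ]
  expect_equal(test_plots$yield, unname(gv[test_plots$genotype]))
})

test_that("p-rep layout produces the expected plot counts", {
  cfg <- small_config(environments = data.frame(location = "LOC1",
                                                year = 2020L))
  gv <- setNames(rnorm(100), paste0("g", 1:100))
  plots <- simulate_field_trial(gv, cfg)
  expect_equal(sum(!plots$is_check), 120)  # 20 duplicated + 80 single
  expect_equal(sum(plots$is_check), 30)    # 3 checks x 10
  plots2 <- simulate_field_trial(gv, cfg)
  expect_identical(plots, plots2)
})

test_that("realised plot variance tracks the configured components", {
  # one component switched on at a time; 50 seeds each
  v_res <- mean(vapply(1:50, function(s) {
    cfg <- small_config(var_env = 0, var_year = 0, var_loc = 0,
                        var_gxe = 0, var_row = 0, var_col = 0,
                        var_resid = 2, seed = s,
                        environments = data.frame(location = "LOC1",
                                                  year = 2020L),
                        n_checks = 0)
    gv <- setNames(rep(0, 40), paste0("g", 1:40))
    var(simulate_field_trial(gv, cfg)$yield)
  }, numeric(1)))
  expect_lt(abs(v_res / 2 - 1), 0.1)
  v_gxe <- mean(vapply(1:50, function(s) {
    cfg <- small_config(var_env = 0, var_year = 0, var_loc = 0,
                        var_gxe = 1.5, var_row = 0, var_col = 0,
                        var_resid = 0, seed = s, n_checks = 0)
    gv <- setNames(rep(0, 40), paste0("g", 1:40))
    pl <- simulate_field_trial(gv, cfg)
    mean(tapply(pl$yield, pl$environment, var))
  }, numeric(1)))
  expect_lt(abs(v_gxe / 1.5 - 1), 0.1)
})

test_that("technical replicates differ only by noise and drift", {
  cfg <- small_config(nirs_noise_sd = 0, baseline_drift_amplitude = 0)
  pop <- small_population()
  sp <- simulate_nirs(pop$hybrids, pop$plots[1:10, ], cfg)
  v <- sp$values
  first <- v[sp$info$replicate == 1, ]
  second <- v[sp$info$replicate == 2, ]
  expect_equal(first, second, ignore_attr = TRUE)
})

test_that("full-range grid yields 1,820-point profiles", {
  cfg <- sim_config(n_markers = 20, n_wavelengths = 1820,
                    family_sizes = rep(2, 5), n_both = 2, n_t1_only = 0,
                    n_t2_only = 0, seed = 5)
  wl <- wavelength_grid(cfg)
  expect_equal(range(wl), c(680, 2499))
  par <- simulate_parent_genomes(cfg)
  pol <- derive_pollinators(par, cfg)
  plots <- data.frame(plot_id = "p1", genotype = rownames(pol$genotypes)[1],
                      environment = "E1", location = "LOC1", year = 2020L,
                      row = 1, col = 1, is_check = FALSE)
  sp <- simulate_nirs(pol$genotypes, plots, cfg)
  expect_equal(ncol(sp$values), 1820)
})

test_that("without genotype-driven signal spectra decouple from genetics", {
  cors <- vapply(1:15, function(s) {
    cfg <- small_config(nirs_geno_sd = 0, nirs_trait_sd = 0, seed = s,
                        family_sizes = rep(6, 5), n_both = 10,
                        n_t1_only = 5, n_t2_only = 5, n_markers = 80,
                        n_wavelengths = 40)
    pop <- simulate_population(cfg)
    sp <- average_technical_replicates(pop$nirs)
    test_rows <- !sp$info$is_check
    means <- rowsum(sp$values[test_rows, ], sp$info$genotype[test_rows])
    means <- means / as.integer(table(sp$info$genotype[test_rows]))
    gv <- pop$genetic_values$yield[rownames(means)]
    cor(gv, rowMeans(means))
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.15)
})

test_that("identical config and seed reproduce the population bit for bit", {
  cfg <- small_config(seed = 11)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$hybrids, b$hybrids)
  expect_identical(a$plots, b$plots)
  expect_identical(a$nirs$values, b$nirs$values)
})
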