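test_that("reml_fit matches balanced one-way ANOVA estimators", {
  y <- c(4, 6, 8, 10, 12, 14)
  f <- reml_fit(y, random = list(group = rep(1:3, each = 2)))
  expect_equal(unname(f$varcomp["group"]), 15, tolerance = 1e-6)
  expect_equal(unname(f$varcomp["residual"]), 2, tolerance = 1e-6)
})

test_that("constant responses collapse to zero variances", {
  f <- reml_fit(rep(3.5, 12), random = list(g = rep(1:4, 3)))
  expect_lt(f$varcomp[["g"]], 1e-8)
  expect_equal(unname(f$beta[1]), 3.5, tolerance = 1e-8)
})

test_that("dense and sparse REML paths agree on identity covariances", {
  set.seed(31)
  for (rep in 1:5) {
    g <- factor(rep(1:8, each = 4))
    y <- rnorm(8, sd = 2)[g] + rnorm(32)
    fs <- reml_fit(y, random = list(g = g))
    Z <- model.matrix(~ 0 + g)
    fd <- reml_fit(y, random = list(g = list(Z = Z, K = NULL)))
    expect_equal(fs$varcomp, fd$varcomp, tolerance = 1e-4)
    expect_equal(unname(fs$beta), unname(fd$beta), tolerance = 1e-5)
  }
})

test_that("adjusted means are exact when non-genetic variance is zero", {
  cfg <- small_config(var_env = 0, var_year = 0, var_loc = 0,
                      var_gxe = 0, var_row = 0, var_col = 0,
                      var_resid = 0, h2_targets = c(yield = 1))
  gv <- setNames(rnorm(25), paste0("g", 1:25))
  plots <- simulate_field_trial(gv, cfg)
  adj <- adjust_trait(plots, "yield")
  got <- setNames(adj$means$value, adj$means$genotype)
  expect_equal(got[names(gv)], gv, tolerance = 1e-6)
})

test_that("balanced environment shifts are absorbed into the env term", {
  # 6 genotypes x 2 environments, pure +/- d environment shift
  d <- 3
  gv <- setNames(seq(0, 5), paste0("g", 1:6))
  plots <- expand.grid(genotype = names(gv), environment = c("E1", "E2"),
                       stringsAsFactors = FALSE)
  plots$plot_id <- paste0("p", seq_len(nrow(plots)))
  plots$location <- plots$environment
  plots$year <- 2020L
  plots$row <- rep(1:6, 2); plots$col <- rep(1:2, each = 6)
  plots$is_check <- FALSE
  set.seed(41)
  plots$yield <- gv[plots$genotype] + ifelse(plots$environment == "E1",
                                             d, -d) + rnorm(12, 0, 0.3)
  adj <- adjust_trait(plots, "yield",
                      model_spec(random = "environment"))
  vals <- setNames(adj$means$value, adj$means$genotype)
  cross_env_mean <- tapply(plots$yield, plots$genotype, mean)
  expect_equal(vals[names(gv)], cross_env_mean[names(gv)],
               tolerance = 1e-6, ignore_attr = TRUE)
  # genotype contrasts are invariant to a constant added to one env
  plots2 <- plots
  plots2$yield[plots2$environment == "E1"] <-
    plots2$yield[plots2$environment == "E1"] + 10
  adj2 <- adjust_trait(plots2, "yield",
                       model_spec(random = "environment"))
  v2 <- setNames(adj2$means$value, adj2$means$genotype)
  expect_equal(diff(vals[names(gv)]), diff(v2[names(gv)]),
               tolerance = 1e-6)
})

test_that("plot exclusions leave remaining genotypes estimable", {
  pop <- small_population()
  plots <- pop$plots
  set.seed(9)
  drop <- sample(which(!plots$is_check), 40)
  masked <- plots[-drop, ]
  adj <- adjust_trait(masked, "yield")
  kept <- unique(masked$genotype[!masked$is_check])
  expect_setequal(adj$means$genotype, kept)
  expect_true(all(is.finite(adj$means$value)))
})

test_that("v_delta_BLUE agrees between vcov formula and explicit pairs", {
  pop <- small_population()
  adj <- adjust_trait(pop$plots, "yield")
  C <- adj$vcov
  g <- nrow(C)
  tot <- 0
  for (i in seq_len(g - 1))
    for (j in (i + 1):g)
      tot <- tot + C[i, i] + C[j, j] - 2 * C[i, j]
  expect_equal(adj$vdblue, tot / (g * (g - 1) / 2), tolerance = 1e-10)
})

test_that("saturated single-environment spectra adjustment is identity", {
  set.seed(12)
  n <- 8; L <- 10
  V <- matrix(rnorm(n * L), n, L)
  rownames(V) <- paste0("p", 1:n)
  sp <- spectra(V, 700 + 0:(L - 1),
                data.frame(sample_id = rownames(V),
                           plot_id = rownames(V)))
  plots <- data.frame(plot_id = rownames(V),
                      genotype = paste0("g", 1:n), environment = "E1",
                      location = "L1", year = 2020L, row = 1:n, col = 1,
                      is_check = FALSE)
  adj <- adjust_spectra(sp, plots, model_spec(reduced = TRUE))
  expect_equal(unname(adj$values), unname(V), tolerance = 1e-8)
})

test_that("additive environment effects are removed from spectra", {
  # 3 genotypes x 2 environments; env adds a constant to every wavelength
  set.seed(42)
  L <- 6
  base <- matrix(rnorm(3 * L), 3, L)
  shift <- 0.7
  V <- rbind(base + shift, base - shift) + rnorm(6 * L, 0, 0.05)
  rownames(V) <- paste0("p", 1:6)
  sp <- spectra(V, 700 + 0:(L - 1),
                data.frame(sample_id = rownames(V), plot_id = rownames(V)))
  plots <- data.frame(plot_id = rownames(V),
                      genotype = rep(paste0("g", 1:3), 2),
                      environment = rep(c("E1", "E2"), each = 3),
                      location = rep(c("L1", "L2"), each = 3),
                      year = 2020L, row = rep(1:3, 2),
                      col = rep(1:2, each = 3), is_check = FALSE)
  adj <- adjust_spectra(sp, plots, model_spec(random = "environment"))
  expect_equal(nrow(adj$values), 3)
  # per genotype, the adjusted profile equals its cross-environment mean
  # (balanced design: the +/- shift cancels exactly)
  cem <- (V[1:3, ] + V[4:6, ]) / 2
  expect_equal(unname(adj$values[adj$info$genotype, ]), unname(cem),
               tolerance = 1e-6)
})

test_that("spectra adjustment drops checks and keeps one row per genotype", {
  pop <- small_population()
  plot_sp <- average_technical_replicates(pop$nirs)
  adj <- adjust_spectra(plot_sp, pop$plots)
  non_checks <- setdiff(unique(pop$plots$genotype),
                        unique(pop$plots$genotype[pop$plots$is_check]))
  expect_equal(nrow(adj$values), length(non_checks))
  expect_false(anyDuplicated(adj$info$genotype) > 0)
})

test_that("shared variance components approximate per-wavelength BLUEs", {
  pop <- small_population()
  plot_sp <- average_technical_replicates(pop$nirs)
  sub <- plot_sp
  sub$values <- sub$values[, 1:20]
  sub$wavelengths <- sub$wavelengths[1:20]
  sub <- spectra(sub$values, sub$wavelengths, sub$info)
  full <- adjust_spectra(sub, pop$plots)
  fast <- adjust_spectra(sub, pop$plots, varcomp_mode = "shared",
                         shared_n = 5)
  expect_identical(rownames(full$values), rownames(fast$values))
  cors <- vapply(seq_len(ncol(full$values)), function(j)
    cor(full$values[, j], fast$values[, j]), numeric(1))
  expect_gt(min(cors), 0.98)
})

test_that("Cullis heritability follows its defining formula", {
  expect_equal(estimate_heritability(15, 2), 0.9375)
  expect_equal(estimate_heritability(0, 5), 0)
  expect_equal(estimate_heritability(3, 0), 1)
  expect_error(estimate_heritability(0, 0), "undefined")
  expect_error(estimate_heritability(-1, 2), "non-negative")
})
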