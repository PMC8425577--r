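test_that("balanced MoM matches brute-force mean-square arithmetic", {
  # 6 entries x 2 reps, 3 genotype classes x 2 entries; values by hand
  geno <- data.frame(entry = paste0("e", 1:6),
                     M = rep(c("AA", "Aa", "aa"), each = 2))
  vals <- c(3.1, 2.9, 4.0, 4.4, 7.2, 6.8, 6.5, 7.1, 1.0, 1.4, 2.2, 1.8)
  phen <- data.frame(entry = rep(geno$entry, each = 2),
                     replicate = rep(1:2, 6), value = vals)
  ds <- asv_dataset(phen, geno, locus_cols = "M",
                    replicate_col = "replicate")
  mm <- anova_mom(ds)

  # independent oracle: direct sums of squares
  y <- vals; r <- 2; n_G <- 6; n_per <- 2
  gm <- mean(y)
  ent_means <- colMeans(matrix(y, nrow = 2))
  cls_means <- colMeans(matrix(ent_means, nrow = 2))
  ss_G <- r * sum((ent_means - gm)^2)
  ss_M <- r * n_per * sum((cls_means - gm)^2)
  ss_GM <- ss_G - ss_M
  ss_eps <- sum((y - rep(ent_means, each = 2))^2)
  ms <- c(M = ss_M / 2, GM = ss_GM / 3, eps = ss_eps / 6)
  expect_equal(mm$ems$table$SS,
               c(ss_M, ss_GM, ss_eps), tolerance = 1e-12)
  expect_equal(unname(mm$fit$sigma2_eps), unname(ms["eps"]))
  expect_equal(unname(mm$fit$components["G:M"]),
               unname((ms["GM"] - ms["eps"]) / r))
  expect_equal(unname(mm$fit$components["M"]),
               unname((ms["M"] - ms["GM"]) / (r * n_per)))
})

test_that("SS and df are additive across the marker partition, MS are not", {
  ds <- make_balanced_ds(n_G = 30, r = 3, seed = 3)
  mm <- anova_mom(ds)
  tab <- mm$ems$table
  ss <- setNames(tab$SS, tab$source)
  df <- setNames(tab$df, tab$source)
  ms <- setNames(tab$MS, tab$source)
  # entry SS recomputed from the entry-only decomposition
  ph <- ds$phenotypes
  gm <- mean(ph$value)
  em <- tapply(ph$value, ph$entry, mean)
  ss_G <- 3 * sum((em - gm)^2)
  expect_equal(unname(ss["M"] + ss["G:M"]), ss_G)
  expect_equal(unname(df["M"] + df["G:M"]), 29)
  expect_gt(abs(ms["M"] + ms["G:M"] - ss_G / 29), 1e-6)
})

test_that("zero-residual data give sigma2_eps = 0 and exact entry variance", {
  geno <- data.frame(entry = paste0("e", 1:6),
                     M = rep(c("AA", "Aa", "aa"), each = 2))
  ent_vals <- c(1, 2, 5, 6, 9, 11)
  phen <- data.frame(entry = rep(geno$entry, each = 2),
                     replicate = rep(1:2, 6),
                     value = rep(ent_vals, each = 2))
  ds <- asv_dataset(phen, geno, locus_cols = "M",
                    replicate_col = "replicate")
  mm <- anova_mom(ds)
  expect_equal(unname(mm$fit$sigma2_eps), 0)
  ent <- fit_entry_model(ds)
  expect_equal(ent$sigma2_eps, 0)
  # MS_G = r * var(entry means), so sigma2_G = var(entry means) exactly
  expect_equal(ent$sigma2_G, var(ent_vals), tolerance = 1e-12)
})

test_that("MoM equals REML on balanced data with interior solutions", {
  for (seed in c(2, 5, 9)) {
    ds <- make_balanced_ds(n_G = 60, r = 3, sigma2_M = 3, sigma2_GM = 1,
                           sigma2_eps = 0.6, seed = seed)
    mom <- anova_mom(ds)$fit
    reml <- reml_fit(ds)
    # parameter agreement to optimizer precision (the restricted likelihood
    # is flat to machine accuracy within ~1e-5 of the optimum in the 2-df
    # marker direction)
    expect_equal(mom$components, reml$components, tolerance = 1e-5)
    expect_equal(mom$sigma2_eps, reml$sigma2_eps, tolerance = 1e-6)
    expect_true(reml$converged)
    # objective agreement: the closed-form solution attains the optimized
    # restricted deviance (to 1e-6 deviance units), i.e. MoM IS the REML
    # optimum on balanced data
    dev_mom <- reml_deviance_at(ds, mom$components["M"],
                                mom$components["G:M"], mom$sigma2_eps)
    dev_opt <- reml_deviance_at(ds, reml$components["M"],
                                reml$components["G:M"], reml$sigma2_eps)
    expect_lt(abs(dev_mom - dev_opt), 1e-6)
  }
})

test_that("MoM refuses unequal replication; REML handles it", {
  ds <- make_unbalanced_ds(n_G = 60, r = 2, loci = "A", seed = 2)
  # drop one observation: replication becomes unequal
  ph <- ds$phenotypes[-1, ]
  dsu <- asv_dataset(ph, ds$genotypes, locus_cols = "A",
                     replicate_col = "replicate")
  expect_error(anova_mom(dsu, marker_factors("A")), "unequal replication")
  # crossed factors with unequal joint counts also refuse
  ds2 <- make_unbalanced_ds(n_G = 60, r = 2, loci = c("A", "B"), seed = 2)
  expect_error(anova_mom(ds2, marker_factors(c("A", "B"))),
               "unequal genotype class counts")
  fit <- reml_fit(ds, marker_factors("A"))
  expect_true(all(fit$components >= 0))
  expect_named(fit$components, c("A", "G:M"))
  expect_equal(unname(fit$df["A"]), 2)
  expect_equal(unname(fit$df["G:M"]), 57)
})

test_that("single-factor MoM stays unbiased under unequal class counts", {
  # the one-way coefficient (n_G - sum n_h^2/n_G)/df_M generalizes the
  # entries-per-class multiplier; method-of-moments stays unbiased
  counts <- c(30, 90, 60); r <- 2
  sigma2_M <- 2; sigma2_GM <- 1; sigma2_eps <- 0.5
  n_rep <- 150
  est <- matrix(NA_real_, n_rep, 2)
  for (i in seq_len(n_rep)) {
    set.seed(7000 + i)
    n_G <- sum(counts)
    geno <- data.frame(entry = sprintf("e%04d", 1:n_G),
                       M = rep(c("AA", "Aa", "aa"), times = counts))
    u <- rnorm(3, 0, sqrt(sigma2_M))
    ent <- u[match(geno$M, c("AA", "Aa", "aa"))] +
      rnorm(n_G, 0, sqrt(sigma2_GM))
    phen <- data.frame(entry = rep(geno$entry, each = r),
                       replicate = rep(1:r, n_G),
                       value = rep(ent, each = r) +
                         rnorm(n_G * r, 0, sqrt(sigma2_eps)))
    ds <- asv_dataset(phen, geno, locus_cols = "M",
                      replicate_col = "replicate")
    f <- anova_mom(ds, marker_factors("M"))$fit
    est[i, ] <- f$components_raw[c("M", "G:M")]
  }
  se <- apply(est, 2, sd) / sqrt(n_rep)
  expect_lt(abs(mean(est[, 1]) - sigma2_M), 3 * se[1])
  expect_lt(abs(mean(est[, 2]) - sigma2_GM), 3 * se[2])
})

test_that("marker-partitioned components over-count the genetic variance", {
  # sigma2_M + sigma2_G:M >= sigma2_G, with the gap (1 - k) sigma2_M
  for (seed in 1:4) {
    ds <- make_balanced_ds(n_G = 60, r = 3, sigma2_M = 4, seed = seed)
    mm <- anova_mom(ds)$fit
    ent <- fit_entry_model(ds)
    lhs <- unname(mm$components["M"] + mm$components["G:M"])
    expect_gte(lhs + 1e-12, ent$sigma2_G)
    k <- k_balanced(3, 20, 60)
    expect_equal(lhs - ent$sigma2_G, (1 - k) * unname(mm$components["M"]),
                 tolerance = 1e-9)
  }
})

test_that("entry model reports entry-mean phenotypic variance", {
  ds <- make_balanced_ds(n_G = 90, r = 4, seed = 6)
  ent <- fit_entry_model(ds)
  expect_equal(ent$sigma2_Pbar, ent$sigma2_G + ent$sigma2_eps / 4)
  expect_equal(ent$df_G, 89)

  ds1 <- make_counts_ds(c(10, 10, 10), r = 1)
  expect_error(fit_entry_model(ds1), "unreplicated")
})

test_that("simulated components are recovered within Monte-Carlo error", {
  truth <- c(M = 2, `G:M` = 1)
  ests <- matrix(NA_real_, 40, 3)
  for (i in 1:40) {
    ds <- make_balanced_ds(n_G = 90, r = 3, sigma2_M = 2, sigma2_GM = 1,
                           sigma2_eps = 0.5, seed = 100 + i)
    f <- anova_mom(ds)$fit
    ests[i, ] <- c(f$components_raw, f$sigma2_eps)
  }
  # sigma2_M has ~chi2_2 spread (3 classes); G:M and eps are high-df
  se <- apply(ests, 2, sd) / sqrt(nrow(ests))
  expect_lt(abs(mean(ests[, 1]) - 2), 3 * se[1])
  expect_lt(abs(mean(ests[, 2]) - 1), 3 * se[2])
  expect_lt(abs(mean(ests[, 3]) - 0.5), 3 * se[3])
})

test_that("fits serialize to JSON with full precision", {
  ds <- make_balanced_ds(n_G = 30, r = 2, seed = 1)
  fit <- anova_mom(ds)$fit
  js <- jsonlite::fromJSON(vc_to_json(fit))
  expect_equal(js$components$M, unname(fit$components["M"]))
  expect_equal(js$method, "MoM")
})
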