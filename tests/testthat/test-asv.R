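test_that("balanced k follows the degrees-of-freedom ratio", {
  expect_equal(k_balanced(3, 180, 540), 360 / 539)
  expect_equal(k_balanced(3, 300, 900), 600 / 899)
  # saturated factor: one entry per class, k = 1
  expect_equal(k_balanced(10, 1, 10), 1)
  expect_error(k_balanced(1, 10), "not estimable")
})

test_that("unbalanced single-factor k reproduces published GWAS values", {
  expect_equal(k_single_locus(c(141, 282, 141)), 0.6261, tolerance = 1e-4)
  expect_equal(k_single_locus(c(16, 177, 371)), 0.4688, tolerance = 1e-4)
  expect_equal(round(k_single_locus(c(16, 177, 371)), 2), 0.47)
  # cattle marginal counts through both routes
  for (cnt in list(c(78, 736, 2159), c(237, 976, 1760))) {
    ds <- make_counts_ds(cnt)
    expect_equal(k_trace(indicator_matrix(ds, "M")), k_single_locus(cnt))
  }
  expect_equal(round(k_single_locus(c(78, 736, 2159)), 2), 0.41)
  expect_equal(round(k_single_locus(c(237, 976, 1760)), 2), 0.54)
  # equal counts reduce to the balanced formula
  expect_equal(k_single_locus(c(180, 180, 180)), k_balanced(3, 180))
  # single class: non-estimable
  k0 <- k_single_locus(c(12))
  expect_equal(as.numeric(k0), 0)
  expect_true(attr(k0, "non_estimable"))
})

test_that("trace k agrees with the closed form and the dense oracle", {
  set.seed(21)
  for (i in 1:15) {
    counts <- sample(1:30, sample(2:5, 1), replace = TRUE)
    ds <- make_counts_ds(counts, seed = 300 + i)
    Z <- indicator_matrix(ds, "M")
    k_tr <- k_trace(Z)
    expect_equal(k_tr, k_single_locus(counts))
    D <- centering_projector(sum(counts))
    expect_equal(k_tr, sum(diag(Z %*% t(Z) %*% D)) / (sum(counts) - 1))
    expect_gt(k_tr, 0); expect_lte(k_tr, 1)
  }
  # entry identity: k = 1
  ds <- make_counts_ds(c(4, 5))
  expect_equal(k_trace(entry_identity(ds)), 1)
})

test_that("semivariance partition scales components by k, nested terms by 1", {
  ds <- make_balanced_ds(n_G = 60, r = 3, seed = 5)
  fit <- anova_mom(ds)$fit
  k <- k_coefficients(ds, marker_factors("M"))
  amv <- amv_partition(fit)
  asv <- asv_partition(fit, k)
  expect_equal(amv, fit$components)  # identity map
  expect_equal(unname(asv["M"]), unname(k_balanced(3, 20, 60) * amv["M"]))
  expect_equal(unname(asv["G:M"]), unname(amv["G:M"]))
  expect_true(all(asv <= amv + 1e-12))
  # correction commutes with summation
  expect_equal(sum(asv), sum(unclass(k)[names(amv)] * amv))
})

test_that("published bias-corrected variances follow from k times sigma2", {
  k493 <- k_single_locus(c(141, 282, 141))
  expect_equal(round(k493 * 1.48, 2), 0.93)
  k20 <- k_single_locus(c(237, 976, 1760))
  expect_equal(round(k20 * 3.81, 2), 2.04)
})

test_that("ratio estimators reproduce the published strawberry row", {
  k396 <- k_single_locus(c(16, 177, 371))
  p <- suppressWarnings(estimate_p(theta_M = k396 * 4.48, sigma2_M = 4.48,
                                   sigma2_G = 3.26))
  expect_equal(round(p$p_star, 2), 0.64)
  expect_equal(round(p$p, 2), 1.37)
  h <- suppressWarnings(estimate_H2M(theta_M = k396 * 4.48, sigma2_M = 4.48,
                                     sigma2_G = 3.26, sigma2_eps = 0.23,
                                     r_G = 4))
  expect_equal(round(h$H2_star, 2), 0.63)
  expect_equal(round(h$H2, 2), 1.35)
  expect_equal(h$denominator, 3.26 + 0.23 / 4)
  expect_warning(estimate_H2M(4.48, 4.48, 3.26, 0.23, 4), "exceeds 1")
})

test_that("estimator ordering chain holds whenever k < 1 and sigma2_M > 0", {
  for (seed in 1:5) {
    ds <- make_balanced_ds(n_G = 60, r = 3, sigma2_M = 3, seed = seed)
    fit <- anova_mom(ds)$fit
    if (fit$components["M"] <= 0) next
    k <- unclass(k_coefficients(ds, marker_factors("M")))["M"]
    s2m <- unname(fit$components["M"])
    s2gm <- unname(fit$components["G:M"])
    p_unc <- s2m / (k * s2m + s2gm)          # conventional, biased up
    p_mid <- s2m / (s2m + s2gm)              # pooled denominator
    p_cor <- k * s2m / (k * s2m + s2gm)      # corrected
    expect_gt(p_unc, p_mid)
    expect_gt(p_mid, p_cor)
  }
})

test_that("balanced fits reconcile: k sigma2_M + sigma2_G:M = sigma2_G", {
  for (seed in c(3, 7, 12)) {
    ds <- make_balanced_ds(n_G = 90, r = 3, seed = seed)
    fit <- anova_mom(ds)$fit
    ent <- fit_entry_model(ds)
    k <- k_balanced(3, 30, 90)
    expect_equal(unname(k * fit$components["M"] + fit$components["G:M"]),
                 ent$sigma2_G, tolerance = 1e-10)
  }
})

test_that("unreplicated pathway uses the phenotypic variance denominator", {
  ds <- make_counts_ds(c(40, 80, 40), r = 1, seed = 13)
  fit <- anova_mom(ds)$fit
  k <- k_coefficients(ds, marker_factors("M"))
  h <- h2_unreplicated(fit, k, s2_P = 10.42)
  expect_equal(h$s2_P, 10.42)
  theta <- unname(asv_partition(fit, k)["M"])
  expect_equal(h$H2_star, theta / 10.42)
  # default denominator: sample variance of the observations
  h2 <- h2_unreplicated(fit, k, dataset = ds)
  expect_equal(h2$s2_P, var(ds$phenotypes$value))
  # zero marker variance gives zero heritability
  fit0 <- fit; fit0$components["M"] <- 0
  expect_equal(h2_unreplicated(fit0, k, s2_P = 2)$H2_star, 0)
  # replicated fits are rejected
  dsr <- make_balanced_ds(n_G = 30, r = 2)
  expect_error(h2_unreplicated(anova_mom(dsr)$fit, k, s2_P = 1),
               "replicated")
})

test_that("asv_report assembles partitions, ratios and a per-source table", {
  ds <- make_balanced_ds(n_G = 90, r = 4, sigma2_M = 4, sigma2_GM = 0.5,
                         sigma2_eps = 0.4, seed = 17)
  rep <- suppressWarnings(asv_report(ds))
  expect_s3_class(rep, "asv_report")
  expect_equal(rep$table$source, c("M", "G:M", "Residual"))
  expect_equal(rep$fit$method, "MoM")
  expect_equal(rep$theta_M,
               unname(unclass(rep$k)["M"] * rep$fit$components["M"]))
  expect_equal(rep$p$p_star, rep$theta_M / rep$entry_model$sigma2_G)
  # JSON and TSV serialization round-trip the headline numbers
  js <- jsonlite::fromJSON(report_to_json(rep))
  expect_equal(js$theta_M, rep$theta_M)
  tsv <- tempfile(fileext = ".tsv")
  report_to_tsv(rep, tsv)
  tab <- read.delim(tsv)
  expect_equal(tab$sigma2_star[1], unname(rep$asv["M"]))
  unlink(tsv)
  # mom on unbalanced data is refused with a pointer to REML
  dsu <- make_unbalanced_ds(n_G = 60, r = 2, loci = "A", seed = 3)
  expect_error(asv_report(dsu, method = "mom"), "reml")
})
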