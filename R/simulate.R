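#' Catalog of the 21 standard simulation study designs
#'
#' Designs 1-3: one to three loci (all interactions), balanced genotypes,
#' n_G = 540 entries, r_G = 5, marker heritability drawn uniformly per
#' population. Design 4: F2-type 1:2:1 segregation (135:270:135).
#' Designs 5-6: balanced genotypes with 10% / 33% of observations deleted at
#' random. Designs 7-11: n_G = 900, H2 = 0.5, r_G in {1,2,5,10,20}.
#' Designs 12-16: r_G = 5, H2 = 0.5, n_G in {450,900,1800,3600,7200}.
#' Designs 17-21: n_G = 450, r_G = 5, H2 in {0.05,...,0.95}.
#'
#' @return Named list of `study_design` objects.
#' @export
design_catalog <- function() {
  mk <- function(id, n_G, r_G, m = 1L, scheme = "balanced",
                 missing = 0, H2 = "uniform") {
    structure(list(id = id, n_G = n_G, r_G = r_G, m = m, n_M = 3L,
                   scheme = scheme, missing = missing, H2 = H2),
              class = "study_design")
  }
  designs <- list(
    mk(1L, 540L, 5L, m = 1L),
    mk(2L, 540L, 5L, m = 2L),
    mk(3L, 540L, 5L, m = 3L),
    mk(4L, 540L, 5L, m = 1L, scheme = "F2"),
    mk(5L, 540L, 5L, m = 1L, missing = 0.10),
    mk(6L, 540L, 5L, m = 1L, missing = 1 / 3))
  r_grid <- c(1L, 2L, 5L, 10L, 20L)
  for (i in seq_along(r_grid))
    designs[[6L + i]] <- mk(6L + i, 900L, r_grid[i], H2 = 0.5)
  n_grid <- c(450L, 900L, 1800L, 3600L, 7200L)
  for (i in seq_along(n_grid))
    designs[[11L + i]] <- mk(11L + i, n_grid[i], 5L, H2 = 0.5)
  h_grid <- seq(0.05, 0.95, length.out = 5L)
  for (i in seq_along(h_grid))
    designs[[16L + i]] <- mk(16L + i, 450L, 5L, H2 = h_grid[i])
  stats::setNames(designs, paste0("design", 1:21))
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(paste0("study design %d: n_G = %d, r_G = %d, %d locus/loci,",
                     " scheme = %s, missing = %.2f, H2 = %s\n"),
              x$id, x$n_G, x$r_G, x$m, x$scheme, x$missing,
              if (identical(x$H2, "uniform")) "uniform(0,1)"
              else format(x$H2)))
  invisible(x)
}

# class counts per locus under the design's scheme
design_locus_counts <- function(design) {
  n_G <- design$n_G
  if (design$scheme == "F2") {
    if (n_G %% 4L != 0L) stop("F2 scheme needs n_G divisible by 4",
                              call. = FALSE)
    return(c(n_G / 4L, n_G / 2L, n_G / 4L))
  }
  if (n_G %% design$n_M != 0L)
    stop("balanced scheme needs n_G divisible by ", design$n_M,
         call. = FALSE)
  rep(n_G / design$n_M, design$n_M)
}

#' Simulate one population for a study design
#'
#' Phenotypes are mu + per-class marker effects (fresh normal draws per
#' factor and population) + normal entry-nested effects + normal residuals.
#' Component variances are solved from the target marker heritability on
#' the semivariance scale: with the entry-mean phenotypic variance
#' normalized to 1, theta_M = H2 (split equally across marker factors,
#' sigma2_c = theta_c / k_c), and the non-marker budget 1 - H2 is split
#' half/half between the entry-nested component and sigma2_eps/r_G.
#'
#' @param design a `study_design` (see [design_catalog()]).
#' @param seed integer seed for this population.
#' @return An [asv_dataset()] with attribute `truth`: list with `H2`,
#'   per-factor `sigma2` and `theta` (= k sigma2), `k`, `sigma2_GM`,
#'   `sigma2_eps`, `p_true`.
#' @export
simulate_population <- function(design, seed) {
  stopifnot(inherits(design, "study_design"))
  set.seed(seed)
  n_G <- design$n_G; r <- design$r_G; m <- design$m
  loci <- paste0("M", seq_len(m))
  counts1 <- design_locus_counts(design)

  # genotype assignment: deterministic expected counts, entries shuffled
  geno <- data.frame(entry = sprintf("e%05d", seq_len(n_G)),
                     stringsAsFactors = FALSE)
  if (m == 1L) {
    cls <- rep(c("AA", "Aa", "aa"), times = counts1)
    geno[[loci]] <- sample(cls)
  } else {
    cells <- do.call(expand.grid,
                     stats::setNames(rep(list(c("AA", "Aa", "aa")), m),
                                     loci))
    per <- n_G / nrow(cells)
    idx <- sample(rep(seq_len(nrow(cells)), each = per))
    for (l in loci) geno[[l]] <- as.character(cells[[l]][idx])
  }

  factors <- marker_factors(loci)
  H2 <- if (identical(design$H2, "uniform")) stats::runif(1) else design$H2

  # per-factor k from the deterministic class counts
  ks <- vapply(factors, function(f) {
    cls <- if (length(f) == 1L) geno[[f]]
           else do.call(paste, c(geno[f], sep = ":"))
    k_single_locus(table(cls))
  }, 0)
  theta_c <- rep(H2 / length(factors), length(factors))
  sigma2_c <- theta_c / ks
  sigma2_GM <- (1 - H2) / 2
  sigma2_eps <- r * (1 - H2) / 2

  # class effects are drawn fresh per population, then centered and scaled
  # so the realized between-entry marker variance equals the target exactly
  # (the simulated QTL explains exactly its share of the phenotypic
  # variance); the estimators' sampling noise, not the effect draw, is then
  # what the replicates measure
  eff <- numeric(n_G)
  for (i in seq_along(factors)) {
    f <- factors[[i]]
    cls <- if (length(f) == 1L) geno[[f]]
           else do.call(paste, c(geno[f], sep = ":"))
    levs <- unique(cls)
    u <- stats::rnorm(length(levs))
    if (theta_c[i] > 0 && length(levs) > 1L) {
      n_c <- as.numeric(table(cls)[levs])
      u <- u - sum(n_c * u) / n_G
      realized <- sum(n_c * u^2) / (n_G - 1)
      u <- u * sqrt(theta_c[i] / realized)
    } else u <- u * 0
    eff <- eff + u[match(cls, levs)]
  }
  g_eff <- stats::rnorm(n_G, 0, sqrt(sigma2_GM))

  phen <- data.frame(
    entry = rep(geno$entry, each = r),
    replicate = rep(seq_len(r), times = n_G),
    value = rep(eff + g_eff, each = r) +
      stats::rnorm(n_G * r, 0, sqrt(sigma2_eps)),
    stringsAsFactors = FALSE)

  ds <- asv_dataset(phen, geno, entry_col = "entry", trait_col = "value",
                    locus_cols = loci, replicate_col = "replicate")
  if (design$missing > 0)
    ds <- apply_missingness(ds, design$missing, seed = seed + 10^6)
  attr(ds, "truth") <- list(
    H2 = H2, k = ks,
    sigma2 = stats::setNames(sigma2_c, names(factors)),
    theta = stats::setNames(theta_c, names(factors)),
    theta_M = sum(theta_c), sigma2_M = sum(sigma2_c),
    sigma2_GM = sigma2_GM, sigma2_eps = sigma2_eps,
    p_true = sum(theta_c) / (sum(theta_c) + sigma2_GM))
  ds
}

#' Delete phenotypic observations at random
#'
#' Removes exactly `floor(fraction * n_obs)` observations uniformly at
#' random; entries left without any observation are dropped (with a
#' message), which also reshapes the genotype class counts downstream k
#' computations see.
#'
#' @param dataset an [asv_dataset()].
#' @param fraction fraction of observations to delete, in [0, 1).
#' @param seed integer seed.
#' @return A new `asv_dataset`.
#' @export
apply_missingness <- function(dataset, fraction, seed) {
  stopifnot(inherits(dataset, "asv_dataset"), fraction >= 0, fraction < 1)
  if (fraction == 0) return(dataset)
  set.seed(seed)
  ph <- dataset$phenotypes
  n_del <- floor(fraction * nrow(ph))
  drop <- sample.int(nrow(ph), n_del)
  ph <- ph[-drop, , drop = FALSE]
  lost <- setdiff(dataset$genotypes$entry, unique(ph$entry))
  if (length(lost))
    message(length(lost), " entr(y/ies) lost all observations and were dropped")
  geno <- dataset$genotypes[!dataset$genotypes$entry %in% lost, ,
                            drop = FALSE]
  suppressWarnings(asv_dataset(ph, geno, entry_col = "entry",
                               trait_col = "value",
                               locus_cols = dataset$loci,
                               replicate_col = "replicate"))
}

# one replicate's estimates for run_design
estimate_replicate <- function(ds, design, estimator) {
  truth <- attr(ds, "truth")
  factors <- marker_factors(paste0("M", seq_len(design$m)))
  balanced <- design$scheme == "balanced" && design$missing == 0
  use_mom <- estimator == "mom" || (estimator == "auto" && balanced)
  fit <- if (use_mom) suppressMessages(anova_mom(ds, factors)$fit)
         else suppressMessages(reml_fit(ds, factors))
  k <- k_coefficients(ds, factors)
  marker <- setdiff(names(fit$components), "G:M")
  sigma2_M <- sum(fit$components[marker])
  theta_M <- sum(asv_partition(fit, k)[marker])

  if (design$r_G > 1L) {
    ent <- suppressMessages(fit_entry_model(ds))
    den_p <- ent$sigma2_G
    den_h <- ent$sigma2_Pbar
    p_amv <- if (den_p > 0) sigma2_M / den_p else NA_real_
    p_asv <- if (den_p > 0) theta_M / den_p else NA_real_
    h_amv <- sigma2_M / den_h
    h_asv <- theta_M / den_h
  } else {
    s2P <- stats::var(ds$phenotypes$value)
    p_amv <- p_asv <- NA_real_
    h_amv <- sigma2_M / s2P
    h_asv <- theta_M / s2P
  }
  c(sigma2_M_amv = sigma2_M, sigma2_M_asv = theta_M,
    p_amv = p_amv, p_asv = p_asv, H2_amv = h_amv, H2_asv = h_asv,
    truth_theta = truth$theta_M, truth_p = truth$p_true,
    truth_H2 = truth$H2)
}

#' Run a simulation study design
#'
#' Simulates `n_reps` independent populations (one RNG stream per replicate,
#' seed = base seed + replicate index) and estimates the marker-associated
#' variance, p and marker heritability per replicate on both the
#' conventional and the semivariance scale. Truth is defined on the
#' semivariance scale (theta_M = k sigma2_M), so the conventional estimator
#' of the marker variance has expected relative bias (1 - k)/k while the
#' corrected one is unbiased.
#'
#' @param design a `study_design`.
#' @param n_reps number of replicate populations.
#' @param seed base seed.
#' @param estimator "auto" (MoM when balanced, REML otherwise), "mom", or
#'   "reml".
#' @return Object of class `sim_summary`: list with `summary` (data.frame:
#'   parameter, estimator, mean, truth, bias, RB, var), `estimates` (the
#'   per-replicate matrix), `n_failed`, `design`.
#' @export
run_design <- function(design, n_reps, seed = 1L,
                       estimator = c("auto", "mom", "reml")) {
  stopifnot(inherits(design, "study_design"), n_reps >= 1L)
  estimator <- match.arg(estimator)
  res <- matrix(NA_real_, nrow = n_reps, ncol = 9L)
  n_failed <- 0L
  for (rep_i in seq_len(n_reps)) {
    est <- tryCatch({
      ds <- suppressMessages(simulate_population(design, seed + rep_i))
      estimate_replicate(ds, design, estimator)
    }, error = function(e) NULL)
    if (is.null(est)) n_failed <- n_failed + 1L else res[rep_i, ] <- est
  }
  colnames(res) <- c("sigma2_M_amv", "sigma2_M_asv", "p_amv", "p_asv",
                     "H2_amv", "H2_asv", "truth_theta", "truth_p",
                     "truth_H2")
  res <- res[stats::complete.cases(res[, c("sigma2_M_amv", "truth_theta")]),
             , drop = FALSE]

  # pooled relative bias: (mean est - mean truth)/mean truth; identical to
  # the usual RB for fixed-truth designs, well-defined when truth varies
  summarize <- function(est_col, truth_col) {
    est <- res[, est_col]; truth <- res[, truth_col]
    ok <- is.finite(est) & is.finite(truth)
    est <- est[ok]; truth <- truth[ok]
    if (length(est) == 0L)
      return(c(mean = NA_real_, truth = NA_real_, bias = NA_real_,
               RB = NA_real_, var = NA_real_, RB_se = NA_real_))
    m <- mean(est); tr <- mean(truth)
    c(mean = m, truth = tr, bias = m - tr,
      RB = if (tr > 0) (m - tr) / tr else NA_real_,
      var = stats::var(est),
      RB_se = if (tr > 0) stats::sd(est) / sqrt(length(est)) / tr
              else NA_real_)
  }
  stats <- rbind(summarize("sigma2_M_amv", "truth_theta"),
                 summarize("sigma2_M_asv", "truth_theta"),
                 summarize("p_amv", "truth_p"),
                 summarize("p_asv", "truth_p"),
                 summarize("H2_amv", "truth_H2"),
                 summarize("H2_asv", "truth_H2"))
  summary <- data.frame(
    parameter = rep(c("sigma2_M", "p", "H2_M"), each = 2L),
    estimator = rep(c("AMV", "ASV"), times = 3L),
    stats, stringsAsFactors = FALSE, row.names = NULL)
  structure(list(summary = summary, estimates = res, n_failed = n_failed,
                 design = design, seed = seed, n_reps = n_reps),
            class = "sim_summary")
}

#' @export
print.sim_summary <- function(x, ...) {
  cat(sprintf("simulation: design %d, %d replicates (%d failed)\n",
              x$design$id, x$n_reps, x$n_failed))
  tab <- x$summary
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}
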