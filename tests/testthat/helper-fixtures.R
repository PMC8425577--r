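# Fixtures are built in code: no data files.

# balanced single-locus dataset with known generating components
make_balanced_ds <- function(n_G = 60, r = 3, sigma2_M = 2, sigma2_GM = 1,
                             sigma2_eps = 0.5, seed = 1,
                             classes = c("AA", "Aa", "aa")) {
  stopifnot(n_G %% length(classes) == 0)
  set.seed(seed)
  geno <- data.frame(entry = sprintf("e%04d", seq_len(n_G)),
                     M = rep(classes, each = n_G / length(classes)),
                     stringsAsFactors = FALSE)
  u <- rnorm(length(classes), 0, sqrt(sigma2_M))
  g <- rnorm(n_G, 0, sqrt(sigma2_GM))
  phen <- data.frame(entry = rep(geno$entry, each = r),
                     replicate = rep(seq_len(r), n_G),
                     value = rep(u[match(geno$M, classes)] + g, each = r) +
                       rnorm(n_G * r, 0, sqrt(sigma2_eps)),
                     stringsAsFactors = FALSE)
  asv_dataset(phen, geno, locus_cols = "M", replicate_col = "replicate")
}

# dataset with prescribed genotype class counts (phenotypes iid noise)
make_counts_ds <- function(counts, r = 1, seed = 1,
                           classes = paste0("c", seq_along(counts))) {
  set.seed(seed)
  n_G <- sum(counts)
  geno <- data.frame(entry = sprintf("e%04d", seq_len(n_G)),
                     M = rep(classes, times = counts),
                     stringsAsFactors = FALSE)
  phen <- data.frame(entry = rep(geno$entry, each = r),
                     replicate = rep(seq_len(r), n_G),
                     value = rnorm(n_G * r),
                     stringsAsFactors = FALSE)
  asv_dataset(phen, geno, locus_cols = "M", replicate_col = "replicate")
}

# unbalanced multi-locus dataset for fixed-effects / REML paths
make_unbalanced_ds <- function(n_G = 90, r = 2, loci = c("A", "B"),
                               seed = 1) {
  set.seed(seed)
  geno <- data.frame(entry = sprintf("e%04d", seq_len(n_G)),
                     stringsAsFactors = FALSE)
  for (l in loci)
    geno[[l]] <- sample(paste0(l, 1:3), n_G, replace = TRUE,
                        prob = c(0.2, 0.5, 0.3))
  effects <- rnorm(n_G, 0, 1)
  for (l in loci) {
    u <- rnorm(3, 0, 1.2)
    effects <- effects + u[match(geno[[l]], paste0(l, 1:3))]
  }
  phen <- data.frame(entry = rep(geno$entry, each = r),
                     replicate = rep(seq_len(r), n_G),
                     value = rep(effects, each = r) + rnorm(n_G * r, 0, 0.7),
                     stringsAsFactors = FALSE)
  asv_dataset(phen, geno, locus_cols = loci, replicate_col = "replicate")
}

# REML deviance of the single-locus observation-level model at a given
# component vector (M, G:M, eps): certifies a candidate solution is the
# REML optimum in objective space, which is better conditioned than
# parameter-space comparison for low-df components
reml_deviance_at <- function(ds, sigma2_M, sigma2_GM, sigma2_eps) {
  ph <- ds$phenotypes
  df <- data.frame(value = ph$value,
                   f1 = ds$genotypes$M[match(ph$entry, ds$genotypes$entry)],
                   entry = ph$entry)
  devfun <- lme4::lmer(value ~ 1 + (1 | f1) + (1 | entry), data = df,
                       REML = TRUE, devFunOnly = TRUE)
  # theta order follows the random-effects terms: entry then f1 (more
  # levels first in lme4's ordering)
  devfun(c(sqrt(sigma2_GM / sigma2_eps), sqrt(sigma2_M / sigma2_eps)))
}

# model frame with factor columns for oracle lm fits
oracle_frame <- function(ds) {
  ph <- ds$phenotypes
  idx <- match(ph$entry, ds$genotypes$entry)
  out <- data.frame(y = ph$value)
  for (l in ds$loci) out[[l]] <- factor(ds$genotypes[[l]][idx])
  out
}
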