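#' Delta-method variance of a ratio
#'
#' First-order expansion for R = num/den:
#' `Var(R) ~= R^2 (Var(num)/num^2 + Var(den)/den^2 - 2 Cov/(num den))`,
#' with the num = 0 case handled by the exact-in-the-limit form
#' `Var(num)/den^2`.
#'
#' @param num,den point estimates (den != 0).
#' @param var_num,var_den their sampling variances.
#' @param cov their sampling covariance (default 0).
#' @return Approximate variance of the ratio (floored at 0: the truncated
#'   expansion can go negative under strong correlation).
#' @export
delta_var_ratio <- function(num, den, var_num, var_den, cov = 0) {
  if (!is.finite(den) || den == 0) stop("den must be nonzero", call. = FALSE)
  if (num == 0) return(var_num / den^2)
  r <- num / den
  max(r^2 * (var_num / num^2 + var_den / den^2 - 2 * cov / (num * den)), 0)
}

#' Sampling variances of balanced MoM variance components
#'
#' Under normality each mean square is distributed as
#' `MS_s ~ E(MS_s) chi^2_df / df`, so `Var(MS_s) ~= 2 MS_s^2 / df_s` (the
#' observed MS plugged in for its expectation). MoM components are the
#' linear map `sigma2 = C^{-1} MS` of the mean squares through the inverse
#' EMS coefficient matrix, so their covariance is
#' `C^{-1} diag(2 MS^2/df) C^{-T}`.
#'
#' @param ems an `ems_table` from [anova_mom()].
#' @return List: `cov` (component covariance matrix, sources as in the EMS
#'   table) and `var_ms` (the mean-square variances).
#' @export
varcomp_sampling_variances <- function(ems) {
  stopifnot(inherits(ems, "ems_table"))
  tab <- ems$table
  var_ms <- 2 * tab$MS^2 / tab$df
  Cinv <- solve(ems$coefficients)
  cov <- Cinv %*% diag(var_ms, nrow = length(var_ms)) %*% t(Cinv)
  dimnames(cov) <- dimnames(ems$coefficients)
  list(cov = cov, var_ms = stats::setNames(var_ms, tab$source))
}

#' Bootstrap variance of a ratio estimator
#'
#' Entries (with all their replicates) are the independent sampling units of
#' the models, so resampling draws whole entry records with replacement.
#' Degenerate resamples in which some modelled factor collapses to a single
#' genotype class are redrawn (the redraw count is reported).
#'
#' @param dataset an [asv_dataset()].
#' @param estimator function(dataset) returning a numeric scalar.
#' @param B number of bootstrap resamples (>= 100).
#' @param seed integer seed; resamples are reproducible from (dataset, B,
#'   seed).
#' @param loci loci that must retain >= 2 classes in each resample
#'   (default: all loci of the dataset).
#' @param level confidence level for the percentile interval.
#' @return Object of class `ratio_variance`: list with `estimate` (on the
#'   full data), `variance`, `se`, `ci` (percentile), `B`, `seed`,
#'   `redraws` and the vector of bootstrap `replicates`.
#' @export
bootstrap_ratio <- function(dataset, estimator, B = 1000L, seed = 1L,
                            loci = dataset$loci, level = 0.95) {
  stopifnot(inherits(dataset, "asv_dataset"), B >= 100L)
  ids <- dataset$genotypes$entry
  phen_by_entry <- split(dataset$phenotypes, dataset$phenotypes$entry)
  set.seed(seed)
  est <- estimator(dataset)
  reps <- numeric(B)
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      pick <- sample(ids, length(ids), replace = TRUE)
      g <- dataset$genotypes[match(pick, ids), , drop = FALSE]
      ok <- all(vapply(loci, function(l)
        length(unique(g[[l]][!is.na(g[[l]])])) >= 2L, TRUE))
      if (ok) break
      redraws <- redraws + 1L
    }
    # resampled entries get fresh ids so duplicates stay distinct units
    new_id <- sprintf("b%06d", seq_along(pick))
    ph <- do.call(rbind, phen_by_entry[pick])
    ph$entry <- rep(new_id, times = vapply(phen_by_entry[pick], nrow, 0L))
    g$entry <- new_id
    ds <- suppressWarnings(asv_dataset(ph, g, entry_col = "entry",
                                       trait_col = "value",
                                       locus_cols = dataset$loci))
    reps[b] <- estimator(ds)
  }
  alpha <- (1 - level) / 2
  structure(list(estimate = est, variance = stats::var(reps),
                 se = stats::sd(reps),
                 ci = stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE),
                 B = B, seed = seed, redraws = redraws, replicates = reps),
            class = "ratio_variance")
}

#' @export
print.ratio_variance <- function(x, ...) {
  cat(sprintf("bootstrap (B = %d, seed = %d): estimate %.4f, se %.4f, %s\n",
              x$B, x$seed, x$estimate,
              x$se, paste0("CI [", paste(round(x$ci, 4), collapse = ", "),
                           "]")))
  if (x$redraws) cat("  degenerate resamples redrawn:", x$redraws, "\n")
  invisible(x)
}
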