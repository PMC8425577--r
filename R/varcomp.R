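#' Marker factor specifications for a genetic model
#'
#' Builds the ordered list of random marker factors (main effects first, then
#' interactions of increasing order) for a set of loci, as used by the
#' estimation functions. Each factor is a character vector of locus names;
#' an interaction is the joint-class (cell-membership) factor of its loci.
#'
#' @param loci character vector of locus names.
#' @param interactions include all interactions among the loci (default TRUE
#'   when more than one locus).
#' @return List of character vectors, named by factor label (loci joined by
#'   ":").
#' @export
marker_factors <- function(loci, interactions = TRUE) {
  stopifnot(length(loci) >= 1L)
  specs <- as.list(loci)
  if (interactions && length(loci) > 1L) {
    for (ord in 2:length(loci))
      specs <- c(specs, utils::combn(loci, ord, simplify = FALSE))
  }
  stats::setNames(specs, vapply(specs, paste, "", collapse = ":"))
}

factor_label <- function(spec) paste(unlist(spec), collapse = ":")

# degrees of freedom for marker factors over observed classes:
# df(f) = (#observed joint classes - 1) - sum df(g) over modelled g strictly
# contained in f. For fully observed balanced data this is prod(n_lev - 1).
marker_dfs <- function(dataset, factors) {
  labs <- vapply(factors, factor_label, "")
  nclass <- vapply(factors, function(f)
    length(genotype_class_counts(dataset, f)), 0L)
  df <- stats::setNames(numeric(length(factors)), labs)
  sizes <- vapply(factors, length, 0L)
  for (i in order(sizes)) {
    contained <- which(vapply(factors, function(g)
      length(factors[[i]]) > length(g) && all(g %in% factors[[i]]), TRUE))
    df[i] <- (nclass[i] - 1) - sum(df[contained])
  }
  df
}

#' ANOVA method-of-moments variance components (balanced data)
#'
#' Closed-form estimators for the replicated marker model
#' y = mu + (marker factors) + G:M + eps and its unreplicated counterpart
#' (no eps; entries-within-markers is the residual). Sums of squares are the
#' classical balanced factorial decomposition, expected mean squares are
#' assembled for the all-random model, and components solve the linear EMS
#' system. For a single locus this reduces to
#' `sigma2_M = (MS_M - MS_G:M)/(r_G n_G:M)` and
#' `sigma2_G:M = (MS_G:M - MS_eps)/r_G`.
#'
#' Refuses unbalanced data (unequal replication or unequal joint genotype
#' class counts) and points at [reml_fit()].
#'
#' @param dataset an [asv_dataset()].
#' @param factors list of marker factor specs (see [marker_factors()]);
#'   default: main effects and all interactions of every locus in the data.
#' @return List with elements `fit` (a `vc_fit`) and `ems` (the EMS table:
#'   source, SS, df, MS and expected-mean-square coefficients).
#' @export
anova_mom <- function(dataset, factors = NULL) {
  stopifnot(inherits(dataset, "asv_dataset"))
  if (is.null(factors)) factors <- marker_factors(dataset$loci)
  dataset <- complete_for_loci(dataset, unique(unlist(factors)))
  labs <- vapply(factors, factor_label, "")

  r_j <- dataset$r_G
  if (length(unique(r_j)) != 1L)
    stop("unequal replication; use reml_fit() for unbalanced data",
         call. = FALSE)
  r <- unname(r_j[1L])
  # closed forms require equal joint class counts for crossed factors; a
  # single factor admits the standard unbalanced one-way coefficient
  # c = (n_G - sum n_h^2 / n_G) / df_M in place of n_G:M
  full_counts <- genotype_class_counts(dataset, unique(unlist(factors)))
  if (length(factors) > 1L &&
      length(unique(as.integer(full_counts))) != 1L)
    stop("unequal genotype class counts; use reml_fit() for unbalanced data",
         call. = FALSE)

  ph <- dataset$phenotypes
  n_G <- dataset$n_G
  gm <- mean(ph$value)
  ybar <- tapply(ph$value, ph$entry, mean)[dataset$genotypes$entry]

  ss_tot <- sum((ph$value - gm)^2)
  ss_G <- r * sum((ybar - gm)^2)
  df_G <- n_G - 1

  # raw (uncorrected) between-cell SS per factor, then subtract contained terms
  raw_ss <- function(spec) {
    cls <- joint_classes(dataset, spec)
    cm <- tapply(ybar, cls, mean)
    nc <- table(cls)[names(cm)]
    r * sum(as.numeric(nc) * (cm - gm)^2)
  }
  sizes <- vapply(factors, length, 0L)
  ss_f <- stats::setNames(numeric(length(factors)), labs)
  for (i in order(sizes)) {
    contained <- which(vapply(factors, function(g)
      sizes[i] > length(g) && all(g %in% factors[[i]]), TRUE))
    ss_f[i] <- raw_ss(factors[[i]]) - sum(ss_f[contained])
  }
  df_f <- marker_dfs(dataset, factors)

  replicated <- r > 1L
  # EMS coefficient on sigma2_f: entries/class when balanced, else the
  # unbalanced one-way coefficient (identical to n/class for equal counts)
  n_per <- vapply(factors, function(f) {
    cnt <- genotype_class_counts(dataset, f)
    trace_zzd(cnt) / (length(cnt) - 1)
  }, 0)

  if (replicated) {
    sources <- c(labs, "G:M", "eps")
    ss <- c(ss_f, ss_G - sum(ss_f), ss_tot - ss_G)
    df <- c(df_f, df_G - sum(df_f), n_G * (r - 1))
  } else {
    sources <- c(labs, "G:M")
    ss <- c(ss_f, ss_tot - sum(ss_f))
    df <- c(df_f, df_G - sum(df_f))
  }
  names(ss) <- names(df) <- sources
  ms <- ss / df

  # EMS coefficient matrix: rows = sources, cols = components (same order)
  C <- matrix(0, length(sources), length(sources),
              dimnames = list(sources, sources))
  if (replicated) {
    C[, "eps"] <- 1
    C["G:M", "G:M"] <- r
    for (i in seq_along(factors)) {
      C[labs[i], "G:M"] <- r
      containing <- which(vapply(factors, function(g)
        all(factors[[i]] %in% g), TRUE))
      for (j in containing) C[labs[i], labs[j]] <- r * n_per[j]
    }
  } else {
    C[, "G:M"] <- 1
    for (i in seq_along(factors)) {
      containing <- which(vapply(factors, function(g)
        all(factors[[i]] %in% g), TRUE))
      for (j in containing) C[labs[i], labs[j]] <- n_per[j]
    }
  }
  est_raw <- solve(C, ms)
  boundary <- est_raw < 0
  est <- pmax(est_raw, 0)
  if (any(boundary))
    message("MoM component(s) truncated at zero: ",
            paste(sources[boundary], collapse = ", "))

  comp_names <- if (replicated) c(labs, "G:M") else c(labs, "G:M")
  fit <- new_vc_fit(
    components = est[comp_names],
    components_raw = est_raw[comp_names],
    sigma2_eps = if (replicated) unname(est["eps"]) else NA_real_,
    method = "MoM", df = df, logLik = NA_real_,
    converged = TRUE, boundary = boundary,
    n_G = n_G, r_G = r, factors = factors)

  ems <- list(table = data.frame(source = sources, SS = as.numeric(ss),
                                 df = as.numeric(df), MS = as.numeric(ms),
                                 stringsAsFactors = FALSE),
              coefficients = C)
  class(ems) <- "ems_table"
  list(fit = fit, ems = ems)
}

#' @export
print.ems_table <- function(x, ...) {
  cat("ANOVA table (balanced method of moments):\n")
  print(x$table, row.names = FALSE)
  cat("expected-mean-square coefficients:\n")
  print(x$coefficients)
  invisible(x)
}

new_vc_fit <- function(components, components_raw, sigma2_eps, method, df,
                       logLik, converged, boundary, n_G, r_G, factors) {
  structure(list(components = components, components_raw = components_raw,
                 sigma2_eps = sigma2_eps, method = method, df = df,
                 logLik = logLik, converged = converged, boundary = boundary,
                 n_G = n_G, r_G = r_G, factors = factors),
            class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat("variance components (", x$method, "):\n", sep = "")
  comps <- c(x$components, eps = x$sigma2_eps)
  print(round(comps, 4))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  if (any(x$boundary, na.rm = TRUE))
    cat("  boundary:", paste(names(x$boundary)[x$boundary], collapse = ", "),
        "\n")
  invisible(x)
}

#' REML variance components for the marker model
#'
#' Restricted-maximum-likelihood fit of the observation-level marker model
#' y = mu + (marker factors) + G:M + eps via [lme4::lmer()] (the estimator
#' is defined by the likelihood, not the solver; lme4 constrains components
#' to be non-negative). When every entry is observed once the entry-nested
#' term is dropped and entries-within-markers becomes the residual.
#'
#' @inheritParams anova_mom
#' @return A `vc_fit` with per-factor components, `G:M`, residual, REML
#'   log-likelihood, convergence and boundary flags.
#' @export
reml_fit <- function(dataset, factors = NULL) {
  stopifnot(inherits(dataset, "asv_dataset"))
  if (is.null(factors)) factors <- marker_factors(dataset$loci)
  dataset <- complete_for_loci(dataset, unique(unlist(factors)))
  labs <- vapply(factors, factor_label, "")

  for (i in seq_along(factors))
    if (length(genotype_class_counts(dataset, factors[[i]])) < 2L)
      stop("factor ", labs[i], " has a single observed class; not estimable",
           call. = FALSE)

  ph <- dataset$phenotypes
  df <- data.frame(value = ph$value, stringsAsFactors = FALSE)
  geno_idx <- match(ph$entry, dataset$genotypes$entry)
  safe <- paste0("f", seq_along(factors))
  for (i in seq_along(factors))
    df[[safe[i]]] <- joint_classes(dataset, factors[[i]])[geno_idx]
  replicated <- any(dataset$r_G > 1L)
  if (replicated) df$entry <- ph$entry

  terms <- paste0("(1|", safe, ")", collapse = " + ")
  if (replicated) terms <- paste(terms, "+ (1|entry)")
  form <- stats::as.formula(paste("value ~ 1 +", terms))

  # bobyqa with a tight trust-region floor: balanced fits must agree with
  # the closed-form ANOVA solutions to ~1e-6 relative
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.nlev.gtr.1 = "stop",
                            optimizer = "bobyqa",
                            optCtrl = list(rhoend = 1e-12))
  fit <- lme4::lmer(form, data = df, REML = TRUE, control = ctrl)
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(grp) vc$vcov[match(grp, vc$grp)]
  comps <- stats::setNames(vapply(safe, get_vc, 0), labs)
  sigma2_gm <- if (replicated) get_vc("entry") else get_vc("Residual")
  sigma2_eps <- if (replicated) get_vc("Residual") else NA_real_
  components <- c(comps, "G:M" = sigma2_gm)

  df_f <- marker_dfs(dataset, factors)
  df_G <- dataset$n_G - 1
  dfs <- c(df_f, "G:M" = df_G - sum(df_f))
  if (replicated) dfs <- c(dfs, eps = sum(dataset$r_G) - dataset$n_G)

  conv <- length(fit@optinfo$conv$lme4) == 0L
  boundary <- components < 1e-8 * max(components, sigma2_eps, na.rm = TRUE)
  new_vc_fit(components = components, components_raw = components,
             sigma2_eps = sigma2_eps, method = "REML", df = dfs,
             logLik = as.numeric(stats::logLik(fit)), converged = conv,
             boundary = boundary, n_G = dataset$n_G,
             r_G = if (dataset$balanced) unname(dataset$r_G[1]) else dataset$r_G,
             factors = factors)
}

#' Entry-only model: genetic and residual variance
#'
#' Fits y = mu + G + eps (no markers). Balanced data use the closed-form
#' ANOVA estimators `sigma2_G = (MS_G - MS_eps)/r_G`; unbalanced data use
#' REML. Also returns the phenotypic variance on an entry-mean basis,
#' `sigma2_Pbar = sigma2_G + sigma2_eps/r_G` (harmonic-mean r under unequal
#' replication, reported with a message since the closed form assumes a
#' common r_G).
#'
#' @param dataset an [asv_dataset()].
#' @return List: `sigma2_G`, `sigma2_eps`, `sigma2_Pbar`, `r_G` (the value
#'   used in the denominator), `df_G`, `method`.
#' @export
fit_entry_model <- function(dataset) {
  stopifnot(inherits(dataset, "asv_dataset"))
  if (all(dataset$r_G == 1L))
    stop(paste("all entries unreplicated: sigma2_G and sigma2_eps are not",
               "separable; use the unreplicated pathway (h2_unreplicated)"),
         call. = FALSE)
  ph <- dataset$phenotypes
  n_G <- dataset$n_G
  if (dataset$balanced) {
    r <- unname(dataset$r_G[1L])
    gm <- mean(ph$value)
    ybar <- tapply(ph$value, ph$entry, mean)
    ss_G <- r * sum((ybar - gm)^2)
    ss_eps <- sum((ph$value - gm)^2) - ss_G
    ms_G <- ss_G / (n_G - 1)
    ms_eps <- ss_eps / (n_G * (r - 1))
    sigma2_eps <- ms_eps
    sigma2_G <- max((ms_G - ms_eps) / r, 0)
    method <- "MoM"
    r_eff <- r
  } else {
    fit <- lme4::lmer(value ~ 1 + (1 | entry), data = ph, REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    sigma2_G <- vc$vcov[vc$grp == "entry"]
    sigma2_eps <- vc$vcov[vc$grp == "Residual"]
    method <- "REML"
    r_eff <- length(dataset$r_G) / sum(1 / dataset$r_G)
    message("unequal replication: sigma2_Pbar uses the harmonic mean of r_j (",
            signif(r_eff, 4), ")")
  }
  list(sigma2_G = sigma2_G, sigma2_eps = sigma2_eps,
       sigma2_Pbar = sigma2_G + sigma2_eps / r_eff,
       r_G = r_eff, df_G = n_G - 1, method = method)
}

#' Serialize a variance-component fit to JSON
#'
#' @param fit a `vc_fit`.
#' @param path optional file; when NULL the JSON string is returned.
#' @export
vc_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "vc_fit"))
  obj <- list(method = fit$method,
              components = as.list(fit$components),
              sigma2_eps = fit$sigma2_eps,
              df = as.list(fit$df),
              logLik = fit$logLik,
              converged = fit$converged,
              boundary = as.list(fit$boundary))
  if (is.null(path))
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  else
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
}
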