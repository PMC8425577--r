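#' k bias coefficient for a balanced single factor
#'
#' For a factor with `n_levels` classes of `n_per_class` entries each among
#' `n_G = n_levels * n_per_class` entries,
#' `k = (n_levels - 1) * n_per_class / (n_G - 1)`. This is the fraction by
#' which the factor's variance component enters the genetic variance, and
#' hence the multiplicative correction that takes a conventional marginal
#' variance component to the semivariance (between-entry) scale.
#'
#' @param n_levels number of genotype classes (>= 2).
#' @param n_per_class entries per class.
#' @param n_G total entries; defaults to `n_levels * n_per_class`.
#' @return k in (0, 1].
#' @export
k_balanced <- function(n_levels, n_per_class, n_G = n_levels * n_per_class) {
  if (n_levels < 2L) stop("factor with < 2 classes is not estimable",
                          call. = FALSE)
  stopifnot(n_G == n_levels * n_per_class)
  (n_levels - 1) * n_per_class / (n_G - 1)
}

#' k bias coefficient for a single factor with unbalanced class counts
#'
#' `k = (n_G - sum(n_h^2)/n_G) / (n_G - 1)` over the observed class counts
#' n_h. Reduces to [k_balanced()] when all counts are equal.
#'
#' @param counts class counts (a [genotype_class_counts()] or plain vector).
#' @return k in (0, 1]; 0 with a `non_estimable` attribute for a single
#'   class.
#' @export
k_single_locus <- function(counts) {
  n <- as.numeric(counts)
  stopifnot(all(n >= 1))
  if (length(n) < 2L) {
    out <- 0
    attr(out, "non_estimable") <- TRUE
    return(out)
  }
  n_G <- sum(n)
  (n_G - sum(n^2) / n_G) / (n_G - 1)
}

#' k bias coefficient from an indicator matrix (trace formula)
#'
#' `k = tr(Z Z' D) / (n_G - 1)` for a class-membership indicator Z and the
#' mean-centering projector D. Computed by count arithmetic on the column
#' sums (the dense product is exercised only in tests); applies unchanged to
#' joint-class indicators of interactions, which is how multilocus k values
#' are obtained here.
#'
#' @param indicator an [indicator_matrix()] (or any 0/1 class-membership
#'   matrix with one 1 per row).
#' @return k in (0, 1].
#' @export
k_trace <- function(indicator) {
  stopifnot(is.matrix(indicator), all(indicator %in% c(0, 1)),
            all(rowSums(indicator) == 1))
  counts <- colSums(indicator)
  n_G <- nrow(indicator)
  trace_zzd(counts) / (n_G - 1)
}

#' k bias coefficients for every factor of a model
#'
#' One k per random marker factor, from that factor's own (joint-class)
#' counts via the trace formula; the entry and entry-nested factors have
#' k = 1 by construction.
#'
#' @param dataset an [asv_dataset()].
#' @param factors list of factor specs (see [marker_factors()]).
#' @return Object of class `k_coefficients`: named numeric vector of k
#'   values (marker factors then `G:M` = 1) with a `formula` attribute
#'   ("balanced", "unbalanced-closed-form" per factor).
#' @export
k_coefficients <- function(dataset, factors) {
  labs <- vapply(factors, factor_label, "")
  ks <- numeric(length(factors))
  tags <- character(length(factors))
  for (i in seq_along(factors)) {
    cnt <- genotype_class_counts(dataset, factors[[i]])
    ks[i] <- k_single_locus(cnt)
    tags[i] <- if (length(unique(as.integer(cnt))) == 1L) "balanced"
               else "unbalanced-closed-form"
  }
  out <- stats::setNames(c(ks, 1), c(labs, "G:M"))
  attr(out, "formula") <- stats::setNames(c(tags, "identity"),
                                          c(labs, "G:M"))
  class(out) <- "k_coefficients"
  out
}

#' @export
print.k_coefficients <- function(x, ...) {
  cat("k bias coefficients:\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Conventional (marginal-variance) partition of a fit
#'
#' On the conventional scale every factor's contribution is its variance
#' component unchanged; this is the identity map, returned explicitly so
#' the two partitions can be compared side by side.
#'
#' @param fit a `vc_fit`.
#' @return Named numeric vector of per-factor variances (marker factors and
#'   `G:M`).
#' @export
amv_partition <- function(fit) {
  stopifnot(inherits(fit, "vc_fit"))
  fit$components
}

#' Semivariance partition of a fit
#'
#' Multiplies each factor's variance component by its k coefficient:
#' `theta_c = k_c * sigma2_c`. Entry-nested components are unchanged
#' (k = 1). On balanced data the marker-side semivariance components plus
#' `G:M` reconstitute the entry-model genetic variance exactly.
#'
#' @param fit a `vc_fit`.
#' @param k a [k_coefficients()] for the same factors.
#' @return Named numeric vector of corrected per-factor variances.
#' @export
asv_partition <- function(fit, k) {
  stopifnot(inherits(fit, "vc_fit"), inherits(k, "k_coefficients"))
  comps <- fit$components
  if (!all(names(comps) %in% names(k)))
    stop("k coefficients missing for: ",
         paste(setdiff(names(comps), names(k)), collapse = ", "),
         call. = FALSE)
  comps * unclass(k)[names(comps)]
}

#' Fraction of genetic variance explained by markers
#'
#' Corrected estimate `p_star = theta_M / sigma2_G` with
#' `theta_M = sum(k_c sigma2_c)` over marker factors, alongside the
#' conventional (upwardly biased) `p = sum(sigma2_c) / sigma2_G`. The
#' preferred denominator is the entry-model genetic variance; when absent it
#' falls back to the reconstruction `theta_M + sigma2_G:M`.
#'
#' @param theta_M corrected marker-associated variance (sum of k-scaled
#'   marker components).
#' @param sigma2_M uncorrected marker-associated variance (sum of raw
#'   marker components).
#' @param sigma2_G entry-model genetic variance, or NULL to use the
#'   fallback denominator.
#' @param sigma2_GM entry-nested component (needed for the fallback).
#' @return List `p_star`, `p` (uncorrected), `denominator`.
#' @export
estimate_p <- function(theta_M, sigma2_M, sigma2_G = NULL, sigma2_GM = NULL) {
  if (is.null(sigma2_G)) {
    if (is.null(sigma2_GM))
      stop("need sigma2_G or sigma2_GM for the denominator", call. = FALSE)
    den <- theta_M + sigma2_GM
  } else den <- sigma2_G
  if (!is.finite(den) || den <= 0)
    stop("genetic variance is zero; p is undefined", call. = FALSE)
  out <- list(p_star = theta_M / den, p = sigma2_M / den, denominator = den)
  if (out$p_star > 1 || out$p > 1)
    warning("p estimate exceeds 1 (reported as-is): ",
            "diagnostic of k bias or sampling noise")
  out
}

#' Marker heritability on an entry-mean basis
#'
#' Corrected `H2_star = theta_M / (sigma2_G + sigma2_eps/r_G)` and the
#' conventional `H2 = sigma2_M / (sigma2_G + sigma2_eps/r_G)`. Estimates
#' greater than 1 are reported as-is with a warning, never truncated: an
#' uncorrected value above 1 is the telltale signature of the design bias.
#'
#' @inheritParams estimate_p
#' @param sigma2_eps residual variance.
#' @param r_G replications per entry (harmonic mean if unequal).
#' @return List `H2_star`, `H2` (uncorrected), `denominator`.
#' @export
estimate_H2M <- function(theta_M, sigma2_M, sigma2_G, sigma2_eps, r_G,
                         sigma2_GM = NULL) {
  if (is.null(sigma2_G)) {
    if (is.null(sigma2_GM))
      stop("need sigma2_G or sigma2_GM for the denominator", call. = FALSE)
    base <- theta_M + sigma2_GM
  } else base <- sigma2_G
  den <- base + sigma2_eps / r_G
  if (!is.finite(den) || den <= 0) stop("phenotypic variance is zero",
                                        call. = FALSE)
  out <- list(H2_star = theta_M / den, H2 = sigma2_M / den,
              denominator = den)
  if (out$H2_star > 1 || out$H2 > 1)
    warning("H2 estimate exceeds 1 (reported as-is): ",
            "diagnostic of k bias or sampling noise")
  out
}

#' Marker heritability for unreplicated entries
#'
#' With one observation per entry the entry-nested genetic term is the
#' residual and sigma2_G cannot be estimated; marker heritability is still
#' estimable as `sum(k_c sigma2_c) / s2_P` against the phenotypic variance
#' among individuals (supplied externally, e.g. from transformed raw data,
#' or computed as the sample variance of the observations).
#'
#' @param fit a `vc_fit` from an unreplicated model (no residual split).
#' @param k matching [k_coefficients()].
#' @param s2_P phenotypic variance among individuals; default the sample
#'   variance of the observations used in the fit.
#' @param dataset the dataset (needed only for the default s2_P).
#' @return List `H2_star`, `H2` (uncorrected), `s2_P`.
#' @export
h2_unreplicated <- function(fit, k, s2_P = NULL, dataset = NULL) {
  stopifnot(inherits(fit, "vc_fit"))
  if (!is.na(fit$sigma2_eps))
    stop("fit has a separate residual: data are replicated; use estimate_H2M",
         call. = FALSE)
  if (is.null(s2_P)) {
    if (is.null(dataset))
      stop("supply s2_P or the dataset to compute it from", call. = FALSE)
    s2_P <- stats::var(dataset$phenotypes$value)
  }
  stopifnot(is.finite(s2_P), s2_P > 0)
  marker <- setdiff(names(fit$components), "G:M")
  theta <- sum(asv_partition(fit, k)[marker])
  raw <- sum(fit$components[marker])
  list(H2_star = theta / s2_P, H2 = raw / s2_P, s2_P = s2_P)
}

#' Full semivariance analysis of a dataset
#'
#' The main entry point for data analysis: fits the entry-only model (when
#' replication permits), fits the marker model by REML (or balanced MoM),
#' computes k per factor, and assembles conventional and corrected variance
#' partitions, p and marker heritability.
#'
#' @param dataset an [asv_dataset()].
#' @param factors marker factor specs; default main effects and all
#'   interactions of every locus.
#' @param method "reml", "mom" or "auto" (MoM when balanced, REML
#'   otherwise).
#' @param s2_P phenotypic variance denominator for unreplicated data
#'   (optional; defaults to the sample variance of the observations).
#' @return Object of class `asv_report`: a list with the fit, k
#'   coefficients, partitions (`amv`, `asv`), `p`, `H2`, denominators and a
#'   Table-style data.frame (`table`).
#' @export
asv_report <- function(dataset, factors = NULL, method = c("auto", "reml",
                                                           "mom"),
                       s2_P = NULL) {
  stopifnot(inherits(dataset, "asv_dataset"))
  method <- match.arg(method)
  if (is.null(factors)) factors <- marker_factors(dataset$loci)
  dataset <- complete_for_loci(dataset, unique(unlist(factors)))

  balanced_classes <- dataset$balanced &&
    length(unique(as.integer(
      genotype_class_counts(dataset, unique(unlist(factors)))))) == 1L
  if (method == "mom" && !balanced_classes)
    stop("data are unbalanced; method 'mom' is only valid for balanced ",
         "data - use method 'reml'", call. = FALSE)
  use_mom <- method == "mom" || (method == "auto" && balanced_classes)

  replicated <- any(dataset$r_G > 1L)
  fit <- if (use_mom) anova_mom(dataset, factors)$fit
         else reml_fit(dataset, factors)
  k <- k_coefficients(dataset, factors)
  amv <- amv_partition(fit)
  asv <- asv_partition(fit, k)
  marker <- setdiff(names(fit$components), "G:M")
  theta_M <- sum(asv[marker])
  sigma2_M <- sum(amv[marker])

  if (replicated) {
    ent <- fit_entry_model(dataset)
    p <- estimate_p(theta_M, sigma2_M, sigma2_G = ent$sigma2_G)
    H2 <- estimate_H2M(theta_M, sigma2_M, sigma2_G = ent$sigma2_G,
                       sigma2_eps = ent$sigma2_eps, r_G = ent$r_G)
  } else {
    ent <- NULL
    p <- NULL
    H2 <- h2_unreplicated(fit, k, s2_P = s2_P, dataset = dataset)
  }

  tab <- data.frame(
    source = c(names(amv), "Residual"),
    df = c(as.numeric(fit$df[names(amv)]),
           if (replicated) as.numeric(fit$df["eps"]) else NA),
    k = c(unclass(k)[names(amv)], NA),
    sigma2 = c(as.numeric(amv), fit$sigma2_eps),
    sigma2_star = c(as.numeric(asv), fit$sigma2_eps),
    stringsAsFactors = FALSE)
  tab$k[tab$source == "G:M"] <- NA

  structure(list(fit = fit, k = k, amv = amv, asv = asv,
                 theta_M = theta_M, sigma2_M = sigma2_M,
                 entry_model = ent, p = p, H2 = H2, table = tab,
                 replicated = replicated),
            class = "asv_report")
}

#' @export
print.asv_report <- function(x, ...) {
  cat("Semivariance analysis (", x$fit$method, " components)\n", sep = "")
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(v) round(v, 2))
  print(tab, row.names = FALSE)
  if (!is.null(x$p))
    cat(sprintf("p: uncorrected %.2f, corrected %.2f\n", x$p$p, x$p$p_star))
  if (!is.null(x$H2)) {
    lab <- if (x$replicated) "H2_M (entry-mean basis)" else
      "H2_M (unreplicated, s2_P denominator)"
    cat(sprintf("%s: uncorrected %.2f, corrected %.2f\n", lab,
                x$H2$H2, x$H2$H2_star))
  }
  invisible(x)
}

#' Serialize a semivariance report
#'
#' `report_to_json()` writes the full-precision report; `report_to_tsv()`
#' writes the per-source table (source, df, k, uncorrected and corrected
#' variances) as tab-separated text.
#'
#' @param report an [asv_report()].
#' @param path output file; for JSON, NULL returns the string.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "asv_report"))
  obj <- list(method = report$fit$method,
              k = as.list(unclass(report$k)),
              amv = as.list(report$amv),
              asv = as.list(report$asv),
              sigma2_eps = report$fit$sigma2_eps,
              theta_M = report$theta_M, sigma2_M = report$sigma2_M,
              entry_model = report$entry_model,
              p = report$p, H2 = report$H2)
  if (is.null(path))
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                            na = "null")
}

#' @rdname report_to_json
#' @export
report_to_tsv <- function(report, path) {
  stopifnot(inherits(report, "asv_report"))
  utils::write.table(report$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
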