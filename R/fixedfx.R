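# Fixed-effects multilocus ANOVA: sequential (Type I), hierarchy-respecting
# (Type II) and fully partial (Type III) reductions in error sums of squares,
# with coefficients of partial determination. Terms are marker main effects
# and interactions, entered as joint-class (cell membership) factors, so
# model spans match the classical factorial parameterization.

# data.frame of response + one factor column per term, named term1..termk
fixed_model_frame <- function(dataset, terms) {
  ph <- dataset$phenotypes
  idx <- match(ph$entry, dataset$genotypes$entry)
  df <- data.frame(y = ph$value)
  for (i in seq_along(terms))
    df[[paste0("term", i)]] <- factor(joint_classes(dataset,
                                                    terms[[i]])[idx])
  if (anyNA(df)) {
    keep <- stats::complete.cases(df)
    df <- df[keep, , drop = FALSE]
  }
  df
}

sse_of <- function(df, cols) {
  if (length(cols) == 0L) {
    fit <- stats::lm(y ~ 1, data = df)
  } else {
    form <- stats::as.formula(paste("y ~", paste(cols, collapse = " + ")))
    fit <- stats::lm(form, data = df)
  }
  list(sse = sum(stats::resid(fit)^2), rank = fit$rank,
       aliased = anyNA(stats::coef(fit)))
}

#' Reduction in error sum of squares for one term
#'
#' `R(term | conditioning) = SSE(conditioning) - SSE(conditioning + term)`
#' from least-squares fits of cell-indicator models. A rank-deficient
#' augmented model is fit over its estimable part (pivoted least squares)
#' and flagged.
#'
#' @param dataset an [asv_dataset()].
#' @param term factor spec: a locus name or character vector of loci.
#' @param conditioning_terms list of factor specs already in the model
#'   (may be empty).
#' @return Numeric SS with attributes `df` (rank increase) and
#'   `rank_deficient`.
#' @export
reduction_in_ss <- function(dataset, term, conditioning_terms = list()) {
  terms <- c(conditioning_terms, list(unlist(term)))
  df <- fixed_model_frame(dataset, terms)
  cols <- paste0("term", seq_along(terms))
  base <- sse_of(df, cols[-length(cols)])
  aug <- sse_of(df, cols)
  out <- base$sse - aug$sse
  attr(out, "df") <- aug$rank - base$rank
  attr(out, "rank_deficient") <- aug$aliased
  out
}

# default interaction entry sequence: pairs in locus order, then the
# highest-order interaction (A x B, A x C, B x C, A x B x C for 3 loci)
interaction_sequence <- function(loci) {
  if (length(loci) < 2L) return(list())
  specs <- list()
  if (length(loci) >= 2L)
    specs <- utils::combn(loci, 2L, simplify = FALSE)
  if (length(loci) >= 3L)
    for (ord in 3:length(loci))
      specs <- c(specs, utils::combn(loci, ord, simplify = FALSE))
  specs
}

new_sstable <- function(term_labels, ss, df, total_ss, type, order = NA) {
  data.frame(term = term_labels, SS = as.numeric(ss), df = as.numeric(df),
             partial_R2 = as.numeric(ss) / total_ss,
             type = type, order = order, stringsAsFactors = FALSE)
}

total_corrected_ss <- function(dataset, terms) {
  df <- fixed_model_frame(dataset, terms)
  sum((df$y - mean(df$y))^2)
}

#' Sequential (Type I) sums of squares
#'
#' Main effects enter in the given order; interactions enter afterwards in a
#' single fixed sequence (two-way interactions in locus order, then higher
#' orders), so the six main-effect orders of a three-locus model share their
#' interaction rows.
#'
#' @param dataset an [asv_dataset()].
#' @param main_effect_order character vector: a permutation of the modelled
#'   loci.
#' @param interactions list of interaction specs to append (default: all
#'   interactions of the ordered loci in the standard sequence); use
#'   `list()` for a main-effects-only model.
#' @return SS table (data.frame: term, SS, df, partial_R2, type, order).
#' @export
type1_table <- function(dataset, main_effect_order,
                        interactions = NULL) {
  loci <- main_effect_order
  stopifnot(all(loci %in% dataset$loci))
  if (is.null(interactions))
    interactions <- interaction_sequence(sort(loci))
  terms <- c(as.list(loci), interactions)
  labels <- vapply(terms, paste, "", collapse = ":")
  ss <- df <- numeric(length(terms))
  for (i in seq_along(terms)) {
    red <- reduction_in_ss(dataset, terms[[i]], terms[seq_len(i - 1L)])
    ss[i] <- red
    df[i] <- attr(red, "df")
  }
  new_sstable(labels, ss, df, total_corrected_ss(dataset, terms),
              type = "I", order = paste(loci, collapse = ""))
}

#' All six Type I orders for a three-locus model
#'
#' @inheritParams type1_table
#' @param loci the three loci (any length >= 2 works; all permutations are
#'   run).
#' @return Named list of SS tables, one per main-effect order.
#' @export
type1_all_orders <- function(dataset, loci = dataset$loci,
                             interactions = NULL) {
  perms <- permutations_of(loci)
  out <- lapply(perms, function(p) type1_table(dataset, p, interactions))
  names(out) <- vapply(perms, paste, "", collapse = "")
  out
}

permutations_of <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(permutations_of(x[-i]), function(p) c(x[i], p)))
  out
}

#' Type II sums of squares
#'
#' Each term is conditioned on every other term in the model that does not
#' contain it: main effects on the other main effects (no interactions),
#' each two-way interaction on all main effects and the other two-way
#' interactions, and so on.
#'
#' @inheritParams type1_table
#' @param terms model terms (default: mains plus all interactions of the
#'   dataset's loci).
#' @return SS table.
#' @export
type2_table <- function(dataset, terms = NULL) {
  if (is.null(terms))
    terms <- c(as.list(dataset$loci), interaction_sequence(dataset$loci))
  labels <- vapply(terms, paste, "", collapse = ":")
  ss <- df <- numeric(length(terms))
  for (i in seq_along(terms)) {
    contains_i <- vapply(terms, function(g)
      all(terms[[i]] %in% g), TRUE)
    cond <- terms[!contains_i]
    red <- reduction_in_ss(dataset, terms[[i]], cond)
    ss[i] <- red
    df[i] <- attr(red, "df")
  }
  new_sstable(labels, ss, df, total_corrected_ss(dataset, terms),
              type = "II")
}

#' Type III sums of squares
#'
#' Each term conditioned on all other terms, under sum-to-zero contrasts
#' over the observed cells (the convention of mainstream ANOVA software;
#' Type III is contrast-dependent when cells are empty, in which case the
#' result carries an `empty_cells` attribute).
#'
#' @inheritParams type2_table
#' @return SS table (attribute `empty_cells` flags missing factorial cells).
#' @export
type3_table <- function(dataset, terms = NULL) {
  if (is.null(terms))
    terms <- c(as.list(dataset$loci), interaction_sequence(dataset$loci))
  labels <- vapply(terms, paste, "", collapse = ":")
  # sum-to-zero model matrix of the crossed factorial in the terms' loci
  loci <- unique(unlist(terms))
  ph <- dataset$phenotypes
  idx <- match(ph$entry, dataset$genotypes$entry)
  mf <- data.frame(y = ph$value)
  for (l in loci) mf[[l]] <- factor(dataset$genotypes[[l]][idx])
  mf <- mf[stats::complete.cases(mf), , drop = FALSE]
  term_formula <- paste(vapply(terms, paste, "", collapse = ":"),
                        collapse = " + ")
  form <- stats::as.formula(paste("y ~", term_formula))
  contrasts_arg <- stats::setNames(rep(list("contr.sum"), length(loci)),
                                   loci)
  X <- stats::model.matrix(form, mf, contrasts.arg = contrasts_arg)
  asgn <- attr(X, "assign")
  tlabs <- attr(stats::terms(form), "term.labels")

  full <- stats::lm.fit(X, mf$y)
  sse_full <- sum(full$residuals^2)
  full_rank <- full$rank
  empty_cells <- full_rank < ncol(X)

  ss <- df <- numeric(length(terms))
  for (i in seq_along(terms)) {
    ti <- match(labels[i], tlabs)
    keep <- asgn != ti
    red_fit <- stats::lm.fit(X[, keep, drop = FALSE], mf$y)
    ss[i] <- sum(red_fit$residuals^2) - sse_full
    df[i] <- full_rank - red_fit$rank
  }
  out <- new_sstable(labels, ss, df, sum((mf$y - mean(mf$y))^2),
                     type = "III")
  attr(out, "empty_cells") <- empty_cells
  out
}

#' Coefficients of partial determination
#'
#' `R2 = SS_term / SS_total` per term of an SS table.
#'
#' @param ss_table an SS table from the type*_table functions.
#' @param total_ss total corrected SS of the response.
#' @return Named numeric vector of per-term R2.
#' @export
partial_r2 <- function(ss_table, total_ss) {
  stopifnot(is.data.frame(ss_table), total_ss > 0)
  stats::setNames(ss_table$SS / total_ss, ss_table$term)
}

#' Combined SS table in wide (per-analysis column) layout
#'
#' One row per term, one column per analysis (each Type I order, Type II,
#' Type III), for writing a compact comparison table.
#'
#' @param tables named list of SS tables sharing the same terms.
#' @return data.frame: term then one SS column per table.
#' @export
sstables_wide <- function(tables) {
  stopifnot(length(tables) >= 1L)
  base <- tables[[1L]]$term
  out <- data.frame(term = base, stringsAsFactors = FALSE)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    out[[nm]] <- tab$SS[match(base, tab$term)]
  }
  out
}
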