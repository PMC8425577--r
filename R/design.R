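#' Indicator design matrix for a marker factor
#'
#' The n_G x n_levels 0/1 class-membership matrix Z for a marker locus or an
#' interaction of loci, over entries sorted by entry id with columns in
#' lexicographic label order (so matrices are bit-reproducible). Rows sum to
#' one; column sums equal the genotype class counts.
#'
#' @param dataset an [asv_dataset()].
#' @param factor_spec locus name or character vector of loci (interaction).
#' @return Numeric matrix with entry ids as rownames and class labels as
#'   colnames.
#' @export
indicator_matrix <- function(dataset, factor_spec) {
  stopifnot(inherits(dataset, "asv_dataset"))
  cls <- joint_classes(dataset, unlist(factor_spec))
  if (anyNA(cls))
    stop("missing genotype classes; apply complete_for_loci() first",
         call. = FALSE)
  levs <- sort(unique(cls))
  Z <- matrix(0, nrow = dataset$n_G, ncol = length(levs),
              dimnames = list(dataset$genotypes$entry, levs))
  Z[cbind(seq_len(dataset$n_G), match(cls, levs))] <- 1
  Z
}

#' Indicator matrix for an interaction of loci
#'
#' Cell-means indicator over the observed joint classes of two or more loci;
#' unobserved combinations contribute no column.
#'
#' @inheritParams indicator_matrix
#' @param loci character vector of at least two locus names.
#' @export
interaction_matrix <- function(dataset, loci) {
  loci <- unlist(loci)
  if (length(loci) < 2L) stop("need at least two loci", call. = FALSE)
  Z <- indicator_matrix(dataset, loci)
  if (ncol(Z) < 2L) attr(Z, "non_estimable") <- TRUE
  Z
}

#' Entry-identity indicator matrix
#'
#' The n_G x n_G identity: each entry its own class. At the entry-means
#' level this is the design for entries and for entries nested in markers
#' alike.
#'
#' @inheritParams indicator_matrix
#' @export
entry_identity <- function(dataset) {
  stopifnot(inherits(dataset, "asv_dataset"))
  ids <- dataset$genotypes$entry
  diag(1, dataset$n_G, dataset$n_G) -> Z
  dimnames(Z) <- list(ids, ids)
  Z
}

#' Mean-centering projector
#'
#' D = I - J/n: symmetric, idempotent, row sums zero, trace n - 1. Used to
#' project out the mean when averaging pairwise squared differences (the
#' semivariance view of total variance).
#'
#' @param n dimension.
#' @return n x n numeric matrix.
#' @export
centering_projector <- function(n) {
  stopifnot(n >= 1)
  D <- diag(1, n) - 1 / n
  # construction-time sanity: idempotent and symmetric to machine tolerance
  stopifnot(isTRUE(all.equal(D, t(D))), isTRUE(all.equal(D %*% D, D)))
  D
}

#' Trace of Z Z' D from class counts
#'
#' For a single-factor indicator Z with class counts n_h over n_G entries,
#' tr(Z Z' D) = n_G - (sum_h n_h^2)/n_G. Count arithmetic only; the dense
#' matrix product is kept to the test oracle.
#'
#' @param counts integer vector of class counts (a [genotype_class_counts()]
#'   result or plain counts).
#' @return The trace (numeric scalar).
#' @export
trace_zzd <- function(counts) {
  n <- as.numeric(counts)
  stopifnot(all(n >= 1), all(n == round(n)))
  n_G <- sum(n)
  n_G - sum(n^2) / n_G
}
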