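#' Assemble a phenotype/genotype dataset
#'
#' Joins a long-format phenotype table (one row per observation) to a
#' per-entry genotype table (one categorical column per marker locus) and
#' validates the result. Entries phenotyped but missing a genotype record at
#' any of the requested loci are dropped with a warning; per-model listwise
#' exclusion of entries with missing genotype classes happens later, at fit
#' time, so that each marker model uses the largest usable subset.
#'
#' @param phenotypes data.frame with one row per phenotypic observation.
#' @param genotypes data.frame with one row per entry and one column per
#'   marker locus holding genotype class labels (e.g. "AA","Aa","aa");
#'   `NA` marks a missing genotype call.
#' @param entry_col name of the entry identifier column (both tables).
#' @param trait_col name of the numeric trait column in `phenotypes`.
#' @param locus_cols character vector of genotype columns to retain; default
#'   all non-entry columns of `genotypes`.
#' @param replicate_col optional name of a replicate-index column; if absent,
#'   replicates are numbered in order of appearance within entry.
#'
#' @return An object of class `asv_dataset`: a list with elements
#'   `phenotypes` (data.frame: entry, replicate, value), `genotypes`
#'   (data.frame: entry + one column per locus), `loci`, `n_G` (number of
#'   entries), `r_G` (named per-entry replicate counts) and `balanced`
#'   (logical, equal replication).
#' @export
asv_dataset <- function(phenotypes, genotypes, entry_col = "entry",
                        trait_col = "value", locus_cols = NULL,
                        replicate_col = NULL) {
  for (col in c(entry_col, trait_col))
    if (!col %in% names(phenotypes))
      stop("column '", col, "' not found in phenotype table", call. = FALSE)
  if (!entry_col %in% names(genotypes))
    stop("column '", entry_col, "' not found in genotype table", call. = FALSE)
  if (is.null(locus_cols))
    locus_cols <- setdiff(names(genotypes), entry_col)
  missing_loci <- setdiff(locus_cols, names(genotypes))
  if (length(missing_loci))
    stop("locus column(s) not found: ", paste(missing_loci, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(phenotypes[[trait_col]]))
    stop("trait column '", trait_col, "' is not numeric", call. = FALSE)

  entry <- as.character(phenotypes[[entry_col]])
  value <- as.numeric(phenotypes[[trait_col]])
  keep <- is.finite(value)
  if (!all(keep)) {
    warning(sum(!keep), " non-finite trait value(s) dropped")
    entry <- entry[keep]; value <- value[keep]
  }

  gt_entry <- as.character(genotypes[[entry_col]])
  if (anyDuplicated(gt_entry))
    stop("duplicated entry ids in genotype table", call. = FALSE)

  ungenotyped <- setdiff(unique(entry), gt_entry)
  if (length(ungenotyped)) {
    warning(length(ungenotyped),
            " phenotyped entr(y/ies) absent from the genotype table dropped")
    sel <- !(entry %in% ungenotyped)
    entry <- entry[sel]; value <- value[sel]
  }

  if (!is.null(replicate_col)) {
    replicate <- as.integer(phenotypes[[replicate_col]][keep])
    if (length(ungenotyped)) replicate <- replicate[sel]
    if (anyDuplicated(paste(entry, replicate)))
      stop("(entry, replicate) pairs are not unique", call. = FALSE)
  } else {
    replicate <- stats::ave(seq_along(entry), entry, FUN = seq_along)
  }

  ord <- order(entry, replicate)
  phen <- data.frame(entry = entry[ord], replicate = replicate[ord],
                     value = value[ord], stringsAsFactors = FALSE)

  ids <- sort(unique(phen$entry))
  if (length(ids) < 3L)
    stop("fewer than 3 entries after filtering", call. = FALSE)
  geno <- genotypes[match(ids, gt_entry), c(entry_col, locus_cols), drop = FALSE]
  names(geno)[1L] <- "entry"
  geno$entry <- ids
  for (lc in locus_cols) geno[[lc]] <- as.character(geno[[lc]])
  rownames(geno) <- NULL

  r_j <- table(phen$entry)[ids]
  r_G <- stats::setNames(as.integer(r_j), ids)

  structure(list(phenotypes = phen, genotypes = geno, loci = locus_cols,
                 n_G = length(ids), r_G = r_G,
                 balanced = length(unique(r_G)) == 1L),
            class = "asv_dataset")
}

#' @export
print.asv_dataset <- function(x, ...) {
  cat("asv_dataset:", x$n_G, "entries,",
      nrow(x$phenotypes), "observations,",
      length(x$loci), "locus/loci (", paste(x$loci, collapse = ", "), ")\n")
  if (x$balanced) cat("  balanced, r_G =", x$r_G[1L], "\n")
  else cat("  unbalanced, r_j in [", min(x$r_G), ",", max(x$r_G), "]\n")
  invisible(x)
}

#' Restrict a dataset to entries fully genotyped at given loci
#'
#' Listwise exclusion per fitted model: entries with a missing genotype class
#' at any locus of the current model are dropped from that fit only.
#'
#' @param dataset an [asv_dataset()].
#' @param loci character vector of loci the model uses.
#' @return A (possibly smaller) `asv_dataset`.
#' @export
complete_for_loci <- function(dataset, loci) {
  stopifnot(inherits(dataset, "asv_dataset"))
  loci <- unique(unlist(loci))
  bad <- setdiff(loci, dataset$loci)
  if (length(bad)) stop("unknown locus: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  geno <- dataset$genotypes
  ok <- rowSums(is.na(geno[, loci, drop = FALSE])) == 0L
  if (all(ok)) return(dataset)
  ids <- geno$entry[ok]
  message(sum(!ok), " entr(y/ies) excluded (missing genotype at modelled loci)")
  phen <- dataset$phenotypes[dataset$phenotypes$entry %in% ids, , drop = FALSE]
  asv_dataset(phen, geno[ok, , drop = FALSE], entry_col = "entry",
              trait_col = "value", locus_cols = dataset$loci,
              replicate_col = "replicate")
}

#' Genotype class counts for a factor
#'
#' Counts of entries nested in each observed genotype class of a marker
#' locus, or in each observed joint class of an interaction of loci.
#' Unobserved class combinations are omitted (they are not levels).
#'
#' @param dataset an [asv_dataset()].
#' @param factor_spec a locus name, or a character vector of locus names for
#'   an interaction.
#' @return An object of class `genotype_counts`: a named integer vector of
#'   class counts with attributes `factor` (label) and `n_G`.
#' @export
genotype_class_counts <- function(dataset, factor_spec) {
  stopifnot(inherits(dataset, "asv_dataset"))
  factor_spec <- unlist(factor_spec)
  bad <- setdiff(factor_spec, dataset$loci)
  if (length(bad)) stop("unknown locus: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cls <- joint_classes(dataset, factor_spec)
  if (anyNA(cls))
    stop("missing genotype classes present; apply complete_for_loci() first",
         call. = FALSE)
  counts <- table(cls)
  counts <- counts[order(names(counts))]
  out <- stats::setNames(as.integer(counts), names(counts))
  if (length(out) < 2L)
    attr(out, "non_estimable") <- TRUE
  attr(out, "factor") <- paste(factor_spec, collapse = ":")
  attr(out, "n_G") <- dataset$n_G
  class(out) <- "genotype_counts"
  out
}

# joint class label per entry (entries in dataset order), NA-propagating
joint_classes <- function(dataset, loci) {
  g <- dataset$genotypes
  if (length(loci) == 1L) return(g[[loci]])
  cols <- g[, loci, drop = FALSE]
  lab <- do.call(paste, c(cols, sep = ":"))
  lab[rowSums(is.na(cols)) > 0L] <- NA_character_
  lab
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat("genotype class counts for", attr(x, "factor"),
      "(n_G =", attr(x, "n_G"), "):\n")
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Entry-level means and their residual variances
#'
#' Unweighted arithmetic per-entry means (the completely-randomized-design
#' BLUEs) with residual variance of each mean `sigma2_eps / r_j`, the
#' first-stage diagonal residual covariance of a two-stage analysis.
#'
#' @param dataset an [asv_dataset()].
#' @param residual_variance the residual variance estimated from the
#'   entry-only model (see [fit_entry_model()]).
#' @return data.frame with columns `entry`, `mean`, `r`, `var_mean`.
#' @export
entry_means <- function(dataset, residual_variance) {
  stopifnot(inherits(dataset, "asv_dataset"),
            is.numeric(residual_variance), residual_variance >= 0)
  ph <- dataset$phenotypes
  m <- tapply(ph$value, ph$entry, mean)
  ids <- names(m)
  r <- dataset$r_G[ids]
  data.frame(entry = ids, mean = as.numeric(m), r = as.integer(r),
             var_mean = residual_variance / as.numeric(r),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read delimited phenotype/genotype tables
#'
#' Thin readers for header-bearing CSV/TSV files; the delimiter is sniffed
#' from the extension (".csv" vs anything else = tab).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", ""))
}

#' Extract named SNP genotypes from a VCF into a genotype table
#'
#' Pulls the requested SNP IDs from a VCF and maps diploid genotype calls to
#' class labels: `0/0` to "AA", `0/1` or `1/0` to "Aa", `1/1` to "aa";
#' anything else (including missing calls) becomes `NA`.
#'
#' @param vcf_path path to an (uncompressed or bgzipped) VCF file.
#' @param snp_ids character vector of SNP IDs (VCF ID column) to extract.
#' @return data.frame with column `entry` (sample names) and one column per
#'   requested SNP.
#' @export
genotypes_from_vcf <- function(vcf_path, snp_ids) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF input requires the 'vcfR' package", call. = FALSE)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  ids <- vcfR::getID(v)
  miss <- setdiff(snp_ids, ids)
  if (length(miss)) stop("SNP id(s) not in VCF: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  out <- data.frame(entry = colnames(gt), stringsAsFactors = FALSE)
  map_gt <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    cls <- rep(NA_character_, length(x))
    cls[x == "0/0"] <- "AA"
    cls[x %in% c("0/1", "1/0")] <- "Aa"
    cls[x == "1/1"] <- "aa"
    cls
  }
  for (s in snp_ids) out[[s]] <- map_gt(gt[match(s, ids), ])
  out
}
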