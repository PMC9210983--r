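#' Construct a genotype matrix
#'
#' The central in-memory container of the package: biallelic diploid dosages
#' (number of copies of the derived, or alternate, allele) for a set of samples
#' assigned to two focal populations and an optional outgroup.
#'
#' @param geno integer matrix, samples in rows and sites in columns, entries in
#'   `{0, 1, 2, NA}` counting the derived (or alternate) allele.
#' @param sample_ids character vector of sample identifiers (one per row).
#' @param pop character vector with one of `"pop1"`, `"pop2"`, `"outgroup"` per
#'   sample.
#' @param chrom single chromosome identifier.
#' @param pos integer vector of 1-based site positions, strictly increasing.
#' @param polarized logical vector per site: `TRUE` when the ancestral state is
#'   known so that dosage counts the derived allele.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, sample_ids, pop, chrom = "chr1", pos,
                            polarized = rep(TRUE, length(pos))) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != length(sample_ids)) stop("one sample id per genotype row required")
  if (nrow(geno) != length(pop)) stop("one population label per sample required")
  if (ncol(geno) != length(pos)) stop("one position per genotype column required")
  if (ncol(geno) != length(polarized)) stop("one polarization flag per site required")
  if (!all(pop %in% c("pop1", "pop2", "outgroup")))
    stop("population labels must be 'pop1', 'pop2' or 'outgroup'")
  pos <- as.integer(pos)
  if (length(pos) > 1 && any(diff(pos) <= 0))
    stop("positions must be strictly increasing")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must lie in {0, 1, 2, NA}")
  rownames(geno) <- sample_ids
  structure(
    list(geno = geno, sample_ids = as.character(sample_ids),
         pop = as.character(pop), chrom = as.character(chrom)[1], pos = pos,
         polarized = as.logical(polarized)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x", length(x$pos),
      "sites on", x$chrom, "\n")
  tab <- table(factor(x$pop, levels = c("pop1", "pop2", "outgroup")))
  cat("  samples:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  positions:", if (length(x$pos)) paste(min(x$pos), "-", max(x$pos)) else "none",
      "| polarized sites:", sum(x$polarized), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

# Dosage submatrix for one population, sites restricted to a window span.
.pop_geno <- function(g, pop, span = NULL) {
  keep <- g$pop == pop
  if (!any(keep)) stop("no samples labelled '", pop, "'")
  m <- g$geno[keep, , drop = FALSE]
  if (!is.null(span)) m <- m[, g$pos >= span[1] & g$pos <= span[2], drop = FALSE]
  m
}

# Per-site observed allele-copy counts and derived-allele counts for one
# population (columns with zero observed copies keep n = 0).
.site_counts <- function(m) {
  n <- 2L * colSums(!is.na(m))
  d <- colSums(m, na.rm = TRUE)
  list(n = as.numeric(n), d = as.numeric(d))
}

# Restrict a genotype matrix to a span, keeping all samples.
.span_sites <- function(g, span) {
  if (is.null(span)) rep(TRUE, length(g$pos))
  else g$pos >= span[1] & g$pos <= span[2]
}

#' Polarize dosages using outgroup samples
#'
#' Sets the ancestral allele per site to the outgroup majority allele and
#' recodes dosages so that they count the derived allele. Sites where the
#' outgroup is entirely missing or evenly split stay unpolarized.
#'
#' @param g a [genotype_matrix] containing samples labelled `"outgroup"`.
#' @return The matrix with dosages flipped where needed and the `polarized`
#'   flags updated.
#' @export
polarize <- function(g) {
  if (!any(g$pop == "outgroup")) stop("no outgroup samples to polarize against")
  og <- g$geno[g$pop == "outgroup", , drop = FALSE]
  cnt <- .site_counts(og)
  # the outgroup majority allele is taken as ancestral; when the majority
  # carries the coded ("1") allele the coding is flipped so dosage counts the
  # derived allele
  flip <- which(cnt$n > 0 & cnt$d > cnt$n / 2)
  undecided <- cnt$n == 0 | cnt$d * 2 == cnt$n
  if (length(flip)) g$geno[, flip] <- 2L - g$geno[, flip]
  g$polarized <- !undecided
  g
}
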