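#' Broad-sense heritability from replicated genotypes
#'
#' `H^2 = Vg / (Vg + Vr / nrep)`: the fraction of phenotypic variance that is
#' genetic, given `nrep` replicate measurements per genotype. Variance
#' components come from a one-way random-effects decomposition by the method
#' of moments: `Vr` is the within-genotype mean square; `Vg = (between MS -
#' within MS) / n_eff`, with `n_eff` the effective replicate number for
#' unbalanced designs, floored at zero. `nrep` is the arithmetic mean
#' replicate count.
#'
#' @param values numeric phenotype vector.
#' @param genotypes genotype label per value.
#' @return A number in `[0, 1]`, with attributes `Vg`, `Vr`, `nrep`.
#' @export
heritability <- function(values, genotypes) {
  stopifnot(length(values) == length(genotypes))
  ok <- is.finite(values)
  values <- values[ok]; genotypes <- as.character(genotypes)[ok]
  grp <- split(values, genotypes)
  k <- length(grp)
  if (k < 2) stop("heritability undefined with a single genotype")
  ni <- lengths(grp)
  N <- sum(ni)
  if (N == k) stop("heritability requires replicated genotypes")
  means <- vapply(grp, mean, numeric(1))
  grand <- mean(values)
  ssw <- sum(vapply(grp, function(v) sum((v - mean(v))^2), numeric(1)))
  msw <- ssw / (N - k)
  msb <- sum(ni * (means - grand)^2) / (k - 1)
  n_eff <- (N - sum(ni^2) / N) / (k - 1)
  vg <- max(0, (msb - msw) / n_eff)
  nrep <- mean(ni)
  h2 <- vg / (vg + msw / nrep)
  structure(h2, Vg = vg, Vr = msw, nrep = nrep)
}

#' Allele effect size of a QTL
#'
#' The model's effect estimate scaled by the mean trait value of the major
#' allele class. Positive values mean the major allele increases the trait;
#' negative values mean the minor allele does.
#'
#' @param estimate effect estimate from the association model.
#' @param major_allele_values trait values of individuals carrying the major
#'   allele.
#' @return `estimate / mean(major_allele_values)`.
#' @export
allele_effect_size <- function(estimate, major_allele_values) {
  m <- mean(major_allele_values)
  if (!is.finite(m) || abs(m) < .Machine$double.eps)
    stop("effect size undefined: major-allele mean is zero")
  estimate / m
}

#' Co-localize trait-associated SNPs into loci within a genomic window
#'
#' On each chromosome, SNPs within `window` base pairs of each other are
#' merged transitively (union-find semantics: a chain of SNPs each <= window
#' apart forms one locus). Each locus is labelled with the set of trait
#' groups represented in it, and Venn counts tally loci per group
#' combination.
#'
#' @param records data.frame with columns `snp`, `chrom`, `pos`, `trait`,
#'   `group` (e.g. univariate / PH / multivariate); `estimate` and `pvalue`
#'   are carried through if present.
#' @param window co-localization window in bp (default 1 Mb). `window = 0`
#'   merges only identical positions.
#' @return list with `loci` (one row per locus: chrom, start, end, n_snps,
#'   groups), `assignments` (input records plus `locus` id), and `venn`
#'   (named counts of loci per sorted group combination).
#' @export
colocalize_tas <- function(records, window = 1e6) {
  need <- c("snp", "chrom", "pos", "group")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  if (any(records$pos < 0)) stop("positions must be non-negative")
  if (window < 0) stop("window must be non-negative")
  df <- records[order(records$chrom, records$pos), , drop = FALSE]
  locus <- character(nrow(df))
  loci <- list()
  for (ch in unique(df$chrom)) {
    i <- which(df$chrom == ch)
    gaps <- diff(df$pos[i])
    cluster <- cumsum(c(1, as.integer(gaps > window)))
    for (cl in unique(cluster)) {
      ii <- i[cluster == cl]
      id <- sprintf("%s:%d", ch, min(df$pos[ii]))
      locus[ii] <- id
      loci[[id]] <- data.frame(
        locus = id, chrom = ch,
        start = min(df$pos[ii]), end = max(df$pos[ii]),
        n_snps = length(ii),
        groups = paste(sort(unique(df$group[ii])), collapse = "+"))
    }
  }
  df$locus <- locus
  loci_df <- do.call(rbind, loci)
  rownames(loci_df) <- NULL
  venn <- table(loci_df$groups)
  list(loci = loci_df, assignments = df,
       venn = stats::setNames(as.integer(venn), names(venn)))
}
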