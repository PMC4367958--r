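#' Two-locus haplotype frequency table
#'
#' For two bi-allelic loci with alleles A1/A2 and B1/B2, holds the four
#' haplotype frequencies and the two A1/B1 marginals. By convention A1/B1
#' denote the alternative (coded 1) alleles; all LD measures computed from
#' the table are invariant to relabelling.
#'
#' @param f11,f10,f01,f00 Frequencies of haplotypes A1B1, A1B2, A2B1, A2B2;
#'   must be non-negative and sum to 1 within 1e-12.
#' @return An object of class `"two_locus_table"`.
#' @examples
#' two_locus_table(0.4, 0.1, 0.1, 0.4)
#' @export
two_locus_table <- function(f11, f10, f01, f00) {
  f <- c(f11, f10, f01, f00)
  if (any(f < -1e-12) || abs(sum(f) - 1) > 1e-12)
    stop("input error: haplotype frequencies must be non-negative and sum ",
         "to 1", call. = FALSE)
  structure(list(freq_A1B1 = f11, freq_A1B2 = f10,
                 freq_A2B1 = f01, freq_A2B2 = f00,
                 p_A1 = f11 + f10, p_B1 = f11 + f01),
            class = "two_locus_table")
}

#' Haplotype frequencies for a marker pair
#'
#' Direct counting over all 2n phased haplotypes; no EM step is needed
#' because the panel is phased.
#'
#' @param panel A [hap_panel()].
#' @param i,j Distinct marker indices (1-based).
#' @return A [two_locus_table()].
#' @export
haplotype_freqs <- function(panel, i, j) {
  m <- n_markers(panel)
  if (any(c(i, j) < 1L) || any(c(i, j) > m))
    stop("input error: marker index out of range", call. = FALSE)
  if (i == j) stop("input error: marker indices must differ", call. = FALSE)
  x <- c(panel$alleles[, , i])
  y <- c(panel$alleles[, , j])
  n <- length(x)
  two_locus_table(sum(x == 1L & y == 1L) / n,
                  sum(x == 1L & y == 0L) / n,
                  sum(x == 0L & y == 1L) / n,
                  sum(x == 0L & y == 0L) / n)
}

#' Linkage disequilibrium coefficient D
#'
#' `D = freq(A1B1) - p(A1) p(B1)`, the raw covariance of allele indicators.
#'
#' @param table A [two_locus_table()].
#' @return D, a real in `[-0.25, 0.25]`.
#' @export
ld_d <- function(table) {
  stopifnot(inherits(table, "two_locus_table"))
  table$freq_A1B1 - table$p_A1 * table$p_B1
}

check_polymorphic <- function(table) {
  marg <- c(table$p_A1, 1 - table$p_A1, table$p_B1, 1 - table$p_B1)
  if (any(marg <= 0))
    stop("undefined-LD error: both loci must be polymorphic", call. = FALSE)
}

#' Lewontin's D'
#'
#' `|D|` standardized by its maximum attainable value given the allele
#' frequencies: for `D > 0`, `Dmax = min(p_A1 q_B1, q_A1 p_B1)`; for
#' `D < 0`, `Dmax = min(p_A1 p_B1, q_A1 q_B1)` (q = 1 - p). D' lies in
#' `[0, 1]`; 0 means no LD, 1 means at least one haplotype class is absent.
#' Returns 0 at exact independence (D = 0) to avoid 0/0.
#'
#' @param table A [two_locus_table()] with both loci polymorphic.
#' @return D' in `[0, 1]`.
#' @examples
#' ld_dprime(two_locus_table(0.4, 0.1, 0.1, 0.4))  # 0.6
#' @export
ld_dprime <- function(table) {
  check_polymorphic(table)
  D <- ld_d(table)
  if (D == 0) return(0)
  pA <- table$p_A1; qA <- 1 - pA
  pB <- table$p_B1; qB <- 1 - pB
  dmax <- if (D > 0) min(pA * qB, qA * pB) else min(pA * pB, qA * qB)
  abs(D) / dmax
}

#' Squared allelic correlation r2
#'
#' `r2 = D^2 / (p_A1 q_A1 p_B1 q_B1)`, the squared correlation of allele
#' indicators across haplotypes.
#'
#' @param table A [two_locus_table()] with both loci polymorphic.
#' @return r2 in `[0, 1]`.
#' @examples
#' ld_rsquared(two_locus_table(0.4, 0.1, 0.1, 0.4))  # 0.36
#' @export
ld_rsquared <- function(table) {
  check_polymorphic(table)
  D <- ld_d(table)
  pA <- table$p_A1; pB <- table$p_B1
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' Pairwise D' matrix for a set of markers
#'
#' Computes the full D' matrix over the given marker indices by one
#' cross-product over the 2n haplotypes. Monomorphic markers yield `NA`
#' rows/columns (D' is undefined there); the diagonal is 1.
#'
#' @param panel A [hap_panel()].
#' @param markers Marker indices (default all).
#' @return A symmetric numeric matrix of D' values.
#' @export
dprime_matrix <- function(panel, markers = seq_len(n_markers(panel))) {
  H <- hap_matrix(panel)[, markers, drop = FALSE]
  storage.mode(H) <- "double"
  nh <- nrow(H)
  p <- colMeans(H)
  P11 <- crossprod(H) / nh
  D <- P11 - outer(p, p)
  q <- 1 - p
  dmax_pos <- pmin(outer(p, q), outer(q, p))
  dmax_neg <- pmin(outer(p, p), outer(q, q))
  dmax <- ifelse(D >= 0, dmax_pos, dmax_neg)
  out <- abs(D) / dmax
  out[D == 0] <- 0
  mono <- p <= 0 | p >= 1
  out[mono, ] <- NA_real_
  out[, mono] <- NA_real_
  diag(out) <- ifelse(mono, NA_real_, 1)
  out
}

#' Mean adjacent-locus D' per chromosome
#'
#' Utility used to characterize simulated LD decay: the average D' between
#' physically adjacent polymorphic marker pairs.
#'
#' @param panel A [hap_panel()].
#' @param map Marker map of the panel.
#' @return Mean adjacent D' (NA pairs dropped).
#' @export
mean_adjacent_dprime <- function(panel, map) {
  vals <- numeric(0)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    if (length(idx) < 2L) next
    Dm <- dprime_matrix(panel, idx)
    vals <- c(vals, Dm[cbind(seq_len(length(idx) - 1L),
                             seq_len(length(idx) - 1L) + 1L)])
  }
  mean(vals, na.rm = TRUE)
}
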