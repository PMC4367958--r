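#' Pedigree-based additive relationship matrix
#'
#' Builds the numerator relationship matrix A by the tabular method:
#' processing animals parents-first,
#' `A[i,i] = 1 + 0.5 * A[sire(i), dam(i)]` and, for earlier animals j,
#' `A[i,j] = 0.5 * (A[j, sire(i)] + A[j, dam(i)])`, with terms for unknown
#' parents dropped. Founders are taken unrelated and non-inbred. The result
#' is symmetric positive semi-definite with `diag(A) = 1 + F` (F = the
#' inbreeding coefficient).
#'
#' @param pedigree Pedigree data frame (`animal`, `sire`, `dam`, optionally
#'   `generation`); validated and topologically sorted internally.
#' @return A dense symmetric numeric matrix with animal ids as dimnames, in
#'   the order of the input pedigree.
#' @export
additive_relationship <- function(pedigree) {
  input_order <- pedigree$animal
  ped <- validate_pedigree(pedigree)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row_i <- numeric(i - 1L)
      if (s > 0L) row_i <- row_i + 0.5 * A[j, s]
      if (d > 0L) row_i <- row_i + 0.5 * A[j, d]
      A[i, j] <- row_i
      A[j, i] <- row_i
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(ped$animal, ped$animal)
  A[input_order, input_order]
}
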