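#' Phased haplotype panel
#'
#' A phased diploid allele container: an individuals x 2 x markers integer
#' array with entries 0 (reference allele) or 1 (alternative allele), plus
#' animal identifiers. The panel is the substrate of all LD computation and
#' design-matrix encoding; it is complete by contract (post-imputation,
#' post-phasing), so no missing entries are allowed.
#'
#' @param alleles Integer array of dimension `c(n, 2, m)` with entries in
#'   \{0, 1\}.
#' @param ids Character vector of `n` unique animal identifiers.
#' @return An object of class `"hap_panel"`.
#' @export
hap_panel <- function(alleles, ids) {
  if (length(dim(alleles)) != 3L || dim(alleles)[2] != 2L)
    stop("input error: 'alleles' must be an n x 2 x m array", call. = FALSE)
  if (dim(alleles)[1] != length(ids))
    stop("input error: 'ids' length does not match the panel", call. = FALSE)
  if (anyDuplicated(ids))
    stop("input error: duplicated animal ids", call. = FALSE)
  if (anyNA(alleles) || !all(alleles %in% c(0L, 1L)))
    stop("input error: panel entries must all be 0 or 1 (no missing data)",
         call. = FALSE)
  structure(list(ids = as.character(ids),
                 alleles = array(as.integer(alleles), dim = dim(alleles))),
            class = "hap_panel")
}

# build a panel from a (2n) x m haplotype matrix, rows paired per animal
hap_panel_from_matrix <- function(H, ids) {
  n <- length(ids)
  stopifnot(nrow(H) == 2L * n)
  alleles <- array(0L, dim = c(n, 2L, ncol(H)))
  alleles[, 1L, ] <- H[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  alleles[, 2L, ] <- H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  hap_panel(alleles, ids)
}

#' @export
print.hap_panel <- function(x, ...) {
  cat("<hap_panel> ", n_animals(x), " animals x ", n_markers(x),
      " markers (phased)\n", sep = "")
  invisible(x)
}

#' Panel dimensions
#' @param panel A [hap_panel()].
#' @return Integer count.
#' @export
n_animals <- function(panel) dim(panel$alleles)[1]

#' @rdname n_animals
#' @export
n_markers <- function(panel) dim(panel$alleles)[3]

#' Haplotype matrix view of a panel
#'
#' Returns the `2n x m` matrix of phased haplotypes; rows `2i - 1` and `2i`
#' are the two haplotypes of animal `i`.
#'
#' @param panel A [hap_panel()].
#' @return Integer matrix.
#' @export
hap_matrix <- function(panel) {
  n <- n_animals(panel)
  m <- n_markers(panel)
  H <- matrix(0L, 2L * n, m)
  H[seq(1L, 2L * n, by = 2L), ] <- panel$alleles[, 1L, ]
  H[seq(2L, 2L * n, by = 2L), ] <- panel$alleles[, 2L, ]
  H
}

#' Alternative-allele dosage matrix
#'
#' @param panel A [hap_panel()].
#' @return `n x m` integer matrix of alt-allele counts (0, 1 or 2), with
#'   animal ids as row names.
#' @export
dosage_matrix <- function(panel) {
  D <- panel$alleles[, 1L, , drop = FALSE] + panel$alleles[, 2L, , drop = FALSE]
  D <- matrix(D, n_animals(panel), n_markers(panel))
  rownames(D) <- panel$ids
  D
}

#' Subset a panel by marker and/or animal indices
#'
#' @param panel A [hap_panel()].
#' @param markers Marker indices to keep (default all).
#' @param animals Animal indices or ids to keep (default all).
#' @return A [hap_panel()].
#' @export
subset_panel <- function(panel, markers = NULL, animals = NULL) {
  al <- panel$alleles
  ids <- panel$ids
  if (!is.null(animals)) {
    if (is.character(animals)) animals <- match(animals, ids)
    if (anyNA(animals)) stop("input error: unknown animal id", call. = FALSE)
    al <- al[animals, , , drop = FALSE]
    ids <- ids[animals]
  }
  if (!is.null(markers)) al <- al[, , markers, drop = FALSE]
  hap_panel(al, ids)
}

#' Marker map constructor/validator
#'
#' A marker map records, per marker: chromosome, 1-based physical position,
#' marker id and the two alleles. Rows must be sorted by (chromosome,
#' position) with strictly increasing positions within chromosome and unique
#' marker ids.
#'
#' @param df Data frame with columns `chrom`, `pos`, `id`, `ref`, `alt`.
#' @return The validated data frame (invisibly classed `"marker_map"` via
#'   attribute-free convention: it stays a plain data frame).
#' @export
marker_map <- function(df) {
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(df)))
    stop("input error: marker map needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$id))
    stop("input error: duplicated marker ids", call. = FALSE)
  pos_ok <- tapply(df$pos, factor(df$chrom, levels = unique(df$chrom)),
                   function(p) all(diff(p) > 0))
  if (!all(unlist(pos_ok)))
    stop("input error: positions must be strictly increasing within ",
         "chromosome", call. = FALSE)
  rownames(df) <- NULL
  df
}

#' Pedigree validator
#'
#' Checks that every named parent appears as an animal, that the pedigree is
#' acyclic, and reorders rows parents-first (stable topological sort).
#'
#' @param ped Data frame with columns `animal`, `sire`, `dam`, `generation`
#'   (`NA` = unknown parent).
#' @return The validated, topologically sorted pedigree data frame.
#' @export
validate_pedigree <- function(ped) {
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(ped)))
    stop("input error: pedigree needs columns animal, sire, dam",
         call. = FALSE)
  if (anyDuplicated(ped$animal))
    stop("input error: duplicated animal ids in pedigree", call. = FALSE)
  if (!("generation" %in% names(ped))) ped$generation <- NA_integer_
  parents <- c(ped$sire, ped$dam)
  unknown <- setdiff(stats::na.omit(parents), ped$animal)
  if (length(unknown) > 0L)
    stop("input error: parents not listed as animals: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  # Kahn's algorithm; report a cycle if it stalls
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  placed <- logical(n)
  order_out <- integer(0)
  repeat {
    ready <- which(!placed &
                     (si == 0L | placed[pmax(si, 1L)]) &
                     (di == 0L | placed[pmax(di, 1L)]))
    if (length(ready) == 0L) break
    placed[ready] <- TRUE
    order_out <- c(order_out, ready)
  }
  if (length(order_out) < n) {
    cyc <- ped$animal[!placed]
    stop("structural error: pedigree contains a cycle involving: ",
         paste(utils::head(cyc, 10), collapse = ", "), call. = FALSE)
  }
  out <- ped[order_out, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' DRP table validator
#'
#' @param df Data frame with columns `animal`, `trait`, `drp`, `reliability`.
#' @return The validated data frame.
#' @export
validate_drp <- function(df) {
  need <- c("animal", "trait", "drp", "reliability")
  if (!all(need %in% names(df)))
    stop("input error: DRP table needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df[, c("animal", "trait")]))
    stop("input error: more than one DRP record per (animal, trait)",
         call. = FALSE)
  if (any(!is.finite(df$reliability)) ||
      any(df$reliability <= 0) || any(df$reliability >= 1))
    stop("value error: DRP reliabilities must lie strictly inside (0, 1)",
         call. = FALSE)
  df
}
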