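#' Read a phased VCF into a haplotype panel
#'
#' Reads a bi-allelic, fully phased VCF (GT field) via the vcfR package.
#' Every genotype must use the phased separator `|`; unphased (`/`),
#' missing, or multi-allelic records are rejected with an error naming the
#' offending record.
#'
#' @param path Path to a VCF file.
#' @return A list with `panel` (a [hap_panel()]) and `map` (marker map).
#' @export
read_phased_vcf <- function(path) {
  if (!file.exists(path))
    stop("input error: file not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    ids <- setdiff(colnames(v@gt), "FORMAT")
    empty <- hap_panel(array(integer(0), dim = c(length(ids), 2L, 0L)), ids)
    return(list(panel = empty,
                map = marker_map(data.frame(chrom = character(0),
                                            pos = integer(0),
                                            id = character(0),
                                            ref = character(0),
                                            alt = character(0)))))
  }
  if (any(grepl(",", fix$ALT, fixed = TRUE)) || any(is.na(fix$ALT)))
    stop("parse error: multi-allelic site at ",
         fix$ID[which(grepl(",", fix$ALT) | is.na(fix$ALT))[1]],
         call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt)))
    gt <- matrix(gt, nrow = nrow(fix),
                 dimnames = list(fix$ID, setdiff(colnames(v@gt), "FORMAT")))
  bad <- !grepl("^[01]\\|[01]$", gt)
  dim(bad) <- dim(gt)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("parse error: genotype '", gt[w[1], w[2]],
         "' (marker ", rownames(gt)[w[1]], ", sample ",
         colnames(gt)[w[2]],
         ") is not a phased bi-allelic call of the form a|b", call. = FALSE)
  }
  m <- nrow(gt); n <- ncol(gt)
  a1 <- matrix(as.integer(substr(gt, 1L, 1L)), m, n)
  a2 <- matrix(as.integer(substr(gt, 3L, 3L)), m, n)
  alleles <- array(0L, dim = c(n, 2L, m))
  alleles[, 1L, ] <- t(a1)
  alleles[, 2L, ] <- t(a2)
  ids <- if (is.null(fix$ID) || anyNA(fix$ID)) {
    paste0(fix$CHROM, "_", fix$POS)
  } else fix$ID
  map <- marker_map(data.frame(chrom = fix$CHROM,
                               pos = as.integer(fix$POS),
                               id = ids,
                               ref = fix$REF, alt = fix$ALT,
                               stringsAsFactors = FALSE))
  list(panel = hap_panel(alleles, colnames(gt)), map = map)
}

#' Write a haplotype panel as a minimal phased VCF
#'
#' Emits a GT-only, bi-allelic, fully phased VCF. Reading it back with
#' [read_phased_vcf()] is an identity on (panel, map).
#'
#' @param panel A [hap_panel()].
#' @param map Marker map consistent with the panel.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_phased_vcf <- function(panel, map, path) {
  if (nrow(map) != n_markers(panel))
    stop("input error: map/panel marker dimension mismatch", call. = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", panel$ids),
                     collapse = "\t")), con)
  m <- n_markers(panel)
  n <- n_animals(panel)
  if (m > 0L) {
    if (n == 0L) {
      lines <- paste(map$chrom, map$pos, map$id, map$ref, map$alt,
                     ".", ".", ".", "GT", sep = "\t")
    } else {
      a1 <- t(matrix(panel$alleles[, 1L, ], n, m))  # m x n
      a2 <- t(matrix(panel$alleles[, 2L, ], n, m))
      gt <- matrix(paste0(a1, "|", a2), m, n)
      gt_part <- apply(gt, 1L, paste, collapse = "\t")
      lines <- paste(map$chrom, map$pos, map$id, map$ref, map$alt,
                     ".", ".", ".", "GT", gt_part, sep = "\t")
    }
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a pedigree CSV
#'
#' Expects columns `animal,sire,dam,generation`; empty parent fields mean
#' unknown. The pedigree is validated (parents present, acyclic) and
#' returned parents-first.
#'
#' @param path CSV path.
#' @return Pedigree data frame.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(animal = "character",
                                       sire = "character",
                                       dam = "character"))
  df$sire[!is.na(df$sire) & df$sire == ""] <- NA_character_
  df$dam[!is.na(df$dam) & df$dam == ""] <- NA_character_
  validate_pedigree(df)
}

#' Read a DRP table CSV
#'
#' Expects columns `animal,trait,drp,reliability`; reliabilities must lie
#' strictly inside (0, 1) (residual weights are undefined at the endpoints).
#'
#' @param path CSV path.
#' @return Validated DRP data frame.
#' @export
read_drp <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(animal = "character"))
  validate_drp(df)
}

#' Marker quality control
#'
#' Applies the two marker-editing rules used for high-density panels before
#' prediction: (1) remove markers with minor allele frequency below
#' `maf_min` (computed over all haplotypes of all panel animals); then (2)
#' scanning each chromosome left to right over the retained markers, remove
#' a marker whose r-squared with the nearest retained marker to its left
#' equals 1 within 1e-12 — such markers are informationally redundant. The
#' left member of a complete-LD pair is always the one kept.
#'
#' @param panel A [hap_panel()].
#' @param map Marker map of the panel.
#' @param maf_min MAF threshold in `[0, 0.5)`; default 0.01.
#' @param drop_complete_ld_adjacent Apply rule (2)? Default `TRUE`.
#' @return A list with the filtered `panel` and `map`, and `report`: counts
#'   `n_input`, `n_removed_maf`, `n_removed_complete_ld`, `n_retained`, and
#'   `removed_ids` (with per-rule vectors `removed_maf_ids`,
#'   `removed_ld_ids`).
#' @export
qc_filter <- function(panel, map, maf_min = 0.01,
                      drop_complete_ld_adjacent = TRUE) {
  if (maf_min < 0 || maf_min >= 0.5)
    stop("input error: 'maf_min' must be in [0, 0.5)", call. = FALSE)
  if (nrow(map) != n_markers(panel))
    stop("input error: map/panel marker dimension mismatch", call. = FALSE)
  H <- hap_matrix(panel)
  storage.mode(H) <- "double"
  p <- colMeans(H)
  maf <- pmin(p, 1 - p)
  rm_maf <- maf < maf_min
  rm_ld <- logical(length(maf))
  if (drop_complete_ld_adjacent) {
    for (ch in unique(map$chrom)) {
      idx <- which(map$chrom == ch & !rm_maf)
      if (length(idx) < 2L) next
      left <- idx[1]
      for (j in idx[-1]) {
        r <- suppressWarnings(stats::cor(H[, left], H[, j]))
        if (!is.na(r) && abs(r^2 - 1) <= 1e-12) {
          rm_ld[j] <- TRUE
        } else {
          left <- j
        }
      }
    }
  }
  keep <- !(rm_maf | rm_ld)
  report <- list(n_input = length(maf),
                 n_removed_maf = sum(rm_maf),
                 n_removed_complete_ld = sum(rm_ld),
                 n_retained = sum(keep),
                 removed_ids = map$id[!keep],
                 removed_maf_ids = map$id[rm_maf],
                 removed_ld_ids = map$id[rm_ld])
  stopifnot(report$n_input == report$n_removed_maf +
              report$n_removed_complete_ld + report$n_retained)
  list(panel = subset_panel(panel, markers = which(keep)),
       map = marker_map(map[keep, , drop = FALSE]),
       report = report)
}
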