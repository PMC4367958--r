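#' Build LD-based haploblocks
#'
#' Partitions each chromosome into contiguous haploblocks such that D'
#' between every two markers inside a block is at least the threshold `d`.
#' The search is a deterministic greedy left-to-right maximal extension: a
#' candidate block starts at the leftmost unassigned marker and is extended
#' to the next adjacent marker if and only if that marker's D' with every
#' marker already in the candidate is `>= d`; when extension fails the
#' candidate is emitted as a block if it holds at least two markers,
#' otherwise its single marker is recorded as non-blocked, and the search
#' restarts at the marker that failed.
#'
#' At `d = 0` each whole chromosome becomes one block; with `d` above the
#' panel's largest pairwise D', every marker is non-blocked.
#'
#' @param panel A quality-controlled [hap_panel()].
#' @param map Marker map of the panel.
#' @param d D' threshold in `[0, 1]`. The classical grid spans 0.25 to 0.75
#'   in steps of 0.10 (see [dprime_threshold_grid()]).
#' @return An object of class `"block_partition"`: list with `threshold_d`,
#'   `blocks` (data frame `chrom`, `start`, `end`, `size`; `start`/`end` are
#'   1-based inclusive marker indices into `map`), and `nonblocked` (integer
#'   marker indices).
#' @export
build_blocks <- function(panel, map, d) {
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0 || d > 1)
    stop("input error: threshold 'd' must lie in [0, 1]", call. = FALSE)
  if (nrow(map) != n_markers(panel))
    stop("input error: map/panel marker dimension mismatch", call. = FALSE)
  blocks <- list()
  nonblocked <- integer(0)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    mm <- length(idx)
    if (mm == 1L) {
      nonblocked <- c(nonblocked, idx)
      next
    }
    Dm <- dprime_matrix(panel, idx)
    s <- 1L
    while (s <= mm) {
      e <- s
      while (e < mm) {
        cand <- Dm[s:e, e + 1L]
        if (isTRUE(all(cand >= d))) e <- e + 1L else break
      }
      if (e > s) {
        blocks[[length(blocks) + 1L]] <-
          data.frame(chrom = ch, start = idx[s], end = idx[e],
                     size = e - s + 1L, stringsAsFactors = FALSE)
      } else {
        nonblocked <- c(nonblocked, idx[s])
      }
      s <- e + 1L
    }
  }
  blocks_df <- if (length(blocks) > 0L) do.call(rbind, blocks) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               size = integer(0), stringsAsFactors = FALSE)
  structure(list(threshold_d = d, blocks = blocks_df,
                 nonblocked = nonblocked),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  cat("<block_partition> d = ", x$threshold_d, ": ", nrow(x$blocks),
      " blocks, ", length(x$nonblocked), " non-blocked SNPs\n", sep = "")
  invisible(x)
}

#' The classical D' threshold grid
#'
#' The six thresholds, from relaxed to strict, over which the haploblock
#' scenarios are usually compared.
#'
#' @return `c(0.25, 0.35, 0.45, 0.55, 0.65, 0.75)`.
#' @export
dprime_threshold_grid <- function() c(0.25, 0.35, 0.45, 0.55, 0.65, 0.75)

#' Enumerate observed haploblock variants
#'
#' A block's variants are the distinct haplotype allele strings observed
#' across all 2n phased haplotypes within the block, with their panel
#' frequencies. Variants are ordered by descending frequency, ties broken by
#' lexicographic string order.
#'
#' @param panel The [hap_panel()] the partition was built on.
#' @param partition A [build_blocks()] result.
#' @return An object of class `"block_variant_catalog"`: a list with one
#'   data frame (`variant`, `freq`) per block, in block order.
#' @export
enumerate_block_variants <- function(panel, partition) {
  H <- hap_matrix(panel)
  out <- vector("list", nrow(partition$blocks))
  for (b in seq_len(nrow(partition$blocks))) {
    cols <- partition$blocks$start[b]:partition$blocks$end[b]
    strings <- do.call(paste0, as.data.frame(H[, cols, drop = FALSE]))
    tab <- table(strings)
    freq <- as.numeric(tab) / nrow(H)
    ord <- order(-freq, names(tab))
    out[[b]] <- data.frame(variant = names(tab)[ord], freq = freq[ord],
                           stringsAsFactors = FALSE)
  }
  structure(out, class = "block_variant_catalog")
}

#' Build the design matrix for genomic prediction
#'
#' Encodes a panel as an `n x q` count matrix with entries 0, 1 or 2:
#' * `"snp"` — one column per marker holding the minor-allele dosage;
#' * `"blocks_plus_nonblocked"` — one column per observed block variant
#'   (count of that variant among the animal's two haplotypes) plus one
#'   minor-allele-dosage column per non-blocked SNP;
#' * `"blocks_only"` — the block-variant columns only.
#'
#' Columns follow map order; within a block, variants follow catalog order.
#' Within each block the variant columns of any animal sum to exactly 2. A
#' haplotype matching no catalogued variant (possible only with external
#' panels) contributes to no column and raises a warning.
#'
#' @param panel A [hap_panel()].
#' @param partition A [build_blocks()] result (ignored for `mode = "snp"`).
#' @param catalog The matching [enumerate_block_variants()] catalog.
#' @param mode One of `"snp"`, `"blocks_plus_nonblocked"`, `"blocks_only"`.
#' @param map Marker map (required for `mode = "snp"` column names; optional
#'   otherwise).
#' @return An object of class `"hb_design"`: the numeric matrix with
#'   attributes `column_meta` (data frame `type`, `marker_id`, `block`,
#'   `variant`) and `encoding_mode`.
#' @export
build_design <- function(panel, partition = NULL, catalog = NULL,
                         mode = c("snp", "blocks_plus_nonblocked",
                                  "blocks_only"),
                         map = NULL) {
  mode <- match.arg(mode)
  n <- n_animals(panel)
  marker_ids <- if (!is.null(map)) map$id else
    sprintf("m%06d", seq_len(n_markers(panel)))
  snp_col <- function(j) {
    dos <- panel$alleles[, 1L, j] + panel$alleles[, 2L, j]
    p_alt <- sum(dos) / (2 * n)
    if (p_alt > 0.5) dos <- 2L - dos   # dosage of the minor allele
    dos
  }
  cols <- list()
  meta <- list()
  add_snp <- function(j) {
    cols[[length(cols) + 1L]] <<- snp_col(j)
    meta[[length(meta) + 1L]] <<-
      data.frame(type = "snp", marker_id = marker_ids[j],
                 block = NA_integer_, variant = NA_character_,
                 stringsAsFactors = FALSE)
  }
  add_block <- function(b) {
    cols_idx <- partition$blocks$start[b]:partition$blocks$end[b]
    Hb <- hap_matrix(subset_panel(panel, markers = cols_idx))
    strings <- do.call(paste0, as.data.frame(Hb))
    vari <- match(strings, catalog[[b]]$variant)
    if (anyNA(vari))
      warning("haplotype(s) in block ", b,
              " match no catalogued variant; they contribute to no column")
    nv <- nrow(catalog[[b]])
    X <- matrix(0L, n, nv)
    hap_animal <- rep(seq_len(n), each = 2L)
    ok <- !is.na(vari)
    for (k in which(ok)) X[hap_animal[k], vari[k]] <- X[hap_animal[k], vari[k]] + 1L
    for (v in seq_len(nv)) {
      cols[[length(cols) + 1L]] <<- X[, v]
      meta[[length(meta) + 1L]] <<-
        data.frame(type = "block_variant", marker_id = NA_character_,
                   block = b, variant = catalog[[b]]$variant[v],
                   stringsAsFactors = FALSE)
    }
  }
  if (mode == "snp") {
    for (j in seq_len(n_markers(panel))) add_snp(j)
  } else {
    if (is.null(partition) || is.null(catalog))
      stop("input error: block modes need a partition and catalog",
           call. = FALSE)
    if (length(catalog) != nrow(partition$blocks))
      stop("input error: catalog does not match partition", call. = FALSE)
    j <- 1L
    m <- n_markers(panel)
    block_at <- rep(NA_integer_, m)
    for (b in seq_len(nrow(partition$blocks)))
      block_at[partition$blocks$start[b]] <- b
    in_block <- logical(m)
    for (b in seq_len(nrow(partition$blocks)))
      in_block[partition$blocks$start[b]:partition$blocks$end[b]] <- TRUE
    while (j <= m) {
      if (!is.na(block_at[j])) {
        add_block(block_at[j])
        j <- partition$blocks$end[block_at[j]] + 1L
      } else {
        if (mode == "blocks_plus_nonblocked" && !in_block[j]) add_snp(j)
        j <- j + 1L
      }
    }
  }
  M <- do.call(cbind, c(cols, list(deparse.level = 0)))
  if (is.null(M)) M <- matrix(0, n, 0)
  storage.mode(M) <- "double"
  rownames(M) <- panel$ids
  meta_df <- if (length(meta) > 0L) do.call(rbind, meta) else
    data.frame(type = character(0), marker_id = character(0),
               block = integer(0), variant = character(0))
  structure(M, column_meta = meta_df, encoding_mode = mode,
            class = c("hb_design", "matrix", "array"))
}

#' @export
print.hb_design <- function(x, ...) {
  cat("<hb_design> ", nrow(x), " animals x ", ncol(x), " columns (mode: ",
      attr(x, "encoding_mode"), ")\n", sep = "")
  invisible(x)
}

#' Subset the rows of a design matrix, keeping metadata
#'
#' @param design An [build_design()] result.
#' @param rows Row indices or animal ids.
#' @return An `"hb_design"` with the same columns.
#' @export
design_rows <- function(design, rows) {
  if (is.character(rows)) rows <- match(rows, rownames(design))
  if (anyNA(rows)) stop("input error: unknown animal id", call. = FALSE)
  out <- design[rows, , drop = FALSE]
  structure(out, column_meta = attr(design, "column_meta"),
            encoding_mode = attr(design, "encoding_mode"),
            class = class(design))
}

#' Summarize a block partition
#'
#' Reports the accounting that characterizes a threshold: number of blocks,
#' number of block-variant design columns (`n_variables`), and number of
#' non-blocked SNPs. `n_variables` counts block-variant columns only;
#' non-blocked SNPs are reported separately so either convention for a
#' "total variables" figure can be recovered.
#'
#' @param partition A [build_blocks()] result.
#' @param catalog The matching [enumerate_block_variants()] catalog.
#' @return A one-row data frame: `threshold`, `n_blocks`, `n_variables`,
#'   `n_nonblocked`, `n_markers`.
#' @export
partition_summary <- function(partition, catalog) {
  if (length(catalog) != nrow(partition$blocks))
    stop("input error: catalog does not match partition", call. = FALSE)
  data.frame(threshold = partition$threshold_d,
             n_blocks = nrow(partition$blocks),
             n_variables = sum(vapply(catalog, nrow, 0L)),
             n_nonblocked = length(partition$nonblocked),
             n_markers = sum(partition$blocks$size) +
               length(partition$nonblocked))
}
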