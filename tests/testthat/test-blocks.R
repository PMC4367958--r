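test_that("perfectly coupled SNPs form one block at a strict threshold", {
  x <- c(rep(0L, 5), rep(1L, 5))
  H <- cbind(x, x, x)
  panel <- panel_from_haps(H)
  part <- build_blocks(panel, map_for(3), 0.75)
  expect_equal(nrow(part$blocks), 1)
  expect_equal(part$blocks$size, 3)
  expect_length(part$nonblocked, 0)
})

test_that("d = 0 selects each whole chromosome as one haploblock", {
  panel <- random_panel(25, 30, seed = 41)
  map <- map_for(30)
  map$chrom <- rep(c("chr1", "chr2"), each = 15)
  map$id <- sprintf("%s_m%04d", map$chrom, rep(1:15, 2))
  part <- build_blocks(panel, map, 0)
  expect_equal(nrow(part$blocks), 2)
  expect_equal(part$blocks$size, c(15L, 15L))
  expect_length(part$nonblocked, 0)
})

test_that("d above the panel maximum makes every SNP non-blocked", {
  # enough haplotypes that every two-locus class is observed, so D' < 1
  panel <- random_panel(200, 20, seed = 42, p_range = c(0.3, 0.7))
  map <- map_for(20)
  Dm <- dprime_matrix(panel)
  dmax <- max(Dm[upper.tri(Dm)], na.rm = TRUE)
  expect_lt(dmax, 1)
  part <- build_blocks(panel, map, dmax + (1 - dmax) / 2)
  expect_equal(nrow(part$blocks), 0)
  expect_equal(sort(part$nonblocked), 1:20)
})

test_that("threshold outside [0, 1] is rejected", {
  panel <- random_panel(5, 4, seed = 1)
  expect_error(build_blocks(panel, map_for(4), -0.1), "\\[0, 1\\]")
  expect_error(build_blocks(panel, map_for(4), 1.5), "\\[0, 1\\]")
})

test_that("build_blocks matches the brute-force greedy oracle with LD", {
  withr::with_seed(55, {
    for (rep in 1:20) {
      m <- sample(20:50, 1)
      H <- ld_chromosome(60, m, corr = runif(1, 0.5, 0.95),
                         seed = sample.int(1e6, 1))
      panel <- panel_from_haps(H)
      d <- sample(dprime_threshold_grid(), 1)
      part <- build_blocks(panel, map_for(m), d)
      oracle <- oracle_blocks(H, d)
      expect_equal(nrow(part$blocks), length(oracle$blocks))
      for (b in seq_along(oracle$blocks)) {
        expect_equal(part$blocks$start[b], oracle$blocks[[b]][1])
        expect_equal(part$blocks$end[b], oracle$blocks[[b]][2])
      }
      expect_equal(part$nonblocked, oracle$nonblocked)
      # certification: every within-block pair satisfies D' >= d
      for (b in seq_len(nrow(part$blocks))) {
        cols <- part$blocks$start[b]:part$blocks$end[b]
        for (i in seq_along(cols)) for (j in seq_along(cols)) {
          if (j <= i) next
          expect_gte(oracle_dprime_pair(H, cols[i], cols[j]), d)
        }
      }
    }
  })
})

test_that("partition covers all markers disjointly with blocks of size >= 2", {
  withr::with_seed(56, {
    for (rep in 1:10) {
      panel <- random_panel(20, 40, seed = sample.int(1e6, 1))
      part <- build_blocks(panel, map_for(40), runif(1))
      covered <- part$nonblocked
      for (b in seq_len(nrow(part$blocks)))
        covered <- c(covered, part$blocks$start[b]:part$blocks$end[b])
      expect_equal(sort(covered), 1:40)
      expect_equal(anyDuplicated(covered), 0)
      if (nrow(part$blocks) > 0) expect_true(all(part$blocks$size >= 2))
    }
  })
})

test_that("block variants are the observed strings with correct frequencies", {
  x <- c(0L, 0L, 1L, 1L, 0L, 0L)
  y <- c(0L, 0L, 1L, 1L, 1L, 0L)
  panel <- panel_from_haps(cbind(x, y))
  part <- build_blocks(panel, map_for(2), 0)
  catg <- enumerate_block_variants(panel, part)
  expect_length(catg, 1)
  expect_equal(catg[[1]]$variant, c("00", "11", "01"))  # freq desc, lex ties
  expect_equal(catg[[1]]$freq, c(3, 2, 1) / 6)
  expect_equal(sum(catg[[1]]$freq), 1)
})

test_that("variant counts respect the 2^k and 2n bounds and sum to 1", {
  panel <- random_panel(15, 25, seed = 61)
  H <- hap_matrix(panel)
  part <- build_blocks(panel, map_for(25), 0.25)
  catg <- enumerate_block_variants(panel, part)
  for (b in seq_len(nrow(part$blocks))) {
    k <- part$blocks$size[b]
    expect_lte(nrow(catg[[b]]), min(2^k, nrow(H)))
    expect_equal(sum(catg[[b]]$freq), 1)
    # counting oracle
    cols <- part$blocks$start[b]:part$blocks$end[b]
    strings <- apply(H[, cols, drop = FALSE], 1, paste, collapse = "")
    tab <- table(strings) / nrow(H)
    expect_equal(sort(catg[[b]]$freq), as.numeric(sort(tab)))
    expect_setequal(catg[[b]]$variant, names(tab))
  }
})

test_that("SNP design equals independently computed minor-allele dosage", {
  panel <- random_panel(3, 5, seed = 71, p_range = c(0.2, 0.95))
  design <- build_design(panel, mode = "snp", map = map_for(5))
  H <- hap_matrix(panel)
  for (j in 1:5) {
    alt_dose <- panel$alleles[, 1, j] + panel$alleles[, 2, j]
    dose <- if (mean(H[, j]) > 0.5) 2 - alt_dose else alt_dose
    expect_equal(as.numeric(design[, j]), as.numeric(dose))
  }
  expect_equal(attr(design, "column_meta")$type, rep("snp", 5))
})

test_that("variant-column counts are forced by the phased haplotypes", {
  # animal with block haplotypes (01 | 01) among variants {00, 01, 11}
  H <- rbind(c(0L, 1L), c(0L, 1L),       # animal 1: 01 / 01
             c(0L, 0L), c(1L, 1L),       # animal 2: 00 / 11
             c(0L, 0L), c(0L, 1L))       # animal 3: 00 / 01
  panel <- panel_from_haps(H)
  part <- build_blocks(panel, map_for(2), 0)
  catg <- enumerate_block_variants(panel, part)
  design <- build_design(panel, part, catg, mode = "blocks_only")
  meta <- attr(design, "column_meta")
  v01 <- which(meta$variant == "01")
  expect_equal(as.numeric(design[1, ]),
               as.numeric(meta$variant == "01") * 2)
  expect_equal(sum(design[1, v01]), 2)
})

test_that("per-animal row sums over each block's columns equal 2", {
  panel <- random_panel(12, 30, seed = 81)
  map <- map_for(30)
  for (mode in c("blocks_plus_nonblocked", "blocks_only")) {
    part <- build_blocks(panel, map, 0.35)
    catg <- enumerate_block_variants(panel, part)
    design <- build_design(panel, part, catg, mode = mode)
    meta <- attr(design, "column_meta")
    for (b in seq_len(nrow(part$blocks))) {
      cols <- which(!is.na(meta$block) & meta$block == b)
      expect_equal(unname(rowSums(design[, cols, drop = FALSE])),
                   rep(2, 12))
    }
  }
})

test_that("non-blocked SNP columns appear only in the combined mode", {
  panel <- random_panel(10, 20, seed = 91)
  map <- map_for(20)
  part <- build_blocks(panel, map, 0.65)
  catg <- enumerate_block_variants(panel, part)
  d_both <- build_design(panel, part, catg, "blocks_plus_nonblocked", map)
  d_only <- build_design(panel, part, catg, "blocks_only", map)
  meta_both <- attr(d_both, "column_meta")
  expect_equal(sum(meta_both$type == "snp"), length(part$nonblocked))
  expect_equal(sum(attr(d_only, "column_meta")$type == "snp"), 0)
  expect_equal(ncol(d_both) - ncol(d_only), length(part$nonblocked))
})

test_that("partition summary accounts blocks, variables and non-blocked", {
  panel <- random_panel(20, 30, seed = 95)
  map <- map_for(30)
  part <- build_blocks(panel, map, 0)
  catg <- enumerate_block_variants(panel, part)
  s <- partition_summary(part, catg)
  expect_equal(s$n_blocks, 1)
  expect_equal(s$n_nonblocked, 0)
  expect_equal(s$n_markers, 30)
})

test_that("non-blocked count is non-decreasing in d on LD panels", {
  H <- ld_chromosome(80, 60, corr = 0.85, seed = 101)
  panel <- panel_from_haps(H)
  map <- map_for(60)
  counts <- vapply(dprime_threshold_grid(), function(d) {
    length(build_blocks(panel, map, d)$nonblocked)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("blocking reduces the variable count on HD-density panels", {
  # adjacent D' near 1, as on dense chips in a low-diversity population
  H <- ld_chromosome(100, 80, corr = 0.985, seed = 111)
  panel <- panel_from_haps(H)
  map <- map_for(80)
  for (d in dprime_threshold_grid()) {
    part <- build_blocks(panel, map, d)
    catg <- enumerate_block_variants(panel, part)
    s <- partition_summary(part, catg)
    expect_lte(s$n_variables + s$n_nonblocked, 80)
    small_blocks <- vapply(seq_along(catg), function(b)
      nrow(catg[[b]]) < 2 * part$blocks$size[b], logical(1))
    if (any(small_blocks))
      expect_lt(s$n_variables + s$n_nonblocked, 80)
  }
})
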