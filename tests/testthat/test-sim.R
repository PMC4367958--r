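test_that("invalid configurations are rejected with the field named", {
  expect_error(sim_config(n_founders = 0), "n_founders")
  expect_error(sim_config(adjacent_corr = 1), "adjacent_corr")
  expect_error(sim_config(maf_range = c(0.4, 0.1)), "maf_range")
  expect_error(sim_config(mixture_props = c(0.5, 0.5, 0.1, 0)),
               "mixture_props")
  expect_error(sim_config(h2 = 1.2), "h2")
  expect_error(sim_config(drp_reliability_range = c(0.5, 1)),
               "drp_reliability_range")
})

test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_founders = 30, n_generations = 3,
                    snps_per_chromosome = 40, seed = 9)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$panel$alleles, d2$panel$alleles)
  expect_identical(d1$pedigree, d2$pedigree)
  expect_identical(d1$drp, d2$drp)
  d3 <- simulate_dataset(sim_config(n_founders = 30, n_generations = 3,
                                    snps_per_chromosome = 40, seed = 10))
  expect_false(identical(d1$panel$alleles, d3$panel$alleles))
})

test_that("adjacent_corr = 0 gives independent adjacent loci", {
  cfg <- sim_config(n_founders = 300, n_generations = 1, n_chromosomes = 1,
                    snps_per_chromosome = 80, adjacent_corr = 0,
                    maf_range = c(0.3, 0.5), seed = 2)
  sim <- simulate_haplotype_panel(cfg)
  H <- hap_matrix(sim$panel)
  observed <- mean_adjacent_dprime(sim$panel, sim$map)
  # permutation null: shuffle each column independently, destroying any LD
  null <- withr::with_seed(77, replicate(200, {
    Hp <- apply(H, 2, sample)
    mean(vapply(seq_len(ncol(Hp) - 1),
                function(j) oracle_dprime_pair(Hp, j, j + 1), numeric(1)),
         na.rm = TRUE)
  }))
  expect_gt(mean(null >= observed), 0.01)  # not in the extreme null tail
})

test_that("high adjacent_corr produces strong adjacent D'", {
  cfg <- sim_config(n_founders = 200, n_generations = 1, n_chromosomes = 1,
                    snps_per_chromosome = 100, adjacent_corr = 0.99,
                    maf_range = c(0.3, 0.5), seed = 1)
  sim <- simulate_haplotype_panel(cfg)
  H <- hap_matrix(sim$panel)
  dp <- vapply(seq_len(99), function(j) oracle_dprime_pair(H, j, j + 1),
               numeric(1))
  expect_gt(mean(dp, na.rm = TRUE), 0.8)
})

test_that("realized adjacent D' increases with adjacent_corr", {
  vals <- vapply(c(0.2, 0.6, 0.95), function(ac) {
    cfg <- sim_config(n_founders = 200, n_generations = 1, n_chromosomes = 1,
                      snps_per_chromosome = 60, adjacent_corr = ac,
                      maf_range = c(0.3, 0.5), seed = 5)
    sim <- simulate_haplotype_panel(cfg)
    mean_adjacent_dprime(sim$panel, sim$map)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("pedigree structure: founders, ordering, acyclicity", {
  cfg1 <- sim_config(n_founders = 15, n_generations = 1, seed = 3)
  ped1 <- simulate_pedigree(cfg1)
  expect_equal(nrow(ped1), 15)
  expect_true(all(is.na(ped1$sire)) && all(is.na(ped1$dam)))

  cfg3 <- sim_config(n_founders = 10, n_generations = 3,
                     offspring_per_mating = 2, seed = 7)
  ped3 <- simulate_pedigree(cfg3)
  expect_silent(validate_pedigree(ped3))  # topological sort succeeds
  pos <- setNames(seq_len(nrow(ped3)), ped3$animal)
  parents_first <- with(ped3, (is.na(sire) | pos[sire] < pos[animal]) &
                          (is.na(dam) | pos[dam] < pos[animal]))
  expect_true(all(parents_first))
  kids <- ped3[!is.na(ped3$sire), ]
  expect_true(all(kids$generation >= 1))
})

test_that("sire-offspring relationship in A equals 0.5 for founder parents", {
  cfg <- sim_config(n_founders = 12, n_generations = 2, seed = 4)
  ped <- simulate_pedigree(cfg)
  A <- additive_relationship(ped)
  kid <- ped[!is.na(ped$sire), ][1, ]
  expect_equal(A[kid$animal, kid$sire], 0.5)
  expect_equal(A[kid$animal, kid$animal], 1)
})

test_that("gene dropping with recomb_prob = 0 transmits intact haplotypes", {
  cfg <- sim_config(n_founders = 10, n_generations = 2, n_chromosomes = 2,
                    snps_per_chromosome = 30, seed = 6)
  founders <- simulate_haplotype_panel(cfg)
  ped <- simulate_pedigree(cfg)
  panel <- drop_genotypes(ped, founders$panel, founders$map, 0, seed = 8)
  idx <- setNames(seq_along(panel$ids), panel$ids)
  kids <- ped[!is.na(ped$sire), ]
  for (k in seq_len(nrow(kids))) {
    for (h in 1:2) {
      parent <- if (h == 1) kids$sire[k] else kids$dam[k]
      gamete <- panel$alleles[idx[kids$animal[k]], h, ]
      # per chromosome the gamete must equal one parental haplotype exactly
      for (ch in unique(founders$map$chrom)) {
        cols <- which(founders$map$chrom == ch)
        ok <- identical(gamete[cols], panel$alleles[idx[parent], 1, cols]) ||
          identical(gamete[cols], panel$alleles[idx[parent], 2, cols])
        expect_true(ok)
      }
    }
  }
})

test_that("recomb_prob = 0.5 switches parental haplotype about half the time", {
  # one founder pair, many offspring; count switch events directly on
  # heterozygous-distinct loci of a designed parent
  n_kids <- 2500
  H <- rbind(rep(0L, 40), rep(1L, 40),  # parent P1: haplotypes all-0 / all-1
             rep(0L, 40), rep(1L, 40))  # parent P2 identical design
  founders <- panel_from_haps(H, c("P1", "P2"))
  map <- map_for(40)
  ped <- data.frame(animal = c("P1", "P2", sprintf("K%04d", seq_len(n_kids))),
                    sire = c(NA, NA, rep("P1", n_kids)),
                    dam = c(NA, NA, rep("P2", n_kids)),
                    generation = c(0L, 0L, rep(1L, n_kids)))
  panel <- drop_genotypes(ped, founders, map, 0.5, seed = 11)
  kid_rows <- match(sprintf("K%04d", seq_len(n_kids)), panel$ids)
  gametes <- panel$alleles[kid_rows, 1, ]       # paternal gametes
  switches <- gametes[, -1] != gametes[, -40]   # origin switch = allele change
  rate <- mean(switches)
  expect_gt(rate, 0.48)
  expect_lt(rate, 0.52)
})

test_that("descendant allele frequencies show no systematic drift", {
  cfg <- sim_config(n_founders = 120, n_generations = 3, n_chromosomes = 1,
                    snps_per_chromosome = 60, adjacent_corr = 0.5,
                    maf_range = c(0.2, 0.5), seed = 12)
  ds <- simulate_dataset(cfg)
  founder_rows <- which(ds$pedigree$generation == 0)
  last_rows <- which(ds$pedigree$generation == 2)
  Hf <- dosage_matrix(subset_panel(ds$panel, animals = founder_rows))
  Hl <- dosage_matrix(subset_panel(ds$panel, animals = last_rows))
  p0 <- colMeans(Hf) / 2
  p2 <- colMeans(Hl) / 2
  n_hap <- 2 * length(last_rows)
  # genetic drift inflates variance beyond one binomial generation; a wide
  # multiple of the binomial SE bounds systematic (directional) drift
  se <- sqrt(p0 * (1 - p0) / n_hap)
  expect_true(mean(abs(p2 - p0) <= 6 * se + 0.05) > 0.95)
  expect_lt(abs(mean(p2 - p0)), 0.02)
})

test_that("phenotypes realize the requested heritability", {
  cfg <- sim_config(n_founders = 2000, n_generations = 1, n_chromosomes = 1,
                    snps_per_chromosome = 100, n_qtl = 50, h2 = 0.39,
                    mixture_props = c(0.7, 0.2, 0.07, 0.03),
                    mixture_sds = c(0.05, 0.2, 0.5, 1), seed = 3)
  sim <- simulate_haplotype_panel(cfg)
  phen <- simulate_phenotypes(sim$panel, sim$map, cfg)
  h2_realized <- cor(phen$tbv$tbv, phen$tbv$phenotype)^2
  expect_lt(abs(h2_realized - 0.39), 0.03)
})

test_that("perfect DRP reliability recovers TBV; zero effects give TBV = 0", {
  cfg <- sim_config(n_founders = 50, n_generations = 1,
                    snps_per_chromosome = 40, n_qtl = 5,
                    drp_reliability_range = c(1 - 1e-9, 1 - 1e-9), seed = 5)
  sim <- simulate_haplotype_panel(cfg)
  phen <- simulate_phenotypes(sim$panel, sim$map, cfg)
  expect_lt(max(abs(phen$drp$drp - phen$tbv$tbv)), 1e-3)

  cfg0 <- sim_config(n_founders = 50, n_generations = 1,
                     snps_per_chromosome = 40, n_qtl = 5,
                     mixture_props = c(1, 0, 0, 0),
                     mixture_sds = c(0, 1, 1, 1), seed = 5)
  phen0 <- simulate_phenotypes(sim$panel, sim$map, cfg0)
  expect_true(all(phen0$tbv$tbv == 0))
  expect_true(all(phen0$qtl$effect == 0))
})

test_that("squared DRP-TBV correlation approaches the mean reliability", {
  cfg <- sim_config(n_founders = 4000, n_generations = 1, n_chromosomes = 1,
                    snps_per_chromosome = 80, n_qtl = 40,
                    drp_reliability_range = c(0.7, 0.9), seed = 21)
  sim <- simulate_haplotype_panel(cfg)
  phen <- simulate_phenotypes(sim$panel, sim$map, cfg)
  r2 <- cor(phen$drp$drp, phen$tbv$tbv)^2
  expect_lt(abs(r2 - mean(phen$drp$reliability)), 0.04)
})
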