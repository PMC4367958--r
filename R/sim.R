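#' Simulation configuration
#'
#' Bundles and validates every parameter of the forward simulator: founder
#' haplotypes with tunable adjacent-locus LD, a multi-generation pedigree,
#' gene dropping with recombination, a sparse-mixture QTL architecture, and
#' de-regressed proofs (DRP) with heterogeneous reliabilities.
#'
#' @param n_founders Number of founder animals (>= 1).
#' @param n_generations Total number of generations including the founders.
#' @param offspring_per_mating Offspring produced by each mating.
#' @param n_chromosomes Number of chromosomes.
#' @param snps_per_chromosome Markers per chromosome.
#' @param adjacent_corr Probability, in `[0, 1)`, that a founder haplotype
#'   copies its allele at locus j to locus j+1 instead of drawing a fresh
#'   allele; controls the decay of adjacent-locus D'.
#' @param maf_range Length-2 numeric in (0, 0.5], ordered; founder minor
#'   allele frequencies are drawn uniformly from this interval.
#' @param recomb_prob_per_interval Probability of a crossover between two
#'   adjacent loci during gamete formation, in `[0, 0.5]`.
#' @param n_qtl Number of QTL sampled (without replacement) among the markers.
#' @param mixture_props Length-4 proportions of the QTL-effect normal mixture,
#'   summing to 1.
#' @param mixture_sds Length-4 non-negative standard deviations of the
#'   mixture components.
#' @param h2 Narrow-sense heritability of the simulated trait, in (0, 1).
#' @param drp_reliability_range Length-2 interval in (0, 1), ordered; each
#'   animal's DRP reliability is drawn uniformly from it.
#' @param seed Integer seed; identical configurations yield identical output.
#'
#' @return A validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_founders = 20, n_generations = 2,
#'                   snps_per_chromosome = 50, seed = 1)
#' @export
sim_config <- function(n_founders = 100,
                       n_generations = 3,
                       offspring_per_mating = 2,
                       n_chromosomes = 2,
                       snps_per_chromosome = 100,
                       adjacent_corr = 0.9,
                       maf_range = c(0.05, 0.5),
                       recomb_prob_per_interval = 0.01,
                       n_qtl = 10,
                       mixture_props = c(0.889, 0.1, 0.01, 0.001),
                       mixture_sds = c(0.01, 0.1, 0.5, 1),
                       h2 = 0.39,
                       drp_reliability_range = c(0.8, 0.95),
                       seed = 1L) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              offspring_per_mating = as.integer(offspring_per_mating),
              n_chromosomes = as.integer(n_chromosomes),
              snps_per_chromosome = as.integer(snps_per_chromosome),
              adjacent_corr = adjacent_corr,
              maf_range = as.numeric(maf_range),
              recomb_prob_per_interval = recomb_prob_per_interval,
              n_qtl = as.integer(n_qtl),
              mixture_props = as.numeric(mixture_props),
              mixture_sds = as.numeric(mixture_sds),
              h2 = h2,
              drp_reliability_range = as.numeric(drp_reliability_range),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  chk_count <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 1L)
      stop("configuration error: '", nm, "' must be a count >= 1",
           call. = FALSE)
  }
  for (nm in c("n_founders", "n_generations", "offspring_per_mating",
               "n_chromosomes", "snps_per_chromosome", "n_qtl"))
    chk_count(cfg[[nm]], nm)
  if (cfg$adjacent_corr < 0 || cfg$adjacent_corr >= 1)
    stop("configuration error: 'adjacent_corr' must be in [0, 1)",
         call. = FALSE)
  if (length(cfg$maf_range) != 2L || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || diff(cfg$maf_range) < 0)
    stop("configuration error: 'maf_range' must be an ordered pair in (0, 0.5]",
         call. = FALSE)
  if (cfg$recomb_prob_per_interval < 0 || cfg$recomb_prob_per_interval > 0.5)
    stop("configuration error: 'recomb_prob_per_interval' must be in [0, 0.5]",
         call. = FALSE)
  if (length(cfg$mixture_props) != 4L ||
      abs(sum(cfg$mixture_props) - 1) > 1e-12 || any(cfg$mixture_props < 0))
    stop("configuration error: 'mixture_props' must be 4 non-negative ",
         "proportions summing to 1", call. = FALSE)
  if (length(cfg$mixture_sds) != 4L || any(cfg$mixture_sds < 0))
    stop("configuration error: 'mixture_sds' must be 4 non-negative reals",
         call. = FALSE)
  if (cfg$h2 <= 0 || cfg$h2 >= 1)
    stop("configuration error: 'h2' must be in (0, 1)", call. = FALSE)
  rr <- cfg$drp_reliability_range
  if (length(rr) != 2L || any(rr <= 0) || any(rr >= 1) || diff(rr) < 0)
    stop("configuration error: 'drp_reliability_range' must be an ordered ",
         "pair in (0, 1)", call. = FALSE)
  invisible(cfg)
}

#' Simulate founder haplotypes with adjacent-locus LD
#'
#' Founder haplotype alleles form a first-order Markov chain along each
#' chromosome: locus j+1 copies locus j's allele with probability
#' `adjacent_corr`, otherwise a fresh allele is drawn Bernoulli at that
#' locus's own minor allele frequency. This gives single-parameter control of
#' the decay of adjacent-pair D', the only LD feature the block builder
#' consumes.
#'
#' @param config A [sim_config()].
#' @return A list with components `panel` (a [hap_panel()] of the founders)
#'   and `map` (a marker map data frame).
#' @export
simulate_haplotype_panel <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    n <- config$n_founders
    m_chr <- config$snps_per_chromosome
    n_hap <- 2L * n
    chroms <- vector("list", config$n_chromosomes)
    maps <- vector("list", config$n_chromosomes)
    for (ch in seq_len(config$n_chromosomes)) {
      maf <- stats::runif(m_chr, config$maf_range[1], config$maf_range[2])
      H <- matrix(0L, n_hap, m_chr)
      fresh <- matrix(stats::rbinom(n_hap * m_chr, 1L,
                                    rep(maf, each = n_hap)),
                      n_hap, m_chr)
      H[, 1L] <- fresh[, 1L]
      if (m_chr > 1L) {
        copy <- matrix(stats::runif(n_hap * (m_chr - 1L)) < config$adjacent_corr,
                       n_hap, m_chr - 1L)
        for (j in 2:m_chr)
          H[, j] <- ifelse(copy[, j - 1L], H[, j - 1L], fresh[, j])
      }
      chroms[[ch]] <- H
      maps[[ch]] <- data.frame(
        chrom = sprintf("chr%d", ch),
        pos = seq_len(m_chr) * 1000L,
        id = sprintf("chr%d_snp%05d", ch, seq_len(m_chr)),
        ref = "A", alt = "G",
        stringsAsFactors = FALSE)
    }
    H_all <- do.call(cbind, chroms)
    map <- marker_map(do.call(rbind, maps))
    ids <- sprintf("F%05d", seq_len(n))
    list(panel = hap_panel_from_matrix(H_all, ids), map = map)
  })
}

#' Simulate a multi-generation random-mating pedigree
#'
#' Founders (generation 0) have unknown parents. Each later generation is
#' produced by random sire-by-dam matings among the previous generation's
#' animals (sexes alternate within a generation), with
#' `offspring_per_mating` offspring per mating; generation sizes stay close
#' to the founder count. Parents always precede offspring in the returned
#' order.
#'
#' @param config A [sim_config()].
#' @return A pedigree data frame with columns `animal`, `sire`, `dam`
#'   (`NA` = unknown) and `generation`.
#' @export
simulate_pedigree <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed + 1L, {
    n0 <- config$n_founders
    ped <- data.frame(animal = sprintf("F%05d", seq_len(n0)),
                      sire = NA_character_, dam = NA_character_,
                      generation = 0L, stringsAsFactors = FALSE)
    prev <- ped$animal
    counter <- 0L
    for (g in seq_len(config$n_generations - 1L)) {
      # alternate sexes within the previous generation
      males <- prev[seq_along(prev) %% 2L == 1L]
      females <- prev[seq_along(prev) %% 2L == 0L]
      if (length(females) == 0L) females <- males
      n_mat <- max(1L, ceiling(n0 / config$offspring_per_mating))
      sires <- sample(males, n_mat, replace = TRUE)
      dams <- sample(females, n_mat, replace = TRUE)
      kids <- data.frame(
        animal = sprintf("G%d_%05d", g,
                         counter + seq_len(n_mat * config$offspring_per_mating)),
        sire = rep(sires, each = config$offspring_per_mating),
        dam = rep(dams, each = config$offspring_per_mating),
        generation = g, stringsAsFactors = FALSE)
      counter <- counter + nrow(kids)
      ped <- rbind(ped, kids)
      prev <- kids$animal
    }
    validate_pedigree(ped)
  })
}

#' Gene-drop founder haplotypes through a pedigree
#'
#' Each non-founder inherits one recombinant gamete from each parent. A
#' gamete starts on a uniformly chosen parental haplotype and switches to the
#' other haplotype between adjacent loci with probability `recomb_prob`,
#' independently per interval and never across chromosome boundaries.
#'
#' @param pedigree Pedigree data frame; founder rows (unknown parents) must
#'   correspond one-to-one, in order, with `founder_panel` individuals.
#' @param founder_panel [hap_panel()] of the founders.
#' @param map Marker map of the panel.
#' @param recomb_prob Per-interval crossover probability.
#' @param seed Integer seed.
#' @return A [hap_panel()] covering every pedigree animal, phased.
#' @export
drop_genotypes <- function(pedigree, founder_panel, map, recomb_prob, seed) {
  pedigree <- validate_pedigree(pedigree)
  founders <- pedigree$animal[is.na(pedigree$sire) & is.na(pedigree$dam)]
  if (length(founders) != n_animals(founder_panel))
    stop("input error: pedigree founders (", length(founders),
         ") do not match founder panel individuals (",
         n_animals(founder_panel), ")", call. = FALSE)
  m <- n_markers(founder_panel)
  if (nrow(map) != m)
    stop("input error: map/panel marker dimension mismatch", call. = FALSE)
  chrom_rle <- rle(map$chrom)
  withr::with_seed(as.integer(seed), {
    n_all <- nrow(pedigree)
    alleles <- array(0L, dim = c(n_all, 2L, m))
    idx <- stats::setNames(seq_len(n_all), pedigree$animal)
    alleles[idx[founders], , ] <- founder_panel$alleles
    # precompute chromosome start offsets
    chr_end <- cumsum(chrom_rle$lengths)
    chr_start <- chr_end - chrom_rle$lengths + 1L
    gamete <- function(parent_row) {
      out <- integer(m)
      for (k in seq_along(chr_start)) {
        len <- chrom_rle$lengths[k]
        start_hap <- sample.int(2L, 1L)
        if (len > 1L) {
          switches <- stats::runif(len - 1L) < recomb_prob
          hap_idx <- 1L + (start_hap - 1L + c(0L, cumsum(switches))) %% 2L
        } else hap_idx <- start_hap
        cols <- chr_start[k]:chr_end[k]
        out[cols] <- alleles[parent_row, , cols][cbind(hap_idx, seq_len(len))]
      }
      out
    }
    for (i in seq_len(n_all)) {
      if (is.na(pedigree$sire[i]) && is.na(pedigree$dam[i])) next
      alleles[i, 1L, ] <- gamete(idx[[pedigree$sire[i]]])
      alleles[i, 2L, ] <- gamete(idx[[pedigree$dam[i]]])
    }
    hap_panel(alleles, pedigree$animal)
  })
}

#' Simulate true breeding values and de-regressed proofs
#'
#' QTL positions are sampled without replacement among the markers; each QTL
#' effect is drawn from a four-component normal mixture. True breeding values
#' (TBV) are genotype dosages times effects, centred. The environmental
#' deviation is orthogonalized against TBV and scaled so the realized
#' heritability `var(TBV)/var(TBV + E)` equals `h2` exactly. Each animal's
#' DRP reliability r2 is drawn uniformly from `drp_reliability_range`, and
#' DRP = TBV + e with `var(e) = var(TBV) (1 - r2) / r2`, the standard
#' de-regression error variance.
#'
#' @param panel [hap_panel()] of all animals.
#' @param map Marker map.
#' @param config A [sim_config()].
#' @return A list with `tbv` (data frame `animal`, `tbv`, `phenotype`),
#'   `drp` (data frame `animal`, `trait`, `drp`, `reliability`) and `qtl`
#'   (data frame `marker_index`, `marker_id`, `component`, `effect`).
#' @export
simulate_phenotypes <- function(panel, map, config) {
  validate_sim_config(config)
  m <- n_markers(panel)
  if (config$n_qtl > m)
    stop("configuration error: 'n_qtl' exceeds the number of markers",
         call. = FALSE)
  withr::with_seed(config$seed + 2L, {
    n <- n_animals(panel)
    qtl_idx <- sort(sample.int(m, config$n_qtl))
    comp <- sample.int(4L, config$n_qtl, replace = TRUE,
                       prob = config$mixture_props)
    eff <- stats::rnorm(config$n_qtl, 0, config$mixture_sds[comp])
    dos <- dosage_matrix(panel)[, qtl_idx, drop = FALSE]
    tbv <- drop(dos %*% eff)
    tbv <- tbv - mean(tbv)
    v_tbv <- stats::var(tbv)
    if (v_tbv > 0) {
      e_env <- stats::rnorm(n)
      e_env <- stats::resid(stats::lm(e_env ~ tbv))    # exact orthogonality
      e_env <- e_env * sqrt(v_tbv * (1 - config$h2) / config$h2 /
                              stats::var(e_env))
    } else e_env <- numeric(n)
    pheno <- tbv + e_env
    r2 <- stats::runif(n, config$drp_reliability_range[1],
                       config$drp_reliability_range[2])
    e_drp <- stats::rnorm(n, 0, sqrt(v_tbv * (1 - r2) / r2))
    drp <- tbv + e_drp
    list(tbv = data.frame(animal = panel$ids, tbv = tbv, phenotype = pheno,
                          stringsAsFactors = FALSE),
         drp = data.frame(animal = panel$ids, trait = "sim", drp = drp,
                          reliability = r2, stringsAsFactors = FALSE),
         qtl = data.frame(marker_index = qtl_idx, marker_id = map$id[qtl_idx],
                          component = comp, effect = eff,
                          stringsAsFactors = FALSE))
  })
}

#' Simulate a complete data set
#'
#' Convenience wrapper chaining [simulate_haplotype_panel()],
#' [simulate_pedigree()], [drop_genotypes()] and [simulate_phenotypes()].
#'
#' @param config A [sim_config()].
#' @return A list with `panel` (all animals), `map`, `pedigree`, `tbv`,
#'   `drp` and `qtl`.
#' @export
simulate_dataset <- function(config) {
  founders <- simulate_haplotype_panel(config)
  ped <- simulate_pedigree(config)
  panel <- drop_genotypes(ped, founders$panel, founders$map,
                          config$recomb_prob_per_interval,
                          config$seed + 3L)
  phen <- simulate_phenotypes(panel, founders$map, config)
  list(panel = panel, map = founders$map, pedigree = ped,
       tbv = phen$tbv, drp = phen$drp, qtl = phen$qtl)
}
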