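# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force (direct counting, dense solves) rather than
# calling the implementation paths they check.

# D' by direct counting of the four haplotype classes in a 2n x m matrix
oracle_dprime_pair <- function(H, i, j) {
  x <- H[, i]; y <- H[, j]
  f11 <- mean(x == 1 & y == 1)
  p <- mean(x == 1); q <- mean(y == 1)
  if (p <= 0 || p >= 1 || q <= 0 || q >= 1) return(NA_real_)
  D <- f11 - p * q
  if (D == 0) return(0)
  dmax <- if (D > 0) min(p * (1 - q), (1 - p) * q) else
    min(p * q, (1 - p) * (1 - q))
  abs(D) / dmax
}

# independently coded greedy maximal-extension block search over one
# chromosome's haplotype matrix
oracle_blocks <- function(H, d) {
  m <- ncol(H)
  blocks <- list(); nonblocked <- integer(0)
  s <- 1L
  while (s <= m) {
    e <- s
    while (e < m) {
      dp <- vapply(s:e, function(i) oracle_dprime_pair(H, i, e + 1L),
                   numeric(1))
      if (all(!is.na(dp)) && all(dp >= d)) e <- e + 1L else break
    }
    if (e > s) blocks[[length(blocks) + 1L]] <- c(s, e) else
      nonblocked <- c(nonblocked, s)
    s <- e + 1L
  }
  list(blocks = blocks, nonblocked = nonblocked)
}

# direct dense solve of the weighted mixed-model equations at fixed
# variance components; equals the posterior mean of (mu, g, a)
oracle_mme <- function(y, w, M, A, rec_animal, sg2, sa2, se2) {
  n <- length(y); p <- ncol(M); q <- nrow(A)
  Z <- matrix(0, n, q)
  Z[cbind(seq_len(n), rec_animal)] <- 1
  X <- cbind(1, M, Z)
  lhs <- crossprod(X, X * w) / se2
  ig <- 1 + seq_len(p); ia <- 1 + p + seq_len(q)
  lhs[ig, ig] <- lhs[ig, ig] + diag(1 / sg2, p)
  lhs[ia, ia] <- lhs[ia, ia] + solve(A) / sa2
  rhs <- crossprod(X, w * y) / se2
  sol <- solve(lhs, rhs)
  list(mu = sol[1], g = sol[ig], a = sol[ia])
}

# tiny helper: panel from an explicit 2n x m haplotype matrix
panel_from_haps <- function(H, ids = sprintf("A%03d", seq_len(nrow(H) / 2))) {
  haplopred:::hap_panel_from_matrix(H, ids)
}

map_for <- function(m, chrom = "chr1") {
  marker_map(data.frame(chrom = chrom, pos = seq_len(m) * 100L,
                        id = sprintf("%s_m%04d", chrom, seq_len(m)),
                        ref = "A", alt = "G", stringsAsFactors = FALSE))
}

# random polymorphic panel for fuzzing
random_panel <- function(n_animals, m, seed, p_range = c(0.1, 0.9)) {
  withr::with_seed(seed, {
    p <- runif(m, p_range[1], p_range[2])
    H <- matrix(rbinom(2 * n_animals * m, 1, rep(p, each = 2 * n_animals)),
                2 * n_animals, m)
    panel_from_haps(H)
  })
}

# small simulated chromosome with genuine LD, as a 2n x m matrix
ld_chromosome <- function(n_hap, m, corr, seed) {
  withr::with_seed(seed, {
    p <- runif(m, 0.2, 0.5)
    H <- matrix(0L, n_hap, m)
    H[, 1] <- rbinom(n_hap, 1, p[1])
    for (j in 2:m) {
      copy <- runif(n_hap) < corr
      H[, j] <- ifelse(copy, H[, j - 1], rbinom(n_hap, 1, p[j]))
    }
    H
  })
}
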