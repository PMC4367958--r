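#' MCMC configuration
#'
#' @param n_cycles Total Gibbs cycles (default 50,000, the conventional
#'   production schedule for these models).
#' @param burn_in Cycles discarded as burn-in (default 20,000); must be
#'   smaller than `n_cycles`.
#' @param thin Keep every `thin`-th post-burn-in cycle (default 1).
#' @param seed Integer seed; identical seed and configuration give
#'   byte-identical chains.
#' @return A list of class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_cycles = 50000L, burn_in = 20000L, thin = 1L,
                        seed = 1L) {
  n_cycles <- as.integer(n_cycles); burn_in <- as.integer(burn_in)
  if (burn_in >= n_cycles)
    stop("config error: 'burn_in' must be smaller than 'n_cycles'",
         call. = FALSE)
  if (thin < 1L) stop("config error: 'thin' must be >= 1", call. = FALSE)
  structure(list(n_cycles = n_cycles, burn_in = burn_in,
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Mixture prior for marker/haploblock effects
#'
#' Four-component normal mixture with fixed mixing proportions and
#' uniformly distributed component variances constrained to be ordered
#' (`s2_1 <= s2_2 <= s2_3 <= s2_4`). The default proportions put 88.9% of
#' effects in the smallest-variance component, so most effects stay near
#' zero while a few may be large.
#'
#' @param proportions Length-4 non-negative proportions summing to 1;
#'   default `c(0.889, 0.1, 0.01, 0.001)`.
#' @return A list of class `"mixture_prior"`.
#' @export
mixture_prior <- function(proportions = c(0.889, 0.1, 0.01, 0.001)) {
  if (length(proportions) != 4L || any(proportions < 0) ||
      abs(sum(proportions) - 1) > 1e-8)
    stop("config error: mixture proportions must be 4 non-negative values ",
         "summing to 1", call. = FALSE)
  structure(list(proportions = as.numeric(proportions)),
            class = "mixture_prior")
}

#' Residual weights from DRP reliabilities
#'
#' `w_i = r2_i / (1 - r2_i)`; record i's residual variance is `se2 / w_i`,
#' which accounts for heterogeneous residual variances caused by differing
#' DRP reliabilities. Undefined at r2 = 0 or 1.
#'
#' @param reliabilities Numeric vector strictly inside (0, 1).
#' @return Positive weights, same length.
#' @examples
#' drp_weights(c(0.5, 0.9))  # 1, 9
#' @export
drp_weights <- function(reliabilities) {
  if (any(!is.finite(reliabilities)) || any(reliabilities <= 0) ||
      any(reliabilities >= 1))
    stop("value error: reliabilities must lie strictly inside (0, 1)",
         call. = FALSE)
  reliabilities / (1 - reliabilities)
}

#' Assemble model input
#'
#' Bundles the training design matrix, phenotypes, weights and relationship
#' matrix for the samplers. The relationship matrix covers all animals
#' (training and selection candidates); animals without records receive no
#' data contribution and their polygenic effects are sampled from the
#' conditional prior given their relatives.
#'
#' @param M Training-row design matrix (an `"hb_design"` or plain matrix)
#'   with animal ids as row names.
#' @param y DRP vector aligned with the rows of `M`.
#' @param reliability DRP reliabilities aligned with `y` (used via
#'   [drp_weights()]).
#' @param A Additive relationship matrix over all animals, with dimnames.
#' @return A list of class `"model_input"`.
#' @export
model_input <- function(M, y, reliability, A) {
  if (length(y) != nrow(M) || length(reliability) != nrow(M))
    stop("input error: y/reliability must align with the rows of M",
         call. = FALSE)
  if (is.null(rownames(M)) || is.null(colnames(A)))
    stop("input error: M needs row names and A needs dimnames", call. = FALSE)
  rec_animal <- match(rownames(M), colnames(A))
  if (anyNA(rec_animal))
    stop("input error: training animals missing from the relationship matrix",
         call. = FALSE)
  w <- drp_weights(reliability)
  structure(list(M = M, y = as.numeric(y), weights = w,
                 reliability = as.numeric(reliability),
                 A = A, rec_animal = rec_animal,
                 animals = colnames(A)),
            class = "model_input")
}

ainverse <- function(A) {
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) ch <- chol(A + diag(1e-8, nrow(A)))  # PSD-but-singular A
  chol2inv(ch)
}

default_inits <- function(input, prior = NULL) {
  vary <- stats::var(input$y)
  if (!is.finite(vary) || vary <= 0) vary <- 1
  p <- ncol(input$M)
  col_var <- if (p > 0) mean(apply(input$M, 2, stats::var)) else 1
  if (!is.finite(col_var) || col_var <= 0) col_var <- 1
  target_g <- 0.4 * vary
  sg2 <- target_g / max(p * col_var, 1)
  s2k <- c(0.01, 0.1, 1, 10)
  if (!is.null(prior)) {
    # scale so the prior-weighted marker variance matches the BLUP target
    scale <- target_g / max(p * col_var * sum(prior$proportions * s2k), 1e-12)
    s2k <- s2k * scale
  }
  list(vary = vary, sg2 = sg2, s2k = s2k,
       sa2 = 0.1 * vary, se2 = 0.5 * vary,
       lower = vary * 1e-10, upper = vary * 1e4)
}

run_gibbs <- function(input, cfg, mixture, prior, fix_variances,
                      keep_samples) {
  init <- default_inits(input, if (mixture) prior else NULL)
  update_var <- is.null(fix_variances)
  if (!update_var) {
    if (!mixture && !is.null(fix_variances$sg2)) init$sg2 <- fix_variances$sg2
    if (mixture && !is.null(fix_variances$s2k)) init$s2k <- fix_variances$s2k
    if (!is.null(fix_variances$sa2)) init$sa2 <- fix_variances$sa2
    if (!is.null(fix_variances$se2)) init$se2 <- fix_variances$se2
  }
  Ainv <- ainverse(input$A)
  res <- withr::with_seed(cfg$seed,
    gibbs_fit(input$y, input$weights, unclass_matrix(input$M),
              input$rec_animal - 1L, Ainv,
              cfg$n_cycles, cfg$burn_in, cfg$thin,
              mixture,
              if (mixture) prior$proportions else rep(0.25, 4),
              update_var,
              init$sg2, init$s2k, init$sa2, init$se2,
              init$lower, init$upper, keep_samples))
  vm <- as.numeric(res$var_mean); vs <- as.numeric(res$var_sd)
  names(vm) <- names(vs) <- c("sg2", "s2_1", "s2_2", "s2_3", "s2_4",
                              "sa2", "se2")
  fit <- list(model = if (mixture) "mixture" else "blup",
              mu_mean = res$mu_mean, mu_sd = res$mu_sd,
              g_mean = as.numeric(res$g_mean), g_sd = as.numeric(res$g_sd),
              a_mean = stats::setNames(as.numeric(res$a_mean), input$animals),
              a_sd = stats::setNames(as.numeric(res$a_sd), input$animals),
              var_mean = vm, var_sd = vs,
              comp_freq = res$comp_freq,
              column_meta = attr(input$M, "column_meta"),
              n_saved = res$n_saved,
              n_order_reject = res$n_order_reject,
              mcmc = cfg,
              prior = if (mixture) prior else NULL,
              samples = res$samples)
  class(fit) <- "hb_fit"
  fit
}

unclass_matrix <- function(M) {
  M <- unclass(M)
  attr(M, "column_meta") <- NULL
  attr(M, "encoding_mode") <- NULL
  storage.mode(M) <- "double"
  M
}

#' Fit the weighted BLUP model by Gibbs sampling
#'
#' Fits `y = mu + M g + Z a + e` with `g ~ N(0, I sg2)`,
#' `a ~ N(0, A sa2)` and `e ~ N(0, D se2)` where `d_ii = 1/w_i` and
#' `w_i = r2_i / (1 - r2_i)`; a flat prior on `mu` and bounded-uniform
#' priors on the variance components, all updated by single-chain Gibbs
#' sampling. Effect columns are updated in fixed map order; polygenic
#' effects animal-by-animal, so animals without records are predicted from
#' the pedigree alone.
#'
#' @param input A [model_input()].
#' @param mcmc An [mcmc_config()].
#' @param fix_variances Optional list with elements among `sg2`, `sa2`,
#'   `se2` (and `s2k` for the mixture); when supplied, variance components
#'   are held fixed at these values and only location parameters are
#'   sampled.
#' @param keep_samples Keep the full retained chains (`mu`, `g`, `a`,
#'   variances)? Memory-heavy; meant for small instances and diagnostics.
#' @return An object of class `"hb_fit"` with posterior means and SDs of
#'   `mu`, `g` (per column), `a` (per animal), variance components, and
#'   sampler diagnostics.
#' @export
fit_blup <- function(input, mcmc = mcmc_config(), fix_variances = NULL,
                     keep_samples = FALSE) {
  stopifnot(inherits(input, "model_input"))
  run_gibbs(input, mcmc, mixture = FALSE, prior = NULL,
            fix_variances = fix_variances, keep_samples = keep_samples)
}

#' Fit the four-component Bayesian mixture model by Gibbs sampling
#'
#' Same linear model as [fit_blup()], but each effect `g_j` carries a
#' four-component normal mixture prior with fixed mixing proportions.
#' Gibbs sampling adds a per-column component indicator (categorical full
#' conditional) and per-component variance updates under uniform priors,
#' with the ordering constraint `s2_1 <= s2_2 <= s2_3 <= s2_4` enforced by
#' rejection of violating draws. Variances and effects are estimated
#' simultaneously.
#'
#' @inheritParams fit_blup
#' @param prior A [mixture_prior()].
#' @return An `"hb_fit"`; additionally carries `comp_freq`, the per-column
#'   posterior frequencies of membership in each mixture component.
#' @export
fit_mixture <- function(input, prior = mixture_prior(),
                        mcmc = mcmc_config(), fix_variances = NULL,
                        keep_samples = FALSE) {
  stopifnot(inherits(input, "model_input"), inherits(prior, "mixture_prior"))
  run_gibbs(input, mcmc, mixture = TRUE, prior = prior,
            fix_variances = fix_variances, keep_samples = keep_samples)
}

#' @export
print.hb_fit <- function(x, ...) {
  cat("<hb_fit> ", x$model, " model: ", length(x$g_mean), " effect columns, ",
      length(x$a_mean), " animals, ", x$n_saved, " retained cycles\n",
      sep = "")
  cat("  variance posterior means:\n")
  print(round(x$var_mean, 5))
  invisible(x)
}

#' Monte-Carlo standard error by batch means
#'
#' @param x Numeric chain (post-burn-in samples).
#' @param n_batches Number of batches (default 20).
#' @return The batch-means MCSE of the chain mean.
#' @export
mcse <- function(x, n_batches = 20L) {
  n <- length(x)
  b <- max(2L, floor(n / n_batches))
  nb <- floor(n / b)
  means <- vapply(seq_len(nb),
                  function(k) mean(x[((k - 1L) * b + 1L):(k * b)]), 0)
  stats::sd(means) / sqrt(nb)
}
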