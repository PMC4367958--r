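#' Genomic estimated breeding values
#'
#' `GEBV_i = sum_j m_ij g_hat_j + a_hat_i` using posterior means; the
#' polygenic term for animals without records comes from their sampled
#' conditional prior given relatives, so no separate projection is needed.
#'
#' @param fit An `"hb_fit"` from [fit_blup()] or [fit_mixture()].
#' @param M_new Design-matrix rows (same columns as the training design)
#'   for the animals to predict; row names are animal ids.
#' @return A data frame `animal`, `gebv`.
#' @export
predict_gebv <- function(fit, M_new) {
  if (ncol(M_new) != length(fit$g_mean))
    stop("input error: design columns do not match the fitted effects",
         call. = FALSE)
  ids <- rownames(M_new)
  if (is.null(ids)) stop("input error: M_new needs animal row names",
                         call. = FALSE)
  a_hat <- fit$a_mean[ids]
  if (anyNA(a_hat))
    stop("input error: animals absent from the fitted relationship matrix: ",
         paste(utils::head(ids[is.na(a_hat)], 5), collapse = ", "),
         call. = FALSE)
  gebv <- drop(unclass_matrix(M_new) %*% fit$g_mean) + as.numeric(a_hat)
  data.frame(animal = ids, gebv = as.numeric(gebv),
             stringsAsFactors = FALSE)
}

#' Prediction reliability and bias
#'
#' Validation reliability is the squared correlation between DRP and GEBV
#' corrected for the mean reliability of the DRP:
#' `r2 = cor(DRP, GEBV)^2 / mean(r2_DRP)`. Prediction bias is assessed by
#' the ordinary least-squares regression coefficient `b` of DRP on GEBV
#' (b = 1 means unbiased).
#'
#' @param drp DRP values of the validation animals.
#' @param gebv GEBV of the same animals, same order.
#' @param drp_reliabilities Per-animal DRP reliabilities, same order.
#' @return A list of class `"evaluation_result"`: `reliability`,
#'   `bias_slope_b`, `raw_correlation`, `mean_drp_reliability`, `n_test`.
#' @export
prediction_reliability <- function(drp, gebv, drp_reliabilities) {
  n <- length(drp)
  if (length(gebv) != n || length(drp_reliabilities) != n)
    stop("input error: inputs must have equal length", call. = FALSE)
  if (n < 3L) stop("input error: need at least 3 validation animals",
                   call. = FALSE)
  if (stats::sd(gebv) == 0)
    stop("undefined-correlation error: GEBV have zero variance",
         call. = FALSE)
  rho <- stats::cor(drp, gebv)
  rbar <- mean(drp_reliabilities)
  structure(list(reliability = rho^2 / rbar,
                 bias_slope_b = stats::cov(drp, gebv) / stats::var(gebv),
                 raw_correlation = rho,
                 mean_drp_reliability = rbar,
                 n_test = n),
            class = "evaluation_result")
}

#' Hotelling-Williams test for two dependent correlations
#'
#' Tests `H0: cor(DRP, GEBV_i) = cor(DRP, GEBV_j)` where both correlations
#' share the DRP vector, using the Hotelling-Williams t statistic
#' referred to a t distribution with n - 3 degrees of freedom:
#' \deqn{t = (r_{1y} - r_{2y})
#'   \sqrt{\frac{(n-1)(1+r_{12})}
#'        {2\frac{n-1}{n-3}|R| + \bar r^2 (1-r_{12})^3}}}
#' with `|R|` the determinant of the 3x3 correlation matrix of
#' (DRP, GEBV_i, GEBV_j) and `r_bar = (r_1y + r_2y)/2`. The one-sided
#' p-value addresses `H0: cor_i >= cor_j` against the alternative that the
#' first correlation is smaller; with identical GEBV vectors t = 0 and the
#' two-sided p is 1.
#'
#' @param drp DRP vector.
#' @param gebv_i,gebv_j GEBV vectors from the two models being compared.
#' @param sidedness `"two"` (default) or `"one"`.
#' @return A list of class `"hotelling_result"`: `t_statistic`, `p_value`,
#'   `r_1y`, `r_2y`, `r_12`, `determinant_D`, `n`, `df`, `sidedness`.
#' @export
hotelling_test <- function(drp, gebv_i, gebv_j,
                           sidedness = c("two", "one")) {
  sidedness <- match.arg(sidedness)
  n <- length(drp)
  if (length(gebv_i) != n || length(gebv_j) != n)
    stop("input error: inputs must have equal length", call. = FALSE)
  if (n < 5L) stop("input error: need at least 5 observations", call. = FALSE)
  if (stats::sd(drp) == 0 || stats::sd(gebv_i) == 0 || stats::sd(gebv_j) == 0)
    stop("undefined-correlation error: constant input vector", call. = FALSE)
  r1 <- stats::cor(drp, gebv_i)
  r2 <- stats::cor(drp, gebv_j)
  r12 <- stats::cor(gebv_i, gebv_j)
  detD <- 1 - r1^2 - r2^2 - r12^2 + 2 * r1 * r2 * r12
  if (r1 == r2) {
    tstat <- 0
    p <- if (sidedness == "two") 1 else 0.5
  } else {
    rbar <- (r1 + r2) / 2
    denom <- 2 * ((n - 1) / (n - 3)) * detD + rbar^2 * (1 - r12)^3
    tstat <- (r1 - r2) * sqrt((n - 1) * (1 + r12) / denom)
    p <- if (sidedness == "two") {
      2 * stats::pt(-abs(tstat), df = n - 3)
    } else {
      # H0: cor_i >= cor_j; small p when r1 is clearly below r2
      stats::pt(tstat, df = n - 3)
    }
  }
  structure(list(t_statistic = tstat, p_value = p,
                 r_1y = r1, r_2y = r2, r_12 = r12,
                 determinant_D = detD, n = n, df = n - 3,
                 sidedness = sidedness),
            class = "hotelling_result")
}

#' @export
print.hotelling_result <- function(x, ...) {
  cat("Hotelling-Williams test (", x$sidedness, "-sided): t = ",
      signif(x$t_statistic, 4), ", df = ", x$df, ", p = ",
      signif(x$p_value, 4), "\n", sep = "")
  cat("  r(DRP, GEBV_i) = ", signif(x$r_1y, 4), ", r(DRP, GEBV_j) = ",
      signif(x$r_2y, 4), ", r(GEBV_i, GEBV_j) = ", signif(x$r_12, 4),
      "\n", sep = "")
  invisible(x)
}

#' Top-k selection overlap
#'
#' Percentage of the top-k animals (by descending GEBV, ties broken by
#' animal id) selected by both rankings.
#'
#' @param gebv_a,gebv_b Data frames `animal`, `gebv` over the same animals.
#' @param k Number of animals selected.
#' @return Overlap percentage in `[0, 100]`.
#' @export
topk_overlap <- function(gebv_a, gebv_b, k) {
  if (!setequal(gebv_a$animal, gebv_b$animal))
    stop("input error: the two GEBV tables must cover the same animals",
         call. = FALSE)
  n <- nrow(gebv_a)
  if (k > n) stop("input error: k exceeds the number of animals",
                  call. = FALSE)
  top <- function(tab)
    tab$animal[order(-tab$gebv, tab$animal)][seq_len(k)]
  100 * length(intersect(top(gebv_a), top(gebv_b))) / k
}

#' Run the scenario grid
#'
#' Enumerates and fits every combination of encoding scenario and model:
#' one individual-SNP scenario, one blocks-plus-non-blocked-SNPs scenario
#' per D' threshold, and one blocks-only scenario per threshold — with six
#' thresholds that is 13 scenarios per trait per model. Each fit is
#' evaluated on the validation animals (split from the training animals by
#' a generation cut-off, the analogue of a birth-date cut-off) and compared
#' with the individual-SNP baseline of the same model by the
#' Hotelling-Williams test.
#'
#' @param panel Quality-controlled [hap_panel()] over all animals.
#' @param map Marker map of the panel.
#' @param pedigree Pedigree data frame covering all panel animals.
#' @param drp DRP table (`animal`, `trait`, `drp`, `reliability`).
#' @param cutoff_generation Animals with `generation <= cutoff_generation`
#'   and a DRP record form the training set; later-generation animals with
#'   records form the validation set.
#' @param thresholds D' thresholds (default [dprime_threshold_grid()]).
#' @param models Character subset of `c("blup", "mixture")`.
#' @param mcmc An [mcmc_config()].
#' @param tbv Optional data frame `animal`, `tbv` of simulated true
#'   breeding values; adds a `cor_tbv` column of validation-set
#'   cor(GEBV, TBV).
#' @return A data frame with one row per (trait, scenario, model):
#'   encoding, threshold, block accounting, reliability, bias slope, raw
#'   correlation, Hotelling p-value against the SNP baseline, and optional
#'   `cor_tbv`. The GEBV tables are attached as attribute `"gebv"`.
#' @export
run_scenarios <- function(panel, map, pedigree, drp, cutoff_generation,
                          thresholds = dprime_threshold_grid(),
                          models = c("blup", "mixture"),
                          mcmc = mcmc_config(), tbv = NULL) {
  if (length(thresholds) == 0L)
    stop("input error: need at least one threshold", call. = FALSE)
  models <- match.arg(models, several.ok = TRUE)
  drp <- validate_drp(drp)
  A <- additive_relationship(pedigree)
  gen <- stats::setNames(pedigree$generation, pedigree$animal)
  rows <- list()
  gebv_store <- list()
  for (trait in unique(drp$trait)) {
    dtr <- drp[drp$trait == trait & drp$animal %in% panel$ids, , drop = FALSE]
    train <- dtr[gen[dtr$animal] <= cutoff_generation, , drop = FALSE]
    test <- dtr[gen[dtr$animal] > cutoff_generation, , drop = FALSE]
    if (nrow(train) < 3L || nrow(test) < 5L)
      stop("input error: generation cut-off leaves too few training or ",
           "validation animals for trait ", trait, call. = FALSE)
    scenarios <- data.frame(encoding = "snp", threshold = NA_real_,
                            stringsAsFactors = FALSE)
    for (d in thresholds)
      scenarios <- rbind(scenarios,
                         data.frame(encoding = c("blocks_plus_nonblocked",
                                                 "blocks_only"),
                                    threshold = d, stringsAsFactors = FALSE))
    baseline <- list()
    for (s in seq_len(nrow(scenarios))) {
      enc <- scenarios$encoding[s]
      d <- scenarios$threshold[s]
      if (enc == "snp") {
        design <- build_design(panel, mode = "snp", map = map)
        summ <- data.frame(n_blocks = NA_integer_, n_variables = NA_integer_,
                           n_nonblocked = NA_integer_)
      } else {
        part <- build_blocks(panel, map, d)
        cat_ <- enumerate_block_variants(panel, part)
        design <- build_design(panel, part, cat_, mode = enc)
        ps <- partition_summary(part, cat_)
        summ <- ps[, c("n_blocks", "n_variables", "n_nonblocked")]
      }
      if (ncol(design) == 0L) next  # blocks_only with no blocks: nothing to fit
      input <- model_input(design_rows(design, train$animal),
                           train$drp, train$reliability, A)
      for (model in models) {
        fit <- if (model == "blup") fit_blup(input, mcmc) else
          fit_mixture(input, mcmc = mcmc)
        gebv <- predict_gebv(fit, design_rows(design, test$animal))
        ev <- prediction_reliability(test$drp, gebv$gebv, test$reliability)
        key <- paste(trait, enc, d, model, sep = "|")
        gebv_store[[key]] <- gebv
        if (enc == "snp") baseline[[model]] <- gebv
        p_vs_snp <- if (enc == "snp") NA_real_ else
          hotelling_test(test$drp, gebv$gebv,
                         baseline[[model]]$gebv)$p_value
        row <- data.frame(trait = trait, encoding = enc, threshold = d,
                          model = model,
                          n_columns = ncol(design), summ,
                          reliability = ev$reliability,
                          bias_slope_b = ev$bias_slope_b,
                          raw_correlation = ev$raw_correlation,
                          p_vs_snp = p_vs_snp,
                          n_train = nrow(train), n_test = nrow(test),
                          stringsAsFactors = FALSE)
        if (!is.null(tbv)) {
          tt <- tbv$tbv[match(test$animal, tbv$animal)]
          row$cor_tbv <- stats::cor(gebv$gebv, tt)
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "gebv") <- gebv_store
  out
}
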