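# PoPS-style polygenic prioritization: marginal feature screening against
# gene-level z-scores, leave-one-chromosome-out (LOCO) ridge prediction,
# sqrt(N) meta-analysis of per-ancestry scores, and genome-wide percentiles.

#' Marginal feature selection against gene z-scores
#'
#' Each feature column is regressed marginally (with intercept) on the gene
#' z-score vector; features whose two-sided marginal p-value is below
#' `alpha` are retained. Constant features are skipped with a warning.
#'
#' @param gene_z Named numeric vector of gene z-scores (names = gene ids,
#'   aligned to `features` rows).
#' @param features Gene x feature numeric matrix.
#' @param alpha Marginal significance threshold.
#' @return Integer vector of selected feature column indices.
#' @export
select_features <- function(gene_z, features, alpha = 0.05) {
  stopifnot(length(gene_z) == nrow(features))
  n <- length(gene_z)
  sds <- apply(features, 2, sd)
  if (any(sds == 0)) {
    warn(sprintf("%d constant feature(s) skipped", sum(sds == 0)))
  }
  ok <- sds > 0
  r <- suppressWarnings(drop(cor(features[, ok, drop = FALSE], gene_z)))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  which(ok)[p < alpha]
}

# Ridge regression with the penalty chosen by generalized cross-validation
# (GCV), via SVD of the standardized design. Returns coefficients on the
# original feature scale plus an intercept, so prediction on held-out rows
# uses only training-fold statistics.
ridge_gcv <- function(X, y, lambda_grid) {
  n <- nrow(X)
  mx <- colMeans(X)
  sx <- apply(X, 2, sd)
  Xs <- sweep(sweep(X, 2, mx), 2, sx, "/")
  my <- mean(y)
  yc <- y - my
  sv <- svd(Xs)
  uty <- drop(crossprod(sv$u, yc))
  d2 <- sv$d^2
  gcv <- vapply(lambda_grid, function(l) {
    shrink <- d2 / (d2 + l)
    rss <- sum((uty * (1 - shrink))^2) + sum(yc^2) - sum(uty^2)
    df <- 1 + sum(shrink)
    n * rss / (n - df)^2
  }, 1)
  l <- lambda_grid[which.min(gcv)]
  beta_s <- drop(sv$v %*% (sv$d / (d2 + l) * uty))
  beta <- beta_s / sx
  list(intercept = my - sum(beta * mx), beta = beta, lambda = l)
}

#' Leave-one-chromosome-out ridge PoPS scores
#'
#' For each chromosome `c`, fits a ridge regression of the gene z-scores on
#' the selected features using only genes *not* on `c` (features centered
#' and scaled with training-fold statistics only), with the penalty chosen
#' by generalized cross-validation on the training fold, and scores the
#' chromosome-`c` genes with that fit. Scores on a chromosome therefore
#' depend only on the z-scores of genes on other chromosomes. With zero
#' selected features every score equals the training fold's mean z.
#'
#' @param gene_z Tibble with columns `gene`, `chrom`, `z`.
#' @param features Gene x feature matrix (row names = gene ids).
#' @param selected Integer feature indices from [select_features()].
#' @param lambda_grid Ridge penalty grid searched by GCV.
#' @param ancestry Optional ancestry label carried in the fit.
#' @return An object of class `pops_fit`: list with `scores` (tibble:
#'   `gene`, `chrom`, `score`), `selected`, `lambda_by_chrom`,
#'   `fit_by_chrom` (per-chromosome intercept/coefficients), `ancestry`.
#' @export
loco_ridge <- function(gene_z, features, selected,
                       lambda_grid = c(0.01, 10^seq(-1, 5, length.out = 31)),
                       ancestry = NA_character_) {
  stopifnot(all(c("gene", "chrom", "z") %in% names(gene_z)))
  chroms <- sort(unique(gene_z$chrom))
  if (length(chroms) < 2) abort("leave-one-chromosome-out needs at least 2 chromosomes with scored genes")
  X <- features[gene_z$gene, selected, drop = FALSE]
  y <- gene_z$z

  out <- vector("list", length(chroms))
  lambdas <- setNames(numeric(length(chroms)), chroms)
  fits <- setNames(vector("list", length(chroms)), chroms)
  for (i in seq_along(chroms)) {
    c_i <- chroms[i]
    test <- gene_z$chrom == c_i
    Xtr <- X[!test, , drop = FALSE]
    ytr <- y[!test]
    if (length(selected) == 0) {
      score <- rep(mean(ytr), sum(test))
      lambdas[i] <- NA_real_
      fits[[i]] <- list(intercept = mean(ytr), beta = numeric(0))
    } else {
      # zero-variance-in-fold features carry no information and break scaling
      keep <- apply(Xtr, 2, sd) > 0
      if (!any(keep)) {
        score <- rep(mean(ytr), sum(test))
        lambdas[i] <- NA_real_
        fits[[i]] <- list(intercept = mean(ytr), beta = numeric(0))
      } else {
        fit <- ridge_gcv(Xtr[, keep, drop = FALSE], ytr, lambda_grid)
        lambdas[i] <- fit$lambda
        fits[[i]] <- fit
        score <- drop(fit$intercept +
                        X[test, keep, drop = FALSE] %*% fit$beta)
      }
    }
    out[[i]] <- tibble::tibble(gene = gene_z$gene[test], chrom = c_i,
                               score = score)
  }
  structure(
    list(scores = dplyr::bind_rows(out) |> dplyr::arrange(match(.data$gene, gene_z$gene)),
         selected = selected, lambda_by_chrom = lambdas,
         fit_by_chrom = fits, ancestry = ancestry),
    class = "pops_fit"
  )
}

#' @export
print.pops_fit <- function(x, ...) {
  cat(sprintf("<pops_fit>%s %d genes, %d selected features\n",
              if (is.na(x$ancestry)) "" else paste0(" ", x$ancestry),
              nrow(x$scores), length(x$selected)))
  invisible(x)
}

#' @rdname loco_ridge
#' @param x,object A `pops_fit`.
#' @param ... Unused.
#' @method tidy pops_fit
#' @export
tidy.pops_fit <- function(x, ...) x$scores

#' @rdname loco_ridge
#' @method glance pops_fit
#' @export
glance.pops_fit <- function(x, ...) {
  tibble::tibble(
    ancestry = x$ancestry,
    n_genes = nrow(x$scores),
    n_selected_features = length(x$selected),
    median_lambda = stats::median(x$lambda_by_chrom, na.rm = TRUE)
  )
}

#' Meta-analyze PoPS scores across ancestries
#'
#' Per gene, the meta score is the weighted mean of the ancestry scores with
#' weights `sqrt(n_eff)` (scores are predictions, not test statistics, so a
#' convex combination — not a z-style combination — preserves their scale).
#' A z-style combination (`sum(w s) / sqrt(sum(w^2))`) is available via
#' `method = "zscale"`.
#'
#' @param scores_by_ancestry List of per-ancestry score tibbles (`gene`,
#'   `score`), aligned gene sets.
#' @param n_eff Numeric vector of effective sample sizes, one per list
#'   element.
#' @param method `"weighted_mean"` (default) or `"zscale"`.
#' @return A tibble: `gene`, `meta_score`.
#' @export
meta_pops <- function(scores_by_ancestry, n_eff,
                      method = c("weighted_mean", "zscale")) {
  method <- match.arg(method)
  stopifnot(length(scores_by_ancestry) == length(n_eff))
  w <- sqrt(n_eff)
  tabs <- purrr::map2(scores_by_ancestry, w, function(s, wi) {
    tibble::tibble(gene = s$gene, score = s$score, w = wi)
  })
  denom_fun <- if (method == "weighted_mean") {
    function(w) sum(w)
  } else {
    function(w) sqrt(sum(w^2))
  }
  dplyr::bind_rows(tabs) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(meta_score = sum(.data$w * .data$score) / denom_fun(.data$w),
                     .groups = "drop")
}

#' Genome-wide PoPS percentiles
#'
#' Rank-based percentile of each gene's meta score, with average ranks for
#' ties, scaled so the genome-wide minimum maps to 0 and the maximum to 1.
#'
#' @param scores Numeric vector of meta PoPS scores (length >= 2).
#' @return Numeric vector of percentiles in `[0, 1]`.
#' @export
pops_percentile <- function(scores) {
  n <- length(scores)
  if (n < 2) abort("percentiles need at least 2 genes")
  (rank(scores, ties.method = "average") - 1) / (n - 1)
}
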