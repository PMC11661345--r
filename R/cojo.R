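# Stepwise conditional-and-joint (COJO-style) analysis from summary
# statistics and a reference LD panel, restricted to one region.
#
# All formulas work on z-scores with the reference correlation matrix R.
# For a conditioning set C and a variant i not in C:
#   z_{i|C}  = (z_i - R_{iC} R_C^{-1} z_C) / sqrt(1 - R_{iC} R_C^{-1} R_{Ci})
# and the joint estimates for a selected set S are
#   z_joint  = (R_S^{-1} z)_i / sqrt((R_S^{-1})_{ii})
#   beta_joint = se_i * (R_S^{-1} z)_i,  se_joint = se_i * sqrt((R_S^{-1})_{ii})
# which follow from the standardized-genotype regression model with
# X'X approximated by the reference LD (per-variant sample sizes enter only
# through the marginal standard errors).

region_stats <- function(region, stats) {
  dplyr::filter(stats, .data$chrom == region$chrom,
                .data$pos >= region$start, .data$pos <= region$end) |>
    dplyr::arrange(.data$pos)
}

# conditional z for candidate indices `cand` given columns `cond` of R
conditional_z <- function(z, R, cand, cond) {
  if (length(cond) == 0) return(z[cand])
  Rc <- R[cond, cond, drop = FALSE]
  sol <- tryCatch(solve(Rc, cbind(z[cond], R[cond, cand, drop = FALSE])),
                  error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  adj <- drop(R[cand, cond, drop = FALSE] %*% sol[, 1])
  k <- colSums(R[cond, cand, drop = FALSE] * sol[, -1, drop = FALSE])
  denom <- sqrt(pmax(1 - k, 1e-12))
  (z[cand] - adj) / denom
}

#' Stepwise selection of independent association signals in a region
#'
#' Forward stepwise selection on summary statistics: start from the region's
#' most significant variant, then repeatedly add the variant with the
#' smallest conditional p-value, provided it stays below `p_thresh` and its
#' squared correlation with every selected variant is below
#' `collinearity_r2`. After selection, joint effects for the selected set
#' are computed from the inverse of the selected-set LD matrix, and hits
#' whose joint p-value exceeds `p_thresh` are dropped (worst first,
#' refitting after each drop). If the selected-set LD matrix is singular the
#' later-entering variant is dropped with a warning.
#'
#' @param region One row of the [clump()] output.
#' @param stats Variant-statistics tibble covering the region.
#' @param panel `ld_panel` providing reference LD.
#' @param p_thresh Significance threshold for conditional and joint p-values.
#' @param collinearity_r2 Maximum allowed r-squared between selected variants.
#' @return A tibble of selected hits: `snp`, `chrom`, `pos`, marginal
#'   `beta`/`se`/`p`, `joint_beta`, `joint_se`, `joint_p`, `entry_order`.
#' @export
cojo_select <- function(region, stats, panel, p_thresh = 5e-8,
                        collinearity_r2 = 0.9) {
  rs <- region_stats(region, stats)
  if (nrow(rs) == 0 || min(rs$p) >= p_thresh) {
    abort("region contains no significant variant")
  }
  R <- panel_ld(panel, rs$snp)
  keep <- !(rs$snp %in% attr(R, "dropped"))
  rs <- rs[keep, ]
  z <- rs$beta / rs$se

  selected <- integer()
  repeat {
    cand <- setdiff(seq_len(nrow(rs)), selected)
    if (length(selected) > 0) {
      max_r2 <- apply(R[cand, selected, drop = FALSE]^2, 1, max)
      cand <- cand[max_r2 < collinearity_r2]
    }
    if (length(cand) == 0) break
    zc <- conditional_z(z, R, cand, selected)
    if (is.null(zc)) break
    pc <- p_from_z(zc)
    best <- which.min(pc)
    if (pc[best] >= p_thresh) break
    selected <- c(selected, cand[best])
  }
  if (length(selected) == 0) selected <- which.min(rs$p)

  # joint fit, with backward elimination of hits above the threshold
  joint <- NULL
  repeat {
    S <- selected
    Rs <- R[S, S, drop = FALSE]
    Rinv <- tryCatch(solve(Rs), error = function(e) NULL)
    if (is.null(Rinv)) {
      warn("singular selected-set LD matrix; dropping the later-entering variant")
      selected <- selected[-length(selected)]
      next
    }
    bz <- drop(Rinv %*% z[S])
    jz <- bz / sqrt(diag(Rinv))
    jp <- p_from_z(jz)
    if (all(jp <= p_thresh) || length(S) == 1) {
      joint <- list(S = S, bz = bz, jse = sqrt(diag(Rinv)), jp = jp)
      break
    }
    selected <- selected[-which.max(jp)]
  }

  S <- joint$S
  tibble::tibble(
    snp = rs$snp[S], chrom = rs$chrom[S], pos = rs$pos[S],
    beta = rs$beta[S], se = rs$se[S], p = rs$p[S],
    joint_beta = unname(rs$se[S] * joint$bz),
    joint_se = unname(rs$se[S] * joint$jse),
    joint_p = unname(joint$jp),
    entry_order = seq_along(S)
  ) |> dplyr::arrange(.data$pos)
}

#' Isolate each selected hit by leave-one-hit-out conditioning
#'
#' For every selected hit, recomputes the region's per-variant association
#' statistics conditional on all of the other selected hits, producing one
#' isolated signal per hit. With a single hit the conditional statistics
#' equal the marginal statistics. Variants in the conditioning set itself
#' get a conditional z of 0 (p = 1).
#'
#' @param region One row of the [clump()] output.
#' @param hits Output of [cojo_select()] for that region.
#' @param stats Variant-statistics tibble covering the region.
#' @param panel `ld_panel` providing reference LD.
#' @return A list of `independent_signal` objects, each a list with
#'   `region`, `lead` (hit variant id), and `cond_stats` (tibble: `snp`,
#'   `chrom`, `pos`, `eaf`, `beta`, `se`, `z`, `p` — conditional scale).
#' @export
leave_one_out_condition <- function(region, hits, stats, panel) {
  rs <- region_stats(region, stats)
  R <- panel_ld(panel, rs$snp)
  rs <- rs[!(rs$snp %in% attr(R, "dropped")), ]
  z <- rs$beta / rs$se

  lapply(seq_len(nrow(hits)), function(h) {
    lead <- hits$snp[h]
    cond_snps <- setdiff(hits$snp, lead)
    cond <- match(cond_snps, rs$snp)
    cond <- cond[!is.na(cond)]
    all_i <- seq_len(nrow(rs))
    if (length(cond) == 0) {
      zc <- z
    } else {
      zc <- numeric(nrow(rs))
      free <- setdiff(all_i, cond)
      zf <- conditional_z(z, R, free, cond)
      if (is.null(zf)) {
        warn("singular conditioning-set LD matrix; dropping the later-entering hit from the conditioning set")
        cond <- cond[-length(cond)]
        zf <- conditional_z(z, R, setdiff(all_i, cond), cond)
        free <- setdiff(all_i, cond)
      }
      zc[free] <- zf
      zc[cond] <- 0
    }
    # conditional variance shrink: se stays the marginal se for variants far
    # from the conditioning set; the conditional z already carries the
    # adjustment, and beta = z * se keeps beta/se consistent with p
    cond_stats <- tibble::tibble(
      snp = rs$snp, chrom = rs$chrom, pos = rs$pos, eaf = rs$eaf,
      beta = zc * rs$se, se = rs$se, z = zc, p = p_from_z(zc)
    )
    structure(list(region = region, lead = lead, hits = hits$snp,
                   cond_stats = cond_stats),
              class = "independent_signal")
  })
}

#' @export
print.independent_signal <- function(x, ...) {
  cat(sprintf("<independent_signal> lead %s (chr%s:%d-%d, %d variants, %d hit(s) in region)\n",
              x$lead, x$region$chrom, x$region$start, x$region$end,
              nrow(x$cond_stats), length(x$hits)))
  invisible(x)
}
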