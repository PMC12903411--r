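#' Mixed-effects association test of cluster membership (MASC-style)
#'
#' Tests whether membership of a nucleus-level cluster (or any per-nucleus
#' indicator) differs between two age groups with a mixed-effects logistic
#' regression: membership ~ age group + sex (fixed) + random intercepts for
#' the configured grouping factors (donor and batch by default). The
#' per-nucleus Bernoulli data are aggregated to binomial counts per
#' (donor, batch, sex, group) cell, which leaves the likelihood unchanged
#' and keeps the fit fast. Significance comes from a likelihood-ratio test
#' dropping the age-group term; the odds ratio is `exp()` of the age
#' coefficient with a Wald 95% CI.
#'
#' If the cluster is entirely absent (or universal) in one group the model
#' is separated: the result carries an infinite/zero OR flag instead of
#' crashing.
#'
#' @param df Per-nucleus tibble with columns `donor_id`, `batch`, `sex`,
#'   `age_group`, and the logical/0-1 column named by `indicator`; or a
#'   `nuclei_dataset` (its `nuc_meta` is used, with `indicator` either a
#'   column name or a vector).
#' @param indicator Column name (or logical vector) marking cluster
#'   membership.
#' @param comparison `c(group1, group2)`; OR > 1 means enrichment in
#'   `group1`.
#' @param random Random-intercept factors (subset of columns).
#' @param fixed Additional fixed-effect columns (default `"sex"`).
#' @return One-row tibble: `comparison`, `or`, `ci_lo`, `ci_hi`,
#'   `p` (LRT), `separated`.
#' @export
masc_test <- function(df, indicator, comparison = c("old", "young"),
                      random = c("donor_id", "batch"), fixed = "sex") {
  if (inherits(df, "nuclei_dataset")) df <- df$nuc_meta
  if (is.character(indicator) && length(indicator) == 1) {
    member <- as.logical(df[[indicator]])
  } else {
    member <- as.logical(indicator)
  }
  stopifnot(length(member) == nrow(df))
  d <- df |>
    mutate(.member = member) |>
    filter(.data$age_group %in% comparison) |>
    mutate(age_group = factor(.data$age_group, levels = rev(comparison)))
  if (nrow(d) == 0) abort("no nuclei in the requested comparison groups")

  agg <- d |>
    group_by(across(all_of(unique(c("age_group", fixed, random))))) |>
    summarise(k = sum(.data$.member), n = n(), .groups = "drop")

  # separation: cluster absent or universal in a group
  by_grp <- agg |> group_by(.data$age_group) |>
    summarise(k = sum(.data$k), n = sum(.data$n), .groups = "drop")
  if (any(by_grp$k == 0) || any(by_grp$k == by_grp$n)) {
    p1 <- by_grp$k[by_grp$age_group == comparison[1]] /
      by_grp$n[by_grp$age_group == comparison[1]]
    p2 <- by_grp$k[by_grp$age_group == comparison[2]] /
      by_grp$n[by_grp$age_group == comparison[2]]
    or <- if (p1 >= p2) Inf else 0
    if (p1 == p2) or <- NA_real_  # both empty (or both full)
    return(tibble(comparison = paste(comparison, collapse = "_vs_"),
                  or = or, ci_lo = NA_real_, ci_hi = NA_real_,
                  p = if (is.na(or)) 1 else NA_real_, separated = TRUE))
  }

  fixed <- fixed[vapply(fixed, function(f) length(unique(agg[[f]])) > 1,
                        logical(1))]
  rhs <- paste(c("age_group", fixed,
                 sprintf("(1 | %s)", random)), collapse = " + ")
  rhs0 <- paste(c("1", fixed, sprintf("(1 | %s)", random)), collapse = " + ")
  ctl <- lme4::glmerControl(check.conv.singular = "ignore",
                            check.response.not.const = "ignore",
                            calc.derivs = FALSE)
  mixed <- tryCatch({
    full <- suppressMessages(suppressWarnings(
      lme4::glmer(as.formula(paste("cbind(k, n - k) ~", rhs)),
                  data = agg, family = stats::binomial(), control = ctl)))
    null <- suppressMessages(suppressWarnings(
      lme4::glmer(as.formula(paste("cbind(k, n - k) ~", rhs0)),
                  data = agg, family = stats::binomial(), control = ctl)))
    lrt <- anova(null, full)
    co <- summary(full)$coefficients
    list(co = co, p = lrt$`Pr(>Chisq)`[2])
  }, error = function(e) NULL)
  if (is.null(mixed)) {
    # degenerate data (e.g. exactly constant proportions) leaves the
    # random-effect variance inestimable; fall back to the fixed-effect fit
    inform("masc_test: mixed fit failed; falling back to fixed-effects glm")
    fr <- paste(c("age_group", fixed), collapse = " + ")
    fr0 <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
    full <- stats::glm(as.formula(paste("cbind(k, n - k) ~", fr)),
                       data = agg, family = stats::binomial())
    null <- stats::glm(as.formula(paste("cbind(k, n - k) ~", fr0)),
                       data = agg, family = stats::binomial())
    lrt_p <- stats::pchisq(null$deviance - full$deviance,
                           df = null$df.residual - full$df.residual,
                           lower.tail = FALSE)
    mixed <- list(co = summary(full)$coefficients, p = lrt_p)
  }
  row <- grep("^age_group", rownames(mixed$co))[1]
  est <- mixed$co[row, 1]; se <- mixed$co[row, 2]
  tibble(comparison = paste(comparison, collapse = "_vs_"),
         or = exp(est),
         ci_lo = exp(est - 1.96 * se),
         ci_hi = exp(est + 1.96 * se),
         p = mixed$p,
         separated = FALSE)
}

#' Pseudobulk differential expression against age
#'
#' A deliberately simple pseudobulk linear model (no precision weights):
#' per-donor summed counts within one broad cell class, log2-CPM
#' transformed, regressed gene-by-gene on donor age in years with sex and
#' batch as fixed covariates. Genes enter only if expressed (count > 0) in
#' at least `min_nuclei` nuclei of the class AND detected in at least
#' `det_frac` of young donors or of old donors (middle donors are not used
#' for the detection rule). P-values are BH-corrected; the effect is
#' reported as log2FC over the young-to-old age span (slope per year times
#' the difference of the group mean ages).
#'
#' @param nuclei A QC'd `nuclei_dataset`.
#' @param cell_class Broad class to analyse.
#' @param min_nuclei Detection rule: minimum expressing nuclei (default 30).
#' @param det_frac Donor-level detection fraction required in young or old
#'   donors (default 0.75).
#' @return Tibble `gene`, `slope_per_year`, `log2fc`, `p`, `q`.
#' @export
pseudobulk_de <- function(nuclei, cell_class, min_nuclei = 30,
                          det_frac = 0.75) {
  stopifnot(inherits(nuclei, "nuclei_dataset"))
  sel <- nuclei$nuc_meta$cell_type == cell_class
  if (!any(sel)) abort(sprintf("no nuclei of class '%s'", cell_class))
  cnt <- nuclei$counts[sel, , drop = FALSE]
  meta <- nuclei$nuc_meta[sel, ]
  if (length(unique(meta$donor_id)) < 3) abort("need at least 3 donors")

  # gene filters
  n_expr <- Matrix::colSums(cnt > 0)
  pb <- rowsum(as.matrix(cnt), meta$donor_id)
  donors <- meta |> distinct(.data$donor_id, .data$age, .data$age_group,
                             .data$sex, .data$batch) |>
    arrange(match(.data$donor_id, rownames(pb)))
  det <- pb > 0
  frac_in <- function(grp) {
    idx <- donors$age_group == grp
    if (!any(idx)) return(rep(0, ncol(pb)))
    colMeans(det[idx, , drop = FALSE])
  }
  keep <- n_expr >= min_nuclei &
    (frac_in("young") >= det_frac | frac_in("old") >= det_frac)
  if (!any(keep)) abort("no genes pass the detection filters")
  pb <- pb[, keep, drop = FALSE]

  tot <- rowSums(pb)
  logcpm <- log2((pb + 0.5) / (tot + 1) * 1e6)

  X <- stats::model.matrix(~ age + sex + batch, data = donors)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(sprintf("design is rank deficient; confounded column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  fit <- stats::lm.fit(X, logcpm)
  df_res <- nrow(X) - ncol(X)
  rss <- colSums(fit$residuals^2)
  XtXinv_aa <- chol2inv(qr.R(qrX))[2, 2]
  se <- sqrt(rss / df_res * XtXinv_aa)
  slope <- fit$coefficients["age", ]
  tval <- slope / se
  pval <- 2 * pt(-abs(tval), df_res)

  span <- mean(donors$age[donors$age_group == "old"]) -
    mean(donors$age[donors$age_group == "young"])
  if (!is.finite(span)) span <- diff(range(donors$age))
  tibble(gene = colnames(pb),
         slope_per_year = unname(slope),
         log2fc = unname(slope) * span,
         p = unname(pval),
         q = p.adjust(unname(pval), method = "BH"))
}

#' Rank genes as markers by ROC AUC
#'
#' For each gene, the area under the ROC curve of its expression as a
#' classifier of group A vs group B, computed rank-based (Mann-Whitney;
#' ties mid-ranked). AUC 1 means perfectly higher in A, 0 perfectly higher
#' in B. Genes are ranked by `|AUC - 0.5|`.
#'
#' @param nuclei A `nuclei_dataset` or a nucleus x gene matrix.
#' @param group_a_mask,group_b_mask Logical masks over nuclei.
#' @return Tibble `gene`, `auc`, `delta_mean`, ordered by discriminative
#'   power.
#' @export
auc_rank_markers <- function(nuclei, group_a_mask, group_b_mask) {
  mat <- if (inherits(nuclei, "nuclei_dataset")) nuclei$counts else nuclei
  if (!any(group_a_mask) || !any(group_b_mask)) {
    abort("both groups must be non-empty")
  }
  na <- sum(group_a_mask); nb <- sum(group_b_mask)
  sub <- as.matrix(mat[c(which(group_a_mask), which(group_b_mask)), ,
                       drop = FALSE])
  is_a <- c(rep(TRUE, na), rep(FALSE, nb))
  auc <- apply(sub, 2, function(v) {
    r <- rank(v)  # average ranks for ties
    (sum(r[is_a]) - na * (na + 1) / 2) / (na * nb)
  })
  dm <- colMeans(sub[is_a, , drop = FALSE]) -
    colMeans(sub[!is_a, , drop = FALSE])
  tibble(gene = colnames(sub) %||% sprintf("g%d", seq_len(ncol(sub))),
         auc = unname(auc), delta_mean = unname(dm)) |>
    arrange(dplyr::desc(abs(.data$auc - 0.5)))
}
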