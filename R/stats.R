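#' Unpaired two-sample t test
#'
#' Welch's t test by default (no equal-variance assumption); the pooled
#' Student variant by `pooled = TRUE`. Two identical constant groups are
#' reported as t = 0, p = 1 with `degenerate = TRUE` instead of an error.
#'
#' @param group_a,group_b numeric vectors, n >= 2 each.
#' @param pooled use the pooled-variance Student test (default FALSE).
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`, `degenerate`.
#' @export
welch_t_test <- function(group_a, group_b, pooled = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs n >= 2", call. = FALSE)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(t = 0, df = NA_real_, p = 1,
                  mean_a = mean(group_a), mean_b = mean(group_b),
                  degenerate = TRUE))
    return(list(t = Inf * sign(mean(group_a) - mean(group_b)),
                df = NA_real_, p = 0,
                mean_a = mean(group_a), mean_b = mean(group_b),
                degenerate = TRUE))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = pooled)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(group_a), mean_b = mean(group_b),
       degenerate = FALSE)
}

#' One-way ANOVA with Tukey-Kramer pairwise comparisons
#'
#' Classical one-way ANOVA followed by Tukey's honest-significant-
#' difference test; the Tukey-Kramer form handles unequal group sizes
#' (e.g. a control cohort of 6 against coated cohorts of 8).
#'
#' @param values numeric measurements.
#' @param group group labels, same length; >= 2 groups, each n >= 2.
#' @return list with `F`, `df` (c(between, within)), `p`, and `pairwise`
#'   (data.frame: comparison, diff, adjusted p).
#' @export
one_way_anova_tukey <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L)
    stop("ANOVA needs at least 2 groups", call. = FALSE)
  if (any(table(group) < 2L))
    stop("every group needs n >= 2", call. = FALSE)
  if (length(values) != length(group))
    stop_field("group", "must match values in length")
  fit <- stats::aov(values ~ group, data = data.frame(values = values,
                                                      group = group))
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$group
  list(F = an[["F value"]][1L],
       df = c(an[["Df"]][1L], an[["Df"]][2L]),
       p = an[["Pr(>F)"]][1L],
       pairwise = data.frame(comparison = rownames(tk),
                             diff = tk[, "diff"],
                             p_adj = tk[, "p adj"],
                             row.names = NULL))
}

#' Sidak multiple-comparison adjustment
#'
#' \deqn{p_{adj} = 1 - (1 - p)^m}
#' for `m` planned comparisons; the identity when `m = 1`, monotone in
#' both `p` and `m`, never smaller than `p`.
#'
#' @param p raw p value(s) in `[0, 1]`.
#' @param m number of planned comparisons (>= 1).
#' @return adjusted p value(s).
#' @examples
#' sidak_adjust(0.01, 4) # 0.0394
#' @export
sidak_adjust <- function(p, m) {
  check_number(m, "m", lower = 1)
  if (!is.numeric(p) || any(p < 0 | p > 1))
    stop_field("p", "must be probabilities in [0, 1]")
  1 - (1 - p)^m
}

#' Two-way ANOVA with Sidak-adjusted simple-effect comparisons
#'
#' Fits `values ~ group * factor2` on a complete two-factor layout and
#' compares the levels of `group` within each level of `factor2` (the
#' planned contrasts of a condition-by-material design). Each contrast's
#' t statistic uses the pooled residual mean square; raw p values are
#' Sidak-adjusted over the full set of planned contrasts.
#'
#' @param values numeric measurements.
#' @param group primary factor, same length.
#' @param factor2 second factor, same length.
#' @return list with `anova` (data.frame: term, df, F, p for both main
#'   effects and the interaction) and `pairwise` (data.frame: factor2
#'   level, comparison, diff, t, p raw, p Sidak-adjusted, stars).
#' @export
two_way_anova_sidak <- function(values, group, factor2) {
  group <- factor(group); factor2 <- factor(factor2)
  if (length(values) != length(group) || length(values) != length(factor2))
    stop_field("group/factor2", "must match values in length")
  if (nlevels(group) < 2L || nlevels(factor2) < 2L)
    stop("both factors need at least 2 levels", call. = FALSE)
  cells <- table(group, factor2)
  if (any(cells < 2L))
    stop("every factor cell needs n >= 2 (no imputation of empty cells)",
         call. = FALSE)
  dat <- data.frame(values = values, group = group, factor2 = factor2)
  fit <- stats::aov(values ~ group * factor2, data = dat)
  an <- summary(fit)[[1L]]
  terms <- trimws(rownames(an))
  anova_tab <- data.frame(term = terms, df = an[["Df"]],
                          F = an[["F value"]], p = an[["Pr(>F)"]])
  mse <- an[["Mean Sq"]][terms == "Residuals"]
  df_res <- an[["Df"]][terms == "Residuals"]

  pairs_g <- utils::combn(levels(group), 2, simplify = FALSE)
  rows <- list()
  for (f2 in levels(factor2)) {
    for (pr in pairs_g) {
      v1 <- dat$values[dat$group == pr[1L] & dat$factor2 == f2]
      v2 <- dat$values[dat$group == pr[2L] & dat$factor2 == f2]
      diff <- mean(v1) - mean(v2)
      se <- sqrt(mse * (1 / length(v1) + 1 / length(v2)))
      tval <- diff / se
      rows[[length(rows) + 1L]] <- data.frame(
        factor2 = f2, comparison = paste(pr[1L], "-", pr[2L]),
        diff = diff, t = tval,
        p = 2 * stats::pt(-abs(tval), df_res))
    }
  }
  pw <- do.call(rbind, rows)
  pw$p_adj <- sidak_adjust(pw$p, nrow(pw))
  pw$stars <- significance_stars(pw$p_adj)
  list(anova = anova_tab, pairwise = pw)
}

#' Significance stars
#'
#' The figure-caption convention: `****` p < 0.0001, `***` p < 0.001,
#' `**` p < 0.01, `*` p < 0.05, `ns` otherwise.
#'
#' @param p p value(s).
#' @return character vector of star codes.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 1e-4) "****" else if (pi < 1e-3) "***"
    else if (pi < 1e-2) "**" else if (pi < 0.05) "*" else "ns"
  }, character(1))
}

#' Normalize qPCR copy numbers and compute fold induction
#'
#' Copy numbers are normalized to the GAPDH housekeeping gene per record;
#' fold induction relates the osteogenic (OB) condition to its matched
#' untreated control (CO) per gene and donor (donor-wise by default;
#' `per_donor = FALSE` relates means over donors instead).
#'
#' @param records data.frame with columns `gene`, `donor`, `condition`
#'   (`"CO"` or `"OB"`), `copies`, `gapdh_copies` (> 0).
#' @param per_donor donor-wise fold induction (default TRUE).
#' @return list with `normalized` (records plus a `normalized` column)
#'   and `fold` (data.frame: gene, donor (if donor-wise), fold =
#'   normalized OB / normalized CO).
#' @export
qpcr_normalize <- function(records, per_donor = TRUE) {
  need <- c("gene", "donor", "condition", "copies", "gapdh_copies")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop_field("records", paste("needs columns", paste(need, collapse = ", ")))
  if (any(records$gapdh_copies <= 0))
    stop("undefined normalization: gapdh_copies must be > 0", call. = FALSE)
  if (!all(records$condition %in% c("CO", "OB")))
    stop_field("condition", 'must be "CO" or "OB"')
  records$normalized <- records$copies / records$gapdh_copies
  ob <- records[records$condition == "OB", ]
  co <- records[records$condition == "CO", ]
  if (per_donor) {
    key <- function(d) paste(d$gene, d$donor, sep = "\r")
    co_map <- tapply(co$normalized, key(co), mean)
    fold <- data.frame(gene = ob$gene, donor = ob$donor,
                       fold = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(ob))) {
      k <- key(ob[i, ])
      if (!k %in% names(co_map))
        stop(sprintf("missing CO control for gene %s, donor %s",
                     ob$gene[i], ob$donor[i]), call. = FALSE)
      if (co_map[[k]] == 0)
        stop(sprintf("zero CO control for gene %s, donor %s",
                     ob$gene[i], ob$donor[i]), call. = FALSE)
      fold$fold[i] <- ob$normalized[i] / co_map[[k]]
    }
  } else {
    co_mean <- tapply(co$normalized, co$gene, mean)
    ob_mean <- tapply(ob$normalized, ob$gene, mean)
    genes <- names(ob_mean)
    if (!all(genes %in% names(co_mean)))
      stop("missing CO control for some gene", call. = FALSE)
    fold <- data.frame(gene = genes,
                       fold = as.numeric(ob_mean / co_mean[genes]),
                       stringsAsFactors = FALSE)
  }
  list(normalized = records, fold = fold)
}

#' Normalize a fluorescence signal to nuclear staining
#'
#' @param signal_intensity staining signal, a.u. (>= 0).
#' @param nuclear_intensity nuclear-staining signal, a.u. (> 0).
#' @return normalized ratio(s).
#' @export
normalize_fluorescence <- function(signal_intensity, nuclear_intensity) {
  if (!is.numeric(signal_intensity) || !is.numeric(nuclear_intensity))
    stop_field("intensities", "must be numeric")
  if (any(nuclear_intensity <= 0))
    stop("undefined normalization: nuclear_intensity must be > 0",
         call. = FALSE)
  signal_intensity / nuclear_intensity
}
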