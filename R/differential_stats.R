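# Differential transcription/translation statistics: the weighted
# beta-binomial t-type test on count proportions, the TE Student test, the
# two-criteria translational-regulation caller, threshold-based differential
# calls, the global fold-change shift analysis, and the qPCR utility.

# One group's variance-minimizing weighted proportion estimate. Each
# replicate's variance is its binomial sampling variance p(1-p)/n_i plus a
# shared between-replicate component estimated by method of moments (clamped
# at 0); weights and estimate are iterated to convergence.
wtt_group_estimate <- function(x, n, tol = 1e-10, max_iter = 50L) {
  k <- length(x)
  p_i <- x / n
  p_hat <- sum(x) / sum(n)
  sb2 <- 0
  for (it in seq_len(max_iter)) {
    pv <- prop_for_variance(p_hat, n)
    v_bin <- pv * (1 - pv) / n
    sb2 <- max(0, sum((p_i - p_hat)^2) / (k - 1) - mean(v_bin))
    w <- 1 / pmax(v_bin + sb2, .Machine$double.xmin)
    p_new <- sum(w * p_i) / sum(w)
    if (abs(p_new - p_hat) < tol) {
      p_hat <- p_new
      break
    }
    p_hat <- p_new
  }
  pv <- prop_for_variance(p_hat, n)
  v_bin <- pv * (1 - pv) / n
  se2 <- 1 / sum(1 / pmax(v_bin + sb2, .Machine$double.xmin))
  # Satterthwaite df: the binomial component is plug-in known; only the
  # between-replicate component carries k - 1 degrees of freedom.
  vbar <- mean(v_bin) + sb2
  df <- if (sb2 <= 0) Inf else (k - 1) * (vbar / sb2)^2
  list(p = p_hat, se2 = se2, df = df, sb2 = sb2)
}

# Guard against a degenerate proportion estimate (0 or 1), whose nominal
# binomial variance would claim infinite precision.
prop_for_variance <- function(p_hat, n) {
  eps <- 0.5 / sum(n)
  min(max(p_hat, eps), 1 - eps)
}

#' Weighted t-type test on count proportions
#'
#' Compares two groups of replicate libraries on the proportion scale
#' (count over total mapped reads). Per group, the proportion is estimated
#' as a variance-minimizing weighted mean of replicate proportions, where
#' each replicate's variance is its binomial sampling variance plus a shared
#' between-replicate variance component estimated by method of moments
#' (clamped at zero); weights and estimate are iterated to convergence
#' (tolerance 1e-10, at most 50 iterations). The statistic is the difference
#' of group estimates over the root of the summed squared standard errors;
#' degrees of freedom follow Welch-Satterthwaite with the binomial component
#' treated as known, and the two-sided p-value comes from the t distribution.
#'
#' @param counts_a,counts_b Integer vectors of per-replicate counts.
#' @param totals_a,totals_b Per-replicate total mapped reads.
#' @return Named numeric `c(statistic, df, p_value)`.
#' @export
weighted_t_test <- function(counts_a, totals_a, counts_b, totals_b) {
  if (length(counts_a) < 2L || length(counts_b) < 2L) {
    stop("need at least 2 replicates per group")
  }
  stopifnot(length(counts_a) == length(totals_a),
            length(counts_b) == length(totals_b))
  if (any(totals_a <= 0) || any(totals_b <= 0)) stop("totals must be > 0")
  if (any(counts_a < 0) || any(counts_b < 0) ||
      any(counts_a > totals_a) || any(counts_b > totals_b)) {
    stop("counts must satisfy 0 <= count <= total")
  }
  if (sum(counts_a) + sum(counts_b) == 0) {
    return(c(statistic = 0, df = length(counts_a) + length(counts_b) - 2,
             p_value = 1))
  }
  ga <- wtt_group_estimate(counts_a, totals_a)
  gb <- wtt_group_estimate(counts_b, totals_b)
  se2 <- ga$se2 + gb$se2
  stat <- (ga$p - gb$p) / sqrt(se2)
  df <- se2^2 / (ga$se2^2 / ga$df + gb$se2^2 / gb$df)
  if (!is.finite(df)) df <- Inf
  p <- if (stat == 0) 1 else 2 * stats::pt(-abs(stat), df)
  c(statistic = stat, df = df, p_value = p)
}

#' Student t test on replicate translation efficiencies
#'
#' Two-sided two-sample Student (pooled-variance) t test on per-replicate TE
#' values, log2-transformed by default for variance stabilization.
#'
#' @param te_reps_a,te_reps_b Numeric vectors of per-replicate TE values
#'   (> 0 when `log2_scale`).
#' @param log2_scale Test on log2 TE (default `TRUE`).
#' @return Two-sided p-value.
#' @export
te_student_test <- function(te_reps_a, te_reps_b, log2_scale = TRUE) {
  if (length(te_reps_a) < 2L || length(te_reps_b) < 2L) {
    stop("need at least 2 replicates per group")
  }
  a <- te_reps_a; b <- te_reps_b
  if (log2_scale) {
    if (any(c(a, b) <= 0)) stop("TE values must be > 0 on the log scale")
    a <- log2(a); b <- log2(b)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  stats::t.test(a, b, var.equal = TRUE)$p.value
}

#' Two-criteria translational-regulation caller
#'
#' A gene is called translationally up-regulated iff (1) its translation
#' efficiency increases at least `te_fold_min`-fold with Student-test
#' p below `alpha`, and (2) its ribosome-profiling expression also increases
#' significantly (weighted t-type test p below `alpha`). The second
#' criterion screens out apparent TE changes driven by transcription.
#'
#' @param te_fc TE fold change, case over control.
#' @param te_p TE Student-test p-value.
#' @param ribo_p Ribosome-profiling differential p-value.
#' @param ribo_fc Optional ribosome-profiling fold change; when supplied, the
#'   change must be in the increasing direction (`> 1`).
#' @param te_fold_min Minimum TE fold change (default 2).
#' @param alpha Significance level (default 0.05).
#' @return Logical (vectorized).
#' @export
call_translational_regulation <- function(te_fc, te_p, ribo_p, ribo_fc = NULL,
                                          te_fold_min = 2, alpha = 0.05) {
  flag <- te_fc >= te_fold_min & te_p < alpha & ribo_p < alpha
  if (!is.null(ribo_fc)) flag <- flag & ribo_fc > 1
  flag
}

#' Threshold-based differential call
#'
#' Up iff fold change exceeds `fold_min` with p below `alpha`; down iff fold
#' change is below `1/fold_min` with p below `alpha`; otherwise none.
#'
#' @param fold_change Positive fold change, case over control.
#' @param p_value Test p-value.
#' @param fold_min Fold-change cutoff (default 3; 1.5 and 2 are the other
#'   conventional settings).
#' @param alpha Significance level (default 0.05).
#' @return Character vector over `{"up", "down", "none"}`.
#' @export
call_differential <- function(fold_change, p_value, fold_min = 3,
                              alpha = 0.05) {
  if (any(fold_change <= 0)) stop("fold_change must be > 0")
  ifelse(fold_change > fold_min & p_value < alpha, "up",
         ifelse(fold_change < 1 / fold_min & p_value < alpha, "down", "none"))
}

#' Global translational shift analysis
#'
#' Computes per-gene fold changes of case over control expression, their
#' arithmetic mean (geometric mean also reported), a binned log2 fold-change
#' histogram, and a two-sample Kolmogorov-Smirnov test of the case-vs-control
#' log2 fold-change distribution against a null distribution built from a
#' control-vs-control replicate split.
#'
#' @param expr_case,expr_ctrl Named per-gene expression vectors (case and
#'   control).
#' @param null_case,null_ctrl Named per-gene expression vectors forming the
#'   null contrast (e.g. control replicate subsets against each other).
#' @param min_genes Genes required after filtering (default 50; fewer genes
#'   give a warning, none an error).
#' @return Object of class `global_shift_result`: `mean_fc`, `geo_mean_fc`,
#'   `mean_fc_null`, `fc_histogram` (data.frame `bin_lo`, `bin_hi`,
#'   `count_case`, `count_null` on log2 scale), `ks_D`, `ks_p`, `n_genes`.
#' @export
global_shift <- function(expr_case, expr_ctrl, null_case, null_ctrl,
                         min_genes = 50L) {
  fc_of <- function(a, b) {
    shared <- intersect(names(a), names(b))
    a <- a[shared]; b <- b[shared]
    keep <- is.finite(a) & is.finite(b) & a > 0 & b > 0
    (a / b)[keep]
  }
  fc <- fc_of(expr_case, expr_ctrl)
  fc_null <- fc_of(null_case, null_ctrl)
  if (length(fc) == 0L || length(fc_null) == 0L) {
    stop("no shared genes with positive expression")
  }
  if (length(fc) < min_genes) {
    warning("only ", length(fc), " shared genes; shift estimate is unstable")
  }
  lfc <- log2(fc); lnull <- log2(fc_null)
  brk <- seq(floor(min(lfc, lnull) / 0.25) * 0.25,
             ceiling(max(lfc, lnull) / 0.25) * 0.25, by = 0.25)
  if (length(brk) < 2L) brk <- c(brk[1] - 0.125, brk[1] + 0.125)
  hc <- hist(lfc, breaks = brk, plot = FALSE)$counts
  hn <- hist(lnull, breaks = brk, plot = FALSE)$counts
  ks <- suppressWarnings(stats::ks.test(lfc, lnull))
  structure(list(
    mean_fc = mean(fc), geo_mean_fc = exp(mean(log(fc))),
    mean_fc_null = mean(fc_null),
    fc_histogram = data.frame(bin_lo = brk[-length(brk)], bin_hi = brk[-1],
                              count_case = hc, count_null = hn),
    ks_D = unname(ks$statistic), ks_p = ks$p.value,
    n_genes = length(fc)
  ), class = "global_shift_result")
}

#' @export
print.global_shift_result <- function(x, ...) {
  cat(sprintf(
    "Global shift over %d genes: mean FC %.3f (null %.3f), KS D = %.3f, p = %.3g\n",
    x$n_genes, x$mean_fc, x$mean_fc_null, x$ks_D, x$ks_p))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; monotone and bounded by 1.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' qPCR fold change by the 2^-ddCt method
#'
#' @param ct_target_case,ct_ref_case Target and reference-gene Ct values in
#'   the case condition.
#' @param ct_target_ctrl,ct_ref_ctrl Same in the control condition.
#' @return Fold change `2^-((dCt_case) - (dCt_ctrl))`.
#' @export
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl) {
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' Per-gene differential table between two genotypes
#'
#' Runs the weighted t-type test per gene on count proportions for one assay,
#' reports the fold change of the variance-weighted proportion estimates,
#' and applies [call_differential()].
#'
#' @param table_case,table_ctrl [count_reads()] results for the two
#'   genotypes.
#' @param assay Assay to test (`"total_rna"` for differential transcription,
#'   `"footprint"` for differential translation).
#' @param genes Genes to test (default: genes passing [filter_expressed()] in
#'   both genotypes).
#' @param fold_min,alpha Call thresholds (defaults 3 and 0.05).
#' @param adjust `"none"` (default, matching the raw p < alpha convention) or
#'   `"bh"`; when `"bh"`, calls use the adjusted p.
#' @param min_reads Detection filter used for the default gene set.
#' @return data.frame `gene_id`, `fold_change`, `log2_fc`, `statistic`, `df`,
#'   `p_value`, `p_adjusted`, `call`.
#' @export
differential_table <- function(table_case, table_ctrl, assay, genes = NULL,
                               fold_min = 3, alpha = 0.05,
                               adjust = c("none", "bh"), min_reads = 10) {
  adjust <- match.arg(adjust)
  if (is.null(genes)) {
    genes <- intersect(filter_expressed(table_case, assay, min_reads),
                       filter_expressed(table_ctrl, assay, min_reads))
  }
  pull <- function(tab, g) {
    cc <- tab$counts[tab$counts$assay == assay & tab$counts$gene_id == g, ]
    cc <- cc[order(cc$replicate), ]
    tot <- tab$total_mapped[tab$total_mapped$assay == assay, ]
    tot <- tot[order(tot$replicate), ]
    list(x = cc$count, n = tot$total[match(cc$replicate, tot$replicate)])
  }
  rows <- lapply(genes, function(g) {
    a <- pull(table_case, g); b <- pull(table_ctrl, g)
    tt <- weighted_t_test(a$x, a$n, b$x, b$n)
    pa <- wtt_group_estimate(a$x, a$n)$p
    pb <- wtt_group_estimate(b$x, b$n)$p
    fc <- if (pb > 0) pa / pb else Inf
    data.frame(gene_id = g, fold_change = fc, log2_fc = log2(fc),
               statistic = tt[["statistic"]], df = tt[["df"]],
               p_value = tt[["p_value"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(gene_id = character(), fold_change = numeric(),
                      log2_fc = numeric(), statistic = numeric(),
                      df = numeric(), p_value = numeric(),
                      p_adjusted = numeric(), call = character(),
                      stringsAsFactors = FALSE))
  }
  out$p_adjusted <- bh_adjust(out$p_value)
  p_for_call <- if (adjust == "bh") out$p_adjusted else out$p_value
  ok <- is.finite(out$fold_change) & out$fold_change > 0
  out$call <- "none"
  out$call[ok] <- call_differential(out$fold_change[ok], p_for_call[ok],
                                    fold_min = fold_min, alpha = alpha)
  rownames(out) <- NULL
  out
}

#' Call translational regulation genome-wide between two genotypes
#'
#' Combines the per-gene TE Student test (criterion 1: at least
#' `te_fold_min`-fold TE increase at p < `alpha`) with the ribosome-profiling
#' weighted t-type test (criterion 2: significant footprint increase at
#' p < `alpha`).
#'
#' @param expr_case,expr_ctrl [compute_rpkm()] results for the two genotypes.
#' @param table_case,table_ctrl Matching [count_reads()] results.
#' @param genes Genes to test (default: joint detected set in both
#'   genotypes).
#' @param ribo_assay,transcr_assay Assay labels.
#' @param te_fold_min,alpha Call thresholds (defaults 2 and 0.05).
#' @param min_reads Detection filter for the default gene set.
#' @return data.frame `gene_id`, `te_case`, `te_ctrl`, `te_fc`, `te_p`,
#'   `ribo_fc`, `ribo_p`, `translational_regulation`.
#' @export
regulation_calls <- function(expr_case, expr_ctrl, table_case, table_ctrl,
                             genes = NULL, ribo_assay = "footprint",
                             transcr_assay = "total_rna", te_fold_min = 2,
                             alpha = 0.05, min_reads = 10) {
  if (is.null(genes)) {
    genes <- intersect(
      filter_joint(table_case, transcr_assay, ribo_assay, min_reads),
      filter_joint(table_ctrl, transcr_assay, ribo_assay, min_reads))
  }
  te_case <- te_table(expr_case, genes, ribo_assay, transcr_assay,
                      trap_assay = NULL)
  te_ctrl <- te_table(expr_ctrl, genes, ribo_assay, transcr_assay,
                      trap_assay = NULL)
  reps_case <- attr(te_case, "te_reps")
  reps_ctrl <- attr(te_ctrl, "te_reps")
  ribo <- differential_table(table_case, table_ctrl, ribo_assay,
                             genes = genes, alpha = alpha)
  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    a <- reps_case$te[reps_case$gene_id == g]
    b <- reps_ctrl$te[reps_ctrl$gene_id == g]
    te_p <- if (length(a) >= 2 && length(b) >= 2 && all(c(a, b) > 0)) {
      te_student_test(a, b)
    } else NA_real_
    te_fc <- te_case$te_ribo[i] / te_ctrl$te_ribo[i]
    j <- match(g, ribo$gene_id)
    data.frame(gene_id = g, te_case = te_case$te_ribo[i],
               te_ctrl = te_ctrl$te_ribo[i], te_fc = te_fc, te_p = te_p,
               ribo_fc = ribo$fold_change[j], ribo_p = ribo$p_value[j],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$translational_regulation <- !is.na(out$te_p) & !is.na(out$ribo_p) &
    call_translational_regulation(out$te_fc, out$te_p, out$ribo_p,
                                  ribo_fc = out$ribo_fc,
                                  te_fold_min = te_fold_min, alpha = alpha)
  out
}
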