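#' Two-sided Student's t-test (pooled variance)
#'
#' Pooled-variance two-sample t with `df = n_a + n_b - 2`; Welch's unequal
#' variance form is available by flag. A pooled variance of zero is rejected
#' as degenerate rather than mapped to p = 0.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param welch use the Welch approximation instead of pooling.
#' @return list `(t, p, df)`.
#' @export
student_ttest <- function(a, b, welch = FALSE) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each sample needs at least 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  if (welch) {
    se2 <- va / na + vb / nb
    if (se2 == 0) stop("degenerate variance")
    t <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (sp2 == 0) stop("degenerate variance")
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Benjamini-Hochberg FDR q-values
#'
#' Step-up adjusted p-values `q_(i) = min_(j >= i) p_(j) * m / j`, clipped
#' at 1 and returned in the original order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Signed fold change of two group means
#'
#' `r = (mean_a + eps) / (mean_b + eps)`; reported as `r` when `r >= 1`,
#' otherwise as `-1 / r`, so that up- and down-regulation are symmetric
#' around +-1. The pseudo-count `eps` guards zero-mean regions.
#'
#' @param mean_a,mean_b non-negative group means.
#' @param epsilon positive pseudo-count (default 0.5).
#' @return signed fold change (|fc| >= 1).
#' @export
signed_fold_change <- function(mean_a, mean_b, epsilon = 0.5) {
  stopifnot(mean_a >= 0, mean_b >= 0, epsilon > 0)
  r <- (mean_a + epsilon) / (mean_b + epsilon)
  ifelse(r >= 1, r, -1 / r)
}

#' Classify regions on the volcano plane
#'
#' `up` when `fc > fc_cut` and `q < q_cut`; `down` when `fc < -fc_cut` and
#' `q < q_cut`; otherwise `ns`. Both inequalities are strict (a region at
#' exactly the cutoff stays `ns`).
#'
#' @param stats data frame with `fold_change` and `q` columns.
#' @param fc_cut,q_cut volcano thresholds (defaults 1.4 and 0.05).
#' @return `stats` with a `significance_class` factor column.
#' @export
volcano_classify <- function(stats, fc_cut = 1.4, q_cut = 0.05) {
  cls <- rep("ns", nrow(stats))
  ok <- !is.na(stats$q) & !is.na(stats$fold_change)
  cls[ok & stats$fold_change > fc_cut & stats$q < q_cut] <- "up"
  cls[ok & stats$fold_change < -fc_cut & stats$q < q_cut] <- "down"
  stats$significance_class <- factor(cls, levels = c("up", "down", "ns"))
  stats
}

#' Relative z-scores of an animal-by-region count matrix
#'
#' Per region, `z = (x - mean) / sd` with mean and sample SD taken over the
#' baseline animals: all animals pooled (default, placing every group on a
#' common scale) or a control group only.
#'
#' @param counts numeric matrix, rows = animals, columns = regions.
#' @param baseline `"pooled"` or `"control"`.
#' @param control_rows row indices of the control animals (needed for
#'   `baseline = "control"`).
#' @return z matrix of the same shape; columns with zero baseline SD are set
#'   to 0 and flagged in `attr(, "degenerate")`.
#' @export
relative_zscore <- function(counts, baseline = c("pooled", "control"),
                            control_rows = NULL) {
  baseline <- match.arg(baseline)
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) stop("at least 2 animals are required")
  ref <- if (baseline == "pooled") counts else {
    if (is.null(control_rows)) stop("control_rows required for control baseline")
    counts[control_rows, , drop = FALSE]
  }
  mu <- colMeans(ref)
  sd_ <- apply(ref, 2, stats::sd)
  degenerate <- sd_ == 0
  sd_[degenerate] <- 1
  z <- sweep(sweep(counts, 2, mu), 2, sd_, `/`)
  z[, degenerate] <- 0
  attr(z, "degenerate") <- degenerate
  z
}

#' Coefficient of variation
#'
#' Sample SD (ddof 1) divided by the mean.
#'
#' @param values numeric sample, length >= 2, nonzero mean.
#' @return scalar CV.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) stop("at least 2 values are required")
  m <- mean(values)
  if (m == 0) stop("zero mean: CV undefined")
  stats::sd(values) / m
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of tie-averaged ranks; p from the t approximation
#' with `n - 2` degrees of freedom (`|rho| = 1` gives p = 0).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list `(rho, p, n)`.
#' @export
spearman <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) stop("need equal-length vectors with n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: Spearman correlation undefined")
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(t), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' All-pairs Spearman correlation structure of one group
#'
#' Computes the region-by-region Spearman rho and p matrices from one
#' group's animal-by-region counts, BH q-values over the distinct pairs, and
#' each region's best partner (maximum |rho|, self excluded, ties broken by
#' lower region index).
#'
#' @param counts numeric matrix, rows = animals (>= 3), columns = regions.
#' @return list of class `correlation_map`: `rho`, `p`, `q` matrices and a
#'   `best_partner` data frame.
#' @export
correlation_map <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 3) stop("at least 3 animals are required")
  m <- ncol(counts)
  if (is.null(colnames(counts))) colnames(counts) <- as.character(seq_len(m))
  rho <- diag(1, m); pmat <- diag(0, m)
  dimnames(rho) <- dimnames(pmat) <- list(colnames(counts), colnames(counts))
  for (i in seq_len(m - 1)) for (j in seq.int(i + 1, m)) {
    s <- spearman(counts[, i], counts[, j])
    rho[i, j] <- rho[j, i] <- s$rho
    pmat[i, j] <- pmat[j, i] <- s$p
  }
  up <- upper.tri(pmat)
  qmat <- pmat
  qmat[up] <- bh_fdr(pmat[up])
  qmat[lower.tri(qmat)] <- t(qmat)[lower.tri(qmat)]
  best <- data.frame(region = colnames(counts),
                     partner = NA_character_, rho = NA_real_)
  for (i in seq_len(m)) {
    cand <- abs(rho[i, ])
    cand[i] <- -Inf
    j <- which.max(cand)       # which.max takes the first (lowest index) tie
    best$partner[i] <- colnames(counts)[j]
    best$rho[i] <- rho[i, j]
  }
  structure(list(rho = rho, p = pmat, q = qmat, best_partner = best),
            class = "correlation_map")
}

#' Region-level group comparison table
#'
#' For each region: group means and standard errors, pooled t statistic and
#' p-value for `group_a` vs `group_b`, BH q-values across regions, signed
#' fold change (`group_a` over `group_b`), volcano significance class and
#' per-group coefficients of variation. Rows are sorted by q ascending.
#'
#' @param counts long data frame `(animal, group, region, count)`.
#' @param group_a,group_b the two groups to compare.
#' @param fc_cut,q_cut,epsilon volcano and fold-change parameters.
#' @param welch use Welch's t instead of the pooled form.
#' @return a `region_stats` data frame.
#' @export
region_group_stats <- function(counts, group_a, group_b,
                               fc_cut = 1.4, q_cut = 0.05, epsilon = 0.5,
                               welch = FALSE) {
  stopifnot(all(c("animal", "group", "region", "count") %in% names(counts)),
            group_a %in% counts$group, group_b %in% counts$group)
  regions <- unique(counts$region)
  out <- data.frame(region = regions, mean_a = NA_real_, mean_b = NA_real_,
                    se_a = NA_real_, se_b = NA_real_, t = NA_real_,
                    p = NA_real_, cv_a = NA_real_, cv_b = NA_real_)
  for (i in seq_along(regions)) {
    va <- counts$count[counts$region == regions[i] & counts$group == group_a]
    vb <- counts$count[counts$region == regions[i] & counts$group == group_b]
    out$mean_a[i] <- mean(va); out$mean_b[i] <- mean(vb)
    out$se_a[i] <- stats::sd(va) / sqrt(length(va))
    out$se_b[i] <- stats::sd(vb) / sqrt(length(vb))
    tt <- tryCatch(student_ttest(va, vb, welch = welch),
                   error = function(e) list(t = NA_real_, p = NA_real_))
    out$t[i] <- tt$t; out$p[i] <- tt$p
    out$cv_a[i] <- if (mean(va) != 0) coefficient_of_variation(va) else NA_real_
    out$cv_b[i] <- if (mean(vb) != 0) coefficient_of_variation(vb) else NA_real_
  }
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_fdr(out$p[ok])
  out$fold_change <- signed_fold_change(out$mean_a, out$mean_b, epsilon)
  out <- volcano_classify(out, fc_cut = fc_cut, q_cut = q_cut)
  out <- out[order(out$q), ]
  rownames(out) <- NULL
  attr(out, "comparison") <- c(group_a, group_b)
  out
}
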