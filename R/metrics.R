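#' Deconvolution accuracy metrics
#'
#' Metrics comparing a predicted spots x cell-types proportion matrix to
#' the ground truth: root mean squared error ([prop_rmse()]),
#' Jensen-Shannon divergence ([prop_jsd()]), normalized mutual information
#' of the per-spot majority cell types ([nmi()]), and the F1 score for
#' presence/absence detection of designated rare cell types
#' ([f1_rare()]).  [evaluate()] bundles them into one report row and
#' [aggregate_report()] summarizes many rows as mean and standard
#' deviation.  [paired_strategy_test()] compares two pipeline variants
#' (e.g. two feature-selection strategies) across paired benchmark runs
#' with a two-sided Wilcoxon signed-rank test.
#'
#' @name metrics
NULL

.check_pair <- function(true, pred) {
  true <- as.matrix(true); pred <- as.matrix(pred)
  if (!identical(dim(true), dim(pred))) {
    stop("'true' and 'pred' must have identical dimensions")
  }
  if (!is.null(colnames(true)) && !is.null(colnames(pred)) &&
      !identical(colnames(true), colnames(pred))) {
    stop("'true' and 'pred' must have identical cell-type columns")
  }
  list(true = true, pred = pred)
}

#' @rdname metrics
#' @param true,pred spots x cell-types proportion matrices with matching
#'   dimensions and column labels.
#' @param pooled if `TRUE`, pool squared errors over all entries instead
#'   of averaging per-spot RMSEs.
#' @return `prop_rmse()`: nonnegative scalar.
#' @examples
#' truep <- rbind(c(0.5, 0.3, 0.2))
#' predp <- rbind(c(0.4, 0.4, 0.2))
#' prop_rmse(truep, predp)  # sqrt(0.02 / 3)
#' @export
prop_rmse <- function(true, pred, pooled = FALSE) {
  m <- .check_pair(true, pred)
  se <- (m$true - m$pred)^2
  if (pooled) sqrt(mean(se)) else mean(sqrt(rowMeans(se)))
}

#' @rdname metrics
#' @details The Jensen-Shannon divergence uses base-2 logarithms, so each
#'   per-spot value lies in \[0, 1\]; rows are defensively renormalized and
#'   `0 * log 0` is taken as 0.
#' @return `prop_jsd()`: scalar in \[0, 1\].
#' @export
prop_jsd <- function(true, pred) {
  m <- .check_pair(true, pred)
  if (any(m$true < 0) || any(m$pred < 0)) {
    stop("proportions must be nonnegative")
  }
  p <- m$true / rowSums(m$true)
  q <- m$pred / rowSums(m$pred)
  xlogx <- function(x, base) ifelse(x > 0, x * log(x, base = base), 0)
  mid <- (p + q) / 2
  kl <- function(a) rowSums(xlogx(a, 2) - ifelse(a > 0,
                                                 a * log(mid, base = 2), 0))
  mean((kl(p) + kl(q)) / 2)
}

#' @rdname metrics
#' @param p a proportion matrix with cell-type column names.
#' @return `majority_labels()`: character vector of per-spot majority
#'   types; ties resolved to the lexicographically smallest label.
#' @export
majority_labels <- function(p) {
  p <- as.matrix(p)
  labs <- colnames(p)
  if (is.null(labs)) labs <- as.character(seq_len(ncol(p)))
  ord <- order(labs)
  apply(p[, ord, drop = FALSE], 1, function(r) labs[ord][which.max(r)])
}

#' @rdname metrics
#' @param labels_a,labels_b two labelings of the same spots.
#' @param normalization denominator of the normalization: arithmetic
#'   `"mean"` (default) or `"max"` of the two entropies.
#' @details NMI is the mutual information of the two labelings divided by
#'   the (arithmetic mean of the) label entropies.  Identical labelings
#'   give 1 even when constant; if either labeling has zero entropy and
#'   they are not identical, NMI is defined as 0.
#' @return `nmi()`: scalar in \[0, 1\].
#' @export
nmi <- function(labels_a, labels_b, normalization = c("mean", "max")) {
  normalization <- match.arg(normalization)
  if (length(labels_a) != length(labels_b)) {
    stop("labelings must have equal length")
  }
  if (length(labels_a) == 0) stop("labelings must be non-empty")
  a <- as.character(labels_a); b <- as.character(labels_b)
  if (identical(a, b)) return(1)
  tab <- table(a, b)
  n <- sum(tab)
  pj <- rowSums(tab) / n
  pk <- colSums(tab) / n
  ent <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  ha <- ent(pj); hb <- ent(pk)
  if (ha == 0 || hb == 0) return(0)
  pjk <- tab / n
  mi <- sum(ifelse(pjk > 0, pjk * log(pjk / outer(pj, pk)), 0))
  denom <- if (normalization == "mean") (ha + hb) / 2 else max(ha, hb)
  min(max(mi / denom, 0), 1)
}

#' @rdname metrics
#' @param type cell-type label whose detection is scored.
#' @param threshold presence threshold on the proportion (default 0.05).
#' @details A cell type is called present in a spot when its proportion is
#'   at least `threshold`, separately in truth and prediction; F1 is the
#'   harmonic mean of the resulting precision and recall, with the
#'   convention that F1 = 0 when the type is never present in truth nor
#'   prediction.
#' @return `f1_rare()`: scalar in \[0, 1\].
#' @export
f1_rare <- function(true, pred, type, threshold = 0.05) {
  m <- .check_pair(true, pred)
  if (threshold <= 0 || threshold >= 1) {
    stop("'threshold' must be in (0, 1)")
  }
  labs <- colnames(m$true)
  if (is.null(labs) || !(type %in% labs)) {
    stop("unknown cell type '", type, "'")
  }
  tt <- m$true[, type] >= threshold
  pp <- m$pred[, type] >= threshold
  tp <- sum(tt & pp)
  if (tp == 0) return(0)
  prec <- tp / sum(pp)
  rec <- tp / sum(tt)
  2 * prec * rec / (prec + rec)
}

#' @rdname metrics
#' @param metric_a,metric_b equal-length paired metric values (one per
#'   benchmark dataset) for the two variants under comparison.
#' @details The signed-rank p-value is exact for up to 25 nonzero
#'   differences, including tied absolute differences (the null
#'   distribution of the statistic is built by dynamic programming over
#'   sign flips of the average ranks); zero differences are discarded as
#'   usual.  Larger samples use the normal approximation of
#'   [stats::wilcox.test()].
#' @return `paired_strategy_test()`: two-sided Wilcoxon signed-rank
#'   p-value.
#' @export
paired_strategy_test <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b)) {
    stop("paired metric lists must have equal length")
  }
  if (length(metric_a) < 5) {
    stop("need at least 5 paired observations")
  }
  d <- metric_a - metric_b
  if (all(d == 0)) stop("all paired differences are zero")
  d <- d[d != 0]
  n <- length(d)
  if (n > 25) {
    return(suppressWarnings(
      wilcox.test(metric_a, metric_b, paired = TRUE)$p.value))
  }
  r2 <- as.integer(round(2 * rank(abs(d))))  # doubled ranks are integers
  v2 <- sum(r2[d > 0])
  # null pmf of the doubled statistic: convolve (1 + x^r2_i)/2 terms
  w <- 1
  for (ri in r2) {
    nw <- c(w, numeric(ri))
    nw[(ri + 1):length(nw)] <- nw[(ri + 1):length(nw)] + w
    w <- nw
  }
  w <- w / 2^n  # support 0 .. sum(r2), index shift 1
  p_ge <- sum(w[(v2 + 1):length(w)])
  p_le <- sum(w[1:(v2 + 1)])
  min(1, 2 * min(p_ge, p_le))
}

#' @rdname metrics
#' @param rare_types cell types whose F1 detection scores are reported.
#' @param method,modality,strategy annotation carried into the report row.
#' @return `evaluate()`: one-row data.frame with columns `method`,
#'   `modality`, `strategy`, `rmse`, `jsd`, `nmi` and one `f1_<type>`
#'   column per rare type.
#' @export
evaluate <- function(true, pred, rare_types = NULL, threshold = 0.05,
                     method = "unknown", modality = NA_character_,
                     strategy = NA_character_) {
  m <- .check_pair(true, pred)
  row <- data.frame(method = method, modality = modality,
                    strategy = strategy,
                    rmse = prop_rmse(m$true, m$pred),
                    jsd = prop_jsd(m$true, m$pred),
                    nmi = nmi(majority_labels(m$true),
                              majority_labels(m$pred)),
                    stringsAsFactors = FALSE)
  for (ty in rare_types) {
    row[[paste0("f1_", ty)]] <- f1_rare(m$true, m$pred, ty, threshold)
  }
  row
}

#' @rdname metrics
#' @param report a data.frame of [evaluate()] rows.
#' @param by grouping columns for aggregation.
#' @return `aggregate_report()`: data.frame with one `mean` and one `sd`
#'   row per group and metric column.
#' @export
aggregate_report <- function(report,
                             by = c("method", "modality", "strategy")) {
  by <- intersect(by, names(report))
  num <- names(report)[vapply(report, is.numeric, TRUE)]
  key <- do.call(paste, c(lapply(report[by], as.character), sep = " / "))
  out <- do.call(rbind, lapply(unique(key), function(k) {
    rows <- report[key == k, , drop = FALSE]
    base <- rows[1, by, drop = FALSE]
    mk <- function(stat, f) {
      r <- base
      r$statistic <- stat
      for (m in num) r[[m]] <- f(rows[[m]])
      r
    }
    rbind(mk("mean", mean), mk("sd", function(x) {
      if (length(x) > 1) sd(x) else 0
    }))
  }))
  rownames(out) <- NULL
  out
}
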