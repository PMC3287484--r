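#' Row-wise z-score normalization of an expression matrix
#'
#' Each gene row is centered at its cohort mean and scaled by its cohort
#' standard deviation (denominator n-1).  Constant rows become all zeros with
#' a warning rather than NaN.
#'
#' @param expr genes x samples numeric matrix (>= 2 samples).
#' @return matrix of the same shape; every non-constant row has mean 0 and
#'   sd 1.
#' @export
zscore_rows <- function(expr) {
  check_expression(expr)
  if (ncol(expr) < 2L) stop("row z-scores need at least 2 samples")
  mu <- rowMeans(expr)
  s <- apply(expr, 1L, sd)
  const <- s == 0
  if (any(const)) {
    warning(sum(const), " constant gene row(s) set to zero")
    s[const] <- 1
  }
  z <- (expr - mu) / s
  z[const, ] <- 0
  z
}

#' Signed z-sum risk score
#'
#' Per sample: the sum of row-normalized z-scores over the MEG+ genes minus
#' the sum over the MEG- genes.  Because every row of the z-matrix sums to
#' zero across the cohort, the cohort mean of the scores is zero (up to
#' floating point) for any signature.  Signature genes absent from the matrix
#' are dropped with a message.
#'
#' @param z row z-score matrix from \code{\link{zscore_rows}}.
#' @param meg_plus,meg_minus character vectors of signature genes.
#' @return named numeric vector of per-sample scores.
#' @export
risk_scores <- function(z, meg_plus, meg_minus) {
  plus <- intersect(meg_plus, rownames(z))
  minus <- intersect(meg_minus, rownames(z))
  dropped <- length(meg_plus) + length(meg_minus) - length(plus) - length(minus)
  if (dropped > 0L)
    message(dropped, " signature gene(s) absent from the matrix, dropped")
  if (length(plus) + length(minus) == 0L)
    stop("no signature genes found in the expression matrix")
  up <- if (length(plus)) colSums(z[plus, , drop = FALSE]) else 0
  dn <- if (length(minus)) colSums(z[minus, , drop = FALSE]) else 0
  up - dn
}

#' Classify samples by the mean-plus-one-SD rule
#'
#' A sample is called high risk when its score strictly exceeds the cohort
#' mean plus one standard deviation.  Sensitivity, specificity and accuracy
#' are computed against the supplied binary outcomes; with only one outcome
#' class present the undefined rate is NA and flagged.
#'
#' @param scores numeric vector of risk scores.
#' @param outcomes logical/0-1 vector aligned to \code{scores} (TRUE = event).
#' @return list: threshold, predicted (logical), tp/fp/tn/fn, sensitivity,
#'   specificity, accuracy, computed (logical flag).
#' @export
classify_risk <- function(scores, outcomes) {
  stopifnot(length(scores) == length(outcomes))
  outcomes <- as.logical(outcomes)
  thr <- mean(scores) + sd(scores)
  pred <- scores > thr
  tp <- sum(pred & outcomes); fn <- sum(!pred & outcomes)
  tn <- sum(!pred & !outcomes); fp <- sum(pred & !outcomes)
  one_class <- !any(outcomes) || all(outcomes)
  if (one_class)
    warning("outcomes contain a single class; sensitivity/specificity not computed")
  list(threshold = thr, predicted = pred,
       tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = (tp + tn) / length(scores),
       computed = !one_class)
}

#' ROC curve and AUC for a risk score
#'
#' The ROC is swept over all distinct score values (predicting positive at
#' score >= threshold), anchored at (0,0) and (1,1).  The AUC is computed by
#' the rank (Mann-Whitney) statistic with ties counted one half, which equals
#' the trapezoidal area under the swept curve.
#'
#' @param scores numeric vector.
#' @param outcomes binary vector with both classes present.
#' @return list with \code{roc} (data.frame fpr, tpr) and \code{auc}.
#' @export
roc_auc <- function(scores, outcomes) {
  stopifnot(length(scores) == length(outcomes))
  outcomes <- as.logical(outcomes)
  n1 <- sum(outcomes); n0 <- sum(!outcomes)
  if (n1 == 0L || n0 == 0L) stop("both outcome classes must be present")
  r <- rank(scores)
  auc <- (sum(r[outcomes]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(outcomes & scores >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(!outcomes & scores >= t) / n0, numeric(1))
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] != 1 || roc$tpr[nrow(roc)] != 1)
    roc <- rbind(roc, data.frame(fpr = 1, tpr = 1))
  list(roc = roc, auc = auc)
}

# Trapezoidal area under a swept ROC; cross-checked against the rank AUC.
trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

#' Split a cohort into three equal-size risk groups
#'
#' Samples are sorted by ascending score (ties kept in input order): the
#' lowest third is the good-prognosis group, the highest third the poor
#' group, the rest intermediate.  When n is not divisible by 3, a single
#' extra sample goes to the intermediate group (n mod 3 = 1), or one each to
#' good and poor (n mod 3 = 2), so group sizes never differ by more than 1.
#'
#' @param scores numeric vector (length >= 3), optionally named.
#' @return character vector of labels in \{good, intermediate, poor\} aligned
#'   to \code{scores}.
#' @export
tertile_groups <- function(scores) {
  n <- length(scores)
  if (n < 3L) stop("tertile grouping needs at least 3 samples")
  base <- n %/% 3L
  rem <- n %% 3L
  sizes <- c(good = base, intermediate = base, poor = base)
  if (rem == 1L) sizes["intermediate"] <- base + 1L
  if (rem == 2L) sizes[c("good", "poor")] <- base + 1L
  ord <- order(scores)  # stable: ties stay in sample order
  labels <- rep(c("good", "intermediate", "poor"), times = sizes)
  out <- character(n)
  out[ord] <- labels
  names(out) <- names(scores)
  out
}

#' Full risk profile of a cohort under a signed gene signature
#'
#' Convenience wrapper: row z-scores, signed z-sum scores, mean+1SD
#' classification, ROC/AUC and tertile groups.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param meg_plus,meg_minus signature gene sets.
#' @param outcomes optional binary outcome vector aligned to the samples;
#'   when NULL only scores and groups are returned.
#' @return object of class \code{RiskProfile}.
#' @export
risk_profile <- function(expr, meg_plus, meg_minus, outcomes = NULL) {
  z <- zscore_rows(expr)
  scores <- risk_scores(z, meg_plus, meg_minus)
  out <- list(scores = scores, groups = tertile_groups(scores))
  if (!is.null(outcomes)) {
    out$classification <- classify_risk(scores, outcomes)
    ra <- roc_auc(scores, outcomes)
    out$roc <- ra$roc
    out$auc <- ra$auc
  }
  structure(out, class = "RiskProfile")
}

#' @export
print.RiskProfile <- function(x, ...) {
  cat("RiskProfile:", length(x$scores), "samples\n")
  cat("  score mean", format(mean(x$scores), digits = 3),
      "sd", format(sd(x$scores), digits = 3), "\n")
  cat("  groups:", paste(names(table(x$groups)), table(x$groups),
                         sep = "=", collapse = " "), "\n")
  if (!is.null(x$auc)) {
    cl <- x$classification
    cat(sprintf("  threshold %.3f: sensitivity %.3f specificity %.3f accuracy %.3f\n",
                cl$threshold, cl$sensitivity, cl$specificity, cl$accuracy))
    cat(sprintf("  AUC %.3f\n", x$auc))
  }
  invisible(x)
}
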