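#' Rank genes by a per-gene two-way ANOVA on stage factors
#'
#' For every gene, expression is modeled on categorical N and T main effects
#' and the gene is ranked by the partial F-test for the N factor (full model
#' N + T against the T-only reduction).  The ranking is directionless.  Stage
#' levels with no samples simply drop out of the factor coding.  All genes
#' are fit in one pass via a multi-response least-squares fit; per-gene
#' results agree with \code{aov}/\code{anova} on the same data.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param annotations sample annotation data.frame; tumor samples are
#'   filtered as in \code{\link{filter_samples}}.
#' @param n_select number of genes to flag as selected (default 40).
#' @return data.frame: gene, statistic (partial F), p_value, direction (NA),
#'   selected; sorted by ascending p, ties by gene symbol.
#' @export
anova_rank <- function(expr, annotations, n_select = 40L) {
  d <- baseline_design(expr, annotations)
  Nf <- factor(d$n_stage)
  Tf <- factor(d$t_stage)
  if (nlevels(Nf) < 2L || nlevels(Tf) < 2L)
    stop("need at least 2 populated levels on each stage axis")
  Y <- t(expr[, d$sample_id, drop = FALSE])
  full <- lm(Y ~ Nf + Tf)
  red <- lm(Y ~ Tf)
  rss_full <- colSums(residuals(full)^2)
  rss_red <- colSums(residuals(red)^2)
  df1 <- red$df.residual - full$df.residual
  df2 <- full$df.residual
  F_stat <- pmax((rss_red - rss_full) / df1, 0) / pmax(rss_full / df2, 1e-300)
  p <- pf(F_stat, df1, df2, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1]
  out <- data.frame(gene = rownames(expr), statistic = F_stat, p_value = p,
                    direction = NA_real_, stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$gene), ]
  out$selected <- seq_len(nrow(out)) <= n_select
  rownames(out) <- NULL
  structure(out, method = "anova")
}

#' Rank genes by per-gene multiple regression on numeric stages
#'
#' For every gene, expression is regressed on numeric N (0--3), numeric T
#' (1--4) and their interaction.  A gene is eligible when its T and
#' interaction coefficients are not significant (p > 0.05); among eligible
#' genes the most significant N coefficients are selected, split by slope
#' sign (up: coefficient > 0, down: < 0), \code{n_per_direction} each.
#'
#' @inheritParams anova_rank
#' @param n_per_direction genes per direction (default 20).
#' @param eligibility_alpha threshold for the T / interaction screens.
#' @return data.frame: gene, statistic (t of the N coefficient), p_value,
#'   direction (+1/-1), p_t, p_interaction, eligible, selected.
#' @export
regression_rank <- function(expr, annotations, n_per_direction = 20L,
                            eligibility_alpha = 0.05) {
  d <- baseline_design(expr, annotations)
  n_num <- as.numeric(d$n_stage)
  t_num <- as.numeric(d$t_stage)
  Y <- t(expr[, d$sample_id, drop = FALSE])
  fit <- lm(Y ~ n_num * t_num)
  X <- model.matrix(fit)
  XtXi <- chol2inv(chol(crossprod(X)))
  sigma2 <- colSums(residuals(fit)^2) / fit$df.residual
  sigma2 <- pmax(sigma2, 1e-300)  # zero-residual genes: keep t finite-signed
  co <- coef(fit)  # coefficients x genes
  se <- sqrt(outer(diag(XtXi), sigma2))
  tval <- co / se
  pval <- 2 * pt(abs(tval), fit$df.residual, lower.tail = FALSE)
  pval <- pmax(pval, .Machine$double.xmin)
  out <- data.frame(gene = rownames(expr),
                    statistic = tval["n_num", ],
                    p_value = pval["n_num", ],
                    direction = sign(co["n_num", ]),
                    p_t = pval["t_num", ],
                    p_interaction = pval["n_num:t_num", ],
                    stringsAsFactors = FALSE)
  out$eligible <- out$p_t > eligibility_alpha & out$p_interaction > eligibility_alpha
  out$selected <- FALSE
  for (dir in c(1, -1)) {
    cand <- out[out$eligible & out$direction == dir, ]
    cand <- cand[order(cand$p_value, cand$gene), ]
    take <- head(cand$gene, n_per_direction)
    if (length(take) < n_per_direction)
      warning("only ", length(take), " eligible ",
              if (dir > 0) "up" else "down", "-direction gene(s) available")
    out$selected[out$gene %in% take] <- TRUE
  }
  rownames(out) <- NULL
  structure(out, method = "regression")
}

# Shared: filter samples, keep annotated tumors present in the matrix.
baseline_design <- function(expr, annotations) {
  check_expression(expr)
  flt <- filter_samples(annotations)
  ann <- annotations[annotations$sample_id %in% flt$kept &
                       !annotations$is_normal, , drop = FALSE]
  ann <- ann[ann$sample_id %in% colnames(expr), , drop = FALSE]
  if (nrow(ann) == 0L) stop("no usable tumor samples")
  ann
}
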