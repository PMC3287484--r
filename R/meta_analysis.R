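P_CLIP <- 1e-15

#' Convert a two-tailed p-value to a directional one-tailed p-value
#'
#' Halves the two-tailed p when the experiment's observed regulation
#' direction matches the direction under test, and complements it
#' (\code{1 - p/2}) otherwise, so that evidence in the wrong direction counts
#' against the set.  Results are clipped to \code{[1e-15, 1 - 1e-15]} to keep
#' downstream z-scores and log terms finite.
#'
#' @param p_two two-tailed p-value(s) in (0, 1].
#' @param observed_direction "up" or "down", the experiment's reported
#'   regulation direction (vectorized).
#' @param tested_direction "up" or "down", the direction being tested.
#' @return one-tailed p-value(s).
#' @export
to_one_tailed <- function(p_two, observed_direction, tested_direction) {
  if (any(is.na(p_two)) || any(p_two <= 0) || any(p_two > 1))
    stop("two-tailed p-values must lie in (0, 1]")
  stopifnot(tested_direction %in% c("up", "down"),
            all(observed_direction %in% c("up", "down")))
  p1 <- ifelse(observed_direction == tested_direction, p_two / 2, 1 - p_two / 2)
  pmin(pmax(p1, P_CLIP), 1 - P_CLIP)
}

#' Construct an experiment table
#'
#' One differential-expression experiment: per-gene two-tailed p-values with
#' regulation directions, an analysis class (e.g. metastasis prognosis,
#' survival prognosis, tumor grade), and the universe of genes the experiment
#' measured.
#'
#' @param experiment_id identifier.
#' @param analysis_class one of MP, RLP, SVP, STM, STN, STT, STG, GRD.
#' @param table data.frame with columns \code{gene}, \code{p_two},
#'   \code{direction} ("up"/"down").
#' @param universe all genes measured; defaults to \code{table$gene}.
#' @return object of class \code{ExperimentTable}.
#' @export
experiment_table <- function(experiment_id, analysis_class, table,
                             universe = table$gene) {
  classes <- c("MP", "RLP", "SVP", "STM", "STN", "STT", "STG", "GRD")
  if (!analysis_class %in% classes)
    stop("analysis_class must be one of: ", paste(classes, collapse = ", "))
  stopifnot(is.data.frame(table),
            all(c("gene", "p_two", "direction") %in% names(table)))
  if (anyDuplicated(table$gene)) stop("duplicate genes in experiment table")
  if (any(table$p_two <= 0 | table$p_two > 1))
    stop("two-tailed p-values must lie in (0, 1]")
  if (!all(table$direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down'")
  structure(list(experiment_id = experiment_id,
                 analysis_class = analysis_class,
                 table = table, universe = universe),
            class = "ExperimentTable")
}

#' Assemble a one-tailed p-value matrix for a gene set across experiments
#'
#' Cell (i, j) holds gene i's one-tailed p in experiment j after alias
#' resolution: the exact symbol is looked up first, then any alias mapping to
#' it.  Genes an experiment did not measure are left missing (NA) and shrink
#' the effective count \code{nk} rather than being imputed.
#'
#' @param gene_set character vector of gene symbols (non-empty).
#' @param experiments list of \code{ExperimentTable}s (non-empty).
#' @param tested_direction "up" or "down".
#' @param alias_table optional data.frame with columns \code{alias},
#'   \code{symbol} mapping legacy names to current symbols.
#' @return object of class \code{PValueMatrix}: \code{P} (genes x
#'   experiments, NA = missing), \code{nk}, \code{tested_direction},
#'   \code{experiment_ids}, \code{analysis_classes}.
#' @export
assemble_pvalue_matrix <- function(gene_set, experiments, tested_direction,
                                   alias_table = NULL) {
  if (length(gene_set) == 0L) stop("empty gene set")
  if (length(experiments) == 0L) stop("empty experiment list")
  stopifnot(all(vapply(experiments, inherits, logical(1), "ExperimentTable")))
  P <- matrix(NA_real_, length(gene_set), length(experiments),
              dimnames = list(gene_set,
                              vapply(experiments, `[[`, character(1), "experiment_id")))
  for (j in seq_along(experiments)) {
    tab <- experiments[[j]]$table
    idx <- match(gene_set, tab$gene)
    if (!is.null(alias_table)) {
      for (g in which(is.na(idx))) {
        al <- alias_table$alias[alias_table$symbol == gene_set[g]]
        hit <- match(al, tab$gene)
        hit <- hit[!is.na(hit)]
        if (length(hit)) idx[g] <- hit[1L]
      }
    }
    found <- !is.na(idx)
    P[found, j] <- to_one_tailed(tab$p_two[idx[found]],
                                 tab$direction[idx[found]], tested_direction)
  }
  structure(list(gene_set = gene_set, P = P, nk = sum(!is.na(P)),
                 tested_direction = tested_direction,
                 experiment_ids = colnames(P),
                 analysis_classes = vapply(experiments, `[[`, character(1),
                                           "analysis_class")),
            class = "PValueMatrix")
}

check_pm <- function(pm) {
  stopifnot(inherits(pm, "PValueMatrix"))
  if (pm$nk == 0L) stop("no gene/experiment cells available (nk = 0)")
  pm$P[!is.na(pm$P)]
}

#' Combine one-tailed p-values by Fisher's inverse chi-square method
#'
#' \code{T = -2 * sum(log p)} over the available cells follows a chi-square
#' distribution with \code{2 * nk} degrees of freedom under the joint null.
#'
#' @param pm a \code{PValueMatrix}.
#' @return \code{MetaResult} list: method, statistic, df, nk, p_combined.
#' @export
fisher_combine <- function(pm) {
  p <- check_pm(pm)
  T_stat <- -2 * sum(log(p))
  df <- 2L * pm$nk
  structure(list(method = "fisher", statistic = T_stat, df = df, nk = pm$nk,
                 tested_direction = pm$tested_direction,
                 p_combined = pchisq(T_stat, df, lower.tail = FALSE)),
            class = "MetaResult")
}

#' Combine one-tailed p-values by Stouffer's Z
#'
#' Each p is transformed to its standard-normal upper-tail quantile; the sum
#' of the z-values divided by \code{sqrt(nk)} is again standard normal under
#' the joint null.
#'
#' @inheritParams fisher_combine
#' @return \code{MetaResult} with \code{statistic} = Z.
#' @export
stouffer_combine <- function(pm) {
  p <- check_pm(pm)
  Z <- sum(qnorm(p, lower.tail = FALSE)) / sqrt(pm$nk)
  structure(list(method = "stouffer", statistic = Z, df = NA, nk = pm$nk,
                 tested_direction = pm$tested_direction,
                 p_combined = pnorm(Z, lower.tail = FALSE)),
            class = "MetaResult")
}

#' Combine p-values by the cumulative binomial (count) method
#'
#' Counts the cells significant at threshold \code{p_h} and reports the
#' binomial upper-tail probability of seeing at least that many by chance,
#' i.e. \code{P(Binomial(nk, p_h) >= n_s)} via the regularized incomplete
#' beta function (as computed by \code{pbinom}).  With no significant cell
#' the combined p is 1.
#'
#' @inheritParams fisher_combine
#' @param p_h per-cell significance threshold in (0, 1); default 0.05.
#' @return \code{MetaResult} with \code{statistic} = n_s.
#' @export
binomial_combine <- function(pm, p_h = 0.05) {
  stopifnot(p_h > 0, p_h < 1)
  p <- check_pm(pm)
  n_s <- sum(p <= p_h)
  p_comb <- if (n_s == 0L) 1 else pbinom(n_s - 1L, pm$nk, p_h, lower.tail = FALSE)
  structure(list(method = "binomial", statistic = n_s, df = NA, nk = pm$nk,
                 p_h = p_h, tested_direction = pm$tested_direction,
                 p_combined = p_comb),
            class = "MetaResult")
}

#' Estimate the background bias of an experiment collection
#'
#' Differential-expression compendia are often up-shifted: more genes reach
#' significance, and more in the up direction, than a calibrated null would
#' give, so even random gene sets look "significant".  This estimates the
#' shift by drawing \code{R} random gene sets of size \code{m} (one draw per
#' experiment, from that experiment's own measured universe), running each
#' through the same one-tailed Stouffer pipeline, and recording the mean and
#' SD of the resulting Z scores.
#'
#' @param experiments list of \code{ExperimentTable}s.
#' @param m gene-set size (default 20).
#' @param R number of random sets (default 1000).
#' @param seed RNG seed; the estimate is fully reproducible.
#' @param tested_direction direction of the Stouffer test; default "up".
#' @return \code{BiasEstimate} list: m, R, mean_Z, sd_Z, seed,
#'   tested_direction, analysis_classes.
#' @export
background_bias <- function(experiments, m = 20L, R = 1000L, seed = 1L,
                            tested_direction = "up") {
  stopifnot(R >= 1L, m >= 1L,
            all(vapply(experiments, inherits, logical(1), "ExperimentTable")))
  # Precompute each experiment's one-tailed p over its full universe
  pools <- lapply(experiments, function(e) {
    if (length(e$universe) < m)
      stop("experiment ", e$experiment_id, " universe smaller than m = ", m)
    idx <- match(e$universe, e$table$gene)
    found <- !is.na(idx)
    p1 <- rep(NA_real_, length(e$universe))
    p1[found] <- to_one_tailed(e$table$p_two[idx[found]],
                               e$table$direction[idx[found]], tested_direction)
    p1
  })
  set.seed(seed)
  zsum <- numeric(R)
  nk <- integer(R)
  for (pool in pools) {
    z <- qnorm(pool, lower.tail = FALSE)
    draws <- vapply(seq_len(R), function(r) {
      zi <- z[sample.int(length(z), m)]
      c(sum(zi, na.rm = TRUE), sum(!is.na(zi)))
    }, numeric(2))
    zsum <- zsum + draws[1L, ]
    nk <- nk + as.integer(draws[2L, ])
  }
  Z <- zsum / sqrt(nk)
  structure(list(m = m, R = R, mean_Z = mean(Z), sd_Z = if (R > 1L) sd(Z) else NA_real_,
                 seed = seed, tested_direction = tested_direction,
                 analysis_classes = unique(vapply(experiments, `[[`,
                                                  character(1), "analysis_class"))),
            class = "BiasEstimate")
}

#' Bias-corrected Stouffer combination
#'
#' Subtracts the expected random-set Z from the observed Z in an
#' up-regulation test (adds it in a down-regulation test), so that
#' enrichment is judged against the compendium's inflated baseline rather
#' than an ideal null.
#'
#' @param pm \code{PValueMatrix} (its \code{tested_direction} must equal
#'   \code{tested_direction}).
#' @param bias \code{BiasEstimate} from \code{\link{background_bias}}.
#' @param tested_direction "up" or "down".
#' @return \code{MetaResult} with extra fields \code{corrected_Z} and
#'   \code{corrected_p}.
#' @export
corrected_stouffer <- function(pm, bias, tested_direction = pm$tested_direction) {
  stopifnot(inherits(bias, "BiasEstimate"))
  if (!identical(tested_direction, pm$tested_direction))
    stop("tested_direction (", tested_direction,
         ") does not match the matrix direction (", pm$tested_direction, ")")
  res <- stouffer_combine(pm)
  cz <- if (tested_direction == "up") res$statistic - bias$mean_Z
        else res$statistic + bias$mean_Z
  res$corrected_Z <- cz
  res$corrected_p <- pnorm(cz, lower.tail = FALSE)
  res$bias_mean_Z <- bias$mean_Z
  res
}

#' Combined class-level score from an up and a down test
#'
#' The up-regulation p of the MEG+ set and the down-regulation p of the MEG-
#' set are multiplied into one combined p, and reported as a log-odds score
#' \code{-log10(p_up) - log10(p_down)}.
#'
#' @param p_up,p_down the two combined p-values (each in (0, 1]).
#' @return list with \code{combined_p} and \code{log_odds}.
#' @export
class_score <- function(p_up, p_down) {
  if (inherits(p_up, "MetaResult"))
    p_up <- if (!is.null(p_up$corrected_p)) p_up$corrected_p else p_up$p_combined
  if (inherits(p_down, "MetaResult"))
    p_down <- if (!is.null(p_down$corrected_p)) p_down$corrected_p else p_down$p_combined
  if (p_up <= 0 || p_down <= 0) stop("p-value of 0 after clipping")
  list(combined_p = p_up * p_down,
       log_odds = -log10(p_up) - log10(p_down))
}

#' Meta-analysis report for signed gene-set signatures
#'
#' For every signature (a \code{plus}/\code{minus} gene-set pair) and every
#' analysis class present in the experiment collection: tests the plus set
#' for up-regulation and the minus set for down-regulation with all three
#' combiners, applies background-bias correction to the Stouffer Z (per
#' class, shared RNG stream), and reports the class-level combined p and
#' log-odds.
#'
#' @param signatures named list; each element is a list with character
#'   vectors \code{plus} and \code{minus}.
#' @param experiments list of \code{ExperimentTable}s.
#' @param p_h binomial significance threshold.
#' @param bias_R random sets per class for bias estimation; 0 disables
#'   correction.
#' @param seed seed for the bias RNG stream.
#' @param alias_table optional alias data.frame (see
#'   \code{\link{assemble_pvalue_matrix}}).
#' @return data.frame, one row per signature x class, with the three
#'   combined p-values per direction, corrected Z/p (when enabled), and the
#'   class score.  Classes with no overlapping genes get NA rows.
#' @export
run_meta <- function(signatures, experiments, p_h = 0.05, bias_R = 1000L,
                     seed = 1L, alias_table = NULL) {
  stopifnot(length(signatures) >= 1L, length(experiments) >= 1L)
  classes <- unique(vapply(experiments, `[[`, character(1), "analysis_class"))
  biases <- list()
  if (bias_R > 0L) {
    for (cl in classes) {
      exps <- Filter(function(e) e$analysis_class == cl, experiments)
      biases[[cl]] <- background_bias(exps, m = 20L, R = bias_R,
                                      seed = seed, tested_direction = "up")
    }
  }
  rows <- list()
  for (sig_name in names(signatures)) {
    sig <- signatures[[sig_name]]
    for (cl in classes) {
      exps <- Filter(function(e) e$analysis_class == cl, experiments)
      row <- list(signature = sig_name, analysis_class = cl)
      pm_up <- assemble_pvalue_matrix(sig$plus, exps, "up", alias_table)
      pm_dn <- assemble_pvalue_matrix(sig$minus, exps, "down", alias_table)
      if (pm_up$nk == 0L || pm_dn$nk == 0L) {
        row <- c(row, list(computed = FALSE))
        rows[[length(rows) + 1L]] <- row
        next
      }
      row$computed <- TRUE
      for (side in c("up", "dn")) {
        pm <- if (side == "up") pm_up else pm_dn
        row[[paste0("nk_", side)]] <- pm$nk
        row[[paste0("fisher_p_", side)]] <- fisher_combine(pm)$p_combined
        st <- stouffer_combine(pm)
        row[[paste0("stouffer_z_", side)]] <- st$statistic
        row[[paste0("stouffer_p_", side)]] <- st$p_combined
        row[[paste0("binomial_p_", side)]] <- binomial_combine(pm, p_h)$p_combined
        if (bias_R > 0L) {
          cs <- corrected_stouffer(pm, biases[[cl]])
          row[[paste0("corrected_z_", side)]] <- cs$corrected_Z
          row[[paste0("corrected_p_", side)]] <- cs$corrected_p
        }
      }
      p_up <- if (bias_R > 0L) row$corrected_p_up else row$stouffer_p_up
      p_dn <- if (bias_R > 0L) row$corrected_p_dn else row$stouffer_p_dn
      sc <- class_score(max(p_up, P_CLIP), max(p_dn, P_CLIP))
      row$class_p <- sc$combined_p
      row$class_log_odds <- sc$log_odds
      rows[[length(rows) + 1L]] <- row
    }
  }
  cols <- unique(unlist(lapply(rows, names)))
  out <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(cols, names(r))] <- NA
    as.data.frame(r[cols], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
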