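#' Configuration for the synthetic staged cohort
#'
#' Defaults emulate the shape of a mid-2000s breast-tumor compendium: about
#' 278 non-metastatic tumors spread over the 16 N x T classes plus a handful
#' of normal references, planted gene archetypes on the log2 scale, and
#' Gaussian array noise.
#'
#' @param samples_per_cell 4 x 4 integer matrix (rows N0..N3, cols T1..T4) of
#'   tumor counts per class; default near-balanced, summing to 278.
#' @param n_normals number of normal samples (default 7).
#' @param n_mono_up,n_mono_down genes rising/falling by \code{delta} per N
#'   step (default 100 each).
#' @param n_leap genes jumping by \code{leap_height} at one N transition
#'   (default 50).
#' @param leap_transition index a of the N\code{a} -> N\code{a+1} leap
#'   (default 1, i.e. N1 -> N2).
#' @param n_fluct genes oscillating with N without net trend (default 100).
#' @param n_mono_up_t genes rising with T instead of N (default 100).
#' @param n_null unstructured genes (default fills to 2000 genes total).
#' @param delta effect size, log2 units per stage step (default 0.5).
#' @param leap_height jump size in log2 units (default 1.0).
#' @param sigma per-observation Gaussian noise SD, log2 units (default 0.5).
#' @param seed RNG seed.
#' @return list of class \code{SimConfig}.
#' @export
sim_config <- function(samples_per_cell = NULL, n_normals = 7L,
                       n_mono_up = 100L, n_mono_down = 100L, n_leap = 50L,
                       leap_transition = 1L, n_fluct = 100L,
                       n_mono_up_t = 100L, n_null = 1550L,
                       delta = 0.5, leap_height = 1.0, sigma = 0.5,
                       seed = 1L) {
  if (is.null(samples_per_cell)) {
    samples_per_cell <- matrix(17L, 4L, 4L)
    samples_per_cell[1:2, 1:3] <- 18L  # 272 + 6 = 278
  }
  stopifnot(is.matrix(samples_per_cell), all(dim(samples_per_cell) == 4L),
            all(samples_per_cell >= 0L), sigma > 0,
            leap_transition %in% 0:2)
  structure(list(samples_per_cell = samples_per_cell, n_normals = n_normals,
                 n_mono_up = n_mono_up, n_mono_down = n_mono_down,
                 n_leap = n_leap, leap_transition = leap_transition,
                 n_fluct = n_fluct, n_mono_up_t = n_mono_up_t,
                 n_null = n_null, delta = delta, leap_height = leap_height,
                 sigma = sigma, seed = seed),
            class = "SimConfig")
}

#' Simulate a staged tumor cohort with planted gene archetypes
#'
#' Every tumor sample in class (N=n, T=t) receives, per gene, a mean equal to
#' a gene-specific baseline plus the archetype effect, plus Gaussian noise:
#' \itemize{
#'   \item mono_up: \code{+delta * (n + 1)} (already shifted at N0 vs normal);
#'   \item mono_down: \code{-delta * (n + 1)};
#'   \item leap: \code{+leap_height} once \code{n > leap_transition};
#'   \item fluct: \code{+delta} at even N stages, 0 at odd ones -- a pattern
#'     whose stage-progression contrast is exactly zero;
#'   \item mono_up_T: \code{+delta * t}, monotone in T but flat in N;
#'   \item null: baseline only.
#' }
#' Normal samples receive baseline plus noise.  Output is fully determined by
#' \code{config$seed}.
#'
#' @param config a \code{SimConfig}.
#' @return list: \code{expr} (genes x samples log2 matrix),
#'   \code{annotations} (data.frame), \code{truth} (data.frame gene,
#'   archetype, direction, transition).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimConfig"))
  if (sum(config$samples_per_cell) == 0L) stop("no tumor samples configured")
  set.seed(config$seed)
  counts <- config$samples_per_cell
  n_stage <- rep(rep(0:3, times = 4L), times = as.vector(counts))
  t_stage <- rep(rep(1:4, each = 4L), times = as.vector(counts))
  n_tumor <- length(n_stage)
  sample_id <- c(sprintf("TUM%03d", seq_len(n_tumor)),
                 sprintf("NRM%03d", seq_len(config$n_normals)))
  annotations <- data.frame(
    sample_id = sample_id,
    n_stage = c(n_stage, rep(NA_integer_, config$n_normals)),
    t_stage = c(t_stage, rep(NA_integer_, config$n_normals)),
    metastatic = c(rep(FALSE, n_tumor), rep(NA, config$n_normals)),
    is_normal = c(rep(FALSE, n_tumor), rep(TRUE, config$n_normals)),
    stringsAsFactors = FALSE)

  archetypes <- rep(c("mono_up", "mono_down", "leap", "fluct", "mono_up_T", "null"),
                    times = c(config$n_mono_up, config$n_mono_down, config$n_leap,
                              config$n_fluct, config$n_mono_up_t, config$n_null))
  n_genes <- length(archetypes)
  genes <- sprintf("G%05d", seq_len(n_genes))
  truth <- data.frame(
    gene = genes, archetype = archetypes,
    direction = c(mono_up = 1, mono_down = -1, leap = 1, fluct = 0,
                  mono_up_T = 1, null = 0)[archetypes],
    transition = ifelse(archetypes == "leap", config$leap_transition, NA_integer_),
    stringsAsFactors = FALSE)

  # archetype effect per gene x tumor sample
  effect <- matrix(0, n_genes, n_tumor)
  eff_row <- function(arch) which(archetypes == arch)
  d <- config$delta
  effect[eff_row("mono_up"), ] <- rep(d * (n_stage + 1), each = config$n_mono_up)
  effect[eff_row("mono_down"), ] <- rep(-d * (n_stage + 1), each = config$n_mono_down)
  effect[eff_row("leap"), ] <- rep(config$leap_height *
                                     (n_stage > config$leap_transition),
                                   each = config$n_leap)
  effect[eff_row("fluct"), ] <- rep(d * (n_stage %% 2 == 0), each = config$n_fluct)
  effect[eff_row("mono_up_T"), ] <- rep(d * t_stage, each = config$n_mono_up_t)

  baseline <- rnorm(n_genes, mean = 8, sd = 0.5)
  n_total <- n_tumor + config$n_normals
  expr <- matrix(rnorm(n_genes * n_total, sd = config$sigma), n_genes, n_total,
                 dimnames = list(genes, sample_id))
  expr <- expr + baseline
  expr[, seq_len(n_tumor)] <- expr[, seq_len(n_tumor)] + effect
  list(expr = expr, annotations = annotations, truth = truth)
}

#' Simulate directional p-value tables with optional background bias
#'
#' Emulates a compendium of pre-analyzed differential-expression tables.
#' Genes in \code{enriched_set} draw their one-tailed p (toward
#' up-regulation) from a Beta(\code{effect_a}, 1) law; null genes draw
#' Uniform(0,1), except that in each experiment a random
#' \code{bias_fraction} of them also draw from the Beta law, injecting the
#' kind of upward background shift observed in real compendia.  Two-tailed
#' p-values and reported directions are derived consistently, so the
#' one-tailed conversion recovers the planted value.
#'
#' @param n_genes universe size per experiment.
#' @param n_experiments number of experiments.
#' @param enriched_set character vector of planted genes (subset of the
#'   universe \code{G00001..}), or NULL / empty for none.
#' @param effect_a Beta shape in (0, 1]; smaller = stronger enrichment.
#' @param bias_fraction fraction of null genes drawn up-shifted, in [0, 1).
#' @param seed RNG seed.
#' @param analysis_class class label stamped on every table.
#' @return list: \code{experiments} (list of \code{ExperimentTable}),
#'   \code{truth} (data.frame gene, enriched).
#' @export
simulate_pvalue_tables <- function(n_genes = 5000L, n_experiments = 5L,
                                   enriched_set = NULL, effect_a = 1,
                                   bias_fraction = 0, seed = 1L,
                                   analysis_class = "MP") {
  stopifnot(effect_a > 0, effect_a <= 1,
            bias_fraction >= 0, bias_fraction < 1)
  genes <- sprintf("G%05d", seq_len(n_genes))
  enriched_set <- as.character(enriched_set)
  if (length(enriched_set) && !all(enriched_set %in% genes))
    stop("enriched set contains genes outside the universe")
  set.seed(seed)
  enriched <- genes %in% enriched_set
  experiments <- lapply(seq_len(n_experiments), function(j) {
    p1 <- runif(n_genes)
    nulls <- which(!enriched)
    n_bias <- round(bias_fraction * length(nulls))
    if (n_bias > 0L) {
      biased <- sample(nulls, n_bias)
      p1[biased] <- rbeta(n_bias, effect_a, 1)
    }
    if (any(enriched)) p1[enriched] <- rbeta(sum(enriched), effect_a, 1)
    direction <- ifelse(p1 <= 0.5, "up", "down")
    p_two <- ifelse(p1 <= 0.5, 2 * p1, 2 * (1 - p1))
    p_two <- pmin(pmax(p_two, 1e-300), 1)
    experiment_table(sprintf("EXP%02d", j), analysis_class,
                     data.frame(gene = genes, p_two = p_two,
                                direction = direction, stringsAsFactors = FALSE))
  })
  list(experiments = experiments,
       truth = data.frame(gene = genes, enriched = enriched,
                          stringsAsFactors = FALSE))
}

#' Simulate a prognosis cohort linked to a gene signature
#'
#' Each sample carries a latent risk \code{u ~ N(0,1)}.  Signature genes
#' track it (positively for the plus set, negatively for the minus set) with
#' Gaussian noise; decoy genes are independent noise.  The binary outcome is
#' drawn with probability \code{plogis(slope * s)} where \code{s} is the
#' standardized signed z-sum of the planted signature, so \code{slope = 0}
#' gives outcomes independent of the score.
#'
#' @param n_samples cohort size.
#' @param signature list with character vectors \code{plus} and \code{minus}.
#' @param slope logistic link slope (>= 0).
#' @param seed RNG seed.
#' @param n_decoys independent decoy genes added to the matrix (default 200).
#' @param loading latent-risk loading per signature gene (default 1).
#' @param sigma residual noise SD (default 0.5).
#' @return list: \code{expr}, \code{outcomes} (data.frame sample_id, event),
#'   \code{truth} (gene, role).
#' @export
simulate_prognosis <- function(n_samples = 286L, signature, slope = 1.5,
                               seed = 1L, n_decoys = 200L, loading = 1,
                               sigma = 0.5) {
  stopifnot(slope >= 0)
  plus <- signature$plus; minus <- signature$minus
  if (length(plus) + length(minus) == 0L) stop("empty signature")
  set.seed(seed)
  u <- rnorm(n_samples)
  decoys <- sprintf("DEC%04d", seq_len(n_decoys))
  genes <- c(plus, minus, decoys)
  sample_id <- sprintf("PAT%04d", seq_len(n_samples))
  sign_load <- c(rep(loading, length(plus)), rep(-loading, length(minus)),
                 rep(0, n_decoys))
  expr <- outer(sign_load, u) +
    matrix(rnorm(length(genes) * n_samples, sd = sigma),
           length(genes), n_samples) + 8
  dimnames(expr) <- list(genes, sample_id)
  s <- risk_scores(zscore_rows(expr), plus, minus)
  s <- as.vector(scale(s))
  event <- rbinom(n_samples, 1L, plogis(slope * s))
  list(expr = expr,
       outcomes = data.frame(sample_id = sample_id, event = event,
                             stringsAsFactors = FALSE),
       truth = data.frame(gene = genes,
                          role = rep(c("plus", "minus", "decoy"),
                                     c(length(plus), length(minus), n_decoys)),
                          stringsAsFactors = FALSE))
}
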