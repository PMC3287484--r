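#' Strict signum
#'
#' Sign function used by the consistency term of the monotonicity score.
#' Strict: no tolerance around zero.
#'
#' @param d finite numeric vector.
#' @return -1, 0 or +1 per element.
#' @export
mega_sign <- function(d) {
  if (any(!is.finite(d))) stop("sign undefined for non-finite input")
  sign(d)
}

#' Construct a leaping-factor matrix
#'
#' The leaping factor up-weights one consecutive stage transition so that
#' genes jumping at that transition rise in the ranking.  Entries off the
#' consecutive superdiagonal are always 1.  Stage transition \code{N<a> ->
#' N<a+1>} maps to grid rows \code{a+1 -> a+2} (0-based \code{a+1 -> b+1})
#' because grid row 0 is the normal baseline.
#'
#' @param p number of stages (grid has p+1 rows).
#' @param transition length-2 integer vector \code{c(a, b)} of consecutive
#'   stage indices (e.g. \code{c(1, 2)} for N1 -> N2), or NULL for the
#'   all-ones matrix.
#' @param weight positive weight for that transition.
#' @return \code{(p+1) x (p+1)} matrix of class \code{beta_matrix}.
#' @examples
#' b <- make_beta(4, c(1, 2), 10)  # leap at N1 -> N2
#' b[3, 4]  # the weighted consecutive entry
#' @export
make_beta <- function(p = 4L, transition = NULL, weight = 1) {
  B <- matrix(1, p + 1L, p + 1L)
  if (!is.null(transition)) {
    if (length(transition) != 2L || transition[2L] != transition[1L] + 1L)
      stop("leaping factor applies only to consecutive stage transitions")
    a <- transition[1L]
    if (a < 0L || a + 1L > p - 1L)
      stop("transition outside stage range 0..", p - 1L)
    if (weight < 0) stop("leaping weight must be non-negative")
    B[a + 2L, a + 3L] <- weight
  }
  structure(B, class = c("beta_matrix", "matrix"))
}

check_beta <- function(beta, p) {
  if (is.null(beta)) return(make_beta(p))
  if (!is.matrix(beta) || any(dim(beta) != p + 1L))
    stop("beta must be a (p+1) x (p+1) matrix")
  off <- beta
  off[cbind(1:p, 2:(p + 1L))] <- 1
  if (any(off != 1))
    stop("beta entries off the consecutive superdiagonal must equal 1")
  if (any(beta[cbind(1:p, 2:(p + 1L))] < 0))
    stop("consecutive beta entries must be non-negative")
  beta
}

#' Raw monotonicity score of a stage grid along one axis
#'
#' Accumulates, for every stage column of the progression axis, the
#' differences between each stage and all earlier stages (starting from the
#' normal baseline): \code{sum over t, over i < j of w(i,j) * (x[j,t] -
#' x[i,t])}, where \code{w(i,j)} is the leaping factor for the consecutive
#' pair \code{j = i + 1} and 1 otherwise.  Monotone columns accumulate;
#' fluctuating columns cancel.  Terms touching a missing cell are skipped.
#'
#' The consistency factor \code{alpha} multiplies each pairwise term by
#' \code{1 + alpha * S(x_j - x_i) * S(x_j - x_{j-1})}, rewarding pairs whose
#' long-range and one-step changes agree in direction; at \code{alpha = 0}
#' (the default used throughout) this reduces exactly to the plain sum.  The
#' alpha term is exposed as an experimental hook.
#'
#' @param grid a \code{StageGrid}.
#' @param axis "N" (progression down the rows) or "T" (down the columns).
#' @param beta leaping-factor matrix from \code{\link{make_beta}}, or NULL
#'   for all ones.
#' @param alpha consistency factor, >= 0; default 0.
#' @return raw score (log2 fold-change units).
#' @export
axis_score <- function(grid, axis = c("N", "T"), beta = NULL, alpha = 0) {
  axis <- match.arg(axis)
  stopifnot(inherits(grid, "StageGrid"), alpha >= 0)
  X <- grid$X
  miss <- grid$missing
  if (axis == "T") {
    X <- t(X)
    miss <- t(miss)
  }
  p <- nrow(X) - 1L
  q <- ncol(X) - 1L
  beta <- check_beta(beta, p)
  tumor <- X[-1L, -1L]
  if (all(miss[-1L, -1L]) || all(is.na(tumor)))
    stop("all tumor cells missing for gene ", grid$gene_id)
  total <- 0
  for (t in 0:q) {
    col <- X[, t + 1L]
    m <- miss[, t + 1L]
    for (j in 1:p) {
      if (m[j + 1L]) next
      for (i in 0:(j - 1L)) {
        if (m[i + 1L]) next
        d <- col[j + 1L] - col[i + 1L]
        w <- if (j == i + 1L) beta[i + 1L, j + 1L] else 1
        term <- w * d
        if (alpha != 0) {
          step <- if (m[j]) 0 else sign(col[j + 1L] - col[j])
          term <- term * (1 + alpha * sign(d) * step)
        }
        total <- total + term
      }
    }
  }
  total
}

#' Closed-form column contrast (verification oracle)
#'
#' For a complete column with unit leaping factors and \code{alpha = 0}, the
#' pairwise accumulation over all \code{i < j} collapses algebraically to the
#' linear contrast \code{sum_j (2j - p) * x_j} (j = 0..p).  Kept as an
#' independent closed form against which the pairwise score is verified.
#'
#' @param column numeric vector of length p+1 (baseline first).
#' @param p number of stages; default \code{length(column) - 1}.
#' @return the contrast value.
#' @export
column_contrast <- function(column, p = length(column) - 1L) {
  stopifnot(length(column) == p + 1L)
  sum((2 * (0:p) - p) * column)
}

#' Normalize a raw monotonicity score by the grid's overall spread
#'
#' Divides the raw score by the overall standard deviation (denominator n-1)
#' of the grid matrix -- all non-missing cells, including the zero baseline
#' row and column -- so that genes are ranked by the shape of their stage
#' profile rather than its amplitude.  Keeping the baseline cells in the
#' spread is essential: it anchors the denominator to the fold-change scale,
#' so a gene that is merely offset from normal but flat across stages has a
#' bounded normalized score instead of a noise-over-noise ratio.  Degenerate
#' grids (all-zero, or fewer than 2 non-missing cells) normalize to 0.
#'
#' @param raw raw score from \code{\link{axis_score}}.
#' @param grid the \code{StageGrid} the score was computed on.
#' @return list of class \code{GeneScore}: \code{gene_id}, \code{raw},
#'   \code{normalized}, \code{sd_used}, \code{direction}.
#' @export
normalize_score <- function(raw, grid) {
  stopifnot(inherits(grid, "StageGrid"))
  cells <- grid$X[!grid$missing]
  cells <- cells[!is.na(cells)]
  s <- if (length(cells) >= 2L) sd(cells) else 0
  norm <- if (is.na(s) || s == 0) 0 else raw / s
  structure(list(gene_id = grid$gene_id, raw = raw, normalized = norm,
                 sd_used = s, direction = sign(norm)),
            class = "GeneScore")
}

#' Score all genes by stage-progression monotonicity
#'
#' Full scoring pass: filter samples, assign N x T classes, build per-gene
#' grids of mean log2 fold-change versus normal, and compute the raw and
#' SD-normalized monotonicity score of every gene along the chosen axis.
#' Genes with more than half their tumor cells missing are scored but flagged
#' \code{excluded} and left out of ranking by \code{\link{select_meg}}.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param annotations sample annotation data.frame.
#' @param axis "N" or "T".
#' @param beta optional leaping-factor matrix (\code{\link{make_beta}}).
#' @param alpha consistency factor; default 0.
#' @param p,q stage counts.
#' @return data.frame (one row per gene): gene, raw, normalized, sd,
#'   direction, n_missing, excluded, axis.
#' @export
mega_score <- function(expr, annotations, axis = c("N", "T"), beta = NULL,
                       alpha = 0, p = 4L, q = 4L) {
  axis <- match.arg(axis)
  check_expression(expr)
  flt <- filter_samples(annotations)
  cmap <- assign_classes(annotations, flt$kept, p = p, q = q)
  normal_ids <- intersect(
    annotations$sample_id[annotations$is_normal %in% TRUE], flt$kept)
  normal_ids <- intersect(normal_ids, colnames(expr))
  b <- grid_builder(expr, cmap, normal_ids, p, q)
  genes <- rownames(expr)
  miss_cells <- matrix(b$counts == 0L, p, q)
  miss_template <- matrix(FALSE, p + 1L, q + 1L)
  miss_template[2:(p + 1L), 2:(q + 1L)] <- miss_cells
  counts_template <- matrix(0L, p + 1L, q + 1L)
  counts_template[2:(p + 1L), 2:(q + 1L)] <- b$counts
  counts_template[1L, 1L] <- length(normal_ids)
  n_missing <- sum(miss_cells)
  res <- lapply(seq_along(genes), function(g) {
    X <- matrix(0, p + 1L, q + 1L)
    X[2:(p + 1L), 2:(q + 1L)] <- matrix(b$cell_means[g, ], p, q) - b$normal_means[g]
    grid <- structure(list(gene_id = genes[g], p = p, q = q, X = X,
                           counts = counts_template, missing = miss_template),
                      class = "StageGrid")
    raw <- axis_score(grid, axis = axis, beta = beta, alpha = alpha)
    normalize_score(raw, grid)
  })
  out <- data.frame(
    gene = genes,
    raw = vapply(res, `[[`, numeric(1), "raw"),
    normalized = vapply(res, `[[`, numeric(1), "normalized"),
    sd = vapply(res, `[[`, numeric(1), "sd_used"),
    direction = vapply(res, `[[`, numeric(1), "direction"),
    n_missing = n_missing,
    excluded = n_missing > (p * q) / 2,
    axis = axis,
    stringsAsFactors = FALSE
  )
  if (any(out$excluded))
    message(sum(out$excluded), " gene(s) excluded from ranking: >50% of stage cells empty")
  out
}

#' Select the top monotonically expressed genes in each direction
#'
#' MEG+ holds the k genes with the largest normalized score (rising with
#' stage), MEG- the k most negative (falling).  Ties at a boundary are broken
#' by gene symbol, ascending.  Genes flagged \code{excluded} never enter.
#'
#' @param scores data.frame from \code{\link{mega_score}}.
#' @param k genes per direction (default 20).
#' @param axis axis label used to name the sets ("N" -> "N-MEG+").
#' @return list with character vectors \code{plus} and \code{minus}, plus the
#'   set names in \code{names_plus} / \code{names_minus}.
#' @export
select_meg <- function(scores, k = 20L, axis = scores$axis[1]) {
  stopifnot(k >= 1L)
  sc <- scores[!scores$excluded, , drop = FALSE]
  if (nrow(sc) < 2L * k)
    stop("need at least ", 2L * k, " scored genes, have ", nrow(sc))
  up <- sc[order(-sc$normalized, sc$gene), ]
  dn <- sc[order(sc$normalized, sc$gene), ]
  plus <- up$gene[seq_len(k)]
  minus <- dn$gene[seq_len(k)]
  if (length(intersect(plus, minus)))
    stop("MEG+ and MEG- overlap; too few distinct scores")
  list(plus = plus, minus = minus,
       names_plus = paste0(axis, "-MEG+"), names_minus = paste0(axis, "-MEG-"))
}
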