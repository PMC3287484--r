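#' Filter samples for stage-progression analysis
#'
#' Tumor samples enter the stage grid only when both pathological stages are
#' recorded and the tumor is non-metastatic; normal samples are always kept
#' (they form the fold-change baseline and carry no stage).
#'
#' @param annotations data.frame with columns \code{sample_id},
#'   \code{n_stage} (integer 0--3 or NA), \code{t_stage} (integer 1--4 or
#'   NA), \code{metastatic} (logical or NA) and \code{is_normal} (logical).
#' @return list with \code{kept} (character vector of sample ids) and
#'   \code{removed} (data.frame of \code{sample_id}, \code{reason}).
#' @examples
#' ann <- data.frame(sample_id = c("s1", "s2", "s3"),
#'                   n_stage = c(0, NA, 2), t_stage = c(1, 2, 3),
#'                   metastatic = c(FALSE, FALSE, TRUE),
#'                   is_normal = FALSE)
#' filter_samples(ann)$removed
#' @export
filter_samples <- function(annotations) {
  check_annotations(annotations)
  kept <- character(0)
  removed_id <- character(0)
  removed_reason <- character(0)
  for (r in seq_len(nrow(annotations))) {
    row <- annotations[r, ]
    if (isTRUE(row$is_normal)) {
      kept <- c(kept, row$sample_id)
      next
    }
    reason <- NULL
    if (is.na(row$n_stage)) {
      reason <- "missing N stage"
    } else if (is.na(row$t_stage)) {
      reason <- "missing T stage"
    } else if (is.na(row$metastatic)) {
      reason <- "missing metastatic status"
    } else if (isTRUE(row$metastatic)) {
      reason <- "metastatic"
    }
    if (is.null(reason)) {
      kept <- c(kept, row$sample_id)
    } else {
      removed_id <- c(removed_id, row$sample_id)
      removed_reason <- c(removed_reason, reason)
    }
  }
  list(kept = kept,
       removed = data.frame(sample_id = removed_id, reason = removed_reason,
                            stringsAsFactors = FALSE))
}

check_annotations <- function(annotations) {
  if (!is.data.frame(annotations) || nrow(annotations) == 0L)
    stop("annotation table is empty")
  need <- c("sample_id", "n_stage", "t_stage", "metastatic", "is_normal")
  miss <- setdiff(need, names(annotations))
  if (length(miss))
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(annotations$sample_id))
    stop("duplicate sample_id in annotation table")
  invisible(annotations)
}

#' Assign filtered tumor samples to N x T stage classes
#'
#' Partitions tumor samples into at most \code{p * q} classes keyed by
#' \code{"N<i>T<j>"}.  Classes with no samples are absent from the map rather
#' than present as empty entries.
#'
#' @param annotations annotation data.frame (see \code{\link{filter_samples}});
#'   only rows whose \code{sample_id} is in \code{sample_ids} and that are not
#'   normals are assigned.
#' @param sample_ids samples to assign (typically the \code{kept} element of
#'   \code{\link{filter_samples}}); default all samples in the table.
#' @param p,q number of N stages (N0..N\code{p-1}) and T stages
#'   (T1..T\code{q}).
#' @return named list mapping "N<i>T<j>" to character vectors of sample ids.
#' @export
assign_classes <- function(annotations, sample_ids = annotations$sample_id,
                           p = 4L, q = 4L) {
  check_annotations(annotations)
  ann <- annotations[annotations$sample_id %in% sample_ids &
                       !annotations$is_normal, , drop = FALSE]
  bad <- !(ann$n_stage %in% 0:(p - 1L)) | !(ann$t_stage %in% 1:q)
  if (any(bad))
    stop("stage value out of range for sample(s): ",
         paste(ann$sample_id[bad], collapse = ", "))
  key <- sprintf("N%dT%d", ann$n_stage, ann$t_stage)
  split(ann$sample_id, key)
}

#' Build the per-gene stage grid of mean log2 fold-changes
#'
#' The grid for one gene is a \code{(p+1) x (q+1)} matrix \code{X} whose row
#' \code{i+1}, column \code{j+1} (for stages N\code{i-1}, T\code{j}) holds the
#' mean log2 expression of the tumor samples in that class minus the mean of
#' the normal samples.  Row 1 and column 1 are the normal baseline and are
#' fixed at 0 (a normal sample has no stage, and its fold-change against
#' itself is zero by definition).  Empty tumor cells are flagged missing.
#'
#' @param expr genes x samples numeric matrix of log2 expression, with gene
#'   symbols as rownames and sample ids as colnames.
#' @param class_map named list from \code{\link{assign_classes}}.
#' @param normal_ids character vector of normal sample ids (at least one).
#' @param gene gene symbol present in \code{rownames(expr)}.
#' @param p,q stage counts as in \code{\link{assign_classes}}.
#' @return object of class \code{StageGrid}: list with \code{gene_id},
#'   \code{p}, \code{q}, \code{X}, \code{counts} and logical \code{missing}
#'   (baseline cells are never missing).
#' @export
build_stage_grid <- function(expr, class_map, normal_ids, gene,
                             p = 4L, q = 4L) {
  check_expression(expr)
  if (!gene %in% rownames(expr)) stop("gene not found in expression matrix: ", gene)
  b <- grid_builder(expr, class_map, normal_ids, p, q)
  g <- match(gene, rownames(expr))
  X <- matrix(0, p + 1L, q + 1L)
  X[2:(p + 1L), 2:(q + 1L)] <- matrix(b$cell_means[g, ], p, q) - b$normal_means[g]
  miss <- matrix(FALSE, p + 1L, q + 1L)
  miss[2:(p + 1L), 2:(q + 1L)] <- b$counts == 0L
  X[miss] <- NA_real_
  counts <- matrix(0L, p + 1L, q + 1L)
  counts[2:(p + 1L), 2:(q + 1L)] <- b$counts
  counts[1L, 1L] <- length(normal_ids)
  structure(list(gene_id = gene, p = p, q = q, X = X, counts = counts,
                 missing = miss),
            class = "StageGrid")
}

check_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(expr))) stop("duplicate sample ids")
  invisible(expr)
}

# Shared vectorized builder: per-cell means/counts for ALL genes at once.
# Returns cell_means (genes x p*q, column-major over (n, t) cells with n
# fastest), counts (p x q) and normal_means (per gene).
grid_builder <- function(expr, class_map, normal_ids, p = 4L, q = 4L) {
  if (length(normal_ids) == 0L) stop("no normal samples")
  if (!all(normal_ids %in% colnames(expr)))
    stop("normal sample(s) absent from expression matrix")
  keys <- as.vector(outer(0:(p - 1L), 1:q, function(i, j) sprintf("N%dT%d", i, j)))
  counts <- integer(length(keys))
  cell_means <- matrix(NA_real_, nrow(expr), length(keys))
  for (c_idx in seq_along(keys)) {
    ids <- class_map[[keys[c_idx]]]
    if (is.null(ids) || length(ids) == 0L) next
    if (!all(ids %in% colnames(expr)))
      stop("class ", keys[c_idx], " references samples absent from expression")
    counts[c_idx] <- length(ids)
    cell_means[, c_idx] <- rowMeans(expr[, ids, drop = FALSE])
  }
  list(cell_means = cell_means,
       counts = matrix(counts, p, q),
       normal_means = rowMeans(expr[, normal_ids, drop = FALSE]),
       keys = keys, p = p, q = q)
}

#' @export
print.StageGrid <- function(x, ...) {
  cat("StageGrid for", x$gene_id, sprintf("(%d N stages x %d T stages)\n", x$p, x$q))
  X <- round(x$X, 3)
  dimnames(X) <- list(c("normal", paste0("N", 0:(x$p - 1L))),
                      c("normal", paste0("T", 1:x$q)))
  print(X)
  invisible(x)
}

#' Export stage grids in long format
#'
#' @param grids list of \code{StageGrid} objects.
#' @return data.frame with columns gene, n, t, value, count; baseline row and
#'   column are omitted (they are identically zero), and n/t are the stage
#'   labels N0..N3 / T1..T4.
#' @export
grids_to_long <- function(grids) {
  do.call(rbind, lapply(grids, function(g) {
    idx <- expand.grid(i = 1:g$p, j = 1:g$q)
    data.frame(gene = g$gene_id,
               n = paste0("N", idx$i - 1L),
               t = paste0("T", idx$j),
               value = g$X[cbind(idx$i + 1L, idx$j + 1L)],
               count = g$counts[cbind(idx$i + 1L, idx$j + 1L)],
               stringsAsFactors = FALSE)
  }))
}
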