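# Shared in-code fixtures: tiny annotation tables and hand-built stage grids.

tumor_ann <- function(sample_id, n, t, metastatic = FALSE) {
  data.frame(sample_id = sample_id, n_stage = n, t_stage = t,
             metastatic = metastatic, is_normal = FALSE,
             stringsAsFactors = FALSE)
}

normal_ann <- function(sample_id) {
  data.frame(sample_id = sample_id, n_stage = NA_integer_,
             t_stage = NA_integer_, metastatic = NA, is_normal = TRUE,
             stringsAsFactors = FALSE)
}

# StageGrid straight from a (p+1) x (q+1) matrix (row/col 1 = baseline 0).
# NA cells are flagged missing.
make_grid <- function(X, gene = "G1") {
  stopifnot(all(X[1, ] == 0, na.rm = TRUE), all(X[, 1] == 0, na.rm = TRUE))
  miss <- is.na(X)
  miss[1, ] <- FALSE
  miss[, 1] <- FALSE
  counts <- matrix(1L, nrow(X), ncol(X))
  counts[miss] <- 0L
  structure(list(gene_id = gene, p = nrow(X) - 1L, q = ncol(X) - 1L,
                 X = X, counts = counts, missing = miss),
            class = "StageGrid")
}

# Grid whose first stage column holds `column` and all other cells are 0.
column_grid <- function(column, q = 4L) {
  p <- length(column) - 1L
  X <- matrix(0, p + 1L, q + 1L)
  X[, 2L] <- column
  make_grid(X)
}

random_grid <- function(p = 4L, q = 4L) {
  X <- matrix(rnorm((p + 1L) * (q + 1L)), p + 1L, q + 1L)
  X[1, ] <- 0
  X[, 1] <- 0
  make_grid(X)
}

# Direct PValueMatrix from a vector/matrix of one-tailed p-values.
pm_from <- function(p, tested_direction = "up") {
  P <- as.matrix(p)
  if (is.null(rownames(P))) rownames(P) <- paste0("g", seq_len(nrow(P)))
  structure(list(gene_set = rownames(P), P = P, nk = sum(!is.na(P)),
                 tested_direction = tested_direction,
                 experiment_ids = paste0("e", seq_len(ncol(P))),
                 analysis_classes = rep("MP", ncol(P))),
            class = "PValueMatrix")
}
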