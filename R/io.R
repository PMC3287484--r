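#' Read a log2 expression matrix from TSV
#'
#' Expected layout: first column gene symbols, header row of sample ids,
#' tab-separated, "." decimal, no quoting.  Lines starting with "#" are
#' treated as comments.
#'
#' @param path file path.
#' @return genes x samples numeric matrix.
#' @export
read_expression <- function(path) {
  df <- read_tsv_checked(path, "expression")
  genes <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric expression values in ", path)
  rownames(m) <- genes
  check_expression(m)
  m
}

#' Write a log2 expression matrix to TSV
#' @param expr genes x samples matrix.
#' @param path file path.
#' @param header optional comment lines (without the leading "#").
#' @export
write_expression <- function(expr, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  writeLines(paste(c("gene", colnames(expr)), collapse = "\t"), con)
  write.table(data.frame(gene = rownames(expr), expr, check.names = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Read a sample annotation table from TSV
#'
#' Columns: sample_id, n_stage, t_stage, metastatic, is_normal; empty string
#' means missing.
#'
#' @param path file path.
#' @return data.frame with typed columns.
#' @export
read_annotations <- function(path) {
  df <- read_tsv_checked(path, "annotation")
  need <- c("sample_id", "n_stage", "t_stage", "metastatic", "is_normal")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$n_stage <- as.integer(df$n_stage)
  df$t_stage <- as.integer(df$t_stage)
  df$metastatic <- as.logical(df$metastatic)
  df$is_normal <- as.logical(df$is_normal)
  df
}

#' Write a data.frame as TSV (tab-separated, no quoting)
#' @param df data.frame.
#' @param path file path.
#' @param header optional comment lines (without the leading "#").
#' @export
write_tsv <- function(df, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

read_tsv_checked <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- tryCatch(
    read.delim(path, sep = "\t", comment.char = "#", check.names = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) stop("malformed ", what, " TSV ", path, ": ",
                             conditionMessage(e)))
  if (nrow(df) == 0L) stop(what, " file ", path, " has no data rows")
  df
}

#' Read gene sets from a GMT file
#'
#' Broad convention: one set per line -- name, description, then member
#' genes, tab-separated.
#'
#' @param path file path.
#' @return named list of character vectors; descriptions in attribute
#'   \code{descriptions}.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields")
    sets[[parts[1L]]] <- parts[-(1:2)]
    desc[parts[1L]] <- parts[2L]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path file path.
#' @param descriptions optional character vector aligned to \code{sets}.
#' @export
write_gmt <- function(sets, path, descriptions = rep("na", length(sets))) {
  stopifnot(!is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an experiment table (TSV + JSON sidecar)
#'
#' The TSV holds columns gene, p_two, direction; the sidecar
#' \code{<path>.json} holds experiment_id, analysis_class and optionally a
#' universe file (one gene per line).  Without a sidecar, id and class must
#' be given explicitly.
#'
#' @param path TSV path.
#' @param experiment_id,analysis_class overrides / fallbacks for the sidecar.
#' @return an \code{ExperimentTable}.
#' @export
read_experiment_table <- function(path, experiment_id = NULL,
                                  analysis_class = NULL) {
  tab <- read_tsv_checked(path, "experiment")
  need <- c("gene", "p_two", "direction")
  if (!all(need %in% names(tab)))
    stop("experiment file ", path, " lacks column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  sidecar <- paste0(path, ".json")
  universe <- tab$gene
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(experiment_id)) experiment_id <- meta$experiment_id
    if (is.null(analysis_class)) analysis_class <- meta$analysis_class
    if (!is.null(meta$universe_file)) {
      upath <- file.path(dirname(path), meta$universe_file)
      universe <- readLines(upath)
    }
  }
  if (is.null(experiment_id) || is.null(analysis_class))
    stop("experiment_id / analysis_class missing for ", path,
         " (no JSON sidecar found)")
  experiment_table(experiment_id, analysis_class, tab, universe)
}

#' Write an experiment table with its JSON sidecar
#' @param exp an \code{ExperimentTable}.
#' @param path TSV path; the sidecar goes to \code{<path>.json}.
#' @export
write_experiment_table <- function(exp, path) {
  stopifnot(inherits(exp, "ExperimentTable"))
  write_tsv(exp$table, path)
  meta <- list(experiment_id = exp$experiment_id,
               analysis_class = exp$analysis_class)
  if (!identical(exp$universe, exp$table$gene)) {
    ufile <- paste0(basename(path), ".universe")
    writeLines(exp$universe, file.path(dirname(path), ufile))
    meta$universe_file <- ufile
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a binary outcome table (sample_id, event)
#' @param path TSV path.
#' @return data.frame with character sample_id and integer event.
#' @export
read_outcomes <- function(path) {
  df <- read_tsv_checked(path, "outcome")
  if (!all(c("sample_id", "event") %in% names(df)))
    stop("outcome file ", path, " needs columns sample_id, event")
  df$sample_id <- as.character(df$sample_id)
  df$event <- as.integer(df$event)
  if (any(!df$event %in% c(0L, 1L)))
    stop("outcome events must be 0/1")
  df
}
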