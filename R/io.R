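#' Read a methylation matrix
#'
#' First column: probe id; remaining columns: samples. Separator inferred from
#' the extension (`.csv` comma, otherwise tab). Lines starting with `#` are
#' ignored.
#'
#' @param path file path.
#' @return Numeric matrix, probes x samples, with probe ids as rownames.
#' @export
read_methylation_matrix <- function(path) {
  if (!file.exists(path)) stop("methylation matrix not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("matrix needs a probe-id column plus sample columns")
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in methylation matrix")
  rownames(m) <- ids
  m
}

#' Write a methylation matrix
#'
#' @param m probes x samples matrix with probe-id rownames.
#' @param path output path (`.csv` comma-separated, otherwise tab).
#' @param comments optional character vector of `#`-prefixed header lines.
#' @export
write_methylation_matrix <- function(m, path, comments = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated with header `sample_id`, `condition`, optional covariate
#' columns, and an optional `subject` column for paired designs.
#'
#' @param path file path.
#' @param samples optional character vector of sample ids (e.g. matrix column
#'   names) the sheet must cover, in that order; an error names any missing
#'   sample.
#' @return A [design_info()] with the sheet attached as attribute `"sheet"`.
#' @export
read_sample_sheet <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "condition")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  if (!is.null(samples)) {
    absent <- setdiff(samples, tab$sample_id)
    if (length(absent)) stop("sample(s) missing from sheet: ",
                             paste(absent, collapse = ", "))
    tab <- tab[match(samples, tab$sample_id), , drop = FALSE]
  }
  covar_cols <- setdiff(names(tab), c("sample_id", "condition", "subject"))
  d <- design_info(condition = tab$condition,
                   covariates = if (length(covar_cols)) tab[covar_cols] else NULL,
                   subject = if ("subject" %in% names(tab)) tab$subject else NULL)
  attr(d, "sheet") <- tab
  d
}

#' Write the per-site inference table
#'
#' Columns: `probe_id,chrom,pos,S,p_xi,q_xi,p_raw,p_adj` (tab-separated).
#'
#' @param sites `sites` component of a [detect_dmrs()] fit.
#' @param path output path.
#' @param comments optional `#`-prefixed provenance lines.
#' @export
write_site_table <- function(sites, path, comments = NULL) {
  cols <- c("probe_id", "chrom", "pos", "S", "p_xi", "q_xi", "p_raw", "p_adj")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(sites[, cols], con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the DMR table
#'
#' Columns: `chrom,start,end,n_probes,p_rep,p_rep_adj,rank` (tab-separated).
#'
#' @param dmrs a `dmr_table` from [agglomerate()].
#' @param path output path.
#' @param comments optional `#`-prefixed provenance lines.
#' @export
write_dmr_table <- function(dmrs, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(as.data.frame(dmrs), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a DMR/calls table
#'
#' @param path tab-separated file with at least `chrom,start,end` columns;
#'   `#` comment lines are skipped.
#' @return Data frame of calls.
#' @export
read_dmr_table <- function(path) {
  if (!file.exists(path)) stop("calls file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  miss <- setdiff(c("chrom", "start", "end"), names(tab))
  if (length(miss)) stop("calls table missing column(s): ", paste(miss, collapse = ", "))
  tab
}

#' Write / read a truth table
#'
#' Tab-separated `region_id,chrom,start,end,label`.
#'
#' @param truth labeled regions from [assign_truth()].
#' @param path file path.
#' @rdname truth_table
#' @export
write_truth_table <- function(truth, path) {
  cols <- c("region_id", "chrom", "start", "end", "label")
  utils::write.table(truth[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname truth_table
#' @export
read_truth_table <- function(path) {
  if (!file.exists(path)) stop("truth table not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  miss <- setdiff(c("chrom", "start", "end", "label"), names(tab))
  if (length(miss)) stop("truth table missing column(s): ", paste(miss, collapse = ", "))
  tab
}

#' Read a simulation configuration from YAML
#'
#' Top-level keys `layout:` (fields of [layout_config()]; `probes_per_chrom`
#' as a chromosome -> count mapping) and `sim:` (fields of [sim_config()]).
#' Missing fields take the defaults.
#'
#' @param path YAML file path.
#' @return List with elements `layout` ([layout_config()]) and `sim`
#'   ([sim_config()]).
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  lay_args <- cfg$layout
  if (!is.null(lay_args$probes_per_chrom))
    lay_args$probes_per_chrom <- unlist(lay_args$probes_per_chrom)
  layout <- do.call(layout_config, lay_args %||% list())
  sim <- do.call(sim_config, cfg$sim %||% list())
  list(layout = layout, sim = sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
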