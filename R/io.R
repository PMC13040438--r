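# TSV/JSON input and output for every artifact the pipeline exchanges.
# The tabular dialect is tab-separated, header row, UTF-8, '.' decimal;
# files written by the package start with '#'-prefixed provenance lines
# (tool version, seed) that every reader skips.

provenance_lines <- function(seed = NULL) {
  ver <- as.character(utils::packageVersion("acetoledger"))
  c(
    sprintf("# tool: acetoledger %s", ver),
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed))
  )
}

write_tsv_with_header <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a counts TSV into a count matrix
#'
#' Expects a `gene_id` column followed by one integer column per sample,
#' and a conditions table mapping sample names to
#' `reference`/`treatment`.
#'
#' @param counts_path Counts TSV (comment lines starting with `#` are
#'   skipped).
#' @param conditions_path Conditions TSV with columns `sample`,
#'   `condition`.
#' @return A [count_matrix()].
#' @export
read_counts_tsv <- function(counts_path, conditions_path) {
  df <- utils::read.delim(counts_path, comment.char = "#", check.names = FALSE)
  if (!"gene_id" %in% names(df)) stop(counts_path, ": no 'gene_id' column")
  cond <- utils::read.delim(conditions_path, comment.char = "#")
  if (!all(c("sample", "condition") %in% names(cond))) {
    stop(conditions_path, ": needs columns 'sample' and 'condition'")
  }
  samples <- setdiff(names(df), "gene_id")
  missing <- setdiff(samples, cond$sample)
  if (length(missing)) {
    stop(conditions_path, ": no condition for sample(s) ", paste(missing, collapse = ", "))
  }
  counts <- as.matrix(df[, samples, drop = FALSE])
  rownames(counts) <- df$gene_id
  count_matrix(counts, cond$condition[match(samples, cond$sample)])
}

#' Write a count matrix (plus conditions) to TSV
#'
#' @param m A [count_matrix()].
#' @param counts_path,conditions_path Output paths.
#' @param seed Optional seed recorded in the provenance header.
#' @return `counts_path`, invisibly.
#' @export
write_counts_tsv <- function(m, counts_path, conditions_path, seed = NULL) {
  df <- data.frame(gene_id = m$gene_ids, m$counts, check.names = FALSE)
  write_tsv_with_header(df, counts_path, seed)
  write_tsv_with_header(
    data.frame(sample = colnames(m$counts), condition = as.character(m$condition)),
    conditions_path, seed
  )
  invisible(counts_path)
}

#' Read a gene-category annotation TSV
#'
#' @param path TSV with columns `gene_id`, `category` (one row per
#'   gene-category pair; genes may recur).
#' @return A data frame.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#")
  if (!all(c("gene_id", "category") %in% names(df))) {
    stop(path, ": needs columns 'gene_id' and 'category'")
  }
  df
}

#' Read an assay trace TSV
#'
#' The file carries its assay metadata in `# key = value` header lines
#' (`epsilon`, `path_length`, `volume`, `protein_mass`,
#' `electrons_per_chromophore`) followed by `time_min` and `absorbance`
#' columns.
#'
#' @param path Trace TSV path.
#' @return An [assay_trace()].
#' @export
read_trace_tsv <- function(path) {
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in header) {
    kv <- regmatches(h, regexec("^#\\s*([a-z_]+)\\s*[=:]\\s*([-0-9.eE+]+)", h))[[1]]
    if (length(kv) == 3) meta[[kv[2]]] <- as.numeric(kv[3])
  }
  needed <- c("epsilon", "protein_mass")
  if (!all(needed %in% names(meta))) {
    stop(path, ": metadata header must provide ", paste(needed, collapse = ", "))
  }
  df <- utils::read.delim(text = lines[!grepl("^#", lines)])
  if (!all(c("time_min", "absorbance") %in% names(df))) {
    stop(path, ": needs columns 'time_min' and 'absorbance'")
  }
  assay_trace(
    df$time_min, df$absorbance,
    epsilon = meta$epsilon,
    path_length = if (is.null(meta$path_length)) 1 else meta$path_length,
    volume = if (is.null(meta$volume)) 1 else meta$volume,
    protein_mass = meta$protein_mass,
    electrons_per_chromophore =
      if (is.null(meta$electrons_per_chromophore)) 2 else meta$electrons_per_chromophore
  )
}

#' Write an assay trace TSV
#'
#' @param trace An [assay_trace()].
#' @param path Output path.
#' @param seed Optional seed for the provenance header.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(trace, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    provenance_lines(seed),
    sprintf("# epsilon = %g", trace$epsilon),
    sprintf("# path_length = %g", trace$path_length),
    sprintf("# volume = %g", trace$volume),
    sprintf("# protein_mass = %g", trace$protein_mass),
    sprintf("# electrons_per_chromophore = %g", trace$electrons_per_chromophore)
  ), con)
  utils::write.table(
    data.frame(time_min = trace$times, absorbance = trace$absorbance),
    con, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a growth curve TSV
#'
#' @param path TSV with columns `time_h`, `od600`.
#' @return A [growth_curve()].
#' @export
read_growth_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#")
  if (!all(c("time_h", "od600") %in% names(df))) {
    stop(path, ": needs columns 'time_h' and 'od600'")
  }
  growth_curve(df$time_h, df$od600)
}

#' Write a growth curve TSV
#'
#' @param curve A [growth_curve()].
#' @param path Output path.
#' @param seed Optional seed for the provenance header.
#' @return `path`, invisibly.
#' @export
write_growth_tsv <- function(curve, path, seed = NULL) {
  write_tsv_with_header(
    data.frame(time_h = curve$times, od600 = curve$od600), path, seed
  )
}

#' Write a report list as JSON with a provenance field
#'
#' @param x A list (e.g. from [ledger_report_as_list()]).
#' @param path Output path.
#' @param seed Optional seed recorded in the provenance block.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path, seed = NULL) {
  x$provenance <- list(
    tool = "acetoledger",
    version = as.character(utils::packageVersion("acetoledger")),
    seed = if (is.null(seed)) NA else as.integer(seed)
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a per-gene DEG results table to TSV
#'
#' Columns: `gene_id`, `base_mean_ref`, `base_mean_trt`, `log2fc`,
#' `pvalue`, `padj`, `is_deg`.
#'
#' @param result A `deg_result` from [classify_and_summarize()].
#' @param path Output path.
#' @param seed Optional provenance seed.
#' @return `path`, invisibly.
#' @export
write_deg_tsv <- function(result, path, seed = NULL) {
  stopifnot(inherits(result, "deg_result"))
  cols <- c("gene_id", "base_mean_ref", "base_mean_trt", "log2fc",
            "pvalue", "padj", "is_deg")
  write_tsv_with_header(result$table[, cols], path, seed)
}
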