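# Reading idxstats tables and writing result / metadata tables.

#' Read a samtools idxstats table
#'
#' The idxstats format has four tab-separated columns per line: reference
#' sequence name, sequence length, number of mapped read segments, number of
#' unmapped read segments. The samtools sentinel row `*` (the unmapped pool)
#' is retained in the table but is never treated as a chromosome.
#'
#' @param path file path.
#' @param sample_id sample identifier; defaults to the file name without the
#'   `.idxstats`/`.txt`/`.tsv` extension.
#' @return Object of class `hostsex_idxstats`: list with `sample_id` and
#'   `table`, a data frame with columns `id`, `length`, `mapped`, `unmapped`.
#' @export
read_idxstats <- function(path, sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- sub("\\.(idxstats|txt|tsv)$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L)
    hs_error(sprintf("%s: empty idxstats file", path), "hostsex_parse_error")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad))
    hs_error(sprintf("%s: line %d does not have 4 tab-separated fields",
                     path, which(keep)[bad[1]]),
             "hostsex_parse_error")
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  num <- suppressWarnings(list(length = as.numeric(m[, 2]),
                               mapped = as.numeric(m[, 3]),
                               unmapped = as.numeric(m[, 4])))
  bad <- which(!is.finite(num$length) | !is.finite(num$mapped) |
               !is.finite(num$unmapped) |
               num$length != round(num$length) | num$mapped != round(num$mapped))
  if (length(bad))
    hs_error(sprintf("%s: line %d has a non-integer count field",
                     path, which(keep)[bad[1]]),
             "hostsex_parse_error")
  if (any(num$mapped < 0 | num$unmapped < 0))
    hs_error(sprintf("%s: negative read count", path), "hostsex_parse_error")
  if (any(num$length <= 0 & m[, 1] != "*"))
    hs_error(sprintf("%s: non-positive length for a named sequence", path),
             "hostsex_parse_error")
  new_idxstats(sample_id,
               data.frame(id = m[, 1], length = num$length,
                          mapped = num$mapped, unmapped = num$unmapped,
                          stringsAsFactors = FALSE))
}

new_idxstats <- function(sample_id, table) {
  structure(list(sample_id = sample_id, table = table),
            class = "hostsex_idxstats")
}

#' @export
print.hostsex_idxstats <- function(x, ...) {
  usable <- x$table$id != "*"
  cat(sprintf("<hostsex_idxstats> sample '%s': %d sequences, %.0f mapped reads\n",
              x$sample_id, sum(usable), sum(x$table$mapped[usable])))
  invisible(x)
}

#' Write an idxstats table in samtools format
#' @param x a `hostsex_idxstats` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_idxstats <- function(x, path) {
  stopifnot(inherits(x, "hostsex_idxstats"))
  tab <- x$table
  writeLines(sprintf("%s\t%.0f\t%.0f\t%.0f",
                     tab$id, tab$length, tab$mapped, tab$unmapped), path)
  invisible(path)
}

#' Total host reads for a sample under a genome spec
#'
#' Sum of mapped reads over the spec's chromosomes with role other than
#' `"ignored"`. Reads on scaffolds absent from the spec, on ignored
#' scaffolds, and in the `*` sentinel row do not count. Samples with fewer
#' than a minimum number of host reads (default 100 in the classification
#' pipeline) are reported as `insufficient_reads` rather than classified.
#'
#' @param x a `hostsex_idxstats` object.
#' @param spec a [genome_spec()] object.
#' @return Total mapped host reads (numeric scalar).
#' @export
total_host_reads <- function(x, spec) {
  stopifnot(inherits(x, "hostsex_idxstats"), inherits(spec, "hostsex_genome"))
  ch <- spec$chromosomes
  use <- ch$id[ch$role != "ignored"]
  tab <- x$table
  sum(tab$mapped[tab$id %in% use])
}

#' Write a classification result table
#'
#' Fixed column order: `sample_id`, `total_host_reads`, `rx`, `ry`,
#' `posterior`, `call`; undefined numeric values are rendered as `NA`.
#'
#' @param results data frame of calls as returned by
#'   [predict.hostsex_model()] (or [classify_samples()]).
#' @param path output path; `""` writes to stdout.
#' @param header optional character vector of comment lines (each prefixed
#'   `# `) recording provenance.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, header = NULL) {
  cols <- c("sample_id", "total_host_reads", "rx", "ry", "posterior", "call")
  stopifnot(all(cols %in% names(results)))
  con <- if (identical(path, "")) stdout() else file(path, "w")
  if (!identical(path, "")) on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(results[, cols], con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a delimited sample-metadata table
#'
#' Tab- or comma-delimited, auto-detected from the file extension
#' (`.csv` means comma; anything else tab) unless `sep` is given.
#'
#' @param path file path.
#' @param sep field separator, or `NULL` to auto-detect.
#' @return Data frame (all columns read as character to guarantee lossless
#'   round-tripping).
#' @export
read_metadata <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE,
                    quote = "", comment.char = "")
}

#' Append classification columns to a metadata table
#'
#' Left join: every metadata row is preserved; samples without a result get
#' empty values in the appended columns. Appended columns are
#' `hostsex_total_host_reads`, `hostsex_rx`, `hostsex_ry`,
#' `hostsex_posterior`, `hostsex_call`.
#'
#' @param metadata data frame (e.g. from [read_metadata()]).
#' @param results result data frame with a `sample_id` column.
#' @param id_column name of the metadata column holding sample IDs.
#' @return The amended data frame.
#' @export
amend_metadata <- function(metadata, results, id_column) {
  if (!id_column %in% names(metadata))
    hs_error(sprintf("metadata has no column '%s'", id_column),
             "hostsex_metadata_error")
  ids <- metadata[[id_column]]
  if (anyDuplicated(ids))
    hs_error("duplicate sample IDs in metadata: join would be ambiguous",
             "hostsex_metadata_error")
  if (anyDuplicated(results$sample_id))
    hs_error("duplicate sample IDs in results", "hostsex_metadata_error")
  idx <- match(ids, results$sample_id)
  pick <- function(col, fmt = as.character) {
    v <- rep("", length(ids))
    hit <- !is.na(idx)
    val <- results[[col]][idx[hit]]
    v[hit] <- ifelse(is.na(val), "NA", fmt(val))
    v
  }
  metadata$hostsex_total_host_reads <- pick("total_host_reads")
  metadata$hostsex_rx <- pick("rx", fmt = function(v) sprintf("%.6g", v))
  metadata$hostsex_ry <- pick("ry", fmt = function(v) sprintf("%.6g", v))
  metadata$hostsex_posterior <- pick("posterior",
                                     fmt = function(v) sprintf("%.6g", v))
  metadata$hostsex_call <- pick("call")
  metadata
}

#' Write a metadata table
#' @param metadata data frame.
#' @param path output path.
#' @param sep separator, auto-detected from extension if `NULL`.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(metadata, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
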