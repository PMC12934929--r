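# Genome specification: chromosome inventory, sex system and copy numbers.

.hs_roles <- c("autosome", "homogametic", "heterogametic", "ignored")

hs_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hostsex_error")))
}

#' Define a host genome specification
#'
#' A genome specification names the chromosomes whose mapped-read counts feed
#' the Rx and Ry coverage statistics, and declares the sex-determination
#' system. Exactly one chromosome must carry the `"homogametic"` role (X in an
#' XY system, Z in a ZW system) and exactly one the `"heterogametic"` role
#' (Y, resp. W). All `"autosome"` chromosomes are assumed diploid in both
#' sexes; `"ignored"` chromosomes (unplaced scaffolds, alt contigs) never
#' contribute reads to any statistic.
#'
#' Copy numbers follow from the roles: the homogametic-pair sex (XX female in
#' XY, ZZ male in ZW) carries two copies of the homogametic chromosome and
#' none of the heterogametic one; the heterogametic sex carries one of each.
#'
#' @param id character vector of chromosome/scaffold names (unique).
#' @param length integer vector of chromosome lengths in bp (positive).
#' @param role character vector, one of `"autosome"`, `"homogametic"`,
#'   `"heterogametic"`, `"ignored"`.
#' @param system `"XY"` (female is the homogametic sex) or `"ZW"` (male is).
#' @param effective_length optional integer vector of effective lengths in bp
#'   (length minus excluded regions such as PARs); defaults to `length`.
#' @return An object of class `hostsex_genome`: a list with elements
#'   `system` and `chromosomes` (a data frame with columns `id`, `length`,
#'   `role`, `effective_length`).
#' @seealso [apply_exclusion_regions()], [read_genome_spec()],
#'   [example_genome()]
#' @examples
#' genome_spec(id = c("A1", "A2", "X", "Y"),
#'             length = c(1000L, 2000L, 1500L, 300L),
#'             role = c("autosome", "autosome", "homogametic", "heterogametic"),
#'             system = "XY")
#' @export
genome_spec <- function(id, length, role, system = c("XY", "ZW"),
                        effective_length = NULL) {
  system <- match.arg(system)
  id <- as.character(id)
  length <- as.numeric(length)
  role <- match.arg(as.character(role), .hs_roles, several.ok = TRUE)
  if (!(base::length(id) == base::length(length) &&
        base::length(id) == base::length(role)))
    hs_error("id, length and role must have equal lengths",
             "hostsex_bad_spec_error")
  if (anyDuplicated(id))
    hs_error(sprintf("duplicate chromosome IDs: %s",
                     paste(unique(id[duplicated(id)]), collapse = ", ")),
             "hostsex_duplicate_id_error")
  if (any(!is.finite(length) | length < 1))
    hs_error(sprintf("non-positive length for: %s",
                     paste(id[!is.finite(length) | length < 1], collapse = ", ")),
             "hostsex_bad_length_error")
  if (sum(role == "homogametic") != 1L || sum(role == "heterogametic") != 1L)
    hs_error("spec must designate exactly one homogametic and one heterogametic sex chromosome",
             "hostsex_missing_sex_chrom_error")
  if (sum(role == "autosome") < 1L)
    hs_error("spec must contain at least one autosome",
             "hostsex_bad_spec_error")
  if (is.null(effective_length)) effective_length <- length
  effective_length <- as.numeric(effective_length)
  if (any(effective_length > length | effective_length < 1))
    hs_error("effective_length must be in [1, length]",
             "hostsex_bad_length_error")
  structure(list(
    system = system,
    chromosomes = data.frame(id = id, length = length, role = role,
                             effective_length = effective_length,
                             stringsAsFactors = FALSE)
  ), class = "hostsex_genome")
}

#' @export
print.hostsex_genome <- function(x, ...) {
  ch <- x$chromosomes
  cat(sprintf("<hostsex_genome> %s system, %d sequences\n", x$system, nrow(ch)))
  cat(sprintf("  autosomes: %d, ignored: %d\n",
              sum(ch$role == "autosome"), sum(ch$role == "ignored")))
  for (r in c("homogametic", "heterogametic")) {
    i <- which(ch$role == r)
    cat(sprintf("  %s: %s (%.0f bp, effective %.0f bp)\n",
                r, ch$id[i], ch$length[i], ch$effective_length[i]))
  }
  invisible(x)
}

#' Number of autosomes in a genome specification
#' @param spec a [genome_spec()] object.
#' @return Integer count of chromosomes with role `"autosome"`.
#' @export
n_autosomes <- function(spec) {
  stopifnot(inherits(spec, "hostsex_genome"))
  sum(spec$chromosomes$role == "autosome")
}

# id of the chromosome carrying a given role ("homogametic"/"heterogametic")
sex_chrom_id <- function(spec, role) {
  spec$chromosomes$id[spec$chromosomes$role == role]
}

#' Map chromosome roles to sex labels for a sex system
#'
#' In an XY system the homogametic-pair individual (XX) is female; in a ZW
#' system (ZZ) it is male.
#'
#' @param system `"XY"` or `"ZW"`.
#' @return Named character vector with elements `homogametic` and
#'   `heterogametic` giving the corresponding sex label.
#' @export
sex_labels <- function(system = c("XY", "ZW")) {
  system <- match.arg(system)
  if (system == "XY") c(homogametic = "female", heterogametic = "male")
  else                c(homogametic = "male",   heterogametic = "female")
}

#' Per-chromosome copy numbers for one sex
#'
#' @param spec a [genome_spec()] object.
#' @param sex `"female"` or `"male"`.
#' @return Named numeric vector of copy numbers (2 for autosomes; 2/0 or 1/1
#'   for the sex chromosomes depending on which sex is homogametic; 0 for
#'   ignored sequences).
#' @export
copy_number <- function(spec, sex = c("female", "male")) {
  stopifnot(inherits(spec, "hostsex_genome"))
  sex <- match.arg(sex)
  lab <- sex_labels(spec$system)
  is_homo_pair <- identical(unname(lab["homogametic"]), sex)
  role <- spec$chromosomes$role
  copies <- ifelse(role == "autosome", 2,
            ifelse(role == "homogametic", if (is_homo_pair) 2 else 1,
            ifelse(role == "heterogametic", if (is_homo_pair) 0 else 1, 0)))
  stats::setNames(copies, spec$chromosomes$id)
}

#' Reduce effective chromosome lengths by excluded regions
#'
#' Excluded regions (typically pseudoautosomal regions, where reads map to
#' both sex chromosomes) are supplied as BED-style intervals: 0-based,
#' half-open `[start, end)`. Overlapping intervals are merged before the
#' total excluded span is subtracted from the chromosome length to give the
#' effective length used in coverage calculations. Mapped-read counts are
#' not modified here; count-level filtering belongs to the upstream
#' alignment pipeline.
#'
#' Effective lengths are always recomputed from the full chromosome length,
#' so applying the same region set twice is a no-op.
#'
#' @param spec a [genome_spec()] object.
#' @param regions a data frame with columns `chrom`, `start`, `end`, or the
#'   path to a BED file (first three columns used).
#' @return The modified `hostsex_genome`.
#' @export
apply_exclusion_regions <- function(spec, regions) {
  stopifnot(inherits(spec, "hostsex_genome"))
  if (is.character(regions) && base::length(regions) == 1L)
    regions <- read_bed3(regions)
  regions <- as.data.frame(regions)
  if (nrow(regions) == 0L) return(spec)
  names(regions)[1:3] <- c("chrom", "start", "end")
  regions$start <- as.numeric(regions$start)
  regions$end <- as.numeric(regions$end)
  if (any(regions$end <= regions$start))
    hs_error("exclusion interval with end <= start", "hostsex_bad_interval_error")
  ch <- spec$chromosomes
  unknown <- setdiff(unique(regions$chrom), ch$id)
  if (base::length(unknown))
    hs_error(sprintf("exclusion regions name unknown chromosomes: %s",
                     paste(unknown, collapse = ", ")),
             "hostsex_bad_interval_error")
  for (cid in unique(regions$chrom)) {
    i <- match(cid, ch$id)
    iv <- regions[regions$chrom == cid, , drop = FALSE]
    if (any(iv$end > ch$length[i]))
      hs_error(sprintf("exclusion interval beyond end of %s", cid),
               "hostsex_bad_interval_error")
    span <- merged_span(iv$start, iv$end)
    ch$effective_length[i] <- max(1, ch$length[i] - span)
  }
  spec$chromosomes <- ch
  spec
}

# total length covered by the union of half-open intervals
merged_span <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  total <- 0; cur_s <- start[1]; cur_e <- end[1]
  for (j in seq_along(start)[-1]) {
    if (start[j] <= cur_e) cur_e <- max(cur_e, end[j])
    else { total <- total + (cur_e - cur_s); cur_s <- start[j]; cur_e <- end[j] }
  }
  total + (cur_e - cur_s)
}

read_bed3 <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  stats::setNames(bed[, 1:3], c("chrom", "start", "end"))
}

#' Read a scaffold inclusion list
#'
#' Plain text, one scaffold ID per line. Two dialects are supported:
#' one column (IDs only, in which case the *last two* lines must name the
#' homogametic and heterogametic sex chromosome, in that order, and all
#' preceding lines are autosomes) or two tab-separated columns
#' `id <TAB> role`.
#'
#' @param path file path.
#' @return Data frame with columns `id` and `role`.
#' @export
read_scaffold_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (base::length(lines) == 0L)
    hs_error("empty scaffold list", "hostsex_parse_error")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (all(ncols == 1L)) {
    n <- base::length(lines)
    if (n < 3L)
      hs_error("one-column scaffold list needs >= 1 autosome plus two sex chromosomes",
               "hostsex_parse_error")
    role <- c(rep("autosome", n - 2L), "homogametic", "heterogametic")
    data.frame(id = lines, role = role, stringsAsFactors = FALSE)
  } else if (all(ncols == 2L)) {
    data.frame(id = vapply(parts, `[`, "", 1L),
               role = match.arg(vapply(parts, `[`, "", 2L), .hs_roles,
                                several.ok = TRUE),
               stringsAsFactors = FALSE)
  } else {
    hs_error("scaffold list must have one or two tab-separated columns on every line",
             "hostsex_parse_error")
  }
}

#' Build a genome spec from a scaffold list plus an idxstats table
#'
#' Chromosome lengths are taken from the idxstats table; scaffolds present in
#' the idxstats file but absent from the list are ignored (the list is the
#' inclusion filter).
#'
#' @param scaffolds data frame from [read_scaffold_list()], or a path.
#' @param idxstats a [read_idxstats()] table supplying lengths.
#' @param system `"XY"` or `"ZW"`.
#' @return A [genome_spec()] object.
#' @export
genome_spec_from_scaffolds <- function(scaffolds, idxstats,
                                       system = c("XY", "ZW")) {
  system <- match.arg(system)
  if (is.character(scaffolds)) scaffolds <- read_scaffold_list(scaffolds)
  tab <- idxstats$table
  miss <- setdiff(scaffolds$id, tab$id)
  if (base::length(miss))
    hs_error(sprintf("scaffold IDs absent from idxstats: %s",
                     paste(miss, collapse = ", ")),
             "hostsex_missing_scaffold_error")
  len <- tab$length[match(scaffolds$id, tab$id)]
  genome_spec(scaffolds$id, len, scaffolds$role, system)
}

#' Read / write a genome specification file
#'
#' The on-disk dialect is a tab-separated table with a `system` pragma line:
#' the first non-comment line is `system<TAB>XY` (or `ZW`), followed by a
#' header line `id length role effective_length` and one row per chromosome.
#' [write_genome_spec()] and [read_genome_spec()] round-trip exactly.
#'
#' @param path file path.
#' @return [read_genome_spec()] returns a `hostsex_genome`;
#'   [write_genome_spec()] returns `path` invisibly.
#' @export
read_genome_spec <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  sys_line <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (base::length(sys_line) != 2L || sys_line[1] != "system")
    hs_error("genome spec file must start with a 'system<TAB>XY|ZW' line",
             "hostsex_parse_error")
  tab <- utils::read.table(text = lines[-1], sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  genome_spec(tab$id, tab$length, tab$role, sys_line[2],
              effective_length = tab$effective_length)
}

#' @rdname read_genome_spec
#' @param spec a [genome_spec()] object.
#' @export
write_genome_spec <- function(spec, path) {
  stopifnot(inherits(spec, "hostsex_genome"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("system\t%s", spec$system), con)
  utils::write.table(spec$chromosomes, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Bundled example genome specifications
#'
#' Convenience chromosome inventories with approximate published assembly
#' lengths: `"human"` (22 autosomes + X + Y, GRCh38-like), `"mouse"`
#' (19 autosomes + X + Y, GRCm39-like) and `"chicken"` (33 autosomes
#' + Z + W, ZW system). They are illustrative defaults, not normative: for
#' real analyses build the spec from your own reference's scaffold list.
#'
#' @param name one of `"human"`, `"mouse"`, `"chicken"`.
#' @return A [genome_spec()] object.
#' @export
example_genome <- function(name = c("human", "mouse", "chicken")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("genome_", name, ".tsv"),
                      package = "hostsex", mustWork = TRUE)
  read_genome_spec(path)
}
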