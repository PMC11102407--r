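.RANKS <- c(d = "domain", k = "domain", p = "phylum", c = "class",
            o = "order", f = "family", g = "genus", s = "species")

#' Canonicalize a species name to a "Genus species" key
#'
#' Species names coming from SILVA-style and MetaPhlAn-style lineages differ in
#' separators and decoration. The canonical key used for cross-platform
#' matching replaces underscores with spaces, strips bracketed genus markers
#' (`"[Ruminococcus]"`), capitalizes the genus, lower-cases the epithet, and
#' drops strain suffixes (tokens beyond the first two).
#'
#' @param x character vector of raw species names (may include the genus or be
#'   a bare epithet).
#' @param genus optional genus name(s) prepended when `x` is a bare epithet.
#' @return character vector of canonical keys.
#' @examples
#' canonicalSpeciesKey("Escherichia_coli")
#' canonicalSpeciesKey("faecalis", genus = "Enterococcus")
#' @export
canonicalSpeciesKey <- function(x, genus = NULL) {
  x <- gsub("_", " ", x, fixed = TRUE)
  x <- gsub("\\[|\\]", "", x)
  x <- trimws(gsub("[ ]+", " ", x))
  if (!is.null(genus)) {
    genus <- trimws(gsub("\\[|\\]", "", gsub("_", " ", genus)))
    genus <- rep_len(genus, length(x))
    one_token <- !grepl(" ", x)
    x[one_token] <- paste(genus[one_token], x[one_token])
  }
  vapply(strsplit(x, " ", fixed = TRUE), function(tok) {
    if (length(tok) == 0L || !nzchar(tok[1])) return(NA_character_)
    g <- tok[1]
    g <- paste0(toupper(substr(g, 1, 1)), tolower(substr(g, 2, nchar(g))))
    if (length(tok) == 1L) return(g)
    paste(g, tolower(tok[2]))
  }, character(1))
}

#' Parse a taxonomic lineage string
#'
#' Understands the two lineage dialects used by species-level profilers:
#' `"metaphlan"` (pipe-separated, `k__...|g__Escherichia|s__Escherichia_coli`)
#' and `"qiime2"` (semicolon-separated SILVA style, `d__Bacteria;...;s__coli`,
#' where the species field may be a bare epithet completed from the `g__`
#' field). The `"plain"` dialect treats the whole string as a species name
#' (rows with a single token carry no species rank).
#'
#' @param raw a single lineage string.
#' @param dialect `"metaphlan"`, `"qiime2"` or `"plain"`.
#' @return A `LineageString`: list with `raw`, `rankValues` (named character,
#'   ranks present), and `speciesKey` (canonical key, or `NA` when no
#'   species-rank name is present).
#' @examples
#' parseLineage("k__Bacteria|g__Bacteroides|s__Bacteroides_fragilis", "metaphlan")
#' parseLineage("d__Bacteria;g__Enterococcus;s__faecalis", "qiime2")
#' @export
parseLineage <- function(raw, dialect = c("metaphlan", "qiime2", "plain")) {
  dialect <- match.arg(dialect)
  stopifnot(is.character(raw), length(raw) == 1L, nzchar(raw))
  rank_values <- character(0)
  if (dialect == "plain") {
    key <- canonicalSpeciesKey(raw)
    if (!grepl(" ", key %||% "")) key <- NA_character_
    if (!is.na(key)) rank_values <- c(genus = strsplit(key, " ")[[1]][1], species = key)
    out <- list(raw = raw, rankValues = rank_values, speciesKey = key)
    class(out) <- "LineageString"
    return(out)
  }
  sep <- if (dialect == "metaphlan") "|" else ";"
  fields <- trimws(strsplit(raw, sep, fixed = TRUE)[[1]])
  fields <- fields[nzchar(fields)]
  prefixes <- sub("__.*$", "", fields)
  values <- sub("^[a-z]__", "", fields)
  known <- prefixes %in% names(.RANKS)
  if (!all(known))
    stop("malformed lineage field(s): ", paste(fields[!known], collapse = ", "))
  rank_values <- setNames(values, .RANKS[prefixes])
  rank_values <- rank_values[nzchar(rank_values)]
  key <- NA_character_
  if ("species" %in% names(rank_values)) {
    key <- canonicalSpeciesKey(rank_values[["species"]],
                               genus = if ("genus" %in% names(rank_values))
                                 rank_values[["genus"]] else NULL)
    if (!is.na(key) && !grepl(" ", key)) key <- NA_character_
    rank_values[["species"]] <- key
  }
  out <- list(raw = raw, rankValues = rank_values, speciesKey = key)
  class(out) <- "LineageString"
  out
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' @export
print.LineageString <- function(x, ...) {
  cat("LineageString:", x$raw, "\n")
  cat("  species key:", if (is.na(x$speciesKey)) "<none>" else x$speciesKey, "\n")
  invisible(x)
}

#' Read a species-level abundance table
#'
#' Reads a tab-separated species-by-sample table (first column lineage
#' strings, header row of sample ids, `#` comment lines ignored), keeps only
#' rows carrying a species-rank assignment (genus-level and higher summary rows
#' in MetaPhlAn output are dropped, not aggregated), and canonicalizes species
#' keys. MetaPhlAn-dialect values are percentages: they are divided by 100 and
#' columns renormalized to sum to 1, yielding `relative_fraction` unit; other
#' dialects default to `absolute_count`.
#'
#' Rows whose lineages collapse to the same canonical species key are summed.
#'
#' @param path file path.
#' @param platform `"S16"` or `"WGS"`.
#' @param dialect `"plain_tsv"`, `"metaphlan"` or `"qiime2_tsv"`.
#' @param unit override the dialect's default unit (optional).
#' @return An [AbundanceTable-class].
#' @export
readAbundanceTable <- function(path, platform = c("S16", "WGS"),
                               dialect = c("plain_tsv", "metaphlan", "qiime2_tsv"),
                               unit = NULL) {
  platform <- match.arg(platform)
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (!length(lines)) stop("parse error: empty table in ", path)
  df <- read.delim(text = lines, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stop("parse error: no columns in ", path)
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(sample_ids)) stop("parse error: duplicate sample ids in header")
  raw_names <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(vals) > 0) {
    storage.mode(vals) <- "double"
    if (any(!is.finite(vals))) stop("validation error: non-finite abundance values")
  }
  pdialect <- c(plain_tsv = "plain", metaphlan = "metaphlan", qiime2_tsv = "qiime2")[[dialect]]
  keys <- vapply(raw_names, function(s) parseLineage(s, pdialect)$speciesKey,
                 character(1), USE.NAMES = FALSE)
  keep <- !is.na(keys)
  vals <- vals[keep, , drop = FALSE]
  keys <- keys[keep]
  if (anyDuplicated(keys)) {
    vals <- rowsum(vals, group = keys)
    keys <- rownames(vals)
  }
  rownames(vals) <- keys
  colnames(vals) <- sample_ids
  default_unit <- if (dialect == "metaphlan") "relative_fraction" else "absolute_count"
  unit <- unit %||% default_unit
  # log_cpm tables (e.g. written predictions) may hold negative model output;
  # counts and fractions may not
  if (unit != "log_cpm" && length(vals) && any(vals < 0))
    stop("validation error: negative abundance values")
  if (dialect == "metaphlan" && unit == "relative_fraction" && nrow(vals) > 0) {
    vals <- vals / 100
    cs <- colSums(vals)
    if (any(cs == 0)) stop("validation error: all-zero sample column(s): ",
                           paste(sample_ids[cs == 0], collapse = ", "))
    vals <- sweep(vals, 2, cs, "/")
  }
  AbundanceTable(vals, platform = platform, unit = unit)
}

#' Write an abundance table to TSV
#'
#' Writes comment lines recording platform and unit, a header row of sample
#' ids, and one row per species. `readAbundanceTable(..., dialect =
#' "plain_tsv")` round-trips species ids, sample ids and values exactly.
#'
#' @param x an [AbundanceTable-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeAbundanceTable <- function(x, path) {
  stopifnot(is(x, "AbundanceTable"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# platform=%s unit=%s", x@platform, x@unit), con)
  v <- abundanceValues(x)
  writeLines(paste(c("species_id", colnames(v)), collapse = "\t"), con)
  if (nrow(v) > 0) {
    lines <- vapply(seq_len(nrow(v)), function(i)
      paste(c(rownames(v)[i], format(v[i, ], digits = 17, trim = TRUE,
                                     scientific = FALSE)), collapse = "\t"),
      character(1))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Match species between two abundance tables
#'
#' Returns the canonical species keys shared by both tables (keys are
#' canonicalized again defensively, so `"Escherichia_coli"` matches
#' `"Escherichia coli"`). Symmetric in its arguments.
#'
#' @param a,b [AbundanceTable-class] objects at species level.
#' @return Sorted character vector of shared canonical keys.
#' @export
matchSpecies <- function(a, b) {
  ka <- canonicalSpeciesKey(speciesIds(a))
  kb <- canonicalSpeciesKey(speciesIds(b))
  sort(intersect(ka[!is.na(ka)], kb[!is.na(kb)]))
}

#' Read a sample metadata table
#'
#' TSV with columns `sample_id`, `group` (binary, coerced to 0/1) and
#' `timepoint` (non-negative integer).
#'
#' @param path file path.
#' @return data.frame with columns sample_id (character), group (0/1 numeric),
#'   timepoint (numeric).
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "group", "timepoint")
  if (!all(need %in% colnames(df)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  if (!is.numeric(df$group)) {
    lev <- sort(unique(df$group))
    if (length(lev) > 2) stop("group must be binary")
    df$group <- as.numeric(match(df$group, lev) - 1L)
  }
  if (!all(df$group %in% c(0, 1))) stop("group must be binary (0/1)")
  df$timepoint <- as.numeric(df$timepoint)
  if (any(df$timepoint < 0)) stop("timepoint must be >= 0")
  df[, need]
}
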