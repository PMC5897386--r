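# Data containers and TSV readers/writers for OTU tables, abiotic variable
# tables, sequence-identity matrices and taxon->function rule sets.
# All files are UTF-8, tab-separated, decimal point ".", taxonomy strings use
# greengenes-style rank prefixes separated by "; " (k__, p__, c__, o__, f__,
# g__).

#' Construct an OTU count table
#'
#' An `otu_table` holds a non-negative integer count matrix (OTUs in rows,
#' samples in columns), an optional per-OTU taxonomy string and optional
#' per-sample metadata giving the site (1-8 in the transect design), the
#' replicate (1-3) and the gradient section (1 or 2) of every sample.
#'
#' @param counts numeric matrix, OTUs x samples, finite and >= 0, with unique
#'   row and column names.
#' @param taxonomy character vector of semicolon-separated rank-prefixed
#'   lineage strings, one per OTU (optionally named by OTU id), or `NULL`.
#' @param sample_meta `data.frame` with columns `sample`, `site`, `replicate`,
#'   `section`, one row per sample, or `NULL`.
#' @return An object of class `otu_table`.
#' @export
otu_table <- function(counts, taxonomy = NULL, sample_meta = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have OTU row names and sample column names")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup))
    stop("duplicate OTU id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid count at OTU '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  if (!is.null(taxonomy)) {
    if (length(taxonomy) != nrow(counts))
      stop("taxonomy length must equal number of OTUs")
    if (is.null(names(taxonomy))) names(taxonomy) <- rownames(counts)
    taxonomy <- taxonomy[rownames(counts)]
  }
  if (!is.null(sample_meta)) {
    sample_meta <- as.data.frame(sample_meta)
    need <- c("sample", "site", "replicate", "section")
    miss <- setdiff(need, names(sample_meta))
    if (length(miss))
      stop("sample_meta missing column(s): ", paste(miss, collapse = ", "))
    if (!all(colnames(counts) %in% sample_meta$sample))
      stop("sample_meta must cover every sample column")
    sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample), ,
                               drop = FALSE]
    rownames(sample_meta) <- NULL
    if (anyNA(sample_meta[need]))
      stop("sample_meta has missing site/replicate/section values")
  }
  structure(list(counts = counts, taxonomy = taxonomy,
                 sample_meta = sample_meta),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples (%s taxonomy, %s metadata)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$taxonomy)) "no" else "with",
              if (is.null(x$sample_meta)) "no" else "with"))
  invisible(x)
}

#' Number of OTUs / samples in an `otu_table`
#' @param x an `otu_table`.
#' @return integer count.
#' @export
n_otus <- function(x) nrow(x$counts)

#' @rdname n_otus
#' @export
n_samples <- function(x) ncol(x$counts)

#' Subset an otu_table by OTU ids and/or sample ids
#' @param x an `otu_table`.
#' @param otus,samples character vectors of ids to keep (default: all).
#' @return the subsetted `otu_table`.
#' @export
subset_otu_table <- function(x, otus = rownames(x$counts),
                             samples = colnames(x$counts)) {
  otu_table(x$counts[otus, samples, drop = FALSE],
            taxonomy = if (!is.null(x$taxonomy)) x$taxonomy[otus],
            sample_meta = if (!is.null(x$sample_meta))
              x$sample_meta[x$sample_meta$sample %in% samples, , drop = FALSE])
}

#' Slice an otu_table to one gradient section
#' @param x an `otu_table` with sample metadata.
#' @param section section id (1 or 2).
#' @param drop_absent drop OTUs with zero total count in the section.
#' @return the section `otu_table`.
#' @export
section_slice <- function(x, section, drop_absent = TRUE) {
  if (is.null(x$sample_meta)) stop("sample metadata required")
  keep <- x$sample_meta$sample[x$sample_meta$section == section]
  out <- subset_otu_table(x, samples = keep)
  if (drop_absent)
    out <- subset_otu_table(out,
                            otus = rownames(out$counts)[rowSums(out$counts) > 0])
  out
}

#' Read an OTU table from TSV
#'
#' Expects the classic BIOM-TSV dialect: an optional leading comment line,
#' a header line whose first field is `#OTU ID` followed by sample ids, one row
#' per OTU, and an optional trailing `taxonomy` column. Sample metadata can be
#' supplied as a sidecar TSV (`sample`, `site`, `replicate`, `section`).
#'
#' @param path TSV file path.
#' @param dialect `"tsv"` or `"biom-tsv"` (identical layout; `biom-tsv` allows
#'   the `# Constructed from biom file` comment line).
#' @param meta_path optional path of the sample-metadata sidecar TSV.
#' @return an [otu_table()].
#' @export
read_otu_table <- function(path, dialect = c("tsv", "biom-tsv"),
                           meta_path = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#OTU ID\t", lines)
  if (!length(hdr)) hdr <- grep("^#OTU ID$", lines)
  if (!length(hdr))
    stop("malformed header: no '#OTU ID' header line found in ", path)
  body <- lines[hdr[1]:length(lines)]
  body <- body[!grepl("^#", body) | seq_along(body) == 1L]
  df <- utils::read.delim(text = body, check.names = FALSE,
                          colClasses = "character", comment.char = "")
  names(df)[1] <- "#OTU ID"
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate OTU id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  taxonomy <- NULL
  if (tolower(names(df)[ncol(df)]) == "taxonomy") {
    taxonomy <- df[[ncol(df)]]
    names(taxonomy) <- ids
    df <- df[-ncol(df)]
  }
  mat <- as.matrix(df[-1])
  suppressWarnings(storage.mode(mat) <- "double")
  bad <- which(is.na(mat) | mat < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid count at row '%s', column '%s' in %s",
                 ids[bad[1, 1]], colnames(mat)[bad[1, 2]], path))
  rownames(mat) <- ids
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- utils::read.delim(meta_path, check.names = FALSE)
    meta$sample <- as.character(meta$sample)
  }
  otu_table(mat, taxonomy = taxonomy, sample_meta = meta)
}

#' Write an OTU table (and optional sample metadata sidecar) to TSV
#' @param x an `otu_table`.
#' @param path output TSV path.
#' @param meta_path optional path for the sample-metadata sidecar.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path, meta_path = NULL) {
  df <- data.frame(`#OTU ID` = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(x$taxonomy)) df$taxonomy <- unname(x$taxonomy)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# Constructed from biom file", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path) && !is.null(x$sample_meta))
    utils::write.table(x$sample_meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Construct an abiotic variable table
#'
#' Real-valued measurements of soil physicochemical/nutritional variables,
#' variables in rows and samples in columns. `pH` must lie in \[0, 14\] and
#' `RelativeHumidity` in \[0, 100\]; variables used for network inference may
#' not contain missing values.
#'
#' @param values numeric matrix, variables x samples, with names.
#' @param sample_meta optional per-sample metadata as in [otu_table()].
#' @return an object of class `abiotic_table`.
#' @export
abiotic_table <- function(values, sample_meta = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have variable row names and sample column names")
  if ("pH" %in% rownames(values)) {
    ph <- values["pH", ]
    if (any(!is.na(ph) & (ph < 0 | ph > 14))) stop("pH outside [0, 14]")
  }
  if ("RelativeHumidity" %in% rownames(values)) {
    rh <- values["RelativeHumidity", ]
    if (any(!is.na(rh) & (rh < 0 | rh > 100)))
      stop("RelativeHumidity outside [0, 100]")
  }
  if (!is.null(sample_meta)) {
    sample_meta <- as.data.frame(sample_meta)
    sample_meta <- sample_meta[match(colnames(values), sample_meta$sample), ,
                               drop = FALSE]
    rownames(sample_meta) <- NULL
  }
  structure(list(values = values, sample_meta = sample_meta),
            class = "abiotic_table")
}

#' @export
print.abiotic_table <- function(x, ...) {
  cat(sprintf("abiotic_table: %d variables x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read / write an abiotic variable table (TSV, first column `variable`)
#' @param path TSV path.
#' @param meta_path optional sample-metadata sidecar TSV.
#' @return an [abiotic_table()].
#' @export
read_abiotic_table <- function(path, meta_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (names(df)[1] != "variable")
    stop("malformed header: first column must be 'variable', got '",
         names(df)[1], "'")
  mat <- as.matrix(df[-1])
  rownames(mat) <- df$variable
  meta <- NULL
  if (!is.null(meta_path)) meta <- utils::read.delim(meta_path)
  abiotic_table(mat, sample_meta = meta)
}

#' @rdname read_abiotic_table
#' @param x an `abiotic_table`.
#' @export
write_abiotic_table <- function(x, path) {
  df <- data.frame(variable = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct / read / write a pairwise sequence-identity matrix
#'
#' Symmetric matrix of pairwise 16S identity fractions in \[0, 1\] over OTU
#' ids, with unit diagonal.
#'
#' @param identity numeric square matrix with identical row/column names.
#' @return the validated matrix, class `seq_similarity`.
#' @export
seq_similarity <- function(identity) {
  identity <- as.matrix(identity)
  if (nrow(identity) != ncol(identity) ||
      !identical(rownames(identity), colnames(identity)))
    stop("identity must be square with identical row/column names")
  if (any(identity < 0 | identity > 1)) stop("identities outside [0, 1]")
  if (max(abs(identity - t(identity))) > 1e-8) stop("identity not symmetric")
  if (max(abs(diag(identity) - 1)) > 1e-8) stop("diagonal must be 1")
  identity <- (identity + t(identity)) / 2
  diag(identity) <- 1
  class(identity) <- c("seq_similarity", class(identity))
  identity
}

#' @rdname seq_similarity
#' @param path TSV path (first column `id`).
#' @export
read_similarity_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  mat <- as.matrix(df[-1])
  rownames(mat) <- as.character(df[[1]])
  seq_similarity(mat)
}

#' @rdname seq_similarity
#' @param x identity matrix.
#' @export
write_similarity_matrix <- function(x, path) {
  df <- data.frame(id = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Taxon-to-function rule sets
#'
#' A rule set maps taxa to putative ecological function categories in the
#' style of FAPROTAX: each rule states a taxonomic rank (`kingdom` ...
#' `genus`), a rank-prefixed pattern (e.g. `g__Nitrospira`) and a function
#' category (e.g. `nitrification`). An OTU receives every category whose rule
#' pattern equals its lineage value at the stated rank.
#'
#' @param rules `data.frame` with columns `rank`, `pattern`, `category`.
#' @return validated `data.frame`, class `rule_set`.
#' @export
rule_set <- function(rules) {
  rules <- as.data.frame(rules, stringsAsFactors = FALSE)
  need <- c("rank", "pattern", "category")
  miss <- setdiff(need, names(rules))
  if (length(miss)) stop("rules missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(!nzchar(rules$pattern))
  if (length(bad)) stop("empty pattern at rule line ", bad[1])
  rules <- unique(rules[need])
  class(rules) <- c("rule_set", class(rules))
  rules
}

#' @rdname rule_set
#' @param path TSV path with header `rank  pattern  category`.
#' @export
read_rules <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  rule_set(df)
}

#' @rdname rule_set
#' @param x a `rule_set`.
#' @export
write_rules <- function(x, path) {
  utils::write.table(as.data.frame(unclass(x)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' The function rule set bundled with the package
#'
#' A trimmed FAPROTAX-style table of genus- and phylum-level rules covering
#' the functional categories relevant to gradient soil communities
#' (chemoheterotrophy, nitrogen fixation, nitrification, nitrate reduction,
#' fermentation, methanotrophy, and others).
#'
#' @return a [rule_set()].
#' @export
default_rules <- function() {
  read_rules(system.file("extdata", "function_rules.tsv", package = "otunet",
                         mustWork = TRUE))
}
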