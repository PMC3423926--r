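#' Taxonomic ranks of an OTU report
#'
#' The six lineage ranks carried by every OTU, coarsest first. The sentinel
#' `"unclassified"` marks ranks to which a sequence could not be assigned;
#' once a rank is unclassified, all finer ranks must be unclassified too.
#'
#' @return character vector of the six rank names.
#' @export
lineage_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus")
}

UNCLASSIFIED <- "unclassified"

#' Construct an OTU table
#'
#' An OTU table couples an OTU x sample matrix of non-negative integer read
#' counts with a six-rank lineage (domain to genus) per OTU. It is the central
#' data structure of the package: community comparison, diversity and
#' responder tests all consume it.
#'
#' @param counts numeric matrix, OTUs in rows, samples in columns; entries
#'   must be non-negative integers.
#' @param lineage data.frame with one row per OTU and the six columns named
#'   by [lineage_ranks()].
#' @param otu_ids unique OTU identifiers; default taken from
#'   `rownames(counts)`.
#' @param sample_ids unique sample identifiers; default from
#'   `colnames(counts)`.
#' @return an object of class `otu_table`: a list with elements `counts`
#'   (integer matrix with dimnames), `lineage`, `otu_ids`, `sample_ids`.
#' @export
otu_table <- function(counts, lineage, otu_ids = rownames(counts),
                      sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(otu_ids)) otu_ids <- sprintf("OTU_%05d", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(ncol(counts)))
  otu_ids <- as.character(otu_ids)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU ids: ", paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ", paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (length(otu_ids) != nrow(counts) || length(sample_ids) != ncol(counts))
    stop("count matrix dimensions do not match id lists", call. = FALSE)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  lineage <- as.data.frame(lineage, stringsAsFactors = FALSE)
  if (nrow(lineage) != nrow(counts))
    stop("lineage must have one row per OTU", call. = FALSE)
  if (!identical(names(lineage), lineage_ranks()))
    stop("lineage columns must be exactly: ", paste(lineage_ranks(), collapse = ", "),
         call. = FALSE)
  validate_lineage(lineage)
  if (nrow(counts) > 0 && any(rowSums(counts) == 0))
    stop("every OTU must have at least one nonzero count; offending OTU(s): ",
         paste(utils::head(otu_ids[rowSums(counts) == 0], 5), collapse = ", "),
         call. = FALSE)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(otu_ids, sample_ids)
  rownames(lineage) <- NULL
  structure(list(counts = counts, lineage = lineage,
                 otu_ids = otu_ids, sample_ids = sample_ids),
            class = "otu_table")
}

# rank-order rule: unclassified at rank r forces unclassified at all finer ranks
validate_lineage <- function(lineage) {
  m <- as.matrix(lineage) == UNCLASSIFIED
  if (nrow(m) == 0) return(invisible(TRUE))
  for (j in seq_len(ncol(m) - 1L)) {
    bad <- m[, j] & !m[, j + 1L]
    if (any(bad))
      stop("lineage rank-order violation in row(s) ",
           paste(utils::head(which(bad), 5), collapse = ", "),
           ": rank '", lineage_ranks()[j],
           "' is unclassified but a finer rank is named", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.otu_table <- function(x, ...) {
  cat("OTU table: ", nrow(x$counts), " OTUs x ", ncol(x$counts), " samples\n", sep = "")
  cat("  total reads: ", sum(x$counts),
      "; sample depths: ", paste(colSums(x$counts), collapse = ", "), "\n", sep = "")
  np <- length(unique(x$lineage$phylum))
  ng <- length(unique(x$lineage$genus[x$lineage$genus != UNCLASSIFIED]))
  cat("  ", np, " phyla, ", ng, " classified genera\n", sep = "")
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Read an OTU report from a tab-separated file
#'
#' The canonical dialect is UTF-8, tab-separated, with an optional leading
#' `otu_id` column, then the six rank columns (domain to genus), then one
#' integer count column per sample. Lines starting with `#` are ignored.
#' When the `otu_id` column is absent, identifiers `OTU_00001`, ... are
#' assigned in row order.
#'
#' @param path path to the report file.
#' @return an [otu_table()].
#' @seealso [write_otu_report()]
#' @export
read_otu_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  has_id <- identical(names(df)[1], "otu_id")
  rank_cols <- if (has_id) 2:7 else 1:6
  if (ncol(df) < max(rank_cols) + 1L)
    stop("format error: expected six rank columns plus at least one sample column",
         call. = FALSE)
  if (!identical(names(df)[rank_cols], lineage_ranks()))
    stop("format error: rank columns must be named ",
         paste(lineage_ranks(), collapse = ", "), call. = FALSE)
  samp_cols <- seq.int(max(rank_cols) + 1L, ncol(df))
  otu_ids <- if (has_id) df[["otu_id"]] else sprintf("OTU_%05d", seq_len(nrow(df)))
  counts <- matrix(NA_integer_, nrow(df), length(samp_cols))
  for (j in seq_along(samp_cols)) {
    raw <- df[[samp_cols[j]]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- is.na(num) | num < 0 | num != round(num)
    if (any(bad))
      stop("format error: count '", raw[which(bad)[1]], "' in row ", which(bad)[1],
           ", sample column '", names(df)[samp_cols[j]], "' is not a non-negative integer",
           call. = FALSE)
    counts[, j] <- as.integer(num)
  }
  otu_table(counts, df[rank_cols], otu_ids = otu_ids,
            sample_ids = names(df)[samp_cols])
}

#' Write an OTU report in the canonical dialect
#'
#' @param x an [otu_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_otu_report <- function(x, path) {
  stopifnot(inherits(x, "otu_table"))
  df <- cbind(otu_id = x$otu_ids, x$lineage,
              as.data.frame(x$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Sample metadata: soil, treatment, replicate per sample
#'
#' Validates the experimental design table and derives the group label
#' `soil.treatment` (e.g. `Cambisol.spiked`) used by all group-wise tests.
#'
#' @param df data.frame with columns `sample_id`, `soil`, `treatment`
#'   (values `control` or `spiked`) and `replicate`.
#' @return a `sample_groups` data.frame with an added `group` column.
#' @export
sample_groups <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "soil", "treatment", "replicate")
  if (!all(need %in% names(df)))
    stop("metadata must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata", call. = FALSE)
  if (!all(df$treatment %in% c("control", "spiked")))
    stop("treatment must be 'control' or 'spiked'", call. = FALSE)
  df$group <- paste(df$soil, df$treatment, sep = ".")
  class(df) <- c("sample_groups", "data.frame")
  df
}

#' Read sample metadata from TSV
#'
#' @param path tab-separated file with columns `sample_id`, `soil`,
#'   `treatment`, `replicate`.
#' @return a [sample_groups()] table.
#' @export
read_sample_metadata <- function(path) {
  sample_groups(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                                  comment.char = "#"))
}

# map sample ids to group labels, erroring on unknown samples
group_labels <- function(groups, sample_ids) {
  i <- match(sample_ids, groups$sample_id)
  if (anyNA(i))
    stop("samples without metadata: ",
         paste(sample_ids[is.na(i)], collapse = ", "), call. = FALSE)
  groups$group[i]
}

#' Aggregate an OTU table at a taxonomic rank
#'
#' Rows are pooled by their lineage prefix up to `rank`; counts of member
#' OTUs are summed, so column (sample) sums are unchanged. Unclassified
#' prefixes are kept as distinct bins: a genus `"unclassified"` under two
#' different families yields two bins, labelled `unclassified_<parent>` after
#' the deepest classified ancestor.
#'
#' @param x an [otu_table()].
#' @param rank one of [lineage_ranks()].
#' @param drop_unclassified drop bins that are unclassified at `rank`?
#' @return an [otu_table()] with one row per lineage prefix; its `otu_ids`
#'   are the taxon bin labels.
#' @export
aggregate_at_rank <- function(x, rank, drop_unclassified = FALSE) {
  stopifnot(inherits(x, "otu_table"))
  j <- match(rank, lineage_ranks())
  if (is.na(j)) stop("unknown rank: '", rank, "'", call. = FALSE)
  prefix <- as.matrix(x$lineage[, seq_len(j), drop = FALSE])
  key <- apply(prefix, 1L, paste, collapse = "\r")
  first <- !duplicated(key)
  agg <- rowsum(x$counts, group = key, reorder = FALSE)
  # rowsum with reorder=FALSE keeps first-appearance order of keys
  lin <- x$lineage[first, , drop = FALSE]
  if (j < length(lineage_ranks()))
    lin[, seq.int(j + 1L, length(lineage_ranks()))] <- UNCLASSIFIED
  labels <- taxon_bin_labels(lin, j)
  keep <- rep(TRUE, nrow(lin))
  if (drop_unclassified) keep <- lin[[rank]] != UNCLASSIFIED
  otu_table(agg[keep, , drop = FALSE], lin[keep, , drop = FALSE],
            otu_ids = make.unique(labels[keep]), sample_ids = x$sample_ids)
}

# display label for an aggregated bin: the name at `rank`, or
# unclassified_<deepest classified ancestor> when that name is the sentinel
taxon_bin_labels <- function(lin, j) {
  vapply(seq_len(nrow(lin)), function(i) {
    nm <- lin[i, j]
    if (nm != UNCLASSIFIED) return(nm)
    anc <- rev(as.character(lin[i, seq_len(j)]))
    anc <- anc[anc != UNCLASSIFIED]
    paste0("unclassified_", if (length(anc)) anc[1] else "root")
  }, character(1))
}

#' Subset an OTU table to the OTUs of one taxon
#'
#' Keeps the rows whose lineage carries `name` at `rank`; all samples are
#' retained even if they end up with zero reads. A name absent at that rank
#' yields an explicit empty table with a warning, never a silent success.
#'
#' @param x an [otu_table()].
#' @param rank one of [lineage_ranks()].
#' @param name taxon name to match at `rank`.
#' @return an [otu_table()] (possibly with zero rows).
#' @export
subset_by_taxon <- function(x, rank, name) {
  stopifnot(inherits(x, "otu_table"))
  if (!rank %in% lineage_ranks()) stop("unknown rank: '", rank, "'", call. = FALSE)
  keep <- x$lineage[[rank]] == name
  if (!any(keep))
    warning("no OTUs with ", rank, " = '", name, "'; returning empty table",
            call. = FALSE)
  otu_table(x$counts[keep, , drop = FALSE], x$lineage[keep, , drop = FALSE],
            otu_ids = x$otu_ids[keep], sample_ids = x$sample_ids)
}

#' Per-sample relative abundances
#'
#' @param x an [otu_table()] or a count matrix with samples in columns.
#' @return matrix of proportions; every column sums to 1.
#' @export
relative_abundance <- function(x) {
  m <- if (inherits(x, "otu_table")) x$counts else as.matrix(x)
  depth <- colSums(m)
  if (any(depth == 0))
    stop("zero-depth sample(s): ",
         paste(colnames(m)[depth == 0] %||% which(depth == 0), collapse = ", "),
         call. = FALSE)
  sweep(m, 2L, depth, "/")
}
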