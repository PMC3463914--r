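#' Construct an expression matrix over ordered leaf zones
#'
#' The central data container of the package: a genes x zones matrix of RPKM
#' (reads per kilobase of exon model per million mapped reads) values measured
#' along the maize leaf developmental gradient. Zones are ordered from
#' youngest to oldest tissue; the default four-zone gradient is basal,
#' transitional, maturing, mature.
#'
#' Cells printed as below the detection limit in the source table are stored
#' as 0 with a parallel logical `below_detection` flag, so the distinction
#' between "measured zero" and "below detection" is never lost.
#'
#' @param values numeric matrix (or coercible), one row per gene, one column
#'   per zone; all values must be finite and >= 0.
#' @param gene_ids character vector of gene-model identifiers aligned to rows.
#'   Duplicates are permitted (the published table reports one gene model
#'   under two symbols); operations that require unique ids say so.
#' @param names optional character vector of gene symbols aligned to rows.
#' @param zones character vector of ordered zone labels.
#' @param below_detection optional logical matrix, same shape as `values`,
#'   marking below-detection cells.
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `names`, `zones`, `below_detection`.
#' @export
expression_matrix <- function(values, gene_ids, names = NULL,
                              zones = c("basal", "transitional", "maturing", "mature"),
                              below_detection = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(below_detection)) {
    below_detection <- matrix(FALSE, nrow(values), ncol(values))
  }
  if (is.null(names)) names <- rep(NA_character_, nrow(values))
  em <- structure(
    list(values = values, gene_ids = as.character(gene_ids),
         names = as.character(names), zones = as.character(zones),
         below_detection = below_detection),
    class = "ExpressionMatrix")
  validate_expression_matrix(em)
  em
}

#' Validate an ExpressionMatrix
#'
#' Checks the container invariants: finite non-negative values, at least two
#' zones, aligned gene index and detection flags. Called by the constructor
#' and by the readers; exported so pipelines can re-validate after editing.
#'
#' @param em an `ExpressionMatrix`.
#' @return `em`, invisibly; errors describe the first violated invariant.
#' @export
validate_expression_matrix <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  v <- em$values
  if (ncol(v) < 2L)
    stop("ExpressionMatrix needs at least 2 zone columns, got ", ncol(v))
  if (length(em$zones) != ncol(v))
    stop("zone labels (", length(em$zones), ") do not match columns (", ncol(v), ")")
  if (length(em$gene_ids) != nrow(v))
    stop("gene index length (", length(em$gene_ids), ") does not match rows (", nrow(v), ")")
  if (any(!is.finite(v)))
    stop("non-finite RPKM value at row ", which(!is.finite(v), arr.ind = TRUE)[1, 1])
  if (any(v < 0)) {
    bad <- which(v < 0, arr.ind = TRUE)[1, , drop = TRUE]
    stop("negative RPKM at gene '", em$gene_ids[bad[1]], "', zone '", em$zones[bad[2]], "'")
  }
  if (any(em$gene_ids == "" | is.na(em$gene_ids)))
    stop("empty gene_id in gene index")
  if (!identical(dim(em$below_detection), dim(v)))
    stop("below_detection flags do not match matrix shape")
  invisible(em)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "genes x", length(x$zones), "zones (",
      paste(x$zones, collapse = " > "), ")\n")
  cat("  RPKM range:", format(min(x$values)), "-", format(max(x$values)),
      "; below-detection cells:", sum(x$below_detection), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
as.matrix.ExpressionMatrix <- function(x, ...) {
  m <- x$values
  rownames(m) <- x$gene_ids
  colnames(m) <- x$zones
  m
}

#' Read an RPKM expression table
#'
#' Reads a tab-separated table with a header row `gene_id`, optionally
#' `name`, then one column per zone in gradient order. Cells written as
#' `0*` (the published table's below-detection mark) parse to 0 with the
#' below-detection flag set. The original cell text is retained so that
#' [write_expression_table()] round-trips the file losslessly.
#'
#' @param path file path.
#' @param dedupe `"allow"` keeps duplicated gene_id rows as printed (the
#'   packaged table reports one gene model under two symbols); `"error"`
#'   raises a duplication error directing to [collapse_duplicates()].
#' @param sep field separator, default tab.
#' @return an `ExpressionMatrix`, input row order preserved.
#' @export
read_expression_table <- function(path, dedupe = c("allow", "error"), sep = "\t") {
  dedupe <- match.arg(dedupe)
  if (length(readLines(path, n = 1L)) == 0L)
    stop("format error: '", path, "' is empty or has no header row")
  raw <- utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", blank.lines.skip = TRUE)
  if (nrow(raw) == 0L && ncol(raw) == 0L)
    stop("format error: '", path, "' is empty or has no header row")
  cols <- names(raw)
  if (!"gene_id" %in% cols)
    stop("format error: header must contain a 'gene_id' column (got: ",
         paste(cols, collapse = ", "), ")")
  has_name <- "name" %in% cols
  zone_cols <- setdiff(cols, c("gene_id", "name"))
  if (length(zone_cols) < 2L)
    stop("dimension error: need at least 2 zone columns, found ", length(zone_cols))
  if (nrow(raw) == 0L)
    stop("format error: '", path, "' contains a header but no gene rows")
  txt <- as.matrix(raw[, zone_cols, drop = FALSE])
  below <- txt == "0*"
  numtxt <- ifelse(below, "0", txt)
  vals <- suppressWarnings(matrix(as.numeric(numtxt), nrow = nrow(txt)))
  if (any(is.na(vals))) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, , drop = TRUE]
    stop("format error: non-numeric cell '", txt[bad[1], bad[2]], "' at row ",
         bad[1], " (gene '", raw$gene_id[bad[1]], "'), column '",
         zone_cols[bad[2]], "'")
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, , drop = TRUE]
    stop("format error: negative RPKM at row ", bad[1], " (gene '",
         raw$gene_id[bad[1]], "'), column '", zone_cols[bad[2]], "'")
  }
  if (dedupe == "error" && anyDuplicated(raw$gene_id))
    stop("duplication error: gene_id '",
         raw$gene_id[duplicated(raw$gene_id)][1],
         "' appears more than once; use collapse_duplicates() to merge rows")
  em <- expression_matrix(vals, gene_ids = raw$gene_id,
                          names = if (has_name) raw$name else NULL,
                          zones = zone_cols, below_detection = below)
  attr(em, "cell_text") <- txt   # verbatim cell text, for lossless round-trip
  em
}

#' Write an RPKM expression table
#'
#' Inverse of [read_expression_table()]. When the matrix still carries the
#' verbatim cell text it was read with (and the numeric values are
#' unmodified), that text is written back so the round-trip is byte-lossless;
#' otherwise numbers are formatted with full precision and below-detection
#' cells are written as `0*`.
#'
#' @param em an `ExpressionMatrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(em, path) {
  validate_expression_matrix(em)
  txt <- attr(em, "cell_text")
  reparse <- function(t) ifelse(t == "0*", 0, suppressWarnings(as.numeric(t)))
  if (is.null(txt) || !identical(dim(txt), dim(em$values)) ||
      !isTRUE(all(reparse(txt) == em$values))) {
    txt <- matrix(vapply(em$values, function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE),
                         character(1)), nrow = nrow(em$values))
    txt[em$below_detection] <- "0*"
  }
  has_name <- !all(is.na(em$names))
  header <- c("gene_id", if (has_name) "name", em$zones)
  rows <- cbind(em$gene_ids, if (has_name) em$names, txt)
  lines <- c(paste(header, collapse = "\t"),
             apply(rows, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Classify a gene symbol into its aquaporin subfamily
#'
#' Maize aquaporin symbols encode their subfamily in the prefix: ZmPIP1/ZmPIP2
#' (plasma membrane intrinsic proteins), ZmTIP (tonoplast), ZmNIP (NOD26-like)
#' and ZmSIP (small basic). Anything without an aquaporin prefix is "other".
#' Total function, vectorised.
#'
#' @param name character vector of gene symbols.
#' @return character vector over `{"PIP1","PIP2","TIP","NIP","SIP","other"}`.
#' @examples
#' classify_by_name(c("ZmPIP2;5", "ZmNIP5;1", "GRMZM2G455124"))
#' @export
classify_by_name <- function(name) {
  name <- as.character(name)
  out <- rep("other", length(name))
  out[startsWith(name, "ZmPIP1")] <- "PIP1"
  out[startsWith(name, "ZmPIP2")] <- "PIP2"
  out[startsWith(name, "ZmTIP")] <- "TIP"
  out[startsWith(name, "ZmNIP")] <- "NIP"
  out[startsWith(name, "ZmSIP")] <- "SIP"
  out
}

#' Merge duplicated gene-model rows
#'
#' The published table reports the indistinguishable isoforms ZmPIP1;3 and
#' ZmPIP1;4 as two rows under one gene model with identical RPKM vectors.
#' This collapses such rows to one per gene_id, concatenating the symbols,
#' and reports each merge. Rows sharing a gene_id with *different* values are
#' a conflict, never silently averaged.
#'
#' @param em an `ExpressionMatrix`.
#' @return list with `matrix` (one row per gene_id) and `merges`, a data.frame
#'   with columns `gene_id`, `names`, `n_rows` (one row per merge performed,
#'   zero rows when there was nothing to merge).
#' @export
collapse_duplicates <- function(em) {
  validate_expression_matrix(em)
  ids <- em$gene_ids
  dup_ids <- unique(ids[duplicated(ids)])
  merges <- data.frame(gene_id = character(), names = character(),
                       n_rows = integer(), stringsAsFactors = FALSE)
  if (length(dup_ids) == 0L)
    return(list(matrix = em, merges = merges))
  keep <- !duplicated(ids)
  names_out <- em$names
  for (id in dup_ids) {
    rows <- which(ids == id)
    ref <- em$values[rows[1], ]
    for (r in rows[-1]) {
      if (!isTRUE(all(em$values[r, ] == ref)))
        stop("conflict error: gene_id '", id,
             "' has rows with differing RPKM vectors; refusing to merge")
    }
    nm <- unique(stats::na.omit(em$names[rows]))
    merged_name <- paste(nm, collapse = "/")
    names_out[rows[1]] <- if (length(nm)) merged_name else NA_character_
    merges <- rbind(merges, data.frame(gene_id = id, names = merged_name,
                                       n_rows = length(rows), stringsAsFactors = FALSE))
  }
  out <- expression_matrix(em$values[keep, , drop = FALSE],
                           gene_ids = ids[keep], names = names_out[keep],
                           zones = em$zones,
                           below_detection = em$below_detection[keep, , drop = FALSE])
  list(matrix = out, merges = merges)
}

#' Read a gene catalogue
#'
#' A catalogue maps gene-model ids to symbols, accessions, a class (aquaporin
#' subfamily, `transporter`, or `other`) and optional GO terms. Format:
#' tab-separated with header
#' `gene_id  name  accession  gene_class  go_terms`; multiple symbols for one
#' gene model are comma-separated in `name`, as are GO ids in `go_terms`.
#' For symbols with an aquaporin prefix the stored class must agree with
#' [classify_by_name()].
#'
#' @param path file path.
#' @return data.frame with columns `gene_id`, `name`, `accession`,
#'   `gene_class`, `go_terms`; gene_ids unique.
#' @export
read_catalogue <- function(path) {
  cat <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                           colClasses = "character", fill = TRUE,
                           blank.lines.skip = TRUE)
  need <- c("gene_id", "name", "accession", "gene_class", "go_terms")
  miss <- setdiff(need, names(cat))
  if (length(miss))
    stop("format error: catalogue missing column(s): ", paste(miss, collapse = ", "))
  cat <- cat[, need]
  cat[is.na(cat)] <- ""
  if (anyDuplicated(cat$gene_id))
    stop("duplication error: catalogue gene_id '",
         cat$gene_id[duplicated(cat$gene_id)][1], "' is not unique")
  if (any(cat$gene_id == ""))
    stop("format error: empty gene_id in catalogue")
  symbols <- strsplit(cat$name, ",", fixed = TRUE)
  for (i in seq_len(nrow(cat))) {
    derived <- unique(classify_by_name(symbols[[i]]))
    derived <- setdiff(derived, "other")
    if (length(derived) && !all(derived == cat$gene_class[i]))
      stop("catalogue gene '", cat$gene_id[i], "': stored class '",
           cat$gene_class[i], "' contradicts symbol-derived class '",
           derived[1], "'")
  }
  cat
}

#' Write a gene catalogue
#' @param cat data.frame as returned by [read_catalogue()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_catalogue <- function(cat, path) {
  utils::write.table(cat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged aquaporin expression table (24 detected isoforms, 4 zones)
#'
#' The published RPKM table of maize aquaporin expression across the four
#' leaf developmental zones, digit-for-digit. Contains 24 rows; ZmPIP1;3 and
#' ZmPIP1;4 appear as separate rows under the shared gene model
#' GRMZM2G392975 (use [collapse_duplicates()] before network construction).
#'
#' @return an `ExpressionMatrix` with 24 rows and 4 zones.
#' @export
table1_matrix <- function() {
  read_expression_table(system.file("extdata", "table1_rpkm.tsv",
                                    package = "leafcoex", mustWork = TRUE))
}

#' Packaged maize aquaporin catalogue (33 gene symbols)
#'
#' All 33 maize aquaporin symbols known from genome annotation: 13 PIP
#' (6 PIP1 + 7 PIP2), 11 TIP, 6 NIP and 3 SIP, covering both the 24 isoforms
#' detected along the gradient and the 9 with no detectable expression.
#' ZmPIP1;3/ZmPIP1;4 share one record (one gene model, two symbols), so the
#' catalogue holds 32 records carrying 33 symbols. ZmPIP1;2 has no published
#' identifier; its record carries the synthetic placeholder id
#' `synthetic:ZmPIP1;2`.
#'
#' @return data.frame in [read_catalogue()] layout.
#' @export
aquaporin_catalogue <- function() {
  read_catalogue(system.file("extdata", "aquaporin_catalogue.tsv",
                             package = "leafcoex", mustWork = TRUE))
}

#' Tally catalogue entries by class
#'
#' Counts gene *symbols* (not records) per class, so a record carrying two
#' symbols for one gene model contributes two. PIP1 and PIP2 are also
#' reported combined as PIP, the convention used when summarising subfamily
#' totals.
#'
#' @param cat catalogue data.frame.
#' @return named integer vector with one element per class present plus
#'   `PIP` (= PIP1 + PIP2) and `total`.
#' @export
catalogue_tallies <- function(cat) {
  symbols <- strsplit(cat$name, ",", fixed = TRUE)
  cls <- rep(cat$gene_class, lengths(symbols))
  tal <- table(cls)
  out <- stats::setNames(as.integer(tal), names(tal))
  out["PIP"] <- sum(out[c("PIP1", "PIP2")], na.rm = TRUE)
  out["total"] <- length(unlist(symbols))
  out
}
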