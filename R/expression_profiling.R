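#' Detection calls along the gradient
#'
#' A gene is called detected when its maximum RPKM over the zones reaches
#' `min_detect`; each zone is called expressed the same way. The default
#' threshold of 1 RPKM is the conventional floor for calling a transcript
#' present in bulk RNA-Seq.
#'
#' Subfamily tallies are computed over detected genes from the gene symbols
#' (via [classify_by_name()] unless the row symbol is missing, in which case
#' the gene counts under "other"); PIP1 and PIP2 are combined as PIP in the
#' summary tally, the convention for subfamily totals.
#'
#' @param em an `ExpressionMatrix`.
#' @param min_detect RPKM detection threshold, >= 0 (default 1.0).
#' @return list with `calls` — data.frame of `gene_id`, `name`, `detected`,
#'   one `expressed_<zone>` logical per zone, `peak_zone` — and `tallies`,
#'   a named integer vector of detected counts per class (incl. combined
#'   `PIP` and `total`).
#' @export
detect_expressed <- function(em, min_detect = 1.0) {
  validate_expression_matrix(em)
  stopifnot(min_detect >= 0)
  v <- em$values
  per_zone <- v >= min_detect
  detected <- apply(per_zone, 1, any)
  peaks <- em$zones[apply(v, 1, which.max)]
  calls <- data.frame(gene_id = em$gene_ids, name = em$names,
                      detected = detected, stringsAsFactors = FALSE)
  for (j in seq_along(em$zones))
    calls[[paste0("expressed_", em$zones[j])]] <- per_zone[, j]
  calls$peak_zone <- peaks
  cls <- classify_by_name(em$names)
  cls[is.na(em$names)] <- "other"
  tal <- table(cls[detected])
  tallies <- stats::setNames(as.integer(tal), names(tal))
  tallies["PIP"] <- sum(tallies[c("PIP1", "PIP2")], na.rm = TRUE)
  tallies["total"] <- sum(detected)
  list(calls = calls, tallies = tallies)
}

#' Stage-silenced classification ("specifically expressed", sensu the source study)
#'
#' Flags, for each detected gene, the zones in which it is low or undetected
#' (RPKM below `low_threshold`). Note the inherited terminology inversion:
#' the source study defines a gene "specifically expressed in" a stage as one
#' expressed at low levels or not detected *in that stage* — i.e. the flag
#' marks where the gene is silent, not where it peaks. The function name and
#' output column say "flagged"/"low" to keep that unambiguous.
#'
#' @param em an `ExpressionMatrix`.
#' @param low_threshold RPKM below which a zone is flagged (default 1.0).
#' @param max_low_zones genes with more flagged zones than this are dropped
#'   from the report (default: number of zones, i.e. no suppression).
#' @param min_detect detection threshold; genes not detected at all receive
#'   no flags (they are absent, not stage-silenced).
#' @return data.frame `gene_id`, `name`, `flagged_zones` (comma-joined zone
#'   labels, "" when none), `n_flagged`.
#' @export
classify_stage_specific <- function(em, low_threshold = 1.0,
                                    max_low_zones = length(em$zones),
                                    min_detect = 1.0) {
  validate_expression_matrix(em)
  det <- detect_expressed(em, min_detect)$calls$detected
  low <- em$values < low_threshold
  flags <- vapply(seq_len(nrow(em$values)), function(i) {
    if (!det[i]) return("")
    paste(em$zones[low[i, ]], collapse = ",")
  }, character(1))
  n <- ifelse(det, rowSums(low), 0L)
  out <- data.frame(gene_id = em$gene_ids, name = em$names,
                    flagged_zones = flags, n_flagged = as.integer(n),
                    stringsAsFactors = FALSE)
  out[out$n_flagged <= max_low_zones, , drop = FALSE]
}

#' RPKM fold change between two zones
#'
#' ratio = (RPKM[zone_a] + pseudocount) / (RPKM[zone_b] + pseudocount).
#' With the default pseudocount of 0 a zero denominator yields `Inf` with
#' `infinite = TRUE` rather than an error — the published ratios are plain
#' divisions of printed values.
#'
#' @param em an `ExpressionMatrix` with unique gene ids (or a unique symbol
#'   match via `name`).
#' @param gene gene_id or gene symbol.
#' @param zone_a numerator zone label.
#' @param zone_b denominator zone label.
#' @param pseudocount value added to both terms, >= 0 (default 0).
#' @return list `gene_id`, `name`, `numerator_zone`, `denominator_zone`,
#'   `ratio`, `pseudocount`, `infinite`.
#' @export
fold_change <- function(em, gene, zone_a, zone_b, pseudocount = 0) {
  validate_expression_matrix(em)
  stopifnot(pseudocount >= 0)
  row <- which(em$gene_ids == gene)
  if (length(row) == 0L) row <- which(em$names == gene)
  if (length(row) == 0L)
    stop("lookup error: gene '", gene, "' not found")
  if (length(row) > 1L)
    stop("lookup error: gene '", gene, "' matches ", length(row),
         " rows; collapse duplicates first")
  ia <- match(zone_a, em$zones); ib <- match(zone_b, em$zones)
  if (is.na(ia) || is.na(ib))
    stop("lookup error: unknown zone '", if (is.na(ia)) zone_a else zone_b, "'")
  num <- em$values[row, ia] + pseudocount
  den <- em$values[row, ib] + pseudocount
  ratio <- if (den == 0) Inf else num / den
  list(gene_id = em$gene_ids[row], name = em$names[row],
       numerator_zone = zone_a, denominator_zone = zone_b,
       ratio = ratio, pseudocount = pseudocount,
       infinite = is.infinite(ratio))
}

#' Peak zone per gene
#'
#' Argmax of RPKM over the gradient for every row. Ties break toward the
#' earlier (younger) zone and are recorded.
#'
#' @param em an `ExpressionMatrix`.
#' @return data.frame `gene_id`, `name`, `peak_zone`, `tie` (logical).
#' @export
peak_zone_table <- function(em) {
  validate_expression_matrix(em)
  idx <- apply(em$values, 1, which.max)   # which.max: first maximum = earlier zone
  tie <- vapply(seq_len(nrow(em$values)), function(i)
    sum(em$values[i, ] == em$values[i, idx[i]]) > 1L, logical(1))
  data.frame(gene_id = em$gene_ids, name = em$names,
             peak_zone = em$zones[idx], tie = tie, stringsAsFactors = FALSE)
}

#' Combined per-gene profiling report
#'
#' One row per gene: identity, class, detection, peak zone, stage-silenced
#' flags, and the RPKM per zone — the layout of the published expression
#' table plus the derived calls.
#'
#' @param em an `ExpressionMatrix`.
#' @param catalogue optional catalogue data.frame for class/accession lookup;
#'   when absent, class is derived from the row symbol.
#' @param min_detect,low_threshold thresholds, see [detect_expressed()] and
#'   [classify_stage_specific()].
#' @return data.frame; write with [utils::write.table()] or via
#'   [run_pipeline()].
#' @export
profile_report <- function(em, catalogue = NULL, min_detect = 1.0,
                           low_threshold = 1.0) {
  det <- detect_expressed(em, min_detect)
  flags <- classify_stage_specific(em, low_threshold, min_detect = min_detect)
  cls <- classify_by_name(em$names)
  if (!is.null(catalogue)) {
    hit <- match(em$gene_ids, catalogue$gene_id)
    cls <- ifelse(!is.na(hit), catalogue$gene_class[hit], cls)
  }
  rep <- data.frame(gene_id = em$gene_ids, name = em$names, class = cls,
                    detected = det$calls$detected,
                    peak_zone = det$calls$peak_zone,
                    flagged_zones = flags$flagged_zones[match(em$gene_ids, flags$gene_id)],
                    stringsAsFactors = FALSE)
  rpkm <- as.data.frame(em$values)
  names(rpkm) <- em$zones
  cbind(rep, rpkm)
}
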