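#' Mine aquaporin-transporter coexpression associations
#'
#' Evaluates every query x target pair (e.g. aquaporins x transmembrane
#' transporters) against the rank-based edge criteria, computed on the full
#' supplied matrix: correlations and neighbour ranks are taken over *all*
#' genes in `em`, so a pair's rank reflects the genome-wide neighbourhood,
#' not just the pair. A pair "exhibits the same expression pattern" exactly
#' when it would be an edge of [build_network()] on the same matrix and
#' parameters.
#'
#' @param em an `ExpressionMatrix` with unique gene ids containing both sets.
#' @param query_ids character vector of query gene_ids (aquaporins).
#' @param target_ids character vector of target gene_ids (transporters);
#'   must be disjoint from `query_ids`.
#' @param params a `NetworkParams` (default: published settings).
#' @param catalogue optional catalogue data.frame; supplies symbols and GO
#'   terms for the output.
#' @return an `AssociationTable`: data.frame of the *passing* records with
#'   columns `query_id`, `query_name`, `target_id`, `target_name`, `cc`,
#'   `rank_qt` (target's rank in the query's list), `rank_tq`,
#'   `target_go_terms`; attribute `n_evaluated` holds the number of pairs
#'   examined.
#' @export
associate <- function(em, query_ids, target_ids, params = network_params(),
                      catalogue = NULL) {
  validate_expression_matrix(em)
  query_ids <- unique(as.character(query_ids))
  target_ids <- unique(as.character(target_ids))
  overlap <- intersect(query_ids, target_ids)
  if (length(overlap))
    stop("input error: query and target sets overlap: ",
         paste(overlap, collapse = ", "))
  missing <- setdiff(c(query_ids, target_ids), em$gene_ids)
  if (length(missing))
    stop("lookup error: id(s) not in matrix: ", paste(missing, collapse = ", "))
  cc <- correlation_matrix(em)
  rk <- rank_neighbors(cc)
  lookup_name <- function(id) {
    if (!is.null(catalogue)) {
      hit <- match(id, catalogue$gene_id)
      if (!is.na(hit)) return(catalogue$name[hit])
    }
    nm <- em$names[match(id, em$gene_ids)]
    if (is.na(nm)) "" else nm
  }
  lookup_go <- function(id) {
    if (is.null(catalogue)) return("")
    hit <- match(id, catalogue$gene_id)
    if (is.na(hit)) "" else catalogue$go_terms[hit]
  }
  recs <- list()
  for (q in query_ids) {
    for (t in target_ids) {
      c_qt <- cc[q, t]
      if (is.na(c_qt) || c_qt <= params$min_cc) next
      pass_rank <- if (params$rank_mode == "either_direction")
        (rk[q, t] <= params$max_rank || rk[t, q] <= params$max_rank)
      else
        (rk[q, t] <= params$max_rank && rk[t, q] <= params$max_rank)
      if (!isTRUE(pass_rank)) next
      recs[[length(recs) + 1L]] <- data.frame(
        query_id = q, query_name = lookup_name(q),
        target_id = t, target_name = lookup_name(t),
        cc = c_qt, rank_qt = rk[q, t], rank_tq = rk[t, q],
        target_go_terms = lookup_go(t), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(recs)) do.call(rbind, recs)
         else data.frame(query_id = character(), query_name = character(),
                         target_id = character(), target_name = character(),
                         cc = numeric(), rank_qt = integer(),
                         rank_tq = integer(), target_go_terms = character(),
                         stringsAsFactors = FALSE)
  out <- out[order(out$query_id, -out$cc, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_evaluated") <- length(query_ids) * length(target_ids)
  class(out) <- c("AssociationTable", class(out))
  out
}

#' Transporters shared by several aquaporins
#'
#' Groups an association table by target: a transporter associated with two
#' or more queries is the "overlapping expression pattern" signature —
#' e.g. one multidrug-resistance ABC transporter matching several tonoplast
#' aquaporins at once. Targets with >= 2 queries come first, descending by
#' count; ordering is deterministic (count, then target_id).
#'
#' @param table an `AssociationTable` from [associate()].
#' @return data.frame `target_id`, `target_name`, `n_queries`, `queries`
#'   (comma-joined query ids, sorted).
#' @export
shared_target_report <- function(table) {
  if (nrow(table) == 0L)
    return(data.frame(target_id = character(), target_name = character(),
                      n_queries = integer(), queries = character(),
                      stringsAsFactors = FALSE))
  sp <- split(table$query_id, table$target_id)
  out <- data.frame(target_id = names(sp),
                    target_name = table$target_name[match(names(sp), table$target_id)],
                    n_queries = lengths(sp),
                    queries = vapply(sp, function(q) paste(sort(unique(q)), collapse = ","),
                                     character(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_queries, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an association table as TSV
#' @param table an `AssociationTable`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
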