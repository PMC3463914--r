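#' Pearson correlation of two expression profiles
#'
#' Product-moment correlation of two equal-length RPKM vectors. A profile
#' with zero variance (flat along the gradient) has no defined correlation:
#' the result is `NA_real_`, which the network construction treats as
#' "undefined" — never 0, never an error.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in \[-1, 1\], or `NA_real_` when either vector has
#'   zero variance.
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y))
    stop("dimension error: profile lengths differ (", length(x), " vs ", length(y), ")")
  if (length(x) < 2L)
    stop("dimension error: profiles need length >= 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Pairwise correlation matrix of an expression matrix
#'
#' Symmetric matrix of Pearson correlations between all gene pairs.
#' Zero-variance rows get `NA` against everything including themselves
#' (their correlation is undefined); all other diagonal entries are 1.
#'
#' @param em an `ExpressionMatrix` with unique gene ids.
#' @return numeric matrix with gene_ids as dimnames; `NA` marks undefined.
#' @export
correlation_matrix <- function(em) {
  validate_expression_matrix(em)
  if (anyDuplicated(em$gene_ids))
    stop("duplication error: gene ids are not unique; use collapse_duplicates() first")
  m <- t(em$values)
  flat <- apply(m, 2, stats::sd) == 0
  cc <- suppressWarnings(stats::cor(m))
  cc[flat, ] <- NA_real_
  cc[, flat] <- NA_real_
  dimnames(cc) <- list(em$gene_ids, em$gene_ids)
  cc
}

#' Rank every gene's neighbours by correlation
#'
#' For each gene g, all other genes with a defined correlation to g are
#' sorted by descending correlation; rank(g, h) is h's 1-based position in
#' g's list. Correlations are quantized to 12 decimals before sorting, so
#' that mathematically tied values (e.g. two exact scaled copies, both cc = 1)
#' cannot be reordered by floating-point rounding; remaining ties break by
#' ascending gene_id, making the ranking fully deterministic. Ranks are not
#' symmetric: rank(g, h) need not equal rank(h, g).
#'
#' @param cc correlation matrix from [correlation_matrix()].
#' @return integer matrix `rank[g, h]`; `NA` where the correlation is
#'   undefined (such pairs are excluded from the list).
#' @export
rank_neighbors <- function(cc) {
  ids <- rownames(cc)
  n <- nrow(cc)
  ccq <- round(cc, 12)
  rk <- matrix(NA_integer_, n, n, dimnames = dimnames(cc))
  for (g in seq_len(n)) {
    others <- setdiff(seq_len(n), g)
    ok <- others[!is.na(cc[g, others])]
    if (length(ok) == 0L) next
    ord <- ok[order(-ccq[g, ok], ids[ok])]
    rk[g, ord] <- seq_along(ord)
  }
  rk
}

#' Parameters of the rank-based network construction
#'
#' The two thresholds of the method: `min_cc`, a floor on the pairwise
#' Pearson correlation (an edge needs cc strictly greater), and `max_rank`,
#' a cap on how far down a gene's correlation-sorted neighbour list the
#' partner may sit. Defaults are the published settings: a stringent
#' correlation floor of 0.95 with a permissive rank cap of 50.
#'
#' @param min_cc correlation threshold in \[-1, 1\] (default 0.95).
#' @param max_rank positive integer rank cap (default 50); 0 is allowed and
#'   makes the rank condition unsatisfiable (empty network).
#' @param rank_mode `"either_direction"` (default): the pair passes when at
#'   least one gene is within the other's top `max_rank`;
#'   `"both_directions"`: both must be.
#' @return a `NetworkParams` list.
#' @export
network_params <- function(min_cc = 0.95, max_rank = 50,
                           rank_mode = c("either_direction", "both_directions")) {
  rank_mode <- match.arg(rank_mode)
  stopifnot(min_cc >= -1, min_cc <= 1, max_rank >= 0, max_rank == round(max_rank))
  structure(list(min_cc = min_cc, max_rank = as.integer(max_rank),
                 rank_mode = rank_mode), class = "NetworkParams")
}

#' Build the rank-based coexpression network
#'
#' An edge connects genes g and h iff (1) their Pearson correlation is
#' strictly greater than `min_cc`, and (2) at least one of the pair is
#' within the other's `max_rank` most-correlated neighbours (both, under
#' `rank_mode = "both_directions"`). Undefined correlations (zero-variance
#' profiles) never form edges. Each edge stores the correlation and the rank
#' in both directions.
#'
#' @param em an `ExpressionMatrix` with >= 2 genes and unique ids.
#' @param params a `NetworkParams` object (default: published settings).
#' @return a `CoexpressionNetwork`: list with `nodes` (all gene ids),
#'   `edges` (data.frame `gene_a`, `gene_b`, `cc`, `rank_ab`, `rank_ba`;
#'   gene_a < gene_b, no duplicates, possibly 0 rows), and `params`.
#' @export
build_network <- function(em, params = network_params()) {
  validate_expression_matrix(em)
  if (nrow(em$values) < 2L)
    stop("dimension error: need at least 2 genes to build a network")
  cc <- correlation_matrix(em)
  rk <- rank_neighbors(cc)
  ids <- rownames(cc)
  n <- length(ids)
  ea <- character(); eb <- character(); ec <- numeric()
  rab <- integer(); rba <- integer()
  for (g in seq_len(n - 1L)) {
    for (h in seq.int(g + 1L, n)) {
      cgh <- cc[g, h]
      if (is.na(cgh) || cgh <= params$min_cc) next
      pass_rank <- if (params$rank_mode == "either_direction")
        (rk[g, h] <= params$max_rank || rk[h, g] <= params$max_rank)
      else
        (rk[g, h] <= params$max_rank && rk[h, g] <= params$max_rank)
      if (!isTRUE(pass_rank)) next
      a <- g; b <- h
      if (ids[b] < ids[a]) { a <- h; b <- g }
      ea <- c(ea, ids[a]); eb <- c(eb, ids[b]); ec <- c(ec, cgh)
      rab <- c(rab, rk[a, b]); rba <- c(rba, rk[b, a])
    }
  }
  edges <- data.frame(gene_a = ea, gene_b = eb, cc = ec,
                      rank_ab = rab, rank_ba = rba, stringsAsFactors = FALSE)
  structure(list(nodes = ids, edges = edges, params = params),
            class = "CoexpressionNetwork")
}

#' @export
print.CoexpressionNetwork <- function(x, ...) {
  cat("CoexpressionNetwork:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges (min_cc =", x$params$min_cc, ", max_rank =", x$params$max_rank,
      ",", x$params$rank_mode, ")\n")
  invisible(x)
}

#' Convert a CoexpressionNetwork to an igraph graph
#' @param net a `CoexpressionNetwork`.
#' @return an undirected [igraph::igraph] with edge attribute `cc`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "CoexpressionNetwork"))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(net$edges)) {
    g <- igraph::add_edges(g, rbind(net$edges$gene_a, net$edges$gene_b))
    igraph::E(g)$cc <- net$edges$cc
    igraph::E(g)$rank_ab <- net$edges$rank_ab
    igraph::E(g)$rank_ba <- net$edges$rank_ba
  }
  g
}

#' Topology summary of a coexpression network
#'
#' Standard unweighted graph statistics: node and edge counts, degree
#' distribution, mean local clustering coefficient (degree < 2 nodes count
#' as 0), connected components with size-1 components (singletons) listed
#' separately, and diameter plus mean shortest-path length per non-trivial
#' component.
#'
#' @param net a `CoexpressionNetwork`.
#' @return list `n_nodes`, `n_edges`, `degree` (named vector),
#'   `degree_distribution` (table), `clustering_coefficient`,
#'   `n_components` (non-singleton), `singletons` (ids), `components`
#'   (data.frame `component`, `size`, `diameter`, `mean_path_length`).
#' @export
graph_stats <- function(net) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  deg <- if (n) igraph::degree(g) else stats::setNames(integer(), character())
  comps <- if (n) igraph::components(g) else list(membership = integer(), csize = integer(), no = 0L)
  singles <- names(comps$membership)[comps$membership %in% which(comps$csize == 1L)]
  big <- which(comps$csize > 1L)
  comp_rows <- lapply(big, function(k) {
    sub <- igraph::induced_subgraph(g, which(comps$membership == k))
    data.frame(component = k, size = igraph::vcount(sub),
               diameter = igraph::diameter(sub, unconnected = FALSE),
               mean_path_length = igraph::mean_distance(sub))
  })
  comp_df <- if (length(comp_rows)) do.call(rbind, comp_rows)
             else data.frame(component = integer(), size = integer(),
                             diameter = numeric(), mean_path_length = numeric())
  clust <- if (n == 0 || igraph::ecount(g) == 0) 0
           else mean(igraph::transitivity(g, type = "localundirected", isolates = "zero"))
  list(n_nodes = n, n_edges = igraph::ecount(g), degree = deg,
       degree_distribution = table(deg), clustering_coefficient = clust,
       n_components = length(big), singletons = singles, components = comp_df)
}

#' Export a network for Cytoscape and downstream tools
#'
#' Writes up to three files under a common prefix: `<prefix>.sif`
#' (`geneA<TAB>cc<TAB>geneB`, correlation rounded to 4 decimals),
#' `<prefix>.graphml` (with cc and rank attributes), and
#' `<prefix>_edges.tsv` (full edge table).
#'
#' @param net a `CoexpressionNetwork`.
#' @param prefix output path prefix.
#' @param formats subset of `c("sif", "graphml", "tsv")`.
#' @return character vector of files written, invisibly.
#' @export
write_network <- function(net, prefix, formats = c("sif", "graphml", "tsv")) {
  formats <- match.arg(formats, several.ok = TRUE)
  written <- character()
  if ("sif" %in% formats) {
    path <- paste0(prefix, ".sif")
    lines <- if (nrow(net$edges))
      sprintf("%s\t%.4f\t%s", net$edges$gene_a, net$edges$cc, net$edges$gene_b)
    else character()
    # isolated nodes still get a line so Cytoscape shows them
    iso <- setdiff(net$nodes, c(net$edges$gene_a, net$edges$gene_b))
    writeLines(c(lines, iso), path)
    written <- c(written, path)
  }
  if ("graphml" %in% formats) {
    path <- paste0(prefix, ".graphml")
    igraph::write_graph(as_igraph(net), path, format = "graphml")
    written <- c(written, path)
  }
  if ("tsv" %in% formats) {
    path <- paste0(prefix, "_edges.tsv")
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, path)
  }
  invisible(written)
}
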