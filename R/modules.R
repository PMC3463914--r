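#' Partition a coexpression network into modules
#'
#' A module is a connected component of the thresholded network with at
#' least `min_module_size` members — with a correlation floor of 0.95 this
#' is the minimal faithful notion of a tightly coexpressed gene group.
#' Smaller components are returned as leftovers, never dropped. Modules are
#' ordered by descending size, ties by the lexicographically smallest
#' member.
#'
#' @param net a `CoexpressionNetwork`.
#' @param min_module_size smallest component reported as a module (default 2).
#' @return list with `modules` — a list of character vectors of member
#'   gene_ids, each sorted — and `leftover`, the gene_ids in smaller
#'   components (including isolated nodes).
#' @export
partition_modules <- function(net, min_module_size = 2) {
  stopifnot(inherits(net, "CoexpressionNetwork"), min_module_size >= 1)
  g <- as_igraph(net)
  if (igraph::vcount(g) == 0L)
    return(list(modules = list(), leftover = character()))
  comps <- igraph::components(g)
  groups <- split(names(comps$membership), comps$membership)
  groups <- lapply(groups, sort)
  big <- groups[lengths(groups) >= min_module_size]
  ord <- order(-lengths(big), vapply(big, `[`, character(1), 1))
  list(modules = unname(big[ord]),
       leftover = sort(unlist(unname(groups[lengths(groups) < min_module_size]),
                              use.names = FALSE)))
}

#' Label a module by its gradient profile
#'
#' A module is `early` when a strict majority of its members peak in the
#' first half of the gradient (basal/transitional), `late` when a strict
#' majority peak in the second half (maturing/mature), and `mixed`
#' otherwise. This reproduces the biological reading of the two published
#' aquaporin modules: one high in young tissue and falling, one rising
#' toward the mature blade.
#'
#' @param members character vector of member gene_ids.
#' @param em the `ExpressionMatrix` the network was built from.
#' @return one of `"early"`, `"late"`, `"mixed"`.
#' @export
label_module <- function(members, em) {
  rows <- match(members, em$gene_ids)
  if (anyNA(rows))
    stop("lookup error: module member(s) not in matrix: ",
         paste(members[is.na(rows)], collapse = ", "))
  half <- length(em$zones) %/% 2
  peak_idx <- apply(em$values[rows, , drop = FALSE], 1, which.max)
  n_early <- sum(peak_idx <= half)
  n_late <- sum(peak_idx > half)
  if (n_early > length(members) / 2) "early"
  else if (n_late > length(members) / 2) "late"
  else "mixed"
}

#' Mean z-scored profile of a gene set
#'
#' Per-zone mean of the members' z-scored profiles (zero-variance members
#' are skipped — they have no shape to average).
#'
#' @param members character vector of gene_ids.
#' @param em the `ExpressionMatrix`.
#' @return numeric vector, one value per zone.
#' @export
module_mean_profile <- function(members, em) {
  rows <- match(members, em$gene_ids)
  if (anyNA(rows)) stop("lookup error: member(s) not in matrix")
  v <- em$values[rows, , drop = FALSE]
  sds <- apply(v, 1, stats::sd)
  v <- v[sds > 0, , drop = FALSE]
  if (nrow(v) == 0L) return(stats::setNames(rep(NA_real_, length(em$zones)), em$zones))
  z <- t(scale(t(v)))
  stats::setNames(colMeans(z), em$zones)
}

#' Module report table
#'
#' One row per module: id, profile label, size, members (ids and symbols).
#' Leftover genes appear as a final pseudo-row with module_id "leftover".
#'
#' @param partition result of [partition_modules()].
#' @param em the source `ExpressionMatrix`.
#' @return data.frame `module_id`, `profile_label`, `size`, `members`,
#'   `member_names`.
#' @export
module_table <- function(partition, em) {
  mk_row <- function(id, members, label) {
    nm <- em$names[match(members, em$gene_ids)]
    data.frame(module_id = id, profile_label = label,
               size = length(members),
               members = paste(members, collapse = ","),
               member_names = paste(ifelse(is.na(nm), "", nm), collapse = ","),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_along(partition$modules), function(i)
    mk_row(paste0("M", i), partition$modules[[i]],
           label_module(partition$modules[[i]], em)))
  if (length(partition$leftover))
    rows <- c(rows, list(mk_row("leftover", partition$leftover, "mixed")))
  if (length(rows)) do.call(rbind, rows)
  else data.frame(module_id = character(), profile_label = character(),
                  size = integer(), members = character(),
                  member_names = character(), stringsAsFactors = FALSE)
}

#' Average-linkage hierarchical alternative partition
#'
#' Exploratory alternative to the component-based partition: average-linkage
#' hierarchical clustering on correlation distance (1 - cc), cut at `k`
#' groups. Useful to probe how sensitive a component partition is to the
#' hard correlation threshold; not used by the default pipeline.
#'
#' @param em an `ExpressionMatrix` with unique ids and >= 2 genes.
#' @param k number of clusters.
#' @return list of character vectors of gene_ids (clusters, ordered as
#'   [partition_modules()] orders modules).
#' @export
hclust_modules <- function(em, k = 2) {
  cc <- correlation_matrix(em)
  ok <- !apply(cc, 1, function(r) all(is.na(r)))
  cc <- cc[ok, ok, drop = FALSE]
  d <- stats::as.dist(1 - cc)
  cut <- stats::cutree(stats::hclust(d, method = "average"), k = k)
  groups <- lapply(split(names(cut), cut), sort)
  ord <- order(-lengths(groups), vapply(groups, `[`, character(1), 1))
  unname(groups[ord])
}

# Adjusted Rand index between two labelings (vectors over the same genes).
# Chance-corrected pair-counting agreement; 1 = identical partitions.
# Kept internal; cross-checked against mclust::adjustedRandIndex in tests.
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) <= 1) return(1)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

#' Score module recovery against ground-truth labels
#'
#' Adjusted Rand index between a recovered partition and true labels,
#' evaluated over the genes in `truth` (genes not recovered into any module
#' are grouped as one "unassigned" cluster).
#'
#' @param partition result of [partition_modules()].
#' @param truth named vector/factor: true block label per gene_id.
#' @return ARI in \[-1, 1\]; 1 means exact recovery.
#' @export
module_recovery_ari <- function(partition, truth) {
  genes <- names(truth)
  rec <- rep("unassigned", length(genes))
  names(rec) <- genes
  for (i in seq_along(partition$modules)) {
    hit <- intersect(partition$modules[[i]], genes)
    rec[hit] <- paste0("M", i)
  }
  adjusted_rand_index(rec, as.character(truth))
}
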