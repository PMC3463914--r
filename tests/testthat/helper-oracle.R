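# Independent brute-force re-implementation of the rank-based edge selection,
# used as the oracle for build_network. Deliberately shares no code with the
# package: correlation from the raw product-moment sums, ranks from a naive
# sort, edges from explicit enumeration of all pairs.

oracle_cor <- function(x, y) {
  n <- length(x)
  sx <- sqrt(sum((x - sum(x) / n)^2))
  sy <- sqrt(sum((y - sum(y) / n)^2))
  if (sx == 0 || sy == 0) return(NA_real_)
  sum((x - sum(x) / n) * (y - sum(y) / n)) / (sx * sy)
}

# edges as a sorted "a|b" character vector, for set comparison
oracle_edges <- function(values, ids, min_cc, max_rank,
                         rank_mode = "either_direction") {
  n <- nrow(values)
  cc <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) cc[i, j] <- oracle_cor(values[i, ], values[j, ])
  # ranking quantizes cc to 12 decimals (ties then break by gene_id), the
  # same stated rule the package implements
  rank_of <- function(g, h) {
    others <- setdiff(seq_len(n), g)
    others <- others[!is.na(cc[g, others])]
    if (!(h %in% others)) return(NA_integer_)
    ord <- others[order(-round(cc[g, others], 12), ids[others])]
    which(ord == h)
  }
  out <- character()
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    cij <- cc[i, j]
    if (is.na(cij) || cij <= min_cc) next
    ri <- rank_of(i, j); rj <- rank_of(j, i)
    ok <- if (rank_mode == "either_direction") (ri <= max_rank || rj <= max_rank)
          else (ri <= max_rank && rj <= max_rank)
    if (isTRUE(ok)) out <- c(out, paste(sort(c(ids[i], ids[j])), collapse = "|"))
  }
  sort(out)
}

edge_keys <- function(net) {
  if (nrow(net$edges) == 0) return(character())
  sort(paste(net$edges$gene_a, net$edges$gene_b, sep = "|"))
}

# Random small expression matrix mixing cloned/scaled rows (guaranteed high
# correlations), noisy copies, constant rows and independent rows — the cases
# the edge criteria must distinguish.
random_small_matrix <- function(n_genes, n_zones = 4) {
  vals <- matrix(NA_real_, n_genes, n_zones)
  base <- abs(rnorm(n_zones, 50, 30)) + 1
  for (i in seq_len(n_genes)) {
    kind <- sample(c("scaled", "noisy", "constant", "independent"), 1,
                   prob = c(0.3, 0.3, 0.1, 0.3))
    vals[i, ] <- switch(kind,
      scaled = base * runif(1, 0.1, 10),
      noisy = pmax(base * runif(1, 0.1, 10) + rnorm(n_zones, 0, 20), 0),
      constant = rep(runif(1, 0, 100), n_zones),
      independent = abs(rnorm(n_zones, 50, 40)))
  }
  expression_matrix(vals, gene_ids = sprintf("G%02d", seq_len(n_genes)))
}

# Generic matrix: independent continuous rows, so all pairwise correlations
# are distinct and well separated. Used for the affine-invariance and
# monotonicity properties, where exact correlation ties (cc == 1 clones)
# would make neighbour order sensitive to floating-point rounding.
random_generic_matrix <- function(n_genes, n_zones = 4) {
  vals <- matrix(abs(rnorm(n_genes * n_zones, 50, 40)) + 0.1, n_genes)
  expression_matrix(vals, gene_ids = sprintf("G%02d", seq_len(n_genes)))
}
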