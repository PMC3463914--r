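#' Specification for a simulated RPKM matrix
#'
#' Describes a synthetic gradient experiment with the statistical structure
#' the analysis assumes: two anti-correlated prototype profiles over the
#' ordered zones (early: monotone decreasing from a high basal value; late:
#' monotone increasing toward the mature blade, both spanning the ~1-1000
#' RPKM range of the real table), a block of genes per prototype, a set of
#' "transporter" genes tied to each prototype, and uncorrelated background
#' genes. Default block sizes (14, 9) mirror the two published aquaporin
#' modules.
#'
#' @param n_zones number of ordered zones (default 4, the study design).
#' @param prototypes list of base profiles (numeric vectors of length
#'   `n_zones`); default two anti-correlated monotone profiles.
#' @param module_sizes integer vector, genes per prototype (default c(14, 9)).
#' @param n_transporters_per_prototype transporter genes generated from each
#'   prototype (default 5).
#' @param n_background uncorrelated genes (default 50).
#' @param noise_sd sd of multiplicative log-normal noise on the log2 scale
#'   (default 0.05).
#' @param seed integer RNG seed (default 1).
#' @return a `SyntheticSpec` list.
#' @export
synthetic_spec <- function(n_zones = 4, prototypes = NULL,
                           module_sizes = c(14, 9),
                           n_transporters_per_prototype = 5,
                           n_background = 50, noise_sd = 0.05, seed = 1) {
  if (is.null(prototypes)) {
    early <- exp(seq(log(1000), log(2), length.out = n_zones))
    prototypes <- list(early = early, late = rev(early))
  }
  stopifnot(all(vapply(prototypes, length, integer(1)) == n_zones),
            all(module_sizes >= 0), n_transporters_per_prototype >= 0,
            n_background >= 0, noise_sd >= 0)
  if (length(module_sizes) != length(prototypes))
    stop("parameter error: module_sizes must have one entry per prototype")
  structure(list(n_zones = n_zones, prototypes = prototypes,
                 module_sizes = module_sizes,
                 n_transporters_per_prototype = n_transporters_per_prototype,
                 n_background = n_background, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

# run expr with an isolated RNG stream seeded by `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate an RPKM matrix with planted structure
#'
#' Module and transporter genes are the prototype profile times a
#' gene-specific positive scale (log-normal, sd 1 on the natural-log scale)
#' times per-zone multiplicative noise `2^N(0, noise_sd)`; positive scaling
#' leaves Pearson correlation untouched, so at `noise_sd = 0` every
#' within-prototype pair has correlation exactly 1. Background genes draw
#' each zone independently from a log-normal spanning the RPKM range.
#' Identical spec + seed gives bit-identical output.
#'
#' @param spec a `SyntheticSpec`.
#' @return list with `matrix` (an `ExpressionMatrix`; zone labels are the
#'   study's four when `n_zones == 4`, else `zone1..zoneN`) and `truth`, a
#'   data.frame `gene_id`, `role` (`module`/`transporter`/`background`),
#'   `prototype` (integer index, NA for background).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  zones <- if (spec$n_zones == 4) c("basal", "transitional", "maturing", "mature")
           else paste0("zone", seq_len(spec$n_zones))
  with_seed(spec$seed, {
    rows <- list(); ids <- character(); role <- character(); proto <- integer()
    gen_gene <- function(p) {
      base <- spec$prototypes[[p]]
      scale_g <- exp(stats::rnorm(1, 0, 1))
      noise <- 2^stats::rnorm(spec$n_zones, 0, spec$noise_sd)
      base * scale_g * noise
    }
    for (p in seq_along(spec$prototypes)) {
      for (i in seq_len(spec$module_sizes[p])) {
        rows[[length(rows) + 1L]] <- gen_gene(p)
        ids <- c(ids, sprintf("MOD%d_G%03d", p, i))
        role <- c(role, "module"); proto <- c(proto, p)
      }
    }
    for (p in seq_along(spec$prototypes)) {
      for (i in seq_len(spec$n_transporters_per_prototype)) {
        rows[[length(rows) + 1L]] <- gen_gene(p)
        ids <- c(ids, sprintf("TRANS%d_G%03d", p, i))
        role <- c(role, "transporter"); proto <- c(proto, p)
      }
    }
    for (i in seq_len(spec$n_background)) {
      rows[[length(rows) + 1L]] <- stats::rlnorm(spec$n_zones,
                                                 meanlog = log(20), sdlog = 1.5)
      ids <- c(ids, sprintf("BG_G%03d", i))
      role <- c(role, "background"); proto <- c(proto, NA_integer_)
    }
    em <- expression_matrix(do.call(rbind, rows), gene_ids = ids, zones = zones)
    truth <- data.frame(gene_id = ids, role = role, prototype = proto,
                        stringsAsFactors = FALSE)
    list(matrix = em, truth = truth)
  })
}

#' Replace a gene's profile to hit a target correlation
#'
#' Rewrites one gene's profile as an exact-construction mixture of the
#' reference profile and orthogonal noise so that the realized Pearson
#' correlation with the reference equals `target_cc` to floating-point
#' precision (checked within +/- 0.02), then shifts/scales into a positive
#' RPKM range. Used to probe edge behaviour right around the correlation
#' floor. `target_cc = 1` (`-1`) degenerates to a positively scaled
#' (sign-flipped) copy.
#'
#' @param em an `ExpressionMatrix`.
#' @param gene_id gene to rewrite.
#' @param target_cc desired correlation with the reference, in \[-1, 1\].
#' @param reference_id reference gene.
#' @param seed RNG seed for the noise draw.
#' @return the modified `ExpressionMatrix`.
#' @export
perturb_gene <- function(em, gene_id, target_cc, reference_id, seed = 1) {
  validate_expression_matrix(em)
  stopifnot(abs(target_cc) <= 1)
  gi <- match(gene_id, em$gene_ids); ri <- match(reference_id, em$gene_ids)
  if (is.na(gi) || is.na(ri))
    stop("lookup error: gene '", if (is.na(gi)) gene_id else reference_id,
         "' not in matrix")
  r <- em$values[ri, ]
  n <- length(r)
  if (stats::sd(r) == 0)
    stop("calibration error: reference profile has zero variance")
  ru <- (r - mean(r)) / sqrt(sum((r - mean(r))^2))
  y0 <- with_seed(seed, {
    zu <- NULL
    for (try in 1:100) {   # redraw if the noise lands (numerically) on ru's span
      z <- stats::rnorm(n)
      z <- z - mean(z)
      z <- z - sum(z * ru) * ru
      if (sqrt(sum(z^2)) > 1e-8) { zu <- z / sqrt(sum(z^2)); break }
    }
    if (is.null(zu)) stop("calibration error: could not draw orthogonal noise")
    target_cc * ru + sqrt(max(0, 1 - target_cc^2)) * zu
  })
  # affine map to a positive RPKM range; correlation is affine-invariant
  y <- 100 + 40 * y0 / max(stats::sd(y0), 1e-12) * (1 / sqrt(n))
  y <- pmax(y, 0)
  realized <- stats::cor(y, r)
  if (abs(realized - target_cc) > 0.02)
    stop("calibration error: realized cc ", format(realized),
         " misses target ", target_cc)
  em$values[gi, ] <- y
  em$below_detection[gi, ] <- FALSE
  attr(em, "cell_text") <- NULL
  em
}
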