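#' Configuration for an end-to-end pipeline run
#'
#' Bundles the inputs and parameters of the full analysis: profiling
#' thresholds, network parameters, output prefix. Fully serializable; a run
#' manifest (config + package version + input checksums) is written beside
#' every output set so a run can be reproduced exactly.
#'
#' @param expression path to the RPKM table (see [read_expression_table()]).
#' @param catalogue optional path to a gene catalogue.
#' @param query_class catalogue classes forming the association query set
#'   (default: the aquaporin subfamilies).
#' @param target_go GO term defining the association target set (default
#'   "GO:0055085", transmembrane transport); targets are catalogue genes
#'   carrying the term. Empty target set simply yields no associations.
#' @param min_detect,low_threshold profiling thresholds (RPKM).
#' @param params a `NetworkParams`.
#' @param min_module_size smallest reported module.
#' @param out_prefix path prefix for outputs.
#' @return a `RunConfig` list.
#' @export
run_config <- function(expression, catalogue = NULL,
                       query_class = c("PIP1", "PIP2", "TIP", "NIP", "SIP"),
                       target_go = "GO:0055085",
                       min_detect = 1.0, low_threshold = 1.0,
                       params = network_params(), min_module_size = 2,
                       out_prefix = "leafcoex_run") {
  structure(list(expression = expression, catalogue = catalogue,
                 query_class = query_class, target_go = target_go,
                 min_detect = min_detect, low_threshold = low_threshold,
                 params = params, min_module_size = min_module_size,
                 out_prefix = out_prefix),
            class = "RunConfig")
}

# atomic TSV write: temp file in the target directory, then rename
write_tsv_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Profiling, network construction, module partition and (when a catalogue
#' with transporter targets is supplied) association mining, in order.
#' Duplicated gene-model rows are collapsed before network construction and
#' the merges reported. All outputs are written atomically (temp file +
#' rename), so a failed run leaves no partial files. Outputs under
#' `<out_prefix>`: `_profile.tsv`, `.sif`/`.graphml`/`_edges.tsv`,
#' `_modules.tsv`, `_associations.tsv`, `_shared_targets.tsv`,
#' `_manifest.json`.
#'
#' @param config a `RunConfig`.
#' @param quiet suppress progress messages.
#' @return (invisibly) list with the in-memory results: `matrix`, `merges`,
#'   `profile`, `network`, `stats`, `partition`, `modules`, `associations`,
#'   `files`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  say <- function(...) if (!quiet) message("[leafcoex] ", ...)
  say("reading expression table: ", config$expression)
  em <- read_expression_table(config$expression)
  cat <- if (!is.null(config$catalogue)) read_catalogue(config$catalogue) else NULL

  say("profiling ", nrow(em$values), " genes")
  prof <- profile_report(em, cat, config$min_detect, config$low_threshold)

  collapsed <- collapse_duplicates(em)
  if (nrow(collapsed$merges))
    say("collapsed ", nrow(collapsed$merges), " duplicated gene model(s)")
  emc <- collapsed$matrix

  say("building network (min_cc = ", config$params$min_cc,
      ", max_rank = ", config$params$max_rank, ")")
  net <- build_network(emc, config$params)
  stats <- graph_stats(net)
  say(stats$n_edges, " edges, ", stats$n_components, " non-trivial component(s)")

  part <- partition_modules(net, config$min_module_size)
  mods <- module_table(part, emc)

  assoc <- NULL; shared <- NULL
  if (!is.null(cat)) {
    query_ids <- intersect(cat$gene_id[cat$gene_class %in% config$query_class],
                           emc$gene_ids)
    has_go <- vapply(strsplit(cat$go_terms, ",", fixed = TRUE),
                     function(g) config$target_go %in% trimws(g), logical(1))
    target_ids <- intersect(cat$gene_id[has_go & !(cat$gene_class %in% config$query_class)],
                            emc$gene_ids)
    say("associating ", length(query_ids), " queries x ",
        length(target_ids), " targets")
    assoc <- associate(emc, query_ids, target_ids, config$params, cat)
    shared <- shared_target_report(assoc)
  }

  prefix <- config$out_prefix
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  files <- c(profile = write_tsv_atomic(prof, paste0(prefix, "_profile.tsv")),
             modules = write_tsv_atomic(mods, paste0(prefix, "_modules.tsv")))
  files <- c(files, network = write_network(net, prefix))
  if (!is.null(assoc)) {
    files <- c(files,
               associations = write_tsv_atomic(as.data.frame(assoc),
                                               paste0(prefix, "_associations.tsv")),
               shared = write_tsv_atomic(shared, paste0(prefix, "_shared_targets.tsv")))
  }
  manifest <- list(
    package = "leafcoex",
    version = as.character(utils::packageVersion("leafcoex")),
    config = list(expression = config$expression,
                  catalogue = config$catalogue,
                  query_class = config$query_class,
                  target_go = config$target_go,
                  min_detect = config$min_detect,
                  low_threshold = config$low_threshold,
                  min_cc = config$params$min_cc,
                  max_rank = config$params$max_rank,
                  rank_mode = config$params$rank_mode,
                  min_module_size = config$min_module_size,
                  out_prefix = config$out_prefix),
    input_md5 = as.list(tools::md5sum(stats::na.omit(c(config$expression, config$catalogue)))),
    n_genes = nrow(em$values), n_edges = stats$n_edges,
    n_modules = length(part$modules))
  manifest_path <- paste0(prefix, "_manifest.json")
  tmp <- tempfile(tmpdir = dirname(manifest_path), fileext = ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  file.rename(tmp, manifest_path)
  files <- c(files, manifest = manifest_path)

  invisible(list(matrix = emc, merges = collapsed$merges, profile = prof,
                 network = net, stats = stats, partition = part,
                 modules = mods, associations = assoc, shared = shared,
                 files = files))
}
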