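# The stepwise refinement pipeline: anchors -> candidate graph -> distance
# pruning -> duplication-aware list alignment -> cograph editing -> event
# mapping, with every stage's artifact retained.

#' Pipeline configuration
#'
#' @param distance see [distance_params()].
#' @param scoring see [scoring_params()].
#' @param join_clusters merge synteny clusters sharing a boundary anchor
#'   before alignment (coarser synteny; default `FALSE`).
#' @param allow_inversions see [build_candidate_graph()].
#' @param exception_pairs see [dollo_events()].
#' @param exact_cograph_bound,cograph_hard_cap see [edit_to_cograph()].
#' @param k_proteins see [interpolation_orthologs()].
#' @param seed RNG seed recorded with the run (the pipeline itself is
#'   deterministic; the seed matters for simulated inputs).
#' @export
pipeline_config <- function(distance = distance_params(),
                            scoring = scoring_params(),
                            join_clusters = FALSE,
                            allow_inversions = FALSE,
                            exception_pairs = list(),
                            exact_cograph_bound = 10,
                            cograph_hard_cap = 40,
                            k_proteins = 10,
                            seed = 1) {
  as.list(environment())
}

#' Load a pipeline configuration from a YAML file
#'
#' Unset keys fall back to the defaults of [pipeline_config()]; nested
#' sections `distance` and `scoring` map onto [distance_params()] and
#' [scoring_params()].
#'
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (k in intersect(names(y), c("join_clusters", "allow_inversions",
                                  "exact_cograph_bound", "cograph_hard_cap",
                                  "k_proteins", "seed"))) {
    cfg[[k]] <- y[[k]]
  }
  if (!is.null(y$exception_pairs)) cfg$exception_pairs <- y$exception_pairs
  if (!is.null(y$distance)) cfg$distance <- do.call(distance_params, y$distance)
  if (!is.null(y$scoring)) cfg$scoring <- do.call(scoring_params, y$scoring)
  cfg
}

#' Run the full orthology pipeline
#'
#' Executes anchors -> candidate graph -> pruned graph -> list alignments ->
#' estimated graph -> cograph editing -> event/remolding/intron inference,
#' asserting the stage-chain invariant (each stage's edges are a subset of
#' the previous stage's) along the way.  Deterministic for fixed inputs.
#'
#' @param genes gene table (all species).
#' @param anchors anchor placement table.
#' @param tree species tree (`ape::phylo`, rooted).
#' @param config see [pipeline_config()].
#' @param output_dir optional directory; when given, every stage's artifact
#'   is written there as TSV/Newick.
#' @return list with `candidate`, `pruned`, `estimated`, `edited`
#'   (orthology graphs), `alignments`, `edit_log`, `events` (per-branch
#'   table + per-component detail), `remoldings`, `introns`, `config`.
#' @export
run_pipeline <- function(genes, anchors, tree, config = pipeline_config(),
                         output_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  missing_sp <- setdiff(unique(genes$species), tree$tip.label)
  if (length(missing_sp) > 0) {
    stop(sprintf("pipeline stage 'events' would fail: species missing from tree: %s",
                 paste(missing_sp, collapse = ", ")))
  }

  gc_ <- stage("candidate", build_candidate_graph(genes, anchors,
                                                  config$allow_inversions))
  if (config$join_clusters) gc_ <- stage("join", join_components(gc_))
  ga <- stage("prune", prune_by_distance(gc_, config$distance))
  est <- stage("align", build_estimated_orthology(ga, config$scoring))
  go <- est$graph
  ed <- stage("edit", edit_orthology_graph(go,
                                           config$exact_cograph_bound,
                                           config$cograph_hard_cap))
  # stage-chain invariant: estimated edges within pruned within candidate
  stopifnot(nrow(graph_compare(ga, gc_)$only_g1) == 0,
            nrow(graph_compare(go, ga)$only_g1) == 0)

  ev <- stage("events", summarize_events(ed$graph, tree,
                                         config$exception_pairs,
                                         config$distance$threshold_fraction))
  rem <- stage("remolding", detect_remoldings(ed$graph, tree,
                                              config$distance$threshold_fraction))
  intr <- stage("introns", intron_consistency(ed$graph))

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(output_dir, f)
    write_anchors_tsv(anchors, p("anchors.tsv"))
    write_edges_tsv(gc_, p("graph_candidate.tsv"))
    write_edges_tsv(ga, p("graph_pruned.tsv"))
    write_edges_tsv(go, p("graph_estimated.tsv"))
    write_edges_tsv(ed$graph, p("graph_edited.tsv"))
    write_clusters_tsv(gc_, p("clusters.tsv"))
    write_event_table_tsv(ev$table, p("events.tsv"))
    write_remoldings_tsv(rem, p("remoldings.tsv"))
    utils::write.table(intr, p("introns.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    ape::write.tree(tree, p("species_tree.nwk"))
  }

  list(candidate = gc_, pruned = ga, estimated = go, edited = ed$graph,
       alignments = est$alignments, edit_log = ed$edit_log,
       events = ev, remoldings = rem, introns = intr, config = config)
}
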