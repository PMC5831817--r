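#' Pipeline configuration
#'
#' Validated settings for an end-to-end run. Input is either a synthetic
#' preset (see [hox_parahox_scenario()]) or a triple of file paths:
#' candidate FASTA, seed homeodomain alignment (aligned FASTA) and a file of
#' seed sequence ids (one per line). Analysis cutoffs must be at least as
#' stringent as the report cutoff so that tightening never needs
#' re-alignment.
#'
#' @param out_dir output directory (created if missing).
#' @param preset synthetic preset name, or `NULL` when using input files.
#' @param severity,sim_seed synthetic preset parameters.
#' @param candidate_fasta,seed_alignment,seed_id_file input paths (used when
#'   `preset` is `NULL`; must exist at validation time).
#' @param scheme `scoring_scheme`.
#' @param report_cutoff permissive E-value cutoff for hit reporting.
#' @param analysis_cutoffs E-value cutoffs for the maps (defaults 1e-33 and
#'   1e-40).
#' @param redundancy_threshold identity threshold for CD-hit-style
#'   clustering.
#' @param calibration_fpr,calibration_n,calibration_seed profile threshold
#'   calibration settings.
#' @param layout_par `layout_params`.
#' @param layout_seed,layout_dims layout RNG seed and dimensionality.
#' @param tie_margin relative tie margin for rankings.
#' @param nj_contrast also run the neighbor-joining contrast?
#' @param plots write map figures?
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            preset = NULL, severity = 1, sim_seed = 1,
                            candidate_fasta = NULL, seed_alignment = NULL,
                            seed_id_file = NULL,
                            scheme = scoring_scheme(),
                            report_cutoff = 1e-2,
                            analysis_cutoffs = c(1e-33, 1e-40),
                            redundancy_threshold = 0.95,
                            calibration_fpr = 1e-3, calibration_n = 1000,
                            calibration_seed = 1,
                            layout_par = layout_params(),
                            layout_seed = 1, layout_dims = 2,
                            tie_margin = 0.10,
                            nj_contrast = FALSE, plots = TRUE) {
  if (any(analysis_cutoffs > report_cutoff)) {
    stop("analysis cutoff(s) more permissive than report_cutoff",
         call. = FALSE)
  }
  if (is.null(preset)) {
    paths <- c(candidate_fasta, seed_alignment, seed_id_file)
    if (length(paths) != 3 || !all(file.exists(paths))) {
      stop("without a preset, candidate_fasta, seed_alignment and ",
           "seed_id_file must all exist", call. = FALSE)
    }
  }
  structure(list(out_dir = out_dir, preset = preset, severity = severity,
                 sim_seed = sim_seed, candidate_fasta = candidate_fasta,
                 seed_alignment = seed_alignment, seed_id_file = seed_id_file,
                 scheme = scheme, report_cutoff = report_cutoff,
                 analysis_cutoffs = analysis_cutoffs,
                 redundancy_threshold = redundancy_threshold,
                 calibration_fpr = calibration_fpr,
                 calibration_n = calibration_n,
                 calibration_seed = calibration_seed,
                 layout_par = layout_par, layout_seed = layout_seed,
                 layout_dims = layout_dims, tie_margin = tie_margin,
                 nj_contrast = nj_contrast, plots = plots),
            class = "pipeline_config")
}

#' Run the full classification pipeline
#'
#' Executes the four workflow steps end to end: profile build + domain scan;
#' redundancy clustering, a first map and seed-cluster selection;
#' re-inflation, the multi-homeodomain filter and annotation; the final
#' all-against-all comparison, maps at each analysis cutoff, the
#' force-directed layout and the assignment report (plus, optionally, the
#' neighbor-joining contrast). Every artifact lands under `config$out_dir`
#' and a JSON manifest with per-stage counts, seeds and artifact checksums
#' is written on success and on failure.
#'
#' @param config `pipeline_config`.
#' @param quiet suppress stage messages?
#' @return list with `graph`, `layout`, `report`, `nj`, `dataset` (synthetic
#'   runs only) and `manifest`, invisibly the same data.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(config = config_snapshot(config),
                   package_version = as.character(utils::packageVersion("parahoxmap")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list())
  stage <- "init"
  result <- try({
    out <- list()
    art <- function(name) file.path(config$out_dir, name)

    stage <- "inputs"
    if (!is.null(config$preset)) {
      dataset <- hox_parahox_scenario(config$preset, config$severity,
                                      config$sim_seed)
      seqs <- dataset$sequences
      seed <- seed_alignment_from_dataset(dataset)
      seed_aln <- seed$alignment
      seed_ids <- seed$seed_ids
      out$dataset <- dataset
      write_fasta(seqs, art("candidates.fasta"))
      write_fasta(seed_aln, art("seed_alignment.fasta"))
      writeLines(seed_ids, art("seed_ids.txt"))
    } else {
      seqs <- read_fasta(config$candidate_fasta)
      seed_aln <- read_fasta(config$seed_alignment)
      seed_ids <- readLines(config$seed_id_file)
    }
    manifest$stages$inputs <- list(n_candidates = nrow(seqs),
                                   n_seed_rows = nrow(seed_aln))
    say("inputs: %d candidate sequences, %d seed alignment rows",
        nrow(seqs), nrow(seed_aln))

    stage <- "profile"
    profile <- build_profile(seed_aln)
    profile <- calibrate_profile(profile, config$calibration_n,
                                 config$calibration_fpr,
                                 config$calibration_seed)
    hits <- scan_sequences(profile, seqs)
    write_hits_tsv(hits, art("domain_hits.tsv"))
    manifest$stages$profile <- list(match_columns = profile$length,
                                    score_threshold = profile$score_threshold,
                                    n_domain_hits = nrow(hits))
    say("profile: %d match columns, threshold %.3f, %d domain hits",
        profile$length, profile$score_threshold, nrow(hits))

    stage <- "redundancy"
    rmap <- cluster_redundant(seqs, config$redundancy_threshold)
    reps <- representatives(rmap)
    write_redundancy_tsv(rmap, art("redundancy_map.tsv"))
    rep_seqs <- seqs[seqs$seq_id %in% reps, , drop = FALSE]
    manifest$stages$redundancy <- list(n_in = nrow(seqs),
                                       n_representatives = length(reps))
    say("redundancy: %d -> %d representatives", nrow(seqs), length(reps))

    stage <- "seed_clusters"
    first_hits <- all_against_all(rep_seqs, config$scheme,
                                  config$report_cutoff)
    first_graph <- similarity_graph(rep_seqs, first_hits,
                                    config$analysis_cutoffs[1])
    comps <- connected_components(first_graph)
    seed_reps <- unique(unname(rmap$representative_of[seed_ids]))
    kept_reps <- select_seed_clusters(comps, seed_reps)
    inflated <- reinflate(kept_reps, rmap, seqs)
    manifest$stages$seed_clusters <- list(n_components = length(comps),
                                          n_kept_representatives = length(kept_reps),
                                          n_after_reinflation = nrow(inflated))
    say("seed clusters: %d components, %d representatives kept, %d after re-inflation",
        length(comps), length(kept_reps), nrow(inflated))

    stage <- "multidomain_filter"
    filt <- filter_multidomain(inflated, profile)
    final <- annotate_groups(filt$kept)
    write_fasta(final, art("final_sequences.fasta"))
    write_annotation_tsv(final, art("annotation.tsv"))
    manifest$stages$multidomain_filter <- list(n_removed = nrow(filt$removed),
                                               n_kept = nrow(final),
                                               n_zero_hit = sum(final$n_domain_hits == 0))
    say("multi-domain filter: removed %d, kept %d", nrow(filt$removed),
        nrow(final))

    stage <- "all_against_all"
    final_hits <- all_against_all(final, config$scheme, config$report_cutoff)
    graph <- similarity_graph(final, final_hits, config$report_cutoff)
    manifest$stages$all_against_all <- list(n_directed_hits = nrow(final_hits))
    say("all-against-all: %d directed hits at report cutoff %g",
        nrow(final_hits), config$report_cutoff)

    stage <- "maps"
    main_graph <- apply_cutoff(graph, config$analysis_cutoffs[1])
    layout <- layout_graph(main_graph, config$layout_par, config$layout_dims,
                           config$layout_seed)
    for (cf in config$analysis_cutoffs) {
      gc_ <- apply_cutoff(graph, cf)
      tag <- sprintf("map_cutoff_%g", cf)
      write_map(gc_, layout, art(paste0(tag, ".clansmap")))
      if (config$plots) {
        suppressWarnings(plot_map(gc_, layout, art(paste0(tag, ".svg"))))
      }
      say("map at cutoff %g: %d edges", cf, nrow(gc_$edges))
    }
    manifest$stages$maps <- list(layout_iterations = layout$iterations_run,
                                 layout_converged = layout$converged)

    stage <- "assignment"
    report <- assignment_report(graph, labels = NULL,
                                cutoffs = config$analysis_cutoffs,
                                layout = layout,
                                tie_margin = config$tie_margin)
    write_assignment_report(report, art("connectivity.tsv"),
                            art("assignment_report.md"))
    if (!is.null(report$divergence)) {
      write_center_distance_tsv(report$divergence, art("center_distance.tsv"))
    }

    nj <- NULL
    if (config$nj_contrast) {
      stage <- "nj_contrast"
      dist <- domain_distance(final, profile)
      nj_tree <- neighbor_joining(dist)
      writeLines(nj_tree$newick, art("nj_tree.nwk"))
      labels <- resolve_labels(similarity_graph(final, final_hits,
                                                config$report_cutoff),
                               NULL, collapse = TRUE)
      grp <- split(labels$seq_id, labels$group_name)
      attract <- NULL
      if (all(c("Cdx", "posterior") %in% names(grp)) &&
          all(lengths(grp[c("Cdx", "posterior")]) >= 2)) {
        attract <- attraction_check(nj_tree, grp$Cdx, grp$posterior)
      }
      nj <- list(distance = dist, tree = nj_tree, attraction = attract)
      manifest$stages$nj_contrast <- list(
        clamped_negative = nj_tree$clamped_negative,
        cdx_posterior_attracted = if (!is.null(attract)) attract$attracted)
      if (!is.null(attract)) {
        say("NJ contrast: Cdx/posterior attracted = %s", attract$attracted)
      }
    }

    out$graph <- graph
    out$layout <- layout
    out$report <- report
    out$nj <- nj
    out
  }, silent = TRUE)

  failed <- inherits(result, "try-error")
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifest$status <- if (failed) "failed" else "ok"
  if (failed) manifest$failed_stage <- stage
  manifest$artifacts <- artifact_checksums(config$out_dir)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  if (failed) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 attr(result, "condition")$message), call. = FALSE)
  }
  result$manifest <- manifest
  invisible(result)
}

config_snapshot <- function(config) {
  snap <- unclass(config)
  snap$scheme <- list(gap_open = config$scheme$gap_open,
                      gap_extend = config$scheme$gap_extend,
                      lambda = config$scheme$lambda, K = config$scheme$K,
                      matrix = "BLOSUM62+X0")
  snap$layout_par <- unclass(config$layout_par)
  snap
}

# md5 checksums of text artifacts (figures and the manifest itself excluded:
# vector-graphic encoders do not guarantee byte stability)
artifact_checksums <- function(out_dir) {
  files <- sort(list.files(out_dir))
  files <- files[!grepl("\\.(svg|png|pdf)$", files) & files != "manifest.json"]
  as.list(tools::md5sum(file.path(out_dir, files))[file.path(out_dir, files)]) |>
    setNames(files)
}
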