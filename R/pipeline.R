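# End-to-end orchestration: simulate (or read) libraries, preprocess, align,
# assign, profile, authenticate, ordinate — from one declarative config, with
# a reproducible JSON manifest.

#' Build a pipeline configuration
#'
#' Defaults equal the pipeline's published filter settings: minimum read
#' length 25 nt, DUST score threshold 1, edit-distance fraction 5%, and a
#' 500-read floor for damage estimates.
#'
#' @param seed Master RNG seed; per-library simulation seeds are derived from
#'   it.
#' @param outdir Output directory (created if missing); `NULL` keeps all
#'   results in memory only.
#' @param libraries List of library specs. Each is a list with `library_id`,
#'   `site`, `layer`, optional `culture` and `library_type`
#'   (`"sediment"`/`"helminth"`), and either `fastq` (path to reads) or `sim`
#'   (argument list for [sim_config()] minus the seed).
#' @param min_len,dust_max,edit_frac,damage_min_reads Filter parameters.
#' @param seq_len Reference length for the generated panel.
#' @param collapse_auto Apply automatic taxon collapsing (default `TRUE`).
#' @param damage_taxa Taxa (names) to estimate damage for; default: all
#'   species-level taxa in the collapsed profile.
#' @param nmds_restarts Random starts for the ordination (default 20).
#' @param tree,panel Optional pre-built [taxonomy_tree()] / `ref_panel`;
#'   by default the toy taxonomy and a panel derived from it are used.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed, libraries, outdir = NULL,
                            min_len = 25, dust_max = 1, edit_frac = 0.05,
                            damage_min_reads = 500, seq_len = 16000,
                            collapse_auto = TRUE, damage_taxa = NULL,
                            nmds_restarts = 20, tree = NULL, panel = NULL) {
  stopifnot(length(libraries) > 0)
  for (lib in libraries) {
    if (is.null(lib$library_id) || is.null(lib$site) || is.null(lib$layer)) {
      stop("each library needs library_id, site and layer")
    }
    if (is.null(lib$fastq) && is.null(lib$sim)) {
      stop("library '", lib$library_id, "' needs a fastq path or a sim block")
    }
  }
  structure(
    list(seed = as.integer(seed), outdir = outdir, libraries = libraries,
         min_len = min_len, dust_max = dust_max, edit_frac = edit_frac,
         damage_min_reads = damage_min_reads, seq_len = seq_len,
         collapse_auto = collapse_auto, damage_taxa = damage_taxa,
         nmds_restarts = nmds_restarts, tree = tree, panel = panel),
    class = "pipeline_config"
  )
}

#' Run the full pipeline
#'
#' simulate/read -> preprocess -> align -> assign -> profile -> damage ->
#' ordinate, with per-stage read accounting. Rerunning with the same config
#' reproduces identical outputs. Ordination requires at least three layers
#' and is skipped (with a manifest note) otherwise.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `tree`, `panel`, `reads`, `hits`,
#'   `assignments`, `metas`, `profile` (collapsed, with fractions),
#'   `concentration`, `damage`, `ordination` (or `NULL`), `report` (per-stage
#'   counts), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  tree <- config$tree %||% make_toy_taxonomy()
  panel <- config$panel %||% make_reference_panel(tree, config$seq_len, config$seed)

  all_reads <- list(); all_hits <- list(); all_assign <- list()
  metas <- list(); stage_counts <- list()
  for (i in seq_along(config$libraries)) {
    lib <- config$libraries[[i]]
    reads <- if (!is.null(lib$fastq)) {
      read_fastq(lib$fastq)
    } else {
      cfg <- do.call(sim_config, c(list(seed = config$seed + i), lib$sim))
      simulate_library(cfg, panel, prefix = lib$library_id)$reads
    }
    n_raw <- nrow(reads)
    pp <- preprocess_reads(reads, config$min_len, config$dust_max)
    hits <- exhaustive_align(pp$reads, panel, edit_frac = config$edit_frac)
    hits <- edit_distance_filter(hits, config$edit_frac)
    ties <- best_hits(hits)
    asg <- assign_reads(ties, panel, tree)
    asg$library_id <- rep(lib$library_id, nrow(asg))
    all_reads[[i]] <- pp$reads
    all_hits[[i]] <- ties
    all_assign[[i]] <- asg
    metas[[i]] <- tibble(
      library_id = lib$library_id, site = lib$site, layer = lib$layer,
      culture = lib$culture %||% NA_character_,
      library_type = lib$library_type %||% "sediment",
      n_reads_analysed = nrow(pp$reads)
    )
    stage_counts[[i]] <- tibble(
      library_id = lib$library_id, n_raw = n_raw,
      n_preprocessed = nrow(pp$reads),
      n_with_hit = dplyr::n_distinct(ties$read_id),
      n_assigned = nrow(asg),
      n_unassigned = nrow(pp$reads) - nrow(asg)
    )
  }
  reads <- dplyr::bind_rows(all_reads)
  hits <- dplyr::bind_rows(all_hits)
  assignments <- dplyr::bind_rows(all_assign)
  metas <- dplyr::bind_rows(metas)
  report <- dplyr::bind_rows(stage_counts)

  vert <- restrict_vertebrate(assignments, tree)
  profile <- merge_layers(vert, metas) |>
    collapse_taxa(tree, auto = config$collapse_auto) |>
    relative_abundance()
  conc <- vertebrate_concentration(profile, tree)

  damage_taxa <- config$damage_taxa %||%
    taxon_name(tree, top_species(profile, tree, n = 10))
  damage <- purrr::map_dfr(damage_taxa, function(tx) {
    ct_frequency(assignments, hits, reads, panel, tree, tx,
                 min_reads = config$damage_min_reads)
  })

  ordination <- NULL
  n_layers <- dplyr::n_distinct(paste(profile$site, profile$layer))
  if (n_layers >= 3) {
    ordination <- nmds(profile_dist(profile), seed = config$seed,
                       restarts = config$nmds_restarts)
  }

  manifest <- list(
    seed = config$seed,
    parameters = list(min_len = config$min_len, dust_max = config$dust_max,
                      edit_frac = config$edit_frac,
                      damage_min_reads = config$damage_min_reads,
                      seq_len = config$seq_len),
    libraries = report,
    totals = list(
      n_raw = sum(report$n_raw),
      n_preprocessed = sum(report$n_preprocessed),
      n_assigned = sum(report$n_assigned),
      n_vertebrate_family_or_lower = nrow(vert)
    ),
    ordination = if (is.null(ordination)) {
      "skipped: fewer than 3 layers"
    } else {
      list(stress = ordination$stress, n_layers = n_layers)
    }
  )

  result <- list(tree = tree, panel = panel, reads = reads, hits = hits,
                 assignments = assignments, metas = metas, profile = profile,
                 concentration = conc, damage = damage,
                 ordination = ordination, report = report, manifest = manifest)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$outdir, f)
    write_ref_panel(panel, out("panel.fasta"), out("panel_taxids.tsv"))
    write_taxonomy(tree, out("nodes.dmp"), out("names.dmp"))
    readr::write_tsv(assignments, out("assignments.tsv"))
    readr::write_tsv(profile, out("profile.tsv"))
    readr::write_tsv(conc, out("vertebrate_concentration.tsv"))
    readr::write_tsv(damage, out("damage.tsv"))
    readr::write_tsv(report, out("stage_counts.tsv"))
    if (!is.null(ordination)) {
      readr::write_tsv(ordination$points, out("ordination.tsv"))
    }
    files <- sort(setdiff(list.files(config$outdir), "manifest.json"))
    manifest$files <- as.list(tools::md5sum(file.path(config$outdir, files)))
    names(manifest$files) <- files
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    result$manifest <- manifest
  }
  invisible(result)
}
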