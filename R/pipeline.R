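#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates every stage end to end: genome and deletion input (or
#' synthetic generation), repeat detection, microhomology matrix,
#' deletion-center statistics, breakpoint clustering, the regression cell
#' table with the microhomology-only and microhomology + contact-zone
#' logistic models, optionally the minimum-AIC contact-point scan, the
#' duplex energy matrix with its repeat-density correlation, and the
#' realized/non-realized repeat contrasts. Every intermediate artifact is
#' written as TSV/JSON under `out_dir` and a manifest (parameters, seeds,
#' per-stage status) is written as `manifest.json`. Identical
#' configuration and inputs give identical outputs.
#'
#' @param config A named list, or the path to a YAML file with the same
#'   structure. Recognised keys (all optional): `genome` (FASTA path;
#'   absent = synthetic genome), `deletions` (breakpoint TSV path; absent
#'   = synthetic deletions), `arc` (`start`, `end`), `grid` (`grid_start`,
#'   `window_length`, `n_windows`), `alignment` (match, mismatch,
#'   gap_open, gap_extend, end_gaps_free), `band_width`, `zone5`, `zone3`,
#'   `repeats` (min_length, min_identity, max_arm), `scan` (logical),
#'   `randomization` (n_replicates), `clustering` (min_cluster_size,
#'   min_samples), `synthetic` (length, gc, beta0, beta_ms, beta_cz),
#'   `seed`.
#' @param out_dir Output directory, created if needed.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = "mitoarc_run") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("mitoarc")),
                   config = cfg, stages = list())
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tick <- Sys.time()
    val <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok",
      seconds = round(as.numeric(Sys.time() - tick, units = "secs"), 3))
    message("[", name, "] done")
    val
  }

  arc <- arc_region(cfg$arc$start, cfg$arc$end)
  grid <- build_grid(arc, cfg$grid$window_length, cfg$grid$n_windows,
                     cfg$grid$grid_start)
  export_grid(grid, file.path(out_dir, "grid.tsv"))

  genome <- stage("genome", {
    if (!is.null(cfg$genome)) {
      read_genome(cfg$genome)
    } else {
      g <- generate_genome(cfg$synthetic$length, cfg$synthetic$gc,
                           seed = cfg$seed)
      write_genome(g$seq, file.path(out_dir, "genome.fa"))
      g$seq
    }
  })

  reps <- stage("repeats", {
    r <- dplyr::bind_rows(
      find_degraded(genome, arc, "direct", cfg$repeats$min_length,
                    cfg$repeats$min_identity, cfg$repeats$max_arm),
      find_degraded(genome, arc, "inverted", cfg$repeats$min_length,
                    cfg$repeats$min_identity, cfg$repeats$max_arm))
    write_repeats(r, file.path(out_dir, "repeats.tsv"))
    r
  })

  mm <- stage("microhomology", {
    ap <- do.call(alignment_params, cfg$alignment)
    m <- microhomology_matrix(genome, grid, ap)
    write_matrix_tsv(m, file.path(out_dir, "microhomology.tsv"))
    m
  })

  dels <- stage("deletions", {
    d <- if (!is.null(cfg$deletions)) {
      filter_major_arc(read_breakpoints(cfg$deletions), arc)
    } else {
      gm <- generative_model(cfg$synthetic$beta0, cfg$synthetic$beta_ms,
                             cfg$synthetic$beta_cz, cfg$zone5, cfg$zone3,
                             cfg$band_width, seed = cfg$seed)
      generate_deletions(grid, mm, gm)$deletions
    }
    write_breakpoints(d, file.path(out_dir, "deletions.tsv"))
    d
  })

  stage("centers", {
    cs <- centers_summary(dels)
    rt <- randomize_centers_test(dels, arc, cfg$randomization$n_replicates,
                                 seed = cfg$seed)
    jsonlite::write_json(c(as.list(cs), glance(rt)),
                         file.path(out_dir, "centers.json"),
                         auto_unbox = TRUE, digits = NA)
    rt
  })

  stage("clusters", {
    cl <- suppressWarnings(
      cluster_breakpoints(dels, cfg$clustering$min_cluster_size,
                          cfg$clustering$min_samples))
    write.table(as.data.frame(cl), file.path(out_dir, "clusters.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    disp <- breakpoint_axis_dispersion(cl)
    write.table(disp, file.path(out_dir, "cluster_dispersion.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cl
  })

  cells <- stage("cells", {
    ct <- build_cell_table(grid, mm, dels, cfg$band_width)
    ct <- code_contact_zone(ct, cfg$zone5, cfg$zone3)
    write_cells(ct, file.path(out_dir, "cells.tsv"))
    ct
  })

  fits <- stage("fit", {
    f1 <- fit_ms_model(cells)
    f2 <- fit_ms_cz_model(cells)
    out <- list(ms_model = c(split(tidy(f1)$estimate, tidy(f1)$term),
                             glance(f1)),
                ms_cz_model = c(split(tidy(f2)$estimate, tidy(f2)$term),
                                glance(f2)))
    jsonlite::write_json(out, file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA)
    list(f1 = f1, f2 = f2)
  })

  if (isTRUE(cfg$scan)) {
    stage("scan", {
      sc <- contact_point_scan(cells, grid)
      write_matrix_tsv(sc$aic_surface, file.path(out_dir, "aic_surface.tsv"))
      jsonlite::write_json(as.list(glance(sc)),
                           file.path(out_dir, "scan.json"),
                           auto_unbox = TRUE, digits = NA)
      sc
    })
  }

  stage("duplex", {
    em <- energy_matrix(genome, grid)
    write_matrix_tsv(em, file.path(out_dir, "duplex_energy.tsv"))
    inv <- reps[reps$kind == "inverted", , drop = FALSE]
    dm <- repeat_density_matrix(inv, grid)
    cc <- tryCatch(correlate_contacts(em, dm, cfg$band_width),
                   error = function(e) tibble::tibble(
                     rho = NA_real_, p_value = NA_real_, n = NA_integer_))
    jsonlite::write_json(as.list(cc), file.path(out_dir, "contact_cor.json"),
                         auto_unbox = TRUE, digits = NA)
    em
  })

  stage("realized", {
    dir_reps <- reps[reps$kind == "direct", , drop = FALSE]
    calls <- call_realization(dir_reps, dels)
    write.table(as.data.frame(calls[setdiff(names(calls), "matched")]),
                file.path(out_dir, "realization_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    enr <- contact_zone_enrichment(calls, cfg$zone5, cfg$zone3)
    cl <- build_motif_clusters(calls)
    contrasts <- tryCatch(paired_position_contrasts(cl),
                          error = function(e) NULL)
    jsonlite::write_json(list(enrichment = as.list(enr),
                              contrasts = if (is.null(contrasts)) NULL
                                          else as.list(contrasts)),
                         file.path(out_dir, "realized.json"),
                         auto_unbox = TRUE, digits = NA)
    calls
  })

  manifest$seconds_total <- round(as.numeric(Sys.time() - t0,
                                             units = "secs"), 3)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

default_config <- function() {
  list(
    genome = NULL,
    deletions = NULL,
    arc = list(start = 5781L, end = 16569L),
    grid = list(grid_start = NULL, window_length = 100L, n_windows = 100L),
    alignment = list(match = 5, mismatch = -4, gap_open = 10,
                     gap_extend = 0.5, end_gaps_free = TRUE),
    band_width = 10L,
    zone5 = c(6000, 9000),
    zone3 = c(13000, 16000),
    repeats = list(min_length = 10L, min_identity = 0.8, max_arm = 100L),
    scan = FALSE,
    randomization = list(n_replicates = 1000L),
    clustering = list(min_cluster_size = 20L, min_samples = 10L),
    synthetic = list(length = 16569L, gc = 0.44,
                     beta0 = -2.38, beta_ms = 0.33, beta_cz = 0.91),
    seed = 1L
  )
}
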