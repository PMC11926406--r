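#' Demo run configuration
#'
#' A small, fully specified synthetic configuration exercising the whole
#' pipeline (simulate -> colocalize -> stats -> atlas) in seconds: three
#' enzymes staggered along the cis->trans axis, two cells per pair, a
#' compact grid.
#'
#' @param out_dir output directory.
#' @param seed master seed; every stochastic step derives from it.
#' @return A config list for [run_pipeline()].
#' @export
demo_config <- function(out_dir, seed = 1L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    enzymes = data.frame(name = c("enzA", "enzB", "enzC"),
                         axial_mu = c(0, 0.2, 0.4)),
    n_cells = 2L,
    scene = list(grid_shape = c(24L, 64L, 64L)),
    seg_method = "otsu",
    voxel_policy = "or",
    below_set = "and",
    normalization = "none",
    control = "enzA",
    write_tiffs = FALSE
  )
}

validate_config <- function(config) {
  required <- c("out_dir", "seed", "enzymes", "n_cells")
  miss <- setdiff(required, names(config))
  if (length(miss) > 0) {
    stop_input("config is missing required key(s): %s", paste(miss, collapse = ", "))
  }
  if (!is_scalar_number(config$seed)) stop_input("config key 'seed' must be a single integer")
  enz <- as.data.frame(config$enzymes)
  if (!all(c("name", "axial_mu") %in% names(enz))) {
    stop_input("config key 'enzymes' needs columns 'name' and 'axial_mu'")
  }
  if (nrow(enz) < 2L) stop_input("need at least 2 enzymes")
  invisible(config)
}

config_enzymes <- function(config) {
  enz <- as.data.frame(config$enzymes)
  lapply(seq_len(nrow(enz)), function(i) {
    enzyme_profile(
      name = enz$name[i], axial_mu = enz$axial_mu[i],
      axial_sigma = if ("axial_sigma" %in% names(enz)) enz$axial_sigma[i] else 0.25,
      brightness = if ("brightness" %in% names(enz)) enz$brightness[i] else 300
    )
  })
}

save_plot <- function(p, path, width = 6, height = 5) {
  # cairo PNG if the build supports it, else fall back to PDF
  ok <- tryCatch({
    grDevices::png(path, width = width * 100, height = height * 100, res = 100,
                   type = if (capabilities("cairo")) "cairo" else "quartz")
    print(p)
    grDevices::dev.off()
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    path <- sub("\\.png$", ".pdf", path)
    grDevices::pdf(path, width = width, height = height)
    print(p)
    grDevices::dev.off()
  }
  path
}

#' Run the full synthetic analysis pipeline
#'
#' Renders the all-pairs synthetic panel, colocalizes every scene (Costes
#' thresholded Pearson + nMDP), summarizes groups with Dunnett comparisons
#' against the control enzyme's dual-label pair, and builds the Golgi
#' atlas. All outputs are CSV/JSON/PNG in `config$out_dir`, the
#' configuration is echoed to `config.json`, and a structured log records
#' thresholds, convergence flags, and any skipped cells. Given the same
#' config, all CSV outputs are bit-identical across runs.
#'
#' @param config list; see [demo_config()] for the shape. Required keys:
#'   `out_dir`, `seed`, `enzymes` (data frame with `name`, `axial_mu`,
#'   optionally `axial_sigma`, `brightness`), `n_cells`. Optional: `scene`
#'   (overrides for [scene_config()]), `seg_method`, `voxel_policy`,
#'   `below_set`, `normalization`, `control`, `write_tiffs`.
#' @return Invisibly, a list with the coloc tibble, stats tibble, atlas
#'   object, and output paths.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  enzymes <- config_enzymes(config)
  cfg <- do.call(scene_config, config$scene %||% list())
  seg_method <- config$seg_method %||% "otsu"
  voxel_policy <- config$voxel_policy %||% "or"
  below_set <- config$below_set %||% "and"
  normalization <- config$normalization %||% "none"
  control <- config$control %||% enzymes[[1]]$name

  echo <- config
  echo$package_version <- as.character(utils::packageVersion("golgiatlas"))
  echo$scene_defaults <- cfg[setdiff(names(cfg), "ribbon_curve")]
  jsonlite::write_json(echo, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  note("simulate: %d enzymes, %d cells/pair, seed %d",
       length(enzymes), config$n_cells, config$seed)
  scenes <- render_panel(cfg, enzymes, config$n_cells, base_seed = config$seed)
  truth <- panel_truth(scenes)
  write_results_table(truth, file.path(config$out_dir, "truth.csv"))
  if (isTRUE(config$write_tiffs)) {
    img_dir <- file.path(config$out_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (sc in scenes) {
      write_volume(sc$image, file.path(img_dir, paste0(gsub("[|]", "_", sc$cell_id), ".tif")))
    }
  }

  rows <- purrr::map(scenes, function(sc) {
    tryCatch(
      colocalize_pair(sc, seg_method = seg_method, voxel_policy = voxel_policy,
                      below_set = below_set)$measurement |>
        dplyr::mutate(status = "ok"),
      error = function(e) {
        note("cell %s skipped: %s", sc$cell_id, conditionMessage(e))
        tibble(cell_id = sc$cell_id, label_a = sc$label_a, label_b = sc$label_b,
               status = paste("failed:", conditionMessage(e)))
      }
    )
  })
  coloc <- dplyr::bind_rows(rows)
  write_results_table(coloc, file.path(config$out_dir, "coloc.csv"))
  ok <- coloc[coloc$status == "ok", , drop = FALSE]
  note("coloc: %d/%d cells measured, %d Costes non-convergences",
       nrow(ok), nrow(coloc), sum(!ok$costes_converged))

  grouped <- ok |> dplyr::mutate(group = paste(.data$label_a, "vs", .data$label_b))
  summaries <- summarize_groups(grouped, .data$r, .data$group)
  control_group <- paste(control, "vs", control)
  family <- grouped |>
    dplyr::filter(.data$label_a == control | .data$label_b == control)
  stats_tbl <- summaries
  family_sizes <- table(family$group)
  if (control_group %in% family$group && length(family_sizes) >= 2L &&
      all(family_sizes >= 2L)) {
    cmp <- dunnett_vs_control(family, .data$r, .data$group, control = control_group,
                              seed = derive_seed(config$seed, 77))
    cmp$group <- sub(sprintf(" vs %s$", gsub("([()])", "\\\\\\1", control_group)),
                     "", cmp$comparison)
    stats_tbl <- dplyr::left_join(summaries, cmp[, c("group", "statistic", "df",
                                                     "p_unadjusted", "p_adjusted", "stars")],
                                  by = "group")
  } else {
    note("stats: Dunnett family skipped (control pair '%s' absent or a group has n < 2)",
         control_group)
  }
  write_results_table(stats_tbl, file.path(config$out_dir, "stats.csv"))

  atlas <- make_atlas(ok, seed = derive_seed(config$seed, 999),
                      normalization = normalization)
  write_results_table(tidy(atlas$distances), file.path(config$out_dir, "distances.csv"))
  write_results_table(tidy(atlas), file.path(config$out_dir, "embedding.csv"))
  plot_path <- save_plot(autoplot(atlas), file.path(config$out_dir, "atlas.png"))
  note("atlas: stress %.4g, PC1 variance %.1f%%", atlas$stress,
       100 * atlas$explained_variance[1])

  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(coloc = coloc, stats = stats_tbl, atlas = atlas,
                 truth = truth,
                 paths = list(out_dir = config$out_dir, atlas_plot = plot_path)))
}

#' Run the built-in synthetic demo
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @return See [run_pipeline()].
#' @export
run_demo <- function(out_dir, seed = 1L) {
  run_pipeline(demo_config(out_dir, seed))
}
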