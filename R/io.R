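#' Read and write cell tables as CSV
#'
#' The on-disk schema is a CSV with exactly the shared columns
#' `cell_id,x_um,y_um,area_um2,s_intensity,m_intensity,class_label,fate_truth`.
#' Metadata travels in a JSON sidecar `<path>.json` (written by default and
#' restored on read when present). A write-then-read round trip reproduces
#' the table.
#'
#' @param table A [cell_table()].
#' @param path CSV path.
#' @param sidecar Write/read the metadata sidecar.
#' @return `write_cell_table()` returns `path` invisibly; `read_cell_table()`
#'   returns a `cell_table`.
#' @export
write_cell_table <- function(table, path, sidecar = TRUE) {
  validate_cell_table(table, cell_meta(table))
  readr::write_csv(as.data.frame(table)[, CELL_TABLE_COLUMNS], path)
  if (sidecar) {
    meta <- cell_meta(table)
    meta$params <- NULL
    meta$config <- NULL
    jsonlite::write_json(meta, paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path, sidecar = TRUE) {
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing_cols <- setdiff(CELL_TABLE_COLUMNS, header)
  if (length(missing_cols) > 0) {
    abort(paste0(
      "cell table CSV is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  data <- readr::read_csv(path,
    col_types = readr::cols(
      cell_id = readr::col_integer(),
      x_um = readr::col_double(),
      y_um = readr::col_double(),
      area_um2 = readr::col_double(),
      s_intensity = readr::col_double(),
      m_intensity = readr::col_double(),
      class_label = readr::col_character(),
      fate_truth = readr::col_character()
    )
  )
  meta <- list(source = "experimental")
  sidecar_path <- paste0(path, ".json")
  if (sidecar && file.exists(sidecar_path)) {
    meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  }
  cell_table(data, meta = meta)
}

#' Run the end-to-end pipeline
#'
#' Orchestrates the package stages on synthetic data: `generate` a cell
#' table, `render` an image window and `segment` it back, `profile` the
#' generated table (classification, transition fits, transition statistics,
#' clustering), and `simulate` the calibrated model. Every artifact is
#' written under `out_dir` together with a run manifest (JSON) recording the
#' command, configuration hash, seeds, package version, timestamps and
#' output paths. Stages can be skipped; deterministic stages re-produce
#' byte-identical CSVs given the same configuration and seeds.
#'
#' @param out_dir Output directory (created if needed).
#' @param stages Stages to run, a subset of
#'   `c("generate", "render", "segment", "profile", "simulate")`.
#' @param gen_params [generator_params()] for the synthetic retina.
#' @param config [sim_config()] for the simulation stage.
#' @param render_window_um Length-2 D-V window rendered/segmented (kept small
#'   by default; rendering a full strip makes very large rasters).
#' @param pixel_size_um Rendering pixel size.
#' @param seed Seed recorded in the manifest and used where stages need one.
#' @return Invisibly, the manifest list.
#' @export
pipeline_run <- function(out_dir,
                         stages = c("generate", "render", "segment", "profile", "simulate"),
                         gen_params = generator_params(),
                         config = sim_config(domain_um = c(length = 5000, width = 200, depth = 5)),
                         render_window_um = c(3400, 3700),
                         pixel_size_um = 0.5,
                         seed = 1L) {
  stages <- match.arg(stages,
    c("generate", "render", "segment", "profile", "simulate"),
    several.ok = TRUE
  )
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    command = "pipeline_run",
    package = "conemosaic",
    version = as.character(utils::packageVersion("conemosaic")),
    seed = as.integer(seed),
    config_hash = rlang::hash(list(gen_params, config, render_window_um, pixel_size_um)),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = stages,
    defaults_used = list(
      generator = setdiff(names(generator_params()), names(gen_params)),
      simulator = setdiff(names(sim_config()), names(config))
    ),
    outputs = list()
  )
  out <- function(name) file.path(out_dir, name)

  tab <- NULL
  if ("generate" %in% stages) {
    gen_params$seed <- as.integer(seed)
    tab <- generate_cell_table(gen_params)
    write_cell_table(tab, out("cells_synthetic.csv"))
    manifest$outputs$cells_synthetic <- out("cells_synthetic.csv")
  } else if (file.exists(out("cells_synthetic.csv"))) {
    tab <- read_cell_table(out("cells_synthetic.csv"))
  }

  if ("render" %in% stages) {
    if (is.null(tab)) abort("render stage needs a generated table (run or cache 'generate')")
    win <- tab[tab$y_um >= render_window_um[1] & tab$y_um < render_window_um[2], ]
    win$y_um <- win$y_um - render_window_um[1]
    win <- cell_table(win, meta = list(
      source = "synthetic",
      strip_length_um = diff(render_window_um),
      strip_width_um = cell_meta(tab)$strip_width_um %||% max(win$x_um)
    ))
    tile <- render_tiles(win, pixel_size_um = pixel_size_um, seed = seed)
    write_image_tile(tile, out("tile.tif"))
    manifest$outputs$tile <- out("tile.tif")
  }

  if ("segment" %in% stages) {
    tile <- read_image_tile(out("tile.tif"))
    seg <- segment_tile(tile)
    write_cell_table(seg, out("cells_segmented.csv"))
    dmap <- density_map(tile)
    readr::write_csv(dmap, out("density_map.csv"))
    manifest$outputs$cells_segmented <- out("cells_segmented.csv")
    manifest$outputs$density_map <- out("density_map.csv")
  }

  if ("profile" %in% stages) {
    if (is.null(tab)) abort("profile stage needs a generated table")
    tabc <- classify_cells(tab)
    s_prof <- fraction_profile(tabc, "s")
    m_prof <- fraction_profile(tabc, "m")
    readr::write_csv(s_prof, out("profile_s_fraction.csv"))
    readr::write_csv(m_prof, out("profile_m_fraction.csv"))
    fits <- list(
      s_fraction = glance(fit_hill(s_prof, direction = "increasing")),
      m_fraction = glance(fit_hill(m_prof, direction = "decreasing"))
    )
    jsonlite::write_json(purrr::map(fits, as.list), out("fits.json"),
      auto_unbox = TRUE, digits = NA
    )
    readr::write_csv(transition_stats(tabc), out("transition_stats.csv"))
    cl <- cluster_cells(tabc)
    jsonlite::write_json(
      list(
        n_clusters = cl$n_clusters,
        min_cluster_size = cl$min_cluster_size
      ),
      out("clusters.json"),
      auto_unbox = TRUE
    )
    manifest$outputs$profiles <- c(
      out("profile_s_fraction.csv"), out("profile_m_fraction.csv"),
      out("fits.json"), out("transition_stats.csv"), out("clusters.json")
    )
  }

  if ("simulate" %in% stages) {
    sim <- run_simulation(config, seed = seed)
    write_cell_table(sim, out("cells_simulated.csv"))
    manifest$outputs$cells_simulated <- out("cells_simulated.csv")
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, out("manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(manifest)
}
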