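#' Run the imaging experiment on synthetic sections
#'
#' The core quantification loop: render `n_sections` paired
#' unstained/stained sections (each its own biological replicate with a
#' fresh seed and misregistration direction), register each stained frame
#' back onto its unstained reference, build the absorbance-difference map
#' with the non-lignified background as offset reference, and sample
#' circular measurement points per cell type. Poplar sections additionally
#' get cambium-distance stage bins.
#'
#' @param scenario `"arabidopsis"` (PX/MX/XF/IF/LP, 50 points of 12 px) or
#'   `"poplar"` (vessel/fiber/ray, 20 points of 5 px, stage bins).
#' @param n_sections biological replicates.
#' @param seed global seed; per-section seeds are derived from it.
#' @param noise_sd sensor noise (grey levels).
#' @param shift_mag_px misregistration magnitude applied to each stained
#'   frame (direction varies by replicate).
#' @param rot_deg misregistration rotation (degrees).
#' @param n_points,area_px sampling design per cell type (NULL: scenario
#'   default).
#' @param base_absorbance scale of the strongest cell type (NULL: scenario
#'   default, 1.0 for Arabidopsis, 0.6 for poplar).
#' @param type_scale named relative true absorbances (NULL: scenario
#'   default).
#' @param register if FALSE, the encoded transform is assumed known
#'   (identity misregistration shortcut for quick runs).
#' @return list: `table` (pooled point table with `replicate`), `means`
#'   (replicate x type means), `alignments`, `truth_means`.
#' @export
run_section_experiment <- function(scenario = c("arabidopsis", "poplar"),
                                   n_sections = 5, seed = 1,
                                   noise_sd = 2, shift_mag_px = 3,
                                   rot_deg = 0,
                                   n_points = NULL, area_px = NULL,
                                   base_absorbance = NULL, type_scale = NULL,
                                   register = TRUE) {
  scenario <- match.arg(scenario)
  if (scenario == "arabidopsis") {
    n_points <- n_points %||% 50; area_px <- area_px %||% 12
    base_absorbance <- base_absorbance %||% 1
  } else {
    n_points <- n_points %||% 20; area_px <- area_px %||% 5
    base_absorbance <- base_absorbance %||% 0.6
  }
  tabs <- list(); aligns <- list(); tms <- list()
  for (s in seq_len(n_sections)) {
    sseed <- derive_seed(seed, paste0("section", s))
    ang <- 2 * pi * s / n_sections + 0.3
    shift <- shift_mag_px * c(cos(ang), sin(ang))
    sp <- if (scenario == "arabidopsis") {
      args <- list(seed = sseed, shift_px = shift, rot_deg = rot_deg,
                   noise_sd = noise_sd, base_absorbance = base_absorbance)
      if (!is.null(type_scale)) args$type_scale <- type_scale
      do.call(arabidopsis_spec, args)
    } else {
      args <- list(seed = sseed, shift_px = shift, rot_deg = rot_deg,
                   noise_sd = noise_sd, base_absorbance = base_absorbance)
      if (!is.null(type_scale)) args$type_scale <- type_scale
      do.call(poplar_spec, args)
    }
    p <- render_pair(sp)
    a <- if (register) {
      register_global(p$unstained, p$stained,
                      rot_range = if (rot_deg != 0) 5 else 0)
    } else identity_alignment()
    m <- difference_map(p$unstained, p$stained, a,
                        background = p$truth$label == 0L,
                        pitch_um = sp$pitch_um)
    tab <- sample_points(m, p$truth, n = n_points, area_px = area_px,
                         seed = derive_seed(sseed, "sample"))
    if (scenario == "poplar")
      tab <- bin_by_cambium_distance(tab, p$truth$cambium, pitch_um = sp$pitch_um)
    tab$replicate <- s
    tabs[[s]] <- tab; aligns[[s]] <- a; tms[[s]] <- p$truth$type_means
  }
  table <- do.call(rbind, tabs)
  means <- stats::aggregate(absorbance ~ replicate + cell_type, table, mean)
  list(table = table, means = means, alignments = aligns,
       truth_means = do.call(rbind, tms))
}

#' Percent deficit of each cell type relative to a reference type
#'
#' @param table point table from [run_section_experiment()].
#' @param reference reference cell type (default: highest mean).
#' @return data.frame: `cell_type`, `mean_dA`, `deficit_pct`
#'   (100 * (1 - mean/reference mean)).
#' @export
type_deficits <- function(table, reference = NULL) {
  mns <- tapply(table$absorbance, table$cell_type, mean)
  if (is.null(reference)) reference <- names(mns)[which.max(mns)]
  data.frame(cell_type = names(mns), mean_dA = as.vector(mns),
             deficit_pct = 100 * (1 - as.vector(mns) / mns[[reference]]),
             row.names = NULL)
}

#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param ... overrides of the defaults.
#' @return named list of class `run_config`.
#' @export
pipeline_config <- function(out_dir = "wiesner-run", ...) {
  cfg <- list(
    scenario = "arabidopsis", seed = 1L, n_sections = 3L,
    noise_sd = 2, shift_mag_px = 3, rot_deg = 0,
    n_points = NULL, area_px = NULL, base_absorbance = NULL,
    alpha = 0.05,
    layers = TRUE, layer_profiles = 20L,
    cooperativity = TRUE,
    cooperativity_pairs = NULL,    # NULL: every ordered type pair
    cooperativity_weights = NULL,  # NULL: no encoded cooperativity (null network)
    out_dir = out_dir
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stopf("unknown config field(s): %s", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = c("run_config", "list"))
}

#' Run the full pipeline and write a manifest
#'
#' Orchestrates section synthesis, registration, absorbance quantification,
#' per-type statistics (Tukey-HSD letters on replicate means, area-weighted
#' total), an optional wall-layer profile stage on an adjacent same-type
#' cell pair, and an optional table-level cooperativity stage on the
#' built-in genotype panel. All outputs are CSV/JSON under `out_dir`; the
#' manifest records the package version, the configuration, seeds and the
#' MD5 of every output file, so identical config + seed reproduces
#' identical hashes. A stage failure aborts with the stage name; partial
#' outputs are moved under a `failed/` prefix.
#'
#' @param config a [pipeline_config()] or path to a YAML file of overrides.
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config))
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  cfg <- config
  if (!cfg$scenario %in% c("arabidopsis", "poplar"))
    stopf("config invalid: unknown scenario '%s'", cfg$scenario)
  if (is.null(cfg$out_dir)) stopf("config invalid: out_dir missing")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  stage <- "init"
  on_fail <- function(e) {
    fdir <- file.path(cfg$out_dir, "failed")
    dir.create(fdir, showWarnings = FALSE)
    for (f in outputs) if (file.exists(f)) file.rename(f, file.path(fdir, basename(f)))
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  }
  tryCatch({
    stage <- "imaging"
    exp <- run_section_experiment(cfg$scenario, n_sections = cfg$n_sections,
                                  seed = cfg$seed, noise_sd = cfg$noise_sd,
                                  shift_mag_px = cfg$shift_mag_px,
                                  rot_deg = cfg$rot_deg,
                                  n_points = cfg$n_points, area_px = cfg$area_px,
                                  base_absorbance = cfg$base_absorbance)
    f_tab <- file.path(cfg$out_dir, "points.csv")
    write.csv(exp$table, f_tab, row.names = FALSE)
    outputs <- c(outputs, f_tab)

    stage <- "stats"
    grp <- split(exp$means$absorbance, exp$means$cell_type)
    tl <- tukey_letters(grp, alpha = cfg$alpha)
    areas <- table(exp$table$cell_type)
    wt <- weighted_total(vapply(grp, mean, 0), as.vector(areas / sum(areas)))
    stats_df <- data.frame(cell_type = names(grp),
                           mean_dA = vapply(grp, mean, 0),
                           letters = unname(tl$letters))
    f_stats <- file.path(cfg$out_dir, "type_stats.csv")
    write.csv(stats_df, f_stats, row.names = FALSE)
    f_def <- file.path(cfg$out_dir, "deficits.csv")
    write.csv(type_deficits(exp$table), f_def, row.names = FALSE)
    outputs <- c(outputs, f_stats, f_def)

    lay_out <- NULL
    if (isTRUE(cfg$layers)) {
      stage <- "layers"
      prof <- synth_wall_profiles(cfg$layer_profiles,
                                  seed = derive_seed(cfg$seed, "layers"))
      cl <- classify_profiles(prof)
      f_lay <- file.path(cfg$out_dir, "layer_profiles.csv")
      write.csv(cl, f_lay, row.names = FALSE)
      outputs <- c(outputs, f_lay)
      lay_out <- f_lay
    }

    coop_out <- NULL
    if (isTRUE(cfg$cooperativity)) {
      stage <- "cooperativity"
      types <- unique(exp$table$cell_type)
      tab <- make_measurement_sets(types, default_genotype_effects(types),
                                   cooperativity = cfg$cooperativity_weights,
                                   seed = derive_seed(cfg$seed, "coop"))
      net <- cooperativity_network(tab, pairs = cfg$cooperativity_pairs,
                                   alpha = cfg$alpha)
      f_edges <- file.path(cfg$out_dir, "edges.csv")
      write.csv(net$edges, f_edges, row.names = FALSE)
      f_json <- file.path(cfg$out_dir, "network.json")
      f_dot <- file.path(cfg$out_dir, "network.dot")
      write_network(net, f_json, f_dot)
      outputs <- c(outputs, f_edges, f_json, f_dot)
      coop_out <- f_json
    }

    stage <- "manifest"
    manifest <- list(
      package = "lignoquant",
      version = tryCatch(as.character(utils::packageVersion("lignoquant")),
                         error = function(e) "dev"),
      seed = cfg$seed,
      config = cfg[setdiff(names(cfg), "cooperativity_pairs")],
      weighted_total = wt,
      outputs = lapply(outputs, function(f)
        list(file = basename(f), md5 = unname(tools::md5sum(f))))
    )
    f_man <- file.path(cfg$out_dir, "manifest.json")
    jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    invisible(manifest)
  }, error = on_fail)
}
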