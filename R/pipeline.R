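pipeline_stage_names <- c(
  "synth_nucleus", "render_nucleus", "measure_nuclei",
  "roughness_group", "stats_permutation"
)

#' Run a declarative synthesis/measurement/statistics pipeline
#'
#' Executes the stages named in a YAML configuration in order and writes a
#' manifest recording every parameter, seed, output file and content digest.
#' Stage names are validated before anything runs (pre-flight), and
#' deterministic stages reproduce their output digests on re-run with the
#' same config.
#'
#' Supported stages: `synth_nucleus` (wrinkled surface; params `volume`,
#' `excess_area_pct`, `seed`), `render_nucleus` (params of
#' [render_stack()]), `measure_nuclei` ([measure_nuclei()] on the rendered
#' stack), `roughness_group` (params `label`, `n_images`,
#' `tall_cell_fraction`, `seed`, plus [make_monolayer()] sizes; computes
#' one roughness SD per simulated image), `stats_permutation` (params
#' `group_a`, `group_b` naming `roughness_group` labels, `n_perm`, `seed`).
#'
#' @param config_path YAML file with fields `seed` (optional global) and
#'   `stages` (list of `name` + `params`).
#' @param out_dir output directory (created); default a `run_<config name>`
#'   sibling of the config file.
#' @return the manifest (list), invisibly; also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config_path, out_dir = NULL) {
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg$stages) || !length(cfg$stages)) stop("config has no stages")
  nm <- vapply(cfg$stages, function(s) s$name %||% "", character(1))
  unknown <- setdiff(nm, pipeline_stage_names)
  if (length(unknown)) {
    stop("unknown pipeline stage(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(out_dir)) {
    out_dir <- file.path(dirname(config_path),
                         paste0("run_", sub("\\.ya?ml$", "", basename(config_path))))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gseed <- cfg$seed %||% 1L
  state <- new.env(parent = emptyenv())
  state$groups <- list()
  manifest <- list(
    config = cfg,
    config_digest = unname(tools::md5sum(config_path)),
    package_version = as.character(utils::packageVersion("nucleodrop")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    stages = list()
  )
  for (i in seq_along(cfg$stages)) {
    st <- cfg$stages[[i]]
    p <- st$params %||% list()
    t0 <- Sys.time()
    outputs <- run_pipeline_stage(st$name, p, state, out_dir, gseed)
    manifest$stages[[i]] <- list(
      name = st$name,
      params = p,
      duration_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      outputs = lapply(outputs, function(f)
        list(file = basename(f), md5 = unname(tools::md5sum(f))))
    )
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_pipeline_stage <- function(name, p, state, out_dir, gseed) {
  switch(name,
    synth_nucleus = {
      res <- make_nucleus_surface(
        volume = p$volume %||% 800,
        excess_area_pct = p$excess_area_pct %||% 37,
        wrinkle_orders = unlist(p$wrinkle_orders %||% 4:8),
        seed = p$seed %||% gseed,
        mesh_edge = p$mesh_edge
      )
      state$nucleus <- res
      f1 <- file.path(out_dir, "nucleus.off")
      write_mesh_off(res$surface, f1)
      f2 <- file.path(out_dir, "nucleus_truth.json")
      jsonlite::write_json(res[c("volume", "area", "excess_pct", "amplitude")],
                           f2, auto_unbox = TRUE, digits = NA)
      c(f1, f2)
    },
    render_nucleus = {
      if (is.null(state$nucleus)) stop("render_nucleus requires synth_nucleus first")
      rs <- render_stack(
        state$nucleus$surface,
        voxel_size = unlist(p$voxel_size %||% c(0.15, 0.15, 0.13)),
        signal = p$signal %||% "shell",
        psf_sigma_um = p$psf_sigma_um %||% 0.2,
        peak = p$peak %||% 300,
        seed = p$seed %||% gseed
      )
      state$rendered <- rs
      f1 <- file.path(out_dir, "nucleus_stack.tif")
      write_stack_tiff(rs$stack, f1)
      c(f1, paste0(f1, ".yaml"))
    },
    measure_nuclei = {
      if (is.null(state$rendered)) stop("measure_nuclei requires render_nucleus first")
      m <- measure_nuclei(state$rendered$stack)
      state$records <- m
      f1 <- file.path(out_dir, "nuclei_records.csv")
      utils::write.csv(m$records, f1, row.names = FALSE)
      f1
    },
    roughness_group = {
      label <- p$label %||% stop("roughness_group needs a label")
      n_img <- p$n_images %||% 4L
      base_seed <- p$seed %||% gseed
      vals <- vapply(seq_len(n_img), function(j) {
        ml <- make_monolayer(
          field_um = unlist(p$field_um %||% c(40, 40)),
          n_cells = p$n_cells %||% 15L,
          base_height = p$base_height %||% 3,
          tall_cell_fraction = p$tall_cell_fraction %||% 0,
          tall_height = p$tall_height %||% 8,
          seed = base_seed + j
        )
        monolayer_height_map(ml$stack,
                             crop_margin = p$crop_margin %||% 2,
                             downsample = p$downsample %||% 4L)$roughness_sd
      }, numeric(1))
      state$groups[[label]] <- vals
      f1 <- file.path(out_dir, paste0("roughness_", label, ".csv"))
      utils::write.csv(data.frame(condition = label, roughness_sd = vals),
                       f1, row.names = FALSE)
      f1
    },
    stats_permutation = {
      ga <- state$groups[[p$group_a %||% stop("needs group_a")]]
      gb <- state$groups[[p$group_b %||% stop("needs group_b")]]
      if (is.null(ga) || is.null(gb)) {
        stop("stats_permutation requires both roughness groups to exist")
      }
      pt <- permutation_test(ga, gb, n_perm = p$n_perm %||% 10000L,
                             seed = p$seed %||% gseed)
      res <- list(
        observed_diff = pt$observed_diff, p_value = pt$p_value,
        n_permutations = pt$n_permutations, seed = pt$seed,
        mann_whitney_p = rank_test_passthrough(ga, gb)
      )
      f1 <- file.path(out_dir, "stats_permutation.json")
      jsonlite::write_json(res, f1, auto_unbox = TRUE, digits = NA)
      f1
    },
    stop("unknown pipeline stage: ", name)
  )
}
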