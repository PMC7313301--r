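# End-to-end orchestration: config handling, the full segmentation +
# parcellation run, artifact writing, and a reproducibility manifest.

#' Default pipeline configuration
#'
#' Nested list of every stage's tunables; matches the YAML layout accepted
#' by [load_config()] and the command-line wrapper. Defaults follow the
#' study conditions for 256 x 256 slices (K = 200 superpixels, 5 parcels)
#' and this package's documented choices elsewhere.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 0L,
    flip_anterior = FALSE,
    slice = NULL,
    adf = list(iterations = 15L, kappa = 0.12, lambda = 0.25,
               conductance = "exponential"),
    cluster = list(k_min = 2L, k_max = 6L, max_units = 256L, sigma = NULL),
    slic = list(K = 200L, compactness = 0.5, max_iters = 10L,
                intensity_mode = "difference", roi = TRUE),
    parcel = list(schemes = c("slic", "witelson", "hofer")),
    eval = list(roi_only = FALSE)
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [default_config()]; unknown keys
#' are rejected so typos fail before any computation.
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) abort_io(sprintf("config file '%s' does not exist", path))
  user <- yaml::read_yaml(path)
  merge_cfg <- function(base, over, prefix = "") {
    for (k in names(over)) {
      if (!k %in% names(base))
        abort_config(sprintf("unknown config key '%s%s'", prefix, k))
      if (is.list(base[[k]]) && is.list(over[[k]]))
        base[[k]] <- merge_cfg(base[[k]], over[[k]], paste0(prefix, k, "."))
      else base[[k]] <- over[[k]]
    }
    base
  }
  merge_cfg(cfg, user)
}

validate_config <- function(cfg) {
  adf_params(cfg$adf$iterations, cfg$adf$kappa, cfg$adf$lambda, cfg$adf$conductance)
  slic_params(cfg$slic$K, cfg$slic$compactness, cfg$slic$max_iters,
              cfg$slic$intensity_mode)
  if (cfg$cluster$k_min < 2L || cfg$cluster$k_max > 10L ||
      cfg$cluster$k_min > cfg$cluster$k_max)
    abort_config("cluster.k_min/k_max must satisfy 2 <= k_min <= k_max <= 10")
  bad <- setdiff(cfg$parcel$schemes, c("slic", "witelson", "hofer"))
  if (length(bad))
    abort_config(sprintf("unknown parcellation scheme(s): %s", paste(bad, collapse = ", ")))
  invisible(cfg)
}

#' Run the full parcellation pipeline
#'
#' Chains every stage on one slice: normalization, anisotropic diffusion,
#' class-count selection and PNN clustering, CC isolation, contour tracing,
#' SLIC superpixels (inside the CC mask by default), the requested parcel
#' maps, and — when ground truth is supplied — metric reports. All artifacts
#' are written under `output_dir` together with a JSON manifest recording
#' the config, seed and per-file MD5 checksums.
#'
#' @param input path to a slice readable by [read_gray()], a numeric image
#'   matrix, or a `phantom_bundle`.
#' @param config nested config list, see [default_config()].
#' @param output_dir directory for artifacts (created if missing); `NULL`
#'   skips writing.
#' @param ground_truth optional `parcel_map` (or label matrix) of true
#'   parcels for evaluation; a `phantom_bundle` input supplies its own.
#' @return (invisibly) list with every stage's result and, if written, the
#'   manifest.
#' @export
run_pipeline <- function(input, config = default_config(), output_dir = NULL,
                         ground_truth = NULL) {
  cfg <- validate_config(config)
  if (inherits(input, "phantom_bundle")) {
    img_raw <- input$image
    if (is.null(ground_truth)) ground_truth <- input$parcels_gt
  } else if (is.matrix(input)) {
    img_raw <- input
  } else {
    img_raw <- read_gray(input, slice = cfg$slice)
  }
  check_gray_image(img_raw, "input image")

  img <- normalize_intensity(img_raw)
  filtered <- anisotropic_diffuse(img, adf_params(cfg$adf$iterations,
                                                  cfg$adf$kappa,
                                                  cfg$adf$lambda,
                                                  cfg$adf$conductance))
  filtered <- normalize_intensity(filtered)
  cluster_map <- with_stage("clustering", select_num_classes(
    filtered, c(cfg$cluster$k_min, cfg$cluster$k_max), seed = cfg$seed,
    max_units = cfg$cluster$max_units, sigma = cfg$cluster$sigma))
  cc <- with_stage("cc_isolation", isolate_cc(cluster_map, filtered))
  contour <- with_stage("contour", trace_contour(cc))
  sp <- with_stage("slic", slic_segment(
    filtered,
    slic_params(cfg$slic$K, cfg$slic$compactness, cfg$slic$max_iters,
                cfg$slic$intensity_mode),
    roi = if (isTRUE(cfg$slic$roi)) cc else NULL))
  parcels <- list()
  for (scheme in cfg$parcel$schemes) {
    parcels[[scheme]] <- with_stage(paste0("parcellation/", scheme),
      if (scheme == "slic") slic_parcellate(sp, cc, flip = cfg$flip_anterior)
      else geometric_parcellate(cc, scheme, flip = cfg$flip_anterior))
  }
  reports <- NULL
  if (!is.null(ground_truth)) {
    reports <- lapply(parcels, function(p)
      metric_report(p, ground_truth, roi_only = cfg$eval$roi_only))
  }
  result <- list(image = img, filtered = filtered, cluster_map = cluster_map,
                 cc_mask = cc, contour = contour, superpixels = sp,
                 parcels = parcels, reports = reports, config = cfg)
  if (!is.null(output_dir)) {
    result$manifest <- write_artifacts(result, output_dir)
  }
  invisible(result)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, ccparcel_error = function(e) {
    stop(errorCondition(sprintf("[%s] %s", stage, conditionMessage(e)),
                        class = class(e)))
  })
}

parcel_palette <- function() {
  rbind(c(0, 0, 0), c(0.894, 0.102, 0.110), c(0.216, 0.494, 0.722),
        c(0.302, 0.686, 0.290), c(0.596, 0.306, 0.639), c(1.000, 0.498, 0))
}

write_parcel_png <- function(map, path) {
  lab <- parcel_labels_of(map)
  pal <- parcel_palette()
  rgb <- array(0, c(nrow(lab), ncol(lab), 3L))
  for (ch in 1:3) rgb[, , ch] <- matrix(pal[lab + 1L, ch], nrow(lab))
  png::writePNG(rgb, path)
  invisible(path)
}

write_artifacts <- function(result, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  wl <- function(name, map) {
    p <- file.path(output_dir, name)
    write_label_map(map, p)
    paths[[name]] <<- p
  }
  wl("cluster_map.tif", result$cluster_map$labels)
  wl("cc_mask.tif", matrix(as.integer(result$cc_mask$mask), nrow(result$cc_mask$mask)))
  wl("superpixels.tif", result$superpixels$labels)
  for (scheme in names(result$parcels)) {
    wl(sprintf("parcels_%s.tif", scheme), result$parcels[[scheme]]$labels)
    p <- file.path(output_dir, sprintf("parcels_%s.png", scheme))
    write_parcel_png(result$parcels[[scheme]], p)
    paths[[basename(p)]] <- p
  }
  cp <- file.path(output_dir, "contour.csv")
  write_contour_csv(result$contour, cp)
  paths[["contour.csv"]] <- cp
  if (!is.null(result$reports)) {
    for (scheme in names(result$reports)) {
      rp <- file.path(output_dir, sprintf("report_%s.csv", scheme))
      utils::write.csv(result$reports[[scheme]], rp, row.names = FALSE)
      paths[[basename(rp)]] <- rp
    }
  }
  manifest <- list(
    config = result$config,
    k_selected = result$cluster_map$k,
    vmep = result$cluster_map$vmep,
    cc_area = result$cc_mask$area,
    n_superpixels = nrow(result$superpixels$centers),
    checksums = as.list(tools::md5sum(unlist(paths)))
  )
  names(manifest$checksums) <- names(paths)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  manifest
}
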