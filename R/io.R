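#' Read a cone-catch scene from disk
#'
#' Loads a multi-page float TIFF stack plus its animal/background masks
#' (PNG or TIFF; nonzero = member) into the in-memory scene containers.
#' Channel count is validated against the observer when one is supplied, and
#' the positivity floor of [cone_catch_image()] is applied.
#'
#' @param stack_path multi-page TIFF of linear cone catches (chromatic
#'   channels then luminance).
#' @param mask_paths named list or vector with entries `animal` and
#'   `background`.
#' @param pixels_per_cm scene calibration.
#' @param obs optional [observer()] for channel-count validation.
#' @return list with `image` ([cone_catch_image()]) and `masks`
#'   ([region_masks()]).
#' @export
read_scene <- function(stack_path, mask_paths, pixels_per_cm, obs = NULL) {
  stack <- read_tiff(stack_path)
  img <- cone_catch_image(stack, pixels_per_cm)
  if (!is.null(obs)) check_image_observer(img, obs)
  animal <- read_mask(mask_paths[["animal"]])
  background <- read_mask(mask_paths[["background"]])
  if (!any(animal))
    stop("animal mask has zero member pixels: ", mask_paths[["animal"]])
  masks <- region_masks(animal, background)
  if (!identical(dim(masks$animal), dim(img)[1:2]))
    stop("mask dimensions do not match the stack")
  list(image = img, masks = masks)
}

#' Write a cone-catch scene to disk
#'
#' Inverse of [read_scene()]: the stack as a multi-page float TIFF and the
#' two masks as grayscale PNGs.
#'
#' @param scene list with `image` and `masks` (as from [generate_scene()]).
#' @param stack_path,mask_paths output paths (`mask_paths` named `animal`,
#'   `background`).
#' @return `stack_path`, invisibly.
#' @export
write_scene <- function(scene, stack_path, mask_paths) {
  write_tiff(unclass(scene$image), stack_path)
  write_mask(scene$masks$animal, mask_paths[["animal"]])
  write_mask(scene$masks$background, mask_paths[["background"]])
  invisible(stack_path)
}

read_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "png") {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3L) px <- px[, , 1]
    px
  } else if (ext %in% c("tif", "tiff")) {
    read_tiff(path)[, , 1]
  } else stop("unsupported mask format '.", ext, "': ", path)
  m != 0
}

write_mask <- function(mask, path) {
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Write / read a tidy pattern-record table
#'
#' The records CSV is the contract between the imaging half and the stats
#' half: one row per individual x distance, plus a `run_id` column tying the
#' table to the logged configuration.
#'
#' @param records data frame from [distance_profile()]/[process_cohort()].
#' @param path CSV path.
#' @param run_id identifier stamped on every row (default: config-free hash
#'   of the table itself).
#' @return `path` invisibly (`write_records`); the data frame
#'   (`read_records`).
#' @export
write_records <- function(records, path, run_id = fnv1a(records)) {
  records$run_id <- run_id
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Export an edge-contrast map as CSV
#'
#' @param map an [local_edge_map()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_edge_map <- function(map, path) {
  stopifnot(inherits(map, "edge_contrast_map"))
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}

# 32-bit FNV-1a over the serialized object, as a short reproducible run id.
# h is kept as a double; the xor only ever touches the low byte (b < 256),
# which stays inside bitwXor's signed-integer range.
fnv1a <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- ((h - low + bitwXor(as.integer(low), b)) * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the statistics battery on a record table
#'
#' Applies the full downstream battery to a tidy record table: per-distance
#' Kruskal-Wallis species comparisons with Dunn/Bonferroni post hocs, the
#' defence-class mixed models, and the unpalatability correlation-vs-distance
#' regression.
#'
#' @param records tidy record table.
#' @param metrics metric columns to analyse.
#' @param df_method forwarded to [lmm_class_distance()].
#' @return list of tables: `kruskal_wallis`, `dunn`, `lmm`, `correlations`,
#'   `regressions`.
#' @export
run_stats <- function(records,
                      metrics = c("lum_boldness", "col_boldness",
                                  "lum_detectability", "col_detectability"),
                      df_method = "satterthwaite") {
  kw_rows <- list(); dunn_rows <- list(); lmm_rows <- list()
  for (m in metrics) {
    for (d in sort(unique(records$distance_cm))) {
      sub <- records[records$distance_cm == d, ]
      groups <- split(sub[[m]], sub$species)
      groups <- groups[lengths(groups) > 0]
      kw <- tryCatch(kruskal_wallis(groups), error = function(e) NULL)
      if (!is.null(kw))
        kw_rows[[length(kw_rows) + 1L]] <- data.frame(
          metric = m, distance_cm = d, H = kw$statistic, df = kw$df,
          p_value = kw$p_value, stringsAsFactors = FALSE)
      if (length(groups) >= 3L) {
        dn <- tryCatch(dunn_posthoc(groups), error = function(e) NULL)
        if (!is.null(dn)) {
          dn$metric <- m; dn$distance_cm <- d
          dunn_rows[[length(dunn_rows) + 1L]] <- dn
        }
      }
    }
    lt <- tryCatch(lmm_class_distance(records, response = m,
                                      df_method = df_method),
                   error = function(e) NULL)
    if (!is.null(lt)) { lt$metric <- m; lmm_rows[[length(lmm_rows) + 1L]] <- lt }
  }
  cors <- distance_correlation_regression(records, metrics = metrics)
  list(kruskal_wallis = do.call(rbind, kw_rows),
       dunn = do.call(rbind, dunn_rows),
       lmm = do.call(rbind, lmm_rows),
       correlations = cors$correlations,
       regressions = cors$regressions)
}

#' Run the end-to-end pipeline from a configuration
#'
#' Orchestrates scenes -> distance profiles -> statistics. Scenes come either
#' from the synthetic cohort generator (config section `cohort`) or from a
#' scene table on disk (config key `scenes`: a CSV listing `stack`,
#' `animal_mask`, `background_mask`, `pixels_per_cm`, `individual_id`,
#' `species`, `defence_class`, `unpalatability`). Everything is deterministic
#' given the config and its seed; the run log records every resolved
#' parameter and the dropped-record count.
#'
#' @param config a config list or a path to a YAML/JSON config file.
#' @param out_dir output directory (created if missing).
#' @param seed overrides `config$seed` when non-NULL.
#' @return (invisibly) list with `records`, `stats` (or NULL), `run_id`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg <- if (is.character(config)) read_config(config) else config
  if (!is.null(seed)) cfg$seed <- seed
  cfg$seed <- cfg$seed %||% 1L
  obs <- observer_from_config(cfg)
  distances <- cfg$pipeline$distances_cm %||% c(2, 5, 10, 30)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run_id <- fnv1a(cfg)

  dropped <- 0L
  if (!is.null(cfg$scenes)) {
    tab <- utils::read.csv(cfg$scenes, stringsAsFactors = FALSE)
    recs <- lapply(seq_len(nrow(tab)), function(i) {
      sc <- read_scene(tab$stack[i],
                       list(animal = tab$animal_mask[i],
                            background = tab$background_mask[i]),
                       tab$pixels_per_cm[i], obs)
      distance_profile(sc$image, sc$masks, obs, distances,
                       individual_id = tab$individual_id[i],
                       species = tab$species[i],
                       defence_class = tab$defence_class[i],
                       unpalatability = tab$unpalatability[i],
                       config = cfg)
    })
    records <- do.call(rbind, recs)
    n_expected <- nrow(tab) * length(distances)
  } else {
    cs_args <- cfg$cohort %||% list()
    cs_args$obs <- obs
    cs_args$seed <- cs_args$seed %||% cfg$seed
    cspec <- do.call(cohort_spec, cs_args)
    cohort <- generate_cohort(cspec)
    records <- process_cohort(cohort, obs, distances, config = cfg)
    utils::write.csv(cohort$metadata, file.path(out_dir, "species_metadata.csv"),
                     row.names = FALSE)
    n_expected <- length(cohort$scenes) * length(distances)
  }
  dropped <- n_expected - nrow(records)
  write_records(records, file.path(out_dir, "records.csv"), run_id)

  stats_enabled <- cfg$stats$enabled %||% TRUE
  stats_out <- NULL
  if (isTRUE(stats_enabled)) {
    stats_out <- run_stats(records,
                           df_method = cfg$stats$df_method %||% "satterthwaite")
    for (nm in names(stats_out)) {
      tb <- stats_out[[nm]]
      if (is.null(tb)) next
      tb$run_id <- run_id
      utils::write.csv(tb, file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  log <- list(run_id = run_id, seed = cfg$seed, distances_cm = distances,
              observer = obs[c("weber_fractions", "luminance_weber",
                               "acuity_cpd")],
              n_records = nrow(records), n_dropped = dropped,
              stats = stats_enabled, config = cfg)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(records = records, stats = stats_out, run_id = run_id,
                 out_dir = out_dir))
}
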