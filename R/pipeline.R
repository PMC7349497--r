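#' Process a scan to per-item volumes
#'
#' The full scan pipeline: read (or take) a mesh, weld it, optionally
#' segment and discard the support plate, split the remainder into items at
#' the given seed points, close every item's holes, and compute watertight
#' volumes. Stages are logged to `message()`.
#'
#' @param scan a [triangle_mesh] or a path to an OBJ file.
#' @param seeds optional matrix of one x,y,z seed point per item; `NULL`
#'   treats each connected component (or the whole mesh) as one item.
#' @param plate if `TRUE`, detect and remove the support plate first.
#' @param fill_cfg a [fill_config()].
#' @param plate_cfg a [plate_config()].
#' @param out_dir optional directory; per-item filled OBJ meshes and a
#'   `volumes.csv` report are written there.
#' @return A data.frame with one row per item: `item`, `label`,
#'   `volume_cm3`, `n_faces`, `orientation_corrected`.
#' @export
process_scan <- function(scan, seeds = NULL, plate = FALSE,
                         fill_cfg = fill_config(),
                         plate_cfg = plate_config(), out_dir = NULL) {
  mesh <- if (is.character(scan)) read_obj(scan) else scan
  mesh <- clean_mesh(mesh)
  message("scan: ", nrow(mesh$vertices), " vertices, ",
          nrow(mesh$faces), " faces after welding")

  items <- list(mesh)
  if (plate) {
    seg <- segment_plate(mesh, plate_cfg)
    message("plate: ", nrow(seg$plate$faces), " faces removed, ",
            length(seg$items), " food component(s) remain")
    items <- seg$items
    if (length(items) == 0L) stop("segmentation left no food faces")
  }
  if (!is.null(seeds)) {
    seeds <- as.matrix(seeds)
    # route each seed to the nearest mesh, then split meshes with >1 seed
    d <- vapply(items, function(m) {
      apply(seeds, 1, function(s) min(rowSums(sweep(m$vertices, 2, s)^2)))
    }, numeric(nrow(seeds)))
    owner <- apply(matrix(d, nrow = nrow(seeds)), 1, which.min)
    items <- do.call(c, lapply(seq_along(items), function(k) {
      sk <- seeds[owner == k, , drop = FALSE]
      if (nrow(sk) <= 1L) list(items[[k]]) else split_items(items[[k]], sk)
    }))
    message("split: ", length(items), " item(s) from ", nrow(seeds),
            " seed(s)")
  }

  rows <- lapply(seq_along(items), function(i) {
    it <- clean_mesh(items[[i]])
    filled <- fill_all_holes(it, fill_cfg)
    vr <- signed_volume(filled)
    message(sprintf("item %d (%s): %d hole(s) filled, volume %.2f cm^3",
                    i, it$label %||% "unlabeled",
                    length(find_holes(it)), vr$volume))
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_obj(filled, file.path(out_dir, sprintf("item_%02d.obj", i)))
    }
    data.frame(item = i, label = it$label %||% paste0("item_", i),
               volume_cm3 = vr$volume, n_faces = nrow(filled$faces),
               orientation_corrected = vr$orientation_corrected)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    utils::write.csv(out, file.path(out_dir, "volumes.csv"),
                     row.names = FALSE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Nutrition report from item volumes
#'
#' @param volumes data.frame with `volume_cm3` and `food_id` columns (e.g.
#'   [process_scan()] output joined with food assignments).
#' @param db_path path to a density/nutrient CSV ([load_density_db()]).
#' @param kitchen_path path to a kitchen record CSV
#'   ([read_kitchen_record()]).
#' @param out_dir optional directory for `meal_account.csv`.
#' @return A `meal_account`.
#' @export
nutrition_report <- function(volumes, db_path, kitchen_path,
                             out_dir = NULL) {
  db <- load_density_db(db_path)
  kitchen <- read_kitchen_record(kitchen_path)
  acc <- meal_report(volumes, db, kitchen)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    df <- data.frame(component = names(acc$RN), served = acc$RN,
                     leftover = acc$CN, consumed = acc$CoN,
                     leftover_exceeds_served = acc$leftover_exceeds_served)
    utils::write.csv(df, file.path(out_dir, "meal_account.csv"),
                     row.names = FALSE)
  }
  acc
}

#' Write a synthetic scan scenario to disk
#'
#' Ground-truth and degraded meshes as OBJ plus a JSON sidecar with the true
#' volume and hole descriptors.
#'
#' @param scenario a `scan_scenario` from [simulate_scan()].
#' @param out_dir output directory.
#' @param name file stem.
#' @return Invisibly, the sidecar path.
#' @export
write_scenario <- function(scenario, out_dir, name = "scenario") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_obj(scenario$ground_truth,
            file.path(out_dir, paste0(name, "_truth.obj")))
  write_obj(scenario$degraded,
            file.path(out_dir, paste0(name, "_scan.obj")))
  sidecar <- file.path(out_dir, paste0(name, ".json"))
  jsonlite::write_json(
    list(true_volume_cm3 = scenario$true_volume, noise_cm = scenario$noise,
         seed = scenario$seed, holes = scenario$holes),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}
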