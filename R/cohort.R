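#' Build a synthetic paired GT/TR cohort
#'
#' Generates one ground-truth (GT) map per subject and a comparison (TR)
#' arm that is either a degraded copy of the GT network (emulating
#' translation artifacts) or an independent draw from the same network
#' spec (a null cohort for calibration studies). Group sizes may be
#' unbalanced; each subject's RNG seed is derived from the master seed by
#' stable hashing of the subject id, so cohorts reproduce exactly.
#'
#' @param groups Named list; each element describes one group as a list
#'   with `n` (subjects, >= 1) and optional `network` / `degrade` lists of
#'   overrides passed to [vascular_network_spec()] and
#'   [degradation_spec()].
#' @param master_seed Integer master seed.
#' @param out_dir Directory for PNG images and the manifest; `NULL` keeps
#'   maps in memory as a `map` list-column instead of writing files.
#' @param tr_mode `"degrade"` (TR = degraded GT network) or
#'   `"independent"` (TR = fresh network, same spec, different seed).
#' @param network,degrade Baseline override lists applied to every group.
#' @return A manifest tibble with one row per (subject, arm): columns
#'   `subject_id`, `group`, `fov`, `arm`, `seed`, and `path` (or `map`).
#'   When `out_dir` is given the manifest is also written as
#'   `manifest.csv` and `manifest.json`.
#' @export
make_cohort <- function(groups, master_seed = 1L, out_dir = NULL,
                        tr_mode = c("degrade", "independent"),
                        network = list(), degrade = list()) {
  tr_mode <- match.arg(tr_mode)
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == "")) {
    abort("`groups` must be a named list of group descriptions")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    img_dir <- file.path(out_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
  }
  rows <- purrr::imap(groups, function(gspec, gname) {
    n <- gspec$n
    if (is.null(n) || n < 1) {
      abort(sprintf("group `%s`: field `n` must be >= 1", gname))
    }
    net_over <- utils::modifyList(network, gspec$network %||% list())
    deg_over <- utils::modifyList(degrade, gspec$degrade %||% list())
    purrr::map(seq_len(n), function(i) {
      sid <- sprintf("%s_%03d", gname, i)
      sseed <- stable_seed(master_seed, sid)
      nspec <- do.call(vascular_network_spec,
                       utils::modifyList(net_over, list(rng_seed = sseed)))
      net <- generate_network(nspec)
      tr_map <- if (tr_mode == "independent") {
        nspec2 <- do.call(vascular_network_spec,
                          utils::modifyList(net_over,
                                            list(rng_seed = stable_seed(sseed, "TR"))))
        generate_network(nspec2)$map
      } else {
        dspec <- do.call(degradation_spec,
                         utils::modifyList(deg_over,
                                           list(rng_seed = stable_seed(sseed, "D"))))
        octamorph::degrade(net, dspec)
      }
      base <- tibble::tibble(subject_id = sid, group = gname,
                             fov = nspec$fov_label, arm = c("GT", "TR"),
                             seed = sseed)
      if (is.null(out_dir)) {
        base$map <- list(net$map, tr_map)
      } else {
        paths <- file.path(img_dir, sprintf("%s_%s.png", sid, c("GT", "TR")))
        write_map(net$map, paths[1L])
        write_map(tr_map, paths[2L])
        base$path <- paths
      }
      base
    })
  })
  manifest <- dplyr::bind_rows(purrr::flatten(rows))
  if (!is.null(out_dir)) {
    write_manifest(manifest, out_dir)
  }
  manifest
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a grayscale map to an 8-bit PNG file
#'
#' @param map Numeric matrix in `[0, 1]`.
#' @param path Output path (`.png`).
#' @export
write_map <- function(map, path) {
  png::writePNG(clamp01(map), target = path)
  invisible(path)
}

#' Read a grayscale projection map
#'
#' Reads a PNG (or single-plane grayscale TIFF via the same interface)
#' into a numeric matrix in `[0, 1]`; color images are averaged to
#' grayscale.
#'
#' @param path Image path.
#' @return Numeric matrix.
#' @export
read_map <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("image file does not exist: %s", path))
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    img <- apply(img[, , seq_len(min(3L, dim(img)[3L])), drop = FALSE],
                 c(1L, 2L), mean)
  }
  img
}

write_manifest <- function(manifest, out_dir) {
  m <- dplyr::select(manifest, "subject_id", "group", "fov", "arm",
                     "path", "seed")
  readr::write_csv(m, file.path(out_dir, "manifest.csv"))
  jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = FALSE, digits = NA)
  invisible(manifest)
}

#' Read and validate a cohort manifest
#'
#' Accepts the CSV or JSON form written by [make_cohort()]. Validation
#' collects all violations (missing columns, unknown `fov`/`arm` levels,
#' duplicate `(subject_id, arm)` keys, nonexistent image paths) into one
#' error; subjects lacking a TR row are kept but flagged with a warning.
#'
#' @param path Manifest file (`.csv` or `.json`).
#' @return A validated manifest tibble.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("manifest not found: %s", path))
  m <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE, comment = "#")
  }
  required <- c("subject_id", "group", "fov", "arm", "path", "seed")
  problems <- character()
  missing <- setdiff(required, names(m))
  if (length(missing)) {
    problems <- c(problems, sprintf("missing columns: %s",
                                    paste(missing, collapse = ", ")))
  }
  if (!length(missing)) {
    if (!all(m$fov %in% c("3mm", "6mm"))) {
      problems <- c(problems, "fov values must be '3mm' or '6mm'")
    }
    if (!all(m$arm %in% c("GT", "TR"))) {
      problems <- c(problems, "arm values must be 'GT' or 'TR'")
    }
    dup <- duplicated(m[, c("subject_id", "arm")])
    if (any(dup)) {
      problems <- c(problems, sprintf("duplicate (subject_id, arm) keys: %s",
                                      paste(unique(m$subject_id[dup]), collapse = ", ")))
    }
    gone <- !file.exists(m$path)
    if (any(gone)) {
      problems <- c(problems, sprintf("nonexistent image paths: %s",
                                      paste(m$path[gone], collapse = ", ")))
    }
    no_gt <- setdiff(unique(m$subject_id), m$subject_id[m$arm == "GT"])
    if (length(no_gt)) {
      problems <- c(problems, sprintf("subjects without a GT row: %s",
                                      paste(no_gt, collapse = ", ")))
    }
  }
  if (length(problems)) {
    abort(paste0("invalid manifest:\n", paste("-", problems, collapse = "\n")))
  }
  no_tr <- setdiff(unique(m$subject_id), m$subject_id[m$arm == "TR"])
  if (length(no_tr)) {
    warn(sprintf("subjects without a TR row: %s", paste(no_tr, collapse = ", ")))
  }
  m$seed <- as.integer(m$seed)
  m
}

# fetch the pixel matrix for one manifest row (in-memory or from disk)
manifest_map <- function(manifest, i) {
  if ("map" %in% names(manifest)) {
    manifest$map[[i]]
  } else {
    read_map(manifest$path[i])
  }
}
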